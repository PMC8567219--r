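#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: simulation settings,
#' classification rules, motif settings, M-Track settings, stage toggles and
#' the master seed. All thresholds default to the analysis defaults
#' (twofold regulation cutoff, 0.70 isoform probability, motif min_seq 20
#' and p-cutoff 0.01, dependency bound 1 log2 unit).
#'
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed; all stage seeds derive from it.
#' @param sim a [sim_config()]; `NULL` uses the demo configuration of
#'   [demo_sim_config()] with this seed.
#' @param rules a [class_rules()] object.
#' @param min_isoform_prob localization filter threshold.
#' @param motif list: `min_seq`, `p_cutoff`.
#' @param mtrack list: `n_baits`, `n_replicates`, `curve_degree`,
#'   `effect_map`, `noise_sd`, `loading_sd`.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "normalize", "sites", "integrate", "motifs", "mtrack")`.
#' @param sr_col,cdc55_col,igo_col setup labels used for set assignment.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL, rules = class_rules(),
                            min_isoform_prob = 0.70,
                            motif = list(min_seq = 20, p_cutoff = 0.01),
                            mtrack = list(n_baits = 8, n_replicates = 4,
                                          curve_degree = 2,
                                          effect_map = c(B01 = 2, B02 = 2, B03 = 2),
                                          noise_sd = 0.25, loading_sd = 0.5),
                            stages = c("simulate", "normalize", "sites",
                                       "integrate", "motifs", "mtrack"),
                            sr_col = "SR", cdc55_col = "cdc55",
                            igo_col = "SR_igo1igo2") {
  if (is.null(sim)) sim <- demo_sim_config(seed)
  structure(list(out_dir = out_dir, seed = seed, sim = sim, rules = rules,
                 min_isoform_prob = min_isoform_prob, motif = motif,
                 mtrack = mtrack, stages = stages, sr_col = sr_col,
                 cdc55_col = cdc55_col, igo_col = igo_col),
            class = "pipeline_config")
}

#' Demo simulation configuration
#'
#' Three setups mirroring a stress-response study design: a stress-response
#' setup (`SR`), a phosphatase-subunit deletion setup (`cdc55`) and the
#' stress response in an endosulfine-deletion background (`SR_igo1igo2`).
#' Planted site classes: static sites, phosphatase-dependent stress-induced
#' sites that lose induction without the endosulfines (strongly, Set1-like,
#' or moderately, Set2-like), kinase-driven stress-induced sites unaffected
#' by the endosulfines, and stress-decreased sites.
#'
#' @param seed integer seed.
#' @return a [sim_config()] object.
#' @export
demo_sim_config <- function(seed = 1) {
  setups <- c("SR", "cdc55", "SR_igo1igo2")
  eff <- function(sr, cdc, igo) c(SR = sr, cdc55 = cdc, SR_igo1igo2 = igo)
  classes <- tibble::tibble(
    class = c("static", "set1", "set2", "kinase_driven", "decreased"),
    prob = c(0.50, 0.12, 0.15, 0.13, 0.10),
    effects = list(eff(0, 0, 0), eff(2.0, 1.9, -1.6), eff(1.8, 1.6, -0.5),
                   eff(2.0, 0, 1.8), eff(-1.8, 0, 0))
  )
  sim_config(n_proteins = 30, protein_length_range = c(150, 400),
             n_evidence = 6000, frac_phospho = 0.5, setups = setups,
             n_replicates = 3, mixing_offset_m = 0.4, proline_factor_c = -0.25,
             noise_sd = 0.15, n_sites = 60, class_table = classes,
             localization_below_frac = 0.1,
             label_swap = c(FALSE, TRUE, FALSE), seed = seed)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order -- simulate, normalize, sites,
#' integrate, motifs, and the independent mtrack branch -- writing each
#' stage's tables under `config$out_dir` and returning a run report with
#' per-stage record counts, dropped-row counts and the fitted normalization
#' factors. Re-running with the same configuration and seed reproduces all
#' outputs byte-identically.
#'
#' @param config a [pipeline_config()] object.
#' @return run report (named list), invisibly; the written files are the
#'   primary output.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  report <- list(seed = config$seed, stages = config$stages)
  stage <- function(name) name %in% config$stages

  if (stage("simulate")) {
    sim <- simulate_evidence(config$sim)
    write_fasta(sim$proteome, path("proteome.fasta"))
    write_evidence(sim$evidence, path("evidence.tsv"))
    readr::write_tsv(sim$swap_map, path("swap_map.tsv"), progress = FALSE)
    if (!is.null(sim$ground_truth$site_effects)) {
      readr::write_tsv(sim$ground_truth$site_effects, path("ground_truth_effects.tsv"),
                       progress = FALSE)
      writeLines(c(paste0("true_m\t", sim$ground_truth$true_m),
                   paste0("true_c\t", sim$ground_truth$true_c)),
                 path("ground_truth_factors.tsv"))
    }
    report$n_evidence_written <- nrow(sim$evidence)
  }

  if (stage("normalize")) {
    ev <- read_evidence(path("evidence.tsv"), dialect = "simple")
    swap_map <- readr::read_tsv(path("swap_map.tsv"), show_col_types = FALSE,
                                progress = FALSE)
    report$n_dropped_ratio <- attr(ev, "n_dropped_ratio")
    ev <- orient_log2(ev, swap_map)
    model <- fit_normalization(ev)
    ev <- apply_normalization(ev, model)
    readr::write_tsv(model, path("normalization_factors.tsv"), progress = FALSE)
    readr::write_tsv(ev, path("corrected.tsv"), progress = FALSE)
    report$normalization <- model
  }

  if (stage("sites")) {
    ev <- readr::read_tsv(path("corrected.tsv"), show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(phospho_positions = readr::col_character(),
                                                  phospho_probs = readr::col_character(),
                                                  other_mods = readr::col_character(),
                                                  .default = readr::col_guess()))
    ev$phospho_positions[is.na(ev$phospho_positions)] <- ""
    ev$phospho_probs[is.na(ev$phospho_probs)] <- ""
    proteome <- read_fasta(path("proteome.fasta"))
    ev <- filter_localization(ev, config$min_isoform_prob)
    report$n_localization_filtered <- attr(ev, "n_filtered")
    for (s in unique(ev$setup_id)) {
      sub <- ev[ev$setup_id == s, , drop = FALSE]
      sites <- assemble_sites(sub, proteome)
      write_site_table(sites, path(paste0("sites_", s, ".tsv")))
      islands <- attach_ucg(build_phosphoislands(sub), sub)
      readr::write_tsv(islands[, setdiff(names(islands), "member_sites")],
                       path(paste0("islands_", s, ".tsv")), progress = FALSE)
    }
    report$setups <- sort(unique(ev$setup_id))
  }

  if (stage("integrate")) {
    setups <- report$setups %||% config$sim$setups
    tables <- lapply(setups, function(s) read_site_table(path(paste0("sites_", s, ".tsv"))))
    names(tables) <- setups
    mat <- merge_setups(tables)
    cls <- tibble::tibble(
      protein_id = mat$protein_id, positions = mat$positions,
      regulation = classify_regulation(mat[[config$sr_col]], config$rules),
      set_label = assign_sets(mat, config$rules, config$sr_col,
                              config$cdc55_col, config$igo_col)
    )
    readr::write_tsv(mat, path("matrix.tsv"), progress = FALSE)
    readr::write_tsv(cls, path("classification.tsv"), progress = FALSE)
    readr::write_tsv(summarize_fractions(mat, config$rules), path("summary.tsv"),
                     progress = FALSE)
    report$n_sites_matrix <- nrow(mat)
  }

  if (stage("motifs")) {
    mat <- readr::read_tsv(path("matrix.tsv"), show_col_types = FALSE, progress = FALSE)
    proteome <- read_fasta(path("proteome.fasta"))
    quantified <- !is.na(mat[[config$sr_col]]) & !is.na(mat[[config$igo_col]])
    fg_rows <- quantified & mat[[config$sr_col]] >= config$rules$up_log2 &
      mat[[config$igo_col]] <= config$rules$down_log2
    bg <- extract_windows(mat[quantified, , drop = FALSE], proteome)
    motifs <- list()
    if (any(fg_rows)) {
      fg <- extract_windows(mat[fg_rows, , drop = FALSE], proteome)
      for (ctr in intersect(c("S", "T"), unique(fg$central))) {
        f <- fg$window[fg$central == ctr]
        b <- bg$window[bg$central == ctr]
        if (length(f) > 0 && length(b) >= length(f)) {
          m <- motifx(f, b, central = ctr, min_seq = config$motif$min_seq,
                      p_cutoff = config$motif$p_cutoff)
          if (nrow(m) > 0) { m$central <- ctr; motifs[[ctr]] <- m }
        }
      }
    }
    out <- if (length(motifs)) dplyr::bind_rows(motifs) else
      tibble::tibble(motif = character(0), fg_matches = integer(0),
                     bg_matches = integer(0), fg_size = integer(0),
                     bg_size = integer(0), score = numeric(0),
                     fold_enrichment = numeric(0), central = character(0))
    readr::write_tsv(out, path("motifs.tsv"), progress = FALSE)
    report$n_motifs <- nrow(out)
  }

  if (stage("mtrack")) {
    mk <- config$mtrack
    dens <- simulate_densitometry(mk$n_baits, mk$n_replicates,
                                  curve_degree = mk$curve_degree,
                                  effect_map = mk$effect_map,
                                  seed = config$seed + 1000L,
                                  noise_sd = mk$noise_sd,
                                  loading_sd = mk$loading_sd)
    write_densitometry(dens, path("densitometry.tsv"))
    prox <- rescale_to_control(correct_and_score(dens))
    res <- test_baits(prox)
    readr::write_tsv(prox, path("proximity.tsv"), progress = FALSE)
    readr::write_tsv(res, path("mtrack_results.tsv"), progress = FALSE)
    report$n_baits_tested <- nrow(res)
  }

  log_lines <- utils::capture.output(utils::str(report, max.level = 2))
  writeLines(log_lines, path("run_log.txt"))
  invisible(report)
}

#' Run the demonstration pipeline
#'
#' Full end-to-end run on the demo configuration: three-setup evidence
#' simulation, normalization, site assembly, integration and classification,
#' motif extraction, and the M-Track branch.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return the run report, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1) {
  run_pipeline(pipeline_config(out_dir, seed = seed))
}
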