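#' Simulation configuration for evidence-table generation
#'
#' Bundles every knob of the evidence simulator. The defaults describe a
#' small SILAC phosphoproteomics experiment: a modest random proteome,
#' lognormal ratio noise on the log2 scale, a mixing offset between heavy and
#' light cultures, a per-proline conversion shift, and per-site condition
#' effects planted from `site_effect_table`.
#'
#' @param n_proteins,protein_length_range,seed passed to [generate_proteome()].
#' @param n_evidence total number of evidence rows to simulate (>= 1).
#' @param frac_phospho fraction of rows carrying at least one phosphosite.
#' @param setups character vector of setup (experiment) labels.
#' @param n_replicates replicates per setup; rows are assigned uniformly.
#' @param mixing_offset_m planted heavy/light mixing offset, log2 units.
#' @param proline_factor_c planted conversion shift per proline, log2 units
#'   (negative values model heavy-arginine-to-proline signal loss).
#' @param noise_sd SD of the Normal log2 ratio noise (>= 0).
#' @param site_effect_table tibble `(protein_id, positions, setup, effect)`
#'   with semicolon-joined 1-based positions; `NULL` lets the simulator plant
#'   `n_sites` sites itself using `class_table`.
#' @param n_sites number of phosphosites to plant when no table is given.
#' @param class_table tibble `(class, prob, effects)` where `effects` is a
#'   list column of named per-setup log2 effects; `NULL` uses a default mix
#'   of static, induced and decreased sites.
#' @param localization_below_frac fraction of phospho rows whose isoform
#'   localization probability is drawn below 0.70 (to exercise the filter).
#' @param localization_alpha Beta shape controlling how tightly confident
#'   probabilities concentrate near 1.
#' @param label_swap logical, recycled over replicates: `TRUE` marks a
#'   replicate with inverted SILAC labels (the written ratio is negated; the
#'   returned swap map tells the orientation step to undo it).
#' @param oxidation_frac fraction of rows flagged with a methionine-oxidation
#'   style secondary modification (merged away during site assembly).
#' @param max_missed maximum missed cleavages in the peptide pool.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 20,
                       protein_length_range = c(150, 400),
                       n_evidence = 2000,
                       frac_phospho = 0.5,
                       setups = "SR",
                       n_replicates = 3,
                       mixing_offset_m = 0,
                       proline_factor_c = 0,
                       noise_sd = 0.3,
                       site_effect_table = NULL,
                       n_sites = 40,
                       class_table = NULL,
                       localization_below_frac = 0.1,
                       localization_alpha = 9,
                       label_swap = FALSE,
                       oxidation_frac = 0.1,
                       max_missed = 2,
                       seed = 1) {
  assert_that(is_count(n_evidence) && n_evidence >= 1, "n_evidence must be >= 1")
  assert_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(frac_phospho >= 0 && frac_phospho <= 1, "frac_phospho must be in [0,1]")
  assert_that(is_count(n_replicates) && n_replicates >= 1, "n_replicates must be >= 1")
  structure(as.list(environment()), class = "sim_config")
}

default_class_table <- function(setups) {
  zero <- stats::setNames(rep(0, length(setups)), setups)
  eff <- function(x) stats::setNames(rep(x, length(setups)), setups)
  tibble::tibble(
    class = c("static", "induced", "decreased"),
    prob = c(0.65, 0.25, 0.10),
    effects = list(zero, eff(1.8), eff(-1.8))
  )
}

#' Plant phosphosite effects on a proteome
#'
#' Samples `n_sites` distinct (protein, position-set) phosphosites whose
#' positions are S/T residues covered by a tryptic peptide, and assigns each
#' a class from `class_table` with the class's per-setup log2 effects.
#'
#' @inheritParams sim_config
#' @param proteome named character vector of sequences.
#' @param setups setup labels the effect table must cover.
#' @return tibble `(protein_id, positions, residues, class, setup, effect)`.
#' @export
make_site_effects <- function(proteome, n_sites, setups, class_table = NULL,
                              max_missed = 2, seed = 1) {
  if (is.null(class_table)) class_table <- default_class_table(setups)
  pool <- peptide_pool(proteome, max_missed = max_missed)
  pool0 <- pool[pool$n_missed == 0, , drop = FALSE]
  withr::with_seed(seed, {
    sites <- list()
    seen <- character(0)
    guard <- 0
    while (length(sites) < n_sites && guard < 50 * n_sites) {
      guard <- guard + 1
      i <- sample(nrow(pool0), 1)
      row <- pool0[i, ]
      chars <- strsplit(row$peptide, "")[[1]]
      st <- which(chars %in% c("S", "T")) + row$start - 1L
      if (length(st) == 0) next
      k <- sample.int(min(2, length(st)), 1)
      pos <- sort(st[sample.int(length(st), k)])
      id <- site_id(row$protein_id, paste(pos, collapse = ";"))
      if (id %in% seen) next
      seen <- c(seen, id)
      res <- substring(proteome[[row$protein_id]], pos, pos)
      sites[[length(sites) + 1L]] <- tibble::tibble(
        protein_id = row$protein_id,
        positions = paste(pos, collapse = ";"),
        residues = paste(res, collapse = ";")
      )
    }
    assert_that(length(sites) == n_sites,
                "could not plant the requested number of phosphosites; enlarge the proteome")
    site_tbl <- dplyr::bind_rows(sites)
    cls <- sample(class_table$class, n_sites, replace = TRUE, prob = class_table$prob)
  })
  site_tbl$class <- cls
  eff <- stats::setNames(class_table$effects, class_table$class)
  long <- tidyr::crossing(site_tbl, setup = setups)
  long$effect <- mapply(function(cl, s) eff[[cl]][[s]], long$class, long$setup)
  long
}

# Flat pool of tryptic peptides over a proteome.
peptide_pool <- function(proteome, max_missed = 2) {
  dplyr::bind_rows(lapply(names(proteome), function(p) {
    d <- digest_tryptic(proteome[[p]], max_missed = max_missed)
    d$protein_id <- p
    d
  }))
}

#' Simulate an evidence table with planted ground truth
#'
#' Generates one peptide-quantification row per evidence event. Each raw
#' log2 ratio is built as
#' `m + n_prolines * c + site_effect + Normal(0, noise_sd)`,
#' where `m` is the mixing offset, `c` the per-proline conversion shift and
#' `site_effect` the planted condition effect (0 for unphosphorylated rows).
#' Replicates flagged in `label_swap` have the written ratio negated, which
#' the orientation step must undo via the returned swap map. Localization
#' probabilities are drawn so that roughly `localization_below_frac` of the
#' phospho rows fall below the 0.70 isoform-probability threshold.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `evidence` (tibble), `proteome` (named
#'   character), `swap_map` (tibble `replicate_id`, `swap`) and
#'   `ground_truth` (list: `true_m`, `true_c`, `site_effects`, `set_labels`).
#' @export
simulate_evidence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  proteome <- generate_proteome(config$n_proteins, config$protein_length_range,
                                seed = config$seed)
  n_phos <- round(config$n_evidence * config$frac_phospho)
  n_unphos <- config$n_evidence - n_phos
  effects <- config$site_effect_table
  if (is.null(effects) && n_phos > 0) {
    effects <- make_site_effects(proteome, config$n_sites, config$setups,
                                 class_table = config$class_table,
                                 max_missed = config$max_missed,
                                 seed = config$seed + 1L)
  }
  if (n_phos > 0 && (is.null(effects) || nrow(effects) == 0)) {
    rlang::abort("phospho evidence requested but site_effect_table is empty")
  }
  pool <- peptide_pool(proteome, max_missed = config$max_missed)
  pool$n_prolines <- count_prolines(pool$peptide)
  replicates <- sprintf("rep%d", seq_len(config$n_replicates))
  swap <- rep_len(as.logical(config$label_swap), config$n_replicates)
  swap_map <- tibble::tibble(replicate_id = replicates, swap = swap)

  withr::with_seed(config$seed + 2L, {
    rows <- list()
    if (n_phos > 0) {
      sites <- dplyr::distinct(effects, .data$protein_id, .data$positions)
      # peptides (incl. missed-cleavage variants) covering each planted site
      cover <- lapply(seq_len(nrow(sites)), function(i) {
        pos <- split_ints(sites$positions[i])[[1]]
        cand <- pool[pool$protein_id == sites$protein_id[i] &
                       pool$start <= min(pos) & pool$end >= max(pos), , drop = FALSE]
        assert_that(nrow(cand) >= 1, "planted site not covered by any tryptic peptide")
        cand
      })
      pick_site <- sample(nrow(sites), n_phos, replace = TRUE)
      pep_idx <- vapply(pick_site, function(i) sample(nrow(cover[[i]]), 1), integer(1))
      pep <- dplyr::bind_rows(lapply(seq_len(n_phos), function(j) cover[[pick_site[j]]][pep_idx[j], ]))
      ph <- tibble::tibble(
        protein_id = pep$protein_id,
        peptide_start = pep$start,
        peptide_end = pep$end,
        bare_sequence = pep$peptide,
        positions = sites$positions[pick_site],
        n_prolines = pep$n_prolines
      )
      ph$n_phospho <- lengths(split_ints(ph$positions))
      rows$phospho <- ph
    }
    if (n_unphos > 0) {
      i <- sample(nrow(pool), n_unphos, replace = TRUE)
      rows$unphos <- tibble::tibble(
        protein_id = pool$protein_id[i],
        peptide_start = pool$start[i],
        peptide_end = pool$end[i],
        bare_sequence = pool$peptide[i],
        positions = "",
        n_prolines = pool$n_prolines[i],
        n_phospho = 0L
      )
    }
    ev <- dplyr::bind_rows(rows)
    n <- nrow(ev)
    ev$replicate_id <- sample(replicates, n, replace = TRUE)
    ev$setup_id <- sample(config$setups, n, replace = TRUE)

    eff <- rep(0, n)
    if (n_phos > 0) {
      key <- paste(ev$protein_id, ev$positions, ev$setup_id)
      ekey <- paste(effects$protein_id, effects$positions, effects$setup)
      hit <- match(key, ekey)
      eff[!is.na(hit)] <- effects$effect[hit[!is.na(hit)]]
    }
    raw <- config$mixing_offset_m + ev$n_prolines * config$proline_factor_c + eff
    if (config$noise_sd > 0) raw <- raw + rnorm(n, 0, config$noise_sd)
    written <- ifelse(swap[match(ev$replicate_id, replicates)], -raw, raw)
    ev$ratio_hl <- 2^written

    # localization probabilities: product over assigned sites = drawn isoform p
    ev$phospho_probs <- ""
    is_ph <- ev$n_phospho > 0
    if (any(is_ph)) {
      m <- sum(is_ph)
      low <- runif(m) < config$localization_below_frac
      p_top <- ifelse(low,
                      runif(m, 0.30, 0.695),
                      1 - 0.3 * rbeta(m, 1, config$localization_alpha))
      k <- ev$n_phospho[is_ph]
      ev$phospho_probs[is_ph] <- join_nums(mapply(function(p, kk) rep(p^(1 / kk), kk),
                                                  p_top, k, SIMPLIFY = FALSE))
    }
    ev$other_mods <- ifelse(runif(n) < config$oxidation_frac &
                              grepl("M", ev$bare_sequence, fixed = TRUE),
                            "oxidation", "")
  })
  ev <- dplyr::rename(ev, phospho_positions = "positions")
  ev$proline_count <- ev$n_prolines
  ev$n_prolines <- NULL
  gt <- list(
    true_m = config$mixing_offset_m,
    true_c = config$proline_factor_c,
    site_effects = effects,
    set_labels = if (!is.null(effects)) truth_set_labels(effects) else NULL
  )
  list(evidence = ev, proteome = proteome, swap_map = swap_map, ground_truth = gt)
}

#' Ground-truth regulation / set labels from planted effects
#'
#' Applies the same thresholds used downstream (twofold regulation cutoff;
#' Set1 = stress- and cdc55-induced with strong negative response to
#' IGO1/IGO2 loss, log2 <= -1; Set2 = same universe with moderate negative
#' response, -1 < log2 < 0) to the planted effect table, so classification
#' recovery can be checked exactly.
#'
#' @param effects long effect table from [make_site_effects()].
#' @param rules a [class_rules()] list.
#' @param sr_col,cdc55_col,igo_col setup labels playing the stress-response,
#'   cdc55-deletion and igo1/igo2-deletion roles; ignored when absent.
#' @return tibble `(protein_id, positions, label)` with labels in
#'   `{Set1, Set2, induced, decreased, static}`.
#' @export
truth_set_labels <- function(effects, rules = class_rules(),
                             sr_col = "SR", cdc55_col = "cdc55",
                             igo_col = "SR_igo1igo2") {
  wide <- tidyr::pivot_wider(
    dplyr::distinct(effects, .data$protein_id, .data$positions, .data$setup, .data$effect),
    names_from = "setup", values_from = "effect"
  )
  setups <- setdiff(names(wide), c("protein_id", "positions"))
  primary <- if (sr_col %in% setups) sr_col else setups[1]
  lab <- classify_regulation(wide[[primary]], rules)
  if (all(c(sr_col, cdc55_col, igo_col) %in% setups)) {
    universe <- wide[[sr_col]] >= rules$up_log2 & wide[[cdc55_col]] >= rules$up_log2
    igo <- wide[[igo_col]]
    lab[universe & igo <= -rules$dependency_log2] <- "Set1"
    lab[universe & igo > -rules$dependency_log2 & igo < 0] <- "Set2"
  }
  tibble::tibble(protein_id = wide$protein_id, positions = wide$positions, label = lab)
}
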