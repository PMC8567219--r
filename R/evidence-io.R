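# Reading and writing the tabular formats the pipeline touches.
#
# The primary on-disk format is the "simple" evidence dialect: tab-delimited
# UTF-8 with header, one row per peptide quantification event, and
# semicolon-joined multi-value fields. A "maxquant-like" dialect maps the
# familiar evidence-table columns onto it.

simple_cols <- c("protein_id", "peptide_start", "bare_sequence",
                 "phospho_positions", "phospho_probs", "other_mods",
                 "ratio_hl", "replicate_id", "setup_id")

maxquant_cols <- c("Proteins", "Start position", "Sequence", "Modified sequence",
                   "Phospho (STY) Probabilities", "Ratio H/L", "Experiment")

#' Read an evidence-style peptide table
#'
#' Rows with a missing or non-positive ratio are dropped (and counted);
#' multi-protein (razor) entries keep the first listed protein. Phospho
#' positions are reported in 1-based protein coordinates.
#'
#' @param path tab-delimited file.
#' @param dialect `"simple"` (native schema) or `"maxquant-like"` (columns
#'   `Proteins`, `Start position`, `Sequence`, `Modified sequence`,
#'   `Phospho (STY) Probabilities`, `Ratio H/L`, `Experiment`).
#' @param drop_contaminants drop rows whose optional `contaminant` column is
#'   `"+"`/`TRUE` (off by default).
#' @return tibble of evidence records with attributes `n_dropped_ratio`,
#'   `n_razor`, `row_errors` (integer row indices that failed to parse).
#' @export
read_evidence <- function(path, dialect = c("simple", "maxquant-like"),
                          drop_contaminants = FALSE) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste("file not found:", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- if (dialect == "simple") simple_cols else maxquant_cols
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("evidence table is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (drop_contaminants && "contaminant" %in% names(raw)) {
    raw <- raw[!(raw$contaminant %in% c("+", "TRUE", "true")), , drop = FALSE]
  }
  if (dialect == "maxquant-like") {
    parsed <- parse_maxquant_rows(raw)
    ev <- parsed$records
    row_errors <- parsed$row_errors
  } else {
    ev <- tibble::tibble(
      protein_id = raw$protein_id,
      peptide_start = suppressWarnings(as.integer(raw$peptide_start)),
      bare_sequence = raw$bare_sequence,
      phospho_positions = ifelse(is.na(raw$phospho_positions), "", raw$phospho_positions),
      phospho_probs = ifelse(is.na(raw$phospho_probs), "", raw$phospho_probs),
      other_mods = ifelse(is.na(raw$other_mods), "", raw$other_mods),
      ratio_hl = suppressWarnings(as.numeric(raw$ratio_hl)),
      replicate_id = raw$replicate_id,
      setup_id = raw$setup_id
    )
    bad <- which(is.na(ev$peptide_start) | is.na(ev$bare_sequence) | is.na(ev$protein_id))
    row_errors <- bad
    if (length(bad) > 0) ev <- ev[-bad, , drop = FALSE]
  }
  n_razor <- sum(grepl(";", ev$protein_id, fixed = TRUE))
  ev$protein_id <- sub(";.*$", "", ev$protein_id)
  has_ratio <- !is.na(ev$ratio_hl) & ev$ratio_hl > 0
  n_dropped <- sum(!has_ratio)
  ev <- ev[has_ratio, , drop = FALSE]
  ev$n_phospho <- lengths(split_ints(ev$phospho_positions))
  ev$peptide_end <- ev$peptide_start + nchar(ev$bare_sequence) - 1L
  ev$proline_count <- count_prolines(ev$bare_sequence)
  check_record_invariants(ev)
  structure(ev, n_dropped_ratio = n_dropped, n_razor = n_razor,
            row_errors = row_errors)
}

# Map maxquant-like columns onto the simple schema. Localization
# probabilities are parsed from strings like "AAS(0.9)PT(0.1)K"; the number
# of phosphorylations comes from "(ph)" marks in the modified sequence and
# the assigned positions are the top-probability candidates.
parse_maxquant_rows <- function(raw) {
  n <- nrow(raw)
  recs <- vector("list", n)
  row_errors <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      start <- as.integer(raw[["Start position"]][i])
      if (is.na(start)) stop("bad start position")
      bare <- raw[["Sequence"]][i]
      modseq <- raw[["Modified sequence"]][i]
      n_ph <- lengths(regmatches(modseq, gregexpr("(ph)", modseq, fixed = TRUE)))
      prob_str <- raw[["Phospho (STY) Probabilities"]][i]
      cand <- parse_probability_string(prob_str)
      if (n_ph > 0 && nrow(cand) < n_ph) stop("fewer probability candidates than phospho marks")
      assigned <- head(cand[order(-cand$prob, cand$pos), , drop = FALSE], n_ph)
      assigned <- assigned[order(assigned$pos), , drop = FALSE]
      ox <- if (grepl("(ox)", modseq, fixed = TRUE)) "oxidation" else ""
      tibble::tibble(
        protein_id = raw[["Proteins"]][i],
        peptide_start = start,
        bare_sequence = bare,
        phospho_positions = paste(assigned$pos + start - 1L, collapse = ";"),
        phospho_probs = paste(format(assigned$prob, trim = TRUE), collapse = ";"),
        other_mods = ox,
        ratio_hl = suppressWarnings(as.numeric(raw[["Ratio H/L"]][i])),
        replicate_id = if ("Replicate" %in% names(raw)) raw[["Replicate"]][i] else "rep1",
        setup_id = raw[["Experiment"]][i]
      )
    }, error = function(e) NULL)
    if (is.null(res)) row_errors <- c(row_errors, i) else recs[[i]] <- res
  }
  list(records = dplyr::bind_rows(recs), row_errors = row_errors)
}

# "_AAS(0.9)PT(0.1)K_" -> peptide-relative candidate positions + probabilities
parse_probability_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(tibble::tibble(pos = integer(0), prob = numeric(0)))
  s <- gsub("^_|_$", "", s)
  toks <- regmatches(s, gregexpr("\\(([0-9.]+)\\)|[A-Z]", s))[[1]]
  pos <- integer(0); prob <- numeric(0); at <- 0L
  for (t in toks) {
    if (grepl("^\\(", t)) {
      p <- as.numeric(sub("^\\(([0-9.]+)\\)$", "\\1", t))
      if (is.na(p) || p < 0 || p > 1) stop("unparsable localization probability: ", t)
      pos <- c(pos, at); prob <- c(prob, p)
    } else {
      at <- at + 1L
    }
  }
  tibble::tibble(pos = pos, prob = prob)
}

check_record_invariants <- function(ev) {
  if (nrow(ev) == 0) return(invisible(ev))
  pos <- split_ints(ev$phospho_positions)
  ok <- mapply(function(p, s, e) length(p) == 0 || (min(p) >= s && max(p) <= e),
               pos, ev$peptide_start, ev$peptide_end)
  assert_that(all(ok), "phospho positions outside the peptide interval")
  pr <- unlist(split_nums(ev$phospho_probs))
  assert_that(all(pr >= 0 & pr <= 1), "localization probabilities must be in [0,1]")
  invisible(ev)
}

#' Write an evidence table in the simple dialect
#'
#' @param evidence evidence tibble (as produced by [simulate_evidence()] or
#'   [read_evidence()]).
#' @param path output path.
#' @export
write_evidence <- function(evidence, path) {
  readr::write_tsv(evidence[, simple_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a protein FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate FASTA identifier(s): ", paste(dup, collapse = ", ")))
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write a protein FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Write / read a phosphorylation-site table
#'
#' Tab-delimited, one row per site: protein, semicolon-joined 1-based
#' positions and residue letters, per-replicate log2 ratios encoded as
#' `rep=value` pairs, final log2 ratio, and evidence count. The pair
#' round-trips losslessly.
#'
#' @param sites site tibble from [assemble_sites()].
#' @param path file path.
#' @export
write_site_table <- function(sites, path) {
  out <- tibble::tibble(
    protein_id = sites$protein_id %||% character(0),
    positions = sites$positions %||% character(0),
    residues = sites$residues %||% character(0),
    per_replicate = vapply(sites$per_replicate_log2 %||% list(), function(v) {
      paste(paste0(names(v), "=", format(v, digits = 15, trim = TRUE, scientific = FALSE)),
            collapse = ";")
    }, character(1)),
    final_log2 = sites$final_log2 %||% numeric(0),
    n_evidence = sites$n_evidence %||% integer(0)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         protein_id = readr::col_character(),
                         positions = readr::col_character(),
                         residues = readr::col_character(),
                         per_replicate = readr::col_character(),
                         final_log2 = readr::col_double(),
                         n_evidence = readr::col_integer()
                       ))
  x$per_replicate_log2 <- lapply(x$per_replicate, function(s) {
    if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  })
  x$per_replicate <- NULL
  x
}
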