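#' Orient raw SILAC ratios on the log2 scale
#'
#' Log2-transforms heavy/light ratios and, for replicates with inverted
#' labeling, negates them, so that a positive value always means higher
#' abundance in the perturbed condition (knockout vs wild type, stressed vs
#' unstressed, inhibited vs not inhibited).
#'
#' @param records evidence tibble with `ratio_hl` and `replicate_id`.
#' @param swap_map tibble `(replicate_id, swap)`; replicates absent from the
#'   map are treated as not swapped. `NULL` means no swapping.
#' @return the records with a `log2_oriented` column added.
#' @export
orient_log2 <- function(records, swap_map = NULL) {
  assert_that(all(records$ratio_hl > 0), "ratio_hl must be > 0 for every record")
  swap <- rep(FALSE, nrow(records))
  if (!is.null(swap_map)) {
    i <- match(records$replicate_id, swap_map$replicate_id)
    swap[!is.na(i)] <- swap_map$swap[i[!is.na(i)]]
  }
  records$log2_oriented <- ifelse(swap, -log2(records$ratio_hl), log2(records$ratio_hl))
  records
}

#' Fit mixing and proline-conversion normalization factors
#'
#' Estimated independently per group (by default per setup and replicate)
#' from unphosphorylated peptides only. The mixing factor `m` is the mean
#' oriented log2 ratio of proline-free unphosphorylated peptides. After
#' subtracting `m`, the proline-conversion factor `c` is the mean over the
#' residuals of one-proline peptides pooled with the halved residuals of
#' two-proline peptides; peptides with three or more prolines never enter
#' the estimate. Groups without any 1- or 2-proline unphosphorylated peptide
#' get `c = 0` with a warning; groups without proline-free unphosphorylated
#' peptides are a hard error.
#'
#' @param records evidence tibble with `log2_oriented` (see [orient_log2()]).
#' @param group_vars character vector of grouping columns.
#' @return tibble, one row per group: `mixing_factor_m`, `proline_factor_c`,
#'   `n_reference_peptides`, `n_one_proline`, `n_two_proline`.
#' @export
fit_normalization <- function(records, group_vars = c("setup_id", "replicate_id")) {
  assert_that("log2_oriented" %in% names(records),
              "records must be oriented first (orient_log2)")
  un <- records[records$n_phospho == 0, , drop = FALSE]
  groups <- dplyr::distinct(records[, group_vars, drop = FALSE])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(un))
    for (v in group_vars) sel <- sel & un[[v]] == groups[[v]][g]
    grp <- un[sel, , drop = FALSE]
    ref <- grp$log2_oriented[grp$proline_count == 0]
    if (length(ref) == 0) {
      rlang::abort(paste0("cannot normalize group ", paste(groups[g, ], collapse = "/"),
                          ": no proline-free unphosphorylated peptides"))
    }
    m <- mean(ref)
    r1 <- grp$log2_oriented[grp$proline_count == 1] - m
    r2 <- grp$log2_oriented[grp$proline_count == 2] - m
    if (length(r1) + length(r2) == 0) {
      rlang::warn(paste0("group ", paste(groups[g, ], collapse = "/"),
                         ": no 1- or 2-proline unphosphorylated peptides; c set to 0"))
      cc <- 0
    } else {
      cc <- mean(c(r1, r2 / 2))
    }
    cbind(groups[g, , drop = FALSE],
          tibble::tibble(mixing_factor_m = m, proline_factor_c = cc,
                         n_reference_peptides = length(ref),
                         n_one_proline = length(r1), n_two_proline = length(r2)))
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}

#' Apply mixing and proline-conversion correction
#'
#' Corrects every record (phosphorylated and unphosphorylated) as
#' `log2_corrected = log2_oriented - m - proline_count * c`, using the
#' normalization model of the record's group.
#'
#' @param records oriented evidence tibble.
#' @param model output of [fit_normalization()].
#' @param group_vars grouping columns, matching those used for the fit.
#' @return the records with a `log2_corrected` column added.
#' @export
apply_normalization <- function(records, model, group_vars = c("setup_id", "replicate_id")) {
  key_r <- do.call(paste, records[, group_vars, drop = FALSE])
  key_m <- do.call(paste, model[, group_vars, drop = FALSE])
  i <- match(key_r, key_m)
  if (anyNA(i)) {
    rlang::abort(paste0("no normalization model for group(s): ",
                        paste(unique(key_r[is.na(i)]), collapse = ", ")))
  }
  records$log2_corrected <- records$log2_oriented - model$mixing_factor_m[i] -
    records$proline_count * model$proline_factor_c[i]
  records
}

#' Protein-level median centering
#'
#' For affinity-purification experiments where bait protein abundance
#' differs between conditions, shifts all peptides of a protein by the
#' negative median corrected log2 ratio of its unphosphorylated peptides.
#'
#' @param records corrected evidence tibble (`log2_corrected` present).
#' @param proteins proteins to center; default all proteins in `records`.
#' @return the records with `log2_corrected` re-centered per protein.
#' @export
normalize_protein_level <- function(records, proteins = unique(records$protein_id)) {
  for (p in proteins) {
    sel <- records$protein_id == p
    un <- records$log2_corrected[sel & records$n_phospho == 0]
    if (length(un) == 0) {
      rlang::abort(paste0("protein ", p, " has no unphosphorylated peptide; cannot center"))
    }
    records$log2_corrected[sel] <- records$log2_corrected[sel] - stats::median(un)
  }
  records
}
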