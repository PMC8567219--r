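#' Simulate a planted site-by-setup ratio matrix
#'
#' Builds a setup matrix with known class composition for testing the
#' fold-change classification: Set1 sites are stress- and cdc55-induced with
#' a strong negative response to IGO1/IGO2 loss, Set2 sites a moderate
#' negative response, static sites sit at 0 everywhere, and decreased sites
#' drop twofold under stress.
#'
#' @param n_set1,n_set2,n_static,n_decreased class counts.
#' @param noise_sd SD of Normal noise added to every cell (0 = exact).
#' @param seed integer seed.
#' @param sr_col,cdc55_col,igo_col setup column names.
#' @return list with `matrix` (tibble: `protein_id`, `positions`, `residues`,
#'   one column per setup) and `truth` (tibble with the planted `label`).
#' @export
simulate_setup_matrix <- function(n_set1 = 40, n_set2 = 60, n_static = 100,
                                  n_decreased = 20, noise_sd = 0, seed = 1,
                                  sr_col = "SR", cdc55_col = "cdc55",
                                  igo_col = "SR_igo1igo2") {
  labels <- rep(c("Set1", "Set2", "static", "decreased"),
                c(n_set1, n_set2, n_static, n_decreased))
  n <- length(labels)
  withr::with_seed(seed, {
    sr <- c(Set1 = 2.0, Set2 = 1.8, static = 0, decreased = -1.8)[labels]
    cdc <- c(Set1 = 1.9, Set2 = 1.6, static = 0, decreased = 0)[labels]
    igo <- c(Set1 = -1.6, Set2 = -0.5, static = 0, decreased = 0)[labels]
    mat <- tibble::tibble(
      protein_id = sprintf("P%04d", seq_len(n)),
      positions = "10",
      residues = "S",
      !!sr_col := sr + rnorm(n, 0, noise_sd),
      !!cdc55_col := cdc + rnorm(n, 0, noise_sd),
      !!igo_col := igo + rnorm(n, 0, noise_sd)
    )
  })
  truth <- tibble::tibble(protein_id = mat$protein_id, positions = mat$positions,
                          label = unname(labels))
  list(matrix = mat, truth = truth)
}

#' Simulate phosphosite sequence windows with a planted motif
#'
#' Draws random 13-residue windows centered on `central` and injects a fixed
#' residue at a fixed offset into a fraction of them, emulating a
#' proline-directed kinase motif in a foreground set.
#'
#' @param n number of windows.
#' @param central central residue, `"S"` or `"T"`.
#' @param planted_offset offset of the planted residue relative to the
#'   central position (-6..6, not 0), or `NULL` for none.
#' @param planted_residue residue planted at that offset.
#' @param rate fraction of windows carrying the planted residue.
#' @param seed integer seed.
#' @return character vector of 13-character windows.
#' @export
simulate_windows <- function(n, central = "S", planted_offset = 1,
                             planted_residue = "P", rate = 0, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    mat <- matrix(sample(aa, 13 * n, replace = TRUE), nrow = n)
    mat[, 7] <- central
    if (!is.null(planted_offset) && rate > 0) {
      hit <- runif(n) < rate
      mat[hit, 7 + planted_offset] <- planted_residue
      # keep the non-carriers free of the planted residue at that offset so
      # the realized rate matches the requested one
      miss <- !hit & mat[, 7 + planted_offset] == planted_residue
      mat[miss, 7 + planted_offset] <- sample(setdiff(aa, planted_residue),
                                              sum(miss), replace = TRUE)
    }
  })
  apply(mat, 1, paste, collapse = "")
}
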