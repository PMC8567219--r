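#' Generate a random protein collection
#'
#' Draws protein sequences uniformly over the 20 amino-acid alphabet to stand
#' in for a reference proteome FASTA. Every sequence is guaranteed to contain
#' at least two K/R residues, so tryptic digestion yields at least two
#' peptides per protein.
#'
#' @param n_proteins number of sequences (>= 1).
#' @param length_range integer vector `c(min, max)` of sequence lengths in
#'   residues; `min` must be >= 20.
#' @param seed integer seed; identical seeds give identical proteomes.
#' @return named character vector of sequences (`P0001`, `P0002`, ...).
#' @examples
#' generate_proteome(3, c(50, 80), seed = 1)
#' @export
generate_proteome <- function(n_proteins, length_range, seed) {
  assert_that(is_count(n_proteins) && n_proteins >= 1, "n_proteins must be a count >= 1")
  assert_that(length(length_range) == 2 && length_range[1] >= 20,
              "length_range minimum must be >= 20 residues")
  assert_that(length_range[2] >= length_range[1], "length_range must be (min, max)")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    cand <- seq(length_range[1], length_range[2])
    lens <- cand[sample.int(length(cand), n_proteins, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      s <- sample(aa, L, replace = TRUE)
      # guarantee >= 2 cleavage residues (keeps digestion non-degenerate)
      kr <- which(s %in% c("K", "R"))
      if (length(kr) < 2) {
        pos <- sample(seq_len(L - 1), 2 - length(kr))
        s[pos] <- sample(c("K", "R"), length(pos), replace = TRUE)
      }
      paste(s, collapse = "")
    }, character(1))
  })
  stats::setNames(seqs, sprintf("P%04d", seq_len(n_proteins)))
}

#' In-silico tryptic digestion (Trypsin/P)
#'
#' Cleaves after every K or R, including when the next residue is a proline
#' (Trypsin/P specificity), and enumerates peptides with up to `max_missed`
#' internal missed cleavage sites.
#'
#' @param sequence a single protein sequence.
#' @param max_missed maximum number of internal K/R sites left uncleaved.
#' @return tibble with columns `peptide`, `start`, `end` (1-based inclusive),
#'   `n_missed`; ordered by start position then missed-cleavage count.
#' @examples
#' digest_tryptic("AAKBBRCC", max_missed = 0)
#' @export
digest_tryptic <- function(sequence, max_missed = 2) {
  assert_that(is.character(sequence) && length(sequence) == 1 && nzchar(sequence),
              "sequence must be a non-empty string")
  assert_that(is_count(max_missed), "max_missed must be a count")
  chars <- strsplit(sequence, "")[[1]]
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < length(chars)]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, length(chars))
  n_frag <- length(starts)
  out <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_frag) break
      out[[length(out) + 1L]] <- c(starts[i], ends[j], m)
    }
  }
  mat <- do.call(rbind, out)
  tibble::tibble(
    peptide = substring(sequence, mat[, 1], mat[, 2]),
    start = as.integer(mat[, 1]),
    end = as.integer(mat[, 2]),
    n_missed = as.integer(mat[, 3])
  )
}
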