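#' Extract sequence windows around phosphosites
#'
#' One 13-residue window (+/- `half_width` residues around the
#' phosphorylated residue) per phosphorylated position; multiply
#' phosphorylated sites contribute one window per residue. Positions beyond
#' the protein termini are padded with `_`. Serine- and threonine-centered
#' windows are kept apart via the `central` column so they can be analyzed
#' independently.
#'
#' @param sites site tibble ([assemble_sites()]).
#' @param proteome named character vector of sequences.
#' @param half_width residues on each side of the central position.
#' @return tibble: `window`, `central`, `protein_id`, `position`.
#' @export
extract_windows <- function(sites, proteome, half_width = 6) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    seqs <- proteome[[sites$protein_id[i]]]
    assert_that(!is.null(seqs), paste0("protein not in proteome: ", sites$protein_id[i]))
    for (pos in split_ints(sites$positions[i])[[1]]) {
      assert_that(pos <= nchar(seqs), "site position exceeds protein length")
      lo <- pos - half_width; hi <- pos + half_width
      core <- substring(seqs, max(1, lo), min(nchar(seqs), hi))
      pad_l <- strrep("_", max(0, 1 - lo))
      pad_r <- strrep("_", max(0, hi - nchar(seqs)))
      w <- paste0(pad_l, core, pad_r)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        window = w, central = substring(seqs, pos, pos),
        protein_id = sites$protein_id[i], position = pos
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  assert_that(all(nchar(out$window) == 2 * half_width + 1), "window length mismatch")
  out
}

#' Iterative motif-x style motif extraction
#'
#' Greedy extraction of overrepresented position-residue patterns from
#' foreground windows against a background: at each step, for every
#' (offset, residue) pair off the central position, the binomial tail
#' probability of observing at least the foreground count given the
#' background frequency is computed; the minimum-p pair with
#' `p <= p_cutoff` whose restricted foreground still holds at least
#' `min_seq` windows is fixed into the motif, both pools are restricted to
#' matching windows, and the step repeats. When no pair qualifies, the motif
#' (if any pair was accepted) is emitted, its matches are removed from both
#' pools, and extraction restarts for further motifs. Ties are broken by
#' smaller signed offset, then alphabetical residue. The padding character
#' `_` participates as an ordinary symbol.
#'
#' @param foreground,background character vectors of equal-width windows
#'   with the phosphorylated residue at the center.
#' @param central central residue the pools share (`"S"` or `"T"`);
#'   lower-cased in the reported motif string.
#' @param min_seq minimum foreground windows a motif must retain.
#' @param p_cutoff per-step binomial p-value cutoff.
#' @return tibble: `motif` (pattern with `.` wildcards), `fg_matches`,
#'   `bg_matches`, `fg_size`, `bg_size`, `score` (summed -log10 p over the
#'   accepted pairs), `fold_enrichment`.
#' @export
motifx <- function(foreground, background, central = "S", min_seq = 20,
                   p_cutoff = 0.01) {
  assert_that(length(foreground) > 0 && length(background) > 0,
              "foreground and background must be non-empty")
  width <- unique(nchar(c(foreground, background)))
  assert_that(length(width) == 1, "all windows must have equal width")
  mid <- (width + 1L) %/% 2L
  fg_all <- do.call(rbind, strsplit(foreground, ""))
  bg_all <- do.call(rbind, strsplit(background, ""))
  fg_size0 <- nrow(fg_all); bg_size0 <- nrow(bg_all)
  results <- list()
  repeat {
    fg <- fg_all; bg <- bg_all
    fixed <- character(0)   # accepted "offset:residue" pairs
    score <- 0
    pattern <- rep(".", width)
    repeat {
      if (nrow(bg) < nrow(fg)) {
        rlang::abort("background smaller than foreground during motif restriction")
      }
      best <- best_pair(fg, bg, mid, fixed, min_seq, p_cutoff)
      if (is.null(best)) break
      fixed <- c(fixed, paste0(best$col, ":", best$residue))
      pattern[best$col] <- best$residue
      score <- score - log10(max(best$p, .Machine$double.xmin))
      keep_fg <- fg[, best$col] == best$residue
      keep_bg <- bg[, best$col] == best$residue
      fg <- fg[keep_fg, , drop = FALSE]
      bg <- bg[keep_bg, , drop = FALSE]
    }
    if (length(fixed) == 0) break
    pattern[mid] <- tolower(central)
    motif <- paste(pattern, collapse = "")
    results[[length(results) + 1L]] <- tibble::tibble(
      motif = motif, fg_matches = nrow(fg), bg_matches = nrow(bg),
      fg_size = fg_size0, bg_size = bg_size0, score = score,
      fold_enrichment = (nrow(fg) / fg_size0) / (nrow(bg) / bg_size0)
    )
    drop_fg <- matches_pattern(fg_all, pattern, mid)
    drop_bg <- matches_pattern(bg_all, pattern, mid)
    fg_all <- fg_all[!drop_fg, , drop = FALSE]
    bg_all <- bg_all[!drop_bg, , drop = FALSE]
    if (nrow(fg_all) < min_seq || nrow(bg_all) == 0) break
  }
  if (length(results) == 0) {
    return(tibble::tibble(motif = character(0), fg_matches = integer(0),
                          bg_matches = integer(0), fg_size = integer(0),
                          bg_size = integer(0), score = numeric(0),
                          fold_enrichment = numeric(0)))
  }
  dplyr::bind_rows(results)
}

# Minimum-p eligible (column, residue) pair, or NULL when none passes.
best_pair <- function(fg, bg, mid, fixed, min_seq, p_cutoff) {
  n_fg <- nrow(fg); n_bg <- nrow(bg)
  best <- NULL
  for (col in seq_len(ncol(fg))) {
    if (col == mid) next
    resid <- sort(unique(fg[, col]))
    for (r in resid) {
      if (paste0(col, ":", r) %in% fixed) next
      k <- sum(fg[, col] == r)
      if (k < min_seq) next
      p0 <- sum(bg[, col] == r) / n_bg
      p <- binom_tail(k, n_fg, p0)
      if (p > p_cutoff) next
      if (is.null(best) || p < best$p ||
          (p == best$p && (col < best$col || (col == best$col && r < best$residue)))) {
        best <- list(col = col, residue = r, p = p, k = k)
      }
    }
  }
  best
}

# Upper binomial tail P(X >= k), X ~ Binomial(n, p0).
binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

matches_pattern <- function(mat, pattern, mid) {
  keep <- rep(TRUE, nrow(mat))
  for (col in seq_along(pattern)) {
    if (col == mid || pattern[col] == ".") next
    keep <- keep & mat[, col] == pattern[col]
  }
  keep
}

#' Threonine-vs-serine enrichment among S/T-P motif sites
#'
#' Restricts foreground and background windows to those with a proline
#' immediately after the central residue (the proline-directed S/T-P motif)
#' and tests the 2x2 association of central residue (T vs S) with set
#' membership via Fisher's exact test.
#'
#' @param fg_windows,bg_windows window tibbles from [extract_windows()].
#' @param require_proline restrict to S/T-P windows (default `TRUE`).
#' @return list: `odds_ratio`, `p_value`, `or_defined`, `table` (the 2x2
#'   counts: rows T/S, columns foreground/background).
#' @export
threonine_enrichment <- function(fg_windows, bg_windows, require_proline = TRUE) {
  mid <- (nchar(fg_windows$window[1]) + 1L) %/% 2L
  pick <- function(w) {
    if (require_proline) w <- w[substring(w$window, mid + 1L, mid + 1L) == "P", , drop = FALSE]
    w
  }
  fg <- pick(fg_windows); bg <- pick(bg_windows)
  tab <- matrix(c(sum(fg$central == "T"), sum(bg$central == "T"),
                  sum(fg$central == "S"), sum(bg$central == "S")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("T", "S"), c("foreground", "background")))
  res <- enrichment_test(tab)
  c(res, list(table = tab))
}
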