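# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# All peptides of `sequence` consistent with cleavage after K/R (Trypsin/P)
# and at most `max_missed` internal missed cleavage sites, by enumerating
# every substring and checking the rule directly.
oracle_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- character(0)
  for (s in seq_len(L)) {
    for (e in s:L) {
      starts_ok <- s == 1 || chars[s - 1] %in% c("K", "R")
      ends_ok <- e == L || chars[e] %in% c("K", "R")
      internal <- if (e > s) sum(chars[s:(e - 1)] %in% c("K", "R")) else 0
      if (starts_ok && ends_ok && internal <= max_missed) {
        out <- c(out, paste0(paste(chars[s:e], collapse = ""), "@", s, "-", e))
      }
    }
  }
  sort(out)
}

# Transitive closure of "shares a phosphorylated position" over a list of
# integer position sets: repeatedly merge groups until stable.
oracle_islands <- function(pos_list) {
  groups <- as.list(seq_along(pos_list))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (merged) break
      for (j in seq_along(groups)) {
        if (j <= i) next
        pi <- unique(unlist(pos_list[groups[[i]]]))
        pj <- unique(unlist(pos_list[groups[[j]]]))
        if (length(intersect(pi, pj)) > 0) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  # canonical form: sorted member indices, sorted by first member
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (sum of probabilities <= observed's).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  amin <- max(0, r1 + c1 - n); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[a - amin + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper binomial tail by direct summation of the mass function.
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# Textbook Benjamini-Hochberg step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Exact two-sided rank-sum p for small groups by enumerating every
# assignment of ranks to group A.
oracle_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_along(a)])
  combs <- utils::combn(n, length(a))
  ws <- apply(combs, 2, function(i) sum(rank(c(a, b))[i]))
  mu <- length(a) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Minimal oriented + normalized evidence tibble for hand-built cases.
toy_records <- function(log2_ratio, proline_count = 0, n_phospho = 0,
                        positions = "", probs = "", replicate_id = "rep1",
                        setup_id = "SR", protein_id = "P1",
                        peptide_start = 1L, bare_sequence = "AAAAAA") {
  n <- length(log2_ratio)
  tibble::tibble(
    protein_id = rep_len(protein_id, n),
    peptide_start = rep_len(as.integer(peptide_start), n),
    bare_sequence = rep_len(bare_sequence, n),
    phospho_positions = rep_len(positions, n),
    phospho_probs = rep_len(probs, n),
    other_mods = "",
    ratio_hl = 2^log2_ratio,
    replicate_id = rep_len(replicate_id, n),
    setup_id = rep_len(setup_id, n),
    n_phospho = rep_len(as.integer(n_phospho), n),
    proline_count = rep_len(as.integer(proline_count), n)
  ) |>
    (\(d) { d$peptide_end <- d$peptide_start + nchar(d$bare_sequence) - 1L; d })()
}

# Phosphopeptide record set from a compact entry list: each element is
# list(pos = c(...), start, seq, rep, value).
toy_phospho <- function(entries, protein_id = "P1") {
  rows <- lapply(entries, function(s) {
    tibble::tibble(
      protein_id = protein_id,
      peptide_start = as.integer(s$start %||% 1L),
      bare_sequence = s$seq %||% strrep("A", max(s$pos) - (s$start %||% 1L) + 3L),
      phospho_positions = paste(s$pos, collapse = ";"),
      phospho_probs = paste(rep(1, length(s$pos)), collapse = ";"),
      other_mods = s$mods %||% "",
      ratio_hl = 2^(s$value %||% 0),
      replicate_id = s$rep %||% "rep1",
      setup_id = "SR",
      n_phospho = length(s$pos),
      proline_count = 0L
    )
  })
  d <- dplyr::bind_rows(rows)
  d$peptide_end <- d$peptide_start + nchar(d$bare_sequence) - 1L
  d$log2_corrected <- log2(d$ratio_hl)
  d
}

`%||%` <- rlang::`%||%`
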