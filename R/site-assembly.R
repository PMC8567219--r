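#' Isoform phosphorylation-site probability
#'
#' The product of the highest individual localization probabilities of a
#' record's assigned phosphosites. Unphosphorylated records get `NA`.
#'
#' @param records evidence tibble.
#' @return numeric vector, one probability per record.
#' @export
isoform_probability <- function(records) {
  probs <- split_nums(records$phospho_probs)
  mapply(function(p, k) {
    if (k == 0) return(NA_real_)
    prod(sort(p, decreasing = TRUE)[seq_len(k)])
  }, probs, records$n_phospho)
}

#' Filter phosphopeptides by localization confidence
#'
#' Discards phosphorylated records whose isoform probability is strictly
#' below the threshold (a record at exactly the threshold is retained).
#' Unphosphorylated records always pass.
#'
#' @param records evidence tibble.
#' @param threshold minimum isoform probability (default 0.70).
#' @return filtered records with attribute `n_filtered`.
#' @export
filter_localization <- function(records, threshold = 0.70) {
  iso <- isoform_probability(records)
  keep <- is.na(iso) | iso >= threshold
  structure(records[keep, , drop = FALSE], n_filtered = sum(!keep))
}

# evidence -> replicate means -> overall mean
two_level_mean <- function(values, replicates) {
  per_rep <- vapply(split(values, replicates), mean, numeric(1))
  list(per_replicate = per_rep, final = mean(per_rep))
}

#' Aggregate evidence into phosphorylation sites
#'
#' Groups phosphopeptides by their exact set of phosphorylated protein
#' residues, regardless of missed cleavages or additional modifications such
#' as oxidation. Ratios are averaged in two levels: evidence entries to a
#' per-replicate mean, then replicate means to the final site ratio.
#'
#' @param records normalized, localization-filtered evidence tibble.
#' @param proteome optional named sequence vector; when given, residue
#'   letters are taken from it and a mismatch with the peptide sequence (or
#'   a non-S/T/Y residue) is a hard error.
#' @param value_col ratio column to aggregate (default `log2_corrected`).
#' @return tibble, one row per site: `protein_id`, `positions`, `residues`,
#'   `per_replicate_log2` (named list column), `final_log2`, `n_evidence`,
#'   `n_replicates`.
#' @export
assemble_sites <- function(records, proteome = NULL, value_col = "log2_corrected") {
  ph <- records[records$n_phospho > 0, , drop = FALSE]
  if (nrow(ph) == 0) {
    return(tibble::tibble(protein_id = character(0), positions = character(0),
                          residues = character(0), per_replicate_log2 = list(),
                          final_log2 = numeric(0), n_evidence = integer(0),
                          n_replicates = integer(0)))
  }
  pos_list <- lapply(split_ints(ph$phospho_positions), sort)
  ph$positions <- join_ints(pos_list)
  residue_letters(ph, pos_list, proteome)  # validates coordinates
  key <- site_id(ph$protein_id, ph$positions)
  idx <- split(seq_len(nrow(ph)), key)
  out <- lapply(idx, function(i) {
    agg <- two_level_mean(ph[[value_col]][i], ph$replicate_id[i])
    tibble::tibble(
      protein_id = ph$protein_id[i[1]],
      positions = ph$positions[i[1]],
      residues = residue_letters(ph[i[1], , drop = FALSE],
                                 pos_list[i[1]], proteome),
      per_replicate_log2 = list(agg$per_replicate),
      final_log2 = agg$final,
      n_evidence = length(i),
      n_replicates = length(agg$per_replicate)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$protein_id, .data$positions)
}

# Residue letters for each record's positions; hard error when the FASTA
# letter disagrees with the peptide sequence or is not a phospho-acceptor.
residue_letters <- function(ph, pos_list, proteome) {
  vapply(seq_len(nrow(ph)), function(j) {
    pos <- pos_list[[j]]
    pep_letters <- substring(ph$bare_sequence[j],
                             pos - ph$peptide_start[j] + 1L,
                             pos - ph$peptide_start[j] + 1L)
    if (!is.null(proteome)) {
      seqs <- proteome[[ph$protein_id[j]]]
      assert_that(!is.null(seqs), paste0("protein ", ph$protein_id[j], " not in FASTA"))
      assert_that(max(pos) <= nchar(seqs), "site position exceeds protein length")
      fa_letters <- substring(seqs, pos, pos)
      assert_that(all(fa_letters == pep_letters),
                  paste0("residue mismatch between evidence and FASTA for ",
                         ph$protein_id[j], ":", ph$positions[j]))
      assert_that(all(fa_letters %in% c("S", "T", "Y")),
                  paste0("non-phosphorylatable residue at ",
                         ph$protein_id[j], ":", ph$positions[j]))
    }
    paste(pep_letters, collapse = ";")
  }, character(1))
}

#' Group phosphopeptides into phosphoislands
#'
#' Islands are the connected components of the graph whose nodes are
#' phosphopeptide evidence records and whose edges join records sharing at
#' least one phosphorylated residue. Sequence overlap alone does not connect
#' two records.
#'
#' @param records localization-filtered evidence tibble.
#' @return tibble, one row per island: `island_id`, `protein_id`,
#'   `positions` (union of phosphorylated positions), `span_start`,
#'   `span_end`, `member_sites` (list of distinct position-set strings),
#'   `n_peptides`.
#' @export
build_phosphoislands <- function(records) {
  ph <- records[records$n_phospho > 0, , drop = FALSE]
  if (nrow(ph) == 0) {
    return(tibble::tibble(island_id = character(0), protein_id = character(0),
                          positions = character(0), span_start = integer(0),
                          span_end = integer(0), member_sites = list(),
                          n_peptides = integer(0)))
  }
  pos_list <- lapply(split_ints(ph$phospho_positions), sort)
  ph$positions <- join_ints(pos_list)
  out <- list()
  for (p in unique(ph$protein_id)) {
    rows <- which(ph$protein_id == p)
    comp <- shared_position_components(pos_list[rows])
    for (cid in unique(comp)) {
      members <- rows[comp == cid]
      all_pos <- sort(unique(unlist(pos_list[members])))
      out[[length(out) + 1L]] <- tibble::tibble(
        protein_id = p,
        positions = paste(all_pos, collapse = ";"),
        span_start = min(all_pos),
        span_end = max(all_pos),
        member_sites = list(sort(unique(ph$positions[members]))),
        n_peptides = length(members)
      )
    }
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$protein_id, .data$span_start)
  res$island_id <- sprintf("isl%04d", seq_len(nrow(res)))
  res[, c("island_id", setdiff(names(res), "island_id"))]
}

# Connected components over records sharing >= 1 phosphorylated position;
# built by linking every record to the positions it phosphorylates.
shared_position_components <- function(pos_list) {
  n <- length(pos_list)
  if (n == 1) return(1L)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(paste0("r", i), paste0("p", pos_list[[i]]))
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  unname(comp[paste0("r", seq_len(n))])
}

#' Attach unphosphorylated counter groups to phosphoislands
#'
#' An island's UCG contains all unphosphorylated records whose peptide
#' interval covers at least one of the island's phosphorylated positions.
#' The UCG ratio uses the same two-level averaging as phosphorylation sites
#' and is `NA` (flagged by `ucg_n = 0`) when no such record exists.
#'
#' @param islands output of [build_phosphoislands()].
#' @param records evidence tibble (unphosphorylated rows are used).
#' @param value_col ratio column to aggregate.
#' @return islands with `ucg_log2` and `ucg_n` columns added.
#' @export
attach_ucg <- function(islands, records, value_col = "log2_corrected") {
  un <- records[records$n_phospho == 0, , drop = FALSE]
  islands$ucg_log2 <- NA_real_
  islands$ucg_n <- 0L
  for (i in seq_len(nrow(islands))) {
    pos <- split_ints(islands$positions[i])[[1]]
    sel <- un$protein_id == islands$protein_id[i] &
      vapply(seq_len(nrow(un)),
             function(j) any(pos >= un$peptide_start[j] & pos <= un$peptide_end[j]),
             logical(1))
    if (any(sel)) {
      agg <- two_level_mean(un[[value_col]][sel], un$replicate_id[sel])
      islands$ucg_log2[i] <- agg$final
      islands$ucg_n[i] <- sum(sel)
    }
  }
  islands
}
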