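#' Classification rule set
#'
#' Thresholds for fold-change classification: a twofold cutoff for induced /
#' decreased calls (log2 of 1 and -1), and the dependency rule |log2| > 1
#' (inclusive at the bound). `set2_lower` is the (exclusive) lower bound of
#' the "moderately affected" Set2 range.
#'
#' @param up_fold fold-change cutoff for induced sites (default 2).
#' @param down_fold fold-change cutoff for decreased sites (default 0.5).
#' @param dependency_log2 |log2| bound defining dependency (default 1).
#' @param set2_lower exclusive lower log2 bound for Set2 (default -1).
#' @return list of class `class_rules`, with derived `up_log2`, `down_log2`.
#' @export
class_rules <- function(up_fold = 2, down_fold = 0.5, dependency_log2 = 1,
                        set2_lower = -1) {
  assert_that(up_fold > 1 && down_fold < 1 && down_fold > 0,
              "need up_fold > 1 > down_fold > 0")
  structure(list(up_fold = up_fold, down_fold = down_fold,
                 up_log2 = log2(up_fold), down_log2 = log2(down_fold),
                 dependency_log2 = dependency_log2, set2_lower = set2_lower),
            class = "class_rules")
}

#' Merge per-setup site tables into one matrix
#'
#' Outer join on site identity (protein + position set); sites missing from
#' a setup stay missing and are never imputed. Conflicting residue letters
#' for the same identity are an error.
#'
#' @param tables named list of site tibbles (see [assemble_sites()]); the
#'   names become the matrix's setup columns.
#' @return tibble: `protein_id`, `positions`, `residues`, one log2 column
#'   per setup.
#' @export
merge_setups <- function(tables) {
  assert_that(length(tables) >= 1 && !is.null(names(tables)) && all(nzchar(names(tables))),
              "tables must be a named list of site tables")
  slim <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    tibble::tibble(protein_id = t$protein_id, positions = t$positions,
                   residues = t$residues, !!nm := t$final_log2)
  })
  mat <- Reduce(function(a, b) {
    dplyr::full_join(a, b, by = c("protein_id", "positions", "residues"))
  }, slim)
  key <- site_id(mat$protein_id, mat$positions)
  if (anyDuplicated(key)) {
    rlang::abort(paste0("conflicting residue letters for site(s): ",
                        paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  mat
}

#' Classify log2 ratios as induced / decreased / static
#'
#' Induced means the fold change reaches the twofold cutoff (log2 >= 1 with
#' default rules), decreased means fold <= 0.5 (log2 <= -1), anything in
#' between is static. Missing values stay unclassified (`NA`).
#'
#' @param log2_ratio numeric vector.
#' @param rules a [class_rules()] object.
#' @return character vector in `{induced, decreased, static, NA}`.
#' @export
classify_regulation <- function(log2_ratio, rules = class_rules()) {
  out <- rep(NA_character_, length(log2_ratio))
  ok <- !is.na(log2_ratio)
  out[ok & log2_ratio >= rules$up_log2] <- "induced"
  out[ok & log2_ratio <= rules$down_log2] <- "decreased"
  out[ok & is.na(out)] <- "static"
  out
}

#' Hog1 dependence of stress-induced sites
#'
#' A site is Hog1-dependent when its stress-response ratio reaches the
#' twofold induction cutoff and kinase-analog inhibition reduces it at least
#' twofold (ratio <= 0.5, log2 <= -1). Either value missing leaves the call
#' undetermined (`NA`).
#'
#' @param sr_log2 log2 ratio in the stress-response setup.
#' @param inhibition_log2 log2 ratio under Hog1-analog inhibition.
#' @param rules a [class_rules()] object.
#' @return logical vector.
#' @export
classify_hog1_dependence <- function(sr_log2, inhibition_log2, rules = class_rules()) {
  ifelse(is.na(sr_log2) | is.na(inhibition_log2), NA,
         sr_log2 >= rules$up_log2 & inhibition_log2 <= rules$down_log2)
}

#' Assign Set1 / Set2 labels
#'
#' Within the universe of sites induced both under stress and upon CDC55
#' deletion, Set1 sites respond strongly to IGO1/IGO2 loss under stress
#' (log2 <= -1 with default rules) and Set2 sites moderately (negative but
#' above the Set1 bound). Everything else in the universe is `other`; sites
#' outside the universe, or with the IGO column missing, are `NA`.
#'
#' @param matrix setup matrix from [merge_setups()].
#' @param rules a [class_rules()] object.
#' @param sr_col,cdc55_col,igo_col setup column names.
#' @return character vector of labels, one per matrix row.
#' @export
assign_sets <- function(matrix, rules = class_rules(), sr_col = "SR",
                        cdc55_col = "cdc55", igo_col = "SR_igo1igo2") {
  for (v in c(sr_col, cdc55_col, igo_col)) {
    assert_that(v %in% names(matrix), paste0("setup column not in matrix: ", v))
  }
  sr <- matrix[[sr_col]]; cdc <- matrix[[cdc55_col]]; igo <- matrix[[igo_col]]
  universe <- !is.na(sr) & !is.na(cdc) & sr >= rules$up_log2 & cdc >= rules$up_log2
  out <- rep(NA_character_, nrow(matrix))
  out[universe & !is.na(igo)] <- "other"
  out[universe & !is.na(igo) & igo <= rules$set2_lower] <- "Set1"
  out[universe & !is.na(igo) & igo > rules$set2_lower & igo < 0] <- "Set2"
  out
}

#' Regulation fractions per setup
#'
#' Percentage of induced, decreased and static sites per setup, over the
#' non-missing cells; rows sum to 100.
#'
#' @param matrix setup matrix from [merge_setups()].
#' @param rules a [class_rules()] object.
#' @param setups setup columns to summarize; default every non-identity
#'   column.
#' @return tibble: `setup`, `n`, `induced`, `decreased`, `static` (percent).
#' @export
summarize_fractions <- function(matrix, rules = class_rules(),
                                setups = setdiff(names(matrix),
                                                 c("protein_id", "positions", "residues"))) {
  out <- lapply(setups, function(s) {
    cls <- classify_regulation(matrix[[s]], rules)
    cls <- cls[!is.na(cls)]
    n <- length(cls)
    tibble::tibble(
      setup = s, n = n,
      induced = if (n) 100 * mean(cls == "induced") else NA_real_,
      decreased = if (n) 100 * mean(cls == "decreased") else NA_real_,
      static = if (n) 100 * mean(cls == "static") else NA_real_
    )
  })
  dplyr::bind_rows(out)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value from the hypergeometric distribution
#' (via [stats::fisher.test()]) together with the sample odds ratio
#' `(a*d)/(b*c)`. With a zero off-diagonal cell the odds ratio is infinite
#' (or `NaN` for a zero margin) and flagged.
#'
#' @param table2x2 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `odds_ratio`, `p_value`, `or_defined`.
#' @export
enrichment_test <- function(table2x2, alternative = "two.sided") {
  assert_that(is.matrix(table2x2) && all(dim(table2x2) == 2) &&
                all(table2x2 >= 0) && all(table2x2 == floor(table2x2)),
              "table2x2 must be a 2x2 matrix of non-negative integer counts")
  a <- table2x2[1, 1]; b <- table2x2[1, 2]; cc <- table2x2[2, 1]; d <- table2x2[2, 2]
  or <- (a * d) / (b * cc)
  defined <- is.finite(or)
  p <- stats::fisher.test(table2x2, alternative = alternative)$p.value
  list(odds_ratio = or, p_value = p, or_defined = defined)
}

#' Compare two groups of log2 ratios
#'
#' Rank-sum (Mann-Whitney / Wilcoxon) or Welch two-sample t-test.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @param method `"wilcoxon"` or `"t"`.
#' @return p-value.
#' @export
compare_distributions <- function(group_a, group_b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs n >= 2")
  if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(group_a, group_b)$p.value)
  } else {
    stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
  }
}
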