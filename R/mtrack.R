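#' Fit a dilution-curve polynomial
#'
#' Least-squares polynomial of log2 signal versus log2 loading for one
#' blot/channel, fitted on the blot's four-point dilution series of a
#' control sample (degree 2 for series 1, degree 1 for series 2).
#'
#' @param loading linear loading fractions (4 distinct values).
#' @param log2_signal log2-transformed peak areas at those loadings.
#' @param degree 1 or 2.
#' @return list of class `dilution_curve`: `coefficients` (intercept first),
#'   `degree`, `residual_norm`, `range` (log2 loading range).
#' @export
fit_dilution_curve <- function(loading, log2_signal, degree) {
  assert_that(degree %in% c(1, 2), "degree must be 1 or 2")
  assert_that(length(loading) == 4 && length(log2_signal) == 4,
              "a dilution series has exactly 4 points")
  assert_that(!anyDuplicated(loading), "duplicate loading values")
  x <- log2(loading)
  fit <- stats::lm(log2_signal ~ stats::poly(x, degree, raw = TRUE))
  structure(list(coefficients = unname(stats::coef(fit)), degree = degree,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 range = range(x)),
            class = "dilution_curve")
}

curve_eval <- function(curve, x) {
  b <- curve$coefficients
  y <- b[1] + b[2] * x
  if (curve$degree == 2) y <- y + b[3] * x^2
  y
}

# Invert a fitted curve: log2 signal -> equivalent log2 loading. Degree-2
# curves must be monotone over the dilution range; the increasing (or
# decreasing) branch consistent with the range is used.
curve_invert <- function(curve, y) {
  b <- curve$coefficients
  if (curve$degree == 1) {
    assert_that(abs(b[2]) > 1e-12, "flat dilution curve cannot be inverted")
    return((y - b[1]) / b[2])
  }
  slope_at <- function(x) b[2] + 2 * b[3] * x
  s <- slope_at(curve$range)
  assert_that(prod(s) > 0, "dilution curve not monotone over the dilution range")
  if (abs(b[3]) < 1e-12) return((y - b[1]) / b[2])
  disc <- b[2]^2 - 4 * b[3] * (b[1] - y)
  disc[disc < 0] <- 0
  r1 <- (-b[2] + sqrt(disc)) / (2 * b[3])
  r2 <- (-b[2] - sqrt(disc)) / (2 * b[3])
  # pick the root on the monotone branch containing the dilution range
  ifelse(abs(slope_at(r1) - s[1]) + abs(slope_at(r1) - s[2]) <
           abs(slope_at(r2) - s[1]) + abs(slope_at(r2) - s[2]), r1, r2)
}

#' Loading-correct densitometry signals and score proximity
#'
#' Fits per-blot, per-channel dilution curves from the `_dilution_` rows,
#' maps each sample lane's log2 area through its blot's curve onto the
#' common equivalent-loading scale, and scores proximity as normalized me3
#' minus normalized HA. A degree-2 curve that is not monotone over the
#' dilution range falls back to degree 1 with a warning.
#'
#' @param densitometry tibble as from [simulate_densitometry()] /
#'   [read_densitometry()].
#' @return tibble: `bait`, `replicate`, `blot_id`, `series`, `proximity`.
#' @export
correct_and_score <- function(densitometry) {
  d <- densitometry
  dil <- d[d$bait == "_dilution_", , drop = FALSE]
  smp <- d[d$bait != "_dilution_", , drop = FALSE]
  assert_that(nrow(dil) > 0 && nrow(smp) > 0,
              "densitometry table needs dilution and sample rows")
  curves <- list()
  for (key in unique(paste(dil$blot_id, dil$channel))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    rows <- dil[dil$blot_id == parts[1] & dil$channel == parts[2], , drop = FALSE]
    degree <- if (rows$series[1] == 1) 2 else 1
    cv <- fit_dilution_curve(rows$loading, log2(rows$area), degree)
    if (cv$degree == 2) {
      s <- cv$coefficients[2] + 2 * cv$coefficients[3] * cv$range
      if (prod(s) <= 0) {
        rlang::warn(paste0("non-monotone degree-2 curve on ", key,
                           "; falling back to degree 1"))
        cv <- fit_dilution_curve(rows$loading, log2(rows$area), 1)
      }
    }
    curves[[key]] <- cv
  }
  wide <- tidyr::pivot_wider(
    smp[, c("blot_id", "bait", "replicate", "series", "channel", "area")],
    names_from = "channel", values_from = "area"
  )
  assert_that(all(c("me3", "ha") %in% names(wide)),
              "each sample lane needs an me3 and an ha area")
  prox <- vapply(seq_len(nrow(wide)), function(i) {
    key_m <- paste(wide$blot_id[i], "me3"); key_h <- paste(wide$blot_id[i], "ha")
    assert_that(!is.null(curves[[key_m]]) && !is.null(curves[[key_h]]),
                paste0("missing dilution curve for blot ", wide$blot_id[i]))
    curve_invert(curves[[key_m]], log2(wide$me3[i])) -
      curve_invert(curves[[key_h]], log2(wide$ha[i]))
  }, numeric(1))
  tibble::tibble(bait = wide$bait, replicate = wide$replicate,
                 blot_id = wide$blot_id, series = wide$series, proximity = prox)
}

#' Rescale proximities to the negative control
#'
#' Subtracts the mean proximity of the negative-control bait from every
#' proximity, so the control mean becomes exactly 0.
#'
#' @param proximities tibble from [correct_and_score()].
#' @param control negative-control bait label.
#' @return the tibble with `proximity` rescaled.
#' @export
rescale_to_control <- function(proximities, control = "NEGATIVE_CONTROL") {
  ctrl <- proximities$proximity[proximities$bait == control]
  assert_that(length(ctrl) >= 1, paste0("no records for control bait ", control))
  proximities$proximity <- proximities$proximity - mean(ctrl)
  proximities
}

# One-tailed (greater) Welch t-test with a small variance floor so
# zero-variance groups still yield a defined statistic.
welch_greater_p <- function(x, y, eps = 1e-8) {
  nx <- length(x); ny <- length(y)
  vx <- max(stats::var(x), eps); vy <- max(stats::var(y), eps)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  stats::pt(t, df, lower.tail = FALSE)
}

#' Test baits against the negative control
#'
#' One-tailed (greater) Welch t-test of each bait's rescaled replicate
#' proximities against all negative-control proximities, with
#' Benjamini-Hochberg q-values over the tested bait family and significance
#' tiers at q < 0.01 and q < 0.05. Baits with fewer than `n_min` replicates
#' are skipped with a warning.
#'
#' @param proximities rescaled tibble ([rescale_to_control()]).
#' @param control negative-control bait label.
#' @param n_min minimum replicates per tested bait (default 3).
#' @return tibble: `bait`, `n`, `mean_proximity`, `p_value`, `q_value`,
#'   `significance_tier` in `{"q<0.01", "q<0.05", "ns"}`.
#' @export
test_baits <- function(proximities, control = "NEGATIVE_CONTROL", n_min = 3) {
  ctrl <- proximities$proximity[proximities$bait == control]
  assert_that(length(ctrl) >= 2, "need >= 2 negative-control replicates")
  baits <- setdiff(unique(proximities$bait), control)
  rows <- list()
  for (b in baits) {
    x <- proximities$proximity[proximities$bait == b]
    if (length(x) < n_min) {
      rlang::warn(paste0("bait ", b, " has fewer than ", n_min,
                         " replicates; skipped"))
      next
    }
    rows[[b]] <- tibble::tibble(bait = b, n = length(x), mean_proximity = mean(x),
                                p_value = welch_greater_p(x, ctrl))
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) return(res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significance_tier <- ifelse(res$q_value < 0.01, "q<0.01",
                                  ifelse(res$q_value < 0.05, "q<0.05", "ns"))
  res
}

#' Read / write a densitometry table
#'
#' Tab-delimited with columns `blot_id`, `bait`, `replicate`, `channel`,
#' `loading`, `area`, `series`.
#'
#' @param path file path.
#' @export
read_densitometry <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    blot_id = readr::col_character(),
                    bait = readr::col_character(),
                    replicate = readr::col_character(),
                    channel = readr::col_character(),
                    loading = readr::col_double(),
                    area = readr::col_double(),
                    series = readr::col_integer()
                  ))
}

#' @rdname read_densitometry
#' @param densitometry table to write.
#' @export
write_densitometry <- function(densitometry, path) {
  readr::write_tsv(densitometry, path, progress = FALSE)
  invisible(path)
}
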