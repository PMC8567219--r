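#' Simulate an M-Track densitometry table
#'
#' Emulates quantified Western blot films from a proximity assay: each
#' replicate is one blot carrying a four-point dilution series of a control
#' sample (both the trimethylation readout, me3, and the HA loading control)
#' plus one me3/HA lane pair per bait. Lane loadings vary around the dilution
#' range; a bait's planted proximity effect enters as extra equivalent
#' loading on the me3 channel, so after dilution-curve correction the
#' recovered proximity equals the planted effect exactly when `noise_sd = 0`.
#' A negative-control bait with effect 0 is always included.
#'
#' @param n_baits number of test baits (`B01`, `B02`, ...).
#' @param n_replicates replicates (= blots); must be >= 2 so a Welch test is
#'   defined downstream.
#' @param curve_degree dilution-curve polynomial degree, 1 or 2 (the assay's
#'   series 2 and series 1, respectively).
#' @param effect_map named numeric vector bait -> planted log2 proximity
#'   effect; `NULL` means all zero.
#' @param seed integer seed.
#' @param noise_sd SD of Normal noise on the me3 log2 signal (the
#'   methylation readout carries the dominant variation; the HA loading
#'   control is treated as exact).
#' @param loading_sd SD of the per-lane log2 loading variation.
#' @param control_label label used for the negative-control bait.
#' @return tibble `(blot_id, bait, replicate, channel, loading, area,
#'   series)`; dilution rows carry `bait = "_dilution_"` and a linear
#'   `loading` fraction, sample rows carry `loading = NA`.
#' @export
simulate_densitometry <- function(n_baits, n_replicates, curve_degree = 1,
                                  effect_map = NULL, seed = 1,
                                  noise_sd = 0, loading_sd = 0.5,
                                  control_label = "NEGATIVE_CONTROL") {
  assert_that(curve_degree %in% c(1, 2), "curve_degree must be 1 or 2")
  assert_that(is_count(n_replicates) && n_replicates >= 2,
              "n_replicates must be >= 2 (Welch test undefined otherwise)")
  baits <- sprintf("B%02d", seq_len(n_baits))
  if (is.null(effect_map)) effect_map <- stats::setNames(rep(0, n_baits), baits)
  assert_that(all(names(effect_map) %in% baits), "effect_map names must match baits")
  effects <- stats::setNames(rep(0, n_baits), baits)
  effects[names(effect_map)] <- effect_map
  effects[control_label] <- 0
  series <- if (curve_degree == 2) 1L else 2L
  dil_log2 <- c(0, -1, -2, -3)
  quad <- if (curve_degree == 2) -0.05 else 0

  withr::with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      blot <- sprintf("blot%02d", r)
      # blot-specific intercepts model between-film exposure differences
      b0 <- c(me3 = runif(1, 2, 4), ha = runif(1, 2, 4))
      dil <- tidyr::crossing(channel = c("me3", "ha"), x = dil_log2)
      dil <- tibble::tibble(
        blot_id = blot, bait = "_dilution_", replicate = NA_character_,
        channel = dil$channel, loading = 2^dil$x,
        area = unname(2^f_vec(dil$channel, dil$x, b0, quad)), series = series
      )
      lanes <- tibble::tibble(bait = names(effects), effect = unname(effects))
      lanes$L <- runif(nrow(lanes), -2, -0.5)
      me3 <- f_vec("me3", lanes$L + lanes$effect, b0, quad) + rnorm(nrow(lanes), 0, noise_sd)
      ha <- f_vec("ha", lanes$L, b0, quad)
      smp <- tibble::tibble(
        blot_id = blot,
        bait = rep(lanes$bait, 2),
        replicate = sprintf("rep%d", r),
        channel = rep(c("me3", "ha"), each = nrow(lanes)),
        loading = NA_real_,
        area = unname(2^c(me3, ha)),
        series = series
      )
      dplyr::bind_rows(dil, smp)
    })
  })
  dplyr::bind_rows(out)
}

f_vec <- function(channel, x, b0, quad) b0[channel] + x + quad * x^2
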