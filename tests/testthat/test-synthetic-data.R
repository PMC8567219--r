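test_that("proteome generation is deterministic, bounded and seed-sensitive", {
  p1 <- generate_proteome(1, c(20, 20), seed = 7)
  p2 <- generate_proteome(1, c(20, 20), seed = 7)
  expect_identical(p1, p2)
  expect_equal(nchar(p1[[1]]), 20)

  p3 <- generate_proteome(3, c(50, 80), seed = 1)
  expect_length(p3, 3)
  expect_true(all(nchar(p3) >= 50 & nchar(p3) <= 80))
  expect_true(all(vapply(p3, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("K", "R")) >= 2
  }, logical(1))))

  expect_false(identical(generate_proteome(2, c(60, 60), seed = 1),
                         generate_proteome(2, c(60, 60), seed = 2)))
  expect_error(generate_proteome(1, c(10, 30), seed = 1), "20")
})

test_that("tryptic digestion follows Trypsin/P and matches brute-force enumeration", {
  d <- digest_tryptic("AAKBBRCC", max_missed = 0)
  expect_equal(d$peptide, c("AAK", "BBR", "CC"))
  expect_equal(d$start, c(1L, 4L, 7L))
  expect_equal(d$end, c(3L, 6L, 8L))

  # cleavage happens after K even when followed by proline
  dp <- digest_tryptic("AAKPBB", max_missed = 0)
  expect_equal(dp$peptide, c("AAK", "PBB"))

  for (seqs in c("AKRB", "MKRSTPKR", "RRKR", "AAAKA")) {
    for (mm in 0:2) {
      got <- digest_tryptic(seqs, max_missed = mm)
      got_key <- sort(paste0(got$peptide, "@", got$start, "-", got$end))
      expect_equal(got_key, oracle_digest(seqs, mm),
                   info = paste(seqs, "mm =", mm))
    }
  }
})

test_that("evidence generator reproduces the planted ratio model exactly without noise", {
  null_cfg <- sim_config(n_evidence = 100, frac_phospho = 0, noise_sd = 0,
                         mixing_offset_m = 0, proline_factor_c = 0, seed = 11)
  sim <- simulate_evidence(null_cfg)
  expect_true(all(log2(sim$evidence$ratio_hl) == 0))

  off_cfg <- sim_config(n_evidence = 100, frac_phospho = 0, noise_sd = 0,
                        mixing_offset_m = 0.5, proline_factor_c = 0, seed = 11)
  sim2 <- simulate_evidence(off_cfg)
  expect_equal(log2(sim2$evidence$ratio_hl), rep(0.5, 100), tolerance = 1e-14)

  pc_cfg <- sim_config(n_evidence = 300, frac_phospho = 0, noise_sd = 0,
                       mixing_offset_m = 0, proline_factor_c = -0.3, seed = 11)
  sim3 <- simulate_evidence(pc_cfg)
  one_p <- sim3$evidence[sim3$evidence$proline_count == 1, ]
  expect_gt(nrow(one_p), 0)
  expect_true(all(abs(log2(one_p$ratio_hl) - (-0.3)) < 1e-12))
  expect_equal(log2(sim3$evidence$ratio_hl),
               sim3$evidence$proline_count * -0.3)
})

test_that("generator conserves counts, site table membership and determinism", {
  cfg <- sim_config(n_evidence = 500, frac_phospho = 0.4, noise_sd = 0.2, seed = 4)
  sim <- simulate_evidence(cfg)
  expect_equal(nrow(sim$evidence), 500)
  ph <- sim$evidence[sim$evidence$n_phospho > 0, ]
  eff_keys <- paste(sim$ground_truth$site_effects$protein_id,
                    sim$ground_truth$site_effects$positions)
  expect_true(all(paste(ph$protein_id, ph$phospho_positions) %in% eff_keys))
  expect_true(all(sim$evidence$proline_count ==
                    lengths(regmatches(sim$evidence$bare_sequence,
                                       gregexpr("P", sim$evidence$bare_sequence)))))
  sim_b <- simulate_evidence(cfg)
  expect_identical(sim, sim_b)
})

test_that("label swap negates the written ratio and orientation undoes it", {
  base <- sim_config(n_evidence = 200, frac_phospho = 0, noise_sd = 0,
                     mixing_offset_m = 0.5, n_replicates = 2,
                     label_swap = c(FALSE, TRUE), seed = 9)
  sim <- simulate_evidence(base)
  sw <- sim$evidence$replicate_id == "rep2"
  expect_equal(log2(sim$evidence$ratio_hl[sw]), rep(-0.5, sum(sw)), tolerance = 1e-14)
  expect_equal(log2(sim$evidence$ratio_hl[!sw]), rep(0.5, sum(!sw)), tolerance = 1e-14)
  oriented <- orient_log2(sim$evidence, sim$swap_map)
  expect_equal(oriented$log2_oriented, rep(0.5, nrow(oriented)), tolerance = 1e-14)
})

test_that("phospho evidence without an effect table is rejected", {
  cfg <- sim_config(n_evidence = 50, frac_phospho = 0.5, seed = 1,
                    site_effect_table = tibble::tibble())
  expect_error(simulate_evidence(cfg), "empty")
})

test_that("localization probabilities land below 0.70 at the configured rate", {
  cfg <- sim_config(n_evidence = 4000, frac_phospho = 1, noise_sd = 0,
                    localization_below_frac = 0.25, seed = 2)
  sim <- simulate_evidence(cfg)
  iso <- isoform_probability(sim$evidence)
  expect_true(all(iso > 0 & iso <= 1))
  frac_low <- mean(iso < 0.70)
  expect_gt(frac_low, 0.20)
  expect_lt(frac_low, 0.30)
})

test_that("densitometry generator propagates planted effects exactly without noise", {
  d0 <- simulate_densitometry(4, 3, curve_degree = 1, seed = 5, noise_sd = 0)
  prox0 <- rescale_to_control(correct_and_score(d0))
  expect_true(all(abs(prox0$proximity) < 1e-9))

  d2 <- simulate_densitometry(4, 3, curve_degree = 2, effect_map = c(B02 = 2),
                              seed = 5, noise_sd = 0)
  prox2 <- rescale_to_control(correct_and_score(d2))
  b2 <- prox2$proximity[prox2$bait == "B02"]
  expect_true(all(abs(b2 - 2) < 1e-9))
  expect_true(all(abs(prox2$proximity[prox2$bait != "B02"]) < 1e-9))

  expect_error(simulate_densitometry(3, 1, seed = 1), "n_replicates")
  expect_error(simulate_densitometry(3, 3, curve_degree = 3, seed = 1), "degree")
})

test_that("dilution rows lie exactly on a degree-2 polynomial", {
  d <- simulate_densitometry(2, 2, curve_degree = 2, seed = 8, noise_sd = 0)
  dil <- d[d$bait == "_dilution_" & d$blot_id == d$blot_id[1] & d$channel == "me3", ]
  x <- log2(dil$loading)
  y <- log2(dil$area)
  fit <- lm(y ~ x + I(x^2))
  expect_lt(sum(residuals(fit)^2), 1e-18)
  # evaluating the fitted polynomial at the 4 dilution levels reproduces them
  expect_equal(unname(predict(fit)), unname(y), tolerance = 1e-12)
})
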