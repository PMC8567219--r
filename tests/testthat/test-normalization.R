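test_that("orientation log2-transforms and obeys the sign convention", {
  r <- toy_records(c(0, 2, -2))
  r$ratio_hl <- c(1, 4, 0.25)
  out <- orient_log2(r)
  expect_equal(out$log2_oriented, c(0, 2, -2))
  swapped <- orient_log2(r, tibble::tibble(replicate_id = "rep1", swap = TRUE))
  expect_equal(swapped$log2_oriented, c(0, -2, 2))
  # involution: swapping twice restores the original
  expect_equal(-swapped$log2_oriented, out$log2_oriented)
  r$ratio_hl[1] <- 0
  expect_error(orient_log2(r), "ratio_hl")
})

test_that("m and c estimators follow the stated pooling", {
  rec <- dplyr::bind_rows(
    toy_records(c(0.5, 0.5), proline_count = 0),
    toy_records(0.2, proline_count = 1),   # residual after m: -0.3
    toy_records(-0.1, proline_count = 2)   # residual after m: -0.6, halved: -0.3
  )
  rec <- orient_log2(rec)
  model <- fit_normalization(rec)
  expect_equal(model$mixing_factor_m, 0.5)
  expect_equal(model$proline_factor_c, -0.3)
  expect_equal(model$n_reference_peptides, 2L)
  expect_equal(model$n_one_proline, 1L)
  expect_equal(model$n_two_proline, 1L)

  corrected <- apply_normalization(rec, model)
  # 2-proline record: -0.1 - 0.5 - 2*(-0.3) = 0
  expect_equal(corrected$log2_corrected[4], 0)
  expect_equal(corrected$log2_corrected[1:2], c(0, 0))
})

test_that("degenerate groups: proline-free-only warns c = 0; none is a hard error", {
  flat <- orient_log2(toy_records(c(0, 0, 0), proline_count = 0))
  expect_warning(model <- fit_normalization(flat), "c set to 0")
  expect_equal(model$mixing_factor_m, 0)
  expect_equal(model$proline_factor_c, 0)

  only_p <- orient_log2(toy_records(c(0.1, 0.2), proline_count = 1))
  expect_error(fit_normalization(only_p), "proline-free")
})

test_that("3+ proline peptides are excluded from c but still corrected", {
  rec <- orient_log2(dplyr::bind_rows(
    toy_records(c(0, 0), proline_count = 0),
    toy_records(-0.2, proline_count = 1),
    toy_records(-0.9, proline_count = 3)
  ))
  model <- suppressWarnings(fit_normalization(rec))
  expect_equal(model$proline_factor_c, -0.2)   # the 3-proline residual is ignored
  corrected <- apply_normalization(rec, model)
  expect_equal(corrected$log2_corrected[4], -0.9 - 3 * (-0.2))
})

test_that("phospho records never enter the factors but are corrected", {
  rec <- orient_log2(dplyr::bind_rows(
    toy_records(c(0.5, 0.5), proline_count = 0),
    toy_records(5, proline_count = 0, n_phospho = 1, positions = "3", probs = "1",
                bare_sequence = "AASAAA")
  ))
  expect_warning(model <- fit_normalization(rec), "c set to 0")
  expect_equal(model$mixing_factor_m, 0.5)
  expect_equal(model$n_reference_peptides, 2L)
  corrected <- apply_normalization(rec, model)
  expect_equal(corrected$log2_corrected[3], 4.5)
})

test_that("identity when m = c = 0 and error for unmodeled groups", {
  rec <- orient_log2(toy_records(c(0.3, -0.3, 0.1, -0.1), proline_count = c(0, 0, 1, 1)))
  model <- fit_normalization(rec)
  expect_equal(model$mixing_factor_m, 0)
  corrected <- apply_normalization(rec, model)
  expect_equal(corrected$log2_corrected, corrected$log2_oriented)

  other <- rec
  other$setup_id <- "other"
  expect_error(apply_normalization(other, model), "no normalization model")
})

test_that("normalization centers every group and is idempotent", {
  sim <- simulate_evidence(sim_config(n_evidence = 2000, frac_phospho = 0.3,
                                      mixing_offset_m = 0.7, proline_factor_c = -0.4,
                                      noise_sd = 0.3, n_replicates = 3, seed = 17))
  ev <- orient_log2(sim$evidence, sim$swap_map)
  model <- fit_normalization(ev)
  ev <- apply_normalization(ev, model)
  un <- ev[ev$n_phospho == 0 & ev$proline_count == 0, ]
  for (g in split(un, paste(un$setup_id, un$replicate_id))) {
    expect_lt(abs(mean(g$log2_corrected)), 1e-12)
  }
  # refitting on corrected data yields the null model
  refit <- ev
  refit$log2_oriented <- refit$log2_corrected
  model2 <- fit_normalization(refit)
  expect_true(all(abs(model2$mixing_factor_m) < 1e-12))
  expect_true(all(abs(model2$proline_factor_c) < 1e-12))
})

test_that("m and c are recovered within sampling error on noisy simulations", {
  hits <- 0; runs <- 20
  for (s in seq_len(runs)) {
    sim <- simulate_evidence(sim_config(n_evidence = 3000, frac_phospho = 0,
                                        mixing_offset_m = 0.4,
                                        proline_factor_c = -0.25,
                                        noise_sd = 0.3, n_replicates = 1,
                                        seed = 100 + s))
    ev <- orient_log2(sim$evidence, sim$swap_map)
    model <- fit_normalization(ev)
    se_c <- 0.3 / sqrt(model$n_one_proline + model$n_two_proline)
    se_m <- 0.3 / sqrt(model$n_reference_peptides)
    if (abs(model$proline_factor_c + 0.25) < 3 * se_c &&
        abs(model$mixing_factor_m - 0.4) < 3 * se_m) hits <- hits + 1
  }
  expect_gte(hits, runs - 2)
})

test_that("protein-level centering subtracts the unphosphorylated median", {
  rec <- toy_phospho(list(list(pos = 5, value = 5, seq = "AAAASAA")))
  un <- toy_records(c(1, 2, 3))
  un$log2_corrected <- c(1, 2, 3)
  d <- dplyr::bind_rows(rec, un)
  out <- normalize_protein_level(d)
  expect_equal(out$log2_corrected[1], 3)

  un2 <- toy_records(c(0, 10))
  un2$log2_corrected <- c(0, 10)
  d2 <- dplyr::bind_rows(rec, un2)
  out2 <- normalize_protein_level(d2)
  expect_equal(out2$log2_corrected, c(0, -5, 5))

  expect_error(normalize_protein_level(rec), "unphosphorylated")
})
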