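test_that("isoform probability multiplies the highest per-site probabilities", {
  r <- dplyr::bind_rows(
    toy_records(0, n_phospho = 1, positions = "3", probs = "0.95", bare_sequence = "AASAAA"),
    toy_records(0, n_phospho = 2, positions = "3;5", probs = "0.9;0.8", bare_sequence = "AASATA"),
    toy_records(0, n_phospho = 2, positions = "3;5", probs = "1;1", bare_sequence = "AASATA"),
    toy_records(0)
  )
  expect_equal(isoform_probability(r), c(0.95, 0.72, 1, NA))
})

test_that("localization filter discards strictly below threshold, keeps the boundary", {
  mk <- function(p1, p2) toy_records(0, n_phospho = 2, positions = "3;5",
                                     probs = paste(p1, p2, sep = ";"),
                                     bare_sequence = "AASATA")
  r <- dplyr::bind_rows(mk(0.9, 0.8),    # 0.72 -> retained
                        mk(0.9, 0.75),   # 0.675 -> discarded
                        mk(1, 0.7),      # exactly 0.70 -> retained
                        toy_records(0))  # unphosphorylated passes
  out <- filter_localization(r, threshold = 0.70)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_filtered"), 1)
  expect_equal(out$phospho_probs[1:2], c("0.9;0.8", "1;0.7"))
})

test_that("sites aggregate by exact position set with two-level averaging", {
  rec <- toy_phospho(list(
    list(pos = 12, start = 10, seq = "AASPTK", rep = "A", value = 1),
    list(pos = 12, start = 10, seq = "AASPTK", rep = "A", value = 3),
    list(pos = 12, start = 10, seq = "AASPTK", rep = "B", value = 2)
  ))
  s <- assemble_sites(rec)
  expect_equal(nrow(s), 1)
  expect_equal(s$per_replicate_log2[[1]], c(A = 2, B = 2))
  expect_equal(s$final_log2, 2)
  expect_equal(s$n_evidence, 3L)

  # missed-cleavage and oxidized variants merge into one site
  rec2 <- toy_phospho(list(
    list(pos = 12, start = 10, seq = "AASPTK", value = 0.5),
    list(pos = 12, start = 6, seq = "AAAKAASPTK", value = 0.5, mods = "oxidation")
  ))
  s2 <- assemble_sites(rec2)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$n_evidence, 2L)
  expect_equal(s2$final_log2, 0.5)

  single <- assemble_sites(toy_phospho(list(list(pos = 12, start = 10,
                                                 seq = "AASPTK", value = 0))))
  expect_equal(single$final_log2, 0)
})

test_that("aggregation is permutation-invariant and site count is bounded", {
  sim <- simulate_evidence(sim_config(n_evidence = 500, frac_phospho = 0.6,
                                      noise_sd = 0.2, seed = 13))
  ev <- orient_log2(sim$evidence, sim$swap_map)
  ev <- apply_normalization(ev, fit_normalization(ev))
  ev <- filter_localization(ev)
  s1 <- assemble_sites(ev)
  shuffled <- ev[withr::with_seed(1, sample(nrow(ev))), ]
  s2 <- assemble_sites(shuffled)
  expect_equal(s1, s2)
  ph <- ev[ev$n_phospho > 0, ]
  expect_lte(nrow(s1), nrow(dplyr::distinct(ph, protein_id, phospho_positions)))
})

test_that("residue letters come from the FASTA and mismatches are hard errors", {
  rec <- toy_phospho(list(list(pos = 12, start = 10, seq = "AASPTK", value = 0)))
  pro_ok <- c(P1 = paste0(strrep("A", 9), "AASPTKAAA"))
  s <- assemble_sites(rec, proteome = pro_ok)
  expect_equal(s$residues, "S")
  pro_bad <- c(P1 = strrep("A", 20))
  expect_error(assemble_sites(rec, proteome = pro_bad), "mismatch")
})

test_that("islands connect peptides through shared phosphorylated residues only", {
  rec <- toy_phospho(list(
    list(pos = 12, start = 8, seq = "AAAASAAK"),
    list(pos = c(12, 15), start = 10, seq = "AASAATAK"),
    list(pos = 20, start = 16, seq = "AAAATAAK")
  ))
  isl <- build_phosphoislands(rec)
  expect_equal(nrow(isl), 2)
  expect_equal(isl$positions, c("12;15", "20"))
  expect_equal(isl$n_peptides, c(2L, 1L))
  expect_equal(isl$member_sites[[1]], c("12", "12;15"))

  # overlapping peptide sequences but disjoint phospho positions stay apart
  rec2 <- toy_phospho(list(
    list(pos = 10, start = 5, seq = "AAAAASAAAAT"),
    list(pos = 15, start = 5, seq = "AAAAASAAAAT")
  ))
  expect_equal(nrow(build_phosphoislands(rec2)), 2)

  expect_equal(nrow(build_phosphoislands(rec2[1, ])), 1)
})

test_that("island partition matches a brute-force transitive closure", {
  for (s in 1:25) {
    pos_list <- withr::with_seed(s, {
      n <- sample(1:30, 1)
      lapply(seq_len(n), function(i) sort(sample(5:40, sample(1:3, 1))))
    })
    rec <- toy_phospho(lapply(pos_list, function(p) {
      list(pos = p, start = min(p) - 2L,
           seq = strrep("A", max(p) - min(p) + 5L))
    }))
    isl <- build_phosphoislands(rec)
    want <- oracle_islands(pos_list)
    expect_equal(nrow(isl), length(want), info = paste("seed", s))
    got_groups <- lapply(isl$positions, function(ps) {
      pp <- as.integer(strsplit(ps, ";")[[1]])
      sort(which(vapply(pos_list, function(q) any(q %in% pp), logical(1))))
    })
    got_groups <- got_groups[order(vapply(got_groups, min, numeric(1)))]
    expect_equal(got_groups, want, info = paste("seed", s))
    # partition: each peptide in exactly one island
    expect_equal(sort(unlist(got_groups)), seq_along(pos_list))
  }
})

test_that("UCGs average covering unphosphorylated peptides with the site rules", {
  isl <- build_phosphoislands(toy_phospho(list(list(pos = 12, start = 10, seq = "AASPTK"))))
  un <- toy_records(0.5, peptide_start = 10L, bare_sequence = "AASPTKAAA")
  un$log2_corrected <- 0.5
  out <- attach_ucg(isl, un)
  expect_equal(out$ucg_log2, 0.5)
  expect_equal(out$ucg_n, 1L)

  far <- toy_records(0.5, peptide_start = 100L, bare_sequence = "AAAA")
  far$log2_corrected <- 0.5
  out2 <- attach_ucg(isl, far)
  expect_true(is.na(out2$ucg_log2))
  expect_equal(out2$ucg_n, 0L)

  two <- toy_records(c(0, 1), peptide_start = 10L, bare_sequence = "AASPTKAAA")
  two$log2_corrected <- c(0, 1)
  out3 <- attach_ucg(isl, two)
  expect_equal(out3$ucg_log2, 0.5)
})

test_that("noise-free null simulations give all-zero site and UCG ratios", {
  sim <- simulate_evidence(sim_config(n_evidence = 400, frac_phospho = 0.5,
                                      noise_sd = 0, seed = 19,
                                      class_table = tibble::tibble(
                                        class = "static", prob = 1,
                                        effects = list(c(SR = 0)))))
  ev <- orient_log2(sim$evidence, sim$swap_map)
  ev <- apply_normalization(ev, suppressWarnings(fit_normalization(ev)))
  ev <- filter_localization(ev)
  sites <- assemble_sites(ev, proteome = sim$proteome)
  expect_true(all(sites$final_log2 == 0))
  isl <- attach_ucg(build_phosphoislands(ev), ev)
  expect_true(all(isl$ucg_log2[!is.na(isl$ucg_log2)] == 0))
})
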