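test_that("window contingency counts match simple constructed reads", {
  reads <- tibble::tibble(read = 1:2, read_id = c("a", "b"),
                          span_start = 1L, span_end = 14L)
  ev <- tibble::tibble(read = c(1L, 1L, 2L, 2L),
                       left = c(1L, 11L, 2L, 12L),
                       right = c(1L, 11L, 2L, 12L),
                       ref = c("G", "C", "G", "C"),
                       alt = c("U", "A", "U", "A"))
  rs <- read_set(reads, ev)
  cont <- window_contingency(rs, 14)
  w <- cont[cont$i == 1 & cont$j == 11, ]
  expect_equal(c(w$n11, w$n10, w$n01, w$n00), c(2L, 0L, 0L, 0L))

  silent <- read_set(reads, ev[0, ])
  expect_true(all(window_contingency(silent, 14)$n11 == 0))
  expect_error(window_contingency(silent, 5), "at least 6")
})

test_that("window contingency equals brute-force enumeration", {
  rs <- random_read_set(17, n_reads = 200, len = 20, event_rate = 0.08)
  for (mode in c("dms", "unfiltered")) {
    got <- window_contingency(rs, 20, mode = mode)
    want <- brute_window_contingency(rs, 20, mode = mode)
    expect_equal(dplyr::arrange(got, i, j), dplyr::arrange(want, i, j))
  }
})

test_that("G statistic is nonnegative, zero under proportionality, and
           matches the mutual-information identity", {
  expect_equal(g_statistic(20, 20, 30, 30), 0)
  expect_equal(g_statistic(0, 0, 0, 0), 0)
  set.seed(61)
  for (k in 1:50) {
    cnt <- as.integer(stats::rpois(4, lambda = sample(c(2, 20, 200), 1)))
    g <- g_statistic(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_gte(g, 0)
    expect_equal(g, brute_g_stat(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9)
  }
})

test_that("pairs below the co-modification cutoff are rejected regardless of G", {
  toy <- toy_two_state()
  s <- toy$structure
  prof <- synthetic_profile(s, rep(0.6, length(s)))
  pairs <- tibble::tibble(i = 11L, j = 56L, n11 = 9L, n10 = 1L, n01 = 1L,
                          n00 = 100000L)
  out <- pair_correlations(pairs, prof, s$sequence)
  expect_equal(out$class, "rejected")
  expect_match(out$reason, "cutoff")
  out2 <- pair_correlations(dplyr::mutate(pairs, n11 = 10L), prof,
                            s$sequence)
  expect_equal(out2$class, "principal")
})

test_that("raising the co-modification cutoff never adds PAIRs", {
  toy <- toy_two_state()
  params <- planted_helix_ensemble(toy$structure, toy$helix, 0.5)
  sim <- simulate_reads(params, 30000, seed = 71)
  cont <- window_contingency(sim, length(toy$structure))
  counts <- count_profile(sim, toy$structure$sequence, mode = "dms")
  prof <- normalize_reactivity(modification_rate(counts))
  n_reported <- vapply(c(5L, 10L, 20L, 40L), function(cut) {
    out <- pair_correlations(cont, prof, toy$structure$sequence,
                             min_comod = cut)
    sum(out$class != "rejected")
  }, integer(1))
  expect_true(all(diff(n_reported) <= 0))
})

test_that("windows overlapping masked reactivity are excluded entirely", {
  toy <- toy_two_state()
  s <- toy$structure
  prof <- synthetic_profile(s, rep(0.6, length(s)))
  prof$mask[12] <- FALSE
  prof$reactivity[12] <- NA
  pairs <- tibble::tibble(i = c(11L, 20L), j = c(51L, 60L),
                          n11 = 50L, n10 = 5L, n01 = 5L, n00 = 10000L)
  out <- pair_correlations(pairs, prof, s$sequence)
  expect_equal(out$class[1], "rejected")
  expect_equal(out$reason[1], "window masked")
})

test_that("ppv/sens score PAIRs against helices with register shifts", {
  toy <- toy_two_state()
  s <- toy$structure
  # windows tiling both helices exactly (antiparallel registers)
  pairs <- tibble::tibble(
    i = c(11L, 14L, 25L), j = c(56L, 53L, 38L),
    n11 = 50L, n10 = 1L, n01 = 1L, n00 = 1000L,
    class = c("principal", "principal", "minor")
  )
  res <- pair_ppv_sens(pairs, s)
  expect_equal(res$ppv, 1)
  expect_equal(res$sens, 1)
  expect_equal(res$n_helices, 2L)

  none <- pairs[0, ]
  res0 <- pair_ppv_sens(none, s)
  expect_true(is.na(res0$ppv))
  expect_equal(res0$sens, 0)

  # shifted by one position: still counted correct
  shifted <- dplyr::mutate(pairs[1, ], i = i + 1L)
  expect_equal(pair_ppv_sens(shifted, s)$ppv, 1)
  # far from any helix: incorrect
  wrong <- dplyr::mutate(pairs[1, ], i = 1L, j = 70L)
  expect_equal(pair_ppv_sens(wrong, s)$ppv, 0)
})

test_that("helices touching masked regions leave the sens denominator", {
  toy <- toy_two_state()
  s <- toy$structure
  mask <- rep(TRUE, length(s))
  mask[26] <- FALSE  # voids the 25-29/36-40 helix
  pairs <- tibble::tibble(i = 11L, j = 56L, n11 = 50L, n10 = 1L, n01 = 1L,
                          n00 = 1000L, class = "principal")
  res <- pair_ppv_sens(pairs, s, mask = mask)
  expect_equal(res$n_helices, 1L)
  expect_equal(res$sens, 1)
})

test_that("independent modifications stay null-calibrated", {
  toy <- toy_two_state()
  params <- sim_params(toy$structure)  # single state: no correlation
  sim <- simulate_reads(params, 50000, seed = 81)
  cont <- window_contingency(sim, length(toy$structure))
  counts <- count_profile(sim, toy$structure$sequence, mode = "dms")
  prof <- normalize_reactivity(modification_rate(counts))
  out <- pair_correlations(cont, prof, toy$structure$sequence, alpha = 0.05)
  tested <- sum(!is.na(out$p))
  sig <- sum(out$corrected_p <= 0.05, na.rm = TRUE)
  expect_gt(tested, 0)
  expect_lte(sig / tested, 0.05)
})
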