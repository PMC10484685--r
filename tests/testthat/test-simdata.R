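test_that("zero rates produce event-free reads and parameters validate", {
  s <- toy_hairpin()
  params <- sim_params(s, unpaired_rates = c(A = 0, C = 0, U = 0, G = 0),
                       n7g_rate = 0, bg_sub = 0, bg_indel = 0)
  sim <- simulate_reads(params, 200, seed = 1)
  expect_equal(nrow(sim$events), 0L)
  expect_equal(nrow(sim$reads), 200L)

  expect_error(sim_params(s, unpaired_rates = c(A = 1.2, C = 0, U = 0, G = 0)),
               "rates")
  expect_error(sim_params(s, signature_n1g = c(C = 0.9)), "sum to 1")
  expect_error(sim_params(list(s, toy_long_structure()),
                          weights = c(0.5, 0.5)), "share a sequence")
})

test_that("empirical mutation rates converge to analytic values", {
  s <- toy_long_structure()
  paired <- s$pair_table != 0
  bases <- strsplit(s$sequence, "")[[1]]
  params <- sim_params(s, n7g_rate = 0, bg_sub = 0, bg_indel = 0)
  n <- 100000
  sim <- simulate_reads(params, n, seed = 11)
  counts <- count_profile(sim, s$sequence, mode = "unfiltered")

  # unpaired A rate ~ 0.02 pooled across positions, within 3 binomial SE
  sel <- bases == "A" & !paired
  rate <- sum(counts$retained_mut[sel]) / sum(counts$effective_depth[sel])
  se <- sqrt(0.02 * 0.98 / sum(counts$effective_depth[sel]))
  expect_lt(abs(rate - 0.02), 3 * se)

  # paired rates are 10-fold lower by default
  selp <- bases == "A" & paired
  ratep <- sum(counts$retained_mut[selp]) / sum(counts$effective_depth[selp])
  sep <- sqrt(0.002 * 0.998 / sum(counts$effective_depth[selp]))
  expect_lt(abs(ratep - 0.002), 3 * sep)

  # N7-G: adduct 0.5 x detection 0.02 -> G>A rate ~ 0.01 at every G
  params7 <- sim_params(s, unpaired_rates = c(A = 0, C = 0, U = 0, G = 0),
                        bg_sub = 0, bg_indel = 0)
  sim7 <- simulate_reads(params7, 50000, seed = 12)
  ev <- sim7$events
  expect_true(all(ev$cause == "n7g"))
  expect_true(all(ev$ref == "G" & ev$alt == "A"))
  n_g <- sum(bases == "G")
  rate7 <- nrow(ev) / (50000 * n_g)
  se7 <- sqrt(0.01 * 0.99 / (50000 * n_g))
  expect_lt(abs(rate7 - 0.01), 3 * se7)

  # with background on, total rate ~ 1-(1-p_adduct)(1-p_bg)
  params_bg <- sim_params(s, n7g_rate = 0)
  simb <- simulate_reads(params_bg, 50000, seed = 13)
  cb <- count_profile(simb, s$sequence, mode = "unfiltered")
  sel <- bases == "A" & !paired
  # adduct, background substitution and indel are independent draws with
  # precedence, so the event rate is one minus the product of misses
  p_exp <- 1 - (1 - 0.02) * (1 - 0.001) * (1 - 0.002)
  rate_b <- sum(cb$retained_mut[sel]) / sum(cb$effective_depth[sel])
  se_b <- sqrt(p_exp * (1 - p_exp) / sum(cb$effective_depth[sel]))
  expect_lt(abs(rate_b - p_exp), 3.5 * se_b)
})

test_that("every event traces to exactly one cause and spans are valid", {
  s <- toy_long_structure()
  sim <- simulate_reads(sim_params(s), 5000, seed = 21)
  expect_true(all(sim$events$cause %in%
                    c("adduct_A", "adduct_C", "adduct_U", "n1g", "n7g",
                      "bg_sub", "bg_indel")))
  # one event per position per read
  dup <- sim$events |>
    dplyr::count(.data$read, .data$left) |>
    dplyr::filter(.data$n > 1)
  expect_equal(nrow(dup), 0L)
  # signature consistency
  n1 <- sim$events[sim$events$cause == "n1g", ]
  expect_true(all(n1$ref == "G" & n1$alt %in% c("C", "U")))
  n7 <- sim$events[sim$events$cause == "n7g", ]
  expect_true(all(n7$alt == "A"))
})

test_that("the signature filter separates N7-G noise from N1-G signal", {
  s <- toy_long_structure()
  sim <- simulate_reads(sim_params(s), 30000, seed = 22)
  status <- classify_events(sim$events, "dms")
  n7 <- sim$events$cause == "n7g"
  n1 <- sim$events$cause == "n1g"
  expect_gte(mean(status[n7] == "no_data"), 0.95)
  expect_gte(mean(status[n1] == "retained"), 0.95)
})

test_that("fragmented read models emit events only inside spans", {
  s <- toy_long_structure()
  params <- sim_params(s, read_length = 50)
  sim <- simulate_reads(params, 2000, seed = 31)
  expect_true(all(sim$reads$span_end - sim$reads$span_start == 49))
  spans <- sim$reads[match(sim$events$read, sim$reads$read), ]
  expect_true(all(sim$events$left >= spans$span_start &
                    sim$events$right <= spans$span_end))
})

test_that("planted-helix ensembles produce correlated co-modification", {
  toy <- toy_two_state()
  expect_error(planted_helix_ensemble(toy$structure, toy$helix, 1.1),
               "open_fraction")
  p0 <- planted_helix_ensemble(toy$structure, toy$helix, 0)
  expect_equal(length(p0$structures), 1L)
  p5 <- planted_helix_ensemble(toy$structure, toy$helix, 0.5)
  expect_equal(p5$weights, c(0.5, 0.5))

  sim <- simulate_reads(p5, 300000, seed = 41)
  states <- attr(sim, "states")
  expect_equal(sort(unique(states$state)), 1:2)
  expect_equal(mean(states$state == 2), 0.5, tolerance = 0.02)

  cont <- window_contingency(sim, length(toy$structure))
  # correct-register window pairs along the planted helix carry excess
  # co-modification far beyond chance
  reg <- cont[cont$i %in% 11:16 & cont$j == 67 - cont$i, ]
  g_helix <- g_statistic(reg$n11, reg$n10, reg$n01, reg$n00)
  expect_gt(max(g_helix), stats::qchisq(1 - 1e-6, df = 1))
  expect_gt(mean(g_helix), stats::qchisq(0.999, df = 1))

  # open_fraction 0: co-modification consistent with independence
  sim0 <- simulate_reads(p0, 150000, seed = 42)
  cont0 <- window_contingency(sim0, length(toy$structure))
  hp0 <- cont0[cont0$i == 13 & cont0$j == 54, ]
  g0 <- g_statistic(hp0$n11, hp0$n10, hp0$n01, hp0$n00)
  expect_lt(g0, stats::qchisq(0.9999, df = 1))
})

test_that("simulation is reproducible and untreated controls are inert", {
  s <- toy_hairpin()
  a <- simulate_reads(sim_params(s), 500, seed = 7)
  b <- simulate_reads(sim_params(s), 500, seed = 7)
  expect_identical(a$events, b$events)

  un <- simulate_reads(untreated_params(sim_params(s)), 5000, seed = 8)
  expect_true(all(un$events$cause %in% c("bg_sub", "bg_indel")))
})
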