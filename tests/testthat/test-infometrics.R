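test_that("auroc follows the Mann-Whitney convention", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_true(is.na(auroc(1:5, rep(TRUE, 5))))

  set.seed(21)
  for (k in 1:100) {
    v <- stats::rnorm(40)
    lab <- stats::runif(40) < 0.4
    if (!any(lab) || all(lab)) next
    expect_equal(auroc(v, lab), brute_auroc(v, lab))
    # invariant under strictly increasing transforms
    expect_equal(auroc(exp(v) + v, lab), auroc(v, lab))
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  v <- c(stats::rnorm(60, 1), stats::rnorm(80))
  lab <- rep(c(TRUE, FALSE), c(60, 80))
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = v,
                                        direction = "<", quiet = TRUE)))
  expect_equal(auroc(v, lab), ref, tolerance = 1e-12)
})

test_that("structural information hits its analytic anchor points", {
  m <- flat_gamma_model()
  # identical likelihoods: no information
  expect_equal(structural_information(c(0.01, 0.2, 1.5), m, m), rep(0, 3))

  # disjoint supports: perfect information
  paired <- point_mass_model()      # all mass at r <= 0
  unpaired <- flat_gamma_model()    # all mass at r > 0
  expect_equal(structural_information(0, paired, unpaired), 1,
               tolerance = 1e-9)
  expect_equal(structural_information(0.5, paired, unpaired), 1,
               tolerance = 1e-9)

  # posterior p(b|r) = 0.25 gives SI = 1 - H(0.25): encode the 1:3 density
  # ratio at r = 0 through the zero-mass point components
  pb2 <- gamma_mixture(c(0.75, 0), c(1, 1), c(1, 1), zero_mass = 0.25)
  pu2 <- gamma_mixture(c(0.25, 0), c(1, 1), c(1, 1), zero_mass = 0.75)
  expect_equal(posterior_paired(0, pb2, pu2), 0.25)
  si_expected <- 1 - (-0.25 * log2(0.25) - 0.75 * log2(0.75))
  expect_equal(structural_information(0, pb2, pu2), si_expected,
               tolerance = 1e-12)
  expect_equal(si_expected, 0.18872187554, tolerance = 1e-9)

  # invariant to common rescaling of both densities
  a <- gamma_mixture(c(0.3, 0.7), c(1, 4), c(0.1, 0.3))
  b <- gamma_mixture(c(0.5, 0.5), c(2, 2), c(0.2, 0.2))
  r <- seq(0.05, 2, length.out = 20)
  pa <- dgamma_mixture(r, a)
  pu <- dgamma_mixture(r, b)
  manual <- function(db, du) {
    p <- db / (db + du)
    h <- function(x) ifelse(x <= 0 | x >= 1, 0, -x * log2(x))
    1 - h(p) - h(1 - p)
  }
  expect_equal(structural_information(r, a, b), manual(pa, pu))
  expect_equal(manual(7 * pa, 7 * pu), manual(pa, pu))
})

test_that("gamma mixture density integrates to its continuous mass", {
  g <- gamma_mixture(c(0.4, 0.4), c(1.5, 6), c(0.05, 0.2), zero_mass = 0.2)
  mass <- stats::integrate(function(x) dgamma_mixture(x, g), 0, Inf,
                           rel.tol = 1e-9)$value
  expect_equal(mass, 0.8, tolerance = 1e-6)
})

test_that("EM recovers known mixture parameters", {
  set.seed(31)
  true_w <- c(0.65, 0.35)
  true_shape <- c(1.2, 6)
  true_scale <- c(0.08, 0.25)
  n <- 5000
  comp <- sample(1:2, n, replace = TRUE, prob = true_w)
  x <- stats::rgamma(n, shape = true_shape[comp], scale = true_scale[comp])
  fit <- fit_gamma_mixture(x, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$zero_mass, 0)
  ord <- order(fit$shapes * fit$scales)
  expect_equal(fit$weights[ord], true_w[order(true_shape * true_scale)],
               tolerance = 0.15)
  got_means <- (fit$shapes * fit$scales)[ord]
  want_means <- sort(true_shape * true_scale)
  expect_true(all(abs(got_means - want_means) / want_means < 0.15))
})

test_that("EM handles nested and degenerate inputs", {
  set.seed(32)
  x <- stats::rgamma(2000, shape = 3, scale = 0.1)
  fit <- fit_gamma_mixture(x, seed = 1)
  expect_gte(max(fit$weights), 0.9 * sum(fit$weights))
  # single-gamma oracle: pooled mixture mean matches an independent MLE fit
  skip_if_not_installed("fitdistrplus")
  ref <- fitdistrplus::fitdist(x, "gamma")
  ref_mean <- ref$estimate[["shape"]] / ref$estimate[["rate"]]
  expect_equal(sum(fit$weights * fit$shapes * fit$scales) / sum(fit$weights),
               ref_mean, tolerance = 0.02)

  expect_error(fit_gamma_mixture(rep(0.2, 100)), "degenerate")
  expect_error(fit_gamma_mixture(stats::rgamma(30, 2, 1)), ">= 50")
})

test_that("zero mass is the empirical nonpositive fraction", {
  set.seed(33)
  x <- c(stats::rgamma(400, 2, scale = 0.1), rep(0, 60), rep(-0.01, 40))
  fit <- fit_gamma_mixture(x, seed = 2)
  expect_equal(fit$zero_mass, 0.2)
  expect_equal(sum(fit$weights) + fit$zero_mass, 1)
})

test_that("ESI spans its bounds and averages SI over the denominator", {
  s <- toy_long_structure()
  prof <- synthetic_profile(s, stats::runif(length(s), 0, 1.5))
  same <- flat_gamma_model()
  models_same <- structure(
    setNames(lapply(c("A", "C", "G", "U"),
                    function(b) list(paired = same, unpaired = same)),
             c("A", "C", "G", "U")),
    class = "structure_models")
  expect_equal(expected_structural_information(prof, models_same)$esi, 0)

  # disjoint-support models: paired positions at r = 0, unpaired r > 0
  paired_mask <- s$pair_table != 0
  prof2 <- synthetic_profile(s, ifelse(paired_mask, 0, 0.5))
  models_sep <- structure(
    setNames(lapply(c("A", "C", "G", "U"),
                    function(b) list(paired = point_mass_model(),
                                     unpaired = flat_gamma_model())),
             c("A", "C", "G", "U")),
    class = "structure_models")
  res <- expected_structural_information(prof2, models_sep)
  expect_equal(res$esi, 1, tolerance = 1e-8)

  # two-base mode: G and U contribute zero but stay in the denominator
  frac_ac <- mean(strsplit(s$sequence, "")[[1]] %in% c("A", "C"))
  res2 <- expected_structural_information(prof2, models_sep,
                                          bases = c("A", "C"))
  expect_equal(res2$esi, frac_ac, tolerance = 1e-8)
  expect_lte(res2$esi, res$esi)  # four-base ESI >= two-base ESI
})

test_that("ESI is monotone in model separation", {
  s <- toy_long_structure()
  paired_mask <- s$pair_table != 0
  set.seed(41)
  prof <- synthetic_profile(s, ifelse(paired_mask,
                                      stats::rgamma(length(s), 2, scale = 0.05),
                                      stats::rgamma(length(s), 2, scale = 0.3)))
  esi_at_sep <- function(unpaired_scale) {
    m <- structure(
      setNames(lapply(c("A", "C", "G", "U"), function(b) {
        list(paired = flat_gamma_model(2, 0.05),
             unpaired = flat_gamma_model(2, unpaired_scale))
      }), c("A", "C", "G", "U")),
      class = "structure_models")
    expected_structural_information(prof, m)$esi
  }
  vals <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), esi_at_sep, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  expect_equal(vals[1], 0)
})

test_that("model serialization round-trips and tidiers summarize fits", {
  set.seed(55)
  x <- stats::rgamma(500, shape = 2, scale = 0.1)
  fit <- fit_gamma_mixture(c(x, rep(0, 50)), seed = 1)
  models <- structure(list(A = list(paired = fit, unpaired = fit)),
                      class = "structure_models")
  path <- withr::local_tempfile(fileext = ".json")
  write_models(models, path)
  back <- read_models(path)
  expect_equal(back$A$paired$weights, fit$weights)
  expect_equal(back$A$paired$shapes, fit$shapes)
  expect_equal(back$A$paired$zero_mass, fit$zero_mass)

  td <- generics::tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(td$mean, td$shape * td$scale)
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_equal(nrow(generics::tidy(models)), 4)
})
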