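#' Area under the ROC curve for pairing-status discrimination
#'
#' Rank-based (Mann-Whitney) AUROC with unpaired as the positive class:
#' the probability that a randomly chosen unpaired position scores higher
#' than a randomly chosen paired one, with ties counted half.
#'
#' @param values Per-position scores (e.g. background-subtracted rates).
#' @param is_unpaired Logical, TRUE where the position is unpaired.
#' @param mask Optional logical; FALSE positions are dropped first.
#' @return AUROC in [0,1], or `NA` if one class is empty after masking.
#' @export
auroc <- function(values, is_unpaired, mask = NULL) {
  keep <- !is.na(values) & !is.na(is_unpaired)
  if (!is.null(mask)) keep <- keep & mask
  v <- values[keep]
  pos <- is_unpaired[keep]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(v)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-component gamma mixture with a zero mass
#'
#' @param weights Two nonnegative continuous-component weights; together
#'   with `zero_mass` they sum to 1.
#' @param shapes,scales Positive gamma parameters per component.
#' @param zero_mass Probability mass at reactivities <= 0.
#' @return An object of class `gamma_mixture`.
#' @export
gamma_mixture <- function(weights, shapes, scales, zero_mass = 0) {
  stopifnot(length(weights) == 2, length(shapes) == 2, length(scales) == 2,
            all(weights >= 0), all(shapes > 0), all(scales > 0),
            zero_mass >= 0, zero_mass <= 1)
  tot <- sum(weights) + zero_mass
  if (abs(tot - 1) > 1e-6) stop("weights + zero_mass must sum to 1")
  structure(list(weights = weights, shapes = shapes, scales = scales,
                 zero_mass = zero_mass, loglik = NA_real_,
                 n_iter = NA_integer_, converged = NA),
            class = "gamma_mixture")
}

#' @export
print.gamma_mixture <- function(x, ...) {
  cat("<gamma_mixture> zero mass ", signif(x$zero_mass, 3), "\n", sep = "")
  for (k in 1:2) {
    cat(sprintf("  component %d: weight %.4f, shape %.4f, scale %.5f\n",
                k, x$weights[k], x$shapes[k], x$scales[k]))
  }
  invisible(x)
}

#' Mixture density over the whole reactivity line
#'
#' For r > 0, the weighted sum of the two gamma densities (integrating to
#' the continuous mass); for r <= 0, the zero-mass point probability is
#' returned so likelihood comparisons are defined on the whole line.
#'
#' @param r Numeric vector of reactivities.
#' @param model A [gamma_mixture()].
#' @return Density / point-mass values, same length as `r`.
#' @export
dgamma_mixture <- function(r, model) {
  out <- numeric(length(r))
  pos <- !is.na(r) & r > 0
  if (any(pos)) {
    out[pos] <- model$weights[1] *
      stats::dgamma(r[pos], shape = model$shapes[1], scale = model$scales[1]) +
      model$weights[2] *
      stats::dgamma(r[pos], shape = model$shapes[2], scale = model$scales[2])
  }
  out[!is.na(r) & r <= 0] <- model$zero_mass
  out[is.na(r)] <- NA_real_
  out
}

# weighted gamma MLE via Newton iteration on log(a) - digamma(a) = s
gamma_mle_weighted <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  s <- log(m) - sum(w * log(x))
  s <- max(s, 1e-8)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (iter in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  a <- min(max(a, 1e-3), 1e6)
  list(shape = a, scale = m / a)
}

#' Fit a double-gamma mixture to reactivity data
#'
#' The zero mass is the empirical fraction of values <= 0; a two-component
#' gamma mixture is fit to the positive values by EM with quantile-split
#' initialization and seeded restarts, keeping the best log-likelihood.
#' This is the likelihood family used for per-class reactivity
#' distributions in structure-information and pseudo-energy analysis.
#'
#' @param values Reactivity sample (>= 50 values, >= 20 positive).
#' @param seed Optional integer seed controlling the restart order.
#' @param n_restarts Number of initializations (default 5).
#' @param tol Convergence tolerance on mean log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @return A fitted [gamma_mixture()] with `loglik`, `n_iter`, `converged`.
#' @export
fit_gamma_mixture <- function(values, seed = NULL, n_restarts = 5,
                              tol = 1e-6, max_iter = 2000) {
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  if (length(values) < 50 || length(pos) < 20) {
    stop("need >= 50 values with >= 20 positive (got ", length(values),
         " / ", length(pos), ")")
  }
  if (stats::sd(pos) < 1e-12 * mean(pos)) {
    stop("degenerate input: positive values are (near-)identical")
  }
  zero_mass <- mean(values <= 0)
  if (!is.null(seed)) {
    old <- .Random.seed_safe()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  # the near-degenerate first split makes nested (single-gamma) data land
  # on a collapsed fit; later splits only replace it on a real likelihood
  # gain, not a tie
  splits <- c(0.95, 0.5, 0.3, 0.7, 0.6, stats::runif(max(0, n_restarts - 5)))
  splits <- splits[seq_len(max(n_restarts, 1))]
  best <- NULL
  for (q in splits) {
    cut <- stats::quantile(pos, q, names = FALSE)
    grp <- pos > cut
    if (sum(grp) < 3 || sum(!grp) < 3) grp <- pos > stats::median(pos)
    if (sum(grp) < 3 || sum(!grp) < 3) next
    init <- list(
      pi = c(mean(!grp), mean(grp)),
      comp = list(gamma_mle_weighted(pos[!grp], rep(1, sum(!grp))),
                  gamma_mle_weighted(pos[grp], rep(1, sum(grp))))
    )
    fit <- tryCatch(
      em_gamma_mixture(pos, init, tol = tol, max_iter = max_iter),
      error = function(e) NULL
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$loglik > best$loglik + tol * length(pos))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("gamma mixture EM failed for all initializations")
  out <- gamma_mixture(best$pi * (1 - zero_mass),
                       c(best$comp[[1]]$shape, best$comp[[2]]$shape),
                       c(best$comp[[1]]$scale, best$comp[[2]]$scale),
                       zero_mass = zero_mass)
  out$loglik <- best$loglik
  out$n_iter <- best$n_iter
  out$converged <- best$converged
  if (!best$converged) {
    warning("EM did not reach tolerance within ", max_iter,
            " iterations; returning best-so-far fit")
  }
  out
}

em_gamma_mixture <- function(x, init, tol, max_iter) {
  n <- length(x)
  pi_k <- init$pi
  comp <- init$comp
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- pi_k[1] * stats::dgamma(x, shape = comp[[1]]$shape,
                                  scale = comp[[1]]$scale)
    d2 <- pi_k[2] * stats::dgamma(x, shape = comp[[2]]$shape,
                                  scale = comp[[2]]$scale)
    tot <- pmax(d1 + d2, 1e-300)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) / n < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- d1 / tot
    w1 <- sum(r1)
    if (w1 < 1e-8 || n - w1 < 1e-8) stop("component collapsed")
    pi_k <- c(w1, n - w1) / n
    comp <- list(gamma_mle_weighted(x, r1), gamma_mle_weighted(x, 1 - r1))
  }
  # order components by mean so parameterization is stable
  ord <- order(c(comp[[1]]$shape * comp[[1]]$scale,
                 comp[[2]]$shape * comp[[2]]$scale))
  list(pi = pi_k[ord], comp = comp[ord], loglik = ll_old, n_iter = iter,
       converged = converged)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Posterior probability of pairing given a reactivity
#'
#' Equal-prior posterior p(b|r) = p(r|b) / (p(r|b) + p(r|u)), with the
#' zero-mass point components handling r <= 0 and a 1e-12 density floor
#' guarding against 0/0.
#'
#' @param r Reactivity values.
#' @param paired_model,unpaired_model Fitted [gamma_mixture()] models.
#' @return p(paired | r), same length as `r`.
#' @export
posterior_paired <- function(r, paired_model, unpaired_model) {
  db <- pmax(dgamma_mixture(r, paired_model), 1e-12)
  du <- pmax(dgamma_mixture(r, unpaired_model), 1e-12)
  db / (db + du)
}

#' Per-position structural information (bits)
#'
#' SI(r) = 1 - H(s | r), the reduction in Shannon entropy of a position's
#' pairing status achieved by observing reactivity r, where the posterior
#' comes from the paired and unpaired likelihoods evaluated at r. SI is 0
#' when the two likelihoods agree (no information) and 1 when only one
#' class has support at r (perfect information).
#'
#' @inheritParams posterior_paired
#' @return SI values in [0,1] bits.
#' @export
structural_information <- function(r, paired_model, unpaired_model) {
  p <- posterior_paired(r, paired_model, unpaired_model)
  h <- function(x) ifelse(x <= 0 | x >= 1, 0, -x * log2(x))
  si <- 1 - (h(p) + h(1 - p))
  pmin(pmax(si, 0), 1)
}

#' Fit paired/unpaired reactivity models per nucleotide type
#'
#' Splits a normalized profile's reactivities by pairing status from a
#' known structure and fits a [gamma_mixture()] to each (base, class)
#' sample.
#'
#' @param profile Normalized `dms_profile` with `reactivity` and `mask`.
#' @param structure An [rna_structure()] of matching length.
#' @param bases Nucleotide types to fit (default all four).
#' @param seed Optional seed passed to [fit_gamma_mixture()].
#' @param min_n Minimum usable positions per (base, class); a base failing
#'   this in either class is omitted with a warning. Default 50.
#' @return A named list of `list(paired, unpaired)` per base, class
#'   `structure_models`.
#' @export
fit_structure_models <- function(profile, structure, bases = c("A", "C", "G", "U"),
                                 seed = NULL, min_n = 50) {
  stopifnot(inherits(structure, "rna_structure"))
  if (nrow(profile) != length(structure)) {
    stop("profile and structure lengths differ")
  }
  paired <- structure$pair_table != 0L
  models <- list()
  for (b in bases) {
    sel <- profile$base == b & profile$mask & !is.na(profile$reactivity)
    vb <- profile$reactivity[sel & paired]
    vu <- profile$reactivity[sel & !paired]
    if (length(vb) < min_n || length(vu) < min_n) {
      warning("insufficient data to fit models for ", b, " (paired n=",
              length(vb), ", unpaired n=", length(vu), "); omitted")
      next
    }
    fits <- tryCatch(
      list(paired = fit_gamma_mixture(vb, seed = seed),
           unpaired = fit_gamma_mixture(vu, seed = seed)),
      error = function(e) {
        warning("insufficient data to fit models for ", b, " (",
                conditionMessage(e), "); omitted")
        NULL
      }
    )
    if (!is.null(fits)) models[[b]] <- fits
  }
  structure(models, class = "structure_models")
}

#' Expected structural information of a probing experiment
#'
#' ESI is the mean per-position SI over all usable (unmasked) positions,
#' in bits: 0 means the data carry no pairing information, 1 means every
#' position's status is perfectly specified. In two-base mode
#' (`bases = c("A","C")`) positions of the excluded bases contribute
#' SI = 0 but stay in the denominator, so two-base ESI is directly
#' comparable to four-base ESI on the same RNA.
#'
#' @param profile Normalized `dms_profile`.
#' @param models A `structure_models` object ([fit_structure_models()]).
#' @param bases Bases whose SI is evaluated; others contribute 0.
#' @return An `esi_result`: list with `si` (per-position tibble), `esi`
#'   (mean SI in bits), `n_used`.
#' @export
expected_structural_information <- function(profile, models,
                                            bases = c("A", "C", "G", "U")) {
  stopifnot(inherits(models, "structure_models"))
  usable <- profile$mask & !is.na(profile$reactivity)
  if (!any(usable)) stop("no unmasked positions with reactivity data")
  si <- rep(0, nrow(profile))
  for (b in intersect(bases, names(models))) {
    sel <- usable & profile$base == b
    if (!any(sel)) next
    si[sel] <- structural_information(profile$reactivity[sel],
                                      models[[b]]$paired,
                                      models[[b]]$unpaired)
  }
  tbl <- tibble::tibble(
    position = profile$position, base = profile$base,
    reactivity = profile$reactivity,
    si = ifelse(usable, si, NA_real_), used = usable
  )
  structure(list(si = tbl, esi = mean(si[usable]), n_used = sum(usable),
                 bases = bases),
            class = "esi_result")
}

#' @export
print.esi_result <- function(x, ...) {
  cat(sprintf("<esi_result> ESI = %.4f bits over %d positions (bases %s)\n",
              x$esi, x$n_used, paste(x$bases, collapse = "")))
  invisible(x)
}

#' Write a per-position SI report
#'
#' TSV of position, base, SI plus a trailing summary comment line.
#'
#' @param x An `esi_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esi <- function(x, path) {
  readr::write_tsv(x$si[, c("position", "base", "si")], path, progress = FALSE)
  cat(sprintf("# ESI\t%.6f\tn_used\t%d\n", x$esi, x$n_used),
      file = path, append = TRUE)
  invisible(path)
}

#' Serialize structure models to JSON
#'
#' @param models A `structure_models` (or `potential_table`) object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  ser <- lapply(unclass(models), function(m) {
    lapply(m[c("paired", "unpaired")], function(g) {
      list(weights = g$weights, shapes = g$shapes, scales = g$scales,
           zero_mass = g$zero_mass)
    })
  })
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read structure models from JSON
#'
#' @param path Path written by [write_models()].
#' @return A `structure_models` object.
#' @export
read_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(raw, function(m) {
    lapply(m, function(g) {
      gamma_mixture(g$weights, g$shapes, g$scales, zero_mass = g$zero_mass)
    })
  })
  structure(models, class = "structure_models")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.gamma_mixture <- function(x, ...) {
  tibble::tibble(component = 1:2, weight = x$weights, shape = x$shapes,
                 scale = x$scales, mean = x$shapes * x$scales)
}

#' @exportS3Method generics::glance
glance.gamma_mixture <- function(x, ...) {
  tibble::tibble(zero_mass = x$zero_mass, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.esi_result <- function(x, ...) x$si

#' @exportS3Method generics::glance
glance.esi_result <- function(x, ...) {
  tibble::tibble(esi = x$esi, n_used = x$n_used,
                 bases = paste(x$bases, collapse = ""))
}

#' @exportS3Method generics::tidy
tidy.structure_models <- function(x, ...) {
  purrr::map_dfr(names(x), function(b) {
    purrr::map_dfr(c("paired", "unpaired"), function(cls) {
      dplyr::mutate(tidy(x[[b]][[cls]]), base = b, class = cls,
                    .before = 1)
    })
  })
}
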