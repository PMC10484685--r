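#' Background-subtracted DMS modification rates
#'
#' Computes the per-position DMS modification rate as the difference between
#' the modified-sample and untreated-control mutation rates, or as the
#' modified-sample rate alone when no control is supplied. Positions failing
#' depth or background quality control are masked (rather than propagating
#' NaN). Negative background-subtracted rates are retained, not clamped.
#'
#' @param treated Counts tibble from [count_profile()] for the DMS-treated
#'   sample.
#' @param untreated Optional counts tibble for the untreated control.
#' @param min_depth Positions with effective depth below this (in either
#'   sample) are masked. Default 1000, the conventional MaP depth floor.
#' @param max_background Positions whose untreated rate exceeds this are
#'   masked (default 0.05).
#' @return A tibble (`dms_profile`) with `position`, `base`, `treated_rate`,
#'   `untreated_rate`, `mod_rate`, `mask` (TRUE = usable data).
#' @export
modification_rate <- function(treated, untreated = NULL, min_depth = 1000,
                              max_background = 0.05) {
  n <- nrow(treated)
  if (!is.null(untreated) && nrow(untreated) != n) {
    stop("treated and untreated tables have different lengths")
  }
  rate <- function(cnt) ifelse(cnt$effective_depth > 0,
                               cnt$retained_mut / cnt$effective_depth,
                               NA_real_)
  treated_rate <- rate(treated)
  mask <- treated$effective_depth >= min_depth & !is.na(treated_rate) &
    treated$base != "N"
  if (is.null(untreated)) {
    untreated_rate <- rep(NA_real_, n)
    mod_rate <- treated_rate
  } else {
    untreated_rate <- rate(untreated)
    mask <- mask & untreated$effective_depth >= min_depth &
      !is.na(untreated_rate) & untreated_rate <= max_background
    mod_rate <- treated_rate - untreated_rate
  }
  mod_rate[!mask] <- NA_real_
  out <- tibble::tibble(
    position = treated$position, base = treated$base,
    treated_rate = treated_rate, untreated_rate = untreated_rate,
    mod_rate = mod_rate, mask = mask
  )
  class(out) <- c("dms_profile", class(out))
  out
}

#' Nucleotide-specific normalization factor
#'
#' For one nucleotide type, N_n = max{ mean of modification rates lying in
#' the 90th-95th percentile band, 75th percentile of rates > 0.001 }.
#' The percentile-band mean makes the factor robust for mostly-unreactive
#' RNAs (e.g. rRNA); the floored 75th-percentile term keeps it anchored
#' when the reactive tail is sparse. Percentiles use linear interpolation
#' between closest ranks (`stats::quantile` type 7). If no rate exceeds
#' 0.001, the band mean alone is used; if the band itself is empty, it
#' falls back to the interpolated 92.5th percentile.
#'
#' @param rates Numeric vector of unmasked modification rates for one
#'   nucleotide type. At least 10 values are required.
#' @return A single positive normalization factor.
#' @export
normalization_factor <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (length(rates) < 10) {
    stop("need at least 10 unmasked rates to normalize (got ",
         length(rates), ")")
  }
  if (all(rates <= 0)) stop("all modification rates are <= 0")
  qs <- stats::quantile(rates, c(0.90, 0.95), type = 7, names = FALSE)
  band <- rates[rates >= qs[1] & rates <= qs[2]]
  term1 <- if (length(band) > 0) mean(band) else
    stats::quantile(rates, 0.925, type = 7, names = FALSE)
  above <- rates[rates > 0.001]
  if (length(above) == 0) return(term1)
  term2 <- stats::quantile(above, 0.75, type = 7, names = FALSE)
  max(term1, term2)
}

#' Normalize a modification-rate profile per nucleotide type
#'
#' Divides each position's modification rate by its nucleotide type's
#' normalization factor, yielding reactivities on the conventional ~0-1
#' scale. Factors are computed per profile (per RNA); pass `factors` to
#' reuse factors pooled from other transcripts. A nucleotide type whose
#' factor cannot be computed has all its positions masked, with a warning.
#'
#' @param profile A `dms_profile` tibble from [modification_rate()].
#' @param factors Optional named numeric vector of per-base factors
#'   (names among A, C, G, U) overriding per-profile computation.
#' @return The profile with `norm_factor` and `reactivity` columns added.
#' @export
normalize_reactivity <- function(profile, factors = NULL) {
  out <- profile
  out$norm_factor <- NA_real_
  out$reactivity <- NA_real_
  for (b in intersect(c("A", "C", "G", "U"), unique(out$base))) {
    sel <- out$base == b
    nf <- if (!is.null(factors) && b %in% names(factors)) {
      factors[[b]]
    } else {
      tryCatch(normalization_factor(out$mod_rate[sel & out$mask]),
               error = function(e) NA_real_)
    }
    if (is.na(nf) || nf <= 0) {
      warning("no normalization factor computable for ", b,
              "; masking its positions")
      out$mask[sel] <- FALSE
      next
    }
    out$norm_factor[sel] <- nf
    out$reactivity[sel] <- out$mod_rate[sel] / nf
  }
  out$reactivity[!out$mask] <- NA_real_
  out
}

#' Write a normalized profile as a .dms text file
#'
#' Whitespace-delimited columns: 1-based position, nucleotide, normalized
#' reactivity. Masked positions carry the no-data sentinel -999.
#'
#' @param profile Normalized `dms_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dms <- function(profile, path) {
  val <- ifelse(profile$mask & !is.na(profile$reactivity),
                sprintf("%.6f", profile$reactivity), "-999")
  writeLines(paste(profile$position, profile$base, val, sep = "\t"), path)
  invisible(path)
}

#' Read a .dms reactivity file
#'
#' @param path Path to a `.dms` file written by [write_dms()] (or any
#'   whitespace-delimited position/base/reactivity file using -999 as the
#'   no-data sentinel).
#' @return A `dms_profile` tibble with `position`, `base`, `reactivity`,
#'   `mask`.
#' @export
read_dms <- function(path) {
  tbl <- utils::read.table(path, col.names = c("position", "base", "reactivity"),
                           colClasses = c("integer", "character", "numeric"))
  mask <- tbl$reactivity > -990
  out <- tibble::tibble(
    position = tbl$position,
    base = toupper(gsub("T", "U", toupper(tbl$base))),
    reactivity = ifelse(mask, tbl$reactivity, NA_real_),
    mask = mask
  )
  class(out) <- c("dms_profile", class(out))
  out
}

#' Reactivity profile bar plot
#'
#' @param profile A `dms_profile` with a `reactivity` column.
#' @return A ggplot object: per-position reactivity colored by base.
#' @export
plot_reactivity <- function(profile) {
  df <- profile[profile$mask & !is.na(profile$reactivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$reactivity,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "Position", y = "Normalized reactivity", fill = NULL) +
    ggplot2::theme_classic()
}
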