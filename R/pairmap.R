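#' Co-modification contingency counts for all 3-nt window pairs
#'
#' Single-molecule counting substrate for PAIR analysis. For every ordered
#' pair of non-overlapping 3-nt windows (starts i and j with i + 2 < j),
#' reads jointly covering both windows with valid (post-filter) data are
#' cross-tabulated by whether each window carries at least one retained
#' mutation: n11 (both modified), n10, n01, n00.
#'
#' @param x A [read_set()].
#' @param length Target sequence length (must be >= 6).
#' @param window Window width (default 3).
#' @param mode Signature-filter mode passed to [classify_events()].
#' @param chunk Reads per block for the matrix cross-products.
#' @return Tibble with `i`, `j` (window starts), `n11`, `n10`, `n01`,
#'   `n00`.
#' @export
window_contingency <- function(x, length, window = 3L, mode = c("dms", "unfiltered"),
                               chunk = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "read_set"))
  n <- as.integer(length)
  if (is.null(chunk)) chunk <- max(1000L, as.integer(4e6 / n))
  if (n < 2L * window) stop("target length must be at least ", 2L * window)
  nw <- n - window + 1L
  wmat <- matrix(0, n, nw)
  for (k in seq_len(window)) wmat[cbind(seq_len(nw) + k - 1L, seq_len(nw))] <- 1

  status <- classify_events(x$events, mode)
  ev <- x$events
  nd <- ev[status == "no_data", , drop = FALSE]
  mut <- ev[status == "retained", , drop = FALSE]

  n11 <- n10 <- tot <- matrix(0, nw, nw)
  reads <- x$reads
  starts <- seq(1L, max(nrow(reads), 1L), by = chunk)
  cols <- seq_len(n)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(reads))
    nr <- length(idx)
    rowmap <- integer(max(reads$read))
    rowmap[reads$read[idx]] <- seq_len(nr)
    valid <- matrix(rep(cols, each = nr), nr, n)
    valid <- valid >= reads$span_start[idx] & valid <= reads$span_end[idx]
    sub_nd <- nd[nd$read %in% reads$read[idx], , drop = FALSE]
    if (nrow(sub_nd) > 0) {
      len <- sub_nd$right - sub_nd$left + 1L
      rr <- rowmap[rep(sub_nd$read, len)]
      pp <- rep(sub_nd$left, len) + sequence(len) - 1L
      valid[cbind(rr, pp)] <- FALSE
    }
    m <- matrix(FALSE, nr, n)
    sub_mut <- mut[mut$read %in% reads$read[idx], , drop = FALSE]
    if (nrow(sub_mut) > 0) {
      len <- sub_mut$right - sub_mut$left + 1L
      rr <- rowmap[rep(sub_mut$read, len)]
      pp <- rep(sub_mut$left, len) + sequence(len) - 1L
      m[cbind(rr, pp)] <- TRUE
    }
    storage.mode(valid) <- "double"
    storage.mode(m) <- "double"
    cw <- (valid %*% wmat) == window          # window fully covered
    mw <- ((m %*% wmat) > 0) & cw             # covered and modified
    storage.mode(cw) <- "double"
    storage.mode(mw) <- "double"
    n11 <- n11 + crossprod(mw)
    n10 <- n10 + crossprod(mw, cw - mw)
    tot <- tot + crossprod(cw)
  }
  keep <- which(upper.tri(tot) & (col(tot) - row(tot)) >= window, arr.ind = TRUE)
  n01 <- t(n10)
  v11 <- as.integer(n11[keep])
  v10 <- as.integer(n10[keep])
  v01 <- as.integer(n01[keep])
  v00 <- as.integer((tot - n11 - n10 - n01)[keep])
  tibble::tibble(i = keep[, 1], j = keep[, 2],
                 n11 = v11, n10 = v10, n01 = v01, n00 = v00) |>
    dplyr::arrange(.data$i, .data$j)
}

#' G-test statistic of independence for 2x2 contingency counts
#'
#' Likelihood-ratio test (df = 1), no continuity or Williams correction.
#' Zero cells contribute zero to the statistic.
#'
#' @param n11,n10,n01,n00 Vectors of cell counts.
#' @return G statistics (nonnegative; 0 when rows are proportional).
#' @export
g_statistic <- function(n11, n10, n01, n00) {
  n11 <- as.numeric(n11)
  n10 <- as.numeric(n10)
  n01 <- as.numeric(n01)
  n00 <- as.numeric(n00)
  n <- n11 + n10 + n01 + n00
  r1 <- n11 + n10
  c1 <- n11 + n01
  term <- function(o, e) ifelse(o > 0 & e > 0, o * log(o / e), 0)
  g <- 2 * (term(n11, r1 * c1 / n) +
            term(n10, r1 * (n - c1) / n) +
            term(n01, (n - r1) * c1 / n) +
            term(n00, (n - r1) * (n - c1) / n))
  ifelse(n > 0, pmax(g, 0), 0)
}

# Watson-Crick or GU wobble complementarity
is_complementary <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# count complementary positions of two 3-nt windows in antiparallel register
window_complementarity <- function(i, j, bases, window = 3L) {
  cnt <- integer(length(i))
  for (k in seq_len(window) - 1L) {
    cnt <- cnt + is_complementary(bases[i + k], bases[j + window - 1L - k])
  }
  cnt
}

#' Detect and classify PAIR correlations between 3-nt windows
#'
#' Window pairs with at least `min_comod` co-modification events are tested
#' for statistical dependence with a 2x2 G-test (df = 1), Bonferroni
#' corrected across every evaluable window pair. Significant pairs must be
#' sequence
#' complementary (>= 2 of 3 Watson-Crick/GU matches in antiparallel
#' register). Surviving correlations are classified by window mean
#' normalized reactivity: minor PAIRs require both windows >= 0.2;
#' principal PAIRs additionally require both windows >= 0.4 and that the
#' two windows are mutually each other's strongest significant partner.
#' Windows overlapping masked reactivity positions are excluded entirely.
#'
#' @param pairs Contingency tibble from [window_contingency()].
#' @param profile Normalized `dms_profile` (needs `reactivity`, `mask`).
#' @param sequence Target sequence.
#' @param alpha Family-wise significance level after Bonferroni (default 0.05).
#' @param min_comod Minimum co-modification count n11 (default 10).
#' @param min_react_minor,min_react_principal Window mean-reactivity gates
#'   (defaults 0.2 and 0.4).
#' @param window Window width (default 3).
#' @return The pair tibble with `g_stat`, `p`, `corrected_p`, `comp_ok`,
#'   `react_i`, `react_j`, `class` (`principal`/`minor`/`rejected`), and a
#'   `reason` for rejected pairs.
#' @export
pair_correlations <- function(pairs, profile, sequence, alpha = 0.05,
                              min_comod = 10L, min_react_minor = 0.2,
                              min_react_principal = 0.4, window = 3L) {
  sequence <- toupper(gsub("T", "U", toupper(sequence)))
  bases <- strsplit(sequence, "")[[1]]
  n <- length(bases)
  nw <- n - window + 1L
  wreact <- wok <- rep(NA_real_, nw)
  react <- profile$reactivity
  mask <- profile$mask & !is.na(react)
  for (w in seq_len(nw)) {
    span <- w:(w + window - 1L)
    if (all(mask[span])) wreact[w] <- mean(react[span])
  }
  out <- pairs
  out$g_stat <- g_statistic(out$n11, out$n10, out$n01, out$n00)
  out$react_i <- wreact[out$i]
  out$react_j <- wreact[out$j]
  windows_ok <- !is.na(out$react_i) & !is.na(out$react_j)
  tested <- out$n11 >= min_comod & windows_ok
  out$p <- NA_real_
  out$p[tested] <- stats::pchisq(out$g_stat[tested], df = 1,
                                 lower.tail = FALSE)
  # the Bonferroni family is every evaluable window pair, independent of
  # the co-modification cutoff, so the cutoff acts as a pure filter
  # (raising it can only remove PAIRs, never admit new ones)
  n_tests <- sum(windows_ok)
  out$corrected_p <- pmin(out$p * n_tests, 1)
  out$comp_ok <- window_complementarity(out$i, out$j, bases, window) >= 2
  sig <- tested & !is.na(out$corrected_p) & out$corrected_p <= alpha
  cand <- sig & out$comp_ok &
    pmin(out$react_i, out$react_j) >= min_react_minor

  # mutual-best among candidate correlations, by G statistic
  best_of <- rep(NA_real_, nw)
  if (any(cand)) {
    long <- rbind(
      data.frame(w = out$i[cand], g = out$g_stat[cand]),
      data.frame(w = out$j[cand], g = out$g_stat[cand])
    )
    agg <- tapply(long$g, long$w, max)
    best_of[as.integer(names(agg))] <- agg
  }
  mutual <- cand & out$g_stat >= best_of[out$i] - 1e-12 &
    out$g_stat >= best_of[out$j] - 1e-12

  out$class <- "rejected"
  out$class[cand] <- "minor"
  out$class[mutual & pmin(out$react_i, out$react_j) >= min_react_principal] <-
    "principal"
  out$reason <- dplyr::case_when(
    out$class != "rejected" ~ "",
    !windows_ok ~ "window masked",
    out$n11 < min_comod ~ "below co-modification cutoff",
    !sig ~ "not significant",
    !out$comp_ok ~ "not complementary",
    TRUE ~ "below reactivity threshold"
  )
  out
}

#' PAIR positive predictive value and sensitivity versus a known structure
#'
#' A reported PAIR is correct if any of its three implied antiparallel base
#' pairs (i+k, j+2-k) matches a pair of the accepted structure, allowing a
#' one-position register shift. Sensitivity is the fraction of accepted
#' helices (>= 3 bp, lying entirely in data-covered regions) hit by at
#' least one correct PAIR; ppv is the fraction of reported PAIRs that are
#' correct (NA when none are reported).
#'
#' @param pairs Classified tibble from [pair_correlations()]; rows with
#'   class `principal` or `minor` count as reported. Pass a pre-filtered
#'   tibble to score one class only.
#' @param structure Accepted [rna_structure()].
#' @param mask Optional logical data-coverage vector; helices touching a
#'   no-data position are excluded from the sensitivity denominator.
#' @param window Window width (default 3).
#' @return One-row tibble: `ppv`, `sens`, `n_reported`, `n_correct`,
#'   `n_helices`.
#' @export
pair_ppv_sens <- function(pairs, structure, mask = NULL, window = 3L) {
  stopifnot(inherits(structure, "rna_structure"))
  rep_pairs <- pairs[pairs$class %in% c("principal", "minor"), , drop = FALSE]
  hel <- structure_helices(structure)
  hel <- hel[hel$helix_len >= 3, , drop = FALSE]
  if (!is.null(mask) && nrow(hel) > 0) {
    ok <- tapply(mask[hel$i] & mask[hel$j], hel$helix, all)
    hel <- hel[hel$helix %in% as.integer(names(ok))[ok], , drop = FALSE]
  }
  acc_key <- paste(hel$i, hel$j)
  acc_helix <- hel$helix
  n_hel <- length(unique(acc_helix))

  hit_helices <- integer(0)
  n_correct <- 0L
  if (nrow(rep_pairs) > 0 && nrow(hel) > 0) {
    shifts <- list(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    for (r in seq_len(nrow(rep_pairs))) {
      found <- NA_integer_
      for (k in seq_len(window) - 1L) {
        a <- rep_pairs$i[r] + k
        b <- rep_pairs$j[r] + window - 1L - k
        for (s in shifts) {
          m <- match(paste(a + s[1], b + s[2]), acc_key)
          if (!is.na(m)) { found <- m; break }
        }
        if (!is.na(found)) break
      }
      if (!is.na(found)) {
        n_correct <- n_correct + 1L
        hit_helices <- c(hit_helices, acc_helix[found])
      }
    }
  }
  tibble::tibble(
    ppv = if (nrow(rep_pairs) == 0) NA_real_ else n_correct / nrow(rep_pairs),
    sens = if (n_hel == 0) NA_real_ else length(unique(hit_helices)) / n_hel,
    n_reported = nrow(rep_pairs), n_correct = n_correct, n_helices = n_hel
  )
}

#' Write a PAIR table TSV
#'
#' Columns i, j, n11, depth, g_stat, corrected_p, class — suitable for
#' arc-plot consumers.
#'
#' @param pairs Classified tibble from [pair_correlations()].
#' @param path Output path.
#' @param keep_rejected Include rejected pairs (default FALSE).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, keep_rejected = FALSE) {
  tbl <- pairs
  if (!keep_rejected) tbl <- tbl[tbl$class != "rejected", , drop = FALSE]
  tbl$depth <- tbl$n11 + tbl$n10 + tbl$n01 + tbl$n00
  readr::write_tsv(
    tbl[, c("i", "j", "n11", "depth", "g_stat", "corrected_p", "class")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Arc plot of PAIR correlations
#'
#' @param pairs Classified tibble from [pair_correlations()].
#' @param structure Optional accepted [rna_structure()] drawn as gray arcs
#'   above the axis.
#' @return A ggplot object.
#' @export
plot_pairs <- function(pairs, structure = NULL) {
  arcs <- function(tbl, ymax) {
    purrr::map_dfr(seq_len(nrow(tbl)), function(r) {
      t <- seq(0, pi, length.out = 40)
      mid <- (tbl$x1[r] + tbl$x2[r]) / 2
      rad <- abs(tbl$x2[r] - tbl$x1[r]) / 2
      tibble::tibble(arc = r, x = mid + rad * cos(t),
                     y = ymax * rad * sin(t) / max(rad, 1),
                     group = tbl$group[r])
    })
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Position", y = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.line.y = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
  if (!is.null(structure)) {
    sp <- structure_pairs(structure)
    if (nrow(sp) > 0) {
      ref <- tibble::tibble(x1 = sp$i, x2 = sp$j, group = "accepted")
      a <- arcs(ref, 1)
      p <- p + ggplot2::geom_path(
        data = a, ggplot2::aes(.data$x, .data$y,
                               group = .data$arc),
        color = "gray70", linewidth = 0.3)
    }
  }
  rep_pairs <- pairs[pairs$class %in% c("principal", "minor"), , drop = FALSE]
  if (nrow(rep_pairs) > 0) {
    tbl <- tibble::tibble(x1 = rep_pairs$i + 1, x2 = rep_pairs$j + 1,
                          group = rep_pairs$class)
    a <- arcs(tbl, -1)
    p <- p + ggplot2::geom_path(
      data = a,
      ggplot2::aes(.data$x, .data$y, group = .data$arc,
                   color = .data$group),
      linewidth = 0.6) +
      ggplot2::scale_color_manual(
        values = c(principal = "#1f5fa8", minor = "#8ab6e0"),
        name = "PAIR class")
  }
  p
}
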