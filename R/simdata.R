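#' Simulation parameters for synthetic DMS-MaP read sets
#'
#' Defines the generative model the pipeline assumes: per-molecule choice
#' of an ensemble state, per-nucleotide Bernoulli adduct formation
#' conditioned on pairing status, class-specific detection efficiencies and
#' mutation-type signatures, and background errors. Defaults encode the
#' chemistry of multiple-hit DMS probing read out by MaP: unpaired
#' Watson-Crick-face methylation rates of ~0.02 at A and C, 0.006 at U and
#' 0.001 at N1-G (paired positions 10-fold lower); pairing-insensitive
#' N7-G methylation at rate 0.5 of which only 2% is detected, read out as
#' G-to-A; N1-G read out as G-to-C/G-to-U.
#'
#' @param structures A single [rna_structure()] or list of them (ensemble
#'   states over one sequence).
#' @param weights Ensemble weights, summing to 1.
#' @param unpaired_rates Named adduct rates per molecule at unpaired
#'   positions; the `G` entry is the N1-G rate.
#' @param paired_fold Paired positions' rates are `unpaired_rates / paired_fold`.
#' @param n7g_rate N7-G adduct rate at every G regardless of pairing.
#' @param detect_eff Detection probability per adduct class
#'   (`A`, `C`, `U`, `n1g`, `n7g`).
#' @param signature_n1g Mutation-type multinomial for detected N1-G
#'   (names are alt bases).
#' @param signature_n7g Multinomial for detected N7-G.
#' @param bg_sub,bg_indel Background substitution / indel rate per position.
#' @param read_length Read length for the uniform-window fragmentation
#'   model; `NULL` (default) emits full-length molecules.
#' @return A `sim_params` object.
#' @export
sim_params <- function(structures, weights = NULL,
                       unpaired_rates = c(A = 0.02, C = 0.02, U = 0.006,
                                          G = 0.001),
                       paired_fold = 10,
                       n7g_rate = 0.5,
                       detect_eff = c(A = 1, C = 1, U = 1, n1g = 1,
                                      n7g = 0.02),
                       signature_n1g = c(C = 0.5, U = 0.5),
                       signature_n7g = c(A = 1),
                       bg_sub = 0.001, bg_indel = 0.002,
                       read_length = NULL) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1,
            all(vapply(structures, inherits, logical(1), "rna_structure")))
  if (is.null(weights)) weights <- rep(1 / length(structures),
                                       length(structures))
  if (length(weights) != length(structures) || abs(sum(weights) - 1) > 1e-8) {
    stop("ensemble weights must match the structures and sum to 1")
  }
  seqs <- vapply(structures, function(s) s$sequence, character(1))
  if (length(unique(seqs)) != 1) stop("ensemble states must share a sequence")
  rates <- c(unpaired_rates, n7g = unname(n7g_rate), bg_sub = unname(bg_sub),
             bg_indel = unname(bg_indel), detect_eff)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (abs(sum(signature_n1g) - 1) > 1e-8 || abs(sum(signature_n7g) - 1) > 1e-8) {
    stop("signature multinomials must sum to 1")
  }
  structure(list(
    structures = structures, weights = weights,
    unpaired_rates = unpaired_rates, paired_fold = paired_fold,
    n7g_rate = n7g_rate, detect_eff = detect_eff,
    signature_n1g = signature_n1g, signature_n7g = signature_n7g,
    bg_sub = bg_sub, bg_indel = bg_indel, read_length = read_length
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", length(x$structures), " ensemble state(s), ",
      nchar(x$structures[[1]]$sequence), " nt\n", sep = "")
  invisible(x)
}

#' Untreated-control version of simulation parameters
#'
#' Same generator with all adduct rates zero: only background errors are
#' emitted, as in an untreated MaP control.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_params` with zero adduct and N7-G rates.
#' @export
untreated_params <- function(params) {
  params$unpaired_rates[] <- 0
  params$n7g_rate <- 0
  params
}

# sample alt bases for a set of events given per-base multinomials
sample_alt <- function(base, sig_list) {
  out <- character(length(base))
  for (b in unique(base)) {
    idx <- which(base == b)
    probs <- sig_list[[b]]
    out[idx] <- sample(names(probs), length(idx), replace = TRUE,
                       prob = probs)
  }
  out
}

#' Simulate a parsed-mutation read set with ground truth
#'
#' For each molecule an ensemble state is drawn; adducts form per position
#' as independent Bernoulli events at rates set by nucleotide type and the
#' state's pairing status; each adduct is detected with its class
#' efficiency and emits a mutation drawn from its class signature;
#' background substitutions and indels are superimposed. At most one event
#' is emitted per position per read, with informative adducts taking
#' precedence over N7-G and background (N1-type > N7-G > background
#' substitution > background indel).
#'
#' @param params A [sim_params()] object.
#' @param n_reads Number of molecules.
#' @param seed Integer seed (required: simulations are reproducible).
#' @param chunk Reads per vectorized block; defaults to keeping each block's
#'   working matrices around a few million cells.
#' @return A [read_set()] whose events carry a `cause` column
#'   (`adduct_A/C/U`, `n1g`, `n7g`, `bg_sub`, `bg_indel`), with attributes
#'   `states` (per-read ensemble state tibble) and `params`.
#' @export
simulate_reads <- function(params, n_reads, seed, chunk = NULL) {
  stopifnot(inherits(params, "sim_params"), n_reads >= 1)
  set.seed(seed)
  seqc <- strsplit(params$structures[[1]]$sequence, "")[[1]]
  L <- length(seqc)
  if (is.null(chunk)) chunk <- max(1000L, as.integer(5e6 / L))
  n_states <- length(params$structures)
  paired_mat <- do.call(rbind, lapply(params$structures,
                                      function(s) s$pair_table != 0L))
  ru <- params$unpaired_rates[seqc]          # N1-type rate if unpaired
  rp <- ru / params$paired_fold
  ru[is.na(ru)] <- 0                          # N positions
  rp[is.na(rp)] <- 0
  det_base <- c(A = unname(params$detect_eff["A"]),
                C = unname(params$detect_eff["C"]),
                U = unname(params$detect_eff["U"]),
                G = unname(params$detect_eff["n1g"]))
  det_vec <- det_base[seqc]
  det_vec[is.na(det_vec)] <- 0
  is_g <- seqc == "G"
  sig_n1 <- list(A = c(C = 1/3, G = 1/3, U = 1/3),
                 C = c(A = 1/3, G = 1/3, U = 1/3),
                 U = c(A = 1/3, C = 1/3, G = 1/3),
                 G = params$signature_n1g)
  other_bases <- list(A = c("C", "G", "U"), C = c("A", "G", "U"),
                      G = c("A", "C", "U"), U = c("A", "C", "G"),
                      N = c("A", "C", "G", "U"))

  all_states <- integer(n_reads)
  ev_list <- list()
  reads_list <- list()
  starts <- seq(1L, n_reads, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, n_reads)
    nr <- length(idx)
    states <- if (n_states == 1) rep(1L, nr) else
      sample.int(n_states, nr, replace = TRUE, prob = params$weights)
    all_states[idx] <- states
    paired <- paired_mat[states, , drop = FALSE]

    rate <- matrix(ru, nr, L, byrow = TRUE)
    rate[paired] <- matrix(rp, nr, L, byrow = TRUE)[paired]
    n1 <- matrix(stats::runif(nr * L), nr, L) < rate
    n1 <- n1 & (matrix(stats::runif(nr * L), nr, L) <
                  matrix(det_vec, nr, L, byrow = TRUE))
    n7 <- matrix(FALSE, nr, L)
    if (any(is_g) && params$n7g_rate > 0) {
      gcols <- which(is_g)
      n7[, gcols] <- matrix(stats::runif(nr * length(gcols)),
                            nr, length(gcols)) <
        params$n7g_rate * unname(params$detect_eff["n7g"])
    }
    bsub <- matrix(stats::runif(nr * L), nr, L) < params$bg_sub
    bind <- matrix(stats::runif(nr * L), nr, L) < params$bg_indel
    # precedence: informative adduct > N7-G > background sub > indel
    n7 <- n7 & !n1
    bsub <- bsub & !n1 & !n7
    bind <- bind & !n1 & !n7 & !bsub

    # read spans (full-length or uniform windows)
    if (is.null(params$read_length) || params$read_length >= L) {
      span_start <- rep(1L, nr)
      span_end <- rep(L, nr)
    } else {
      span_start <- sample.int(L - params$read_length + 1L, nr,
                               replace = TRUE)
      span_end <- span_start + params$read_length - 1L
    }

    emit <- function(hits, maker, cause) {
      if (length(hits) == 0) return(NULL)
      rr <- ((hits - 1L) %% nr) + 1L
      pp <- ((hits - 1L) %/% nr) + 1L
      keep <- pp >= span_start[rr] & pp <= span_end[rr]
      rr <- rr[keep]; pp <- pp[keep]
      if (length(rr) == 0) return(NULL)
      ev <- maker(rr, pp)
      ev$read <- idx[rr]
      ev$cause <- if (length(cause) == 1) cause else cause[pp]
      ev
    }
    ev_n1 <- emit(which(n1), function(rr, pp) {
      tibble::tibble(left = pp, right = pp, ref = seqc[pp],
                     alt = sample_alt(seqc[pp], sig_n1))
    }, ifelse(is_g, "n1g", paste0("adduct_", seqc)))
    ev_n7 <- emit(which(n7), function(rr, pp) {
      tibble::tibble(left = pp, right = pp, ref = seqc[pp],
                     alt = sample_alt(seqc[pp],
                                      list(G = params$signature_n7g)))
    }, "n7g")
    ev_bs <- emit(which(bsub), function(rr, pp) {
      alt <- vapply(seqc[pp], function(b) sample(other_bases[[b]], 1),
                    character(1))
      tibble::tibble(left = pp, right = pp, ref = seqc[pp], alt = unname(alt))
    }, "bg_sub")
    ev_bi <- emit(which(bind), function(rr, pp) {
      is_del <- stats::runif(length(rr)) < 0.5
      alt <- ifelse(is_del, "",
                    sample(c("A", "C", "G", "U"), length(rr), replace = TRUE))
      tibble::tibble(left = pp, right = pp,
                     ref = ifelse(is_del, seqc[pp], ""), alt = alt)
    }, "bg_indel")
    ev_list[[length(ev_list) + 1L]] <- dplyr::bind_rows(ev_n1, ev_n7,
                                                        ev_bs, ev_bi)
    reads_list[[length(reads_list) + 1L]] <- tibble::tibble(
      read = idx, read_id = sprintf("sim_%07d", idx),
      span_start = span_start, span_end = span_end
    )
  }
  events <- dplyr::bind_rows(ev_list)
  if (nrow(events) == 0) {
    events <- tibble::tibble(read = integer(), left = integer(),
                             right = integer(), ref = character(),
                             alt = character(), cause = character())
  }
  out <- read_set(dplyr::bind_rows(reads_list),
                  events[, c("read", "left", "right", "ref", "alt", "cause")])
  attr(out, "states") <- tibble::tibble(read = seq_len(n_reads),
                                        state = all_states)
  attr(out, "params") <- params
  out
}

#' Two-state ensemble with a planted melted helix
#'
#' State 1 is the base structure (helix formed); state 2 has the helix
#' melted (both strands unpaired), drawn with probability `open_fraction`.
#' Molecules in state 2 modify both strands at unpaired rates, producing
#' correlated co-modification across the helix — the signal PAIR analysis
#' detects.
#'
#' @param base_structure An [rna_structure()] containing the helix.
#' @param helix Tibble or data frame with columns `i`, `j`: the helix pairs
#'   to melt. All must be present in `base_structure`.
#' @param open_fraction Fraction of molecules with the helix open, in
#'   `[0, 1)`. Zero yields a single-state ensemble.
#' @param ... Further arguments passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
planted_helix_ensemble <- function(base_structure, helix, open_fraction, ...) {
  stopifnot(inherits(base_structure, "rna_structure"))
  if (open_fraction < 0 || open_fraction >= 1) {
    stop("open_fraction must lie in [0, 1)")
  }
  pt <- base_structure$pair_table
  if (any(pt[helix$i] != helix$j)) {
    stop("helix pairs must be present in the base structure")
  }
  if (open_fraction == 0) {
    return(sim_params(base_structure, ...))
  }
  pt2 <- pt
  pt2[c(helix$i, helix$j)] <- 0L
  melted <- rna_structure(base_structure$sequence, pt2,
                          name = paste0(base_structure$name, "_melted"))
  sim_params(list(base_structure, melted),
             weights = c(1 - open_fraction, open_fraction), ...)
}
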