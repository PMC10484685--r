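# --- toy structures -------------------------------------------------------

# small hairpin: 5'-GGGGC AAAA GCCCC-3' paired (1..5)-(14..10)
toy_hairpin <- function() {
  rna_structure("GGGGCAAAAGCCCC",
                c(14, 13, 12, 11, 10, 0, 0, 0, 0, 5, 4, 3, 2, 1),
                name = "hairpin")
}

# 80-nt two-helix toy used for PAIR tests: planted 8-bp helix 11-18 / 51-58
# (strand sequence chosen so off-register and intra-strand window
# alignments never reach 2/3 complementarity, even counting GU wobble),
# background 5-bp helix 25-29 / 36-40, remainder unpaired with all four
# bases common
toy_two_state <- function() {
  seq_chars <- rep("N", 80)
  pt <- integer(80)
  h1_i <- 11:18
  h1_j <- 58:51
  seq_chars[h1_i] <- strsplit("AGCUUCGA", "")[[1]]
  seq_chars[51:58] <- strsplit("UCGAAGCU", "")[[1]]
  pt[h1_i] <- h1_j
  pt[h1_j] <- h1_i
  h2_i <- 25:29
  h2_j <- 40:36
  seq_chars[h2_i] <- strsplit("GCGCG", "")[[1]]
  seq_chars[h2_j] <- strsplit("CGCGC", "")[[1]]
  pt[h2_i] <- h2_j
  pt[h2_j] <- h2_i
  fill <- strsplit(paste0("ACGUCAUGCU", "GUACACGUAC", "UGCAGUCAGC",
                          "AUGCUAGCAU", "CAGUACGAUG", "CUAGACGAUC"), "")[[1]]
  seq_chars[seq_chars == "N"] <- fill[seq_len(sum(seq_chars == "N"))]
  # helix-adjacent flanks kept non-complementary to both strands so edge
  # windows cannot form spurious 2/3-complementary registers
  seq_chars[c(9, 10, 19, 20, 49, 50, 59, 60)] <- "A"
  structure <- rna_structure(paste(seq_chars, collapse = ""), pt,
                             name = "two_state_toy")
  list(structure = structure,
       helix = tibble::tibble(i = h1_i, j = h1_j))
}

# ~150-nt multi-hairpin toy with G in both pairing classes
toy_long_structure <- function(seed = 42) {
  set.seed(seed)
  wc <- list(A = "U", U = "A", G = "C", C = "G")
  seq_chars <- character(0)
  pt_all <- integer(0)
  offset <- 0L
  for (h in 1:5) {
    stem <- sample(c("A", "C", "G", "U"), 8, replace = TRUE)
    loop <- sample(c("A", "C", "G", "U"), 6, replace = TRUE)
    spacer <- sample(c("A", "C", "G", "U"), 4, replace = TRUE)
    block <- c(stem, loop, unlist(wc[rev(stem)]), spacer)
    n <- length(block)
    pt <- integer(n)
    pt[1:8] <- offset + 22:15
    pt[15:22] <- offset + 8:1
    seq_chars <- c(seq_chars, block)
    pt_all <- c(pt_all, ifelse(pt == 0, 0L, pt))
    offset <- offset + n
  }
  rna_structure(paste(seq_chars, collapse = ""), pt_all, name = "toy150")
}

# random nested structure for property tests (no pseudoknots)
random_structure <- function(n, seed) {
  set.seed(seed)
  db <- rep(".", n)
  i <- 1L
  while (i <= n - 8) {
    if (stats::runif(1) < 0.4) {
      stem <- sample(2:4, 1)
      loop <- sample(3:5, 1)
      if (i + 2 * stem + loop - 1 <= n) {
        db[i:(i + stem - 1)] <- "("
        db[(i + stem + loop):(i + 2 * stem + loop - 1)] <- ")"
        i <- i + 2L * stem + loop + sample(0:3, 1)
        next
      }
    }
    i <- i + 1L
  }
  parse_dotbracket(paste(db, collapse = ""),
                   sequence = paste(sample(c("A", "C", "G", "U"), n,
                                           replace = TRUE), collapse = ""))
}

# --- random read fixtures -------------------------------------------------

random_read_set <- function(seed, n_reads, len, event_rate = 0.05) {
  set.seed(seed)
  span_start <- sample.int(max(len - 10, 1), n_reads, replace = TRUE)
  span_end <- pmin(span_start + sample(8:(len - 1), n_reads, replace = TRUE),
                   len)
  events <- list()
  bases <- c("A", "C", "G", "U")
  for (r in seq_len(n_reads)) {
    pos <- span_start[r]:span_end[r]
    hit <- pos[stats::runif(length(pos)) < event_rate]
    if (length(hit) == 0) next
    type <- sample(c("mm", "del", "ins", "multi"), length(hit),
                   replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
    keep <- rep(TRUE, length(hit))
    ev <- vector("list", length(hit))
    for (k in seq_along(hit)) {
      p <- hit[k]
      if (k > 1 && p <= max(vapply(ev[seq_len(k - 1)][keep[seq_len(k - 1)]],
                                   function(e) e$right, integer(1),
                                   USE.NAMES = FALSE), -1L)) {
        keep[k] <- FALSE
        next
      }
      if (type[k] == "multi" && p + 1 <= span_end[r]) {
        ref <- sample(bases, 2, replace = TRUE)
        alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
        ev[[k]] <- tibble::tibble(read = r, left = p, right = p + 1L,
                                  ref = paste(ref, collapse = ""),
                                  alt = paste(alt, collapse = ""))
      } else if (type[k] == "del") {
        ev[[k]] <- tibble::tibble(read = r, left = p, right = p,
                                  ref = sample(bases, 1), alt = "")
      } else if (type[k] == "ins") {
        ev[[k]] <- tibble::tibble(read = r, left = p, right = p,
                                  ref = "", alt = sample(bases, 1))
      } else {
        ref <- sample(bases, 1)
        ev[[k]] <- tibble::tibble(read = r, left = p, right = p, ref = ref,
                                  alt = sample(setdiff(bases, ref), 1))
      }
    }
    events[[length(events) + 1]] <- dplyr::bind_rows(ev[keep])
  }
  ev_tbl <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(read = integer(), left = integer(), right = integer(),
                   ref = character(), alt = character())
  read_set(tibble::tibble(read = seq_len(n_reads),
                          read_id = paste0("r", seq_len(n_reads)),
                          span_start = span_start, span_end = span_end),
           ev_tbl)
}

# --- independent brute-force oracles --------------------------------------

# naive O(reads x length) per-position tally
brute_count_profile <- function(x, len, mode) {
  retained <- filtered <- depth <- integer(len)
  for (r in x$reads$read) {
    rd <- x$reads[x$reads$read == r, ]
    valid <- rep(FALSE, len)
    valid[rd$span_start:rd$span_end] <- TRUE
    muts <- rep(FALSE, len)
    ev <- x$events[x$events$read == r, ]
    if (nrow(ev) > 0) {
      st <- classify_events(ev, mode)
      for (k in seq_len(nrow(ev))) {
        span <- ev$left[k]:ev$right[k]
        if (st[k] == "no_data") {
          valid[span] <- FALSE
          filtered[span] <- filtered[span] + 1L
        } else {
          muts[span] <- TRUE
        }
      }
    }
    depth <- depth + valid
    retained <- retained + (muts & valid)
  }
  list(retained = retained, depth = depth, filtered = filtered)
}

# pairwise Mann-Whitney count
brute_auroc <- function(values, is_unpaired) {
  u <- values[is_unpaired]
  b <- values[!is_unpaired]
  tot <- 0
  for (x in u) tot <- tot + sum(x > b) + 0.5 * sum(x == b)
  tot / (length(u) * length(b))
}

# interpolated percentile by explicit rank formula (quantile type 7)
brute_percentile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

brute_norm_factor <- function(rates) {
  p90 <- brute_percentile(rates, 0.90)
  p95 <- brute_percentile(rates, 0.95)
  band <- rates[rates >= p90 & rates <= p95]
  term1 <- if (length(band) > 0) mean(band) else brute_percentile(rates, 0.925)
  above <- rates[rates > 0.001]
  if (length(above) == 0) return(term1)
  max(term1, brute_percentile(above, 0.75))
}

# per-read enumeration of window-pair contingency tables
brute_window_contingency <- function(x, len, window = 3, mode = "dms") {
  nw <- len - window + 1
  starts <- seq_len(nw)
  res <- list()
  per_read <- lapply(x$reads$read, function(r) {
    rd <- x$reads[x$reads$read == r, ]
    valid <- rep(FALSE, len)
    valid[rd$span_start:rd$span_end] <- TRUE
    muts <- rep(FALSE, len)
    ev <- x$events[x$events$read == r, ]
    if (nrow(ev) > 0) {
      st <- classify_events(ev, mode)
      for (k in seq_len(nrow(ev))) {
        span <- ev$left[k]:ev$right[k]
        if (st[k] == "no_data") valid[span] <- FALSE
        else muts[span] <- TRUE
      }
    }
    wcov <- vapply(starts, function(w) all(valid[w:(w + window - 1)]),
                   logical(1))
    wmod <- vapply(starts, function(w) any(muts[w:(w + window - 1)] &
                                             valid[w:(w + window - 1)]),
                   logical(1)) & wcov
    list(cov = wcov, mod = wmod)
  })
  for (i in starts) {
    for (j in starts[starts >= i + window]) {
      n11 <- n10 <- n01 <- n00 <- 0L
      for (pr in per_read) {
        if (pr$cov[i] && pr$cov[j]) {
          if (pr$mod[i] && pr$mod[j]) n11 <- n11 + 1L
          else if (pr$mod[i]) n10 <- n10 + 1L
          else if (pr$mod[j]) n01 <- n01 + 1L
          else n00 <- n00 + 1L
        }
      }
      res[[length(res) + 1]] <- tibble::tibble(i = i, j = j, n11 = n11,
                                               n10 = n10, n01 = n01,
                                               n00 = n00)
    }
  }
  dplyr::bind_rows(res)
}

# G statistic via the mutual-information identity G = 2*N*MI(nats)
brute_g_stat <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    if (p[a, b] > 0) mi <- mi + p[a, b] * log(p[a, b] / (pr[a] * pc[b]))
  }
  2 * n * mi
}

# single-class helpers for building separating mixture models
point_mass_model <- function() gamma_mixture(c(0, 0), c(1, 1), c(1, 1),
                                             zero_mass = 1)
flat_gamma_model <- function(shape = 2, scale = 0.2) {
  gamma_mixture(c(0.5, 0.5), c(shape, shape), c(scale, scale), zero_mass = 0)
}

# uniform synthetic normalized profile over a structure
synthetic_profile <- function(structure, reactivity, mask = NULL) {
  n <- length(structure)
  out <- tibble::tibble(
    position = seq_len(n),
    base = strsplit(structure$sequence, "")[[1]],
    mod_rate = reactivity,
    mask = if (is.null(mask)) rep(TRUE, n) else mask,
    reactivity = reactivity
  )
  out$reactivity[!out$mask] <- NA_real_
  class(out) <- c("dms_profile", class(out))
  out
}

make_training_profile <- function(structure, table, seed) {
  set.seed(seed)
  n <- length(structure)
  paired <- structure$pair_table != 0
  bases <- strsplit(structure$sequence, "")[[1]]
  react <- numeric(n)
  for (i in seq_len(n)) {
    g <- table[[bases[i]]][[if (paired[i]) "paired" else "unpaired"]]
    u <- stats::runif(1)
    if (u < g$zero_mass) {
      react[i] <- 0
    } else {
      k <- sample(1:2, 1, prob = g$weights)
      react[i] <- stats::rgamma(1, shape = g$shapes[k], scale = g$scales[k])
    }
  }
  synthetic_profile(structure, react)
}

# a large random structure so every (base, class) has hundreds of positions
big_structure <- function(n = 5000, seed = 1) {
  set.seed(seed)
  stopifnot(n %% 2 == 0)
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  half <- sample(c("A", "C", "G", "U"), n / 2, replace = TRUE)
  paired_half <- stats::runif(n / 2) < 0.5
  seq_chars <- character(n)
  pt <- integer(n)
  seq_chars[seq_len(n / 2)] <- half
  # pair position i with n+1-i when flagged, keeping nestedness
  for (i in seq_len(n / 2)) {
    j <- n + 1L - i
    if (paired_half[i]) {
      seq_chars[j] <- wc[[half[i]]]
      pt[i] <- j
      pt[j] <- i
    } else {
      seq_chars[j] <- sample(c("A", "C", "G", "U"), 1)
    }
  }
  rna_structure(paste(seq_chars, collapse = ""), pt, name = "big")
}

reference_table <- function() {
  mk <- function(w1, s1, sc1, s2, sc2, z) {
    gamma_mixture(c(w1, 1 - z - w1), c(s1, s2), c(sc1, sc2), zero_mass = z)
  }
  tbl <- list(
    A = list(paired = mk(0.55, 1.0, 0.05, 4, 0.12, 0.10),
             unpaired = mk(0.35, 2.0, 0.25, 6, 0.30, 0.02)),
    C = list(paired = mk(0.55, 1.2, 0.04, 4, 0.10, 0.10),
             unpaired = mk(0.35, 2.0, 0.30, 6, 0.25, 0.02)),
    G = list(paired = mk(0.55, 1.0, 0.06, 3, 0.15, 0.15),
             unpaired = mk(0.40, 2.5, 0.20, 7, 0.25, 0.03)),
    U = list(paired = mk(0.55, 1.1, 0.05, 4, 0.12, 0.12),
             unpaired = mk(0.40, 2.0, 0.28, 6, 0.28, 0.03))
  )
  structure(tbl, class = c("potential_table", "structure_models"))
}

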