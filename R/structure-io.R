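#' RNA secondary structure with pair table
#'
#' Constructs a reference secondary structure: a sequence over {A,C,G,U,N}
#' together with a symmetric 1-based pair table (0 = unpaired). Crossing
#' (pseudoknotted) pairs are representable; no nesting constraint is imposed.
#'
#' @param sequence Character scalar, the RNA sequence. T is normalized to U.
#' @param pair_table Integer vector, one entry per position: the 1-based
#'   partner index, or 0 for unpaired.
#' @param name Optional text label.
#' @return An object of class `rna_structure` with fields `name`, `sequence`
#'   and `pair_table`.
#' @export
rna_structure <- function(sequence, pair_table, name = "structure") {
  sequence <- toupper(gsub("T", "U", toupper(sequence)))
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "U", "N"))) {
    bad <- setdiff(unique(bases), c("A", "C", "G", "U", "N"))
    stop("sequence contains invalid characters: ", paste(bad, collapse = ", "))
  }
  pair_table <- as.integer(pair_table)
  n <- length(bases)
  if (length(pair_table) != n) {
    stop("pair_table length (", length(pair_table),
         ") does not match sequence length (", n, ")")
  }
  if (any(pair_table < 0L | pair_table > n)) {
    stop("pair_table entries must lie in [0, sequence length]")
  }
  paired <- which(pair_table != 0L)
  if (any(pair_table[paired] == paired)) {
    stop("self-pairing is not allowed")
  }
  bad <- paired[pair_table[pair_table[paired]] != paired]
  if (length(bad) > 0) {
    stop("pair_table is not symmetric at position ", bad[1])
  }
  structure(
    list(name = name, sequence = sequence, pair_table = pair_table),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  n_pairs <- sum(x$pair_table != 0L) / 2
  cat("<rna_structure> ", x$name, ": ", nchar(x$sequence), " nt, ",
      n_pairs, " base pairs\n", sep = "")
  invisible(x)
}

#' @export
length.rna_structure <- function(x) nchar(x$sequence)

# bracket tiers used for dot-bracket I/O; tier k may cross tier j != k
.db_open  <- c("(", "[", "{", "<")
.db_close <- c(")", "]", "}", ">")

#' Parse a dot-bracket structure string
#'
#' Supports up to four bracket tiers `()[]{}<>` so crossing (pseudoknotted)
#' pairs survive a round trip. An optional `>name` header line and a sequence
#' line may precede the bracket line (as in connectivity files written by
#' common folding tools).
#'
#' @param text Either a bare dot-bracket string or multi-line text
#'   (`>name`, sequence, brackets).
#' @param sequence Optional sequence; defaults to all-N if absent from `text`.
#' @param name Optional label, overriding any header in `text`.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("((..))", sequence = "GGAACC")
#' @export
parse_dotbracket <- function(text, sequence = NULL, name = NULL) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  db <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      if (is.null(name)) name <- sub("^>\\s*", "", ln)
    } else if (grepl("^[ACGUTNacgutn]+$", ln) && is.null(sequence)) {
      sequence <- ln
    } else {
      db <- ln
    }
  }
  if (is.null(db) || nchar(db) == 0) stop("no dot-bracket line found")
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  pt <- integer(n)
  stacks <- rep(list(integer(0)), length(.db_open))
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == ".") next
    tier <- match(ch, .db_open)
    if (!is.na(tier)) {
      stacks[[tier]] <- c(stacks[[tier]], i)
      next
    }
    tier <- match(ch, .db_close)
    if (is.na(tier)) {
      stop("unknown character '", ch, "' at position ", i)
    }
    if (length(stacks[[tier]]) == 0) {
      stop("unbalanced bracket '", ch, "' at position ", i)
    }
    j <- stacks[[tier]][length(stacks[[tier]])]
    stacks[[tier]] <- stacks[[tier]][-length(stacks[[tier]])]
    pt[i] <- j
    pt[j] <- i
  }
  leftover <- which(lengths(stacks) > 0)
  if (length(leftover) > 0) {
    pos <- stacks[[leftover[1]]][1]
    stop("unbalanced bracket '", .db_open[leftover[1]], "' at position ", pos)
  }
  if (is.null(sequence)) sequence <- strrep("N", n)
  if (nchar(sequence) != n) stop("sequence and dot-bracket lengths differ")
  rna_structure(sequence, pt, name = name %||% "structure")
}

#' Write a structure as dot-bracket text
#'
#' Crossing pairs are assigned to higher bracket tiers greedily (a pair goes
#' to the lowest tier it does not cross).
#'
#' @param x An [rna_structure()].
#' @param path Optional file path; if `NULL` the text is returned invisibly.
#' @return The dot-bracket text, invisibly.
#' @export
write_dotbracket <- function(x, path = NULL) {
  stopifnot(inherits(x, "rna_structure"))
  pt <- x$pair_table
  n <- length(pt)
  chars <- rep(".", n)
  pairs <- which(pt > seq_len(n))
  tiers <- rep(list(matrix(0, 0, 2)), length(.db_open))
  for (i in pairs) {
    j <- pt[i]
    placed <- FALSE
    for (t in seq_along(tiers)) {
      tp <- tiers[[t]]
      crosses <- any((tp[, 1] < i & i < tp[, 2] & tp[, 2] < j) |
                     (i < tp[, 1] & tp[, 1] < j & j < tp[, 2]))
      if (!crosses) {
        tiers[[t]] <- rbind(tp, c(i, j))
        chars[i] <- .db_open[t]
        chars[j] <- .db_close[t]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("structure needs more than ", length(.db_open),
                      " bracket tiers")
  }
  out <- paste0(">", x$name, "\n", x$sequence, "\n",
                paste(chars, collapse = ""), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", out), path)
  invisible(out)
}

#' Parse a CT-format secondary structure
#'
#' Standard 6-column CT: a header line whose first field is the length
#' (remaining header text becomes the name), then one line per position with
#' index, base, i-1, i+1, partner (0 = unpaired), natural index.
#'
#' @param text CT text (scalar or lines) or a file path.
#' @return An [rna_structure()].
#' @export
parse_ct <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("CT record too short")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n) || n <= 0) stop("CT header must begin with the length")
  name <- if (length(header) > 1) paste(header[-1], collapse = " ") else "structure"
  body <- lines[-1]
  if (length(body) < n) stop("CT body has ", length(body),
                             " lines but header declares ", n)
  body <- body[seq_len(n)]
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) < 6)) stop("CT lines must have 6 columns")
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  idx <- as.integer(mat[, 1])
  if (!identical(idx, seq_len(n))) stop("CT position indices must run 1..", n)
  bases <- mat[, 2]
  partner <- as.integer(mat[, 5])
  if (anyNA(partner)) stop("non-numeric partner column in CT record")
  paired <- which(partner != 0L)
  bad <- paired[partner[paired] > n | partner[partner[paired]] != paired]
  if (length(bad) > 0) {
    stop("inconsistent partner columns at position ", bad[1],
         " (partner ", partner[bad[1]], " does not point back)")
  }
  rna_structure(paste(bases, collapse = ""), partner, name = name)
}

#' Write a structure in CT format
#'
#' @param x An [rna_structure()].
#' @param path Optional output path; if `NULL`, text is returned invisibly.
#' @return CT text, invisibly.
#' @export
write_ct <- function(x, path = NULL) {
  stopifnot(inherits(x, "rna_structure"))
  n <- length(x$pair_table)
  bases <- strsplit(x$sequence, "")[[1]]
  body <- sprintf("%d %s %d %d %d %d",
                  seq_len(n), bases, seq_len(n) - 1L,
                  c(seq_len(n)[-1], 0L), x$pair_table, seq_len(n))
  out <- c(paste(n, x$name), body)
  if (!is.null(path)) writeLines(out, path)
  invisible(paste(out, collapse = "\n"))
}

#' Base pairs of a structure as a tibble
#'
#' @param x An [rna_structure()].
#' @return A tibble with columns `i`, `j` (i < j), one row per pair.
#' @export
structure_pairs <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  i <- which(x$pair_table > seq_along(x$pair_table))
  tibble::tibble(i = i, j = x$pair_table[i])
}

#' Helices (stacked runs of pairs) of a structure
#'
#' A helix is a maximal run of pairs (i,j), (i+1,j-1), ... with no
#' interruption. Used for singleton-pair removal and PAIR sensitivity.
#'
#' @param x An [rna_structure()].
#' @return A tibble with columns `helix`, `i`, `j`, `helix_len`.
#' @export
structure_helices <- function(x) {
  pairs <- dplyr::arrange(structure_pairs(x), .data$i)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(helix = integer(), i = integer(), j = integer(),
                          helix_len = integer()))
  }
  new_helix <- c(TRUE, !(diff(pairs$i) == 1 & diff(pairs$j) == -1))
  pairs$helix <- cumsum(new_helix)
  dplyr::mutate(dplyr::group_by(pairs, .data$helix),
                helix_len = dplyr::n()) |>
    dplyr::ungroup()
}

# drop pairs with no stacked neighbor ((i-1,j+1) nor (i+1,j-1))
drop_singletons <- function(pairs_tbl) {
  if (nrow(pairs_tbl) == 0) return(pairs_tbl)
  key <- paste(pairs_tbl$i, pairs_tbl$j)
  up <- paste(pairs_tbl$i - 1L, pairs_tbl$j + 1L) %in% key
  dn <- paste(pairs_tbl$i + 1L, pairs_tbl$j - 1L) %in% key
  pairs_tbl[up | dn, , drop = FALSE]
}

#' Compare a predicted structure to an accepted structure
#'
#' Scores predicted base pairs against an accepted reference with the
#' conventions standard in chemical-probing benchmarks: an optional
#' one-position register shift (a predicted pair (i,j) matches (i,j),
#' (i-1,j), (i+1,j), (i,j-1) or (i,j+1)), optional removal of singleton
#' pairs (pairs with no stacked neighbor) from both structures before
#' counting, and optional exclusion of positions without data. Each accepted
#' pair can be claimed by at most one predicted pair (greedy, 5'-first).
#'
#' @param predicted,accepted [rna_structure()] objects of equal length.
#' @param allow_shift Allow one-position register shifts (default `TRUE`).
#' @param ignore_singletons Remove singleton pairs first (default `TRUE`).
#' @param mask Optional logical vector (TRUE = has data); pairs touching a
#'   no-data position are excluded from both numerator and denominator.
#' @return A tibble with one row: `ppv`, `sens`, `tp`, `n_predicted`,
#'   `n_accepted`. `ppv` is `NA` when no pairs are predicted.
#' @export
compare_structures <- function(predicted, accepted, allow_shift = TRUE,
                               ignore_singletons = TRUE, mask = NULL) {
  stopifnot(inherits(predicted, "rna_structure"),
            inherits(accepted, "rna_structure"))
  if (length(predicted) != length(accepted)) {
    stop("predicted and accepted structures have different lengths")
  }
  pred <- structure_pairs(predicted)
  acc <- structure_pairs(accepted)
  if (ignore_singletons) {
    pred <- drop_singletons(pred)
    acc <- drop_singletons(acc)
  }
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(predicted))
    keep <- function(p) p[mask[p$i] & mask[p$j], , drop = FALSE]
    pred <- keep(pred)
    acc <- keep(acc)
  }
  tp <- 0L
  if (nrow(pred) > 0 && nrow(acc) > 0) {
    acc_key <- paste(acc$i, acc$j)
    shifts <- if (allow_shift) {
      list(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    } else {
      list(c(0L, 0L))
    }
    pred <- dplyr::arrange(pred, .data$i, .data$j)
    # each accepted pair may be claimed by at most one predicted pair;
    # the one-to-one assignment is resolved by maximum bipartite matching
    # (augmenting paths, predicted pairs seeded 5'-first) so that a valid
    # global assignment is never lost to claiming order
    cand <- lapply(seq_len(nrow(pred)), function(k) {
      hits <- vapply(shifts, function(s) {
        match(paste(pred$i[k] + s[1], pred$j[k] + s[2]), acc_key)
      }, integer(1))
      unique(hits[!is.na(hits)])
    })
    owner <- rep(NA_integer_, nrow(acc))
    seen <- logical(nrow(acc))
    augment <- function(k) {
      for (a in cand[[k]]) {
        if (seen[a]) next
        seen[a] <<- TRUE
        if (is.na(owner[a]) || Recall(owner[a])) {
          owner[a] <<- k
          return(TRUE)
        }
      }
      FALSE
    }
    for (k in seq_len(nrow(pred))) {
      seen[] <- FALSE
      if (augment(k)) tp <- tp + 1L
    }
  }
  tibble::tibble(
    ppv = if (nrow(pred) == 0) NA_real_ else tp / nrow(pred),
    sens = if (nrow(acc) == 0) NA_real_ else tp / nrow(acc),
    tp = tp, n_predicted = nrow(pred), n_accepted = nrow(acc)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
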