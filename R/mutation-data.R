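#' Per-read parsed mutation records
#'
#' Container pairing a table of reads (aligned spans on the target) with a
#' table of mutation events. The pipeline starts here: alignment and
#' mutation parsing happen upstream (e.g. in ShapeMapper with
#' `--output-parsed-mutations`); a small adapter converts that output to the
#' TSV dialect read by [read_parsed_mutations()].
#'
#' @param reads Tibble with columns `read` (integer index), `read_id`,
#'   `span_start`, `span_end` (1-based inclusive).
#' @param events Tibble with columns `read`, `left`, `right` (1-based target
#'   span of changed reference bases), `ref` (reference bases spanned; empty
#'   for insertion), `alt` (read bases observed; empty for deletion).
#'   Optional `cause` column (simulator truth).
#' @return An object of class `read_set`.
#' @export
read_set <- function(reads, events) {
  reads <- tibble::as_tibble(reads)
  events <- tibble::as_tibble(events)
  stopifnot(all(c("read", "read_id", "span_start", "span_end") %in% names(reads)),
            all(c("read", "left", "right", "ref", "alt") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$left > events$right)) stop("event with left > right")
    span <- reads[match(events$read, reads$read), ]
    bad <- which(events$left < span$span_start | events$right > span$span_end)
    if (length(bad) > 0) {
      stop("event outside read span (first offender: read ",
           events$read[bad[1]], ")")
    }
  }
  events$kind <- event_kind(events$ref, events$alt)
  events <- dplyr::arrange(events, .data$read, .data$left)
  structure(list(reads = reads, events = events), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", nrow(x$reads), " reads, ", nrow(x$events),
      " mutation events\n", sep = "")
  invisible(x)
}

#' Classify mutation events by ref/alt lengths
#'
#' @param ref,alt Character vectors of reference and read bases.
#' @return One of `"mismatch"`, `"insertion"`, `"deletion"`, `"multi"`.
#' @export
event_kind <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  kind <- rep(NA_character_, length(ref))
  kind[nr == 1 & na == 1] <- "mismatch"
  kind[nr == 0 & na > 0] <- "insertion"
  kind[nr > 0 & na == 0] <- "deletion"
  kind[nr > 1 & na == nr] <- "multi"
  if (anyNA(kind)) {
    stop("unclassifiable event (ref length ", nr[which(is.na(kind))[1]],
         ", alt length ", na[which(is.na(kind))[1]], ")")
  }
  kind
}

#' Apply the DMS mutation-signature filter to events
#'
#' In `dms` mode, mutation types that predominantly report N7-G methylation
#' or reverse-transcription artifacts are set to no-data: G-to-A
#' single-nucleotide mismatches, multi-nucleotide mismatches whose reference
#' span contains a G, and insertions and deletions at all nucleotides.
#' Everything else (G-to-C, G-to-T, and all A/C/U mismatches) is retained as
#' evidence of Watson-Crick-face methylation. In `unfiltered` mode every
#' event is retained (traditional DMS-MaP behavior).
#'
#' @param events Tibble of events (columns `ref`, `alt`; `kind` optional).
#' @param mode `"dms"` or `"unfiltered"`.
#' @return Character vector, `"retained"` or `"no_data"`, one per event.
#' @export
classify_events <- function(events, mode = c("dms", "unfiltered")) {
  mode <- match.arg(mode)
  n <- nrow(events)
  if (mode == "unfiltered") return(rep("retained", n))
  kind <- if ("kind" %in% names(events)) events$kind else
    event_kind(events$ref, events$alt)
  ref <- toupper(gsub("T", "U", toupper(events$ref)))
  alt <- toupper(gsub("T", "U", toupper(events$alt)))
  out <- rep("retained", n)
  out[kind %in% c("insertion", "deletion")] <- "no_data"
  out[kind == "mismatch" & ref == "G" & alt == "A"] <- "no_data"
  out[kind == "multi" & grepl("G", ref, fixed = TRUE)] <- "no_data"
  out
}

# per-position increment over [left, right] spans via a difference array
span_tally <- function(left, right, n) {
  delta <- numeric(n + 1L)
  if (length(left) > 0) {
    add <- tapply(rep(1L, length(left)), factor(left, levels = seq_len(n)),
                  sum, default = 0L)
    sub <- tapply(rep(1L, length(right)),
                  factor(right + 1L, levels = seq_len(n + 1L)),
                  sum, default = 0L)
    delta[seq_len(n)] <- delta[seq_len(n)] + as.numeric(add)
    delta <- delta - as.numeric(sub)
  }
  cumsum(delta)[seq_len(n)]
}

#' Accumulate per-position mutation counts and effective depths
#'
#' Applies the signature filter read-by-read: a no-data event clears the
#' read's validity over the event's own reference span (so the read no
#' longer contributes depth there), while retained events increment the
#' mutation count at each changed position. `N` reference positions never
#' accumulate mutation counts.
#'
#' @param x A [read_set()].
#' @param sequence Target sequence (character scalar); T normalized to U.
#' @param mode `"dms"` (signature filter on) or `"unfiltered"`.
#' @return A tibble with columns `position`, `base`, `retained_mut`,
#'   `effective_depth`, `filtered` (reads whose event(s) at the position
#'   were set to no-data).
#' @export
count_profile <- function(x, sequence, mode = c("dms", "unfiltered")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "read_set"))
  sequence <- toupper(gsub("T", "U", toupper(sequence)))
  n <- nchar(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (nrow(x$reads) > 0 && (min(x$reads$span_start) < 1 ||
                            max(x$reads$span_end) > n)) {
    stop("read span outside sequence bounds")
  }
  coverage <- span_tally(x$reads$span_start, x$reads$span_end, n)
  ev <- x$events
  status <- classify_events(ev, mode)
  nd <- ev[status == "no_data", , drop = FALSE]
  # insertions sit between bases; they void only their anchor position
  filtered <- span_tally(nd$left, pmax(nd$right, nd$left), n)
  keep <- ev[status == "retained", , drop = FALSE]
  retained <- span_tally(keep$left, pmax(keep$right, keep$left), n)
  retained[bases == "N"] <- 0
  tibble::tibble(
    position = seq_len(n),
    base = bases,
    retained_mut = as.integer(retained),
    effective_depth = as.integer(coverage - filtered),
    filtered = as.integer(filtered)
  )
}

#' Mutation spectrum split by reference base and pairing status
#'
#' Diagnostic, pre-filter view of the raw mutation signal: for each
#' reference base and mutation type, the per-position event rate at paired
#' versus unpaired positions (unfiltered counting — this is the table used
#' to discover which mutation types carry structure signal).
#'
#' @param x A [read_set()].
#' @param sequence Target sequence.
#' @param structure An [rna_structure()] of equal length.
#' @return A tibble with `ref_base`, `mutation` (e.g. `"G>A"`, `"del"`,
#'   `"ins"`, `"multi"`), `paired`, `n_events`, `depth`, `rate`, and a
#'   `low_data` attribute flag when the read set is empty.
#' @export
mutation_spectrum <- function(x, sequence, structure) {
  stopifnot(inherits(x, "read_set"), inherits(structure, "rna_structure"))
  sequence <- toupper(gsub("T", "U", toupper(sequence)))
  n <- nchar(sequence)
  if (length(structure) != n) stop("structure length != sequence length")
  bases <- strsplit(sequence, "")[[1]]
  paired <- structure$pair_table != 0L
  depth <- span_tally(x$reads$span_start, x$reads$span_end, n)

  ev <- x$events
  if (nrow(ev) > 0) {
    ref_u <- toupper(gsub("T", "U", toupper(ev$ref)))
    alt_u <- toupper(gsub("T", "U", toupper(ev$alt)))
    label <- dplyr::case_when(
      ev$kind == "mismatch" ~ paste0(ref_u, ">", alt_u),
      ev$kind == "deletion" ~ "del",
      ev$kind == "insertion" ~ "ins",
      TRUE ~ "multi"
    )
    # count the event at every spanned position (insertions at their anchor)
    len <- pmax(ev$right, ev$left) - ev$left + 1L
    pos <- ev$left[rep(seq_len(nrow(ev)), len)] +
      sequence(len) - 1L
    lab <- rep(label, len)
    per_pos <- tibble::tibble(
      position = pos, mutation = lab,
      ref_base = bases[pos], paired = paired[pos]
    )
    counts <- dplyr::count(per_pos, .data$ref_base, .data$mutation,
                           .data$paired, name = "n_events")
  } else {
    counts <- tibble::tibble(ref_base = character(), mutation = character(),
                             paired = logical(), n_events = integer())
  }
  denom <- tibble::tibble(base = bases, paired = paired, depth = depth) |>
    dplyr::group_by(ref_base = .data$base, paired = .data$paired) |>
    dplyr::summarise(depth = sum(.data$depth), .groups = "drop")
  out <- dplyr::left_join(counts, denom, by = c("ref_base", "paired")) |>
    dplyr::mutate(rate = ifelse(.data$depth > 0,
                                .data$n_events / .data$depth, 0)) |>
    dplyr::arrange(.data$ref_base, .data$mutation, .data$paired)
  attr(out, "low_data") <- nrow(x$reads) == 0
  out
}

#' Read parsed-mutation records from TSV
#'
#' One read per line, tab-separated: `read_id`, `span_start`, `span_end`,
#' `events`, where `events` is `.` (no events) or a semicolon-delimited list
#' of `left|right|ref|alt` (empty `ref` = insertion, empty `alt` =
#' deletion). Lossless and trivially convertible from ShapeMapper
#' parsed-mutation output.
#'
#' @param path TSV file path.
#' @return A [read_set()].
#' @export
read_parsed_mutations <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_names = c("read_id", "span_start", "span_end", "events"),
    col_types = readr::cols(
      read_id = readr::col_character(),
      span_start = readr::col_integer(),
      span_end = readr::col_integer(),
      events = readr::col_character()
    ),
    na = character(), progress = FALSE
  )
  reads <- tibble::tibble(
    read = seq_len(nrow(tbl)), read_id = tbl$read_id,
    span_start = tbl$span_start, span_end = tbl$span_end
  )
  has_ev <- which(tbl$events != "." & nzchar(tbl$events))
  if (length(has_ev) > 0) {
    split_ev <- strsplit(tbl$events[has_ev], ";", fixed = TRUE)
    ridx <- rep(has_ev, lengths(split_ev))
    parts <- strsplit(unlist(split_ev), "|", fixed = TRUE)
    grab <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else "",
                               character(1))
    events <- tibble::tibble(
      read = ridx,
      left = as.integer(grab(1)), right = as.integer(grab(2)),
      ref = grab(3), alt = grab(4)
    )
  } else {
    events <- tibble::tibble(read = integer(), left = integer(),
                             right = integer(), ref = character(),
                             alt = character())
  }
  read_set(reads, events)
}

#' Write parsed-mutation records as TSV
#'
#' @param x A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parsed_mutations <- function(x, path) {
  stopifnot(inherits(x, "read_set"))
  ev_str <- rep(".", nrow(x$reads))
  if (nrow(x$events) > 0) {
    per_read <- x$events |>
      dplyr::mutate(txt = paste(.data$left, .data$right, .data$ref,
                                .data$alt, sep = "|")) |>
      dplyr::group_by(.data$read) |>
      dplyr::summarise(txt = paste(.data$txt, collapse = ";"))
    ev_str[match(per_read$read, x$reads$read)] <- per_read$txt
  }
  readr::write_tsv(
    tibble::tibble(read_id = x$reads$read_id,
                   span_start = x$reads$span_start,
                   span_end = x$reads$span_end,
                   events = ev_str),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Write a per-position counted-mutations table
#'
#' @param counts Output of [count_profile()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counted_mutations <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
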