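#' Fit pseudo-energy reactivity potentials from a profile and structure
#'
#' Fits nucleotide-specific paired/unpaired reactivity likelihoods (double
#' gamma mixtures with a zero mass) to a normalized profile with known
#' pairing status. The resulting table is the likelihood basis for folding
#' pseudo-energies: the log ratio log p(r|unpaired)/log p(r|paired) scores
#' how strongly a reactivity disfavors pairing.
#'
#' @param profile Normalized `dms_profile`.
#' @param structure Known [rna_structure()] used as training truth.
#' @param seed Optional seed for the mixture fits.
#' @param min_n Minimum usable positions per (base, class); bases failing
#'   it are omitted with a warning (default 50).
#' @param provenance Label recording the training profile.
#' @return A `potential_table`: a `structure_models` list with a
#'   `provenance` attribute.
#' @export
fit_potentials <- function(profile, structure, seed = NULL, min_n = 50,
                           provenance = "training profile") {
  models <- fit_structure_models(profile, structure, seed = seed,
                                 min_n = min_n)
  attr(models, "provenance") <- provenance
  class(models) <- c("potential_table", class(models))
  models
}

#' Log likelihood ratio of unpaired versus paired at given reactivities
#'
#' @param r Reactivity grid.
#' @param table A `potential_table` or `structure_models`.
#' @param base Nucleotide type.
#' @return log(p(r|u) / p(r|b)) with the 1e-12 density floor, finite
#'   everywhere on the grid.
#' @export
log_likelihood_ratio <- function(r, table, base) {
  m <- table[[base]]
  if (is.null(m)) stop("no potentials fitted for base ", base)
  log(pmax(dgamma_mixture(r, m$unpaired), 1e-12)) -
    log(pmax(dgamma_mixture(r, m$paired), 1e-12))
}

#' Write a dists-style potentials file
#'
#' Emits the fitted per-nucleotide paired/unpaired mixture parameters in a
#' plain-text grammar patterned after the distribution tables consumed by
#' thermodynamic folding engines: a header, then one block per nucleotide
#' with one line per class carrying weights, shapes, scales and zero mass.
#' Bases without fitted potentials get an explicit `ABSENT` marker.
#'
#' @param table A `potential_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dists_file <- function(table, path) {
  lines <- c(
    "# four-base DMS reactivity likelihood distributions",
    paste0("# provenance: ", attr(table, "provenance") %||% "unknown"),
    "# base class w1 w2 shape1 shape2 scale1 scale2 zero_mass"
  )
  for (b in c("A", "C", "G", "U")) {
    m <- table[[b]]
    if (is.null(m)) {
      lines <- c(lines, paste(b, "ABSENT"))
      next
    }
    for (cls in c("paired", "unpaired")) {
      g <- m[[cls]]
      lines <- c(lines, paste(
        b, cls,
        paste(sprintf("%.10g", c(g$weights, g$shapes, g$scales, g$zero_mass)),
              collapse = " ")
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a dists-style potentials file
#'
#' @param path Path written by [write_dists_file()].
#' @return A `potential_table`.
#' @export
read_dists_file <- function(path) {
  lines <- readLines(path)
  prov <- sub("^# provenance: ", "", grep("^# provenance:", lines, value = TRUE))
  body <- lines[!startsWith(lines, "#")]
  models <- list()
  for (ln in body) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2 || f[2] == "ABSENT") next
    v <- as.numeric(f[3:9])
    models[[f[1]]][[f[2]]] <- gamma_mixture(v[1:2], v[3:4], v[5:6],
                                            zero_mass = v[7])
  }
  structure(models, provenance = if (length(prov)) prov else "unknown",
            class = c("potential_table", "structure_models"))
}

#' @export
print.potential_table <- function(x, ...) {
  cat("<potential_table> bases fitted: ",
      paste(names(x), collapse = ", "),
      " (", attr(x, "provenance") %||% "unknown", ")\n", sep = "")
  invisible(x)
}
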