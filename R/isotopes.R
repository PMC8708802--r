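# Physical constants (CODATA). Masses in Da.
ELECTRON_MASS <- 0.000548579909
PROTON_MASS <- 1.00727646688

# The carbon-13 natural abundance used for carbon-count estimation from the
# M+1 peak. Deliberately ~1.11% (the value conventionally quoted for this
# back-of-envelope estimate) rather than the tabulated 1.07%; the divisor is
# an argument everywhere it is used.
DEFAULT_C13_ABUNDANCE <- 0.0111

.msipair_env <- new.env(parent = emptyenv())

#' Isotope reference table
#'
#' Monoisotopic and heavy-isotope masses with natural abundances for the
#' elements handled by the mass algebra (C, H, N, O, P, S, F). Values are
#' NIST/CODATA reference constants shipped as a plain-text table under
#' `inst/extdata/isotope_table.tsv` so they are auditable.
#'
#' @param path Optional path to an alternative isotope table with columns
#'   `element`, `isotope`, `mass`, `abundance`.
#' @return A tibble with one row per isotope, sorted by element and mass;
#'   within each element abundances sum to 1 (checked to 1e-6).
#' @examples
#' isotope_table()
#' @export
isotope_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.msipair_env$isotopes)) {
      return(.msipair_env$isotopes)
    }
    path <- system.file("extdata", "isotope_table.tsv", package = "msipair",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("element", "isotope", "mass", "abundance") %in% names(tab)))
  if (any(tab$mass <= 0)) {
    abort("isotope table contains non-positive masses")
  }
  sums <- tapply(tab$abundance, tab$element, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    abort(paste0("isotope abundances do not sum to 1 for: ",
                 paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", ")))
  }
  tab <- tab[order(tab$element, tab$mass), ]
  if (cache) .msipair_env$isotopes <- tab
  tab
}

# Named vector of lightest-isotope masses, cached.
monoisotopic_masses <- function() {
  if (is.null(.msipair_env$mono)) {
    tab <- isotope_table()
    first <- tab[!duplicated(tab$element), ]
    .msipair_env$mono <- setNames(first$mass, first$element)
  }
  .msipair_env$mono
}

# Per-element isotope distribution keyed by integer neutron offset from the
# lightest isotope: list(offsets, prob, mass).
element_isotopes <- function(element) {
  if (is.null(.msipair_env$elem_iso)) .msipair_env$elem_iso <- list()
  hit <- .msipair_env$elem_iso[[element]]
  if (!is.null(hit)) return(hit)
  tab <- isotope_table()
  rows <- tab[tab$element == element, ]
  if (nrow(rows) == 0) abort(paste0("element not in isotope table: ", element))
  out <- list(offset = as.integer(round(rows$mass - rows$mass[1])),
              prob = rows$abundance, mass = rows$mass)
  .msipair_env$elem_iso[[element]] <- out
  out
}
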