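#' Parse an elemental formula
#'
#' Turns a Hill-style formula string such as `"C18H32O2"` into a named
#' integer vector of element counts. The grammar is deliberately minimal:
#' a sequence of element symbols, each optionally followed by a positive
#' integer count. No parentheses, hydrates, isotope labels or charges —
#' charge is carried separately by the ion functions. Element order is
#' irrelevant (`"C2NH7O4P"` and `"C2H7NO4P"` parse identically) and repeated
#' symbols accumulate.
#'
#' @param text A single formula string, e.g. `"C8H17N"`.
#' @return An `elemental_formula`: a named integer vector of counts.
#' @examples
#' parse_formula("C8H17N")
#' parse_formula("C2NH7O4P")
#' @export
parse_formula <- function(text) {
  if (inherits(text, "elemental_formula")) return(text)
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text)) {
    abort("formula must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    abort(paste0("cannot parse formula: '", text, "'"))
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(cnt), suppressWarnings(as.integer(cnt)), 1L)
  if (any(is.na(n)) || any(n <= 0L)) {
    abort(paste0("explicit counts must be positive integers in '", text, "'"))
  }
  known <- unique(isotope_table()$element)
  bad <- setdiff(sym, known)
  if (length(bad)) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  }
  counts <- tapply(n, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  # canonical Hill order: C, H, then alphabetical
  ord <- c(intersect(c("C", "H"), names(out)),
           sort(setdiff(names(out), c("C", "H"))))
  structure(out[ord], class = "elemental_formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Format an elemental formula as a string
#'
#' @param f An `elemental_formula` (or string, which is passed through parse).
#' @return A single string in Hill order, counts of 1 omitted.
#' @export
format_formula <- function(f) {
  f <- parse_formula(f)
  f <- f[f > 0]
  paste0(names(f), ifelse(unclass(f) > 1, unclass(f), ""), collapse = "")
}

#' Element-wise formula arithmetic
#'
#' Addition and subtraction of atom counts. Subtraction that would drive any
#' element negative is an error — there is no such molecule.
#'
#' @param f,g Formulas (strings or `elemental_formula` objects).
#' @return An `elemental_formula`.
#' @examples
#' formula_add("C18H32O2", "C21H44N2")
#' formula_subtract("C21H44N2", "C8H17N")
#' @export
formula_add <- function(f, g) {
  f <- parse_formula(f); g <- parse_formula(g)
  els <- union(names(f), names(g))
  out <- setNames(integer(length(els)), els)
  out[names(f)] <- out[names(f)] + unclass(f)
  out[names(g)] <- out[names(g)] + unclass(g)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  structure(out[ord], class = "elemental_formula")
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f, g) {
  f <- parse_formula(f); g <- parse_formula(g)
  els <- union(names(f), names(g))
  out <- setNames(integer(length(els)), els)
  out[names(f)] <- out[names(f)] + unclass(f)
  out[names(g)] <- out[names(g)] - unclass(g)
  if (any(out < 0)) {
    abort(paste0("subtraction yields negative count for: ",
                 paste(names(out)[out < 0], collapse = ", ")))
  }
  out <- out[out > 0]
  els <- names(out)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  structure(out[ord], class = "elemental_formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the lightest-isotope mass from the
#' packaged isotope table.
#'
#' @param f A formula (string or `elemental_formula`).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C2H5N") # 43.0422
#' @export
monoisotopic_mass <- function(f) {
  f <- parse_formula(f)
  if (sum(f) == 0) abort("empty formula has no mass")
  masses <- monoisotopic_masses()
  sum(masses[names(f)] * unclass(f))
}

#' m/z of an ion
#'
#' Electron-mass-aware mass-to-charge ratio: the composition `formula` is the
#' full atomic composition of the ion (for `[M+H]+` pass M plus one H); the
#' charge determines how many electrons are removed (positive) or added
#' (negative).
#'
#' @param formula Atomic composition of the ion (string or
#'   `elemental_formula`).
#' @param charge Signed integer charge, non-zero.
#' @return m/z = (mass - charge * electron mass) / |charge|.
#' @examples
#' ion_mz("C21H44N2", charge = 2) # 162.1747, the dication reagent
#' ion_mz("C21H44N2F", charge = 1) # 343.3483, its fluoride ion pair
#' @export
ion_mz <- function(formula, charge = 1L) {
  if (length(charge) != 1 || is.na(charge) || charge == 0) {
    abort("charge must be a non-zero integer")
  }
  (monoisotopic_mass(formula) - charge * ELECTRON_MASS) / abs(charge)
}

#' m/z of the deprotonated ion [M-H]-
#'
#' Convenience wrapper: neutral monoisotopic mass minus a proton
#' (equivalently: remove H, add an electron).
#'
#' @inheritParams monoisotopic_mass
#' @return m/z of `[M-H]-`.
#' @export
deprotonated_mz <- function(f) {
  monoisotopic_mass(f) - PROTON_MASS
}

#' m/z of the protonated ion [M+H]+
#'
#' @inheritParams monoisotopic_mass
#' @return m/z of `[M+H]+`.
#' @export
protonated_mz <- function(f) {
  monoisotopic_mass(f) + PROTON_MASS
}
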