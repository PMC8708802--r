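#' Ion-pairing reagent definition
#'
#' Reads a dicationic ion-pairing reagent definition from a two-column
#' `field`/`value` table. `default_reagent()` returns the packaged
#' 1,5-pentanediyl-bis(1-butylpyrrolidinium) (C5(bpyr)2) difluoride reagent:
#' a +2 dication of composition C21H44N2 observed at m/z 162.1747 (z = 2),
#' whose singly charged fluoride ion pair C21H44N2F+ appears at 343.3483.
#' Under collisional activation the adducted dication sheds the neutral
#' butylpyrrolidine arm C8H17N (127.1361 Da) and, on its own, additionally a
#' hydrogen to give the reagent-derived fragment C13H26N+ at m/z 196.2060.
#'
#' @param path Path to a reagent definition table (`field`, `value`).
#' @return A `reagent` object: list with `name`, `dication_formula`,
#'   `dication_charge`, `neutral_loss_formula`, `fragment_formula`,
#'   `counterion_formula`.
#' @examples
#' default_reagent()
#' @export
read_reagent <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("field", "value") %in% names(tab)))
  val <- setNames(tab$value, tab$field)
  need <- c("name", "dication_formula", "dication_charge",
            "neutral_loss_formula", "fragment_formula", "counterion_formula")
  miss <- setdiff(need, names(val))
  if (length(miss)) abort(paste0("reagent file missing fields: ",
                                 paste(miss, collapse = ", ")))
  out <- list(
    name = unname(val[["name"]]),
    dication_formula = parse_formula(val[["dication_formula"]]),
    dication_charge = as.integer(val[["dication_charge"]]),
    neutral_loss_formula = parse_formula(val[["neutral_loss_formula"]]),
    fragment_formula = parse_formula(val[["fragment_formula"]]),
    counterion_formula = parse_formula(val[["counterion_formula"]])
  )
  if (out$dication_charge != 2L) abort("dication charge must be +2")
  class(out) <- "reagent"
  out
}

#' @rdname read_reagent
#' @export
default_reagent <- function() {
  if (is.null(.msipair_env$reagent)) {
    .msipair_env$reagent <- read_reagent(
      system.file("extdata", "reagent_c5bpyr2.tsv", package = "msipair",
                  mustWork = TRUE))
  }
  .msipair_env$reagent
}

#' @export
print.reagent <- function(x, ...) {
  cat("<reagent>", x$name,
      sprintf("[%s]%+d, m/z %.4f (z=2); shift %.4f Da\n",
              format_formula(x$dication_formula), x$dication_charge,
              ion_mz(x$dication_formula, 2L), dication_shift(x)))
  invisible(x)
}

#' Mass shift contributed by the dication
#'
#' The m/z shift between a deprotonated metabolite `[M-H]-` and its net +1
#' reagent adduct `[M-H+reagent]+`: the monoisotopic mass of the dication
#' composition minus two electron masses (324.3494 Da for C5(bpyr)2).
#'
#' @param reagent A `reagent` object.
#' @return Shift in Da.
#' @examples
#' dication_shift() # 324.3494
#' @export
dication_shift <- function(reagent = default_reagent()) {
  monoisotopic_mass(reagent$dication_formula) -
    reagent$dication_charge * ELECTRON_MASS
}

#' Predicted adduct m/z of a metabolite
#'
#' m/z of the ion-pairing adduct `[M-H+reagent]+`: the deprotonated anion
#' mass plus the dication mass, net charge +1. This is the species by which
#' metabolites that normally require negative ionization mode become visible
#' in positive mode.
#'
#' @param metabolite Neutral metabolite formula (string or
#'   `elemental_formula`); must contain at least one abstractable H.
#' @param reagent A `reagent` object.
#' @return m/z of `[M-H+reagent]+`.
#' @examples
#' adduct_mz("C47H83O13P") # PI(38:4) adduct, 1209.8992
#' @export
adduct_mz <- function(metabolite, reagent = default_reagent()) {
  metabolite <- parse_formula(metabolite)
  h <- unclass(metabolite)["H"]
  if (is.na(h) || h < 1) abort("metabolite has no abstractable proton (H count 0)")
  deprotonated_mz(metabolite) + dication_shift(reagent)
}

#' Strip the dication mass shift from an observed m/z
#'
#' Subtracting the dication mass from an observed adduct m/z recovers the
#' candidate `[M-H]-` m/z, which is then searched against a deprotonated
#' metabolite library.
#'
#' @param observed_mz Observed m/z value(s), each greater than the shift.
#' @param reagent A `reagent` object.
#' @return Candidate `[M-H]-` m/z value(s).
#' @examples
#' strip_shift(1209.8991) # 885.55, deprotonated PI(38:4)
#' @export
strip_shift <- function(observed_mz, reagent = default_reagent()) {
  shift <- dication_shift(reagent)
  if (any(observed_mz <= shift)) {
    abort("observed m/z at or below the dication shift cannot be an adduct")
  }
  observed_mz - shift
}
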