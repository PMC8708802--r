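#' Glycerophospholipid headgroup fragmentation rules
#'
#' In MS/MS of dication-adducted glycerophospholipids the ionic bond between
#' the lipid headgroup and one cationic arm of the reagent survives while
#' covalent bonds cleave, producing a characteristic
#' `[headgroup + reagent - C8H17N]+` fragment per lipid class. The rules are
#' shipped as an editable plain-text table: `lipid_class`, the headgroup
#' anion composition (`headgroup_anion_formula`, charge -1), and an optional
#' `secondary_neutral_loss` (C2H5N for PE, whose loss collapses the PE
#' headgroup fragment onto the PA one). The packaged defaults cover PA
#' (dihydrogen phosphate, H2PO4-), PE (deprotonated phosphoethanolamine)
#' and PI (deprotonated inositol monophosphate). PC is deliberately absent:
#' phosphatidylcholines appear protonated, not adducted.
#'
#' @param path Optional path to an alternative rules table.
#' @return A tibble of headgroup rules.
#' @export
headgroup_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "headgroup_rules.tsv", package = "msipair",
                        mustWork = TRUE)
  }
  tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE,
                              na.strings = c("NA", "")))
  stopifnot(all(c("lipid_class", "headgroup_anion_formula") %in% names(tab)))
  if (!"secondary_neutral_loss" %in% names(tab)) {
    tab$secondary_neutral_loss <- NA_character_
  }
  tab
}

#' Predict diagnostic MS/MS fragments of a dication adduct
#'
#' For any adducted metabolite two generic fragments are always predicted:
#' the neutral loss of the butylpyrrolidine arm,
#' `[M-H+reagent-C8H17N]+`, and the reagent-derived fragment ion (C13H26N+,
#' m/z 196.2060). For glycerophospholipid classes with a headgroup rule the
#' class-specific `[headgroup+reagent-C8H17N]+` fragment is added, plus a
#' secondary fragment when the rule defines an additional neutral loss
#' (PE: loss of C2H5N, 43.0422 Da, yielding the PA-type fragment at
#' 294.1829).
#'
#' @param metabolite Neutral metabolite formula.
#' @param lipid_class Class string (e.g. "PA", "PE", "PI", "FA"). Classes
#'   without a headgroup rule get only the generic fragments.
#' @param reagent A `reagent` object.
#' @param rules Headgroup rule table (see [headgroup_rules()]).
#' @return A tibble of predictions: `label`, `mz`, `rule` (one of
#'   "neutral_loss", "reagent_fragment", "headgroup", "headgroup_secondary"),
#'   ordered deterministically as listed.
#' @examples
#' predict_fragments("C41H71O8P", "PA") # PA(38:5): 918.69 and 294.18
#' @export
predict_fragments <- function(metabolite, lipid_class = "generic",
                              reagent = default_reagent(),
                              rules = headgroup_rules()) {
  metabolite <- parse_formula(metabolite)
  precursor <- adduct_mz(metabolite, reagent)
  loss_mass <- monoisotopic_mass(reagent$neutral_loss_formula)
  loss_str <- format_formula(reagent$neutral_loss_formula)
  out <- tibble(
    label = c(sprintf("[M-H+%s-%s]+", reagent$name, loss_str),
              sprintf("[%s]+ (reagent fragment)",
                      format_formula(reagent$fragment_formula))),
    mz = c(precursor - loss_mass, ion_mz(reagent$fragment_formula, 1L)),
    rule = c("neutral_loss", "reagent_fragment")
  )
  rule <- rules[rules$lipid_class == lipid_class, ]
  if (nrow(rule) == 1) {
    hg <- parse_formula(rule$headgroup_anion_formula)
    # anion (one extra electron) + dication (2 e- short) - neutral arm
    hg_mz <- monoisotopic_mass(hg) + ELECTRON_MASS +
      dication_shift(reagent) - loss_mass
    out <- dplyr::bind_rows(out, tibble(
      label = sprintf("[%s+%s-%s]+", format_formula(hg), reagent$name, loss_str),
      mz = hg_mz, rule = "headgroup"))
    if (!is.na(rule$secondary_neutral_loss)) {
      sec <- parse_formula(rule$secondary_neutral_loss)
      out <- dplyr::bind_rows(out, tibble(
        label = sprintf("[%s+%s-%s-%s]+", format_formula(hg), reagent$name,
                        loss_str, format_formula(sec)),
        mz = hg_mz - monoisotopic_mass(sec), rule = "headgroup_secondary"))
    }
  } else if (!identical(lipid_class, "generic") &&
             !lipid_class %in% rules$lipid_class) {
    attr(out, "unknown_class") <- lipid_class
  }
  attr(out, "precursor_mz") <- precursor
  out
}

#' Validate an MS/MS spectrum against predicted fragments
#'
#' Matches each predicted fragment to the nearest observed peak within an
#' absolute m/z tolerance and assigns a confidence tier: `"high"` when the
#' reagent fragment and at least one class-specific (headgroup) fragment are
#' found, `"medium"` when only the generic neutral-loss evidence is present,
#' `"low"` otherwise. A missing fragment (e.g. a low-abundance precursor
#' suppressing its neutral-loss peak) is reported, never fatal.
#'
#' @param predicted Prediction tibble from [predict_fragments()].
#' @param observed Data frame with `mz` and `abundance` columns (may be
#'   empty: everything is reported missing, tier `"low"`).
#' @param tol_da Absolute tolerance in Da (default 0.01).
#' @return An `msms_validation` object with per-fragment results (`tidy()`)
#'   and a one-row summary (`glance()`).
#' @export
match_msms <- function(predicted, observed, tol_da = 0.01) {
  stopifnot(is.data.frame(predicted), all(c("label", "mz", "rule") %in% names(predicted)))
  if (tol_da <= 0) abort("tol_da must be positive")
  if (is.null(observed) || nrow(observed) == 0) {
    observed <- tibble(mz = numeric(), abundance = numeric())
  }
  match_one <- function(mz) {
    if (nrow(observed) == 0) return(NA_integer_)
    d <- abs(observed$mz - mz)
    i <- which.min(d)
    if (d[i] <= tol_da) i else NA_integer_
  }
  idx <- vapply(predicted$mz, match_one, integer(1))
  res <- dplyr::mutate(predicted,
    found = !is.na(idx),
    observed_mz = ifelse(is.na(idx), NA_real_, observed$mz[idx]),
    error_da = .data$observed_mz - .data$mz,
    observed_abundance = ifelse(is.na(idx), NA_real_, observed$abundance[idx]))
  found_rules <- res$rule[res$found]
  tier <- if ("reagent_fragment" %in% found_rules &&
              any(c("headgroup", "headgroup_secondary") %in% found_rules)) {
    "high"
  } else if ("neutral_loss" %in% found_rules ||
             "reagent_fragment" %in% found_rules) {
    "medium"
  } else {
    "low"
  }
  out <- list(fragments = res, tier = tier,
              n_found = sum(res$found), n_predicted = nrow(res))
  class(out) <- "msms_validation"
  out
}

#' @export
print.msms_validation <- function(x, ...) {
  cat(sprintf("<msms_validation> tier: %s (%d/%d fragments found)\n",
              x$tier, x$n_found, x$n_predicted))
  print(x$fragments)
  invisible(x)
}

#' @rdname match_msms
#' @param x An `msms_validation` object.
#' @param ... Unused.
#' @method tidy msms_validation
#' @export
tidy.msms_validation <- function(x, ...) x$fragments

#' @rdname match_msms
#' @method glance msms_validation
#' @export
glance.msms_validation <- function(x, ...) {
  tibble(tier = x$tier, n_found = x$n_found, n_predicted = x$n_predicted)
}
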