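# Per-step A/B form calls. Clear-cut A-form is rare in real structures;
# most steps fall in a continuum, so the call is deliberately conservative:
# it gates only on the two discriminants that best separate the forms, the
# Zp phosphorus statistic and the mean glycosidic torsion of the step's
# 3'-side nucleotides. Slide and twist are carried along as features but do
# not gate the call.

#' Default A/B form-call thresholds
#'
#' Zp is >= 1.5 Angstrom in A-form and <= 0.5 Angstrom in B-form steps;
#' chi is ~ -150 degrees in A-form and ~ -100 degrees in B-form
#' nucleotides, split at -120.
#'
#' @return Named list of thresholds (`zp_a`, `zp_b`, `chi_split`).
#' @export
form_thresholds <- function() {
  list(zp_a = 1.5, zp_b = 0.5, chi_split = -120)
}

#' Classify a dinucleotide step as A-form, B-form or intermediate
#'
#' A pure function of the step features: `"A"` requires `zp >= zp_a` and
#' mean chi on the A side of the split (`<= chi_split`); `"B"` requires
#' `zp <= zp_b` and mean chi on the B side; anything else is
#' `"intermediate"`.
#'
#' @param zp Zp of the step, Angstrom.
#' @param chi_mean Mean glycosidic torsion of the step's 3'-side
#'   nucleotides, degrees.
#' @param slide,twist Optional features carried into the result.
#' @param thresholds List as from [form_thresholds()].
#' @return List of class `"form_call"` with `label` ("A", "B" or
#'   "intermediate") and `features`.
#' @export
classify_form <- function(zp, chi_mean, slide = NA_real_, twist = NA_real_,
                          thresholds = form_thresholds()) {
  label <- if (is.na(zp) || is.na(chi_mean)) {
    "intermediate"
  } else if (zp >= thresholds$zp_a && chi_mean <= thresholds$chi_split) {
    "A"
  } else if (zp <= thresholds$zp_b && chi_mean >= thresholds$chi_split) {
    "B"
  } else {
    "intermediate"
  }
  structure(list(label = label,
                 features = c(zp = zp, chi_mean = chi_mean,
                              slide = slide, twist = twist)),
            class = "form_call")
}

#' @export
print.form_call <- function(x, ...) {
  cat(sprintf("<form_call %s (zp %.2f, chi %.1f)>\n", x$label,
              x$features[["zp"]], x$features[["chi_mean"]]))
  invisible(x)
}
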