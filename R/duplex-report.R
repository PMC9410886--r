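# The umbrella geometry report: step parameters, Zp, groove widths, per-
# nucleotide chi and per-step form calls for a duplex, in the shape used by
# the CLI's per-step and per-nucleotide TSV outputs.

#' Per-step geometry report for a duplex
#'
#' Combines [step_parameters()], [groove_widths()], the mean glycosidic
#' torsion of each step's 3'-side nucleotides, and the A/B/intermediate
#' form call of [classify_form()].
#'
#' @param duplex A `"duplex"`.
#' @param thresholds Form-call thresholds, see [form_thresholds()].
#' @return data.frame with one row per step: `step_index` (0-based), `bp1`,
#'   `bp2`, the six step parameters, `zp`, `chi_mean`, `major_groove`
#'   (width at the step's 5' base-pair position, `NA` where undefined) and
#'   `form_call`.
#' @export
duplex_report <- function(duplex, thresholds = form_thresholds()) {
  steps <- step_parameters(duplex, warn_missing_p = FALSE)
  gw <- groove_widths(duplex)
  chi_of <- function(nt) tryCatch(chi(nt), error = function(e) NA_real_)
  chi_mean <- vapply(seq_len(nrow(steps)), function(i) {
    mean(c(chi_of(duplex[[i + 1]]$nt1), chi_of(duplex[[i]]$nt2)))
  }, numeric(1))
  major <- vapply(steps$step_index + 1L, function(pos) {
    hit <- gw$major[gw$position == pos]
    if (length(hit)) hit else NA_real_
  }, numeric(1))
  form <- vapply(seq_len(nrow(steps)), function(i) {
    classify_form(steps$zp[i], chi_mean[i], steps$slide[i], steps$twist[i],
                  thresholds)$label
  }, character(1))
  cbind(steps, chi_mean = chi_mean, major_groove = major,
        form_call = form, stringsAsFactors = FALSE)
}

#' Per-nucleotide geometry report
#'
#' @param duplex A `"duplex"`.
#' @return data.frame with `chain`, `resno`, `base`, `strand` (I or II),
#'   `chi` (degrees; `NA` when sugar atoms are absent).
#' @export
nucleotide_report <- function(duplex) {
  grab <- function(nt, strand) {
    data.frame(chain = nt$chain, resno = nt$resno, base = nt$base,
               strand = strand,
               chi = tryCatch(chi(nt), error = function(e) NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- c(lapply(duplex, function(bp) grab(bp$nt1, "I")),
           lapply(duplex, function(bp) grab(bp$nt2, "II")))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
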