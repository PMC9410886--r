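# SYNTHETIC trinucleotide B-to-A free-energy scale.
#
# A-philicity profiling scores each trinucleotide with the free-energy cost
# dG(B->A) of converting it from B- to A-form (kcal/mol; low = A-philic).
# The experimentally derived published scale could not be bundled here, so
# this file embeds a synthetic stand-in constructed to preserve the
# structural properties profiling relies on:
#   * reverse-complement symmetry (a duplex trinucleotide and its
#     complement share one value), hence exactly 32 unique values;
#   * G/C-rich trimers are the most A-philic (GGC/GCC lowest) and A/T
#     tracts the most B-philic (AAA/TTT, AAT/ATT highest), with YR-step
#     containing trimers intermediate;
#   * a spread of ~0.04-1.32 kcal/mol and a human-genome-composition
#     (41% G+C) average of ~0.71, the flat background level expected for
#     random genomic sequence.
# Absolute per-trimer values are NOT the published measurements; analyses
# that depend on exact entries rather than on the ordering/symmetry/scale
# above should substitute a measured table via the `table` arguments.

.dg_b2a_unique <- c(
  GGC = 0.036, CGG = 0.182, GCG = 0.109, GGG = 0.146, GCA = 0.201,
  GGA = 0.255, GGT = 0.310, AGC = 0.347, CGA = 0.383, CCA = 0.420,
  AGG = 0.456, ACG = 0.502, TCA = 0.547, CAG = 0.566, GAC = 0.584,
  CAC = 0.602, AGA = 0.639, GAG = 0.657, ATG = 0.675, ACT = 0.712,
  CTA = 0.748, GAT = 0.766, CAA = 0.803, ACA = 0.821, GTA = 0.867,
  GAA = 0.894, AAC = 0.931, AAG = 0.967, TAA = 1.004, ATA = 1.095,
  AAT = 1.204, AAA = 1.323
)

#' Reverse complement of a character DNA string
#'
#' @param x Character vector of DNA strings (ACGTN alphabet).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Trinucleotide B-to-A transition free-energy table (synthetic scale)
#'
#' Returns the embedded 64-entry trinucleotide -> dG(B->A) map (kcal/mol).
#' The scale is synthetic (see the package vignette): it reproduces the
#' reverse-complement symmetry, ordering and magnitude of sequence-
#' dependent B-to-A energetics, with 32 unique values, but not the exact
#' published per-trimer measurements.
#'
#' @return Named numeric vector of length 64; `value[t] == value[revcomp(t)]`.
#' @export
trinuc_dg_table <- function() {
  tab <- c(.dg_b2a_unique,
           stats::setNames(.dg_b2a_unique, revcomp(names(.dg_b2a_unique))))
  tab[order(names(tab))]
}

#' @noRd
validate_dg_table <- function(table) {
  if (length(table) != 64 || is.null(names(table))) {
    stop("dG table must be a named 64-entry vector")
  }
  if (!all(is.finite(table))) stop("dG table values must be finite")
  if (any(abs(table[names(table)] - table[revcomp(names(table))]) > 1e-9)) {
    stop("dG table must be reverse-complement symmetric")
  }
  table
}

#' Composition-weighted mean of a trinucleotide dG table
#'
#' The expected profile level for random sequence with independent bases at
#' the given composition; used as the flat-background reference.
#'
#' @param composition Named probabilities for A, C, G, T (summing to 1).
#' @param table Trinucleotide table, default [trinuc_dg_table()].
#' @return Numeric scalar, kcal/mol.
#' @export
dg_background_mean <- function(composition = c(A = 0.295, C = 0.205,
                                               G = 0.205, T = 0.295),
                               table = trinuc_dg_table()) {
  stopifnot(abs(sum(composition) - 1) < 1e-6)
  table <- validate_dg_table(table)
  w <- vapply(names(table), function(t) {
    b <- strsplit(t, "")[[1]]
    composition[[b[1]]] * composition[[b[2]]] * composition[[b[3]]]
  }, numeric(1))
  sum(w * table) / sum(w)
}
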