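# Standard reference-frame base geometries (Tsukuba convention): idealized
# base atoms expressed in the standard base coordinate system, in which the
# x-axis points from the pair center toward the major groove, the y-axis runs
# along the long (C1'-C1') axis toward the strand carrying the base, and the
# z-axis (x cross y) points along the 5'->3' direction of that strand. Ring
# atoms plus C1' are tabulated; only the ring atoms enter frame fitting.
# Units: Angstrom.

.std_base_tab <- list(
  A = rbind(
    N9  = c(-1.291, 4.498, 0.000),
    C8  = c( 0.024, 4.897, 0.000),
    N7  = c( 0.877, 3.902, 0.000),
    C5  = c( 0.071, 2.771, 0.000),
    C6  = c( 0.369, 1.398, 0.000),
    N1  = c(-0.668, 0.532, 0.000),
    C2  = c(-1.912, 1.023, 0.000),
    N3  = c(-2.320, 2.290, 0.000),
    C4  = c(-1.267, 3.124, 0.000),
    `C1'` = c(-2.479, 5.346, 0.000)
  ),
  G = rbind(
    N9  = c(-1.289, 4.551, 0.000),
    C8  = c( 0.023, 4.962, 0.000),
    N7  = c( 0.870, 3.969, 0.000),
    C5  = c( 0.071, 2.833, 0.000),
    C6  = c( 0.424, 1.460, 0.000),
    N1  = c(-0.700, 0.641, 0.000),
    C2  = c(-1.999, 1.087, 0.000),
    N3  = c(-2.342, 2.364, 0.001),
    C4  = c(-1.265, 3.177, 0.000),
    `C1'` = c(-2.477, 5.399, 0.000)
  ),
  C = rbind(
    N1  = c(-1.285, 4.542, 0.000),
    C2  = c(-1.472, 3.158, 0.000),
    N3  = c(-0.391, 2.344, 0.000),
    C4  = c( 0.837, 2.868, 0.000),
    C5  = c( 1.056, 4.275, 0.000),
    C6  = c(-0.023, 5.068, 0.000),
    `C1'` = c(-2.477, 5.402, 0.000)
  ),
  T = rbind(
    N1  = c(-1.284, 4.500, 0.000),
    C2  = c(-1.462, 3.135, 0.000),
    N3  = c(-0.298, 2.407, 0.000),
    C4  = c( 0.994, 2.897, 0.000),
    C5  = c( 1.106, 4.338, 0.000),
    C6  = c(-0.024, 5.057, 0.000),
    `C1'` = c(-2.481, 5.354, 0.000)
  ),
  U = rbind(
    N1  = c(-1.284, 4.500, 0.000),
    C2  = c(-1.462, 3.131, 0.000),
    N3  = c(-0.302, 2.397, 0.000),
    C4  = c( 0.989, 2.884, 0.000),
    C5  = c( 1.089, 4.311, 0.000),
    C6  = c(-0.024, 5.053, 0.000),
    `C1'` = c(-2.481, 5.354, 0.000)
  )
)

.purines <- c("A", "G")
.pyrimidines <- c("C", "T", "U")

#' Ring atom names required to fit a base reference frame
#'
#' Nine atoms for purines (N9, C8, N7, C5, C6, N1, C2, N3, C4) and six for
#' pyrimidines (N1, C2, N3, C4, C5, C6). Exocyclic atoms are deliberately
#' excluded: they degrade the fit on chemically modified or strongly
#' deformed bases.
#'
#' @param base Single base letter, one of `"A"`, `"C"`, `"G"`, `"T"`, `"U"`.
#' @return Character vector of atom names.
#' @export
ring_atoms <- function(base) {
  base <- toupper(base)
  if (base %in% .purines) {
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  } else if (base %in% .pyrimidines) {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  } else {
    stop("unknown base: ", base)
  }
}

#' Standard reference-frame coordinates of an idealized base
#'
#' @param base Single base letter (A, C, G, T or U).
#' @param atoms Optional subset of atom names to return.
#' @return Numeric matrix (atoms x 3) of coordinates in the standard base
#'   frame, in Angstrom. Row names are atom labels.
#' @export
standard_base_coords <- function(base, atoms = NULL) {
  base <- toupper(base)
  tab <- .std_base_tab[[base]]
  if (is.null(tab)) stop("unknown base: ", base)
  colnames(tab) <- c("x", "y", "z")
  if (!is.null(atoms)) {
    missing <- setdiff(atoms, rownames(tab))
    if (length(missing)) {
      stop("no standard coordinates for atom(s): ",
           paste(missing, collapse = ", "))
    }
    tab <- tab[atoms, , drop = FALSE]
  }
  tab
}

# Glycosidic atoms defining chi: O4'-C1'-N9-C4 (purines), O4'-C1'-N1-C2
# (pyrimidines), listed 5'-sugar side first.
#' @noRd
chi_atoms <- function(base) {
  base <- toupper(base)
  if (base %in% .purines) c("O4'", "C1'", "N9", "C4")
  else if (base %in% .pyrimidines) c("O4'", "C1'", "N1", "C2")
  else stop("unknown base: ", base)
}

#' @noRd
glycosidic_n <- function(base) if (toupper(base) %in% .purines) "N9" else "N1"

#' @noRd
complement_base <- function(base) {
  c(A = "T", C = "G", G = "C", T = "A", U = "A")[[toupper(base)]]
}
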