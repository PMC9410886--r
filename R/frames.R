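# Base reference frames: least-squares superposition of the idealized
# standard-frame base onto observed ring atoms, plus the glycosidic torsion.

#' Fit the standard reference frame of a base
#'
#' Rigidly superposes the embedded standard base geometry onto the observed
#' base ring atoms (9 for purines, 6 for pyrimidines) by least squares and
#' returns the transformed standard frame. The frame origin is the image of
#' the standard-frame origin; the rotation columns are the frame x, y and z
#' axes expressed in global coordinates.
#'
#' @param nt A [nucleotide] record containing all required ring atoms.
#' @return A list of class `"ref_frame"`: `origin` (length-3 numeric, in
#'   Angstrom), `rotation` (3x3 orthonormal, det +1) and `rmsd` (the fit
#'   root-mean-square deviation in Angstrom).
#' @export
fit_base_frame <- function(nt) {
  ra <- ring_atoms(nt$base)
  missing <- setdiff(ra, rownames(nt$atoms))
  if (length(missing)) {
    stop(sprintf("nucleotide %s%d (%s): missing ring atom(s) %s",
                 nt$chain, nt$resno, nt$base, paste(missing, collapse = ", ")))
  }
  std <- standard_base_coords(nt$base, ra)
  obs <- nt$atoms[ra, , drop = FALSE]
  fit <- kabsch(std, obs)
  frame <- list(origin = as.numeric(fit$t), rotation = fit$R, rmsd = fit$rmsd)
  class(frame) <- "ref_frame"
  frame
}

#' @export
print.ref_frame <- function(x, ...) {
  cat(sprintf("<ref_frame origin (%.2f, %.2f, %.2f), rmsd %.3f A>\n",
              x$origin[1], x$origin[2], x$origin[3], x$rmsd))
  invisible(x)
}

#' Glycosidic torsion angle chi
#'
#' Signed dihedral O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
#' pyrimidines, in degrees in (-180, 180]. Values near -150 are typical of
#' A-form and near -100 of B-form nucleotides.
#'
#' @param nt A [nucleotide] with O4', C1' and the glycosidic base atoms.
#' @return Numeric scalar in degrees.
#' @export
chi <- function(nt) {
  nm <- chi_atoms(nt$base)
  pts <- lapply(nm, nt_atom, nt = nt)
  bad <- nm[vapply(pts, is.null, logical(1))]
  if (length(bad)) {
    stop(sprintf("nucleotide %s%d (%s): missing atom(s) %s for chi",
                 nt$chain, nt$resno, nt$base, paste(bad, collapse = ", ")))
  }
  dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}
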