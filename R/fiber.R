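# Idealized A- and B-form fiber duplexes. Construction is by global helical
# symmetry: every base pair carries the standard-reference-frame base
# geometry, placed on a regular helix defined by per-form helical twist,
# helical rise, x-displacement of the pair from the helix axis, and base
# inclination. The glycosidic O4' is built at the canonical chi torsion and
# the phosphorus at a fixed per-form position in the base frame. Because the
# generator works in global helical coordinates (never through the
# mid-step-frame algebra), it is an independent geometric reference for the
# step-parameter engine.

# Per-form parameters. Helical twist/rise are the fiber-diffraction values
# (B: 10 bp/turn, 3.38 A; A: 11 bp/turn, 2.56 A). Inclination and
# x-displacement reproduce the canonical local-step values (B: twist 36,
# slide ~0; A: local twist ~31, slide <= -1.5). chi targets are canonical
# fiber values. The phosphorus position (base-frame coordinates, identical
# for every residue of a form) was calibrated once against canonical
# phosphate observables: intra-strand P-P spacing (B 7.0 A, A 5.9 A),
# Zp (B ~ -0.3 A, A ~ +2.2 A) and direct cross-strand groove widths.
.fiber_pars <- list(
  B = list(twist = 36.0, rise = 3.38, xdisp = 0.0, incl = 0.0,
           chi = -102, p_local = c(0.649, 9.762, -1.983)),
  A = list(twist = 32.7, rise = 2.56, xdisp = -4.50, incl = 19.1,
           chi = -157, p_local = c(1.746, 9.724, 0.506))
)

#' @noRd
validate_dna_string <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2) stop("sequence must have length >= 2")
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over the ACGT alphabet")
  sequence
}

# Build all atoms of one nucleotide given its base frame (R, o): ring atoms,
# C1', O4' at the requested chi, and optionally P at p_local.
#' @noRd
fiber_nucleotide <- function(base, R, o, chi_deg, p_local, with_p,
                             chain, resno) {
  std <- standard_base_coords(base)
  atoms <- t(R %*% t(std)) + matrix(o, nrow(std), 3, byrow = TRUE)
  rownames(atoms) <- rownames(std)
  n_name <- glycosidic_n(base)
  ref_name <- chi_atoms(base)[4]
  o4 <- place_by_internal(a = atoms[ref_name, ], b = atoms[n_name, ],
                          c = atoms["C1'", ],
                          length = 1.414, angle = 108.2, torsion = chi_deg)
  atoms <- rbind(atoms, `O4'` = o4)
  if (with_p) {
    atoms <- rbind(atoms, P = as.numeric(o + R %*% p_local))
  }
  nucleotide(chain, resno, base, atoms)
}

#' Build an idealized A- or B-form fiber duplex
#'
#' Generates full-duplex coordinates (base ring atoms, C1', O4', P) for an
#' arbitrary sequence on a regular helix with canonical per-form geometry.
#' The 5'-terminal residue of each strand carries no phosphate, as in real
#' oligonucleotides.
#'
#' @param sequence Strand-I sequence, 5'->3', over ACGT, length >= 2.
#' @param form `"A"` or `"B"`.
#' @return A `"duplex"` whose strand II is the reverse complement of
#'   `sequence` (chains "A" and "B"). Attribute `"nucleotides"` holds the
#'   flat nucleotide list for structure output.
#' @export
build_fiber_duplex <- function(sequence, form = c("B", "A")) {
  form <- match.arg(form)
  sequence <- validate_dna_string(sequence)
  par <- .fiber_pars[[form]]
  bases <- strsplit(sequence, "")[[1]]
  n <- length(bases)
  om <- deg2rad(par$twist)
  incl <- deg2rad(par$incl)
  flip <- diag(c(1, -1, -1))
  s1 <- vector("list", n); s2 <- vector("list", n)
  for (i in seq_len(n)) {
    Ri <- rot_z((i - 1) * om) %*% rot_x(incl)
    oi <- c(par$xdisp * cos((i - 1) * om), par$xdisp * sin((i - 1) * om),
            (i - 1) * par$rise)
    s1[[i]] <- fiber_nucleotide(bases[i], Ri, oi, par$chi, par$p_local,
                                with_p = (i > 1), chain = "A", resno = i)
    # complementary strand: z-flipped frame; its 5' terminus pairs bp n
    s2[[i]] <- fiber_nucleotide(complement_base(bases[i]), Ri %*% flip, oi,
                                par$chi, par$p_local,
                                with_p = (i < n), chain = "B",
                                resno = n - i + 1)
  }
  dup <- duplex_from_strands(s1, s2, check_wc = FALSE)
  attr(dup, "nucleotides") <- c(s1, rev(s2))
  attr(dup, "form") <- form
  dup
}

#' Reconstruct a duplex from explicit step parameters
#'
#' Chains base-pair frames from a starting frame through the exact inverse
#' of the mid-step-frame construction and dresses each frame with standard
#' base atoms. Recomputing step parameters from the result reproduces the
#' input to numerical precision, which makes this the round-trip oracle for
#' the extraction algebra. Backbone atoms are not modeled, so Zp and chi
#' are undefined on the output.
#'
#' @param sequence Strand-I sequence (ACGT), length `length(params) + 1`.
#' @param params data.frame with columns `shift`, `slide`, `rise`, `tilt`,
#'   `roll`, `twist`, one row per step.
#' @return A `"duplex"`.
#' @export
build_from_step_parameters <- function(sequence, params) {
  sequence <- validate_dna_string(sequence)
  bases <- strsplit(sequence, "")[[1]]
  need <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  stopifnot(all(need %in% names(params)))
  if (nrow(params) != length(bases) - 1) {
    stop("need exactly length(sequence) - 1 parameter rows")
  }
  frames <- vector("list", length(bases))
  frames[[1]] <- structure(list(origin = c(0, 0, 0), rotation = diag(3),
                                rmsd = NA_real_), class = "ref_frame")
  for (i in seq_len(nrow(params))) {
    frames[[i + 1]] <- frames_from_step(frames[[i]],
                                        params$shift[i], params$slide[i],
                                        params$rise[i], params$tilt[i],
                                        params$roll[i], params$twist[i])$f2
  }
  flip <- diag(c(1, -1, -1))
  n <- length(bases)
  s1 <- vector("list", n); s2 <- vector("list", n)
  for (i in seq_len(n)) {
    R <- frames[[i]]$rotation; o <- frames[[i]]$origin
    std1 <- standard_base_coords(bases[i])
    a1 <- t(R %*% t(std1)) + matrix(o, nrow(std1), 3, byrow = TRUE)
    rownames(a1) <- rownames(std1)
    s1[[i]] <- nucleotide("A", i, bases[i], a1)
    cb <- complement_base(bases[i])
    std2 <- standard_base_coords(cb)
    Rf <- R %*% flip
    a2 <- t(Rf %*% t(std2)) + matrix(o, nrow(std2), 3, byrow = TRUE)
    rownames(a2) <- rownames(std2)
    s2[[i]] <- nucleotide("B", n - i + 1, cb, a2)
  }
  dup <- duplex_from_strands(s1, s2, check_wc = FALSE)
  attr(dup, "nucleotides") <- c(s1, rev(s2))
  dup
}
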