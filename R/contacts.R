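# Protein-DNA contact enumeration at a distance cutoff, with each contact
# annotated by the DNA moiety touched (base / sugar / phosphate; the three
# classes partition the heavy-atom names of a nucleotide) and, for contacts
# near a base-pair plane, the groove side approached.

.phosphate_atoms <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O5'", "O3'")
.sugar_atoms <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'")

#' @noRd
dna_moiety <- function(atom_name) {
  if (atom_name %in% .phosphate_atoms) "phosphate"
  else if (atom_name %in% .sugar_atoms) "sugar"
  else "base"
}

# Groove side of a point relative to a base-pair frame: in the standard
# frame +x points toward the major groove. Points close to the frame
# x-axis region are assigned major (x >= 1) or minor (x <= -1); anything
# ambiguous or far from the pair (> 12 A radial) is "none".
#' @noRd
groove_side <- function(point, frame) {
  v <- as.numeric(crossprod(frame$rotation, point - frame$origin))
  if (vnorm(v) > 12 || abs(v[1]) < 1) return("none")
  if (v[1] >= 1) "major" else "minor"
}

#' Enumerate protein-DNA atomic contacts
#'
#' All protein-atom / DNA-atom pairs within the cutoff distance. The
#' default of 3.9 Angstrom covers both Van der Waals and donor-acceptor
#' hydrogen-bond contacts between heavy atoms.
#'
#' @param structure A `"dna_structure"` containing protein and DNA.
#' @param cutoff Distance cutoff in Angstrom (default 3.9).
#' @param duplex Optional `"duplex"` built from the structure; when given,
#'   each contact is annotated with the groove side of the nearest base
#'   pair, otherwise groove is `"none"`.
#' @return data.frame with one row per contact: protein chain/resno/resid/
#'   atom, DNA chain/resno/base/atom, `distance`, `dna_moiety`, `groove`.
#' @export
find_contacts <- function(structure, cutoff = 3.9, duplex = NULL) {
  prot <- structure$protein
  if (!nrow(prot)) stop("structure contains no protein residues")
  nts <- structure$nucleotides
  if (!length(nts)) stop("structure contains no DNA residues")
  pm <- as.matrix(prot[, c("x", "y", "z")])
  frames <- if (!is.null(duplex)) lapply(duplex, `[[`, "frame") else NULL
  rows <- list()
  for (nt in nts) {
    dm <- nt$atoms
    # squared-distance block between this nucleotide and all protein atoms
    for (a in seq_len(nrow(dm))) {
      d2 <- rowSums(sweep(pm, 2, dm[a, ])^2)
      hit <- which(d2 <= cutoff^2)
      for (h in hit) {
        groove <- "none"
        if (!is.null(frames)) {
          dists <- vapply(frames, function(f) vnorm(f$origin - dm[a, ]),
                          numeric(1))
          groove <- groove_side(as.numeric(pm[h, ]),
                                frames[[which.min(dists)]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          protein_chain = prot$chain[h], protein_resno = prot$resno[h],
          protein_resid = prot$resid[h], protein_atom = prot$elety[h],
          dna_chain = nt$chain, dna_resno = nt$resno, dna_base = nt$base,
          dna_atom = rownames(dm)[a],
          distance = sqrt(d2[h]),
          dna_moiety = dna_moiety(rownames(dm)[a]),
          groove = groove,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_chain = character(), protein_resno = integer(),
                      protein_resid = character(), protein_atom = character(),
                      dna_chain = character(), dna_resno = integer(),
                      dna_base = character(), dna_atom = character(),
                      distance = numeric(), dna_moiety = character(),
                      groove = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
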