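# Structure input: PDB / mmCIF parsing into the package's light-weight
# nucleotide + protein representation. File reading is delegated to bio3d;
# this layer resolves altlocs, strips hydrogens and waters, normalizes atom
# labels and groups DNA atoms per residue.

.dna_resids <- c(DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
                 A = "A", C = "C", G = "G", T = "T", U = "U",
                 ADE = "A", CYT = "C", GUA = "G", THY = "T", URA = "U")

.aa_resids <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

#' Construct a nucleotide record
#'
#' A nucleotide is the unit the geometry engine works on: a base identity
#' plus a named set of heavy-atom coordinates.
#'
#' @param chain Chain identifier.
#' @param resno Residue number (integer).
#' @param base Base letter (A, C, G, T or U).
#' @param atoms Numeric matrix (n x 3) with atom names as row names;
#'   coordinates in Angstrom. All coordinates must be finite.
#' @return An object of class `"nucleotide"`.
#' @export
nucleotide <- function(chain, resno, base, atoms) {
  stopifnot(is.matrix(atoms), ncol(atoms) == 3, !is.null(rownames(atoms)))
  if (!all(is.finite(atoms))) stop("non-finite atom coordinates")
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T", "U")) stop("unknown base: ", base)
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 base = base, atoms = atoms),
            class = "nucleotide")
}

#' @export
print.nucleotide <- function(x, ...) {
  cat(sprintf("<nucleotide %s %s%d, %d atoms>\n",
              x$base, x$chain, x$resno, nrow(x$atoms)))
  invisible(x)
}

#' @noRd
nt_atom <- function(nt, name) {
  if (!name %in% rownames(nt$atoms)) return(NULL)
  as.numeric(nt$atoms[name, ])
}

# Normalize atom labels: primes for old-style asterisks, C7 for thymine C5M.
#' @noRd
normalize_elety <- function(x) {
  x <- gsub('^"|"$', "", x)           # mmCIF-quoted labels (e.g. "C1'")
  x <- gsub("*", "'", x, fixed = TRUE)
  x[x == "C5M"] <- "C7"
  x
}

# Altloc resolution: keep the highest-occupancy alternate per
# (chain, resno, insert, atom); ties resolved by file order.
#' @noRd
resolve_altloc <- function(atom) {
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(atom)))
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(key[ord]), , drop = FALSE]
}

#' Parse a DNA-containing structure from PDB or mmCIF
#'
#' Reads an atomic coordinate file, resolves alternate locations to the
#' highest-occupancy conformer, discards hydrogens and waters, and returns
#' DNA residues grouped per nucleotide together with the protein atoms
#' retained for contact analysis.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"` or `"mmcif"`. Defaults from the file extension.
#' @return An object of class `"dna_structure"`: a list with elements
#'   `nucleotides` (list of [nucleotide] records, file order),
#'   `protein` (data.frame of protein atoms: chain, resno, resid, elety,
#'   x, y, z) and `source` (the input path).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE,
                                         verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("unreadable ", format, " file: ",
                             conditionMessage(e), call. = FALSE)
  )
  atom <- pdb$atom
  atom$insert[is.na(atom$insert)] <- ""
  atom <- atom[atom$resid != "HOH", , drop = FALSE]
  elesy <- if (!is.null(atom$elesy)) atom$elesy else
    substr(gsub("[^A-Za-z].*", "", atom$elety), 1, 1)
  atom <- atom[!(toupper(trimws(elesy)) %in% c("H", "D")), , drop = FALSE]
  atom$elety <- normalize_elety(trimws(atom$elety))
  atom <- resolve_altloc(atom)
  # restore file order after altloc resolution
  atom <- atom[order(as.numeric(rownames(atom))), , drop = FALSE]

  is_dna <- atom$resid %in% names(.dna_resids)
  is_prot <- atom$resid %in% .aa_resids
  if (!any(is_dna)) stop("no nucleic-acid residues found in ", path)

  dna <- atom[is_dna, , drop = FALSE]
  key <- paste(dna$chain, dna$resno, dna$insert, sep = "\r")
  nts <- lapply(split(seq_len(nrow(dna)), factor(key, levels = unique(key))),
                function(i) {
    d <- dna[i, , drop = FALSE]
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- d$elety
    nucleotide(d$chain[1], d$resno[1], .dna_resids[[d$resid[1]]], m)
  })
  names(nts) <- NULL

  prot <- atom[is_prot, c("chain", "resno", "resid", "elety", "x", "y", "z"),
               drop = FALSE]
  rownames(prot) <- NULL
  structure(list(nucleotides = nts, protein = prot, source = path),
            class = "dna_structure")
}

#' @export
print.dna_structure <- function(x, ...) {
  cat(sprintf("<dna_structure: %d nucleotides, %d protein atoms (%s)>\n",
              length(x$nucleotides), nrow(x$protein), x$source))
  invisible(x)
}

#' Write a set of nucleotides (and optional protein atoms) to a PDB file
#'
#' Used by the fiber generator and the CLI to emit standard PDB output.
#'
#' @param nts List of [nucleotide] records.
#' @param file Output path.
#' @export
write_structure_pdb <- function(nts, file) {
  resid_of <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DU")
  xyz <- NULL; elety <- character(); resid <- character()
  chain <- character(); resno <- integer()
  for (nt in nts) {
    xyz <- rbind(xyz, nt$atoms)
    elety <- c(elety, rownames(nt$atoms))
    resid <- c(resid, rep(resid_of[[nt$base]], nrow(nt$atoms)))
    chain <- c(chain, rep(nt$chain, nrow(nt$atoms)))
    resno <- c(resno, rep(nt$resno, nrow(nt$atoms)))
  }
  bio3d::write.pdb(file = file, xyz = as.vector(t(xyz)), type = "ATOM",
                   elety = elety, resid = resid, chain = chain, resno = resno)
  invisible(file)
}
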