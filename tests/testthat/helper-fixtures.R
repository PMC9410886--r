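# Shared fixtures and independent oracles, all generated in code.

rot_about <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th); vt <- 1 - ct
  matrix(c(ct + u[1]^2 * vt, u[1] * u[2] * vt - u[3] * st, u[1] * u[3] * vt + u[2] * st,
           u[1] * u[2] * vt + u[3] * st, ct + u[2]^2 * vt, u[2] * u[3] * vt - u[1] * st,
           u[1] * u[3] * vt - u[2] * st, u[2] * u[3] * vt + u[1] * st, ct + u[3]^2 * vt),
         3, 3, byrow = TRUE)
}

random_rotation <- function() rot_about(rnorm(3), runif(1, 0, 360))

make_frame <- function(origin = c(0, 0, 0), rotation = diag(3)) {
  structure(list(origin = origin, rotation = rotation, rmsd = NA_real_),
            class = "ref_frame")
}

# A nucleotide with standard base atoms placed by an explicit frame.
nt_at_frame <- function(base, R = diag(3), o = c(0, 0, 0), chain = "A",
                        resno = 1, flip = FALSE, extra = NULL) {
  std <- standard_base_coords(base)
  if (flip) std <- std %*% diag(c(1, -1, -1))
  atoms <- t(R %*% t(std)) + matrix(o, nrow(std), 3, byrow = TRUE)
  rownames(atoms) <- rownames(std)
  if (!is.null(extra)) atoms <- rbind(atoms, extra)
  nucleotide(chain, resno, base, atoms)
}

# Apply one rigid motion to every atom of every nucleotide in a duplex.
transform_duplex <- function(duplex, R, t) {
  move <- function(nt) {
    nt$atoms <- t(R %*% t(nt$atoms)) + matrix(t, nrow(nt$atoms), 3,
                                              byrow = TRUE)
    nt
  }
  s1 <- lapply(duplex, function(bp) move(bp$nt1))
  s2 <- lapply(duplex, function(bp) move(bp$nt2))
  duplex_from_strands(s1, s2)
}

# Swap strands and reverse order: the same double helix read from the
# other strand.
reverse_duplex <- function(duplex) {
  s1 <- rev(lapply(duplex, `[[`, "nt2"))
  s2 <- rev(lapply(duplex, `[[`, "nt1"))
  duplex_from_strands(s1, s2)
}

# Brute-force all-pairs contact oracle.
brute_force_contacts <- function(structure, cutoff = 3.9) {
  prot <- structure$protein
  hits <- 0L
  pairs <- list()
  for (nt in structure$nucleotides) {
    for (a in seq_len(nrow(nt$atoms))) {
      for (h in seq_len(nrow(prot))) {
        d <- sqrt(sum((nt$atoms[a, ] - c(prot$x[h], prot$y[h], prot$z[h]))^2))
        if (d <= cutoff) {
          pairs[[length(pairs) + 1L]] <-
            c(prot$elety[h], rownames(nt$atoms)[a], sprintf("%.6f", d))
        }
      }
    }
  }
  pairs
}

# Hand-written single-residue PDB / mmCIF fixtures.
write_tiny_pdb <- function(nts, path) {
  resid_of <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DU")
  lines <- character(); serial <- 0L
  for (nt in nts) {
    for (a in seq_len(nrow(nt$atoms))) {
      serial <- serial + 1L
      nm <- rownames(nt$atoms)[a]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, nm, resid_of[[nt$base]], nt$chain, nt$resno,
        nt$atoms[a, 1], nt$atoms[a, 2], nt$atoms[a, 3], 1.00, 0.00,
        substr(nm, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

write_tiny_cif <- function(nts, path) {
  resid_of <- c(A = "DA", C = "DC", G = "DG", T = "DT", U = "DU")
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
              "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
  lines <- c("data_fixture", "loop_", paste0("_atom_site.", fields))
  serial <- 0L
  for (nt in nts) {
    for (a in seq_len(nrow(nt$atoms))) {
      serial <- serial + 1L
      nm <- rownames(nt$atoms)[a]
      lines <- c(lines, sprintf(
        'ATOM %d %s "%s" . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s "%s" 1',
        serial, substr(nm, 1, 1), nm, resid_of[[nt$base]], nt$chain,
        nt$resno, nt$atoms[a, 1], nt$atoms[a, 2], nt$atoms[a, 3],
        nt$resno, resid_of[[nt$base]], nt$chain, nm))
    }
  }
  writeLines(c(lines, "#"), path)
  path
}

# Monte-Carlo standard error of a profile position for i.i.d. background.
profile_mc_se <- function(table, composition, n) {
  tab <- table
  w <- vapply(names(tab), function(t) {
    b <- strsplit(t, "")[[1]]
    composition[[b[1]]] * composition[[b[2]]] * composition[[b[3]]]
  }, numeric(1))
  w <- w / sum(w)
  mu <- sum(w * tab)
  sqrt(sum(w * (tab - mu)^2) / n)
}
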