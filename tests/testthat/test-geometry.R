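# Geometry engine: frame fitting, torsions, step parameters, Zp, grooves,
# contacts and form calls.

test_that("base frame fitting recovers identity, known motions and stays accurate under noise", {
  # standard atoms verbatim: identity frame, zero rmsd
  nt <- nt_at_frame("G")
  f <- fit_base_frame(nt)
  expect_lt(max(abs(f$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(f$origin)), 1e-9)
  expect_lt(f$rmsd, 1e-9)

  # forward-constructed rotation + translation is recovered exactly
  set.seed(11)
  for (k in 1:20) {
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    base <- sample(c("A", "C", "G", "T"), 1)
    f <- fit_base_frame(nt_at_frame(base, R, t))
    expect_lt(max(abs(f$rotation - R)), 1e-9)
    expect_lt(max(abs(f$origin - t)), 1e-9)
    expect_true(abs(det(f$rotation) - 1) < 1e-9)
    expect_lt(max(abs(crossprod(f$rotation) - diag(3))), 1e-6)
  }

  # 0.1 A isotropic perturbation keeps the fit rmsd bounded
  set.seed(12)
  for (k in 1:50) {
    nt <- nt_at_frame("A")
    # 0.1 A isotropic displacement per atom (0.1/sqrt(3) per coordinate)
    nt$atoms <- nt$atoms + matrix(rnorm(length(nt$atoms), sd = 0.1 / sqrt(3)),
                                  nrow(nt$atoms), 3)
    expect_lte(fit_base_frame(nt)$rmsd, 0.2)
  }

  # missing ring atoms are an error
  bad <- nt_at_frame("A")
  bad$atoms <- bad$atoms[rownames(bad$atoms) != "N7", ]
  expect_error(fit_base_frame(bad), "missing ring atom")
})

test_that("chi is the signed glycosidic dihedral", {
  base_nt <- function(torsion) {
    nt <- nt_at_frame("A")
    o4 <- dnaform:::place_by_internal(
      a = nt$atoms["C4", ], b = nt$atoms["N9", ], c = nt$atoms["C1'", ],
      length = 1.414, angle = 108.2, torsion = torsion)
    nt$atoms <- rbind(nt$atoms, `O4'` = o4)
    nt
  }
  expect_equal(chi(base_nt(0)), 0, tolerance = 1e-8)
  expect_equal(chi(base_nt(-120)), -120, tolerance = 1e-8)
  expect_equal(chi(base_nt(150)), 150, tolerance = 1e-8)
  expect_error(chi(nt_at_frame("A")), "missing atom")
})

test_that("structure parsing handles PDB, mmCIF and altlocs consistently", {
  nt <- nt_at_frame("A")
  pdb <- write_tiny_pdb(list(nt), withr::local_tempfile(fileext = ".pdb"))
  st <- parse_structure(pdb, "pdb")
  expect_length(st$nucleotides, 1)
  expect_identical(st$nucleotides[[1]]$base, "A")
  expect_equal(nrow(st$nucleotides[[1]]$atoms), 10)

  cif <- write_tiny_cif(list(nt), withr::local_tempfile(fileext = ".cif"))
  st2 <- parse_structure(cif, "mmcif")
  expect_identical(st$nucleotides[[1]]$base, st2$nucleotides[[1]]$base)
  expect_equal(st$nucleotides[[1]]$atoms, st2$nucleotides[[1]]$atoms,
               tolerance = 1e-6)

  expect_error(parse_structure("no-such-file.pdb"), "not found")

  # altloc: highest occupancy wins
  alt <- c(
    sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
            1L, "N9", "A", "DA", "A", 1L, -1.291, 4.498, 0.0, 0.40, 0.0),
    sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
            2L, "N9", "B", "DA", "A", 1L, 10.0, 10.0, 10.0, 0.60, 0.0),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, f)
  st3 <- parse_structure(f, "pdb")
  expect_equal(as.numeric(st3$nucleotides[[1]]$atoms["N9", ]),
               c(10, 10, 10))
})

test_that("step parameters satisfy trivial constructions and round-trip to 1e-6", {
  f1 <- make_frame()
  # pure 3.4 A rise
  st <- dnaform:::step_from_frames(f1, make_frame(c(0, 0, 3.4)))
  expect_equal(unlist(st[c("shift", "slide", "rise", "tilt", "roll", "twist")]),
               c(shift = 0, slide = 0, rise = 3.4, tilt = 0, roll = 0,
                 twist = 0), tolerance = 1e-9)
  # 36 degree twist about z plus rise
  st <- dnaform:::step_from_frames(
    f1, make_frame(c(0, 0, 3.4), rot_about(c(0, 0, 1), 36)))
  expect_equal(st$twist, 36, tolerance = 1e-9)
  expect_equal(st$rise, 3.4, tolerance = 1e-9)
  expect_equal(abs(st$slide) + abs(st$shift) + abs(st$roll) + abs(st$tilt),
               0, tolerance = 1e-9)

  # property: random parameter vectors rebuild and re-extract exactly
  set.seed(21)
  for (k in 1:100) {
    f0 <- make_frame(rnorm(3, sd = 5), random_rotation())
    p <- c(shift = rnorm(1), slide = rnorm(1), rise = runif(1, 2, 4),
           tilt = rnorm(1, 0, 10), roll = rnorm(1, 0, 10),
           twist = runif(1, -170, 170))
    fb <- dnaform:::frames_from_step(f0, p[1], p[2], p[3], p[4], p[5], p[6])
    got <- dnaform:::step_from_frames(f0, fb$f2)
    expect_equal(unlist(got[c("shift", "slide", "rise", "tilt", "roll",
                              "twist")]),
                 p, tolerance = 1e-6)
    expect_lt(max(abs(crossprod(fb$f2$rotation) - diag(3))), 1e-6)
  }
})

test_that("Zp reflects strand-sense phosphate elevation and guards missing atoms", {
  # two parallel pair frames 3.4 A apart; mid-frame z is global z
  p_at <- function(z1, z2) {
    nt1a <- nt_at_frame("G", o = c(0, 0, 0), resno = 1)
    nt1b <- nt_at_frame("C", o = c(0, 0, 0), flip = TRUE, chain = "B",
                        resno = 2, extra = rbind(P = c(3, 6, -z2 + 1.7)))
    nt2a <- nt_at_frame("G", o = c(0, 0, 3.4), resno = 2,
                        extra = rbind(P = c(-3, 6, z1 + 1.7)))
    nt2b <- nt_at_frame("C", o = c(0, 0, 3.4), flip = TRUE, chain = "B",
                        resno = 1)
    d <- duplex_from_strands(list(nt1a, nt2a), list(nt1b, nt2b))
    zp(d[[1]], d[[2]])
  }
  # both phosphates in the mid-step xy-plane
  expect_equal(p_at(0, 0), 0, tolerance = 1e-9)
  # strand-sense-consistent elevation of +2 A on both strands
  expect_equal(p_at(2, 2), 2, tolerance = 1e-9)

  # missing bridging phosphate: NA with a warning from step_parameters
  d <- build_fiber_duplex("GCGC", "B")
  s1 <- lapply(d, `[[`, "nt1")
  s2 <- lapply(d, `[[`, "nt2")
  s1[[2]]$atoms <- s1[[2]]$atoms[rownames(s1[[2]]$atoms) != "P", ]
  d2 <- duplex_from_strands(s1, s2)
  expect_warning(sp <- step_parameters(d2), "Zp undefined")
  expect_true(is.na(sp$zp[1]))       # step 0 bridged by the deleted P
  expect_false(anyNA(sp$zp[2]))
  expect_error(zp(d2[[1]], d2[[2]]), "phosphate missing")
})

test_that("geometry outputs are invariant under global rigid-body motion", {
  d0 <- build_fiber_duplex("GCATGCAT", "A")
  ref_steps <- step_parameters(d0, warn_missing_p = FALSE)
  ref_chi <- nucleotide_report(d0)$chi
  set.seed(31)
  for (k in 1:5) {
    d1 <- transform_duplex(d0, random_rotation(), rnorm(3, sd = 20))
    st <- step_parameters(d1, warn_missing_p = FALSE)
    for (col in c("shift", "slide", "rise", "tilt", "roll", "twist", "zp")) {
      expect_equal(st[[col]], ref_steps[[col]], tolerance = 1e-6)
    }
    expect_equal(nucleotide_report(d1)$chi, ref_chi, tolerance = 1e-6)
  }
})

test_that("reversing and swapping strands maps parameters by their known symmetry", {
  base <- build_fiber_duplex("GCATTACGGC", "B")
  # jitter the coordinates so every step is distinct and the symmetry is
  # exercised on heterogeneous values
  set.seed(32)
  jitter_nt <- function(nt) {
    nt$atoms <- nt$atoms + matrix(rnorm(length(nt$atoms), sd = 0.05),
                                  nrow(nt$atoms), 3)
    nt
  }
  d0 <- duplex_from_strands(lapply(base, function(bp) jitter_nt(bp$nt1)),
                            lapply(base, function(bp) jitter_nt(bp$nt2)))
  fwd <- step_parameters(d0, warn_missing_p = FALSE)
  rev <- step_parameters(reverse_duplex(d0), warn_missing_p = FALSE)
  n <- nrow(fwd)
  flip <- function(v) rev(v)
  expect_equal(rev$shift, -flip(fwd$shift), tolerance = 1e-6)
  expect_equal(rev$tilt, -flip(fwd$tilt), tolerance = 1e-6)
  expect_equal(rev$slide, flip(fwd$slide), tolerance = 1e-6)
  expect_equal(rev$rise, flip(fwd$rise), tolerance = 1e-6)
  expect_equal(rev$roll, flip(fwd$roll), tolerance = 1e-6)
  expect_equal(rev$twist, flip(fwd$twist), tolerance = 1e-6)
  expect_equal(rev$zp, flip(fwd$zp), tolerance = 1e-6)
})

test_that("form calls follow the Zp / chi gating rule", {
  expect_identical(classify_form(2.0, -150, slide = -1.8, twist = 31)$label, "A")
  expect_identical(classify_form(0.0, -100, slide = 0.2, twist = 36)$label, "B")
  expect_identical(classify_form(1.0, -130)$label, "intermediate")
  expect_identical(classify_form(2.0, -100)$label, "intermediate")
  expect_identical(classify_form(0.2, -150)$label, "intermediate")
})

test_that("contact finder equals the brute-force all-pairs oracle", {
  # toy: one base-only nucleotide + hand-placed protein atoms
  nt <- nt_at_frame("G")
  mk_struct <- function(prot) {
    structure(list(nucleotides = list(nt), protein = prot, source = "toy"),
              class = "dna_structure")
  }
  far <- mk_struct(data.frame(chain = "P", resno = 1, resid = "ALA",
                              elety = "CB",
                              x = nt$atoms["N7", 1] + 5, y = nt$atoms["N7", 2],
                              z = nt$atoms["N7", 3]))
  expect_equal(nrow(find_contacts(far, cutoff = 3.9)), 0)

  near <- mk_struct(data.frame(chain = "P", resno = 1, resid = "ALA",
                               elety = "CB",
                               x = nt$atoms["N7", 1] + 3.5,
                               y = nt$atoms["N7", 2], z = nt$atoms["N7", 3]))
  ct <- find_contacts(near, cutoff = 3.9)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.5, tolerance = 1e-9)
  expect_identical(ct$dna_atom, "N7")
  expect_identical(ct$dna_moiety, "base")

  # default cutoff is 3.9 A
  expect_identical(formals(find_contacts)$cutoff, 3.9)

  # random toy system vs brute force
  set.seed(41)
  d <- build_fiber_duplex("GCAT", "B")
  nts <- attr(d, "nucleotides")
  prot <- data.frame(chain = "P", resno = seq_len(60), resid = "GLY",
                     elety = "CA",
                     x = runif(60, -12, 12), y = runif(60, -12, 12),
                     z = runif(60, -4, 16))
  st <- structure(list(nucleotides = nts, protein = prot, source = "toy"),
                  class = "dna_structure")
  got <- find_contacts(st, cutoff = 3.9)
  oracle <- brute_force_contacts(st, cutoff = 3.9)
  expect_equal(nrow(got), length(oracle))
  expect_setequal(sprintf("%.6f", got$distance),
                  vapply(oracle, `[`, character(1), 3))

  # moiety labels partition atom classes
  expect_identical(dnaform:::dna_moiety("P"), "phosphate")
  expect_identical(dnaform:::dna_moiety("O5'"), "phosphate")
  expect_identical(dnaform:::dna_moiety("C1'"), "sugar")
  expect_identical(dnaform:::dna_moiety("N7"), "base")
})

test_that("groove widths match direct distances and respect the length guard", {
  # too short for the fixed offsets: empty profile, no error
  d4 <- build_fiber_duplex("GCAT", "B")
  gw4 <- groove_widths(d4)
  expect_true(all(is.na(gw4$major)) || nrow(gw4) == 0)

  d <- build_fiber_duplex("GCATGCATGCATGCATGCAT", "B")
  gw <- groove_widths(d)
  expect_gt(nrow(gw), 0)
  # oracle: direct pairwise distance on the generated coordinates
  for (r in which(!is.na(gw$major))) {
    i <- gw$position[r]
    p1 <- dnaform:::nt_atom(d[[i]]$nt1, "P")
    p2 <- dnaform:::nt_atom(d[[i + 3]]$nt2, "P")
    expect_equal(gw$major[r], sqrt(sum((p1 - p2)^2)), tolerance = 1e-12)
  }
  expect_true(all(gw$major[!is.na(gw$major)] > 0))
})
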