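# Trinucleotide dG(B->A) table, A-philicity profiling, peak spacing and
# site loading / random controls.

test_that("the embedded trinucleotide table has the required structure", {
  tab <- trinuc_dg_table()
  expect_length(tab, 64)
  expect_true(all(is.finite(tab)))
  expect_equal(length(unique(tab)), 32)
  expect_equal(unname(tab[names(tab)]), unname(tab[revcomp(names(tab))]))
  # G/C-rich trimers A-philic, A/T tracts B-philic
  expect_lt(tab[["GGC"]], tab[["AAA"]])
  expect_lt(max(tab[c("GGC", "GCG", "GGG")]), min(tab[c("AAA", "AAT", "ATA")]))
  # genome-like background sits at the flat RIC level
  expect_gt(dg_background_mean(), 0.68)
  expect_lt(dg_background_mean(), 0.74)
})

test_that("profiles reproduce constant and hand-tallied inputs", {
  tab <- trinuc_dg_table()
  # constant poly-A input: every position is value(AAA)
  sA <- site_set(rep(strrep("A", 9), 4), anchor = 4, tsd = 6)
  pA <- deltaG_profile(sA, tab)
  expect_true(all(abs(pA$mean_dg - tab[["AAA"]]) < 1e-12))
  expect_true(all(pA$n_used == 4))

  # two hand-written 7-mers, center assignment, hand lookup
  s <- site_set(c("ACGTACG", "TTTGGGC"), anchor = 3, tsd = 6)
  p <- deltaG_profile(s, tab)
  hand <- sapply(1:5, function(k) {
    mean(c(tab[[substr("ACGTACG", k, k + 2)]],
           tab[[substr("TTTGGGC", k, k + 2)]]))
  })
  expect_equal(p$mean_dg, hand, tolerance = 1e-12)
  expect_equal(p$position, (1:5) - 3)

  # N windows are dropped per trinucleotide, not per site
  sN <- site_set(c("ACGTACG", "ACNTACG"), anchor = 3, tsd = 6)
  pN <- deltaG_profile(sN, tab)
  expect_equal(pN$n_used, c(1, 1, 1, 2, 2))
  expect_equal(pN$mean_dg[4],
               mean(c(tab[["TAC"]], tab[["TAC"]])), tolerance = 1e-12)
  expect_true(all(pN$mean_dg >= min(tab) & pN$mean_dg <= max(tab)))

  expect_error(deltaG_profile(site_set(c("AC"), 0, 6)), ">= 3")
})

test_that("profile obeys associativity and reverse-complement symmetry", {
  set.seed(61)
  mk <- function(n, seed) {
    simulate_site_set(sim_spec(n = n, window = 21, tsd = 6,
                               aphilic_strength = 0.4, seed = seed))
  }
  a <- mk(40, 1); b <- mk(25, 2)
  pa <- deltaG_profile(a); pb <- deltaG_profile(b)
  pc <- deltaG_profile(concat_sites(a, b))
  expect_equal(pc$mean_dg,
               (pa$mean_dg * pa$n_used + pb$mean_dg * pb$n_used) /
                 (pa$n_used + pb$n_used), tolerance = 1e-12)

  # reverse complementing (anchor remapped to the partner junction)
  # mirrors the profile about the midpoint between the joining positions
  p <- deltaG_profile(a)
  pr <- deltaG_profile(revcomp_sites(a))
  m <- merge(p, transform(pr, position = a$tsd - pr$position),
             by = "position")
  expect_equal(m$mean_dg.x, m$mean_dg.y, tolerance = 1e-12)
})

test_that("uniform-random sites give a flat profile at the composition mean", {
  comp <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  ss <- simulate_site_set(sim_spec(n = 6000, window = 31, tsd = 6,
                                   background = comp, seed = 7))
  p <- deltaG_profile(ss)
  mu <- dg_background_mean(comp)
  se <- profile_mc_se(trinuc_dg_table(), comp, 6000)
  expect_true(all(abs(p$mean_dg - mu) < 4 * se))
})

test_that("peak spacing finds constructed minima and rejects degenerate profiles", {
  mkprof <- function(vals, positions = seq_along(vals) - 11) {
    out <- data.frame(position = positions, mean_dg = vals,
                      n_used = 100)
    attr(out, "tsd") <- 6
    class(out) <- c("aphilicity_profile", "data.frame")
    out
  }
  # V-shaped pair of minima at 0 and 6
  pos <- -10:15
  vals <- 0.7 - 0.3 * (abs(pos) == 0) - 0.25 * (abs(pos - 6) == 0)
  ps <- peak_spacing(mkprof(vals, pos))
  expect_equal(ps$spacing, 6)
  expect_equal(ps$minima$position, c(0, 6))

  # monotone profile: no local minima
  expect_error(peak_spacing(mkprof(seq(0.5, 0.9, length.out = 26), pos)),
               "fewer than two local minima")
})

test_that("load_sites extracts strand-aware windows and deduplicates", {
  sim <- simulate_genome(1000, seed = 13)
  g <- sim$genome
  gs <- as.character(g[[1]])
  # + strand: window 51 centered on the junction base at 0-based p
  p <- 300
  bed <- data.frame(chrom = "chr1", start = p, strand = "+")
  ss <- load_sites(bed, g, window = 51, tsd = 6)
  expect_identical(ss$sequences, substr(gs, p - 25 + 1, p + 25 + 1 - 1 + 1))
  expect_equal(ss$anchor, 25)
  expect_identical(substr(ss$sequences, 26, 26), substr(gs, p + 1, p + 1))

  # - strand: reverse complement of the mirrored window
  bedm <- data.frame(chrom = "chr1", start = p, strand = "-")
  sm <- load_sites(bedm, g, window = 51, tsd = 6)
  expect_identical(sm$sequences,
                   revcomp(substr(gs, p - 25 + 1, p + 25 + 1)))

  # planted window is recovered exactly
  planted <- strrep("GCGCA", 5)            # 25 bp, anchor 12
  sim2 <- simulate_genome(1000, planted_sites = data.frame(
    pos = 500, strand = "+", seq = planted, anchor = 12,
    stringsAsFactors = FALSE), seed = 14)
  got <- load_sites(sim2$bed, sim2$genome, window = 25, tsd = 6)
  expect_identical(got$sequences, planted)

  # duplicates removed; out-of-contig errors
  bed2 <- rbind(bed, bed)
  expect_equal(n_sites(load_sites(bed2, g, 51, 6)), 1)
  expect_error(load_sites(data.frame(chrom = "chr1", start = 5,
                                     strand = "+"), g, 51, 6),
               "outside the contig")
  expect_error(load_sites(data.frame(chrom = "chrX", start = 100,
                                     strand = "+"), g, 51, 6),
               "contig not in genome")
})

test_that("random controls are seeded, uniform and motif-restrictable", {
  g <- simulate_genome(4000, seed = 17)$genome
  r1 <- random_control(g, 200, window = 21, seed = 5)
  r2 <- random_control(g, 200, window = 21, seed = 5)
  expect_identical(r1$sequences, r2$sequences)
  r3 <- random_control(g, 200, window = 21, seed = 6)
  expect_false(identical(r1$sequences, r3$sequences))

  # uniformity sanity check on positions (chi-squared over 8 bins)
  pos <- attr(random_control(g, 2000, window = 21, seed = 8),
              "positions")$start
  bins <- table(cut(pos, breaks = 8))
  expect_gt(stats::chisq.test(bins)$p.value, 1e-3)

  # degenerate motif case: every window near the single motif occurrence
  gm <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("C", 500), "TTAA",
                                                 strrep("G", 500))))
  rm <- random_control(gm, 8, window = 11, seed = 9, motif = "TTAA",
                       motif_dist = 3)
  expect_true(all(abs(attr(rm, "positions")$start - 501.5) < 10))
  expect_error(random_control(gm, 1e6, window = 11, seed = 9,
                              motif = "TTAA", motif_dist = 0),
               "eligible positions")
})
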