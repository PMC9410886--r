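# Synthetic integration-site windows and genomes with planted signals.
# The generator emulates the statistical structure of retroviral
# integration-site alignments: A-philic (low-dG) trinucleotides at both
# joining positions (relative positions 0 and tsd, the scissile-phosphate
# spacing), flexible YR dinucleotides at the central step of the TSD, and a
# ~10-bp periodic A/T preference outside the TSD that mimics nucleosomal
# integration. A single integer seed makes every output reproducible.

#' Simulation specification for integration-site windows
#'
#' @param n Number of sites (>= 1).
#' @param window Window width in bp.
#' @param tsd TSD length (4-6).
#' @param background Base composition (A, C, G, T probabilities summing
#'   to 1). Default approximates mammalian genomic DNA (41% G+C).
#' @param aphilic_strength Probability in `[0, 1]` that a site carries a
#'   planted low-dG trinucleotide at each joining position.
#' @param central_yr_boost Probability that the central TSD step is
#'   replaced by a random YR dinucleotide.
#' @param periodic_at Amplitude in `[0, 1]` of the 10-bp periodic A/T bias
#'   outside the TSD.
#' @param seed Integer seed.
#' @return List of class `"sim_spec"`.
#' @export
sim_spec <- function(n, window = 41, tsd = 6,
                     background = c(A = 0.295, C = 0.205,
                                    G = 0.205, T = 0.295),
                     aphilic_strength = 0, central_yr_boost = 0,
                     periodic_at = 0, seed = 1) {
  stopifnot(n >= 1, window >= tsd + 3, tsd %in% 4:6)
  if (abs(sum(background) - 1) > 1e-6 || any(background < 0)) {
    stop("background must be a probability vector over A, C, G, T")
  }
  for (p in c(aphilic_strength, central_yr_boost, periodic_at)) {
    if (p < 0 || p > 1) stop("signal strengths must lie in [0, 1]")
  }
  structure(list(n = as.integer(n), window = as.integer(window),
                 tsd = as.integer(tsd), background = background,
                 aphilic_strength = aphilic_strength,
                 central_yr_boost = central_yr_boost,
                 periodic_at = periodic_at, seed = as.integer(seed)),
            class = "sim_spec")
}

# Low-dG trinucleotide pool: bottom quartile of the table, sampled with
# softmax(-dG / tau) weights, tau = 0.2 kcal/mol.
#' @noRd
aphilic_pool <- function(table = trinuc_dg_table(), tau = 0.2) {
  cut <- stats::quantile(unique(table), 0.25)
  pool <- table[table <= cut]
  w <- exp(-pool / tau)
  list(trinucs = names(pool), prob = w / sum(w))
}

#' Simulate an aligned integration-site set
#'
#' Draws `n` windows of i.i.d. background bases, applies the periodic A/T
#' bias outside the TSD, boosts the central TSD step to YR, and plants
#' low-dG trinucleotides centered at the two joining positions (relative
#' positions 0 and `tsd`), each with probability `aphilic_strength`.
#' The anchor is placed so the TSD region is centered in the window.
#'
#' @param spec A `"sim_spec"` (or arguments forwarded to [sim_spec()]).
#' @param table Trinucleotide table used for the A-philic pool.
#' @return A `"site_set"` with attribute `"truth"`: data.frame with one
#'   row per site recording which signals were planted.
#' @export
simulate_site_set <- function(spec, table = trinuc_dg_table()) {
  if (!inherits(spec, "sim_spec")) stop("spec must be a sim_spec")
  W <- spec$window; tsd <- spec$tsd; n <- spec$n
  anchor <- (W - 1L) %/% 2L - tsd %/% 2L     # TSD (0..tsd) centered
  pool <- aphilic_pool(table)
  with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    m <- matrix(sample(bases, n * W, replace = TRUE, prob = spec$background),
                nrow = n, ncol = W)
    rel <- (seq_len(W) - 1L) - anchor
    # periodic A/T bias outside [0, tsd]
    if (spec$periodic_at > 0) {
      outside <- which(rel < 0 | rel > tsd)
      for (j in outside) {
        d <- if (rel[j] < 0) -rel[j] else rel[j] - tsd
        pr <- spec$periodic_at * (0.5 + 0.5 * cos(2 * pi * d / 10))
        hit <- stats::runif(n) < pr
        if (any(hit)) {
          m[hit, j] <- sample(c("A", "T"), sum(hit), replace = TRUE)
        }
      }
    }
    # central YR step of the TSD
    yr_hit <- stats::runif(n) < spec$central_yr_boost
    c1 <- anchor + (tsd - 1L) %/% 2L + 1L    # 1-based column of step 5' base
    if (any(yr_hit)) {
      k <- sum(yr_hit)
      m[yr_hit, c1] <- sample(c("C", "T"), k, replace = TRUE)
      m[yr_hit, c1 + 1L] <- sample(c("A", "G"), k, replace = TRUE)
    }
    plant <- function(m, center_rel, hit) {
      if (!any(hit)) return(m)
      tri <- sample(pool$trinucs, sum(hit), replace = TRUE, prob = pool$prob)
      cols <- anchor + center_rel + c(0L, 1L, 2L)  # 1-based: center-1..center+1
      for (o in 0:2) {
        m[hit, cols[o + 1L]] <- substr(tri, o + 1L, o + 1L)
      }
      m
    }
    hit0 <- stats::runif(n) < spec$aphilic_strength
    hitT <- stats::runif(n) < spec$aphilic_strength
    m <- plant(m, 0L, hit0)                  # centered at position 0
    m <- plant(m, tsd, hitT)                 # centered at position tsd
    seqs <- apply(m, 1, paste, collapse = "")
    out <- site_set(seqs, anchor, tsd,
                    label = sprintf("simulated (seed %d)", spec$seed))
    attr(out, "truth") <- data.frame(aphilic_0 = hit0, aphilic_tsd = hitT,
                                     yr_boost = yr_hit)
    attr(out, "spec") <- spec
    out
  })
}

#' Simulate a genome with planted integration-site windows
#'
#' Generates a single random contig at the requested composition and
#' overwrites it with the given windows at planted junction coordinates,
#' returning the genome together with the matching BED-style junction
#' table (0-based, strand-aware), ready for [load_sites()].
#'
#' @param length Contig length in bp.
#' @param composition Base composition (A, C, G, T).
#' @param planted_sites Optional data.frame with columns `pos` (0-based
#'   junction base), `strand` (+/-), `seq` (window sequence as seen on the
#'   site's strand) and `anchor` (0-based junction column within `seq`).
#' @param seed Integer seed.
#' @param contig Contig name (default "chr1").
#' @return List with `genome` (`DNAStringSet`) and `bed` (data.frame:
#'   chrom, start, end, name, score, strand; zero rows when nothing is
#'   planted).
#' @export
simulate_genome <- function(length, composition = c(A = 0.295, C = 0.205,
                                                    G = 0.205, T = 0.295),
                            planted_sites = NULL, seed = 1,
                            contig = "chr1") {
  stopifnot(length >= 1)
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition must sum to 1")
  }
  g <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                    replace = TRUE, prob = composition),
                             collapse = ""))
  bed <- data.frame(chrom = character(), start = integer(), end = integer(),
                    name = character(), score = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  if (!is.null(planted_sites) && nrow(planted_sites)) {
    need <- c("pos", "strand", "seq", "anchor")
    stopifnot(all(need %in% names(planted_sites)))
    occupied <- integer()
    for (i in seq_len(nrow(planted_sites))) {
      p <- planted_sites$pos[i]
      s <- toupper(planted_sites$seq[i])
      a <- planted_sites$anchor[i]
      W <- nchar(s)
      if (planted_sites$strand[i] == "+") {
        from0 <- p - a
        top <- s
      } else {
        from0 <- p - (W - 1L - a)
        top <- revcomp(s)
      }
      to0 <- from0 + W - 1L
      if (from0 < 0 || to0 > length - 1L) {
        stop("planted site does not fit inside the genome")
      }
      span <- from0:to0
      if (any(span %in% occupied)) {
        stop("planted sites overlap")
      }
      occupied <- c(occupied, span)
      substr(g, from0 + 1L, to0 + 1L) <- top
      bed <- rbind(bed, data.frame(
        chrom = contig, start = p, end = p + 1L,
        name = sprintf("site%d", i), score = 0L,
        strand = planted_sites$strand[i], stringsAsFactors = FALSE))
    }
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(g, contig))
  list(genome = genome, bed = bed)
}

#' Write a BED table of junction positions
#'
#' @param bed data.frame as returned by [simulate_genome()].
#' @param file Output path.
#' @export
write_bed <- function(bed, file) {
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a site set as FASTA
#'
#' Records the anchor, TSD and label in the headers so the file round-trips.
#'
#' @param sites A `"site_set"`.
#' @param file Output path.
#' @export
write_sites_fasta <- function(sites, file) {
  s <- Biostrings::DNAStringSet(sites$sequences)
  names(s) <- sprintf("site%06d anchor=%d tsd=%d %s",
                      seq_along(sites$sequences), sites$anchor, sites$tsd,
                      sites$label)
  Biostrings::writeXStringSet(s, file)
  invisible(file)
}

#' Read a site set from FASTA
#'
#' @param file FASTA of equal-width windows.
#' @param anchor,tsd Anchor column and TSD; defaults recover the values
#'   written by [write_sites_fasta()] from the first header.
#' @return A `"site_set"`.
#' @export
read_sites_fasta <- function(file, anchor = NULL, tsd = NULL) {
  s <- Biostrings::readDNAStringSet(file)
  hdr <- names(s)[1]
  if (is.null(anchor)) {
    m <- regmatches(hdr, regexpr("anchor=\\d+", hdr))
    if (!length(m)) stop("anchor not given and not recorded in the FASTA header")
    anchor <- as.integer(sub("anchor=", "", m))
  }
  if (is.null(tsd)) {
    m <- regmatches(hdr, regexpr("tsd=\\d+", hdr))
    if (!length(m)) stop("tsd not given and not recorded in the FASTA header")
    tsd <- as.integer(sub("tsd=", "", m))
  }
  site_set(as.character(s), anchor, tsd, label = basename(file))
}
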