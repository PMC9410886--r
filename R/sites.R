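# Aligned integration-site windows. A site set holds n equal-width
# sequences anchored so that relative position 0 is the first joined tDNA
# base (the base whose 5'-phosphate receives the viral 3'-OH) on the
# sequenced strand. The partner joining event on the opposite strand is
# modeled `tsd` bp downstream of position 0: the two scissile
# phosphodiesters of a strand-transfer event are separated by `tsd` bp,
# the spacing that also sets the target-site duplication length.

#' Construct a set of aligned integration-site windows
#'
#' @param sequences Character vector (or `DNAStringSet`) of equal-width
#'   sequences over ACGTN.
#' @param anchor 0-based column index of relative position 0 (the first
#'   joined base). Must lie inside the window.
#' @param tsd Target-site duplication length in bp (4, 5 or 6).
#' @param label Free-text description.
#' @return Object of class `"site_set"`.
#' @export
site_set <- function(sequences, anchor, tsd, label = "") {
  sequences <- toupper(as.character(sequences))
  if (!length(sequences)) stop("a site set requires at least one sequence")
  W <- unique(nchar(sequences))
  if (length(W) != 1) stop("all sequences must have equal width")
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("sequences must be over the ACGTN alphabet")
  }
  anchor <- as.integer(anchor)
  if (anchor < 0 || anchor >= W) stop("anchor must lie in [0, width)")
  if (!tsd %in% 4:6) stop("tsd must be 4, 5 or 6")
  structure(list(sequences = sequences, anchor = anchor,
                 tsd = as.integer(tsd), width = W, label = label),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("<site_set '%s': %d sites x %d bp, anchor %d, tsd %d>\n",
              x$label, length(x$sequences), x$width, x$anchor, x$tsd))
  invisible(x)
}

#' Number of sites in a site set
#' @param x A `"site_set"`.
#' @export
n_sites <- function(x) length(x$sequences)

#' Reverse complement a site set
#'
#' Remaps the anchor to the partner junction. With
#' `partner = "phosphate"` (the profiling convention) relative position p
#' becomes `tsd - p`, so the two joining signals at 0 and `tsd` swap;
#' with `partner = "base"` position p becomes `tsd - 1 - p`, so the
#' duplicated bases 0 .. tsd-1 map onto themselves (the convention under
#' which base-level matrices mirror exactly).
#'
#' @param x A `"site_set"`.
#' @param partner `"phosphate"` or `"base"` anchor remapping.
#' @return A `"site_set"` of the reverse-complemented sequences.
#' @export
revcomp_sites <- function(x, partner = c("phosphate", "base")) {
  partner <- match.arg(partner)
  shift <- if (partner == "phosphate") x$tsd else x$tsd - 1L
  new_anchor <- x$width - 1L - (x$anchor + shift)
  if (new_anchor < 0 || new_anchor >= x$width) {
    stop("window too narrow to remap the anchor to the partner junction")
  }
  site_set(revcomp(x$sequences), new_anchor, x$tsd,
           label = paste0(x$label, " (revcomp)"))
}

#' Concatenate site sets
#'
#' @param ... `"site_set"` objects with identical width, anchor and tsd.
#' @return A combined `"site_set"`.
#' @export
concat_sites <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  W <- unique(vapply(parts, `[[`, integer(1), "width"))
  a <- unique(vapply(parts, `[[`, integer(1), "anchor"))
  t <- unique(vapply(parts, `[[`, integer(1), "tsd"))
  if (length(W) != 1 || length(a) != 1 || length(t) != 1) {
    stop("site sets must share width, anchor and tsd")
  }
  site_set(unlist(lapply(parts, `[[`, "sequences")), a, t,
           label = paste(vapply(parts, `[[`, character(1), "label"),
                         collapse = "+"))
}

#' @noRd
load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*", "", names(g))
    return(g)
  }
  stop("genome must be a FASTA path or a DNAStringSet")
}

#' Load integration sites from BED + genome FASTA
#'
#' BED intervals (0-based half-open, strand required) mark the single
#' sequenced junction base. For each unique site a window of `window` bp is
#' extracted such that the junction base sits at the anchor position on the
#' reported strand; minus-strand sites are reverse complemented. Duplicate
#' (contig, position, strand) entries are removed.
#'
#' @param bed Path to a BED file, or a data.frame with columns `chrom`,
#'   `start` (0-based), `strand`.
#' @param genome FASTA path or `DNAStringSet`.
#' @param window Window width in bp.
#' @param tsd Target-site duplication length (4-6).
#' @param anchor 0-based anchor column; default centers the junction base
#'   (`(window - 1) %/% 2`).
#' @return A `"site_set"`.
#' @export
load_sites <- function(bed, genome, window, tsd,
                       anchor = (window - 1) %/% 2) {
  g <- load_genome(genome)
  if (is.character(bed)) {
    gr <- rtracklayer::import(bed, format = "BED")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    df <- bed[, c("chrom", "start", "strand")]
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("every interval must carry a +/- strand")
  }
  df <- df[!duplicated(df[, c("chrom", "start", "strand")]), , drop = FALSE]
  W <- as.integer(window)
  seqs <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    contig <- df$chrom[i]
    if (!contig %in% names(g)) stop("contig not in genome: ", contig)
    p <- df$start[i]                   # 0-based junction base
    len <- Biostrings::nchar(g[[contig]])
    if (df$strand[i] == "+") {
      from <- p - anchor + 1L          # 1-based
    } else {
      from <- p - (W - 1L - anchor) + 1L
    }
    to <- from + W - 1L
    if (from < 1 || to > len) {
      stop(sprintf("window for %s:%d(%s) falls outside the contig",
                   contig, p, df$strand[i]))
    }
    s <- as.character(Biostrings::subseq(g[[contig]], from, to))
    if (df$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s
  }
  site_set(seqs, anchor, tsd, label = "loaded sites")
}

# Seeded evaluation that restores the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random integration control (RIC) windows
#'
#' Samples n positions uniformly from the genome (optionally restricted to
#' lie within `motif_dist` bp of a restriction-site motif occurrence, as a
#' proxy for restriction-fragment-based random controls), draws a random
#' strand for each, and extracts windows exactly as [load_sites()] does.
#' Fixed seeds give identical output.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param n Number of control sites.
#' @param window Window width in bp.
#' @param seed Integer seed.
#' @param tsd TSD length carried into the result (default 6).
#' @param anchor 0-based anchor column, default centered.
#' @param motif Optional DNA motif (e.g. "TTAA"); when given, candidate
#'   positions are restricted to within `motif_dist` of a motif match.
#' @param motif_dist Maximum distance to a motif occurrence.
#' @return A `"site_set"` with attribute `"positions"` (data.frame of
#'   chrom, start, strand).
#' @export
random_control <- function(genome, n, window, seed, tsd = 6,
                           anchor = (window - 1) %/% 2,
                           motif = NULL, motif_dist = 0) {
  g <- load_genome(genome)
  W <- as.integer(window)
  margin_l <- anchor
  margin_r <- W - 1L - anchor
  cand <- list()
  for (contig in names(g)) {
    len <- Biostrings::nchar(g[[contig]])
    lo <- max(margin_l, margin_r)     # safe on both strands
    hi <- len - 1L - max(margin_l, margin_r)
    if (hi < lo) next
    pos <- lo:hi
    if (!is.null(motif)) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                    g[[contig]])
      if (!length(m)) { pos <- integer(); }
      else {
        starts0 <- Biostrings::start(m) - 1L
        ends0 <- Biostrings::end(m) - 1L
        keep <- vapply(pos, function(p) {
          any(p >= starts0 - motif_dist & p <= ends0 + motif_dist)
        }, logical(1))
        pos <- pos[keep]
      }
    }
    if (length(pos)) cand[[contig]] <- pos
  }
  total <- sum(lengths(cand))
  if (n > total) {
    stop(sprintf("requested %d controls but only %d eligible positions", n,
                 total))
  }
  df <- with_seed(seed, {
    contigs <- rep(names(cand), lengths(cand))
    allpos <- unlist(cand, use.names = FALSE)
    idx <- sample.int(length(allpos), n)
    data.frame(chrom = contigs[idx], start = allpos[idx],
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- load_sites(df, g, W, tsd, anchor)
  out$label <- "random control"
  attr(out, "positions") <- df
  out
}
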