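# Sequence-preference statistics at integration sites: per-position base
# frequency matrices (logo data), YR/RY dinucleotide usage, degenerate
# consensus strings, and viral-end utilities (3'-processing arithmetic,
# branched strand-transfer substrate model).

#' Per-position base frequency matrix centered on the TSD
#'
#' Computes the probability of base usage for a stretch of `window` bp
#' centered on the midpoint of the target-site duplication (relative
#' positions 0 .. tsd-1, midpoint (tsd-1)/2). N bases are excluded per
#' column.
#'
#' @param sites A `"site_set"`.
#' @param window Number of columns (default 50, the conventional logo
#'   stretch). Must not exceed the available width.
#' @return List of class `"freq_matrix"`: `probs` (4 x window matrix, rows
#'   A,C,G,T; columns sum to 1 over non-N observations), `counts` (non-N
#'   observations per column), `positions` (relative positions), `anchor_col`
#'   (column index of relative position 0, NA if outside).
#' @export
frequency_matrix <- function(sites, window = 50) {
  W <- sites$width
  a <- sites$anchor
  if (window > W) stop("window exceeds the site width")
  mid <- (sites$tsd - 1) / 2
  first <- floor(mid) - window %/% 2 + 1     # relative position of column 1
  positions <- seq(first, length.out = window)
  cols <- positions + a                       # 0-based columns
  if (cols[1] < 0 || cols[window] > W - 1) {
    stop("window exceeds the site width around the TSD midpoint")
  }
  probs <- matrix(0, 4, window, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts <- integer(window)
  for (j in seq_len(window)) {
    b <- substr(sites$sequences, cols[j] + 1L, cols[j] + 1L)
    b <- b[b != "N"]
    counts[j] <- length(b)
    if (length(b)) probs[, j] <- tabulate(factor(b, levels = rownames(probs)),
                                          4) / length(b)
  }
  structure(list(probs = probs, counts = counts, positions = positions,
                 anchor_col = if (0 %in% positions)
                   which(positions == 0) else NA_integer_,
                 tsd = sites$tsd),
            class = "freq_matrix")
}

#' Per-column information content of a frequency matrix
#'
#' Shannon information in bits (log2, 2 - H, no small-sample correction),
#' the per-column letter heights of a sequence logo.
#'
#' @param fm A `"freq_matrix"`.
#' @return Numeric vector, bits per column.
#' @export
info_content <- function(fm) {
  apply(fm$probs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Degenerate consensus from a frequency matrix
#'
#' Per column, the base whose probability reaches the plurality threshold,
#' otherwise N; a `/` marks the junction (immediately before relative
#' position 0). A low default threshold (0.30) reflects the marginal
#' sequence preferences typical of retroviral integration sites.
#'
#' @param fm A `"freq_matrix"`.
#' @param plurality_threshold Fraction in (0.25, 1].
#' @return Single consensus string.
#' @export
consensus <- function(fm, plurality_threshold = 0.30) {
  if (plurality_threshold <= 0.25 || plurality_threshold > 1) {
    stop("plurality threshold must be in (0.25, 1]")
  }
  letters <- apply(fm$probs, 2, function(p) {
    i <- which.max(p)
    if (p[i] >= plurality_threshold) rownames(fm$probs)[i] else "N"
  })
  if (!is.na(fm$anchor_col)) {
    letters <- append(letters, "/", after = fm$anchor_col - 1L)
  }
  paste(letters, collapse = "")
}

#' YR / RY dinucleotide usage per step
#'
#' For every dinucleotide step the percentage of sites whose step is
#' pyrimidine-purine (YR), purine-pyrimidine (RY) or neither (YY/RR).
#' Flexible YR steps are enriched at the center of retroviral target
#' sites. Steps containing N are excluded from the denominator.
#'
#' @param sites A `"site_set"` of width >= 2.
#' @return data.frame with `step` (relative position of the step's 5'
#'   base), `pct_yr`, `pct_ry`, `pct_other` (summing to 100 per step) and
#'   `n_used`.
#' @export
yr_ry_profile <- function(sites) {
  W <- sites$width
  if (W < 2) stop("site width must be >= 2")
  is_y <- function(b) b %in% c("C", "T")
  is_r <- function(b) b %in% c("A", "G")
  rows <- lapply(seq_len(W - 1), function(k) {
    b1 <- substr(sites$sequences, k, k)
    b2 <- substr(sites$sequences, k + 1L, k + 1L)
    ok <- b1 != "N" & b2 != "N"
    n <- sum(ok)
    yr <- sum(is_y(b1[ok]) & is_r(b2[ok]))
    ry <- sum(is_r(b1[ok]) & is_y(b2[ok]))
    data.frame(step = (k - 1L) - sites$anchor,
               pct_yr = if (n) 100 * yr / n else NA_real_,
               pct_ry = if (n) 100 * ry / n else NA_real_,
               pct_other = if (n) 100 * (n - yr - ry) / n else NA_real_,
               n_used = n)
  })
  do.call(rbind, rows)
}

#' 3'-processing of a viral DNA end
#'
#' Integrase cleaves the transferred strand immediately 3' of the invariant
#' CpA dinucleotide, releasing the terminal dinucleotide and leaving a
#' recessed CA-3'-OH end. The substrate must therefore carry CA directly
#' before its last two bases.
#'
#' @param seq Transferred-strand sequence, 5'->3'.
#' @return List of class `"viral_end"`: `sequence` (the processed strand,
#'   ending in CA), `released` (the terminal dinucleotide) and
#'   `processed = TRUE`.
#' @export
process_vdna_end <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 4) stop("not a processable viral end: sequence too short")
  if (substr(seq, n - 3L, n - 2L) != "CA") {
    stop("not a processable viral end: no CA at the cleavage register")
  }
  structure(list(sequence = substr(seq, 1L, n - 2L),
                 released = substr(seq, n - 1L, n),
                 processed = TRUE),
            class = "viral_end")
}

#' @export
print.viral_end <- function(x, ...) {
  cat(sprintf("<viral_end %d nt, ...%s | %s released>\n",
              nchar(x$sequence),
              substr(x$sequence, nchar(x$sequence) - 2, nchar(x$sequence)),
              x$released))
  invisible(x)
}

#' Branched strand-transfer (bDNA) substrate model
#'
#' Validates and describes the three-strand branched DNA that mimics the
#' concerted integration product: a transferred strand running 5'->3' from
#' the viral end into target DNA, the non-transferred viral strand (with
#' its 5' overhang), and the distal target-DNA bottom strand. The target
#' segment between the two joining points must be self-complementary
#' (palindromic) so that two copies of the three strands anneal into the
#' two-fold symmetric substrate whose joined 5'-phosphates are `tsd` bp
#' apart.
#'
#' @param vdna_transferred Transferred strand: processed viral end (ending
#'   CA) followed contiguously by the target segment, 5'->3'.
#' @param vdna_nontransferred Non-transferred viral strand (may carry a 5'
#'   overhang beyond the region complementary to the viral end).
#' @param tdna Distal target bottom strand, complementary to the 3' part of
#'   `vdna_transferred`.
#' @param tsd Expected joining spacing / TSD length.
#' @return List of class `"bdna_substrate"`: `vdna` (viral portion of the
#'   transferred strand), `overhang` (non-transferred 5' overhang),
#'   `joint` (the palindromic segment between the joining points),
#'   `joining_spacing` (= `tsd`), and the input strands.
#' @export
build_bdna <- function(vdna_transferred, vdna_nontransferred, tdna, tsd) {
  tr <- toupper(vdna_transferred)
  ntr <- toupper(vdna_nontransferred)
  td <- toupper(tdna)
  nt <- nchar(tr)
  # distal target arm: tdna pairs with the 3' end of the transferred strand
  arm <- revcomp(td)
  if (nchar(arm) >= nt ||
      substr(tr, nt - nchar(arm) + 1L, nt) != arm) {
    stop("complementarity violation: tdna does not pair with the 3' end of the transferred strand")
  }
  rest <- substr(tr, 1L, nt - nchar(arm))
  # viral portion: longest prefix whose reverse complement ends the
  # non-transferred strand
  vlen <- 0L
  for (L in seq(min(nchar(rest), nchar(ntr)), 1L)) {
    cand <- substr(rest, 1L, L)
    if (substr(ntr, nchar(ntr) - L + 1L, nchar(ntr)) == revcomp(cand)) {
      vlen <- L
      break
    }
  }
  if (vlen == 0L) {
    stop("complementarity violation: non-transferred strand does not pair with the viral end")
  }
  vdna <- substr(rest, 1L, vlen)
  if (substr(vdna, vlen - 1L, vlen) != "CA") {
    stop("transferred viral strand must end in the invariant CA")
  }
  joint <- substr(rest, vlen + 1L, nchar(rest))
  if (nchar(joint) != tsd) {
    stop(sprintf("joining spacing is %d bp, expected tsd = %d",
                 nchar(joint), tsd))
  }
  if (revcomp(joint) != joint) {
    stop("target segment between the joining points is not palindromic")
  }
  structure(list(vdna = vdna,
                 overhang = substr(ntr, 1L, nchar(ntr) - vlen),
                 joint = joint,
                 joining_spacing = as.integer(tsd),
                 strands = list(transferred = tr, nontransferred = ntr,
                                tdna = td)),
            class = "bdna_substrate")
}

#' @export
print.bdna_substrate <- function(x, ...) {
  cat(sprintf("<bdna_substrate: vDNA %d nt ...%s, joint %s, spacing %d bp>\n",
              nchar(x$vdna), substr(x$vdna, nchar(x$vdna) - 1, nchar(x$vdna)),
              x$joint, x$joining_spacing))
  invisible(x)
}
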