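# Base-pair identification and pair (mid) frames. A duplex is an ordered
# list of base pairs, 5'->3' along strand I; the complementary base's frame
# is z-flipped so both frames share the strand-I sense before averaging.

#' Construct a base pair with its mid-frame
#'
#' @param nt1,nt2 [nucleotide] records on opposite strands. `nt1` is the
#'   strand-I base that sets the pair orientation.
#' @param is_wc Flag recording whether the pair was accepted as
#'   Watson-Crick (complementary bases with paired ring geometry).
#' @return Object of class `"base_pair"` with `nt1`, `nt2`, `frame`
#'   (pair mid-frame, a `"ref_frame"`), and `is_wc`.
#' @export
base_pair <- function(nt1, nt2, is_wc = TRUE) {
  if (identical(nt1$chain, nt2$chain) && nt1$resno == nt2$resno)
    stop("a base pair requires two distinct residues")
  f1 <- fit_base_frame(nt1)
  f2 <- fit_base_frame(nt2)
  flip <- diag(c(1, -1, -1))
  R2f <- f2$rotation %*% flip        # complementary base seen from strand I
  R <- rot_mid(f1$rotation, R2f)
  frame <- structure(list(origin = (f1$origin + f2$origin) / 2,
                          rotation = R, rmsd = NA_real_),
                     class = "ref_frame")
  structure(list(nt1 = nt1, nt2 = nt2, frame = frame, is_wc = is_wc,
                 frame1 = f1, frame2 = f2),
            class = "base_pair")
}

# Watson-Crick acceptance test: complementary bases, N1...N3 hydrogen-bond
# geometry within 3.5 A, base planes within 65 degrees of (anti)parallel.
#' @noRd
is_wc_geometry <- function(nt1, nt2, dist_cut = 3.5, angle_cut = 65) {
  comp <- complement_base(nt1$base)
  ok <- nt2$base == comp || (comp == "T" && nt2$base == "U")
  if (!ok) return(FALSE)
  # the purine N1 pairs with the pyrimidine N3
  a1 <- if (nt1$base %in% c("A", "G")) nt_atom(nt1, "N1") else nt_atom(nt1, "N3")
  a2 <- if (nt2$base %in% c("A", "G")) nt_atom(nt2, "N1") else nt_atom(nt2, "N3")
  if (is.null(a1) || is.null(a2)) return(FALSE)
  if (vnorm(a1 - a2) > dist_cut) return(FALSE)
  z1 <- fit_base_frame(nt1)$rotation[, 3]
  z2 <- fit_base_frame(nt2)$rotation[, 3]
  ang <- rad2deg(acos(min(1, max(-1, abs(sum(z1 * z2))))))
  ang <= angle_cut
}

#' Assemble a duplex from two aligned strands
#'
#' @param strand1 List of [nucleotide] records, 5'->3'.
#' @param strand2 List of [nucleotide] records pairing positionally with
#'   `strand1` (i.e. `strand2[[i]]` pairs `strand1[[i]]`; for a strand given
#'   5'->3' reverse it first).
#' @param check_wc Validate Watson-Crick geometry for every pair.
#' @return Object of class `"duplex"`: list of [base_pair]s.
#' @export
duplex_from_strands <- function(strand1, strand2, check_wc = FALSE) {
  stopifnot(length(strand1) == length(strand2))
  if (length(strand1) < 2) stop("a duplex requires at least 2 base pairs")
  pairs <- mapply(function(a, b) {
    wc <- if (check_wc) is_wc_geometry(a, b) else TRUE
    base_pair(a, b, is_wc = wc)
  }, strand1, strand2, SIMPLIFY = FALSE)
  structure(pairs, class = "duplex")
}

#' @export
print.duplex <- function(x, ...) {
  seq1 <- paste(vapply(x, function(p) p$nt1$base, character(1)), collapse = "")
  cat(sprintf("<duplex of %d bp: 5'-%s-3'>\n", length(x), seq1))
  invisible(x)
}

#' Infer a Watson-Crick paired duplex from a parsed structure
#'
#' Either applies an explicit pairing map or infers Watson-Crick pairs by
#' base complementarity plus N1...N3 distance (<= 3.5 A) and base-plane
#' angle (<= 65 degrees). Explicit pairing is the reliable route for
#' branched or unusual substrates where sequential pairing fails.
#'
#' @param structure A `"dna_structure"` from [parse_structure()].
#' @param chains Optional character vector restricting the DNA chains used.
#' @param pairing Optional data.frame with columns `chain1`, `resno1`,
#'   `chain2`, `resno2`, one row per base pair ordered 5'->3' along
#'   strand I.
#' @return A `"duplex"`.
#' @export
infer_duplex <- function(structure, chains = NULL, pairing = NULL) {
  nts <- structure$nucleotides
  if (!is.null(chains)) {
    nts <- Filter(function(nt) nt$chain %in% chains, nts)
  }
  if (!length(nts)) stop("no nucleotides in the selected chains")
  key <- vapply(nts, function(nt) paste0(nt$chain, "\r", nt$resno), character(1))
  lookup <- stats::setNames(seq_along(nts), key)

  if (!is.null(pairing)) {
    need <- c("chain1", "resno1", "chain2", "resno2")
    stopifnot(all(need %in% names(pairing)))
    s1 <- lookup[paste0(pairing$chain1, "\r", pairing$resno1)]
    s2 <- lookup[paste0(pairing$chain2, "\r", pairing$resno2)]
    if (anyNA(s1) || anyNA(s2)) stop("pairing refers to residues not in the structure")
    return(duplex_from_strands(nts[s1], nts[s2], check_wc = FALSE))
  }

  n <- length(nts)
  partner <- rep(NA_integer_, n)
  for (i in seq_len(n - 1)) {
    if (!is.na(partner[i])) next
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(n)) {
      if (j == i || !is.na(partner[j])) next
      if (!is_wc_geometry(nts[[i]], nts[[j]])) next
      a1 <- if (nts[[i]]$base %in% c("A", "G")) nt_atom(nts[[i]], "N1") else nt_atom(nts[[i]], "N3")
      a2 <- if (nts[[j]]$base %in% c("A", "G")) nt_atom(nts[[j]], "N1") else nt_atom(nts[[j]], "N3")
      d <- vnorm(a1 - a2)
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (!is.na(best)) { partner[i] <- best; partner[best] <- i }
  }
  paired <- which(!is.na(partner) & seq_len(n) < partner)
  if (length(paired) < 2) stop("fewer than 2 Watson-Crick pairs inferred")
  # order along strand I (chain of the first paired residue, by resno)
  ch1 <- nts[[paired[1]]]$chain
  onstrand <- paired[vapply(paired, function(i) nts[[i]]$chain == ch1, logical(1))]
  ord <- onstrand[order(vapply(onstrand, function(i) nts[[i]]$resno, numeric(1)))]
  duplex_from_strands(nts[ord], nts[partner[ord]], check_wc = FALSE)
}
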