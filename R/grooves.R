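# Groove widths as direct cross-strand phosphorus-phosphorus distances with
# a fixed index-offset convention. Offsets were chosen as the cross-strand
# separations that realize the canonical groove widths on an ideal B-form
# duplex (direct P-P: minor ~ 11.7 A, major ~ 17.2 A) and are reported raw,
# without any phosphate-radius subtraction, matching the convention of raw
# phosphate-phosphate distances (~16-17 A across the B-form major groove).

.groove_offsets <- c(minor = -4L, major = 3L)

#' Major and minor groove widths of a duplex
#'
#' For base-pair position i the major groove width is the distance between
#' the phosphorus of strand-I residue i and the phosphorus of the strand-II
#' residue paired with base pair i+3; the minor groove width uses the
#' strand-II residue paired with base pair i-4. Positions where either
#' phosphate is absent (duplex ends, 5' termini) are omitted; a duplex
#' shorter than the offsets yields an empty profile.
#'
#' @param duplex A `"duplex"`.
#' @return data.frame with columns `position` (1-based bp index of the
#'   strand-I phosphate), `major`, `minor` (Angstrom; `NA` where undefined).
#'   Zero rows when no position is defined.
#' @export
groove_widths <- function(duplex) {
  n <- length(duplex)
  p1 <- lapply(seq_len(n), function(i) nt_atom(duplex[[i]]$nt1, "P"))
  p2 <- lapply(seq_len(n), function(i) nt_atom(duplex[[i]]$nt2, "P"))
  dist_at <- function(i, k) {
    j <- i + k
    if (j < 1 || j > n) return(NA_real_)
    if (is.null(p1[[i]]) || is.null(p2[[j]])) return(NA_real_)
    vnorm(p1[[i]] - p2[[j]])
  }
  rows <- lapply(seq_len(n), function(i) {
    maj <- dist_at(i, .groove_offsets[["major"]])
    mnr <- dist_at(i, .groove_offsets[["minor"]])
    if (is.na(maj) && is.na(mnr)) return(NULL)
    data.frame(position = i, major = maj, minor = mnr)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(position = integer(), major = numeric(),
                      minor = numeric()))
  }
  do.call(rbind, rows)
}
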