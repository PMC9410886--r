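# A-philicity profiling: per-position mean trinucleotide dG(B->A) across
# aligned integration-site windows, and detection of the A-philic peak
# spacing at the target-site duplication.

#' Mean dG(B->A) profile across aligned sites
#'
#' Assigns each trinucleotide of every aligned sequence its table value and
#' keeps a per-position running sum and count. By default a trinucleotide's
#' value is tallied at its central base (which keeps the profile symmetric
#' under reverse complementation); `assign = "start"` tallies at the first
#' base instead. Windows containing N contribute nothing at the affected
#' positions but the rest of the site is still used.
#'
#' @param sites A `"site_set"` of width >= 3.
#' @param table Named 64-entry trinucleotide table, default
#'   [trinuc_dg_table()].
#' @param assign `"center"` or `"start"`.
#' @return data.frame of class `"aphilicity_profile"` with `position`
#'   (relative to the anchor), `mean_dg` (kcal/mol) and `n_used`; attribute
#'   `"tsd"` carries the site set's TSD.
#' @export
deltaG_profile <- function(sites, table = trinuc_dg_table(),
                           assign = c("center", "start")) {
  assign <- match.arg(assign)
  table <- validate_dg_table(table)
  W <- sites$width
  if (W < 3) stop("window width must be >= 3")
  starts <- seq_len(W - 2)                     # 1-based trinucleotide starts
  pos0 <- if (assign == "center") starts else starts - 1L  # 0-based column
  rows <- lapply(seq_along(starts), function(j) {
    tri <- substr(sites$sequences, starts[j], starts[j] + 2L)
    v <- unname(table[tri])                    # NA for N-containing windows
    data.frame(position = pos0[j] - sites$anchor,
               mean_dg = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
               n_used = sum(!is.na(v)))
  })
  out <- do.call(rbind, rows)
  attr(out, "tsd") <- sites$tsd
  class(out) <- c("aphilicity_profile", "data.frame")
  out
}

#' A-philic peak spacing at the target site
#'
#' Finds local minima of the profile inside a search window around the two
#' joining positions (relative positions 0 and `tsd`), and returns the two
#' deepest together with their separation in bp. For integration-site sets
#' with A-philic selection at both joining events the spacing equals the
#' scissile-phosphodiester separation, i.e. the TSD length (6 bp for MMTV).
#'
#' @param profile An `"aphilicity_profile"`.
#' @param search_radius Search window extends from `-search_radius` to
#'   `tsd + search_radius`.
#' @param window Optional explicit `c(lo, hi)` overriding the radius.
#' @param tsd TSD length; defaults to the profile attribute.
#' @return List with `spacing` (bp), `minima` (data.frame of the two
#'   deepest local minima) and `all_minima` (every local minimum found).
#' @export
peak_spacing <- function(profile, search_radius = 10, window = NULL,
                         tsd = attr(profile, "tsd")) {
  if (is.null(window)) {
    if (is.null(tsd)) stop("tsd unknown; give `tsd` or an explicit window")
    window <- c(-search_radius, tsd + search_radius)
  }
  p <- profile[profile$position >= window[1] & profile$position <= window[2] &
                 !is.na(profile$mean_dg), , drop = FALSE]
  p <- p[order(p$position), , drop = FALSE]
  if (nrow(p) < 3) stop("fewer than two local minima in the search window")
  y <- p$mean_dg
  i <- which(diff(sign(diff(y))) > 0) + 1     # strict interior local minima
  if (length(i) < 2) stop("fewer than two local minima in the search window")
  mins <- p[i, c("position", "mean_dg")]
  mins <- mins[order(mins$mean_dg), , drop = FALSE]
  deepest <- mins[1:2, ]
  deepest <- deepest[order(deepest$position), ]
  list(spacing = diff(deepest$position),
       minima = deepest,
       all_minima = mins[order(mins$position), , drop = FALSE])
}

#' Write a profile as TSV
#'
#' @param profile An `"aphilicity_profile"`.
#' @param file Output path.
#' @export
write_profile_tsv <- function(profile, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# position\tmean_dg [kcal/mol]\tn_used", con)
  utils::write.table(profile, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
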