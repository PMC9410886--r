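# Base-pair step parameters via the mid-step-frame (CEHS) construction, the
# Zp phosphorus statistic, and the exact inverse used to rebuild frames from
# parameters.
#
# Convention: a base-pair frame has x toward the major groove, y along the
# long pair axis toward strand I, z along the strand-I 5'->3' helix sense.
# For the step between pairs i and i+1 the two frames are symmetrically
# rolled/tilted onto a shared z-axis (half the hinge rotation each), twist
# is measured about that shared axis, and displacements are expressed in
# the mid-step frame. Roll/tilt are the components of the hinge rotation
# along the mid-step y/x axes.

# Step parameters between two frames. Returns the six parameters plus the
# mid-step frame (used downstream for Zp).
#' @noRd
step_from_frames <- function(f1, f2) {
  R1 <- f1$rotation; R2 <- f2$rotation
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cr <- cross3(z1, z2)
  gamma <- atan2(vnorm(cr), sum(z1 * z2))
  if (vnorm(cr) > 1e-9) {
    hinge <- unitize(cr)
    H <- rot_axis(hinge, gamma / 2)
    R1p <- H %*% R1
    R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- c(0, 0, 0)
    R1p <- R1; R2p <- R2
  }
  zc <- R1p[, 3]                         # common z after half-rotations
  twist <- signed_angle(R1p[, 1], R2p[, 1], zc)
  xm <- unitize(R1p[, 1] + R2p[, 1])
  ym <- unitize(R1p[, 2] + R2p[, 2])
  Rm <- cbind(cross3(ym, zc), ym, zc)
  Rm[, 1] <- unitize(Rm[, 1])
  # roll/tilt: components of the hinge rotation along mid-frame y/x
  if (gamma > 1e-10) {
    roll <- gamma * sum(hinge * Rm[, 2])
    tilt <- gamma * sum(hinge * Rm[, 1])
  } else {
    roll <- 0; tilt <- 0
  }
  disp <- as.numeric(crossprod(Rm, f2$origin - f1$origin))
  mid <- structure(list(origin = (f1$origin + f2$origin) / 2,
                        rotation = Rm, rmsd = NA_real_),
                   class = "ref_frame")
  list(shift = disp[1], slide = disp[2], rise = disp[3],
       tilt = rad2deg(tilt), roll = rad2deg(roll), twist = rad2deg(twist),
       mid = mid)
}

# Exact inverse of step_from_frames: given frame i and the six parameters,
# construct frame i+1 (and the mid-step frame).
#' @noRd
frames_from_step <- function(f1, shift, slide, rise, tilt, roll, twist) {
  R1 <- f1$rotation
  tw <- deg2rad(twist)
  gamma <- sqrt(deg2rad(tilt)^2 + deg2rad(roll)^2)
  phi <- atan2(deg2rad(tilt), deg2rad(roll))   # hinge azimuth from mid-y
  # hinge is perpendicular to z1; its azimuth in the frame-1 xy-plane is
  # (90 - phi) advanced by half the twist.
  beta <- pi / 2 - phi + tw / 2
  hinge <- as.numeric(R1 %*% c(cos(beta), sin(beta), 0))
  if (gamma > 1e-12) {
    H <- rot_axis(hinge, gamma / 2)
  } else {
    H <- diag(3)
  }
  zc <- as.numeric(H %*% R1[, 3])
  R2 <- if (gamma > 1e-12) {
    H %*% rot_axis(zc, tw) %*% H %*% R1
  } else {
    rot_axis(zc, tw) %*% R1
  }
  Rm <- rot_axis(zc, tw / 2) %*% H %*% R1
  o2 <- f1$origin + as.numeric(Rm %*% c(shift, slide, rise))
  list(
    f2 = structure(list(origin = o2, rotation = R2, rmsd = NA_real_),
                   class = "ref_frame"),
    mid = structure(list(origin = (f1$origin + o2) / 2, rotation = Rm,
                         rmsd = NA_real_),
                    class = "ref_frame")
  )
}

#' Base-pair step parameters for a duplex
#'
#' Computes shift, slide and rise (Angstrom) and tilt, roll and twist
#' (degrees) for every dinucleotide step of a duplex via the mid-step-frame
#' construction, together with the Zp statistic: the mean z-coordinate of
#' the two bridging phosphorus atoms of the dimer expressed in the mid-step
#' frame. Zp is greater than about 1.5 Angstrom for A-form and below about
#' 0.5 Angstrom for B-form steps.
#'
#' @param duplex A `"duplex"` (ordered [base_pair] list).
#' @param warn_missing_p Warn when a bridging phosphate is absent (5'
#'   termini have none) and report `NA` Zp for that step.
#' @return data.frame with one row per step (`n_bp - 1` rows): `step_index`
#'   (0-based), `bp1`, `bp2` (dinucleotide bases on strand I), `shift`,
#'   `slide`, `rise`, `tilt`, `roll`, `twist`, `zp`.
#' @export
step_parameters <- function(duplex, warn_missing_p = TRUE) {
  n <- length(duplex)
  if (n < 2) stop("a duplex requires at least 2 base pairs")
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    st <- step_from_frames(duplex[[i]]$frame, duplex[[i + 1]]$frame)
    zp <- zp_from_step(duplex[[i]], duplex[[i + 1]], st$mid)
    if (is.na(zp) && warn_missing_p) {
      warning(sprintf("step %d: bridging phosphate missing, Zp undefined",
                      i - 1), call. = FALSE)
    }
    out[[i]] <- data.frame(
      step_index = i - 1L,
      bp1 = duplex[[i]]$nt1$base, bp2 = duplex[[i + 1]]$nt1$base,
      shift = st$shift, slide = st$slide, rise = st$rise,
      tilt = st$tilt, roll = st$roll, twist = st$twist, zp = zp,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Zp for one step: the two phosphates bridging the dimer (strand I: P of
# the 3' residue of the step; strand II: P of the residue paired with bp i,
# which lies 3' of the dimer on that strand), each projected onto the
# mid-step z-axis in the reading sense of its own strand. The strand-II
# dimer frame is the z- (and y-) flipped mid-step frame, so its projection
# carries the opposite sign. Averaging the two same-sense projections in a
# single common frame would cancel identically on any dyad-symmetric
# duplex and could never reproduce the known A/B reference values.
#' @noRd
zp_from_step <- function(bp_a, bp_b, mid) {
  p1 <- nt_atom(bp_b$nt1, "P")
  p2 <- nt_atom(bp_a$nt2, "P")
  if (is.null(p1) || is.null(p2)) return(NA_real_)
  z <- mid$rotation[, 3]
  mean(c(sum((p1 - mid$origin) * z), -sum((p2 - mid$origin) * z)))
}

#' Zp for one dinucleotide step
#'
#' Convenience wrapper computing Zp for a single pair of adjacent base
#' pairs; errors if a bridging phosphorus atom is absent.
#'
#' @param bp_a,bp_b Adjacent [base_pair]s (bp_a 5' of bp_b on strand I).
#' @return Zp in Angstrom.
#' @export
zp <- function(bp_a, bp_b) {
  st <- step_from_frames(bp_a$frame, bp_b$frame)
  v <- zp_from_step(bp_a, bp_b, st$mid)
  if (is.na(v)) stop("bridging phosphate missing: Zp undefined for this step")
  v
}
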