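# Dimer orientation and deviation metrics: tilt angle, crossing angle,
# Kabsch superposition, RMSD and RMSF series.
#
# Tilt is the angle between the motif-span vector (COM of the pooled
# three-residue flanks above the two motifs minus the COM of the pooled
# flanks below) and the membrane normal z, folded into [0, 90] degrees.
# The crossing angle is the unsigned angle in [0, 180] between the two
# per-chain vectors joining the residues immediately below and above each
# motif.

.residue_atom_idx <- function(frame, chain, resids, backbone_only = FALSE) {
  sel <- frame$atoms$chain == chain & frame$atoms$resid %in% resids
  if (backbone_only) sel <- sel & frame$atoms$name %in% c("N", "CA", "C", "O")
  which(sel)
}

#' Center of mass of a residue selection
#'
#' @param frame an `mm_frame`.
#' @param chain chain label.
#' @param resids 0-based residue indices.
#' @param mass_weighted use atomic masses as weights (default); otherwise
#'   the unweighted centroid.
#' @param backbone_only restrict to N, CA, C, O.
#' @return length-3 numeric vector (Angstrom).
#' @export
residue_com <- function(frame, chain, resids, mass_weighted = TRUE,
                        backbone_only = FALSE) {
  idx <- .residue_atom_idx(frame, chain, resids, backbone_only)
  if (length(idx) == 0L)
    stop("no atoms for chain ", chain, " residues ",
         paste(resids, collapse = ","))
  w <- if (mass_weighted) frame$atoms$mass[idx] else rep(1, length(idx))
  colSums(frame$xyz[idx, , drop = FALSE] * w) / sum(w)
}

.vec_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) stop("degenerate geometry: zero-length vector")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Dimer tilt angle
#'
#' Angle between the motif-span vector and the z axis.  The top of the span
#' is the COM of the six pooled residues C-terminal to the two motifs (three
#' per chain), the bottom the COM of the six pooled residues N-terminal to
#' them.  Folded into \[0, 90\] degrees (the membrane has up-down symmetry).
#'
#' @param frame an `mm_frame` (or 1-frame `mm_traj`).
#' @param topo an `mm_topology`.
#' @param mass_weighted mass-weight the COMs (default TRUE).
#' @param backbone_only restrict COMs to backbone atoms.
#' @return tilt angle in degrees, in \[0, 90\].
#' @export
dimer_tilt <- function(frame, topo, mass_weighted = TRUE,
                       backbone_only = FALSE) {
  frame <- as_frame(frame)
  v <- .motif_span_vector(frame, topo, mass_weighted, backbone_only)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate geometry: motif top coincides with bottom")
  acos(min(1, abs(v[3]) / nv)) * 180 / pi
}

.pooled_flank_com <- function(frame, topo, side, mass_weighted,
                              backbone_only) {
  fl <- motif_flank_selection(topo, side)
  ia <- .residue_atom_idx(frame, topo$chain_a, fl$a, backbone_only)
  ib <- .residue_atom_idx(frame, topo$chain_b, fl$b, backbone_only)
  idx <- c(ia, ib)
  if (length(idx) == 0L) stop("flank selection '", side, "' selects no atoms")
  w <- if (mass_weighted) frame$atoms$mass[idx] else rep(1, length(idx))
  colSums(frame$xyz[idx, , drop = FALSE] * w) / sum(w)
}

.motif_span_vector <- function(frame, topo, mass_weighted = TRUE,
                               backbone_only = FALSE) {
  top <- .pooled_flank_com(frame, topo, "above", mass_weighted, backbone_only)
  bottom <- .pooled_flank_com(frame, topo, "below", mass_weighted,
                              backbone_only)
  top - bottom
}

#' Crossing angle of the two helices
#'
#' For each chain, a vector runs from the COM of the residue immediately
#' N-terminal of the motif to the COM of the residue immediately C-terminal
#' of it (`anchors = "single"`, the default) or between the three-residue
#' flank COMs (`anchors = "triplet"`).  The crossing angle is the unsigned
#' angle between the two chain vectors, in \[0, 180\] degrees; no handedness
#' sign is attached.
#'
#' @inheritParams dimer_tilt
#' @param anchors `"single"` or `"triplet"` residue anchors.
#' @return crossing angle in degrees, in \[0, 180\].
#' @export
crossing_angle <- function(frame, topo, mass_weighted = TRUE,
                           backbone_only = FALSE,
                           anchors = c("single", "triplet")) {
  frame <- as_frame(frame)
  anchors <- match.arg(anchors)
  chain_vec <- function(chain, start) {
    stop_ <- start + 8L
    if (anchors == "single") {
      lo <- residue_com(frame, chain, start - 1L, mass_weighted,
                        backbone_only)
      hi <- residue_com(frame, chain, stop_ + 1L, mass_weighted,
                        backbone_only)
    } else {
      lo <- residue_com(frame, chain, (start - 3L):(start - 1L),
                        mass_weighted, backbone_only)
      hi <- residue_com(frame, chain, (stop_ + 1L):(stop_ + 3L),
                        mass_weighted, backbone_only)
    }
    hi - lo
  }
  va <- chain_vec(topo$chain_a, topo$motif_start_a)
  vb <- chain_vec(topo$chain_b, topo$motif_start_b)
  .vec_angle_deg(va, vb)
}

#' Per-frame tilt and crossing angle series
#'
#' @param traj an `mm_traj`.
#' @param topo an `mm_topology`.
#' @param discard_fraction leading fraction of frames to drop before
#'   analysis (equilibrium-averaging convention; default 0 reports all
#'   frames).
#' @inheritParams dimer_tilt
#' @return data.frame with columns `frame`, `time_ps`, `tilt_deg`,
#'   `crossing_deg`.
#' @export
tilt_series <- function(traj, topo, discard_fraction = 0,
                        mass_weighted = TRUE, backbone_only = FALSE) {
  validate_trajectory(traj)
  nf0 <- n_frames(traj)
  keep <- if (discard_fraction > 0) {
    (min(nf0, floor(nf0 * discard_fraction) + 1L)):nf0
  } else seq_len(nf0)
  res <- lapply(keep, function(k) {
    fr <- get_frame(traj, k)
    c(tilt = dimer_tilt(fr, topo, mass_weighted, backbone_only),
      crossing = crossing_angle(fr, topo, mass_weighted, backbone_only))
  })
  m <- do.call(rbind, res)
  data.frame(frame = keep, time_ps = traj$time[keep],
             tilt_deg = m[, "tilt"], crossing_deg = m[, "crossing"])
}

# ---- superposition and deviation ------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the weighted squared
#' deviation of `mobile` onto `reference` (SVD solution, with the usual
#' determinant sign fix to exclude reflections).
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @param weights per-atom weights (default: uniform).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3,
#'   applied after rotation), `fitted` (transformed mobile), and `rmsd`
#'   (weighted RMSD after the fit, Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3L) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("rank error: reference points are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- sweep(X %*% t(R), 2, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       fitted = fitted, rmsd = rmsd)
}

.resolve_rmsd_selection <- function(traj, topo, selection, backbone_only) {
  if (is.numeric(selection)) return(as.integer(selection))
  at <- traj$atoms
  if (identical(selection, "whole_dimer")) {
    return(which(at$chain %in% c(topo$chain_a, topo$chain_b)))
  }
  if (identical(selection, "motif5")) {
    con <- motif_conserved_residues(topo)
    sel <- (at$chain == topo$chain_a & at$resid %in% con$a) |
           (at$chain == topo$chain_b & at$resid %in% con$b)
    sel <- sel & at$name %in% c("N", "CA", "C", "O")
    return(which(sel))
  }
  stop("unknown selection '", selection, "'")
}

#' Per-frame RMSD after least-squares fitting
#'
#' The reference is a designated frame (default: the first).  `"motif5"`
#' selects the backbone atoms of the five conserved motif residues
#' (G, V, G, V, T) of each chain; `"whole_dimer"` every peptide atom; an
#' integer vector selects atoms directly.
#'
#' @param traj an `mm_traj`.
#' @param topo an `mm_topology` (needed for the named selections).
#' @param selection `"motif5"`, `"whole_dimer"`, or atom indices.
#' @param fit_selection atoms used for the superposition (default: the
#'   analysis selection itself).
#' @param reference_frame frame number serving as reference (default 1).
#' @param mass_weighted mass-weight fit and RMSD (default TRUE).
#' @return data.frame with columns `frame`, `time_ps`, `rmsd`; the
#'   reference frame id is attached as attribute `"reference"`.
#' @export
rmsd_series <- function(traj, topo = NULL, selection = "motif5",
                        fit_selection = NULL, reference_frame = 1L,
                        mass_weighted = TRUE) {
  validate_trajectory(traj)
  idx <- .resolve_rmsd_selection(traj, topo, selection, FALSE)
  if (length(idx) == 0L) stop("empty analysis selection")
  fit_idx <- if (is.null(fit_selection)) idx
             else .resolve_rmsd_selection(traj, topo, fit_selection, FALSE)
  wfit <- if (mass_weighted) traj$atoms$mass[fit_idx] else NULL
  wana <- if (mass_weighted) traj$atoms$mass[idx] else rep(1, length(idx))
  wana <- wana / sum(wana)
  ref_fit <- traj$xyz[fit_idx, , reference_frame]
  ref_ana <- traj$xyz[idx, , reference_frame]
  nf <- n_frames(traj)
  rmsd <- vapply(seq_len(nf), function(k) {
    fit <- kabsch_superpose(traj$xyz[fit_idx, , k], ref_fit, wfit)
    moved <- sweep(traj$xyz[idx, , k] %*% t(fit$rotation), 2,
                   fit$translation, "+")
    sqrt(sum(wana * rowSums((moved - ref_ana)^2)))
  }, numeric(1))
  out <- data.frame(frame = seq_len(nf), time_ps = traj$time, rmsd = rmsd)
  attr(out, "reference") <- reference_frame
  out
}

#' Per-residue RMSF of alpha carbons
#'
#' Frames are least-squares fitted to the time-average structure (computed
#' iteratively: fit to the first frame, average, re-fit to the average) and
#' the root-mean-square fluctuation of each selected CA about its mean
#' position is reported.
#'
#' @param traj an `mm_traj` with at least 2 frames.
#' @param selection atom indices to analyse (default: all CA atoms).
#' @param n_iter mean-structure refinement iterations (default 2).
#' @return data.frame with columns `chain`, `resid`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = NULL, n_iter = 2L) {
  validate_trajectory(traj)
  if (n_frames(traj) < 2L) stop("RMSF undefined for a single frame")
  if (is.null(selection)) selection <- which(traj$atoms$name == "CA")
  idx <- as.integer(selection)
  if (length(idx) < 3L) stop("need at least 3 atoms for fitting")
  nf <- n_frames(traj)
  w <- traj$atoms$mass[idx]
  ref <- traj$xyz[idx, , 1]
  fitted <- array(NA_real_, c(length(idx), 3, nf))
  for (it in seq_len(n_iter)) {
    for (k in seq_len(nf)) {
      fitted[, , k] <- kabsch_superpose(traj$xyz[idx, , k], ref, w)$fitted
    }
    ref <- apply(fitted, c(1, 2), mean)
  }
  mean_pos <- ref
  disp2 <- sapply(seq_len(nf), function(k)
    rowSums((fitted[, , k] - mean_pos)^2))
  rmsf <- sqrt(rowMeans(disp2))
  data.frame(chain = traj$atoms$chain[idx], resid = traj$atoms$resid[idx],
             rmsf = rmsf)
}
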