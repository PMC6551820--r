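# Bilayer analysis: leaflet decomposition, gridded thickness maps
# (phosphorus-phosphorus or chain-alpha-carbon "hydrophobic" surfaces),
# far-field bulk thickness, and hydrophobic length/mismatch calculus.
#
# The lateral (x, y) plane is periodic; leaflets are separated along z.
# The default 3.3 Angstrom grid spacing matches the 0.33 nm convention of
# lateral membrane-property mapping tools.

#' Split marker atoms into upper and lower leaflets
#'
#' Assignment is frozen on the first frame: markers above the mass-weighted
#' marker midplane go to the upper leaflet, the rest to the lower.  No
#' flip-flop tracking is attempted (planar bilayers only).
#'
#' @param traj an `mm_traj`.
#' @param marker_query selection for the marker atoms (default `"name P"`,
#'   the head-group phosphorus; use e.g. `"name C22,C32"` for the acyl
#'   chain alpha carbons defining the hydrophobic surfaces).
#' @return list of class `mm_leaflets`: `upper`, `lower` (atom indices),
#'   `midplane_z` (per frame, Angstrom), `marker_query`.
#' @export
split_leaflets <- function(traj, marker_query = "name P") {
  validate_trajectory(traj)
  idx <- select_atoms(traj, marker_query)
  if (length(idx) < 4L) stop("need at least 2 marker atoms per leaflet")
  w <- traj$atoms$mass[idx]
  z1 <- traj$xyz[idx, 3, 1]
  mid1 <- sum(w * z1) / sum(w)
  upper <- idx[z1 > mid1]
  lower <- idx[z1 <= mid1]
  if (length(upper) < 2L || length(lower) < 2L)
    stop("degenerate bilayer: markers do not form two leaflets")
  midplane <- vapply(seq_len(n_frames(traj)), function(k) {
    zz <- traj$xyz[idx, 3, k]
    sum(w * zz) / sum(w)
  }, numeric(1))
  structure(list(upper = upper, lower = lower, midplane_z = midplane,
                 marker_query = marker_query), class = "mm_leaflets")
}

#' Gridded membrane thickness map
#'
#' Marker atoms are binned per frame into a periodic lateral grid; the
#' per-cell surface is the time-and-atom mean z of each leaflet, and
#' thickness is their difference.  Cells left empty in either leaflet are
#' filled from the nearest occupied cell (periodic), by inverse-distance
#' weighting, or flagged `NA` (`fill = "none"`).
#'
#' @param traj an `mm_traj` (box must be constant across frames within 1%).
#' @param split an `mm_leaflets` from [split_leaflets()].
#' @param spacing lateral grid spacing in Angstrom (default 3.3; the grid
#'   dimensions round the box to whole cells).
#' @param fill empty-cell policy: `"nearest"` (default), `"idw"`, `"none"`.
#' @param discard_fraction leading fraction of frames to drop (default 0).
#' @return object of class `mm_thickness_map`: list with `spacing`,
#'   `nx`, `ny`, `cell_x`, `cell_y` (cell-center coordinates), matrices
#'   `upper_z`, `lower_z`, `thickness`, `occupancy_upper`,
#'   `occupancy_lower`, the box, and the analysed frame count.
#' @export
thickness_map <- function(traj, split, spacing = 3.3,
                          fill = c("nearest", "idw", "none"),
                          discard_fraction = 0) {
  validate_trajectory(traj)
  fill <- match.arg(fill)
  if (spacing <= 0) stop("spacing must be positive")
  box <- traj$box[1, ]
  if (any(abs(sweep(traj$box, 2, box, "/") - 1) > 0.01))
    stop("box dimensions vary by more than 1% across frames")
  if (spacing > min(box[1], box[2]) / 2)
    stop("grid error: spacing exceeds half the lateral box")
  nx <- max(2L, round(box[1] / spacing)); ny <- max(2L, round(box[2] / spacing))
  dx <- box[1] / nx; dy <- box[2] / ny
  nf0 <- n_frames(traj)
  frames <- if (discard_fraction > 0) {
    (min(nf0, floor(nf0 * discard_fraction) + 1L)):nf0
  } else seq_len(nf0)
  accum <- function(atom_idx) {
    zsum <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
    for (k in frames) {
      x <- traj$xyz[atom_idx, 1, k] %% box[1]
      y <- traj$xyz[atom_idx, 2, k] %% box[2]
      ix <- pmin(nx - 1L, floor(x / dx)) + 1L
      iy <- pmin(ny - 1L, floor(y / dy)) + 1L
      zz <- traj$xyz[atom_idx, 3, k]
      for (a in seq_along(atom_idx)) {
        zsum[ix[a], iy[a]] <- zsum[ix[a], iy[a]] + zz[a]
        cnt[ix[a], iy[a]] <- cnt[ix[a], iy[a]] + 1L
      }
    }
    list(mean = ifelse(cnt > 0, zsum / pmax(cnt, 1L), NA_real_), count = cnt)
  }
  up <- accum(split$upper); lo <- accum(split$lower)
  upper_z <- .fill_grid(up$mean, dx, dy, fill)
  lower_z <- .fill_grid(lo$mean, dx, dy, fill)
  structure(list(spacing = spacing, nx = nx, ny = ny,
                 cell_x = (seq_len(nx) - 0.5) * dx,
                 cell_y = (seq_len(ny) - 0.5) * dy,
                 upper_z = upper_z, lower_z = lower_z,
                 thickness = upper_z - lower_z,
                 occupancy_upper = up$count, occupancy_lower = lo$count,
                 box = box, n_frames = length(frames)),
            class = "mm_thickness_map")
}

#' @export
print.mm_thickness_map <- function(x, ...) {
  cat(sprintf("<mm_thickness_map> %dx%d cells @ %.2f A, mean thickness %.2f A\n",
              x$nx, x$ny, x$spacing, mean(x$thickness, na.rm = TRUE)))
  invisible(x)
}

.fill_grid <- function(m, dx, dy, fill) {
  empty <- which(is.na(m), arr.ind = TRUE)
  if (nrow(empty) == 0L || fill == "none") return(m)
  occ <- which(!is.na(m), arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("no occupied cells")
  nx <- nrow(m); ny <- ncol(m)
  Lx <- nx * dx; Ly <- ny * dy
  ox <- (occ[, 1] - 0.5) * dx; oy <- (occ[, 2] - 0.5) * dy
  vals <- m[occ]
  out <- m
  for (r in seq_len(nrow(empty))) {
    ex <- (empty[r, 1] - 0.5) * dx; ey <- (empty[r, 2] - 0.5) * dy
    ddx <- abs(ox - ex); ddx <- pmin(ddx, Lx - ddx)
    ddy <- abs(oy - ey); ddy <- pmin(ddy, Ly - ddy)
    d2 <- ddx^2 + ddy^2
    if (fill == "nearest") {
      out[empty[r, 1], empty[r, 2]] <- vals[which.min(d2)]
    } else {
      wgt <- 1 / pmax(d2, 1e-6)
      out[empty[r, 1], empty[r, 2]] <- sum(wgt * vals) / sum(wgt)
    }
  }
  out
}

#' Bulk (far-field) membrane thickness
#'
#' The reference thickness of the unperturbed membrane: the occupancy-
#' weighted mean thickness over the grid cells whose minimal periodic
#' lateral distance to the protein footprint falls in the top
#' `far_fraction` of the distance distribution.
#'
#' @param map an `mm_thickness_map`.
#' @param protein_xy `n x 2` matrix of lateral protein coordinates
#'   (Angstrom), e.g. the time-averaged peptide atom positions.
#' @param far_fraction fraction of the furthest cells to average
#'   (default 0.25; 1.0 averages the whole map).
#' @return bulk thickness in Angstrom.
#' @export
bulk_thickness <- function(map, protein_xy, far_fraction = 0.25) {
  stopifnot(inherits(map, "mm_thickness_map"))
  protein_xy <- as.matrix(protein_xy)
  if (nrow(protein_xy) == 0L) stop("protein footprint is empty")
  if (far_fraction <= 0 || far_fraction > 1)
    stop("far_fraction must be in (0, 1]")
  Lx <- map$box[1]; Ly <- map$box[2]
  px <- protein_xy[, 1] %% Lx; py <- protein_xy[, 2] %% Ly
  grid <- expand.grid(ix = seq_len(map$nx), iy = seq_len(map$ny))
  cx <- map$cell_x[grid$ix]; cy <- map$cell_y[grid$iy]
  dmin <- vapply(seq_along(cx), function(i) {
    ddx <- abs(px - cx[i]); ddx <- pmin(ddx, Lx - ddx)
    ddy <- abs(py - cy[i]); ddy <- pmin(ddy, Ly - ddy)
    min(ddx^2 + ddy^2)
  }, numeric(1))
  th <- map$thickness[cbind(grid$ix, grid$iy)]
  occ <- (map$occupancy_upper + map$occupancy_lower)[cbind(grid$ix, grid$iy)]
  ok <- !is.na(th)
  if (!any(ok)) stop("no defined thickness cells")
  cut <- stats::quantile(dmin[ok], probs = 1 - far_fraction, names = FALSE)
  far <- ok & dmin >= cut
  if (!any(far)) stop("far cell set is empty")
  wgt <- pmax(occ[far], 1)
  sum(wgt * th[far]) / sum(wgt)
}

#' Per-cell thickness perturbation versus bulk
#'
#' @param map an `mm_thickness_map`.
#' @param bulk bulk thickness (Angstrom), e.g. from [bulk_thickness()].
#' @return matrix `nx x ny` of thickness minus bulk.
#' @export
perturbation_map <- function(map, bulk) {
  stopifnot(inherits(map, "mm_thickness_map"), is.finite(bulk))
  map$thickness - bulk
}

#' Hydrophobic length of a helical segment
#'
#' The canonical alpha-helix rise is 1.5 Angstrom per residue, so a
#' hydrophobic stretch of `n` residues spans `1.5 * n` Angstrom of the
#' membrane hydrocarbon core.
#'
#' @param n_residues non-negative integer residue count (vectorised).
#' @return length in Angstrom.
#' @export
#' @examples
#' hydrophobic_length(c(17, 23, 29))  # 25.5, 34.5, 43.5
hydrophobic_length <- function(n_residues) {
  if (any(n_residues < 0)) stop("residue count must be non-negative")
  if (any(n_residues != round(n_residues)))
    stop("residue count must be integer")
  1.5 * n_residues
}

#' Hydrophobic mismatch report
#'
#' Mismatch is peptide hydrophobic length minus membrane hydrophobic
#' thickness: positive when the TM segment is longer than the membrane is
#' thick, negative when shorter, and "matched" inside a tolerance deadband.
#'
#' @param peptide_len peptide hydrophobic length, Angstrom.
#' @param hydrophobic_thickness membrane hydrophobic thickness, Angstrom.
#' @param tolerance deadband half-width for the "matched" label
#'   (default 1.0 Angstrom).
#' @return list of class `mm_mismatch`: `peptide_len`,
#'   `membrane_thickness`, `mismatch`, `label`.
#' @export
#' @examples
#' mismatch_report(43.5, 20.0)$label  # "positive"
mismatch_report <- function(peptide_len, hydrophobic_thickness,
                            tolerance = 1.0) {
  stopifnot(peptide_len >= 0, hydrophobic_thickness >= 0, tolerance >= 0)
  mismatch <- peptide_len - hydrophobic_thickness
  label <- if (abs(mismatch) < tolerance) "matched"
           else if (mismatch > 0) "positive" else "negative"
  structure(list(peptide_len = peptide_len,
                 membrane_thickness = hydrophobic_thickness,
                 mismatch = mismatch, label = label),
            class = "mm_mismatch")
}

#' @export
print.mm_mismatch <- function(x, ...) {
  cat(sprintf("<mm_mismatch> peptide %.1f A vs membrane %.1f A: %+.1f A (%s)\n",
              x$peptide_len, x$membrane_thickness, x$mismatch, x$label))
  invisible(x)
}

#' Time-averaged lateral protein footprint
#'
#' @param traj an `mm_traj`.
#' @param chains peptide chain labels.
#' @param discard_fraction leading fraction of frames to drop.
#' @return `n x 2` matrix of time-averaged (x, y) atom positions.
#' @export
protein_footprint <- function(traj, chains = c("A", "B"),
                              discard_fraction = 0) {
  validate_trajectory(traj)
  idx <- which(traj$atoms$chain %in% chains)
  if (length(idx) == 0L) stop("no atoms in chains ",
                              paste(chains, collapse = ","))
  nf0 <- n_frames(traj)
  frames <- if (discard_fraction > 0) {
    (min(nf0, floor(nf0 * discard_fraction) + 1L)):nf0
  } else seq_len(nf0)
  xy <- apply(traj$xyz[idx, 1:2, frames, drop = FALSE], c(1, 2), mean)
  colnames(xy) <- c("x", "y")
  xy
}
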