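# Synthetic ground truth: ideal helical dimers inside planar pseudo-bilayers
# with controllable tilt, crossing angle, thickness, Gaussian dent, and
# per-frame thermal noise; plus plate-style fluorescence assay tables.
# The generator validates estimators -- it does not simulate physics.

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Cylindrical backbone parameters of the ideal alpha helix: radius (A),
# phase offset (deg, relative to CA) and z offset (A, relative to CA),
# derived once from a chain built at canonical phi/psi = (-57, -47) with
# standard bond geometry, then locked to exact rise 1.5 A and twist
# 100 deg/residue.  The handedness matches the derivation (twist applied
# with a negative sign in this frame).
.HELIX_PARAMS <- list(
  N  = c(r = 1.5504, ph =  26.805, dz = -0.9186),
  CA = c(r = 2.2744, ph =   0.000, dz =  0.0000),
  C  = c(r = 1.6651, ph = -26.775, dz =  1.0689),
  O  = c(r = 1.9196, ph = -20.364, dz =  2.2565)
)
.HELIX_RISE <- 1.5
.HELIX_TWIST <- -100 * pi / 180

#' Build an ideal alpha helix (backbone only)
#'
#' CA atoms lie on a helix with exactly 1.5 Angstrom rise and 100 degrees
#' twist per residue about the z axis; N, C and O are placed on concentric
#' helices with offsets consistent with canonical alpha phi/psi
#' (-57, -47 degrees) and standard bond geometry.  The helix is centered:
#' the axis runs through x = y = 0 and the CA z-extent is symmetric about 0.
#'
#' @param sequence 1-letter residue string (length >= 4).
#' @param chain chain label for the atoms table.
#' @return an `mm_frame` with 4 backbone atoms per residue and a generous
#'   default box.
#' @export
#' @examples
#' h <- build_ideal_helix("LLLLGVLLGVLLTLLLL")
#' range(h$xyz[h$atoms$name == "CA", 3])  # spans 16 * 1.5 = 24 A
build_ideal_helix <- function(sequence, chain = "A") {
  res1 <- strsplit(sequence, "")[[1]]
  if (length(res1) < 4L) stop("sequence must have at least 4 residues")
  res3 <- .AA1TO3[res1]
  if (any(is.na(res3)))
    stop("unknown residue letter(s): ",
         paste(unique(res1[is.na(res3)]), collapse = ", "))
  n <- length(res1)
  zc <- (seq_len(n) - 1) * .HELIX_RISE
  zc <- zc - mean(range(zc))  # center axially
  name <- character(0); resid <- integer(0); resn <- character(0)
  xyz <- matrix(NA_real_, 4L * n, 3L)
  row <- 0L
  for (i in seq_len(n)) {
    base_th <- (i - 1) * .HELIX_TWIST
    for (at in c("N", "CA", "C", "O")) {
      p <- .HELIX_PARAMS[[at]]
      th <- base_th + p[["ph"]] * pi / 180
      row <- row + 1L
      xyz[row, ] <- c(p[["r"]] * cos(th), p[["r"]] * sin(th),
                      zc[i] + p[["dz"]])
      name <- c(name, at); resid <- c(resid, i - 1L)
      resn <- c(resn, res3[i])
    }
  }
  atoms <- atom_table(name, resid, resn, chain)
  structure(list(atoms = atoms, xyz = xyz,
                 box = c(100, 100, 100), time = 0),
            class = "mm_frame")
}

#' Synthetic system configuration
#'
#' Defaults mirror the simulated systems the generator emulates: 200 lipids
#' per leaflet, a DOPC-like bilayer (phosphorus-phosphorus thickness
#' 38.7 Angstrom, hydrophobic thickness 27.4 Angstrom), a 23-residue
#' leucine-flanked GVxxGVxxT peptide in both chains, 7 Angstrom inter-axial
#' separation, and an area per lipid of 68 Angstrom^2 (typical fluid-phase
#' phosphatidylcholine) which sizes the lateral box.
#'
#' @param sequence_a,sequence_b 1-letter peptide sequences (must contain a
#'   GVxxGVxxT motif away from the termini).
#' @param tilt_deg dimer tilt, degrees (orientation of the motif-span
#'   vector relative to z).
#' @param crossing_deg helix crossing angle, degrees.
#' @param inter_axial_distance helix-helix axial separation, Angstrom.
#' @param bulk_pp_thickness phosphorus-phosphorus thickness, Angstrom.
#' @param bulk_hydrophobic_thickness chain alpha-carbon thickness, Angstrom
#'   (must be smaller than the P-P thickness).
#' @param lipids_per_leaflet marker "lipids" per leaflet.
#' @param area_per_lipid Angstrom^2 per lipid; sets the lateral box.
#' @param dent_amplitude Gaussian thickness perturbation at the dimer
#'   center, Angstrom (negative = local thinning).
#' @param dent_sigma lateral width of the dent, Angstrom.
#' @param noise_sigma per-atom, per-frame isotropic Gaussian displacement,
#'   Angstrom.
#' @param n_frames number of frames for [generate_trajectory()].
#' @param time_step frame spacing, ps.
#' @param seed RNG seed (R Mersenne-Twister, Inversion normals).
#' @return list of class `mm_syncfg`.
#' @export
synthetic_config <- function(sequence_a = "LLLLLLLGVLLGVLLTLLLLLLL",
                             sequence_b = sequence_a,
                             tilt_deg = 0, crossing_deg = 0,
                             inter_axial_distance = 7.0,
                             bulk_pp_thickness = 38.7,
                             bulk_hydrophobic_thickness = 27.4,
                             lipids_per_leaflet = 200L,
                             area_per_lipid = 68,
                             dent_amplitude = 0, dent_sigma = 10,
                             noise_sigma = 0, n_frames = 1L,
                             time_step = 100, seed = 42L) {
  cfg <- list(sequence_a = sequence_a, sequence_b = sequence_b,
              tilt_deg = tilt_deg, crossing_deg = crossing_deg,
              inter_axial_distance = inter_axial_distance,
              bulk_pp_thickness = bulk_pp_thickness,
              bulk_hydrophobic_thickness = bulk_hydrophobic_thickness,
              lipids_per_leaflet = as.integer(lipids_per_leaflet),
              area_per_lipid = area_per_lipid,
              dent_amplitude = dent_amplitude, dent_sigma = dent_sigma,
              noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
              time_step = time_step, seed = as.integer(seed),
              rng = "Mersenne-Twister/Inversion")
  stopifnot(cfg$bulk_pp_thickness > 0, cfg$bulk_hydrophobic_thickness > 0,
            cfg$bulk_hydrophobic_thickness < cfg$bulk_pp_thickness,
            cfg$n_frames >= 1L, cfg$noise_sigma >= 0,
            cfg$inter_axial_distance > 0, cfg$dent_sigma > 0,
            cfg$lipids_per_leaflet >= 4L)
  class(cfg) <- "mm_syncfg"
  cfg
}

.rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
.rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
.rot_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s <- sin(angle_rad); C <- 1 - c_
  matrix(c(a[1]*a[1]*C + c_,      a[2]*a[1]*C + a[3]*s, a[3]*a[1]*C - a[2]*s,
           a[1]*a[2]*C - a[3]*s,  a[2]*a[2]*C + c_,     a[3]*a[2]*C + a[1]*s,
           a[1]*a[3]*C + a[2]*s,  a[2]*a[3]*C - a[1]*s, a[3]*a[3]*C + c_),
         3, 3)
}

.lipid_lattice <- function(n, Lx, Ly) {
  ny <- max(2L, floor(sqrt(n)))
  while (n %% ny != 0L) ny <- ny - 1L
  nx <- n %/% ny
  dx <- Lx / nx; dy <- Ly / ny
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  cbind(g$i * dx, g$j * dy)
}

#' Build one synthetic dimer-in-bilayer frame
#'
#' Two ideal helices are placed side by side (translation-related, same
#' internal phase) at the configured inter-axial separation, rotated by
#' +/- crossing/2 about the axis joining them, then rigidly rotated so that
#' the dimer's motif-span vector — the exact quantity [dimer_tilt()]
#' measures — sits at the configured tilt from z.  The bilayer is two
#' lateral marker lattices per leaflet surface: head-group phosphorus `P`
#' at +/- (P-P thickness)/2 and chain alpha carbons `C22`/`C32` at
#' +/- (hydrophobic thickness)/2, every surface displaced by a radial
#' Gaussian dent centered on the dimer's lateral position (the box center).
#'
#' @param cfg an `mm_syncfg` from [synthetic_config()].
#' @return list with `frame` (`mm_frame`), `topo` (`mm_topology`), and
#'   `truth` (class `mm_syntruth`: the config plus derived quantities —
#'   box, dent center, expected bulk thicknesses).
#' @export
build_dimer_frame <- function(cfg) {
  stopifnot(inherits(cfg, "mm_syncfg"))
  topo <- dimer_topology(cfg$sequence_a, cfg$sequence_b)
  Lx <- sqrt(cfg$lipids_per_leaflet * cfg$area_per_lipid)
  Ly <- Lx
  Lz <- max(100, cfg$bulk_pp_thickness + 60)
  ha <- build_ideal_helix(cfg$sequence_a, chain = "A")
  hb <- build_ideal_helix(cfg$sequence_b, chain = "B")
  zspan <- max(diff(range(ha$xyz[, 3])), diff(range(hb$xyz[, 3])))
  if (zspan > Lz - 10)
    stop("geometry error: helices do not fit the box height")
  d <- cfg$inter_axial_distance
  ha$xyz <- sweep(ha$xyz, 2, c(-d / 2, 0, 0), "+")
  hb$xyz <- sweep(hb$xyz, 2, c(+d / 2, 0, 0), "+")
  # crossing: opposite rotations about x through each helix's own center
  rot_about <- function(xyz, R, center) {
    sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
  }
  ha$xyz <- rot_about(ha$xyz, .rot_x(+cfg$crossing_deg / 2), c(-d / 2, 0, 0))
  hb$xyz <- rot_about(hb$xyz, .rot_x(-cfg$crossing_deg / 2), c(+d / 2, 0, 0))
  pep_atoms <- rbind(ha$atoms, hb$atoms)
  pep_xyz <- rbind(ha$xyz, hb$xyz)
  # orient the motif-span vector to the configured tilt (in the x-z plane)
  tmp <- structure(list(atoms = pep_atoms, xyz = pep_xyz,
                        box = c(Lx, Ly, Lz), time = 0), class = "mm_frame")
  v <- .motif_span_vector(tmp, topo)
  v <- v / sqrt(sum(v^2))
  target <- c(sin(cfg$tilt_deg * pi / 180), 0, cos(cfg$tilt_deg * pi / 180))
  ax <- c(v[2] * target[3] - v[3] * target[2],
          v[3] * target[1] - v[1] * target[3],
          v[1] * target[2] - v[2] * target[1])
  if (sqrt(sum(ax^2)) > 1e-12) {
    ang <- acos(max(-1, min(1, sum(v * target))))
    R <- .rot_axis(ax, ang)
    ctr <- colMeans(pep_xyz)
    pep_xyz <- rot_about(pep_xyz, R, ctr)
  }
  # drop the dimer at the box center, motif midplane at z = 0
  top <- .pooled_flank_com(structure(list(atoms = pep_atoms, xyz = pep_xyz),
                                     class = "mm_frame"), topo, "above",
                           TRUE, FALSE)
  bottom <- .pooled_flank_com(structure(list(atoms = pep_atoms,
                                             xyz = pep_xyz),
                                        class = "mm_frame"), topo, "below",
                              TRUE, FALSE)
  mid <- (top + bottom) / 2
  pep_xyz <- sweep(pep_xyz, 2, c(Lx / 2 - mid[1], Ly / 2 - mid[2], -mid[3]),
                   "+")
  # bilayer marker lattices
  lat <- .lipid_lattice(cfg$lipids_per_leaflet, Lx, Ly)
  dent <- function(x, y) {
    ddx <- abs(x - Lx / 2); ddx <- pmin(ddx, Lx - ddx)
    ddy <- abs(y - Ly / 2); ddy <- pmin(ddy, Ly - ddy)
    (cfg$dent_amplitude / 2) *
      exp(-(ddx^2 + ddy^2) / (2 * cfg$dent_sigma^2))
  }
  g <- dent(lat[, 1], lat[, 2])
  nl <- nrow(lat)
  one_leaflet <- function(sign, resid0) {
    zp <- sign * (cfg$bulk_pp_thickness / 2) + sign * g
    zc <- sign * (cfg$bulk_hydrophobic_thickness / 2) + sign * g
    name <- rep(c("P", "C22", "C32"), nl)
    resid <- rep(resid0 + seq_len(nl) - 1L, each = 3L)
    xyz <- matrix(NA_real_, 3L * nl, 3L)
    xyz[seq(1, 3 * nl, 3), ] <- cbind(lat, zp)
    xyz[seq(2, 3 * nl, 3), ] <- cbind(lat, zc)
    xyz[seq(3, 3 * nl, 3), ] <- cbind(lat, zc)
    list(atoms = atom_table(name, resid, "LIP", "L",
                            element = rep(c("P", "C", "C"), nl)),
         xyz = xyz)
  }
  up <- one_leaflet(+1, 0L)
  lo <- one_leaflet(-1, nl)
  atoms <- rbind(pep_atoms, up$atoms, lo$atoms)
  xyz <- rbind(pep_xyz, up$xyz, lo$xyz)
  frame <- structure(list(atoms = atoms, xyz = xyz, box = c(Lx, Ly, Lz),
                          time = 0), class = "mm_frame")
  truth <- structure(c(unclass(cfg),
                       list(box = c(Lx, Ly, Lz),
                            dent_center = c(Lx / 2, Ly / 2),
                            motif_start_a = topo$motif_start_a,
                            motif_start_b = topo$motif_start_b)),
                     class = "mm_syntruth")
  list(frame = frame, topo = topo, truth = truth)
}

#' Expected thickness of the synthetic membrane at a lateral point
#'
#' Closed-form ground truth: bulk thickness plus the Gaussian dent.
#'
#' @param truth an `mm_syntruth`.
#' @param x,y lateral coordinates, Angstrom (vectorised).
#' @param surface `"pp"` or `"hydrophobic"`.
#' @return expected thickness, Angstrom.
#' @export
expected_thickness <- function(truth, x, y, surface = c("pp",
                                                        "hydrophobic")) {
  surface <- match.arg(surface)
  bulk <- if (surface == "pp") truth$bulk_pp_thickness
          else truth$bulk_hydrophobic_thickness
  Lx <- truth$box[1]; Ly <- truth$box[2]
  ddx <- abs(x - truth$dent_center[1]); ddx <- pmin(ddx, Lx - ddx)
  ddy <- abs(y - truth$dent_center[2]); ddy <- pmin(ddy, Ly - ddy)
  bulk + truth$dent_amplitude *
    exp(-(ddx^2 + ddy^2) / (2 * truth$dent_sigma^2))
}

#' Generate a noisy synthetic trajectory
#'
#' `n_frames` copies of the base frame receive i.i.d. per-atom Gaussian
#' displacements (`noise_sigma`); deterministic under the configured seed.
#' Optional linear schedules support melting/tilting experiments:
#' `schedule = list(noise_sigma_end = ...)` ramps the noise linearly
#' across frames, `list(tilt_end = ...)` rebuilds the base frame with a
#' linearly interpolated tilt.
#'
#' @param cfg an `mm_syncfg`.
#' @param schedule optional list with `noise_sigma_end` and/or `tilt_end`.
#' @return list with `traj` (`mm_traj`), `topo`, `truth`.
#' @export
generate_trajectory <- function(cfg, schedule = NULL) {
  stopifnot(inherits(cfg, "mm_syncfg"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  nf <- cfg$n_frames
  sigmas <- rep(cfg$noise_sigma, nf)
  if (!is.null(schedule$noise_sigma_end) && nf > 1L)
    sigmas <- seq(cfg$noise_sigma, schedule$noise_sigma_end, length.out = nf)
  tilts <- rep(cfg$tilt_deg, nf)
  if (!is.null(schedule$tilt_end) && nf > 1L)
    tilts <- seq(cfg$tilt_deg, schedule$tilt_end, length.out = nf)
  retilt <- !is.null(schedule$tilt_end) && nf > 1L
  base <- build_dimer_frame(cfg)
  na <- nrow(base$frame$atoms)
  xyz <- array(NA_real_, c(na, 3L, nf))
  for (k in seq_len(nf)) {
    fr_xyz <- if (retilt) {
      cfg_k <- cfg; cfg_k$tilt_deg <- tilts[k]
      build_dimer_frame(cfg_k)$frame$xyz
    } else base$frame$xyz
    noise <- if (sigmas[k] > 0)
      matrix(rnorm(na * 3L, sd = sigmas[k]), na, 3L) else 0
    xyz[, , k] <- fr_xyz + noise
  }
  traj <- mm_trajectory(base$frame$atoms, xyz, base$frame$box,
                        time = (seq_len(nf) - 1) * cfg$time_step)
  list(traj = traj, topo = base$topo, truth = base$truth)
}

#' Generate a synthetic fluorescence assay table
#'
#' Emulates a plate assay with construct-level effect sizes and
#' multiplicative (lognormal) noise: each record's raw signal is
#' `effect * normalizer * lognormal(-s^2/2, s)` with
#' `s = sqrt(log(1 + cv^2))`, so the noise multiplier has mean exactly 1;
#' the normalizer (OD600- or luciferase-like) is itself lognormal around
#' `normalizer_mean`.  With `cv = 0` the normalized signal equals the
#' configured effect exactly.
#'
#' @param design data.frame with columns `construct_n`, `construct_c`,
#'   `effect` (> 0): one row per construct pair.
#' @param n_replicates replicates per pair (default 6).
#' @param cv coefficient of variation of the multiplicative noise, in
#'   `[0, 1)`.
#' @param normalizer_mean central value of the normalizer signal.
#' @param normalizer_cv coefficient of variation of the normalizer.
#' @param batch batch id assigned to all records (default 1).
#' @param seed RNG seed.
#' @return data.frame (`construct_n`, `construct_c`, `replicate`, `batch`,
#'   `raw_fluorescence`, `normalizer`), long format.
#' @export
generate_assay_table <- function(design, n_replicates = 6L, cv = 0.1,
                                 normalizer_mean = 0.5,
                                 normalizer_cv = 0.2, batch = 1L,
                                 seed = 1L) {
  stopifnot(all(c("construct_n", "construct_c", "effect") %in%
                  names(design)),
            all(design$effect > 0), cv >= 0, cv < 1)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  s <- sqrt(log(1 + cv^2))
  sn <- sqrt(log(1 + normalizer_cv^2))
  rows <- list()
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(n_replicates)) {
      normalizer <- rlnorm(1, meanlog = log(normalizer_mean) - sn^2 / 2,
                           sdlog = sn)
      noise <- if (cv > 0) rlnorm(1, meanlog = -s^2 / 2, sdlog = s) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        construct_n = design$construct_n[i],
        construct_c = design$construct_c[i],
        replicate = r, batch = batch,
        raw_fluorescence = design$effect[i] * normalizer * noise,
        normalizer = normalizer, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
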