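# Core containers: atoms table, single frames, multi-frame trajectories.
# Unit convention: Angstrom everywhere, z is the membrane normal.

.MM_ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, NA_ = 22.990, CL = 35.45
)

#' Atomic mass lookup
#'
#' Masses come from a built-in element table; an unknown element symbol falls
#' back to the mass of carbon (12.011) with a warning, so that analyses that
#' only need relative center-of-mass weights keep working on exotic marker
#' atoms.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in atomic mass units.
#' @export
#' @examples
#' element_mass(c("C", "P", "H"))
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .MM_ELEMENT_MASS[key]
  bad <- is.na(m)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(element[bad]), collapse = ", "),
            "; using mass 12.011")
    m[bad] <- 12.011
  }
  unname(m)
}

#' Guess an element symbol from an atom name
#'
#' Strips digits/primes and takes the leading alphabetic character(s),
#' following the PDB convention that atom names open with the element.
#' Two-letter elements present in the built-in table (e.g. \code{CL}) are
#' recognised; anything else maps to its first letter.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(stripped, 1, 2)
  out <- substr(stripped, 1, 1)
  known2 <- two %in% c("CL", "NA")
  out[known2] <- two[known2]
  out
}

.fnv1a <- function(txt) {
  # 32-bit FNV-1a over the raw bytes, returned as 8 hex digits.  Used for
  # topology identity only, not security.  Arithmetic is done in doubles,
  # with the modular multiply split into 16-bit halves to stay exact.
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

topology_signature <- function(atoms) {
  .fnv1a(paste(atoms$name, atoms$element, atoms$resid, atoms$resname,
               atoms$chain, sep = "|"))
}

#' Build an atoms metadata table
#'
#' @param name atom names.
#' @param resid 0-based residue index within each chain.
#' @param resname 3-letter residue codes.
#' @param chain single-character chain labels.
#' @param element element symbols; guessed from \code{name} when omitted.
#' @param mass atomic masses; looked up from \code{element} when omitted.
#' @return data.frame with columns name, element, resid, resname, chain, mass.
#' @export
atom_table <- function(name, resid, resname, chain, element = NULL,
                       mass = NULL) {
  if (is.null(element)) element <- guess_element(name)
  if (is.null(mass)) mass <- element_mass(element)
  stopifnot(all(mass > 0), all(nzchar(chain)))
  data.frame(name = as.character(name), element = as.character(element),
             resid = as.integer(resid), resname = as.character(resname),
             chain = as.character(chain), mass = as.numeric(mass),
             stringsAsFactors = FALSE)
}

#' Construct a trajectory
#'
#' A trajectory couples one atoms table with a stack of coordinate frames.
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom;
#' each frame carries a periodic box (x, y, z lengths, Angstrom) and a time
#' stamp in ps.
#'
#' @param atoms atoms table from [atom_table()].
#' @param xyz coordinate array `n_atoms x 3 x n_frames` (a plain
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @param box numeric length-3 vector, or `n_frames x 3` matrix.
#' @param time frame times in ps.
#' @return object of class `mm_traj`.
#' @export
mm_trajectory <- function(atoms, xyz, box, time = NULL) {
  if (length(dim(xyz)) == 2L) xyz <- array(xyz, c(nrow(xyz), 3L, 1L))
  nf <- dim(xyz)[3]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (is.null(time)) time <- seq_len(nf) - 1
  traj <- structure(list(atoms = atoms, xyz = xyz, box = box,
                         time = as.numeric(time),
                         topology_hash = topology_signature(atoms)),
                    class = "mm_traj")
  validate_trajectory(traj)
  traj
}

#' @export
print.mm_traj <- function(x, ...) {
  cat(sprintf("<mm_traj> %d atoms, %d frame(s), chains: %s\n",
              nrow(x$atoms), n_frames(x),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "mm_traj"))
  na <- nrow(traj$atoms); nf <- dim(traj$xyz)[3]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (dim(traj$xyz)[1] != na || dim(traj$xyz)[2] != 3L)
    stop("coordinate array does not match the atoms table")
  if (!all(is.finite(traj$xyz))) stop("non-finite coordinates")
  if (nrow(traj$box) != nf) stop("box does not match frame count")
  if (!all(traj$box > 0)) stop("box lengths must be positive")
  invisible(traj)
}

#' Number of frames / atoms
#' @param traj an `mm_traj`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Extract one frame
#'
#' @param traj an `mm_traj`.
#' @param i frame number (1-based).
#' @return object of class `mm_frame`: list(atoms, xyz matrix, box, time).
#' @export
get_frame <- function(traj, i = 1L) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure(list(atoms = traj$atoms, xyz = traj$xyz[, , i, drop = TRUE],
                 box = traj$box[i, ], time = traj$time[i]),
            class = "mm_frame")
}

#' @export
print.mm_frame <- function(x, ...) {
  cat(sprintf("<mm_frame> %d atoms, t = %g ps\n", nrow(x$atoms), x$time))
  invisible(x)
}

#' Promote a frame to a one-frame trajectory
#' @param frame an `mm_frame`.
#' @return an `mm_traj` with a single frame.
#' @export
frame_to_trajectory <- function(frame) {
  mm_trajectory(frame$atoms, frame$xyz, frame$box, frame$time)
}

as_frame <- function(x) {
  if (inherits(x, "mm_frame")) return(x)
  if (inherits(x, "mm_traj")) return(get_frame(x, 1L))
  stop("expected an mm_frame or mm_traj")
}

#' Subset frames of a trajectory
#' @param traj an `mm_traj`.
#' @param idx frame indices to keep (1-based).
#' @return an `mm_traj`.
#' @export
subset_frames <- function(traj, idx) {
  mm_trajectory(traj$atoms, traj$xyz[, , idx, drop = FALSE],
                traj$box[idx, , drop = FALSE], traj$time[idx])
}

#' Drop an initial fraction of frames
#'
#' Analyses of equilibrium properties conventionally discard the first part
#' of a trajectory; the default keeps the last half, mirroring averaging over
#' the final 500 ns of a 1 us run.
#'
#' @param traj an `mm_traj`.
#' @param discard_fraction fraction in `[0, 1)` of leading frames to drop.
#' @return an `mm_traj`.
#' @export
discard_initial <- function(traj, discard_fraction = 0.5) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  nf <- n_frames(traj)
  first <- min(nf, floor(nf * discard_fraction) + 1L)
  subset_frames(traj, first:nf)
}
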