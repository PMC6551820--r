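# Structure file I/O: fixed-column PDB (wwPDB v3.3 dialect, MODEL/ENDMDL
# multi-frame) and GROMACS GRO (nm, fixed width, optionally multi-block).
# Everything is converted to Angstrom on the way in.

#' Read a structure or multi-frame coordinate file
#'
#' PDB files with `MODEL`/`ENDMDL` records yield one frame per model;
#' concatenated GRO blocks likewise.  GRO coordinates (nm) are multiplied by
#' 10 so that all internal lengths are in Angstrom.  GRO carries no chain
#' labels: atoms are assigned chain `"A"` unless `chain_map` is given.
#'
#' @param path file path.
#' @param format `"pdb"`, `"gro"`, or `"auto"` (resolve from the extension).
#' @param chain_map optional named list mapping chain labels to 0-based
#'   *molecule* residue ranges, e.g. `list(A = c(0, 22), B = c(23, 45))`,
#'   applied to the sequential residue numbering of a GRO file.
#' @return an [mm_trajectory()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           chain_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", gro = "gro",
                     stop("cannot resolve format from extension '.", ext, "'"))
  }
  switch(format,
         pdb = read_pdb(path),
         gro = read_gro(path, chain_map = chain_map))
}

#' Write a trajectory to PDB or GRO
#'
#' PDB coordinates are written with 3 decimals (0.001 Angstrom); GRO with 3
#' decimals in nm (0.01 Angstrom).  Multi-frame trajectories become
#' `MODEL`/`ENDMDL` blocks (PDB) or concatenated blocks (GRO).
#'
#' @param traj an `mm_traj`.
#' @param path output path.
#' @param format `"pdb"` or `"gro"` (default: from the extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path, format = c("auto", "pdb", "gro")) {
  validate_trajectory(traj)
  if (n_frames(traj) < 1L) stop("no frames")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot resolve format from extension '.", ext, "'"))
  }
  switch(format, pdb = write_pdb(traj, path), gro = write_gro(traj, path))
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  box <- c(100, 100, 100)
  cry <- which(startsWith(lines, "CRYST1"))
  if (length(cry) > 0) {
    box <- .parse_cryst1(lines[cry[1]], cry[1])
  }
  # split atom lines into models
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("no ATOM records in ", path)
  groups <- split(atom_idx, model_id[atom_idx])
  n_per <- vapply(groups, length, 1L)
  if (length(unique(n_per)) != 1L)
    stop("inconsistent atom count across models: ",
         paste(unique(n_per), collapse = ", "))
  first <- groups[[1]]
  meta <- .parse_pdb_atoms(lines[first], first)
  coords <- lapply(groups, function(ix) .parse_pdb_xyz(lines[ix], ix))
  nf <- length(coords)
  xyz <- array(NA_real_, c(length(first), 3L, nf))
  for (k in seq_len(nf)) xyz[, , k] <- coords[[k]]
  mm_trajectory(meta, xyz, box, time = seq_len(nf) - 1)
}

.parse_cryst1 <- function(line, lineno) {
  a <- suppressWarnings(as.numeric(substr(line, 7, 15)))
  b <- suppressWarnings(as.numeric(substr(line, 16, 24)))
  c_ <- suppressWarnings(as.numeric(substr(line, 25, 33)))
  if (any(is.na(c(a, b, c_))))
    stop("malformed CRYST1 record at line ", lineno)
  c(a, b, c_)
}

.parse_pdb_atoms <- function(lines, linenos) {
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resseq <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  element <- trimws(substr(lines, 77, 78))
  if (any(is.na(resseq)))
    stop("malformed residue number at line ", linenos[which(is.na(resseq))[1]])
  chain[chain == " "] <- "A"
  element[!nzchar(element)] <- guess_element(name[!nzchar(element)])
  # renumber residues 0-based within each chain, in order of appearance
  resid <- .renumber_residues(chain, resseq)
  atom_table(name, resid, resname, chain, element)
}

.renumber_residues <- function(chain, resseq) {
  key <- paste(chain, resseq, sep = "/")
  resid <- integer(length(key))
  for (ch in unique(chain)) {
    sel <- chain == ch
    kk <- key[sel]
    resid[sel] <- match(kk, unique(kk)) - 1L
  }
  resid
}

.parse_pdb_xyz <- function(lines, linenos) {
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("malformed coordinate field at line ", linenos[bad[1]])
  cbind(x, y, z)
}

write_pdb <- function(traj, path) {
  at <- traj$atoms
  nf <- n_frames(traj)
  serial <- seq_len(nrow(at))
  if (max(serial) > 99999L) stop("PDB writer supports at most 99999 atoms")
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$box[1, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  substr(at$name, 1, 4))
  for (k in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- traj$xyz[, , k]
    recs <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name4, substr(at$resname, 1, 3), substr(at$chain, 1, 1),
      at$resid + 1L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(at$element, 1, 2))
    writeLines(recs, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- GRO ------------------------------------------------------------------

read_gro <- function(path, chain_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  meta <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat)) stop("malformed atom count at line ", pos + 1L)
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    box_line <- lines[pos + 2L + nat]
    parsed <- .parse_gro_atoms(atom_lines, pos + 2L)
    if (is.null(meta)) {
      meta <- parsed$meta
    } else if (nrow(meta) != nat) {
      stop("inconsistent atom count across GRO blocks")
    }
    bx <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
    if (length(bx) < 3 || any(is.na(bx[1:3])))
      stop("malformed box line at line ", pos + 2L + nat)
    frames[[length(frames) + 1L]] <- list(xyz = parsed$xyz, box = bx[1:3] * 10)
    pos <- pos + 3L + nat
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (length(frames) == 0L) stop("no frames in ", path)
  resid <- meta$resid
  chain <- rep("A", nrow(meta))
  if (!is.null(chain_map)) {
    for (ch in names(chain_map)) {
      rng <- chain_map[[ch]]
      chain[resid >= rng[1] & resid <= rng[2]] <- ch
    }
  }
  atoms <- atom_table(meta$name, resid, meta$resname, chain)
  atoms$resid <- .renumber_residues(atoms$chain, resid)
  nf <- length(frames)
  xyz <- array(NA_real_, c(nrow(atoms), 3L, nf))
  box <- matrix(NA_real_, nf, 3)
  for (k in seq_len(nf)) {
    xyz[, , k] <- frames[[k]]$xyz
    box[k, ] <- frames[[k]]$box
  }
  mm_trajectory(atoms, xyz, box, time = seq_len(nf) - 1)
}

.parse_gro_atoms <- function(lines, first_lineno) {
  resnum <- suppressWarnings(as.integer(substr(lines, 1, 5)))
  resname <- trimws(substr(lines, 6, 10))
  name <- trimws(substr(lines, 11, 15))
  x <- suppressWarnings(as.numeric(substr(lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(lines, 37, 44)))
  bad <- which(is.na(resnum) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("malformed GRO atom record at line ", first_lineno + bad[1] - 1L)
  # sequential 0-based residue numbering (GRO residue numbers may wrap)
  resid <- cumsum(c(0L, diff(resnum) != 0L))
  list(meta = data.frame(name = name, resname = resname, resid = resid,
                         stringsAsFactors = FALSE),
       xyz = cbind(x, y, z) * 10)
}

write_gro <- function(traj, path) {
  at <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  # GRO residue numbers: sequential over chains, 1-based
  gid <- .global_residue_index(at) + 1L
  serial <- ((seq_len(nrow(at)) - 1L) %% 99999L) + 1L
  for (k in seq_len(nf)) {
    writeLines(sprintf("memmatch frame t=%g", traj$time[k]), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    xyz <- traj$xyz[, , k] / 10
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       gid %% 100000L, substr(at$resname, 1, 5),
                       substr(at$name, 1, 5), serial,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    b <- traj$box[k, ] / 10
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
  }
  invisible(path)
}

.global_residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, sep = "/")
  match(key, unique(key)) - 1L
}
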