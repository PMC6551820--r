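# Alpha-helicity assignment via the Kabsch-Sander electrostatic
# hydrogen-bond model.  Only the alpha class (H) is assigned: a backbone
# i->i+4 hydrogen bond (energy below -0.5 kcal/mol) defines a 4-turn at i,
# and two consecutive 4-turns (at i-1 and i) make residues i..i+3 helical.
# 3-10 and pi helices collapse into "other".

.KS_Q <- 0.084 * 332  # coupling constant, kcal/mol * Angstrom

.backbone_index <- function(frame, chain) {
  at <- frame$atoms
  sel <- at$chain == chain
  resids <- sort(unique(at$resid[sel]))
  pick <- function(nm) {
    idx <- integer(length(resids))
    for (j in seq_along(resids)) {
      hit <- which(sel & at$resid == resids[j] & at$name == nm)
      idx[j] <- if (length(hit) > 0) hit[1] else NA_integer_
    }
    idx
  }
  list(resids = resids, N = pick("N"), CA = pick("CA"), C = pick("C"),
       O = pick("O"), H = pick("H"))
}

#' Place amide hydrogens on backbone nitrogens
#'
#' For every non-N-terminal residue lacking an explicit `H`, the amide
#' hydrogen is placed 1.01 Angstrom from N along the unit bisector opposing
#' the C(prev)->N and CA->N directions (i.e. along the normalized sum of the
#' unit vectors from C(prev) to N and from CA to N).  Existing hydrogens are
#' left untouched.
#'
#' @param frame an `mm_frame`.
#' @param chains chain labels to process (default: all chains that have a
#'   complete N, CA, C, O backbone).
#' @return a new `mm_frame` including the placed `H` atoms.
#' @export
place_amide_hydrogens <- function(frame, chains = NULL) {
  frame <- as_frame(frame)
  at <- frame$atoms
  if (is.null(chains)) {
    chains <- unique(at$chain[at$name == "CA"])
  }
  new_atoms <- list(); new_xyz <- list()
  for (ch in chains) {
    bb <- .backbone_index(frame, ch)
    need <- c("N", "CA", "C", "O")
    for (nm in need) {
      miss <- which(is.na(bb[[nm]]))
      if (length(miss) > 0)
        stop("chain ", ch, " residue ", bb$resids[miss[1]],
             ": missing backbone atom ", nm)
    }
    nres <- length(bb$resids)
    if (nres < 2L) next
    for (j in 2:nres) {
      if (!is.na(bb$H[j])) next  # explicit hydrogen: keep
      is_pro <- at$resname[bb$CA[j]] %in% c("PRO", "P")
      if (is_pro) next           # proline never donates
      N <- frame$xyz[bb$N[j], ]
      u1 <- N - frame$xyz[bb$C[j - 1], ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- N - frame$xyz[bb$CA[j], ];    u2 <- u2 / sqrt(sum(u2^2))
      u <- u1 + u2; u <- u / sqrt(sum(u^2))
      new_atoms[[length(new_atoms) + 1L]] <-
        data.frame(name = "H", element = "H", resid = bb$resids[j],
                   resname = at$resname[bb$CA[j]], chain = ch,
                   mass = element_mass("H"), stringsAsFactors = FALSE)
      new_xyz[[length(new_xyz) + 1L]] <- N + 1.01 * u
    }
  }
  if (length(new_atoms) == 0L) return(frame)
  atoms2 <- rbind(at, do.call(rbind, new_atoms))
  xyz2 <- rbind(frame$xyz, do.call(rbind, new_xyz))
  structure(list(atoms = atoms2, xyz = xyz2, box = frame$box,
                 time = frame$time), class = "mm_frame")
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a putative backbone hydrogen bond from the amide
#' group (N-H) of the donor residue to the carbonyl group (C=O) of the
#' acceptor:
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A bond is called when `E < -0.5` kcal/mol.
#'
#' @param donor list with numeric positions `N` and `H` (Angstrom).
#' @param acceptor list with numeric positions `C` and `O` (Angstrom).
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(donor, acceptor) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  r_on <- d(acceptor$O, donor$N); r_ch <- d(acceptor$C, donor$H)
  r_oh <- d(acceptor$O, donor$H); r_cn <- d(acceptor$C, donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5)
    stop("atom clash: inter-atomic distance below 0.5 Angstrom")
  .KS_Q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

.KS_CUTOFF <- -0.5

#' Assign alpha-helix residues in one chain
#'
#' Hydrogens are placed first (if absent).  For every residue pair (i, i+4)
#' the Kabsch-Sander energy of the bond O(i) <- H-N(i+4) is evaluated; a
#' 4-turn at i requires energy below -0.5 kcal/mol.  Two consecutive
#' 4-turns (i-1 and i) label residues i..i+3 as `H`; all other residues are
#' `"-"`.  Terminal residues lacking an i+4 partner can never seed a helix.
#'
#' @param frame an `mm_frame`.
#' @param chain chain label.
#' @return character vector (one element per residue of the chain, in
#'   residue order) with values `"H"` or `"-"`.
#' @export
assign_alpha <- function(frame, chain) {
  frame <- as_frame(frame)
  if (!chain %in% frame$atoms$chain) stop("chain ", chain, " absent")
  frame <- place_amide_hydrogens(frame, chain)
  bb <- .backbone_index(frame, chain)
  nres <- length(bb$resids)
  ss <- rep("-", nres)
  if (nres < 5L) return(ss)
  turn4 <- rep(FALSE, nres)
  for (i in seq_len(nres - 4L)) {
    j <- i + 4L
    if (is.na(bb$H[j])) next  # proline or N-terminus: no donor
    # clashing (< 0.5 A) geometries are unphysical contacts, not H-bonds
    e <- tryCatch(
      hbond_energy(donor = list(N = frame$xyz[bb$N[j], ],
                                H = frame$xyz[bb$H[j], ]),
                   acceptor = list(C = frame$xyz[bb$C[i], ],
                                   O = frame$xyz[bb$O[i], ])),
      error = function(cond) 0)
    turn4[i] <- e < .KS_CUTOFF
  }
  for (i in 2:max(2L, nres - 4L)) {
    if (turn4[i - 1L] && turn4[i]) ss[i:(i + 3L)] <- "H"
  }
  ss
}

#' Helicity series over a trajectory
#'
#' Per-chain, per-frame fraction of residues assigned alpha-helix; reported
#' separately for the two chains so that hetero-dimers with unlike peptide
#' lengths remain comparable.
#'
#' @param traj an `mm_traj`.
#' @param topo an `mm_topology` naming the two chains.
#' @return list with `fraction`: data.frame (`frame`, `time_ps`, `chain`,
#'   `helicity`), and `assignment`: list of per-frame named character
#'   vectors of residue classes per chain.
#' @export
helicity_series <- function(traj, topo) {
  validate_trajectory(traj)
  chains <- c(topo$chain_a, topo$chain_b)
  nf <- n_frames(traj)
  rows <- list(); assigns <- vector("list", nf)
  for (k in seq_len(nf)) {
    fr <- get_frame(traj, k)
    per_chain <- lapply(chains, function(ch) assign_alpha(fr, ch))
    names(per_chain) <- chains
    assigns[[k]] <- per_chain
    for (ch in chains) {
      ss <- per_chain[[ch]]
      rows[[length(rows) + 1L]] <-
        data.frame(frame = k, time_ps = traj$time[k], chain = ch,
                   helicity = mean(ss == "H"), stringsAsFactors = FALSE)
    }
  }
  list(fraction = do.call(rbind, rows), assignment = assigns)
}
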