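# Independent oracles used by the test suite.  These deliberately avoid the
# package's own code paths: superposition via Horn's quaternion method,
# DSSP via an all-pairs brute force, BH via direct enumeration.

# Horn quaternion-method superposition RMSD (oracle for kabsch_superpose).
quaternion_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  X <- sweep(mobile, 2, colSums(mobile * w))
  Y <- sweep(reference, 2, colSums(reference * w))
  S <- t(X * w) %*% Y
  Sxx <- S[1,1]; Sxy <- S[1,2]; Sxz <- S[1,3]
  Syx <- S[2,1]; Syy <- S[2,2]; Syz <- S[2,3]
  Szx <- S[3,1]; Szy <- S[3,2]; Szz <- S[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- sum(w * rowSums(X^2)) + sum(w * rowSums(Y^2)) - 2 * lam
  sqrt(max(0, msd))
}

# Brute-force Kabsch-Sander alpha assignment for one chain of a frame:
# evaluates every ordered donor/acceptor pair (|i - j| >= 2), calls bonds at
# E < -0.5 kcal/mol, marks 4-turns, and closes runs of two consecutive
# 4-turns into H labels.  Hydrogens must already be present (or are placed
# with the package helper, whose own correctness is tested separately).
brute_force_alpha <- function(frame, chain) {
  frame <- memmatch::place_amide_hydrogens(frame, chain)
  at <- frame$atoms
  sel <- at$chain == chain
  resids <- sort(unique(at$resid[sel]))
  nres <- length(resids)
  coord <- function(nm, j) {
    i <- which(sel & at$resid == resids[j] & at$name == nm)
    if (length(i) == 0) return(NULL)
    frame$xyz[i[1], ]
  }
  q <- 0.084 * 332
  bonded <- matrix(FALSE, nres, nres)  # bonded[i, j]: CO of i <- NH of j
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (abs(i - j) < 2) next
      Cp <- coord("C", i); Op <- coord("O", i)
      Np <- coord("N", j); Hp <- coord("H", j)
      if (is.null(Hp)) next
      dists <- c(sqrt(sum((Op-Np)^2)), sqrt(sum((Cp-Hp)^2)),
                 sqrt(sum((Op-Hp)^2)), sqrt(sum((Cp-Np)^2)))
      if (min(dists) < 0.5) next  # clash: not a hydrogen bond
      e <- q * (1/dists[1] + 1/dists[2] - 1/dists[3] - 1/dists[4])
      bonded[i, j] <- e < -0.5
    }
  }
  turn4 <- vapply(seq_len(nres), function(i)
    i + 4 <= nres && bonded[i, i + 4], logical(1))
  ss <- rep("-", nres)
  for (i in seq_len(nres)) {
    if (i >= 2 && turn4[i - 1] && turn4[i]) ss[i:(i + 3)] <- "H"
  }
  ss
}

# Direct-enumeration Benjamini-Hochberg (oracle for bh_adjust): for each
# p in input order, q_i = min over all p_j >= p_i of m * p_(j) / rank(j).
brute_force_bh <- function(p) {
  m <- length(p)
  s <- sort(p)
  q_at_rank <- vapply(seq_len(m), function(i)
    min(1, min(m * s[i:m] / (i:m))), numeric(1))
  vapply(p, function(pi) q_at_rank[match(pi, s)], numeric(1))
}

# Geometric amide-H construction on explicit vectors (oracle for
# place_amide_hydrogens): same definition, independent arithmetic path.
oracle_amide_h <- function(N, C_prev, CA) {
  normed <- function(v) v / sqrt(sum(v * v))
  b <- normed(normed(N - C_prev) + normed(N - CA))
  N + 1.01 * b
}

# A "stick dimer": one CA pseudo-atom per residue placed exactly on a line,
# giving angle metrics with no off-axis COM offsets.  direction_b flips the
# z direction of chain B for antiparallel cases.
stick_dimer_frame <- function(seq = "LLLLLLLGVLLGVLLTLLLLLLL",
                              separation = 7, direction_b = +1) {
  n <- nchar(seq)
  res3 <- c(A="ALA",G="GLY",L="LEU",T="THR",V="VAL")[strsplit(seq, "")[[1]]]
  z <- (seq_len(n) - 1) * 1.5
  mk <- function(chain, x0, dir) {
    list(atoms = memmatch::atom_table(rep("CA", n), 0:(n-1), res3, chain,
                                      element = rep("C", n)),
         xyz = cbind(x0, 0, dir * z))
  }
  a <- mk("A", -separation/2, +1)
  b <- mk("B", +separation/2, direction_b)
  structure(list(atoms = rbind(a$atoms, b$atoms),
                 xyz = rbind(a$xyz, b$xyz),
                 box = c(100, 100, 100), time = 0), class = "mm_frame")
}

rotate_frame <- function(frame, R) {
  frame$xyz <- frame$xyz %*% t(R)
  frame
}

rot_z_deg <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y_deg <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a*a+b*b-c*c-d*d, 2*(b*c+a*d),     2*(b*d-a*c),
           2*(b*c-a*d),     a*a-b*b+c*c-d*d, 2*(c*d+a*b),
           2*(b*d+a*c),     2*(c*d-a*b),     a*a-b*b-c*c+d*d), 3, 3)
}

default_topology <- function() {
  memmatch::dimer_topology("LLLLLLLGVLLGVLLTLLLLLLL")
}
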