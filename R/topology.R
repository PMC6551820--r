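# Dimer topology: the two peptide chains and the GVxxGVxxT motif anchors
# from which every residue selection in the geometry module derives.

.MM_HYDROPHOBIC <- c("A", "V", "L", "I", "F", "M", "G", "T")
.MM_MOTIF_RE <- "GV[AVLIFMGT]{2}GV[AVLIFMGT]{2}T"

#' Locate the GVxxGVxxT dimerization motif in a sequence
#'
#' `x` positions accept any residue from the hydrophobic set
#' A, V, L, I, F, M, G, T.
#'
#' @param sequence 1-letter residue string.
#' @return 0-based index of the motif-opening glycine, or `NA` if absent
#'   (first match wins).
#' @export
find_motif <- function(sequence) {
  m <- regexpr(.MM_MOTIF_RE, sequence)
  if (m[1] == -1L) return(NA_integer_)
  as.integer(m[1]) - 1L
}

#' Define a two-chain dimer topology
#'
#' Anchors all residue selections on the 9-residue GVxxGVxxT motif of each
#' chain.  The motif must sit far enough from the termini that three
#' flanking residues exist on both sides (plus margin): `motif_start >= 4`
#' and `motif_start + 8 <= length - 5`.
#'
#' @param sequence_a,sequence_b 1-letter residue strings for chains A and B.
#' @param motif_start_a,motif_start_b 0-based index of the motif-opening G;
#'   located automatically with [find_motif()] when `NULL`.
#' @param chain_a,chain_b chain labels in the coordinate files.
#' @return object of class `mm_topology`.
#' @export
dimer_topology <- function(sequence_a, sequence_b = sequence_a,
                           motif_start_a = NULL, motif_start_b = NULL,
                           chain_a = "A", chain_b = "B") {
  if (is.null(motif_start_a)) motif_start_a <- find_motif(sequence_a)
  if (is.null(motif_start_b)) motif_start_b <- find_motif(sequence_b)
  .check_motif(sequence_a, motif_start_a, "A")
  .check_motif(sequence_b, motif_start_b, "B")
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 sequence_a = sequence_a, sequence_b = sequence_b,
                 motif_start_a = as.integer(motif_start_a),
                 motif_start_b = as.integer(motif_start_b)),
            class = "mm_topology")
}

.check_motif <- function(sequence, motif_start, label) {
  if (is.na(motif_start))
    stop("chain ", label, ": no GVxxGVxxT motif found")
  n <- nchar(sequence)
  span <- substr(sequence, motif_start + 1L, motif_start + 9L)
  if (!grepl(paste0("^", .MM_MOTIF_RE, "$"), span))
    stop("chain ", label, ": residues ", motif_start, "..", motif_start + 8,
         " ('", span, "') do not match GVxxGVxxT")
  if (motif_start < 4L || motif_start + 8L > n - 5L)
    stop("chain ", label, ": motif too close to a terminus (start ",
         motif_start, ", length ", n, ")")
  invisible(TRUE)
}

#' @export
print.mm_topology <- function(x, ...) {
  cat(sprintf("<mm_topology> %s (%d aa, motif @%d) / %s (%d aa, motif @%d)\n",
              x$chain_a, nchar(x$sequence_a), x$motif_start_a,
              x$chain_b, nchar(x$sequence_b), x$motif_start_b))
  invisible(x)
}

#' Residue selections flanking the dimerization motif
#'
#' `"above"` gives the three residues C-terminal to the motif end (towards
#' higher residue index), `"below"` the three residues N-terminal to the
#' motif start, and `"adjacent"` the single residues immediately before and
#' after the motif — the anchor points of the crossing-angle vectors.
#'
#' @param topo an `mm_topology`.
#' @param side `"above"`, `"below"`, or `"adjacent"`.
#' @return list with components `a` and `b`: 0-based residue indices per
#'   chain.
#' @export
#' @examples
#' topo <- dimer_topology(strrep("L", 7) %+% "GVLLGVLLT" %+% strrep("L", 7))
#' motif_flank_selection(topo, "above")
motif_flank_selection <- function(topo, side = c("above", "below",
                                                 "adjacent")) {
  side <- match.arg(side)
  one <- function(start, len) {
    stop_ <- start + 8L
    idx <- switch(side,
                  above = (stop_ + 1L):(stop_ + 3L),
                  below = (start - 3L):(start - 1L),
                  adjacent = c(start - 1L, stop_ + 1L))
    if (min(idx) < 0L || max(idx) > len - 1L)
      stop("fewer than 3 flanking residues on side '", side, "'")
    idx
  }
  list(a = one(topo$motif_start_a, nchar(topo$sequence_a)),
       b = one(topo$motif_start_b, nchar(topo$sequence_b)))
}

#' Paste operator for sequences
#' @param a,b character scalars.
#' @return `paste0(a, b)`.
#' @export
#' @name grapes-plus-grapes
`%+%` <- function(a, b) paste0(a, b)

#' Conserved motif residue indices (G, V, G, V, T)
#'
#' The five strictly conserved positions of the GVxxGVxxT motif; offsets
#' 0, 1, 4, 5, 8 from the motif start.  These define the "motif5" RMSD
#' selection (5 residues per peptide).
#'
#' @param topo an `mm_topology`.
#' @return list with components `a` and `b` (0-based residue indices).
#' @export
motif_conserved_residues <- function(topo) {
  off <- c(0L, 1L, 4L, 5L, 8L)
  list(a = topo$motif_start_a + off, b = topo$motif_start_b + off)
}
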