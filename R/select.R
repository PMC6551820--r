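# Minimal atom-selection language over the atoms table.
#
# Grammar:  expr  := term { "and" term }
#           term  := "chain"   <label>[,<label>...]
#                  | "name"    <name>[,<name>...]
#                  | "resname" <code>[,<code>...]
#                  | "resid"   <i> | <i>:<j>   (0-based, inclusive)
#                  | "backbone"                 (name in N, CA, C, O)
#                  | "all"
# Terms are conjoined; results are returned in file order.

#' Select atoms by query
#'
#' @param x an `mm_frame` or `mm_traj`.
#' @param query selection string, e.g. `"chain A and name CA"`,
#'   `"name P"`, `"resid 4:6 and backbone"`, `"name C22,C32"`.
#' @return integer vector of atom indices (1-based, file order); may be
#'   empty.
#' @export
#' @examples
#' \dontrun{
#' select_atoms(frame, "chain A and name CA")
#' }
select_atoms <- function(x, query) {
  atoms <- if (inherits(x, "mm_traj") || inherits(x, "mm_frame")) x$atoms
           else stop("expected an mm_frame or mm_traj")
  toks <- strsplit(trimws(query), "\\s+")[[1]]
  if (length(toks) == 0L || !nzchar(toks[1]))
    stop("selection syntax error: empty query")
  keep <- rep(TRUE, nrow(atoms))
  i <- 1L
  expect_term <- TRUE
  while (i <= length(toks)) {
    tok <- toks[i]
    if (!expect_term) {
      if (tolower(tok) != "and")
        stop("selection syntax error: expected 'and', got '", tok, "'")
      i <- i + 1L
      expect_term <- TRUE
      next
    }
    key <- tolower(tok)
    if (key %in% c("all", "backbone")) {
      keep <- keep & (if (key == "all") TRUE
                      else atoms$name %in% c("N", "CA", "C", "O"))
      i <- i + 1L
    } else if (key %in% c("chain", "name", "resname", "resid")) {
      if (i + 1L > length(toks))
        stop("selection syntax error: '", key, "' needs an argument")
      arg <- toks[i + 1L]
      keep <- keep & .match_term(atoms, key, arg)
      i <- i + 2L
    } else {
      stop("selection syntax error: unknown keyword '", tok, "'")
    }
    expect_term <- FALSE
  }
  if (expect_term) stop("selection syntax error: dangling 'and'")
  which(keep)
}

.match_term <- function(atoms, key, arg) {
  if (key == "resid") {
    if (!grepl("^-?[0-9]+(:-?[0-9]+)?$", arg))
      stop("selection syntax error: bad resid range '", arg, "'")
    parts <- as.integer(strsplit(arg, ":")[[1]])
    lo <- parts[1]; hi <- if (length(parts) > 1) parts[2] else parts[1]
    return(atoms$resid >= lo & atoms$resid <= hi)
  }
  vals <- strsplit(arg, ",")[[1]]
  col <- switch(key, chain = atoms$chain, name = atoms$name,
                resname = atoms$resname)
  col %in% vals
}
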