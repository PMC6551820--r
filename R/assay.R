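# Dimerization-assay statistics: per-record normalization, relative
# fluorescence against a positive control, merged-homodimer fold change for
# hetero-pairs with Student's t significance, Benjamini-Hochberg FDR
# adjustment, and the three-way dimer/reduced/background classification.

.check_assay_table <- function(table) {
  need <- c("construct_n", "construct_c", "replicate", "batch",
            "raw_fluorescence", "normalizer")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("assay table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$raw_fluorescence <= 0))
    stop("raw fluorescence must be positive (record ",
         which(table$raw_fluorescence <= 0)[1], ")")
  key <- paste(table$construct_n, table$construct_c, table$replicate,
               table$batch)
  if (anyDuplicated(key))
    stop("duplicate (construct_n, construct_c, replicate, batch) record")
  invisible(table)
}

#' Normalize raw fluorescence by the per-record normalizer signal
#'
#' Divides each raw fluorescence reading by its normalizer (culture OD600
#' in bacterial reporter assays, co-transfected luciferase counts in
#' BiFC-style assays), record by record.
#'
#' @param table assay data.frame with columns `construct_n`,
#'   `construct_c`, `replicate`, `batch`, `raw_fluorescence`, `normalizer`.
#' @return the table with an added `normalized` column.
#' @export
normalize_assay <- function(table) {
  .check_assay_table(table)
  if (any(table$normalizer <= 0))
    stop("normalizer must be positive (record ",
         which(table$normalizer <= 0)[1], ")")
  table$normalized <- table$raw_fluorescence / table$normalizer
  table
}

.pair_rows <- function(table, pair) {
  table$construct_n == pair[1] & table$construct_c == pair[2]
}

#' Relative fluorescence versus the positive control
#'
#' Scales normalized values by the mean normalized signal of the positive
#' control pair (optionally batch-matched), so that the control averages
#' exactly 1.
#'
#' @param table output of [normalize_assay()].
#' @param positive_control length-2 character vector
#'   `(construct_n, construct_c)` naming the control pair.
#' @param batchwise match controls within each batch (default FALSE).
#' @return the table with an added `relative` column.
#' @export
relative_to_control <- function(table, positive_control,
                                batchwise = FALSE) {
  if (is.null(table$normalized)) table <- normalize_assay(table)
  ctrl <- .pair_rows(table, positive_control)
  if (!any(ctrl))
    stop("positive control pair ", paste(positive_control, collapse = "/"),
         " absent from the table")
  if (batchwise) {
    batches <- unique(table$batch)
    missing <- batches[!batches %in% unique(table$batch[ctrl])]
    if (length(missing) > 0)
      stop("positive control missing in batch(es): ",
           paste(missing, collapse = ", "))
    ref <- tapply(table$normalized[ctrl], table$batch[ctrl], mean)
    table$relative <- table$normalized / as.numeric(ref[as.character(table$batch)])
  } else {
    table$relative <- table$normalized / mean(table$normalized[ctrl])
  }
  table
}

.safe_t_test <- function(x, y, var_equal = TRUE) {
  # two-sample two-sided Student's t; degenerate zero-variance cases are
  # resolved by the limit (identical means -> p = 1, else p -> 0)
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 replicates per group")
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Fold change of a hetero-pair against its merged homo-dimer reference
#'
#' The reference set concatenates the relative values of the two homo
#' pairs (X/X and Y/Y); the fold change is the hetero mean divided by the
#' reference mean, and the p-value comes from a two-sample two-sided
#' Student's t-test (pooled variance by default, Welch via
#' `var_equal = FALSE`) of the hetero values against the reference set.
#'
#' @param table output of [relative_to_control()] (must carry `relative`).
#' @param pair length-2 character vector `(X, Y)`; hetero records match
#'   either orientation (X/Y or Y/X).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return list: `fold_change`, `p_value`, `hetero_mean`, `reference_mean`,
#'   `n_hetero`, `n_reference`.
#' @export
hetero_fold_change <- function(table, pair, var_equal = TRUE) {
  if (is.null(table$relative))
    stop("table lacks 'relative'; run relative_to_control() first")
  x <- pair[1]; y <- pair[2]
  het <- if (x == y) {
    table$relative[.pair_rows(table, c(x, y))]
  } else {
    table$relative[.pair_rows(table, c(x, y)) | .pair_rows(table, c(y, x))]
  }
  homo_x <- table$relative[.pair_rows(table, c(x, x))]
  homo_y <- table$relative[.pair_rows(table, c(y, y))]
  if (length(homo_x) == 0L) stop("no homo-dimer records for ", x)
  if (length(homo_y) == 0L) stop("no homo-dimer records for ", y)
  if (length(het) == 0L) stop("no hetero records for ", x, "/", y)
  ref <- c(homo_x, homo_y)
  list(fold_change = mean(het) / mean(ref),
       p_value = .safe_t_test(het, ref, var_equal),
       hetero_mean = mean(het), reference_mean = mean(ref),
       n_hetero = length(het), n_reference = length(ref))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order; `q >= p` elementwise.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(ranked))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Classify tested pairs into dimer / reduced / background
#'
#' Decision rule at level `alpha` on BH-adjusted q-values:
#' `dimer` when the pair is significantly above the negative control but
#' not significantly different from its homo-dimer reference
#' (`q_vs_negative < alpha` and `q_vs_homo >= alpha`); `reduced` when it
#' differs significantly from both; `background` when it is
#' indistinguishable from the negative control (`q_vs_negative >= alpha`).
#'
#' @param results data.frame with columns `q_vs_negative` and `q_vs_homo`.
#' @param alpha significance level (default 0.05).
#' @return character vector of calls.
#' @export
classify_pairs <- function(results, alpha = 0.05) {
  if (is.null(results$q_vs_negative) || is.null(results$q_vs_homo))
    stop("results must carry q_vs_negative and q_vs_homo")
  ifelse(results$q_vs_negative >= alpha, "background",
         ifelse(results$q_vs_homo < alpha, "reduced", "dimer"))
}

#' End-to-end hetero-dimerization analysis of an assay table
#'
#' Normalizes, scales to the positive control, and for every unordered
#' hetero pair (X, Y) with homo records for both partners computes the
#' merged-homodimer fold change, a Student's t p-value against the merged
#' homo reference, and one against the negative-control records.  Each
#' comparison type is BH-adjusted across all tested pairs (one family per
#' comparison), and pairs are classified with [classify_pairs()].
#'
#' @param table raw assay data.frame.
#' @param positive_control,negative_control length-2 character vectors
#'   naming the control pairs.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t-tests (default TRUE).
#' @param batchwise batch-matched positive-control scaling.
#' @return data.frame: one row per tested hetero pair with columns
#'   `construct_x`, `construct_y`, `fold_change`, `p_vs_homo`,
#'   `p_vs_negative`, `q_vs_homo`, `q_vs_negative`, `call`.
#' @export
analyze_assay <- function(table, positive_control, negative_control,
                          alpha = 0.05, var_equal = TRUE,
                          batchwise = FALSE) {
  table <- relative_to_control(normalize_assay(table), positive_control,
                               batchwise)
  neg <- table$relative[.pair_rows(table, negative_control)]
  if (length(neg) < 2L)
    stop("negative control pair ", paste(negative_control, collapse = "/"),
         " absent or has fewer than 2 records")
  pairs <- unique(table[, c("construct_n", "construct_c")])
  hetero <- pairs[pairs$construct_n != pairs$construct_c, , drop = FALSE]
  seen <- character(0); rows <- list()
  for (i in seq_len(nrow(hetero))) {
    x <- hetero$construct_n[i]; y <- hetero$construct_c[i]
    key <- paste(sort(c(x, y)), collapse = "/")
    if (key %in% seen) next
    has_x <- any(.pair_rows(table, c(x, x)))
    has_y <- any(.pair_rows(table, c(y, y)))
    if (!has_x || !has_y) next
    seen <- c(seen, key)
    fc <- hetero_fold_change(table, c(x, y), var_equal)
    het <- table$relative[.pair_rows(table, c(x, y)) |
                            .pair_rows(table, c(y, x))]
    rows[[length(rows) + 1L]] <- data.frame(
      construct_x = x, construct_y = y, fold_change = fc$fold_change,
      p_vs_homo = fc$p_value,
      p_vs_negative = .safe_t_test(het, neg, var_equal),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable hetero pairs in the table")
  out <- do.call(rbind, rows)
  out$q_vs_homo <- bh_adjust(out$p_vs_homo)
  out$q_vs_negative <- bh_adjust(out$p_vs_negative)
  out$call <- classify_pairs(out, alpha)
  out
}
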