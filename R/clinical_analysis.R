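#' Median split of a clinical variable
#'
#' Partitions patients at the sample median of `values`; subjects with
#' `value >= threshold` form the high (long-duration / late-onset) group,
#' matching the convention that, e.g., duration >= 5 years is "long" when 5
#' is the median. Missing values are excluded and reported.
#'
#' @param values numeric vector (>= 4 non-missing values).
#' @param ids subject identifiers aligned with `values` (default positions).
#' @param variable label of the split variable (e.g. `"duration"`).
#' @return An object of class `subgroup_split` with `threshold`, `high_ids`,
#'   `low_ids`, `excluded_ids`, `variable`.
#' @export
median_split <- function(values, ids = seq_along(values), variable = "variable") {
  if (length(values) != length(ids)) stopf("values and ids differ in length")
  ok <- !is.na(values)
  if (sum(ok) < 4L) stopf("need >= 4 non-missing values to split")
  v <- values[ok]
  if (max(v) - min(v) < 1e-12)
    stopf("all '%s' values identical; median split impossible", variable)
  thr <- stats::median(v) # even n: mean of the two middle order statistics
  structure(list(variable = variable, threshold = thr,
                 high_ids = ids[ok][v >= thr], low_ids = ids[ok][v < thr],
                 excluded_ids = ids[!ok]),
            class = "subgroup_split")
}

#' @export
print.subgroup_split <- function(x, ...) {
  cat(sprintf("<subgroup_split> %s >= %g: high n=%d, low n=%d, excluded n=%d\n",
              x$variable, x$threshold, length(x$high_ids), length(x$low_ids),
              length(x$excluded_ids)))
  invisible(x)
}

#' Patient subgroup comparison along a median split
#'
#' Runs the identical permutation + FDR machinery used for the main
#' patient-control contrast, with groups given by the split halves (high =
#' case).
#'
#' @param table patients-only `edge_table`.
#' @param split a [median_split()] result over the same subjects.
#' @param config an [inference_config()].
#' @return An `edge_results` data frame (case = high subgroup).
#' @export
subgroup_comparison <- function(table, split, config = inference_config()) {
  tab <- table[table$subject_id %in% c(split$high_ids, split$low_ids), , drop = FALSE]
  grp <- ifelse(tab$subject_id %in% split$high_ids, "high", "low")
  if (min(table(grp)) < 2L) stopf("degenerate subgroup (< 2 subjects)")
  tab$.split <- grp
  attr(tab, "edges") <- attr(table, "edges")
  attr(tab, "network") <- attr(table, "network")
  attr(tab, "stage") <- attr(table, "stage")
  test_edges(tab, config, group_col = ".split", case = "high", ref = "low")
}

spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y)) # average ranks for ties
}

#' Symptom-severity correlation per edge
#'
#' Spearman rank correlation (average-rank ties) between each edge's z
#' values and a symptom score (e.g. BDI), with a two-sided p-value:
#' permutation-based (seeded, `config$n_perm` draws) for n < 30, asymptotic
#' t-approximation otherwise; FDR correction across edges.
#'
#' @param table patients-only `edge_table`.
#' @param scores numeric symptom score per subject (aligned with rows;
#'   no missing values).
#' @param config an [inference_config()].
#' @return Data frame with `edge`, `rho`, `p`, `q`.
#' @export
symptom_correlation <- function(table, scores, config = inference_config()) {
  z <- z_matrix(table)
  n <- nrow(z)
  if (length(scores) != n) stopf("scores length (%d) != subjects (%d)", length(scores), n)
  if (anyNA(scores)) stopf("missing symptom scores; drop those subjects first")
  if (n < 4L) stopf("need >= 4 subjects")
  if (stats::sd(scores) < 1e-12) stopf("constant symptom scores")
  rs <- rank(scores)
  rho <- apply(z, 2L, function(col) stats::cor(rank(col), rs))
  if (n < 30L) {
    R <- with_seed(config$seed,
                   t(replicate(config$n_perm, sample(rs))))
    rz <- apply(z, 2L, rank)
    rz <- scale(rz)
    Rs <- scale(t(R))
    # permuted spearman rho = crossprod of standardized ranks / (n - 1)
    perm_rho <- crossprod(Rs, rz) / (n - 1)
    p <- (1 + colSums(abs(perm_rho) >= rep(abs(rho), each = config$n_perm) - 1e-12)) /
      (config$n_perm + 1)
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  fc <- fdr_correct(pmin(1, p), config$alpha, config$fdr_method)
  data.frame(edge = colnames(z), rho = as.numeric(rho), p = as.numeric(pmin(1, p)),
             q = as.numeric(fc$q), row.names = NULL, stringsAsFactors = FALSE)
}
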