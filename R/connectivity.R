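#' Pearson correlations for every network edge
#'
#' @param ts frames x nodes matrix (columns named by node abbrevs).
#' @param network a [network_model()]; edges are taken in canonical order.
#' @return Named numeric vector of Pearson r, one per edge.
#' @export
edge_correlations <- function(ts, network) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stopf("need at least 3 frames to correlate")
  ab <- node_abbrevs(network)
  if (!all(ab %in% colnames(ts)))
    stopf("series is missing nodes: %s", paste(setdiff(ab, colnames(ts)), collapse = ", "))
  ts <- ts[, ab, drop = FALSE]
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds < 1e-12))
    stopf("zero-variance node series: %s", paste(ab[sds < 1e-12], collapse = ", "))
  cm <- stats::cor(ts)
  stats::setNames(cm[cbind(network$edges$i, network$edges$j)], network$edges$label)
}

#' Fisher z transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform of the Pearson correlation. Degenerate correlations with
#' `|r| >= 1 - 1e-12` raise an error rather than being clamped: an exactly
#' (anti-)duplicated series upstream is a pipeline bug, not data.
#'
#' @param r correlation value(s) in (-1, 1).
#' @return z value(s).
#' @examples
#' fisher_z(0.5) # 0.549306
#' @export
fisher_z <- function(r) {
  r <- as.numeric(r)
  if (anyNA(r)) stopf("NA correlation passed to fisher_z")
  if (any(abs(r) >= 1 - 1e-12))
    stopf("degenerate edge: |r| >= 1 - 1e-12 (r = %s)",
          paste(signif(r[abs(r) >= 1 - 1e-12], 6), collapse = ", "))
  atanh(r)
}

#' Assemble an edge connectivity table
#'
#' One row per subject: metadata columns (`subject_id`, `site`, `diagnosis`)
#' followed by one Fisher-z column per canonical network edge.
#'
#' @param z_rows subjects x edges matrix of Fisher z values (column names
#'   must match the network's edge labels), or a list of named per-subject
#'   vectors.
#' @param meta data frame with columns `subject_id`, `site`, `diagnosis`
#'   (one row per subject, same order).
#' @param network the [network_model()] shared by all subjects.
#' @return A `data.frame` of class `edge_table` with attributes `network`
#'   (name), `edges` (labels) and `stage` (`"raw"`).
#' @export
build_edge_table <- function(z_rows, meta, network) {
  if (is.list(z_rows) && !is.data.frame(z_rows))
    z_rows <- do.call(rbind, z_rows)
  z_rows <- as.matrix(z_rows)
  labs <- network$edges$label
  if (is.null(colnames(z_rows)) || !setequal(colnames(z_rows), labs))
    stopf("edge columns do not match network '%s' edges", network$name)
  z_rows <- z_rows[, labs, drop = FALSE]
  if (!all(is.finite(z_rows))) stopf("non-finite z values in edge table")
  meta <- as.data.frame(meta)
  need <- c("subject_id", "site", "diagnosis")
  if (!all(need %in% names(meta)))
    stopf("meta must have columns %s", paste(need, collapse = ", "))
  if (nrow(meta) != nrow(z_rows))
    stopf("meta has %d rows but z has %d", nrow(meta), nrow(z_rows))
  out <- cbind(meta[need], as.data.frame(z_rows, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, network = network$name, edges = labs, stage = "raw",
            class = c("edge_table", "data.frame"))
}

edge_labels <- function(table) attr(table, "edges")

# subjects x edges numeric matrix from an edge_table
z_matrix <- function(table) {
  as.matrix(table[, edge_labels(table), drop = FALSE])
}

set_z_matrix <- function(table, z) {
  for (lab in edge_labels(table)) table[[lab]] <- as.numeric(z[, lab])
  table
}
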