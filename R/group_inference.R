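#' Inference configuration
#'
#' @param n_perm number of Monte-Carlo permutations (>= 100; default 10000).
#' @param alpha significance level on FDR-adjusted q values (default 0.05).
#' @param fdr_method multiplicity procedure, passed to [stats::p.adjust()]
#'   (default Benjamini-Hochberg `"BH"`).
#' @param seed RNG seed for the permutation draws; the same seeded
#'   permutation sequence is applied to every edge so that cross-edge
#'   dependence is preserved.
#' @param tail `"two_sided"` (default) or `"greater"` (case group mean
#'   larger).
#' @param within_site if `TRUE`, permute diagnosis labels only within site
#'   (restricted exchangeability); default `FALSE` permutes across the
#'   pooled, site-adjusted sample.
#' @return An object of class `inference_config`. The reported posterior
#'   probability is `1 - p_perm`, so the significance threshold on the
#'   posterior scale is `1 - alpha`.
#' @export
inference_config <- function(n_perm = 10000L, alpha = 0.05, fdr_method = "BH",
                             seed = 1L, tail = c("two_sided", "greater"),
                             within_site = FALSE) {
  if (!is_number(n_perm) || n_perm < 100) stopf("n_perm must be >= 100")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  tail <- match.arg(tail)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 posterior_threshold = 1 - alpha, fdr_method = fdr_method,
                 seed = as.integer(seed), tail = tail,
                 within_site = isTRUE(within_site)),
            class = "inference_config")
}

#' Remove site-related variance from an edge table
#'
#' Per edge, the z scores are decomposed by a saturated site x diagnosis
#' model in sum-to-zero coding, and the site main-effect and the
#' site-by-diagnosis interaction components are subtracted; the intercept
#' and diagnosis components are retained. With balanced cells this equals
#' subtracting cell-wise site deviations, and the pooled patient-control
#' difference of the adjusted scores equals the unweighted mean of the
#' within-site differences.
#'
#' @param table an `edge_table` from [build_edge_table()].
#' @param group_col,levels grouping column and its two levels
#'   (case first); defaults to `diagnosis` with patient vs control.
#' @return The adjusted `edge_table` with attribute `stage = "site_adjusted"`.
#' @export
remove_site_effects <- function(table, group_col = "diagnosis",
                                levels = c("patient", "control")) {
  site <- as.character(table$site)
  grp <- as.character(table[[group_col]])
  if (!all(grp %in% levels))
    stopf("grouping column contains values outside {%s}", paste(levels, collapse = ", "))
  sites <- sort(unique(site))
  tab <- table(factor(site, sites), factor(grp, levels))
  if (any(tab == 0L))
    stopf("site '%s' lacks one diagnosis group; site effects are inseparable",
          sites[which(rowSums(tab == 0L) > 0)[1]])
  if (any(tab[, 1] != tab[, 2]))
    warnf("unbalanced site x diagnosis cells (%s); adjustment uses unweighted cell means",
          paste(apply(tab, 1, paste, collapse = "/"), collapse = "; "))
  z <- z_matrix(table)
  n_edge <- ncol(z)
  cell <- interaction(factor(site, sites), factor(grp, levels), drop = FALSE)
  # unweighted cell-mean decomposition == saturated OLS in sum-to-zero coding
  cm <- apply(z, 2L, function(col) tapply(col, cell, mean))
  for (e in seq_len(n_edge)) {
    m <- matrix(cm[, e], nrow = length(sites), ncol = 2L) # sites x groups
    grand <- mean(m)
    site_eff <- rowMeans(m) - grand
    grp_eff <- colMeans(m) - grand
    inter <- m - grand - outer(site_eff, rep(1, 2)) - outer(rep(1, length(sites)), grp_eff)
    adj <- site_eff[match(site, sites)] +
      inter[cbind(match(site, sites), match(grp, levels))]
    z[, e] <- z[, e] - adj
  }
  out <- set_z_matrix(table, z)
  attr(out, "stage") <- "site_adjusted"
  out
}

# Shared machinery: permutation weight matrix giving, per permutation, the
# difference of permuted group means as W %*% z. Rows are permutations.
perm_weight_matrix <- function(labels_case, n_perm, seed, site = NULL, within_site = FALSE) {
  n <- length(labels_case)
  n1 <- sum(labels_case)
  n2 <- n - n1
  W <- matrix(-1 / n2, n_perm, n)
  with_seed(seed, {
    if (within_site && !is.null(site)) {
      site <- as.character(site)
      us <- unique(site)
      for (b in seq_len(n_perm)) {
        sel <- integer(0)
        for (s in us) {
          idx <- which(site == s)
          k <- sum(labels_case[idx])
          sel <- c(sel, sample(idx, k))
        }
        W[b, sel] <- 1 / n1
      }
    } else {
      for (b in seq_len(n_perm)) W[b, sample.int(n, n1)] <- 1 / n1
    }
  })
  W
}

#' Monte-Carlo permutation test of a group difference per edge
#'
#' The test statistic is the difference of group means of Fisher z values
#' (case minus reference). The null of group-label exchangeability is
#' simulated by drawing `n_perm` uniform label reassignments that preserve
#' group sizes; the identical seeded permutation sequence is applied to all
#' edges. The p-value uses the add-one correction
#' `p = (1 + #[|stat_perm| >= |stat_obs|]) / (n_perm + 1)` (signed comparison
#' for `tail = "greater"`), so p is never 0.
#'
#' @param z numeric vector (one edge) or subjects x edges matrix.
#' @param labels factor/character with exactly two levels.
#' @param config an [inference_config()].
#' @param case level of `labels` treated as the case group (default:
#'   `"patient"` if present, else the first level).
#' @param site optional site labels for the restricted within-site scheme.
#' @return List with `p` (per edge), `observed` (case minus reference mean),
#'   `n_case`, `n_ref`.
#' @export
permutation_group_test <- function(z, labels, config = inference_config(),
                                   case = NULL, site = NULL) {
  z <- as.matrix(z)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stopf("labels must contain exactly 2 groups, got %d", length(lv))
  case <- case %||% (if ("patient" %in% lv) "patient" else lv[1])
  is_case <- labels == case
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (min(n1, n2) < 2L) stopf("each group needs >= 2 subjects (got %d/%d)", n1, n2)
  if (nrow(z) != length(labels)) stopf("z rows (%d) != labels (%d)", nrow(z), length(labels))
  obs <- colMeans(z[is_case, , drop = FALSE]) - colMeans(z[!is_case, , drop = FALSE])
  W <- perm_weight_matrix(is_case, config$n_perm, config$seed,
                          site = site, within_site = config$within_site)
  stats_perm <- W %*% z
  eps <- 1e-12
  p <- if (config$tail == "two_sided") {
    (1 + colSums(abs(stats_perm) >= rep(abs(obs), each = config$n_perm) - eps)) /
      (config$n_perm + 1)
  } else {
    (1 + colSums(stats_perm >= rep(obs, each = config$n_perm) - eps)) /
      (config$n_perm + 1)
  }
  list(p = stats::setNames(as.numeric(p), colnames(z)), observed = obs,
       n_case = n1, n_ref = n2)
}

#' False-discovery-rate correction
#'
#' Benjamini-Hochberg step-up adjusted p-values (via [stats::p.adjust()])
#' and the rejection set at level `alpha`.
#'
#' @param p vector of p-values in (0, 1].
#' @param alpha FDR level.
#' @param method adjustment method (default `"BH"`).
#' @return List with `q` (adjusted values) and `reject` (logical).
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.04, 0.20))$q # 0.04 0.04 0.0533 0.20
#' @export
fdr_correct <- function(p, alpha = 0.05, method = "BH") {
  if (length(p) == 0L) stopf("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) stopf("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p, method = method)
  list(q = q, reject = q <= alpha)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_case - mean_ref) / s_pooled`,
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x_case,x_ref numeric vectors (>= 2 each).
#' @return Cohen's d.
#' @export
cohens_d <- function(x_case, x_ref) {
  n1 <- length(x_case); n2 <- length(x_ref)
  if (min(n1, n2) < 2L) stopf("each group needs >= 2 values")
  sp <- sqrt(((n1 - 1) * stats::var(x_case) + (n2 - 1) * stats::var(x_ref)) /
               (n1 + n2 - 2))
  if (sp < 1e-14) stopf("zero pooled standard deviation")
  (mean(x_case) - mean(x_ref)) / sp
}

#' Within-group coupling test
#'
#' One-sample sign-flip permutation test of the group-mean z against 0 for
#' each edge (two-sided, add-one correction, shared seeded flips across
#' edges), FDR-corrected across edges. The verdict per edge is `"positive"`
#' if rejected with positive mean, `"negative"` if rejected with negative
#' mean, else `"none"`.
#'
#' @param z subjects x edges matrix (or vector) of one group's z values.
#' @param config an [inference_config()].
#' @return Data frame with columns `edge`, `mean_z`, `p`, `q`, `verdict`.
#' @export
within_group_coupling <- function(z, config = inference_config()) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L) stopf("group needs >= 2 subjects")
  obs <- colMeans(z)
  S <- with_seed(config$seed,
                 matrix(sample(c(-1, 1), config$n_perm * n, replace = TRUE),
                        config$n_perm, n) / n)
  stats_perm <- S %*% z
  eps <- 1e-12
  p <- (1 + colSums(abs(stats_perm) >= rep(abs(obs), each = config$n_perm) - eps)) /
    (config$n_perm + 1)
  fc <- fdr_correct(p, config$alpha, config$fdr_method)
  verdict <- ifelse(!fc$reject, "none", ifelse(obs > 0, "positive", "negative"))
  data.frame(edge = colnames(z) %||% paste0("e", seq_along(obs)),
             mean_z = as.numeric(obs), p = as.numeric(p), q = as.numeric(fc$q),
             verdict = verdict, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a significant edge difference
#'
#' Combines the group-difference verdict with the reference (control) group's
#' within-group coupling: a significant positive shift on a positively
#' coupled edge is `hyperconnectivity_of_positive_coupling`; a significant
#' positive shift on an edge anti-correlated in the reference group is
#' `loss_of_anticorrelation`; a significant negative shift is
#' `hypoconnectivity`; otherwise `none`.
#'
#' @param significant logical (FDR-level significance of the group test).
#' @param delta case minus reference mean z.
#' @param ref_verdict reference-group coupling verdict
#'   (`"positive"`/`"negative"`/`"none"`).
#' @return Character classification (vectorized).
#' @export
classify_edge <- function(significant, delta, ref_verdict) {
  out <- rep("none", length(delta))
  pos <- significant & delta > 0
  out[pos & ref_verdict == "negative"] <- "loss_of_anticorrelation"
  out[pos & ref_verdict != "negative"] <- "hyperconnectivity_of_positive_coupling"
  out[significant & delta < 0] <- "hypoconnectivity"
  out
}

#' Edge-wise group inference on an edge table
#'
#' Full per-edge analysis: permutation test of the case-vs-reference
#' difference, FDR correction across the network's edges, Cohen's d,
#' within-group coupling verdicts for both groups, and edge classification.
#'
#' @param table an `edge_table` (typically site-adjusted).
#' @param config an [inference_config()].
#' @param group_col column holding the two group labels.
#' @param case,ref the case and reference levels (defaults
#'   patient/control).
#' @return Data frame of class `edge_results`, one row per edge.
#' @export
test_edges <- function(table, config = inference_config(),
                       group_col = "diagnosis", case = "patient", ref = "control") {
  z <- z_matrix(table)
  grp <- as.character(table[[group_col]])
  keep <- grp %in% c(case, ref)
  z <- z[keep, , drop = FALSE]
  grp <- grp[keep]
  gt <- permutation_group_test(z, grp, config, case = case,
                               site = table$site[keep])
  fc <- fdr_correct(gt$p, config$alpha, config$fdr_method)
  zc <- z[grp == case, , drop = FALSE]
  zr <- z[grp == ref, , drop = FALSE]
  d <- vapply(seq_len(ncol(z)), function(e) cohens_d(zc[, e], zr[, e]), numeric(1))
  wg_ref <- within_group_coupling(zr, config)
  wg_case <- within_group_coupling(zc, config)
  res <- data.frame(
    edge = colnames(z),
    n_case = gt$n_case, n_ref = gt$n_ref,
    mean_z_case = colMeans(zc), mean_z_ref = colMeans(zr),
    delta = as.numeric(gt$observed),
    p_perm = as.numeric(gt$p),
    posterior_p = 1 - as.numeric(gt$p),
    q_fdr = as.numeric(fc$q),
    cohen_d = d,
    significant = fc$reject,
    ref_verdict = wg_ref$verdict, ref_q = wg_ref$q,
    case_verdict = wg_case$verdict, case_q = wg_case$q,
    row.names = NULL, stringsAsFactors = FALSE)
  res$classification <- classify_edge(res$significant, res$delta, res$ref_verdict)
  structure(res, class = c("edge_results", "data.frame"),
            case = case, ref = ref, network = attr(table, "network"),
            stage = attr(table, "stage"))
}

#' @export
print.edge_results <- function(x, ...) {
  cat(sprintf("<edge_results> network '%s' (%s), %s vs %s, %d edges, %d significant\n",
              attr(x, "network") %||% "?", attr(x, "stage") %||% "raw",
              attr(x, "case"), attr(x, "ref"), nrow(x), sum(x$significant)))
  print.data.frame(cbind(x[c("edge", "delta", "p_perm", "q_fdr", "cohen_d")],
                         class = x$classification), digits = 4, row.names = FALSE)
  invisible(x)
}
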