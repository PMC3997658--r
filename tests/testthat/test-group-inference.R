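make_table <- function(z, site, dx, net = two_node_network()) {
  meta <- data.frame(subject_id = sprintf("s%03d", seq_along(z)),
                     site = site, diagnosis = dx, stringsAsFactors = FALSE)
  build_edge_table(cbind("A-B" = z), meta, net)
}

test_that("site adjustment equals the balanced cell-mean oracle", {
  set.seed(1)
  n <- 10
  site <- rep(c("a", "b"), each = 2 * n)
  dx <- rep(rep(c("patient", "control"), each = n), 2)
  z <- rnorm(4 * n, 0.3, 0.2)
  z[site == "b"] <- z[site == "b"] + 0.5                       # site effect
  z[site == "b" & dx == "patient"] <- z[site == "b" & dx == "patient"] + 0.4 # interaction
  adj <- remove_site_effects(make_table(z, site, dx))
  za <- adj[["A-B"]]
  pooled <- mean(za[dx == "patient"]) - mean(za[dx == "control"])
  within <- sapply(c("a", "b"), function(s)
    mean(z[site == s & dx == "patient"]) - mean(z[site == s & dx == "control"]))
  expect_equal(pooled, mean(within), tolerance = 1e-10)
  expect_equal(attr(adj, "stage"), "site_adjusted")
  # adjusted cell means no longer differ between sites within a group
  cm <- tapply(za, list(site, dx), mean)
  expect_equal(unname(cm["a", ]), unname(cm["b", ]), tolerance = 1e-10)
})

test_that("site adjustment is a no-op without site structure and shift-stable", {
  set.seed(2)
  n <- 8
  site <- rep(c("a", "b"), each = 2 * n)
  dx <- rep(rep(c("patient", "control"), each = n), 2)
  z <- rnorm(4 * n, 0.2, 0.3)
  tab <- make_table(z, site, dx)
  adj <- remove_site_effects(tab)
  # data with no systematic site effect: adjustment only moves cell means,
  # which are near zero here; exact no-op holds when cell means already agree
  z_eq <- z - ave(z, interaction(site, dx)) + ave(z, dx)
  adj_eq <- remove_site_effects(make_table(z_eq, site, dx))
  expect_equal(adj_eq[["A-B"]], z_eq, tolerance = 1e-10)
  # adding a constant to one site changes adjusted values only by a common
  # constant (the retained grand mean), so all contrasts are invariant
  z2 <- z; z2[site == "b"] <- z2[site == "b"] + 0.3
  adj2 <- remove_site_effects(make_table(z2, site, dx))
  diffs <- adj2[["A-B"]] - adj[["A-B"]]
  expect_lt(max(diffs) - min(diffs), 1e-10)
  expect_error(remove_site_effects(make_table(z[site == "a"], site[site == "a"],
                                              rep("patient", 2 * n))),
               "outside|lacks")
  one_dx <- make_table(c(z[site == "a"], rnorm(4)),
                       c(site[site == "a"], rep("b", 4)),
                       c(dx[site == "a"], rep("patient", 4)))
  expect_error(remove_site_effects(one_dx), "lacks")
})

test_that("permutation p matches full enumeration and its trivial bounds", {
  cfg <- inference_config(n_perm = 4000, seed = 7)
  # all values equal -> p = 1
  expect_equal(unname(permutation_group_test(rep(1, 8),
                                             rep(c("patient", "control"), 4),
                                             cfg)$p), 1)
  # 2+2 toy: exact enumeration over all 6 partitions gives 2/6
  p22 <- permutation_group_test(c(1.0, 1.2, 0.0, 0.2),
                                c("patient", "patient", "control", "control"),
                                cfg)$p
  expect_lt(abs(p22 - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / cfg$n_perm) + 2 / cfg$n_perm)
  # huge separation attains the add-one floor (groups large enough that a
  # random reassignment essentially never reproduces the observed split)
  psep <- permutation_group_test(c(rnorm(20, 100), rnorm(20, 0)),
                                 rep(c("patient", "control"), each = 20), cfg)$p
  expect_equal(unname(psep), 1 / (cfg$n_perm + 1))
  expect_error(permutation_group_test(rnorm(3), c("patient", "patient", "control"),
                                      cfg), ">= 2")
})

test_that("permutation p is invariant to common affine transforms of z", {
  set.seed(3)
  z <- rnorm(16)
  lab <- rep(c("patient", "control"), each = 8)
  cfg <- inference_config(n_perm = 1000, seed = 11)
  p1 <- permutation_group_test(z, lab, cfg)$p
  p2 <- permutation_group_test(5 - 2.3 * z, lab, cfg)$p
  expect_equal(p1, p2)
})

test_that("BH correction reproduces the hand-computed example", {
  fc <- fdr_correct(c(0.01, 0.02, 0.04, 0.20), alpha = 0.05)
  expect_equal(fc$q, c(0.04, 0.04, 0.0533333333, 0.20), tolerance = 1e-9)
  # step-up at alpha = 0.05: q = 0.0533 stays above the level, so 2 rejections
  expect_equal(sum(fc$reject), 2)
  expect_equal(fdr_correct(0.03)$q, 0.03)
  expect_equal(fdr_correct(rep(0.2, 5))$q, rep(0.2, 5))
  p <- runif(10)
  expect_true(all(fdr_correct(p)$q >= p))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 0)), "0, 1")
})

test_that("cohens_d follows the pooled-SD formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- 1 + scale(rnorm(20))[, 1]
  b <- 0 + scale(rnorm(20))[, 1]
  expect_equal(cohens_d(a, b), 1, tolerance = 1e-12)
  set.seed(4)
  x <- 0.6 + 1.2 * scale(rnorm(10))[, 1]
  y <- 0.1 + 0.8 * scale(rnorm(10))[, 1]
  expect_equal(cohens_d(x, y), 0.5 / sqrt((1.2^2 + 0.8^2) / 2), tolerance = 1e-10)
  expect_equal(cohens_d(x, y), 0.4902903, tolerance = 1e-6)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled")
})

test_that("within-group coupling verdicts follow sign and significance", {
  cfg <- inference_config(n_perm = 2000, seed = 5)
  z0 <- matrix(0, 12, 3, dimnames = list(NULL, c("e1", "e2", "e3")))
  expect_true(all(within_group_coupling(z0, cfg)$verdict == "none"))
  set.seed(6)
  zpos <- matrix(rnorm(30 * 2, 0.5, 0.1), 30, 2, dimnames = list(NULL, c("a", "b")))
  wg <- within_group_coupling(zpos, cfg)
  expect_true(all(wg$verdict == "positive"))
  expect_true(all(wg$q <= 0.05))
  wgneg <- within_group_coupling(-zpos, cfg)
  expect_true(all(wgneg$verdict == "negative"))
  expect_equal(wg$p, wgneg$p) # sign symmetry under identical flips
})

test_that("edge classification implements the sign/coupling rules", {
  expect_equal(classify_edge(TRUE, 0.2, "positive"),
               "hyperconnectivity_of_positive_coupling")
  expect_equal(classify_edge(TRUE, 0.2, "negative"), "loss_of_anticorrelation")
  expect_equal(classify_edge(TRUE, -0.2, "positive"), "hypoconnectivity")
  expect_equal(classify_edge(FALSE, 0.4, "positive"), "none")
  expect_equal(classify_edge(c(TRUE, FALSE), c(0.2, 0.2), c("none", "positive")),
               c("hyperconnectivity_of_positive_coupling", "none"))
})

test_that("test_edges ties the machinery together on a planted table", {
  set.seed(7)
  isa <- load_network("isa")
  n <- 30
  z <- matrix(rnorm(2 * n * 10, 0.3, 0.25), 2 * n, 10)
  colnames(z) <- isa$edges$label
  dx <- rep(c("patient", "control"), each = n)
  z[dx == "patient", "SGC-PrC"] <- z[dx == "patient", "SGC-PrC"] + 0.4
  z[, "ACC-AmyL"] <- z[, "ACC-AmyL"] - 0.6
  z[dx == "patient", "ACC-AmyL"] <- z[dx == "patient", "ACC-AmyL"] + 0.45
  meta <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n)),
                     site = "x", diagnosis = dx)
  res <- test_edges(build_edge_table(z, meta, isa),
                    inference_config(n_perm = 3000, seed = 8))
  expect_s3_class(res, "edge_results")
  expect_equal(res$posterior_p, 1 - res$p_perm)
  expect_true(all(res$q_fdr >= res$p_perm - 1e-15))
  expect_identical(res$significant, res$q_fdr <= 0.05)
  sgc <- res[res$edge == "SGC-PrC", ]
  expect_true(sgc$significant)
  expect_equal(sgc$classification, "hyperconnectivity_of_positive_coupling")
  acc <- res[res$edge == "ACC-AmyL", ]
  expect_true(acc$significant)
  expect_equal(acc$classification, "loss_of_anticorrelation")
})
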