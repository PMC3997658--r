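test_that("median_split follows the >= threshold convention", {
  sp <- median_split(c(1, 2, 5, 9, 30), ids = c("a", "b", "c", "d", "e"),
                     variable = "duration")
  expect_equal(sp$threshold, 5)
  expect_setequal(sp$high_ids, c("c", "d", "e")) # >= 5 years is "long"
  expect_setequal(sp$low_ids, c("a", "b"))
  sp2 <- median_split(c(18, 20, 24, 30), variable = "onset_age")
  expect_equal(sp2$threshold, 22) # even n: mean of middle order statistics
  expect_equal(sp2$high_ids, c(3, 4))
  sp3 <- median_split(c(1, 2, NA, 5, 9, 30), ids = 1:6)
  expect_equal(sp3$excluded_ids, 3)
  expect_equal(length(sp3$high_ids) + length(sp3$low_ids), 5)
  expect_error(median_split(rep(4, 6)), "identical")
  expect_error(median_split(c(1, 2, NA, NA)), ">= 4")
})

test_that("median_split is invariant under strictly increasing transforms", {
  set.seed(1)
  x <- rexp(15)
  a <- median_split(x, ids = 1:15)
  b <- median_split(log(x + 1), ids = 1:15)
  expect_setequal(a$high_ids, b$high_ids)
})

test_that("subgroup comparison reuses the group machinery with planted power", {
  set.seed(2)
  isa <- load_network("isa")
  n <- 15
  hits <- 0L
  seeds <- 1:10
  for (s in seeds) {
    set.seed(s + 100)
    z <- matrix(rnorm(2 * n * 10, 0.3, 0.2), 2 * n, 10)
    colnames(z) <- isa$edges$label
    dur <- c(runif(n, 0, 4), runif(n, 6, 20)) # clean split at 5
    z[(n + 1):(2 * n), "SGC-PrC"] <- z[(n + 1):(2 * n), "SGC-PrC"] + 0.5
    meta <- data.frame(subject_id = sprintf("p%02d", 1:(2 * n)), site = "a",
                       diagnosis = "patient")
    tab <- build_edge_table(z, meta, isa)
    sp <- median_split(dur, ids = meta$subject_id, variable = "duration")
    res <- subgroup_comparison(tab, sp, inference_config(n_perm = 2000, seed = s))
    if (res$significant[res$edge == "SGC-PrC"]) hits <- hits + 1L
  }
  expect_gte(hits, 9) # ~95% power oracle at this SNR
  # identical halves stay null
  set.seed(3)
  z <- matrix(rnorm(2 * n * 10, 0.3, 0.2), 2 * n, 10)
  colnames(z) <- isa$edges$label
  meta <- data.frame(subject_id = sprintf("p%02d", 1:(2 * n)), site = "a",
                     diagnosis = "patient")
  tab <- build_edge_table(z, meta, isa)
  sp <- median_split(runif(2 * n), ids = meta$subject_id)
  res0 <- subgroup_comparison(tab, sp, inference_config(n_perm = 2000, seed = 4))
  expect_lte(sum(res0$significant), 1)
  # one-subject subgroup is degenerate
  sp1 <- sp; sp1$high_ids <- sp$high_ids[1]; sp1$low_ids <- setdiff(meta$subject_id, sp1$high_ids)
  expect_error(subgroup_comparison(tab, sp1, inference_config(seed = 1)), "degenerate")
})

test_that("spearman correlation handles monotone, tied and null cases", {
  isa <- load_network("isa")
  n <- 12
  z <- matrix(0.1, n, 10)
  colnames(z) <- isa$edges$label
  bdi <- seq_len(n)
  z[, 1] <- bdi^3            # strictly increasing transform
  z[, 2] <- -sqrt(bdi)       # strictly decreasing
  z[, 3:10] <- matrix(rnorm(8 * n), n)
  meta <- data.frame(subject_id = sprintf("p%02d", 1:n), site = "a",
                     diagnosis = "patient")
  tab <- build_edge_table(z, meta, isa)
  sc <- symptom_correlation(tab, bdi, inference_config(n_perm = 2000, seed = 5))
  expect_equal(sc$rho[1], 1)
  expect_equal(sc$rho[2], -1)
  # tied data match the rank-then-Pearson oracle with average ranks
  x <- c(1, 2, 3, 4); y <- c(2, 2, 5, 5)
  expect_equal(rsfcnet:::spearman_rho(x, y), cor(rank(x), rank(y)))
  expect_error(symptom_correlation(tab, rep(3, n), inference_config(seed = 1)),
               "constant")
  expect_error(symptom_correlation(tab, bdi[1:5], inference_config(seed = 1)),
               "length")
})

test_that("spearman rho is invariant under increasing transforms of either side", {
  set.seed(6)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  expect_equal(rsfcnet:::spearman_rho(x, y), rsfcnet:::spearman_rho(exp(x), y))
  expect_equal(rsfcnet:::spearman_rho(x, y), rsfcnet:::spearman_rho(x, y^3 + y))
})

test_that("null symptom correlations reject at roughly the nominal rate", {
  set.seed(7)
  isa <- load_network("isa")
  n <- 40 # asymptotic branch
  rejections <- 0L
  tests <- 0L
  for (rep in 1:30) {
    z <- matrix(rnorm(n * 10), n, 10)
    colnames(z) <- isa$edges$label
    meta <- data.frame(subject_id = sprintf("p%02d", 1:n), site = "a",
                       diagnosis = "patient")
    tab <- build_edge_table(z, meta, isa)
    sc <- symptom_correlation(tab, rnorm(n), inference_config(seed = rep))
    rejections <- rejections + sum(sc$p <= 0.05)
    tests <- tests + nrow(sc)
  }
  rate <- rejections / tests # 300 tests; 95% band around 0.05 is ~[0.026, 0.075]
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})
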