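test_that("roster is balanced and ROI records have coherent shapes", {
  spec <- tiny_spec(n_per_group = 3)
  r <- cohort_roster(spec)
  expect_equal(nrow(r), 12)
  expect_true(all(table(r$site, r$diagnosis) == 3)) # balanced by construction
  co <- generate_roi_cohort(spec)
  expect_length(co$records, 12)
  for (rec in co$records[c(1, 7)]) {
    expect_equal(dim(rec$bold), c(80L, 5L))
    expect_equal(nrow(rec$motion), 80L)
    expect_equal(nrow(rec$tissue_means), 80L)
  }
})

test_that("generation is deterministic and order-independent under one seed", {
  spec <- tiny_spec(n_per_group = 2, seed = 99)
  a <- generate_roi_cohort(spec)
  b <- generate_roi_cohort(spec)
  expect_identical(a$records[[3]]$bold, b$records[[3]]$bold)
  expect_identical(a$records[[3]]$motion, b$records[[3]]$motion)
  expect_identical(a$records[[3]]$covariates, b$records[[3]]$covariates)
  # streaming a single subject reproduces the batch record
  solo <- generate_subject(spec, 5, roi_level = TRUE)
  expect_identical(solo$bold, a$records[[5]]$bold)
})

test_that("equal group targets give zero planted difference everywhere", {
  tg <- network_targets(load_network("isa"), control = 0.25, patient = 0.25)
  spec <- tiny_spec(targets = tg)
  co <- generate_roi_cohort(spec)
  expect_true(all(co$ground_truth$targets$delta_true == 0))
})

test_that("latent power concentrates in the 0.01-0.08 Hz passband at both TRs", {
  spec <- tiny_spec(n_per_group = 2, n_frames = 300, seed = 4)
  co <- generate_roi_cohort(spec)
  for (rec in co$records[c(1, 5)]) { # one per site
    sp <- stats::spec.pgram(stats::ts(rec$bold[, 1], deltat = rec$tr),
                            plot = FALSE, taper = 0, detrend = FALSE)
    frac <- sum(sp$spec[sp$freq >= 0.01 & sp$freq <= 0.08]) / sum(sp$spec)
    expect_gt(frac, 0.80)
  }
})

test_that("clean long series converge to the target correlations", {
  # sampling SD of r for band-limited series at T = 5000 is ~0.024, so the
  # per-subject estimate is checked through its mean over 12 subjects
  # (3 SE ~ 0.02)
  spec <- cohort_spec(sites = list(site_spec("a", tr = 2, n_frames = 5000,
                                             n_per_group = 6)),
                      targets = isa_default_targets(), subject_sd = 0,
                      site_offset = c(a = 0), seed = 31)
  co <- generate_roi_cohort(spec)
  net <- load_network("isa")
  rs <- vapply(co$records, function(r) edge_correlations(r$bold, net), numeric(10))
  ctrl_idx <- vapply(co$records, function(r) r$diagnosis == "control", logical(1))
  tg <- co$ground_truth$targets
  expect_lt(max(abs(rowMeans(rs[, ctrl_idx]) - tanh(tg$z_control[1:10]))), 0.02)
  expect_lt(max(abs(rowMeans(rs[, !ctrl_idx]) - tanh(tg$z_patient[1:10]))), 0.02)
})

test_that("planted group difference reproduces the closed-form z gap", {
  net <- two_node_network()
  tg <- network_targets(net, control = 0.3, patient = 0.6)
  spec <- cohort_spec(sites = list(site_spec("a", tr = 2, n_frames = 1000,
                                             n_per_group = 100)),
                      targets = tg, subject_sd = 0, site_offset = c(a = 0),
                      seed = 8)
  co <- generate_roi_cohort(spec)
  z <- vapply(co$records, function(r)
    fisher_z(edge_correlations(r$bold, net)), numeric(1))
  pat <- vapply(co$records, function(r) r$diagnosis == "patient", logical(1))
  gap <- mean(z[pat]) - mean(z[!pat])
  expect_lt(abs(gap - (atanh(0.6) - atanh(0.3))), 0.03) # 0.3835 +- MC bound
})

test_that("degenerate correlation targets and zero-variance requests fail loudly", {
  net <- two_node_network()
  expect_error(network_targets(net, control = 0.99), "0.95")
  # an inconsistent 3-node target set far from PSD is rejected
  tri <- network_model("tri", list(voi("A", peak_mni = c(0, 0, 0)),
                                   voi("B", peak_mni = c(21, 0, 0)),
                                   voi("C", peak_mni = c(0, 21, 0))))
  tg <- network_targets(tri, control = c("A-B" = 0.9, "A-C" = 0.9, "B-C" = -0.9))
  expect_error(
    cohort_spec(sites = list(site_spec("a", tr = 2, n_frames = 100,
                                       n_per_group = 2)),
                targets = tg, subject_sd = 0, seed = 1),
    "positive semi-definite")
  expect_error(rsfcnet:::standardize_cols(matrix(1, 50, 2)), "zero-variance")
})

test_that("covariate draws respect anchors, supports and invariants", {
  model <- default_covariate_model()
  cv <- generate_covariates(model, 10000, "control", seed = 7)
  expect_lt(abs(mean(cv$bdi) - 1.33), 0.1) # Table-anchor calibration
  expect_true(all(cv$bdi >= 0))
  expect_true(all(is.na(cv$onset_age)))
  cvp <- generate_covariates(model, 3000, "patient", seed = 8)
  expect_true(all(cvp$onset_age <= cvp$age))
  expect_true(all(cvp$duration <= cvp$age - cvp$onset_age + 1))
  expect_gt(mean(cvp$bdi), mean(cv$bdi[1:3000])) # patient BDI dominates
  # SD = 0 collapses to the mean
  m0 <- model
  m0$control$bdi <- c(5, 0, 0, Inf)
  cv0 <- generate_covariates(m0, 20, "control", seed = 9)
  expect_true(all(cv0$bdi == 5))
  mneg <- model
  mneg$control$bdi <- c(5, -1, 0, Inf)
  expect_error(generate_covariates(mneg, 5, "control", seed = 1), "negative SD")
})

test_that("site offsets shift measured connectivity additively on the z scale", {
  spec <- cohort_spec(sites = list(site_spec("a", tr = 2, n_frames = 600,
                                             n_per_group = 25),
                                   site_spec("b", tr = 2, n_frames = 600,
                                             n_per_group = 25)),
                      targets = network_targets(two_node_network(),
                                                control = 0.3, patient = 0.3),
                      subject_sd = 0, site_offset = c(a = 0.3, b = -0.3), seed = 12)
  co <- generate_roi_cohort(spec)
  z <- vapply(co$records, function(r)
    fisher_z(edge_correlations(r$bold, two_node_network())), numeric(1))
  sitea <- vapply(co$records, function(r) r$site == "a", logical(1))
  expect_equal(mean(z[sitea]) - mean(z[!sitea]), 0.6, tolerance = 0.06)
})
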