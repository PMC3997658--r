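#' Acquisition-site specification
#'
#' @param name site label.
#' @param tr repetition time in seconds.
#' @param n_frames frames acquired (before discarding).
#' @param voxel_size acquisition voxel edge in mm (metadata; the synthetic
#'   cohort lives on a common analysis grid, as real data do after spatial
#'   normalization).
#' @param n_per_group subjects per diagnostic group at this site (the design
#'   is balanced by construction: equal patients and controls).
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(name, tr, n_frames, n_per_group, voxel_size = 3) {
  if (!is_number(tr) || tr <= 0) stopf("tr must be > 0")
  if (!is_number(n_frames) || n_frames <= 20) stopf("n_frames must be > 20")
  if (!is_number(n_per_group) || n_per_group < 1) stopf("n_per_group must be >= 1")
  structure(list(name = as.character(name), tr = tr,
                 n_frames = as.integer(n_frames),
                 n_per_group = as.integer(n_per_group),
                 voxel_size = voxel_size), class = "site_spec")
}

#' Per-group edge connectivity targets for one network
#'
#' @param network a [network_model()].
#' @param control,patient target Pearson correlation per edge for each
#'   group: a scalar (recycled) or a named vector over (a subset of) the
#'   network's edge labels; unnamed edges take the scalar `fill`.
#' @param fill default correlation for edges not named.
#' @return Object of class `network_targets` with full named vectors.
#' @export
network_targets <- function(network, control = 0.3, patient = control, fill = 0.3) {
  labs <- network$edges$label
  expand <- function(x) {
    if (is.null(names(x))) {
      if (length(x) == 1L) return(stats::setNames(rep(x, length(labs)), labs))
      if (length(x) == length(labs)) return(stats::setNames(as.numeric(x), labs))
      stopf("unnamed target vector must have length 1 or %d", length(labs))
    }
    bad <- setdiff(names(x), labs)
    if (length(bad)) stopf("unknown edge label(s): %s", paste(bad, collapse = ", "))
    out <- stats::setNames(rep(fill, length(labs)), labs)
    out[names(x)] <- x
    out
  }
  ctrl <- expand(control)
  pat <- expand(patient)
  if (any(abs(c(ctrl, pat)) > 0.95)) stopf("|target correlations| must be <= 0.95")
  structure(list(network = network, control = ctrl, patient = pat),
            class = "network_targets")
}

#' Default targets emulating the study pattern on the ISA network
#'
#' Controls show moderate positive coupling (r = 0.30) on all edges except a
#' negative ACC-AmyL coupling (r = -0.25); patients show increased coupling
#' on SGC-ACC, SGC-PrC, ACC-PrC, AmyL-PrC (r = 0.40) and a weakened
#' anti-correlation on ACC-AmyL (r = -0.14). The planted shift (~0.11 on the
#' Fisher-z scale) corresponds to standardized group differences of roughly
#' 0.4-0.5 against the measured between-subject z dispersion (~0.25) at the
#' default acquisition and noise settings, the range of the main-analysis
#' effect sizes.
#'
#' @return A [network_targets()] for the built-in ISA network.
#' @export
isa_default_targets <- function() {
  network_targets(load_network("isa"),
                  control = c("ACC-AmyL" = -0.25), fill = 0.30,
                  patient = c("SGC-ACC" = 0.40, "SGC-PrC" = 0.40,
                              "ACC-PrC" = 0.40, "AmyL-PrC" = 0.40,
                              "ACC-AmyL" = -0.14))
}

#' Default (null) targets for the language control network
#'
#' Identical mild coupling (r = 0.2) in both groups: no group difference.
#'
#' @return A [network_targets()] for the built-in control network.
#' @export
control_default_targets <- function() {
  network_targets(load_network("control"), control = 0.2, patient = 0.2, fill = 0.2)
}

# ---- truncated-normal covariate machinery --------------------------------

tn_moments <- function(mu, sig, lower, upper) {
  a <- (lower - mu) / sig
  b <- (upper - mu) / sig
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (!is.finite(Z) || Z < 1e-12) return(c(NA_real_, NA_real_))
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  m <- mu + sig * (da - db) / Z
  v <- sig^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

# Inverse Mills ratio phi(a) / (1 - Phi(a)), numerically stable.
mills <- function(a) {
  exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

.tn_cache <- new.env(parent = emptyenv())

# Moment-match truncated-normal parameters: realized mean equals `m`
# exactly; realized SD matches `s` as closely as the support allows (a mean
# just above a lower bound with a large SD caps the attainable SD).
fit_truncnorm <- function(m, s, lower = -Inf, upper = Inf) {
  if (s < 0) stopf("negative SD in covariate model")
  if (s == 0) return(list(mu = min(max(m, lower), upper), sig = 0))
  key <- paste(m, s, lower, upper)
  hit <- .tn_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (is.finite(lower) && !is.finite(upper)) {
    # one-sided: parametrize by a = (lower - mu)/sig; the mean constraint
    # then fixes sig = (m - lower) / (mills(a) - a) in closed form.
    if (m <= lower) stopf("covariate mean must exceed the lower bound")
    sd_at <- function(a) {
      lam <- mills(a)
      sig <- (m - lower) / (lam - a)
      c(sig, sig * sqrt(max(1 + a * lam - lam^2, 0)))
    }
    opt <- stats::optimize(function(a) (sd_at(a)[2] - s)^2, interval = c(-12, 12))
    a <- opt$minimum
    sig <- sd_at(a)[1]
    list(mu = lower - a * sig, sig = sig)
  } else {
    solve_mu <- function(sig) {
      f <- function(mu) tn_moments(mu, sig, lower, upper)[1] - m
      res <- try(stats::uniroot(f, interval = c(m - 6 * (s + sig), m + 6 * (s + sig)),
                                extendInt = "yes", tol = 1e-9), silent = TRUE)
      if (inherits(res, "try-error")) NA_real_ else res$root
    }
    obj <- function(lsig) {
      sig <- exp(lsig)
      mu <- solve_mu(sig)
      if (!is.finite(mu)) return(1e6)
      (tn_moments(mu, sig, lower, upper)[2] - s)^2
    }
    opt <- stats::optimize(obj, interval = log(c(s / 20, s * 8)))
    sig <- exp(opt$minimum)
    list(mu = solve_mu(sig), sig = sig)
  }
  .tn_cache[[key]] <- out
  out
}

rtruncnorm <- function(n, mu, sig, lower = -Inf, upper = Inf) {
  if (sig <= 0) return(rep(min(max(mu, lower), upper), n))
  if (stats::pnorm(lower, mu, sig) < 0.5) {
    pa <- stats::pnorm(lower, mu, sig)
    pb <- stats::pnorm(upper, mu, sig)
    x <- stats::qnorm(stats::runif(n, pa, pb), mu, sig)
  } else {
    # support sits in the far upper tail of N(mu, sig): invert through the
    # upper-tail CDF, which keeps full precision for tiny tail masses
    qa <- stats::pnorm(lower, mu, sig, lower.tail = FALSE)
    qb <- stats::pnorm(upper, mu, sig, lower.tail = FALSE)
    x <- stats::qnorm(stats::runif(n, qb, qa), mu, sig, lower.tail = FALSE)
  }
  pmin(pmax(x, lower), upper)
}

#' Default clinical covariate model
#'
#' Mean/SD anchors per group for age, education, BDI, HRSD, illness onset
#' age, illness duration and episode count, with hard supports (scores >= 0,
#' onset <= age, duration <= age - onset + 1). Values are drawn from
#' truncated normals whose parameters are moment-matched so the realized
#' mean equals the anchor (the SD is matched as closely as the support
#' allows; a near-zero mean with a large SD on a non-negative score cannot
#' be represented exactly by a truncated normal).
#'
#' @return Nested list `list(control = ..., patient = ...)`; each field is
#'   `c(mean, sd, lower, upper)`, plus `p_male`.
#' @export
default_covariate_model <- function() {
  list(
    control = list(age = c(36.74, 11.48, 18, 65),
                   education = c(13.78, 2.93, 8, 25),
                   bdi = c(1.33, 2.34, 0, Inf),
                   p_male = 30 / 57),
    patient = list(age = c(36.89, 11.40, 18, 65),
                   education = c(13.81, 3.39, 8, 25),
                   bdi = c(20.12, 9.18, 0, Inf),
                   hrsd = c(16.23, 10.07, 0, Inf),
                   onset_age = c(25.74, 10.36, 12, Inf),
                   duration = c(9.09, 9.35, 0, Inf),
                   n_episodes = c(3.23, 3.03, 1, Inf),
                   p_male = 30 / 57)
  )
}

# Draw one subject's covariates using the current RNG state.
draw_covariates <- function(model, group) {
  gm <- model[[group]]
  draw <- function(anchor, upper_override = NULL) {
    up <- upper_override %||% anchor[4]
    fit <- fit_truncnorm(anchor[1], anchor[2], anchor[3], anchor[4])
    rtruncnorm(1, fit$mu, fit$sig, anchor[3], up)
  }
  age <- draw(gm$age)
  out <- list(age = age,
              sex = if (stats::runif(1) < gm$p_male) "M" else "F",
              education = draw(gm$education),
              bdi = draw(gm$bdi))
  if (group == "patient") {
    onset <- draw(gm$onset_age, upper_override = age)
    out$hrsd <- draw(gm$hrsd)
    out$onset_age <- onset
    out$duration <- draw(gm$duration, upper_override = age - onset + 1)
    out$n_episodes <- round(draw(gm$n_episodes))
  } else {
    out$hrsd <- NA_real_; out$onset_age <- NA_real_
    out$duration <- NA_real_; out$n_episodes <- NA_real_
  }
  out
}

#' Draw clinical covariates for a group
#'
#' @param model covariate model (see [default_covariate_model()]).
#' @param n number of subjects.
#' @param group `"patient"` or `"control"`.
#' @param seed RNG seed.
#' @return Data frame with one row per subject (controls have `NA` for the
#'   illness fields).
#' @export
generate_covariates <- function(model, n, group = c("control", "patient"), seed = 1L) {
  group <- match.arg(group)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i)
      as.data.frame(draw_covariates(model, group), stringsAsFactors = FALSE)))
  })
}

# ---- correlation-structured band-limited latent signals ------------------

# Nearest positive-semidefinite correlation matrix: eigenvalue clipping at
# `floor`, then diagonal renormalization. Errors if the projection moves any
# entry by more than `proj_tol` (the requested targets were inconsistent).
nearest_psd <- function(M, floor = 1e-8, proj_tol = 0.05) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) return(M)
  v <- pmax(e$values, floor)
  M2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M2))
  M2 <- M2 / tcrossprod(d)
  if (max(abs(M2 - M)) > proj_tol)
    stopf("target correlation matrix is far from positive semi-definite (max change %.3f)",
          max(abs(M2 - M)))
  M2
}

# Band-limited node signals with population correlation matrix R:
# white Gaussian noise -> Butterworth band-pass -> column standardization ->
# mixing by the Cholesky factor of the (PSD-projected) matrix. Per-subject
# matrices (target + random effects) are projected unconditionally; the
# consistency check against the *requested* group targets happens once in
# cohort_spec().
latent_signals <- function(n_frames, tr, R, band = c(0.01, 0.08)) {
  k <- ncol(R)
  f <- matrix(stats::rnorm(n_frames * k), n_frames, k)
  f <- bandpass(f, tr, band)
  f <- standardize_cols(f)
  Rp <- nearest_psd(R, proj_tol = Inf)
  y <- f %*% chol(Rp + diag(1e-10, k))
  colnames(y) <- colnames(R)
  y
}

# Edge-target vector (z scale) -> node correlation matrix for one network.
edge_z_to_corr <- function(z_edges, network) {
  n <- length(network$nodes)
  R <- diag(n)
  dimnames(R) <- list(node_abbrevs(network), node_abbrevs(network))
  R[cbind(network$edges$i, network$edges$j)] <- tanh(z_edges[network$edges$label])
  R[cbind(network$edges$j, network$edges$i)] <- tanh(z_edges[network$edges$label])
  R
}

# ---- cohort specification -------------------------------------------------

#' Synthetic cohort specification
#'
#' Full generative description of a two-site (or k-site), two-group
#' resting-state cohort. Per subject, each network's nodes receive
#' band-limited latent signals whose inter-node correlation equals the
#' group's target (Fisher-z scale) plus a per-site offset (the site
#' confound) plus a subject-level random effect. Volumetric generation
#' embeds the node signals into the VOI spheres on the grid and adds slow
#' drift, a motion-coupled artifact (smooth gain field times framewise
#' motion magnitude), tissue-mean signals, and white noise.
#'
#' @param sites list of [site_spec()]s (defaults: "aachen" TR 2.2 s, 250
#'   frames, 30/group; "goettingen" TR 2.0 s, 156 frames, 27/group).
#' @param targets a [network_targets()] or list of them (defaults: ISA
#'   network with the study-like planted pattern plus a null language
#'   control network).
#' @param site_offset named per-site additive shift of latent connectivity
#'   on the Fisher-z scale (default +0.05 / -0.05 for the first two sites).
#' @param subject_sd SD of the per-subject, per-edge random effect on the
#'   z scale.
#' @param band passband of the latent signals, Hz.
#' @param noise_sd thermal (white) noise SD, volumetric path.
#' @param drift_amp low-frequency drift amplitude.
#' @param motion_trans_sd,motion_rot_sd per-frame random-walk step SDs of
#'   the motion trace (mm, rad).
#' @param artifact_gain coupling of framewise motion magnitude into the
#'   voxel signal via a smooth spatial gain field.
#' @param tissue_amp amplitude of the tissue-mean (GM/WM/CSF) signals.
#' @param baseline,signal_amp mean volume intensity and node-signal
#'   injection amplitude.
#' @param covariate_model see [default_covariate_model()].
#' @param grid analysis [voxel_grid()] shared by all subjects (common
#'   stereotaxic space); default [default_grid()].
#' @param seed master RNG seed; every subject derives a child seed from it,
#'   so generation is reproducible and independent of evaluation order.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(sites = NULL, targets = NULL, site_offset = NULL,
                        subject_sd = 0.15, band = c(0.01, 0.08),
                        noise_sd = 1, drift_amp = 1,
                        motion_trans_sd = 0.06, motion_rot_sd = 0.0012,
                        artifact_gain = 0.5, tissue_amp = 0.3,
                        baseline = 100, signal_amp = 1,
                        covariate_model = default_covariate_model(),
                        grid = NULL, seed = 1L) {
  sites <- sites %||% list(
    site_spec("aachen", tr = 2.2, n_frames = 250, n_per_group = 30, voxel_size = 3),
    site_spec("goettingen", tr = 2.0, n_frames = 156, n_per_group = 27, voxel_size = 3.1))
  targets <- targets %||% list(isa_default_targets(), control_default_targets())
  if (inherits(targets, "network_targets")) targets <- list(targets)
  site_names <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(site_names)) stopf("duplicate site names")
  if (is.null(site_offset)) {
    site_offset <- stats::setNames(rep(0, length(sites)), site_names)
    if (length(sites) >= 2L) site_offset[1:2] <- c(0.05, -0.05)
  }
  if (is.null(names(site_offset))) names(site_offset) <- site_names
  if (!all(site_names %in% names(site_offset)))
    stopf("site_offset must name every site")
  ab_all <- unlist(lapply(targets, function(tg) node_abbrevs(tg$network)))
  if (anyDuplicated(ab_all)) stopf("node abbrevs must be unique across networks")
  # the requested group targets must be (near-)consistent correlation matrices
  for (tg in targets) {
    for (grp in c("control", "patient"))
      nearest_psd(edge_z_to_corr(atanh(tg[[grp]]), tg$network), proj_tol = 0.05)
  }
  structure(list(sites = sites, targets = targets,
                 site_offset = site_offset[site_names], subject_sd = subject_sd,
                 band = band, noise_sd = noise_sd, drift_amp = drift_amp,
                 motion_trans_sd = motion_trans_sd, motion_rot_sd = motion_rot_sd,
                 artifact_gain = artifact_gain, tissue_amp = tissue_amp,
                 baseline = baseline, signal_amp = signal_amp,
                 covariate_model = covariate_model,
                 grid = grid %||% default_grid(), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Subject roster implied by a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with `subject_id`, `site`, `diagnosis`, `tr`,
#'   `n_frames`, in the canonical generation order.
#' @export
cohort_roster <- function(spec) {
  npg <- vapply(spec$sites, `[[`, integer(1), "n_per_group")
  nm <- vapply(spec$sites, `[[`, character(1), "name")
  tr <- vapply(spec$sites, `[[`, numeric(1), "tr")
  nf <- vapply(spec$sites, `[[`, integer(1), "n_frames")
  total <- sum(2L * npg)
  data.frame(subject_id = sprintf("sub-%03d", seq_len(total)),
             site = rep(nm, times = 2L * npg),
             diagnosis = unlist(lapply(npg, function(k)
               rep(c("patient", "control"), each = k))),
             tr = rep(tr, times = 2L * npg),
             n_frames = rep(nf, times = 2L * npg),
             stringsAsFactors = FALSE)
}

reflect_bound <- function(x, b) {
  r <- (x + b) %% (4 * b)
  ifelse(r < 2 * b, r - b, 3 * b - r)
}

# Rigid-body motion trace: reflected Gaussian random walk, 3 translations
# (mm) and 3 rotations (rad).
motion_trace <- function(n_frames, trans_sd, rot_sd,
                         trans_bound = 1.5, rot_bound = 0.03) {
  steps <- cbind(matrix(stats::rnorm(n_frames * 3, 0, trans_sd), n_frames, 3),
                 matrix(stats::rnorm(n_frames * 3, 0, rot_sd), n_frames, 3))
  walk <- apply(steps, 2L, cumsum)
  walk[, 1:3] <- reflect_bound(walk[, 1:3], trans_bound)
  walk[, 4:6] <- reflect_bound(walk[, 4:6], rot_bound)
  colnames(walk) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  walk
}

#' Geometric tissue masks for the synthetic grid
#'
#' Grey matter: voxels within 10 mm of any network peak (the signal-bearing
#' cortex surrogate); the remaining voxels are split by slice into white
#' matter (lower half) and CSF (upper half). Purely geometric: the synthetic
#' phantom makes no anatomical claim.
#'
#' @param grid a [voxel_grid()].
#' @param networks list of [network_model()]s.
#' @return List of linear-index vectors `gm`, `wm`, `csf`.
#' @export
tissue_masks <- function(grid, networks) {
  if (inherits(networks, "network_model")) networks <- list(networks)
  gm <- sort(unique(unlist(lapply(networks, function(net)
    unlist(lapply(net$nodes, function(v) {
      vv <- v; vv$radius_mm <- 10
      sphere_voxels(vv, grid)
    }))))))
  rest <- setdiff(seq_len(prod(grid$shape)), gm)
  kz <- lin_to_arr(grid, rest)[, 3]
  list(gm = gm, wm = rest[kz <= stats::median(kz)], csf = rest[kz > stats::median(kz)])
}

# Smooth unit-variance spatial gain field for the motion artifact.
gain_field <- function(grid, fwhm_mm = 12) {
  g <- array(stats::rnorm(prod(grid$shape)), dim = grid$shape)
  g <- smooth_gaussian(g, fwhm_mm, grid$voxel_size[1])
  g <- as.numeric(g)
  (g - mean(g)) / stats::sd(g)
}

#' Generate one synthetic subject
#'
#' Deterministic given the spec: subject `i` of the [cohort_roster()] is
#' generated under child seed `i` of the master seed, so single subjects can
#' be (re-)generated in any order, allowing the pipeline to stream large
#' volumetric cohorts one subject at a time.
#'
#' @param spec a [cohort_spec()].
#' @param i roster row index.
#' @param roi_level if `TRUE`, return node-level series (no volumes).
#' @param keep_bold volumetric path: keep the BOLD data in the record.
#' @param flat_bold volumetric path: store the volume as a voxels x frames
#'   matrix (attribute `flat`) instead of a 4-D array; avoids a reshape copy
#'   when streaming through the pipeline.
#' @param masks precomputed [tissue_masks()] (computed if `NULL`).
#' @param roster precomputed [cohort_roster()] (computed if `NULL`).
#' @return A subject record: list with `subject_id`, `site`, `diagnosis`,
#'   `tr`, `bold` (frames x nodes matrix or X x Y x Z x T array), `motion`,
#'   `tissue_means`, `covariates`, `true_z` (per-edge ground-truth Fisher z),
#'   `roi_level`.
#' @export
generate_subject <- function(spec, i, roi_level = FALSE, keep_bold = TRUE,
                             flat_bold = FALSE, masks = NULL, roster = NULL) {
  roster <- roster %||% cohort_roster(spec)
  if (i < 1L || i > nrow(roster)) stopf("roster index out of range")
  row <- roster[i, ]
  nt <- row$n_frames
  tr <- row$tr
  with_seed(child_seed(spec$seed, i), {
    covs <- draw_covariates(spec$covariate_model, row$diagnosis)
    # per-network ground-truth z and latent node signals
    true_z <- numeric(0)
    sig_list <- list()
    for (tg in spec$targets) {
      base <- if (row$diagnosis == "patient") tg$patient else tg$control
      z <- atanh(base) + spec$site_offset[[row$site]] +
        stats::rnorm(length(base), 0, spec$subject_sd)
      names(z) <- names(base)
      true_z <- c(true_z, z)
      R <- edge_z_to_corr(z, tg$network)
      sig_list[[length(sig_list) + 1L]] <- latent_signals(nt, tr, R, spec$band)
    }
    node_sig <- do.call(cbind, sig_list)
    motion <- motion_trace(nt, spec$motion_trans_sd, spec$motion_rot_sd)
    if (roi_level) {
      tissue <- bandpass(matrix(stats::rnorm(nt * 3), nt, 3), tr, c(0, 0.03)) *
        spec$tissue_amp
      colnames(tissue) <- c("gm", "wm", "csf")
      rec <- list(subject_id = row$subject_id, site = row$site,
                  diagnosis = row$diagnosis, tr = tr, bold = node_sig,
                  motion = motion, tissue_means = tissue,
                  covariates = covs, true_z = true_z, roi_level = TRUE)
      return(rec)
    }
    grid <- spec$grid
    masks <- masks %||% tissue_masks(grid, lapply(spec$targets, `[[`, "network"))
    nvox <- prod(grid$shape)
    flat <- matrix(stats::rnorm(nvox * nt, spec$baseline, spec$noise_sd), nvox, nt)
    # node signals into their spheres (rep(..., each=) fills column-major,
    # matching the voxels-by-frames layout without a byrow transpose)
    for (tg in spec$targets) {
      for (nd in tg$network$nodes) {
        vox <- sphere_voxels(nd, grid)
        flat[vox, ] <- flat[vox, ] +
          rep(spec$signal_amp * node_sig[, nd$abbrev], each = length(vox))
      }
    }
    # slow scanner drift (global, below the passband) and tissue-specific
    # slow signals; the tissue masks partition the grid, so both are added
    # in a single pass over each partition
    tt <- seq_len(nt) / nt
    drift <- spec$drift_amp * (stats::rnorm(1) * scale(tt)[, 1] +
                                 stats::rnorm(1) * scale(tt^2)[, 1] +
                                 stats::rnorm(1) * cos(2 * pi * tt + stats::runif(1, 0, 2 * pi)))
    tsig <- bandpass(matrix(stats::rnorm(nt * 3), nt, 3), tr, c(0, 0.03)) * spec$tissue_amp
    for (j in 1:3) {
      vox <- masks[[j]]
      flat[vox, ] <- flat[vox, ] + rep(drift + tsig[, j], each = length(vox))
    }
    # motion-coupled artifact: smooth gain field x framewise motion magnitude
    if (spec$artifact_gain > 0) {
      g <- gain_field(grid)
      fd <- framewise_displacement(motion)$frame
      m_t <- c(0, fd)
      m_t <- m_t - mean(m_t)
      flat <- flat + spec$artifact_gain * tcrossprod(g, m_t)
    }
    M <- Matrix::sparseMatrix(
      i = rep(1:3, lengths(masks)), j = unlist(masks),
      x = rep(1 / lengths(masks), lengths(masks)), dims = c(3L, nvox))
    tmeans <- t(as.matrix(M %*% flat))
    colnames(tmeans) <- c("gm", "wm", "csf")
    bold <- if (!keep_bold) NULL
    else if (flat_bold) structure(flat, grid = grid, flat = TRUE)
    else array(flat, dim = c(grid$shape, nt))
    list(subject_id = row$subject_id, site = row$site, diagnosis = row$diagnosis,
         tr = tr, bold = bold, motion = motion, tissue_means = tmeans,
         covariates = covs, true_z = true_z, roi_level = FALSE)
  })
}

#' Generate a complete synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param roi_level if `TRUE`, subjects carry node-level series directly
#'   (fast path, no volumes).
#' @return Object of class `cohort`: list with `records` (subject records),
#'   `spec`, and `ground_truth` (per-edge group targets/differences on the
#'   z scale plus the per-subject true z matrix).
#' @export
generate_cohort <- function(spec, roi_level = FALSE) {
  roster <- cohort_roster(spec)
  masks <- if (!roi_level) tissue_masks(spec$grid, lapply(spec$targets, `[[`, "network"))
  records <- lapply(seq_len(nrow(roster)), function(i)
    generate_subject(spec, i, roi_level = roi_level, masks = masks,
                     roster = roster))
  truth <- ground_truth(spec, records)
  structure(list(records = records, spec = spec, ground_truth = truth),
            class = "cohort")
}

#' @rdname generate_cohort
#' @export
generate_roi_cohort <- function(spec) generate_cohort(spec, roi_level = TRUE)

ground_truth <- function(spec, records) {
  targets <- do.call(rbind, lapply(spec$targets, function(tg)
    data.frame(network = tg$network$name, edge = names(tg$control),
               z_control = atanh(tg$control), z_patient = atanh(tg$patient),
               delta_true = atanh(tg$patient) - atanh(tg$control),
               row.names = NULL, stringsAsFactors = FALSE)))
  subj_z <- do.call(rbind, lapply(records, `[[`, "true_z"))
  rownames(subj_z) <- vapply(records, `[[`, character(1), "subject_id")
  list(targets = targets, subject_true_z = subj_z)
}

#' @export
print.cohort <- function(x, ...) {
  r <- cohort_roster(x$spec)
  cat(sprintf("<cohort> %d subjects (%s), %s\n", nrow(r),
              paste(sprintf("%s: %d+%d", unique(r$site),
                            tapply(r$diagnosis == "patient", r$site, sum)[unique(r$site)],
                            tapply(r$diagnosis == "control", r$site, sum)[unique(r$site)]),
                    collapse = "; "),
              if (x$records[[1]]$roi_level) "ROI-level" else "volumetric"))
  invisible(x)
}

#' Calibrate the measured Fisher-z dispersion of the generator
#'
#' Monte-Carlo estimate of the between-subject SD of measured edge z values
#' under the generator + preprocessing pipeline at a given operating point.
#' Used to translate a standardized group difference d into a planted z
#' shift: `delta_z = d * calibrate_z_sd(...)`.
#'
#' @param tr,n_frames acquisition parameters of the simulated site.
#' @param r operating-point correlation target.
#' @param subject_sd per-subject z random-effect SD.
#' @param band latent passband, Hz.
#' @param preproc a [preproc_config()] applied before measuring (NULL =
#'   correlate the generated series directly).
#' @param n_cal calibration subjects.
#' @param seed RNG seed.
#' @return Estimated SD of measured z.
#' @export
calibrate_z_sd <- function(tr = 2.0, n_frames = 154, r = 0.3, subject_sd = 0.15,
                           band = c(0.01, 0.08), preproc = preproc_config(),
                           n_cal = 600, seed = 1L) {
  calibrate_effect(1, tr = tr, n_frames = n_frames, r = r,
                   subject_sd = subject_sd, band = band, preproc = preproc,
                   n_cal = n_cal, seed = seed)$sd
}

#' Calibrate a planted standardized group difference
#'
#' Translates a target standardized difference d of *measured* edge z values
#' into the latent Fisher-z shift the generator must plant. Monte-Carlo with
#' common random numbers: each calibration subject is measured twice — at
#' the reference correlation and at a shifted one — on the same latent
#' noise, motion and tissue draws, so the measured-scale response to a
#' latent shift (slope) is estimated with negligible variance. The returned
#' shift is `d * sd / slope`, correcting the small inflation the
#' sample-correlation estimator introduces on the measured scale.
#'
#' @inheritParams calibrate_z_sd
#' @param d target standardized difference on the measured scale.
#' @return List with `delta` (latent z shift to plant), `sd` (between-subject
#'   SD of measured z), and `slope` (measured change per unit latent shift).
#' @export
calibrate_effect <- function(d, tr = 2.0, n_frames = 154, r = 0.3,
                             subject_sd = 0.15, band = c(0.01, 0.08),
                             preproc = preproc_config(), n_cal = 600, seed = 1L) {
  z0 <- atanh(r)
  delta0 <- max(0.05, abs(d)) * 0.25 # probe shift; result is slope-scaled
  zz <- vapply(seq_len(n_cal), function(i) {
    with_seed(child_seed(seed, i), {
      e <- stats::rnorm(1, 0, subject_sd)
      f <- matrix(stats::rnorm(n_frames * 2), n_frames, 2)
      f <- standardize_cols(bandpass(f, tr, band))
      motion <- tissue <- NULL
      if (!is.null(preproc)) {
        motion <- motion_trace(n_frames, 0.06, 0.0012)
        tissue <- bandpass(matrix(stats::rnorm(n_frames * 3), n_frames, 3), tr,
                           c(0, 0.03))
      }
      vapply(c(z0 + e, z0 + e + delta0), function(z) {
        rho <- tanh(z)
        y <- cbind(f[, 1], rho * f[, 1] + sqrt(1 - rho^2) * f[, 2])
        if (!is.null(preproc))
          y <- preprocess_node_series(y, motion, tissue, tr, preproc)
        atanh(stats::cor(y[, 1], y[, 2]))
      }, numeric(1))
    })
  }, numeric(2))
  sd0 <- stats::sd(zz[1, ])
  slope <- mean(zz[2, ] - zz[1, ]) / delta0
  list(delta = d * sd0 / slope, sd = sd0, slope = slope)
}

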