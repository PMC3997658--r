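#' DVARS: RMS frame-to-frame intensity change
#'
#' The whole series is first rescaled so that the in-mask mean intensity
#' over all frames equals 100 (so values are comparable across scalings);
#' then `DVARS_t = sqrt(mean_mask((I_t - I_(t-1))^2))` for `t >= 2`.
#'
#' @param bold X x Y x Z x T array or voxels x frames matrix.
#' @param mask optional logical array/vector selecting in-mask voxels
#'   (default: all voxels).
#' @return List with `frame` (length frames - 1) and `mean`.
#' @export
dvars <- function(bold, mask = NULL) {
  if (is.array(bold) && length(dim(bold)) == 4L)
    bold <- matrix(bold, prod(dim(bold)[1:3]), dim(bold)[4])
  bold <- as.matrix(bold)
  if (ncol(bold) < 2L) stopf("need >= 2 frames for DVARS")
  if (!is.null(mask)) {
    keep <- which(as.logical(mask))
    if (length(keep) == 0L) stopf("empty mask")
    bold <- bold[keep, , drop = FALSE]
  }
  m <- mean(bold)
  if (abs(m) < 1e-12) stopf("in-mask mean intensity is ~0; cannot rescale to 100")
  bold <- bold * (100 / m)
  d <- bold[, -1L, drop = FALSE] - bold[, -ncol(bold), drop = FALSE]
  fr <- sqrt(colMeans(d^2))
  list(frame = as.numeric(fr), mean = mean(fr))
}

check_motion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stopf("motion trace must have 6 columns, got %d", ncol(motion))
  if (nrow(motion) < 2L) stopf("need >= 2 frames")
  motion
}

#' Framewise displacement (FD)
#'
#' Power-style scalar head-motion per frame transition:
#' `FD_t = sum(|delta translations|) + head_radius * sum(|delta rotations|)`,
#' translations in mm, rotations in radians converted to arc length at
#' `head_radius` mm.
#'
#' @param motion frames x 6 matrix (tx, ty, tz mm; rx, ry, rz rad).
#' @param head_radius sphere radius for rotation-to-mm conversion (mm).
#' @return List with `frame` (length frames - 1) and `mean`.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- check_motion(motion)
  d <- diff(motion)
  fr <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    head_radius * rowSums(abs(d[, 4:6, drop = FALSE]))
  list(frame = as.numeric(fr), mean = mean(fr))
}

#' RMS motion per frame
#'
#' Root-mean-square of the six frame-to-frame displacement deltas, with
#' rotations converted to mm at `head_radius`:
#' `RMS_t = sqrt(mean(c(dt, head_radius * dr)^2))`. This is a documented
#' package convention for a scalar RMS displacement summary (the literature
#' uses several variants); the formula used is recorded in pipeline
#' manifests.
#'
#' @inheritParams framewise_displacement
#' @return List with `frame` (length frames - 1) and `mean`.
#' @export
rms_motion <- function(motion, head_radius = 50) {
  motion <- check_motion(motion)
  d <- diff(motion)
  d[, 4:6] <- d[, 4:6] * head_radius
  fr <- sqrt(rowMeans(d^2))
  list(frame = as.numeric(fr), mean = mean(fr))
}

#' Per-subject motion/quality summary table
#'
#' @param records list of subject records (see [generate_cohort()]); DVARS is
#'   computed only for volumetric records (NA otherwise).
#' @param mask optional mask for DVARS.
#' @return Data frame with one row per subject: `subject_id`, `site`,
#'   `diagnosis`, `dvars_mean`, `fd_mean`, `rms_mean`.
#' @export
motion_summary <- function(records, mask = NULL) {
  rows <- lapply(records, function(rec) {
    dv <- if (!is.null(rec$bold) && is.array(rec$bold) && length(dim(rec$bold)) == 4L)
      dvars(rec$bold, mask)$mean else NA_real_
    data.frame(subject_id = rec$subject_id, site = rec$site,
               diagnosis = rec$diagnosis,
               dvars_mean = dv,
               fd_mean = framewise_displacement(rec$motion)$mean,
               rms_mean = rms_motion(rec$motion)$mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare motion metrics across groups, overall and per site
#'
#' For each metric (DVARS, FD, RMS) and each stratum (entire sample, then
#' each site), reports group means/SDs and two-sided Welch t-test and
#' Wilcoxon rank-sum p-values, the layout used for motion QC tables.
#'
#' @param summaries data frame from [motion_summary()].
#' @param group_col,levels grouping column and its two levels (case first).
#' @return Data frame with one row per metric x stratum.
#' @export
compare_motion <- function(summaries, group_col = "diagnosis",
                           levels = c("patient", "control")) {
  metrics <- c(dvars = "dvars_mean", fd = "fd_mean", rms = "rms_mean")
  strata <- c("entire", sort(unique(as.character(summaries$site))))
  out <- list()
  for (mn in names(metrics)) {
    col <- metrics[[mn]]
    if (all(is.na(summaries[[col]]))) next
    for (st in strata) {
      sub <- if (st == "entire") summaries else summaries[summaries$site == st, ]
      a <- sub[[col]][sub[[group_col]] == levels[1]]
      b <- sub[[col]][sub[[group_col]] == levels[2]]
      if (length(a) < 2L || length(b) < 2L) stopf("degenerate cell in stratum '%s'", st)
      tt <- stats::t.test(a, b)$p.value
      wt <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      out[[length(out) + 1L]] <- data.frame(
        metric = mn, stratum = st,
        case_mean = mean(a), case_sd = stats::sd(a),
        ref_mean = mean(b), ref_sd = stats::sd(b),
        p_ttest = tt, p_ranksum = wt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
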