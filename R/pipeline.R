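#' Pipeline run configuration
#'
#' Exactly one input mode: synthetic (a [cohort_spec()]) or file paths (a
#' directory written by [write_cohort()] or laid out the same way).
#'
#' @param cohort_spec a [cohort_spec()] for synthetic mode.
#' @param paths directory containing a cohort on disk (file mode).
#' @param networks list of [network_model()]s to analyse; defaults to the
#'   networks of the cohort spec (synthetic mode) or the built-in ISA +
#'   control networks (file mode).
#' @param roi_level synthetic mode: generate node-level records (fast path)
#'   instead of volumes.
#' @param preproc a [preproc_config()].
#' @param inference an [inference_config()].
#' @param gm_mask optional inclusion mask for sphere extraction.
#' @param restrict_smoothing volumetric fast path: evaluate the smoothing
#'   kernel only at sphere voxels (algebraically identical to full-volume
#'   smoothing followed by subsetting) and run nuisance regression and
#'   filtering on those voxels only.
#' @param clinical,qc toggles for the clinical subgroup/correlation analyses
#'   and the motion QC table.
#' @param out_dir if non-NULL, result tables and a manifest are written here.
#' @param case,ref diagnosis labels contrasted (case minus ref).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort_spec = NULL, paths = NULL, networks = NULL,
                       roi_level = FALSE, preproc = preproc_config(),
                       inference = inference_config(), gm_mask = NULL,
                       restrict_smoothing = TRUE, clinical = TRUE, qc = TRUE,
                       out_dir = NULL, case = "patient", ref = "control") {
  if (is.null(cohort_spec) == is.null(paths))
    stopf("exactly one of cohort_spec (synthetic) or paths (file mode) must be given")
  structure(list(cohort_spec = cohort_spec, paths = paths, networks = networks,
                 roi_level = isTRUE(roi_level), preproc = preproc,
                 inference = inference, gm_mask = gm_mask,
                 restrict_smoothing = isTRUE(restrict_smoothing),
                 clinical = isTRUE(clinical), qc = isTRUE(qc),
                 out_dir = out_dir, case = case, ref = ref),
            class = "run_config")
}

# Preprocess + extract node series for one subject record; returns
# frames x nodes matrix over all networks' nodes plus a QC row.
process_record <- function(rec, networks, config, sphere_sets = NULL, W = NULL,
                           grid = NULL) {
  pp <- config$preproc
  qc_row <- NULL
  if (config$qc) {
    dv <- if (!rec$roi_level) dvars(flatten_bold(rec$bold))$mean else NA_real_
    qc_row <- data.frame(subject_id = rec$subject_id, site = rec$site,
                         diagnosis = rec$diagnosis, dvars_mean = dv,
                         fd_mean = framewise_displacement(rec$motion)$mean,
                         rms_mean = rms_motion(rec$motion)$mean,
                         stringsAsFactors = FALSE)
  }
  if (rec$roi_level) {
    series <- preprocess_node_series(rec$bold, rec$motion, rec$tissue_means,
                                     rec$tr, pp)
    node_series <- do.call(cbind, lapply(networks, function(net)
      extract_node_series(series, net)))
  } else {
    if (is.null(grid)) stopf("volumetric record but no grid available")
    flat <- flatten_bold(rec$bold)
    if (pp$n_discard > 0) flat <- flat[, -seq_len(pp$n_discard), drop = FALSE]
    motion <- discard_initial(as.matrix(rec$motion), pp$n_discard)
    tissue <- discard_initial(as.matrix(rec$tissue_means), pp$n_discard)
    nt <- ncol(flat)
    X <- suppressWarnings(build_nuisance(motion, tissue, pp$nuisance_order))
    if (pp$filter_nuisance) {
      nonint <- colnames(X) != "intercept"
      X[, nonint] <- bandpass(X[, nonint, drop = FALSE], rec$tr, pp$band)
    }
    if (config$restrict_smoothing) {
      sm <- as.matrix(W %*% flat)              # needed voxels x frames
      series <- t(sm)                          # frames x needed voxels
      series <- regress_out(series, X)
      series <- bandpass(series, rec$tr, pp$band)
      cols <- lapply(networks, function(net) {
        out <- matrix(NA_real_, nt, length(net$nodes),
                      dimnames = list(NULL, node_abbrevs(net)))
        for (nd in seq_along(net$nodes)) {
          pos <- sphere_sets[[net$name]]$pos[[nd]]
          out[, nd] <- first_eigenvariate(t(series[, pos, drop = FALSE]))
        }
        out
      })
      node_series <- do.call(cbind, cols)
    } else {
      arr <- array(flat, dim = c(grid$shape, nt))
      arr <- smooth_gaussian(arr, pp$fwhm, grid$voxel_size[1])
      series <- t(matrix(arr, prod(grid$shape), nt))
      series <- regress_out(series, X)
      series <- bandpass(series, rec$tr, pp$band)
      arr <- array(t(series), dim = c(grid$shape, nt))
      node_series <- do.call(cbind, lapply(networks, function(net)
        extract_node_series(arr, net, grid, config$gm_mask)))
    }
  }
  list(node_series = node_series, qc = qc_row)
}

flatten_bold <- function(bold) {
  if (is.matrix(bold)) return(bold) # already voxels x frames
  d <- dim(bold)
  matrix(bold, prod(d[1:3]), d[4])
}

#' Run the full analysis pipeline
#'
#' Executes generate/ingest, preprocessing, VOI extraction, edge
#' connectivity, site adjustment, permutation group inference, clinical
#' analyses and motion QC, per network. With a fixed configuration and seed
#' the result tables are byte-identical across runs.
#'
#' @param config a [run_config()].
#' @return A run report: list with `edge_tables` (raw), `adjusted_tables`,
#'   `results` (per network [test_edges()] output), `clinical`, `qc`,
#'   `covariates`, `manifest`, and `files` when `out_dir` was set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must come from run_config()")
  synthetic <- !is.null(config$cohort_spec)
  if (synthetic) {
    spec <- config$cohort_spec
    roster <- cohort_roster(spec)
    networks <- config$networks %||% lapply(spec$targets, `[[`, "network")
    grid <- spec$grid
    masks <- if (!config$roi_level) tissue_masks(grid, networks)
    get_record <- function(i) generate_subject(spec, i, roi_level = config$roi_level,
                                               flat_bold = config$restrict_smoothing,
                                               masks = masks, roster = roster)
  } else {
    cohort <- read_cohort(config$paths)
    roster <- do.call(rbind, lapply(cohort$records, function(r)
      data.frame(subject_id = r$subject_id, site = r$site, diagnosis = r$diagnosis,
                 stringsAsFactors = FALSE)))
    networks <- config$networks %||% list(load_network("isa"), load_network("control"))
    grid <- cohort$grid
    get_record <- function(i) cohort$records[[i]]
  }
  volumetric <- if (synthetic) !config$roi_level else {
    r1 <- get_record(1)
    !isTRUE(r1$roi_level)
  }
  sphere_sets <- NULL
  W <- NULL
  if (volumetric && config$restrict_smoothing) {
    sphere_sets <- list()
    needed <- integer(0)
    for (net in networks) {
      vox <- lapply(net$nodes, sphere_voxels, grid = grid, mask = config$gm_mask)
      empty <- lengths(vox) == 0L
      if (any(empty))
        stopf("node '%s': sphere contains no voxels after masking",
              node_abbrevs(net)[which(empty)[1]])
      sphere_sets[[net$name]] <- list(vox = vox)
      needed <- c(needed, unlist(vox))
    }
    needed <- sort(unique(needed))
    for (net in networks) {
      sphere_sets[[net$name]]$pos <-
        lapply(sphere_sets[[net$name]]$vox, match, table = needed)
    }
    W <- sphere_smooth_weights(grid, needed, config$preproc$fwhm, grid$voxel_size)
  }
  n_sub <- nrow(roster)
  series_list <- vector("list", n_sub)
  qc_rows <- vector("list", n_sub)
  cov_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    rec <- get_record(i)
    pr <- tryCatch(process_record(rec, networks, config, sphere_sets, W, grid),
                   error = function(e) stopf("subject %s: %s", rec$subject_id,
                                             conditionMessage(e)))
    series_list[[i]] <- pr$node_series
    qc_rows[[i]] <- pr$qc
    cov_rows[[i]] <- if (!is.null(rec$covariates))
      cbind(data.frame(subject_id = rec$subject_id, site = rec$site,
                       diagnosis = rec$diagnosis, stringsAsFactors = FALSE),
            as.data.frame(rec$covariates, stringsAsFactors = FALSE))
  }
  covariates <- if (!all(vapply(cov_rows, is.null, logical(1))))
    do.call(rbind, cov_rows)
  meta <- roster[c("subject_id", "site", "diagnosis")]
  multi_site <- length(unique(meta$site)) > 1L
  edge_tables <- list(); adjusted <- list(); results <- list(); clinical <- list()
  for (net in networks) {
    z_rows <- t(vapply(series_list, function(s) {
      fisher_z(edge_correlations(s, net))
    }, numeric(nrow(net$edges))))
    if (nrow(net$edges) == 1L) z_rows <- matrix(z_rows, ncol = 1L)
    colnames(z_rows) <- net$edges$label
    tab <- build_edge_table(z_rows, meta, net)
    edge_tables[[net$name]] <- tab
    adj <- if (multi_site) remove_site_effects(tab, levels = c(config$case, config$ref))
    else tab
    adjusted[[net$name]] <- adj
    results[[net$name]] <- test_edges(adj, config$inference,
                                      case = config$case, ref = config$ref)
    if (config$clinical && !is.null(covariates))
      clinical[[net$name]] <- clinical_analyses(adj, covariates, config)
  }
  qc <- NULL
  if (config$qc) {
    qc_tab <- do.call(rbind, qc_rows)
    qc <- list(subjects = qc_tab,
               comparison = compare_motion(qc_tab, levels = c(config$case, config$ref)))
  }
  manifest <- list(
    mode = if (synthetic) "synthetic" else "paths",
    seed = if (synthetic) config$cohort_spec$seed else NA,
    n_subjects = n_sub,
    networks = vapply(networks, `[[`, character(1), "name"),
    n_perm = config$inference$n_perm, alpha = config$inference$alpha,
    tail = config$inference$tail, fdr_method = config$inference$fdr_method,
    preproc = unclass(config$preproc),
    site_adjusted = multi_site,
    motion_metrics = list(
      fd = "sum |d trans| + 50 mm * sum |d rot|",
      rms = "sqrt(mean(c(d trans, 50 mm * d rot)^2))",
      dvars = "rms over voxels of frame difference, series rescaled to mean 100"),
    version = as.character(utils::packageVersion("rsfcnet")))
  manifest$config_hash <- config_hash(manifest)
  report <- list(edge_tables = edge_tables, adjusted_tables = adjusted,
                 results = results, clinical = clinical, qc = qc,
                 covariates = covariates, manifest = manifest)
  if (!is.null(config$out_dir)) report$files <- write_report(report, config$out_dir)
  report
}

clinical_analyses <- function(adj_table, covariates, config) {
  pat <- adj_table[adj_table$diagnosis == config$case, , drop = FALSE]
  for (a in c("edges", "network", "stage")) attr(pat, a) <- attr(adj_table, a)
  cv <- covariates[match(pat$subject_id, covariates$subject_id), ]
  out <- list()
  for (v in c("duration", "onset_age")) {
    if (!v %in% names(cv)) next
    sp <- tryCatch(median_split(cv[[v]], ids = pat$subject_id, variable = v),
                   error = function(e) NULL)
    if (is.null(sp)) next
    out[[v]] <- list(split = sp,
                     results = subgroup_comparison(pat, sp, config$inference))
  }
  if ("bdi" %in% names(cv) && !anyNA(cv$bdi) && stats::sd(cv$bdi) > 1e-12)
    out$bdi <- symptom_correlation(pat, cv$bdi, config$inference)
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  for (nm in names(report$edge_tables)) {
    wt(report$edge_tables[[nm]], sprintf("edges_raw_%s.tsv", nm))
    wt(report$adjusted_tables[[nm]], sprintf("edges_adjusted_%s.tsv", nm))
    wt(report$results[[nm]], sprintf("results_%s.tsv", nm))
    cl <- report$clinical[[nm]]
    if (!is.null(cl)) {
      for (v in intersect(c("duration", "onset_age"), names(cl))) {
        wt(cl[[v]]$results, sprintf("subgroup_%s_%s.tsv", nm, v))
        sp <- cl[[v]]$split
        jp <- file.path(out_dir, sprintf("split_%s_%s.json", nm, v))
        jsonlite::write_json(list(variable = sp$variable, threshold = sp$threshold,
                                  n_high = length(sp$high_ids), n_low = length(sp$low_ids),
                                  excluded = sp$excluded_ids),
                             jp, auto_unbox = TRUE, digits = NA)
        files <- c(files, jp)
      }
      if (!is.null(cl$bdi)) wt(cl$bdi, sprintf("symptom_corr_%s.tsv", nm))
    }
  }
  if (!is.null(report$qc)) {
    wt(report$qc$subjects, "qc_subjects.tsv")
    utils::write.csv(report$qc$comparison, file.path(out_dir, "qc_comparison.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(out_dir, "qc_comparison.csv"))
  }
  if (!is.null(report$covariates)) wt(report$covariates, "covariates.tsv")
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, mp)
}

# ---- cohort file I/O ------------------------------------------------------

subject_stub <- function(rec) sprintf("%s_site-%s", rec$subject_id, rec$site)

#' Write a synthetic cohort to disk
#'
#' Standard flat layout: per subject a NIfTI BOLD volume (volumetric
#' records) or node-series TSV (ROI-level), a 6-column motion TSV
#' (tx, ty, tz, rx, ry, rz) and a tissue-means TSV; cohort-level
#' `covariates.csv`, `grid.json` and `ground_truth.json`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$spec$grid
  for (rec in cohort$records) {
    stub <- subject_stub(rec)
    utils::write.table(as.data.frame(rec$motion),
                       file.path(dir, paste0(stub, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(rec$tissue_means),
                       file.path(dir, paste0(stub, "_tissue.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (rec$roi_level) {
      utils::write.table(as.data.frame(rec$bold),
                         file.path(dir, paste0(stub, "_node-series.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      im <- RNifti::asNifti(rec$bold)
      a0 <- grid$affine
      a0[1:3, 4] <- a0[1:3, 4] + a0[1:3, 1:3] %*% rep(1, 3) # 0-based convention
      im <- RNifti::`sform<-`(im, structure(a0, code = 2L))
      RNifti::writeNifti(im, file.path(dir, paste0(stub, "_task-rest_bold.nii.gz")))
    }
  }
  meta <- do.call(rbind, lapply(cohort$records, function(r)
    cbind(data.frame(subject_id = r$subject_id, site = r$site, diagnosis = r$diagnosis,
                     tr = r$tr, roi_level = r$roi_level, stringsAsFactors = FALSE),
          as.data.frame(r$covariates, stringsAsFactors = FALSE))))
  utils::write.csv(meta, file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(list(shape = grid$shape, affine = grid$affine),
                       file.path(dir, "grid.json"), digits = NA, matrix = "rowmajor")
  gt <- cohort$ground_truth
  jsonlite::write_json(list(targets = gt$targets,
                            subject_true_z = as.data.frame(gt$subject_true_z)),
                       file.path(dir, "ground_truth.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()].
#'
#' @param dir cohort directory.
#' @return List with `records` and `grid` (NULL for ROI-level cohorts).
#' @export
read_cohort <- function(dir) {
  cov_path <- file.path(dir, "covariates.csv")
  if (!file.exists(cov_path)) stopf("no covariates.csv under %s", dir)
  meta <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  grid <- NULL
  gpath <- file.path(dir, "grid.json")
  if (file.exists(gpath)) {
    gj <- jsonlite::fromJSON(gpath)
    grid <- voxel_grid(gj$shape, affine = as.matrix(gj$affine))
  }
  records <- lapply(seq_len(nrow(meta)), function(i) {
    r <- meta[i, ]
    stub <- sprintf("%s_site-%s", r$subject_id, r$site)
    motion <- as.matrix(utils::read.delim(file.path(dir, paste0(stub, "_motion.tsv"))))
    tissue <- as.matrix(utils::read.delim(file.path(dir, paste0(stub, "_tissue.tsv"))))
    roi <- isTRUE(r$roi_level)
    bold <- if (roi) {
      as.matrix(utils::read.delim(file.path(dir, paste0(stub, "_node-series.tsv"))))
    } else {
      p <- file.path(dir, paste0(stub, "_task-rest_bold.nii.gz"))
      if (!file.exists(p)) stopf("missing BOLD volume for subject %s", r$subject_id)
      arr <- as.array(RNifti::readNifti(p))
      arr
    }
    covs <- as.list(r[setdiff(names(r), c("subject_id", "site", "diagnosis",
                                          "tr", "roi_level"))])
    list(subject_id = r$subject_id, site = r$site, diagnosis = r$diagnosis,
         tr = r$tr, bold = bold, motion = motion, tissue_means = tissue,
         covariates = covs, roi_level = roi)
  })
  list(records = records, grid = grid)
}

#' Validate an on-disk cohort
#'
#' Checks file readability, frame-count consistency between BOLD, motion and
#' tissue series, and covariate completeness; returns an issue table instead
#' of raising.
#'
#' @param dir cohort directory.
#' @return Data frame with columns `subject_id` and `issue` (zero rows when
#'   everything is consistent).
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  add <- function(id, msg) issues[[length(issues) + 1L]] <<-
    data.frame(subject_id = id, issue = msg, stringsAsFactors = FALSE)
  cov_path <- file.path(dir, "covariates.csv")
  if (!file.exists(cov_path)) {
    add("-", "missing covariates.csv")
  } else {
    meta <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(meta))) {
      r <- meta[i, ]
      id <- r$subject_id %||% sprintf("row %d", i)
      if (is.na(r$diagnosis) || !nzchar(r$diagnosis)) add(id, "missing diagnosis")
      if (is.null(r$site) || is.na(r$site)) add(id, "missing site")
      stub <- sprintf("%s_site-%s", r$subject_id, r$site)
      mfile <- file.path(dir, paste0(stub, "_motion.tsv"))
      nb <- NA_integer_
      roi <- isTRUE(r$roi_level)
      bfile <- file.path(dir, paste0(stub, if (roi) "_node-series.tsv"
                                     else "_task-rest_bold.nii.gz"))
      if (!file.exists(bfile)) {
        add(id, "missing BOLD data")
      } else {
        nb <- if (roi) nrow(utils::read.delim(bfile))
        else rev(dim(RNifti::readNifti(bfile)))[1]
      }
      if (!file.exists(mfile)) {
        add(id, "missing motion trace")
      } else if (!is.na(nb)) {
        nm <- nrow(utils::read.delim(mfile))
        if (nm != nb) add(id, sprintf("frame mismatch: BOLD %d vs motion %d", nb, nm))
      }
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(subject_id = character(0), issue = character(0))
}
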