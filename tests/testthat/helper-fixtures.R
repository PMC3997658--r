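# Shared fixtures: small networks, grids and cohort specs built in code.

two_node_network <- function() {
  network_model("pair", list(voi("A", peak_mni = c(0, 0, 0)),
                             voi("B", peak_mni = c(21, 0, 0))))
}

small_grid <- function(n = 21, vs = 3) {
  half <- (n - 1) / 2 * vs
  voxel_grid(c(n, n, n), voxel_size = vs, origin = c(-half, -half, -half))
}

# Fast ROI-level spec: one or two small sites on the ISA network.
tiny_spec <- function(n_per_group = 3, sites = 2, n_frames = 80, seed = 1,
                      targets = isa_default_targets(), ...) {
  sl <- list(site_spec("siteA", tr = 2.2, n_frames = n_frames, n_per_group = n_per_group))
  if (sites >= 2)
    sl <- c(sl, list(site_spec("siteB", tr = 2.0, n_frames = n_frames,
                               n_per_group = n_per_group)))
  cohort_spec(sites = sl, targets = targets, seed = seed, ...)
}

# Edge table straight from ROI-level records (no preprocessing).
table_from_cohort <- function(cohort, network) {
  z <- t(vapply(cohort$records, function(r)
    fisher_z(edge_correlations(r$bold, network)), numeric(nrow(network$edges))))
  colnames(z) <- network$edges$label
  meta <- data.frame(
    subject_id = vapply(cohort$records, `[[`, character(1), "subject_id"),
    site = vapply(cohort$records, `[[`, character(1), "site"),
    diagnosis = vapply(cohort$records, `[[`, character(1), "diagnosis"),
    stringsAsFactors = FALSE)
  build_edge_table(z, meta, network)
}
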