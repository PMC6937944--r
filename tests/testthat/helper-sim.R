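# Small simulation configurations shared across tests. Depth means keep the
# one-decade class separation of the full-size defaults only where a test
# needs the classification bands; most tests run far below that scale.

tiny_profiles <- function(n_genes = 40, cell_types = c("alpha", "beta"),
                          n_mt_genes = 4, markers_per_type = 4,
                          marker_mass = 0.5) {
  make_cell_type_profiles(n_genes = n_genes, cell_types = cell_types,
                          n_mt_genes = n_mt_genes,
                          markers_per_type = markers_per_type,
                          marker_mass = marker_mass)
}

tiny_config <- function(n_donors = 2, tissues = "spleen",
                        time_points_h = c(0, 72), n_cells = 150,
                        n_debris = 0, n_ambient = 0, n_genes = 40,
                        mean_umis = 800, degradation = degradation_params(),
                        seed = 42L, ...) {
  sim_config(n_donors = n_donors, tissues = tissues,
             time_points_h = time_points_h,
             n_cells_per_sample = n_cells, n_debris_droplets = n_debris,
             n_ambient_droplets = n_ambient, n_genes = n_genes,
             cell_type_profiles = tiny_profiles(n_genes = n_genes),
             mean_umis_per_cell = mean_umis,
             mean_umis_per_debris = mean_umis / 50,
             mean_umis_per_ambient = max(mean_umis / 500, 1.5),
             degradation = degradation, seed = seed, ...)
}

# collect one sample's cell-droplet covariates with truth cell types
cells_from_sample <- function(s, keep_class = "cell") {
  tr <- s$truth$droplets
  sel <- tr$class %in% keep_class
  cov <- cell_covariates(s$droplets$counts[, sel, drop = FALSE])
  cov$cell_type <- tr$cell_type[sel]
  cov$sample_id <- s$metadata$sample_id
  cov$donor <- s$metadata$donor
  cov$tissue <- s$metadata$tissue
  cov$time_h <- s$metadata$time_h
  cov
}

cells_from_experiment <- function(exp, keep_class = "cell") {
  out <- do.call(rbind, lapply(exp$samples, cells_from_sample,
                               keep_class = keep_class))
  rownames(out) <- NULL
  out
}
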