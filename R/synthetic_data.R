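#' Degradation parameters for the synthetic generator
#'
#' Encodes the storage-time effects the generator can inject: multiplicative
#' inflation of the mitochondrial fraction per (tissue, cell type, time),
#' an additive shift of the intronic read fraction per (tissue, time) taken
#' out of the exonic fraction, a target share of total run UMIs held by
#' ambient droplets per (tissue, time), and a set of storage-signature genes
#' whose expression is scaled with time. Calling with no arguments gives the
#' null mode: every factor 1, every shift 0 at all times.
#'
#' @param mt_fold_change data.frame with columns `tissue`, `cell_type`,
#'   `time_h`, `fold` (fold > 0). `"*"` wildcards tissue or cell type.
#' @param intron_shift data.frame with columns `tissue`, `time_h`, `shift`
#'   (shift in `[0, 1)`, added to the intronic fraction and removed from the
#'   exonic fraction).
#' @param ambient_umi_fraction data.frame with columns `tissue`, `time_h`,
#'   `fraction` in `[0, 1)`: the target fraction of the run's total UMIs held
#'   by ambient droplets. When a (tissue, time) has no entry the ambient
#'   depth comes from `mean_umis_per_ambient` instead.
#' @param signature_genes integer indices (into the gene universe) of
#'   storage-signature genes.
#' @param signature_fold data.frame with columns `time_h`, `fold`: factor
#'   applied to the expression-profile mass of the signature genes at that
#'   time (profiles are renormalized afterwards).
#' @return object of class `degradation_params`.
#' @export
degradation_params <- function(mt_fold_change = NULL, intron_shift = NULL,
                               ambient_umi_fraction = NULL,
                               signature_genes = integer(0),
                               signature_fold = NULL) {
  if (!is.null(mt_fold_change)) {
    stopifnot(all(c("tissue", "cell_type", "time_h", "fold") %in%
                    names(mt_fold_change)))
    if (any(mt_fold_change$fold <= 0)) {
      stop("degradation field 'mt_fold_change': folds must be > 0")
    }
    if (any(mt_fold_change$time_h == 0 & mt_fold_change$fold != 1)) {
      stop("degradation field 'mt_fold_change': fold must be 1 at time 0")
    }
  }
  if (!is.null(intron_shift)) {
    stopifnot(all(c("tissue", "time_h", "shift") %in% names(intron_shift)))
    if (any(intron_shift$shift < 0 | intron_shift$shift >= 1)) {
      stop("degradation field 'intron_shift': shifts must lie in [0, 1)")
    }
    if (any(intron_shift$time_h == 0 & intron_shift$shift != 0)) {
      stop("degradation field 'intron_shift': shift must be 0 at time 0")
    }
  }
  if (!is.null(ambient_umi_fraction)) {
    stopifnot(all(c("tissue", "time_h", "fraction") %in%
                    names(ambient_umi_fraction)))
    if (any(ambient_umi_fraction$fraction < 0 |
            ambient_umi_fraction$fraction >= 1)) {
      stop("degradation field 'ambient_umi_fraction': fractions must lie in [0, 1)")
    }
  }
  if (!is.null(signature_fold)) {
    stopifnot(all(c("time_h", "fold") %in% names(signature_fold)))
    if (any(signature_fold$fold <= 0)) {
      stop("degradation field 'signature_fold': folds must be > 0")
    }
    if (any(signature_fold$time_h == 0 & signature_fold$fold != 1)) {
      stop("degradation field 'signature_fold': fold must be 1 at time 0")
    }
  }
  structure(list(mt_fold_change = mt_fold_change,
                 intron_shift = intron_shift,
                 ambient_umi_fraction = ambient_umi_fraction,
                 signature_genes = as.integer(signature_genes),
                 signature_fold = signature_fold),
            class = "degradation_params")
}

#' Default degradation emulating the reported spleen-only 72-hour effects
#'
#' Mitochondrial fraction doubled and intronic fraction shifted up by 0.10 in
#' every spleen cell type at 72 h; lung and esophagus left stable at all
#' times, matching the observation that degradation was confined to the
#' spleen at the last time point.
#'
#' @return a `degradation_params` object.
#' @export
default_degradation <- function() {
  degradation_params(
    mt_fold_change = data.frame(tissue = "spleen", cell_type = "*",
                                time_h = 72, fold = 2),
    intron_shift = data.frame(tissue = "spleen", time_h = 72, shift = 0.10)
  )
}

# --- degradation lookups (time 0 always returns the neutral value) ---------

deg_mt_fold <- function(deg, tissue, cell_type, time_h) {
  if (time_h == 0 || is.null(deg$mt_fold_change)) return(1)
  d <- deg$mt_fold_change
  hit <- (d$tissue == tissue | d$tissue == "*") &
    (d$cell_type == cell_type | d$cell_type == "*") & d$time_h == time_h
  if (!any(hit)) 1 else d$fold[which(hit)[1L]]
}

deg_intron_shift <- function(deg, tissue, time_h) {
  if (time_h == 0 || is.null(deg$intron_shift)) return(0)
  d <- deg$intron_shift
  hit <- (d$tissue == tissue | d$tissue == "*") & d$time_h == time_h
  if (!any(hit)) 0 else d$shift[which(hit)[1L]]
}

deg_ambient_fraction <- function(deg, tissue, time_h) {
  if (is.null(deg$ambient_umi_fraction)) return(NA_real_)
  d <- deg$ambient_umi_fraction
  hit <- (d$tissue == tissue | d$tissue == "*") & d$time_h == time_h
  if (!any(hit)) NA_real_ else d$fraction[which(hit)[1L]]
}

deg_signature_fold <- function(deg, time_h) {
  if (time_h == 0 || is.null(deg$signature_fold) ||
      length(deg$signature_genes) == 0) return(1)
  d <- deg$signature_fold
  hit <- d$time_h == time_h
  if (!any(hit)) 1 else d$fold[which(hit)[1L]]
}

#' Build block-marker cell-type expression profiles
#'
#' Gene-expression probability vectors over a gene universe whose last
#' `n_mt_genes` entries are mitochondrial genes (named `MT-1`, `MT-2`, ...).
#' Each cell type places `marker_mass` of its probability on its own disjoint
#' marker block and spreads the rest uniformly over all non-mitochondrial,
#' non-marker genes; mitochondrial content is handled separately by the
#' generator's binomial MT split, so profiles carry zero MT mass.
#'
#' @param n_genes total genes including the MT block.
#' @param cell_types character vector of type labels.
#' @param n_mt_genes number of mitochondrial genes at the end of the
#'   universe.
#' @param markers_per_type size of each type's marker block.
#' @param marker_mass probability mass a type places on its own markers.
#' @return list with `profiles` (matrix genes x types, columns sum to 1),
#'   `features` (gene names) and `marker_sets` (list of index vectors).
#' @export
make_cell_type_profiles <- function(n_genes = 200,
                                    cell_types = c("T_cell", "B_cell", "NK",
                                                   "Mono_macro",
                                                   "Endothelial", "Plasma"),
                                    n_mt_genes = 10,
                                    markers_per_type = 15,
                                    marker_mass = 0.5) {
  k <- length(cell_types)
  n_body <- n_genes - n_mt_genes
  if (n_body < k * markers_per_type) {
    stop("profile dimension mismatch: n_genes too small for ",
         k, " x ", markers_per_type, " marker blocks")
  }
  features <- c(sprintf("G%04d", seq_len(n_body)),
                sprintf("MT-%d", seq_len(n_mt_genes)))
  profiles <- matrix(0, n_genes, k, dimnames = list(features, cell_types))
  marker_sets <- vector("list", k)
  names(marker_sets) <- cell_types
  for (i in seq_len(k)) {
    block <- ((i - 1) * markers_per_type + 1):(i * markers_per_type)
    marker_sets[[i]] <- block
    p <- rep(0, n_genes)
    p[seq_len(n_body)] <- (1 - marker_mass) / n_body
    p[block] <- p[block] + marker_mass / markers_per_type
    profiles[, i] <- p / sum(p)
  }
  list(profiles = profiles, features = features, marker_sets = marker_sets)
}

#' Configuration of a synthetic droplet experiment
#'
#' Defines a multi-donor, multi-tissue, four-time-point droplet experiment
#' with ambient, debris and cell droplets. The defaults emulate the cold
#' storage study design at desk scale: 5 donors, three tissues, time points
#' 0/12/24/72 h, and depth means one decade apart per droplet class so that
#' the normalized-UMI intervals (0, 0.25], (0.25, 5] and (5, Inf) separate
#' the classes.
#'
#' @param n_donors number of donors.
#' @param tissues tissue labels.
#' @param time_points_h storage times in hours (distinct, sorted).
#' @param n_cells_per_sample,n_debris_droplets,n_ambient_droplets droplet
#'   counts per sample.
#' @param n_genes gene-universe size (when `cell_type_profiles` is NULL).
#' @param cell_type_profiles optional list as returned by
#'   [make_cell_type_profiles()]; built with defaults when NULL.
#' @param cell_type_proportions named numeric vector (shared by all donors)
#'   or list of such vectors keyed by donor label; each sums to 1.
#' @param mean_umis_per_cell,mean_umis_per_debris,mean_umis_per_ambient
#'   arithmetic-mean UMI totals per droplet class.
#' @param umi_sdlog log-scale standard deviation of droplet UMI totals
#'   (log-normal totals).
#' @param baseline_mt_fraction mitochondrial UMI fraction of an unstressed
#'   cell, in `[0, 1)`.
#' @param base_exonic_fraction mean exonic fraction of confidently mapped
#'   reads at time 0.
#' @param exonic_sd standard deviation of the per-barcode beta-distributed
#'   exonic fraction (fixed across time so a mean shift translates the
#'   distribution).
#' @param intergenic_fraction mean intergenic fraction of confident reads.
#' @param reads_per_umi expected confident reads per UMI (sets read-category
#'   totals).
#' @param ambient_soup_weights optional named numeric up-weighting of cell
#'   types in the ambient soup mixture (e.g. plasma-like high-secretion
#'   profiles); weights are multiplied onto the proportion weights.
#' @param degradation a [degradation_params()] object.
#' @param seed integer global seed; per-sample substreams are derived from
#'   (seed, donor, tissue, time).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_donors = 5,
                       tissues = c("lung", "esophagus", "spleen"),
                       time_points_h = c(0, 12, 24, 72),
                       n_cells_per_sample = 2000,
                       n_debris_droplets = 1000,
                       n_ambient_droplets = 8000,
                       n_genes = 200,
                       cell_type_profiles = NULL,
                       cell_type_proportions = NULL,
                       mean_umis_per_cell = 20000,
                       mean_umis_per_debris = 60,
                       mean_umis_per_ambient = 3,
                       umi_sdlog = 0.5,
                       baseline_mt_fraction = 0.05,
                       base_exonic_fraction = 0.75,
                       exonic_sd = 0.06,
                       intergenic_fraction = 0.04,
                       reads_per_umi = 3,
                       ambient_soup_weights = NULL,
                       degradation = default_degradation(),
                       seed = 1L) {
  if (n_donors < 1) stop("configuration error in field 'n_donors': must be positive")
  if (length(tissues) < 1) stop("configuration error in field 'tissues': empty")
  tp <- time_points_h
  if (any(tp < 0)) stop("configuration error in field 'time_points_h': negative hours")
  if (anyDuplicated(tp) || is.unsorted(tp)) {
    stop("configuration error in field 'time_points_h': must be distinct and sorted")
  }
  for (fld in c("n_cells_per_sample", "n_genes")) {
    if (get(fld) <= 0) stop("configuration error in field '", fld, "': must be positive")
  }
  for (fld in c("n_debris_droplets", "n_ambient_droplets")) {
    if (get(fld) < 0) stop("configuration error in field '", fld, "': must be non-negative")
  }
  for (fld in c("mean_umis_per_cell", "mean_umis_per_debris",
                "mean_umis_per_ambient")) {
    if (get(fld) <= 0) stop("configuration error in field '", fld, "': must be positive")
  }
  if (baseline_mt_fraction < 0 || baseline_mt_fraction >= 1) {
    stop("configuration error in field 'baseline_mt_fraction': must lie in [0, 1)")
  }
  if (is.null(cell_type_profiles)) {
    cell_type_profiles <- make_cell_type_profiles(n_genes = n_genes)
  }
  prof <- cell_type_profiles$profiles
  if (nrow(prof) != n_genes) {
    stop("configuration error in field 'cell_type_profiles': profile dimension ",
         nrow(prof), " does not match n_genes = ", n_genes)
  }
  sums <- colSums(prof)
  if (any(prof < 0) || any(abs(sums - 1) > 1e-8)) {
    stop("configuration error in field 'cell_type_profiles': ",
         "each profile must be non-negative and sum to 1")
  }
  types <- colnames(prof)
  donors <- sprintf("D%d", seq_len(n_donors))
  if (is.null(cell_type_proportions)) {
    cell_type_proportions <- stats::setNames(rep(1 / length(types),
                                                 length(types)), types)
  }
  if (!is.list(cell_type_proportions)) {
    cell_type_proportions <- stats::setNames(
      rep(list(cell_type_proportions), n_donors), donors)
  }
  if (!all(donors %in% names(cell_type_proportions))) {
    stop("configuration error in field 'cell_type_proportions': ",
         "missing donors ", paste(setdiff(donors, names(cell_type_proportions)),
                                  collapse = ", "))
  }
  for (d in donors) {
    pp <- cell_type_proportions[[d]]
    if (!all(types %in% names(pp)) || any(pp < 0) ||
        abs(sum(pp) - 1) > 1e-6) {
      stop("configuration error in field 'cell_type_proportions': ",
           "donor ", d, " proportions must cover all cell types, be ",
           "non-negative and sum to 1")
    }
  }
  if (!inherits(degradation, "degradation_params")) {
    stop("configuration error in field 'degradation': ",
         "must be a degradation_params object")
  }
  if (length(degradation$signature_genes) &&
      any(degradation$signature_genes > n_genes)) {
    stop("configuration error in field 'degradation': ",
         "signature_genes index beyond n_genes")
  }
  structure(list(
    n_donors = as.integer(n_donors), donors = donors, tissues = tissues,
    time_points_h = tp,
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_debris_droplets = as.integer(n_debris_droplets),
    n_ambient_droplets = as.integer(n_ambient_droplets),
    n_genes = as.integer(n_genes),
    cell_type_profiles = cell_type_profiles,
    cell_types = types,
    cell_type_proportions = cell_type_proportions,
    mean_umis_per_cell = mean_umis_per_cell,
    mean_umis_per_debris = mean_umis_per_debris,
    mean_umis_per_ambient = mean_umis_per_ambient,
    umi_sdlog = umi_sdlog,
    baseline_mt_fraction = baseline_mt_fraction,
    base_exonic_fraction = base_exonic_fraction,
    exonic_sd = exonic_sd,
    intergenic_fraction = intergenic_fraction,
    reads_per_umi = reads_per_umi,
    ambient_soup_weights = ambient_soup_weights,
    degradation = degradation,
    seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_donors, "donors x",
      length(x$tissues), "tissues x", length(x$time_points_h),
      "time points;", x$n_cells_per_sample, "cells,",
      x$n_debris_droplets, "debris,", x$n_ambient_droplets,
      "ambient droplets per sample;", x$n_genes, "genes; seed", x$seed, "\n")
  invisible(x)
}

# log-normal integer totals with arithmetic mean `mean`
rlnorm_totals <- function(n, mean, sdlog) {
  if (n == 0) return(integer(0))
  as.integer(round(stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)))
}

# draw gene counts for droplets sharing one profile; sizes may differ.
# Returns genes x n integer matrix.
draw_counts <- function(sizes, prob) {
  n_genes <- length(prob)
  out <- matrix(0L, n_genes, length(sizes))
  pos <- which(sizes > 0)
  for (j in pos) out[, j] <- stats::rmultinom(1, sizes[j], prob)[, 1]
  out
}

# beta draw with given mean and sd (sd shrunk if infeasible for the mean)
rbeta_mean_sd <- function(n, mean, sd) {
  mean <- min(max(mean, 0.02), 0.98)
  max_sd <- sqrt(mean * (1 - mean)) * 0.95
  sd <- min(sd, max_sd)
  kappa <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

# Generate one sample's droplet table, read categories and truth.
generate_sample <- function(config, donor, tissue, time_h) {
  prof <- config$cell_type_profiles$profiles
  types <- config$cell_types
  n_genes <- config$n_genes
  features <- config$cell_type_profiles$features
  mt_idx <- grep("^MT-", features)
  deg <- config$degradation

  # storage-signature scaling of profile mass, then renormalize
  sig_fold <- deg_signature_fold(deg, time_h)
  if (sig_fold != 1) {
    prof[deg$signature_genes, ] <- prof[deg$signature_genes, ] * sig_fold
    prof <- sweep(prof, 2, colSums(prof), `/`)
  }

  props <- config$cell_type_proportions[[donor]][types]
  n_cells <- config$n_cells_per_sample
  n_debris <- config$n_debris_droplets
  n_ambient <- config$n_ambient_droplets

  cell_types_drawn <- sample(types, n_cells, replace = TRUE, prob = props)
  debris_types <- if (n_debris > 0) {
    sample(types, n_debris, replace = TRUE, prob = props)
  } else character(0)

  totals_cell <- rlnorm_totals(n_cells, config$mean_umis_per_cell,
                               config$umi_sdlog)
  totals_debris <- rlnorm_totals(n_debris, config$mean_umis_per_debris,
                                 config$umi_sdlog)

  # ambient depth: either the configured mean or scaled so ambient droplets
  # hold the target fraction f of the run's total UMIs
  f_amb <- deg_ambient_fraction(deg, tissue, time_h)
  mean_amb <- if (is.na(f_amb) || n_ambient == 0) {
    config$mean_umis_per_ambient
  } else {
    f_amb / (1 - f_amb) * (sum(totals_cell) + sum(totals_debris)) / n_ambient
  }
  totals_ambient <- rlnorm_totals(n_ambient, max(mean_amb, 1e-6),
                                  config$umi_sdlog)

  # per-class MT fractions: cells get the (tissue, type, time) fold applied
  # to the baseline; debris and ambient stay at baseline
  base_f <- config$baseline_mt_fraction
  counts <- matrix(0L, n_genes,  n_cells + n_debris + n_ambient)

  draw_class <- function(cols, sizes, type_of, mt_f_of) {
    for (ty in unique(type_of)) {
      sel <- type_of == ty
      f <- mt_f_of(ty)
      sz <- sizes[sel]
      mt_counts <- stats::rbinom(length(sz), sz, f)
      body <- draw_counts(sz - mt_counts, prof[, ty] / sum(prof[, ty]))
      if (length(mt_idx)) {
        mtm <- draw_counts(mt_counts, rep(1 / length(mt_idx), length(mt_idx)))
        body[mt_idx, ] <- body[mt_idx, ] + mtm
      }
      counts[, cols[sel]] <<- body
    }
  }

  cell_cols <- seq_len(n_cells)
  mt_fold_of <- vapply(types, function(ty)
    deg_mt_fold(deg, tissue, ty, time_h), numeric(1))
  draw_class(cell_cols, totals_cell, cell_types_drawn,
             function(ty) min(base_f * mt_fold_of[[ty]], 0.9))

  if (n_debris > 0) {
    draw_class(n_cells + seq_len(n_debris), totals_debris, debris_types,
               function(ty) base_f)
  }

  if (n_ambient > 0) {
    w <- props
    if (!is.null(config$ambient_soup_weights)) {
      up <- config$ambient_soup_weights
      w[names(up)] <- w[names(up)] * up
    }
    soup <- as.vector(prof %*% (w / sum(w)))
    amb_cols <- n_cells + n_debris + seq_len(n_ambient)
    mt_counts <- stats::rbinom(n_ambient, totals_ambient, base_f)
    body <- draw_counts(totals_ambient - mt_counts, soup / sum(soup))
    if (length(mt_idx)) {
      mtm <- draw_counts(mt_counts, rep(1 / length(mt_idx), length(mt_idx)))
      body[mt_idx, ] <- body[mt_idx, ] + mtm
    }
    counts[, amb_cols] <- body
  }

  n_total <- ncol(counts)
  barcodes <- sprintf("BC%06d", seq_len(n_total))
  umi_total <- as.integer(colSums(counts))

  # per-barcode read categories: beta exonic fraction with time-shifted
  # mean, constant intergenic mean, remainder intronic
  shift <- deg_intron_shift(deg, tissue, time_h)
  g0 <- config$intergenic_fraction
  me <- config$base_exonic_fraction - shift
  e <- rbeta_mean_sd(n_total, me, config$exonic_sd)
  e <- pmin(e, 1 - g0 - 0.01)
  n_reads <- stats::rpois(n_total, umi_total * config$reads_per_umi)
  exonic <- stats::rbinom(n_total, n_reads, e)
  rest <- n_reads - exonic
  intergenic <- stats::rbinom(n_total, rest, pmin(g0 / (1 - e), 1))
  intronic <- rest - intergenic
  read_categories <- data.frame(barcode = barcodes, exonic = exonic,
                                intronic = intronic, intergenic = intergenic,
                                stringsAsFactors = FALSE)

  truth_class <- rep(c("cell", "debris", "ambient"),
                     c(n_cells, n_debris, n_ambient))
  truth <- data.frame(
    barcode = barcodes,
    class = truth_class,
    cell_type = c(cell_types_drawn, debris_types, rep(NA, n_ambient)),
    stringsAsFactors = FALSE)

  mt_means <- data.frame(
    cell_type = types,
    true_mt_pct = 100 * pmin(base_f * mt_fold_of, 0.9),
    stringsAsFactors = FALSE)

  amb_umis <- sum(umi_total[truth_class == "ambient"])
  list(
    droplets = droplet_table(
      sample_id = paste(donor, tissue, sprintf("T%02dh", time_h), sep = "_"),
      barcodes = barcodes,
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                           "CsparseMatrix"),
      features = features),
    read_categories = read_categories,
    truth = list(droplets = truth, mt_means = mt_means,
                 target_ambient_fraction = f_amb,
                 realized_ambient_fraction =
                   amb_umis / max(sum(umi_total), 1)))
}

#' Generate a complete synthetic droplet experiment
#'
#' One sample per (donor, tissue, time point). Cell droplets draw gene
#' counts from their cell type's profile with log-normal UMI totals and a
#' binomial mitochondrial split at `baseline_mt_fraction` times the
#' configured fold change; debris droplets draw from cell profiles at
#' reduced depth; ambient droplets draw from the proportion-weighted soup
#' mixture of all profiles. Per-barcode read categories use a
#' beta-distributed exonic fraction whose mean is shifted by the configured
#' intron shift. Generation is a pure function of the config: the same
#' config (including seed) yields a bit-identical experiment.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_experiment`: a list with `samples`
#'   (per-sample metadata, droplet table, read categories, truth), `samples_df`
#'   (the sample sheet), `features` and the `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(donor = config$donors, tissue = config$tissues,
                      time_h = config$time_points_h,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$donor, grid$tissue, grid$time_h), , drop = FALSE]
  rownames(grid) <- NULL
  grid$sample_id <- paste(grid$donor, grid$tissue,
                          sprintf("T%02dh", grid$time_h), sep = "_")
  samples <- vector("list", nrow(grid))
  names(samples) <- grid$sample_id
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$donor[i], grid$tissue[i], grid$time_h[i], sep = "|")
    sub_seed <- substream_seed(config$seed, key)
    s <- with_seed(sub_seed, generate_sample(config, grid$donor[i],
                                             grid$tissue[i], grid$time_h[i]))
    s$metadata <- grid[i, c("sample_id", "donor", "tissue", "time_h")]
    samples[[i]] <- s
  }
  structure(list(samples = samples,
                 samples_df = grid[, c("sample_id", "donor", "tissue",
                                       "time_h")],
                 features = config$cell_type_profiles$features,
                 config = config),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("synthetic_experiment:", length(x$samples), "samples,",
      length(x$features), "genes\n")
  invisible(x)
}

#' Generate matched bulk RNA-seq counts for a synthetic experiment
#'
#' Per sample, bulk counts are drawn from the true tissue-level cell-type
#' mixture (all types at their true proportions, no dissociation bias) at a
#' fixed library size. An optional dissociation-signature offset scales the
#' bulk-side probability mass of chosen genes by `2^signature_log2fc`;
#' a negative offset therefore plants genes that are higher in single-cell
#' pseudo-bulk than in bulk, giving differential-expression analyses known
#' positives.
#'
#' @param experiment a `synthetic_experiment`.
#' @param library_size bulk reads per sample (positive integer).
#' @param signature_genes optional integer gene indices carrying the offset.
#' @param signature_log2fc log2 offset applied to bulk mass of those genes.
#' @return integer matrix genes x samples with feature/sample dimnames.
#' @export
generate_bulk <- function(experiment, library_size = 1e6,
                          signature_genes = NULL, signature_log2fc = 0) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (length(library_size) != 1 || library_size <= 0) {
    stop("library_size must be a positive integer")
  }
  config <- experiment$config
  prof <- config$cell_type_profiles$profiles
  features <- experiment$features
  mt_idx <- grep("^MT-", features)
  deg <- config$degradation
  sdf <- experiment$samples_df
  out <- matrix(0L, length(features), nrow(sdf),
                dimnames = list(features, sdf$sample_id))
  for (i in seq_len(nrow(sdf))) {
    donor <- sdf$donor[i]; tissue <- sdf$tissue[i]; time_h <- sdf$time_h[i]
    p <- prof
    sig_fold <- deg_signature_fold(deg, time_h)
    if (sig_fold != 1) {
      p[deg$signature_genes, ] <- p[deg$signature_genes, ] * sig_fold
      p <- sweep(p, 2, colSums(p), `/`)
    }
    props <- config$cell_type_proportions[[donor]][config$cell_types]
    mix <- as.vector(p %*% props)
    # fold MT content in at the proportion-weighted true MT fraction
    f <- config$baseline_mt_fraction *
      sum(props * vapply(config$cell_types, function(ty)
        deg_mt_fold(deg, tissue, ty, time_h), numeric(1)))
    f <- min(f, 0.9)
    mix <- mix * (1 - f)
    if (length(mt_idx)) mix[mt_idx] <- mix[mt_idx] + f / length(mt_idx)
    if (!is.null(signature_genes) && signature_log2fc != 0) {
      mix[signature_genes] <- mix[signature_genes] * 2^signature_log2fc
    }
    mix <- mix / sum(mix)
    sub_seed <- substream_seed(config$seed,
                               paste("bulk", donor, tissue, time_h, sep = "|"))
    out[, i] <- with_seed(sub_seed,
                          stats::rmultinom(1, library_size, mix)[, 1])
  }
  out
}

#' Serialize a synthetic experiment as a plain-text fixture
#'
#' Each sample is written as an MTX triplet plus barcodes/features TSVs, a
#' read-category TSV and a droplet-truth TSV under `directory/<sample_id>/`;
#' a `samples.tsv` sheet and a checksum manifest cover the whole experiment.
#' [load_experiment_fixture()] reproduces the in-memory tables exactly.
#'
#' @param experiment a `synthetic_experiment`.
#' @param directory output directory (created if absent).
#' @return data.frame manifest with columns `sample_id`, `file`, `md5`.
#' @export
write_fixture <- function(experiment, directory) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  files <- character(0); ids <- character(0)
  for (s in experiment$samples) {
    sid <- s$metadata$sample_id
    sdir <- file.path(directory, sid)
    dir.create(sdir, showWarnings = FALSE)
    Matrix::writeMM(s$droplets$counts, file.path(sdir, "matrix.mtx"))
    writeLines(s$droplets$barcodes, file.path(sdir, "barcodes.tsv"))
    writeLines(s$droplets$features, file.path(sdir, "features.tsv"))
    write_tsv(s$read_categories, file.path(sdir, "read_categories.tsv"))
    write_tsv(s$truth$droplets, file.path(sdir, "truth_droplets.tsv"))
    write_tsv(s$truth$mt_means, file.path(sdir, "truth_mt_means.tsv"))
    new <- file.path(sdir, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                             "read_categories.tsv", "truth_droplets.tsv",
                             "truth_mt_means.tsv"))
    files <- c(files, new); ids <- c(ids, rep(sid, length(new)))
  }
  write_tsv(experiment$samples_df, file.path(directory, "samples.tsv"))
  files <- c(files, file.path(directory, "samples.tsv"))
  ids <- c(ids, NA)
  manifest <- data.frame(sample_id = ids,
                         file = sub(paste0("^", directory, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(directory, "manifest.tsv"))
  manifest
}

#' Load a serialized experiment fixture
#'
#' Inverse of [write_fixture()]: reads the sample sheet, per-sample MTX
#' triplets, read categories and truth tables back into the in-memory layout.
#'
#' @param directory fixture directory written by [write_fixture()].
#' @return list with `samples`, `samples_df` and `features`.
#' @export
load_experiment_fixture <- function(directory) {
  sdf <- read_tsv(file.path(directory, "samples.tsv"))
  samples <- vector("list", nrow(sdf))
  names(samples) <- sdf$sample_id
  features <- NULL
  for (i in seq_len(nrow(sdf))) {
    sid <- sdf$sample_id[i]
    sdir <- file.path(directory, sid)
    dt <- load_count_matrix(file.path(sdir, "matrix.mtx"),
                            file.path(sdir, "barcodes.tsv"),
                            file.path(sdir, "features.tsv"),
                            sample_id = sid)
    features <- dt$features
    samples[[i]] <- list(
      metadata = sdf[i, , drop = FALSE],
      droplets = dt,
      read_categories = read_tsv(file.path(sdir, "read_categories.tsv")),
      truth = list(droplets = read_tsv(file.path(sdir, "truth_droplets.tsv")),
                   mt_means = read_tsv(file.path(sdir, "truth_mt_means.tsv"))))
  }
  list(samples = samples, samples_df = sdf, features = features)
}
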