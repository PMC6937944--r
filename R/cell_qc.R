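#' Cell QC thresholds
#'
#' The filter bounds applied to called cells: fewer than `min_genes` or more
#' than `max_genes` detected genes (`max_genes_esophagus` in esophagus),
#' more than `max_umi` UMIs, or more than `max_mt_pct` percent mitochondrial
#' reads removes a cell; boundary values are kept ("less than"/"more than"
#' are strict). Genes detected in fewer than `min_cells_per_gene` cells per
#' tissue are removed.
#'
#' @param min_genes,max_genes,max_genes_esophagus,max_umi,max_mt_pct,min_cells_per_gene
#'   filter bounds; see description.
#' @return object of class `cell_qc_thresholds`.
#' @export
cell_qc_thresholds <- function(min_genes = 300, max_genes = 5000,
                               max_genes_esophagus = 8000, max_umi = 20000,
                               max_mt_pct = 10, min_cells_per_gene = 3) {
  if (min_genes >= max_genes) stop("min_genes must be below max_genes")
  if (any(c(min_genes, max_genes, max_genes_esophagus, max_umi, max_mt_pct,
            min_cells_per_gene) <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_genes_esophagus = max_genes_esophagus,
                 max_umi = max_umi, max_mt_pct = max_mt_pct,
                 min_cells_per_gene = min_cells_per_gene),
            class = "cell_qc_thresholds")
}

#' Per-barcode read-category fractions
#'
#' Fractions of confidently mapped reads falling in exons, introns and
#' intergenic space. Barcodes whose three categories sum to zero are flagged
#' and excluded from downstream summaries rather than erroring.
#'
#' @param counts data.frame with columns barcode, exonic, intronic,
#'   intergenic (non-negative integers).
#' @return data.frame with the input columns plus total, exonic_frac,
#'   intronic_frac, intergenic_frac (NA when flagged) and `flagged`.
#' @export
read_category_fractions <- function(counts) {
  req <- c("barcode", "exonic", "intronic", "intergenic")
  if (!all(req %in% names(counts))) {
    stop("read-category table must have columns ",
         paste(req, collapse = ", "))
  }
  if (any(counts$exonic < 0 | counts$intronic < 0 | counts$intergenic < 0)) {
    stop("read-category counts must be non-negative")
  }
  total <- counts$exonic + counts$intronic + counts$intergenic
  flagged <- total == 0
  safe <- ifelse(flagged, NA_real_, total)
  data.frame(counts[req],
             total = total,
             exonic_frac = counts$exonic / safe,
             intronic_frac = counts$intronic / safe,
             intergenic_frac = counts$intergenic / safe,
             flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Top- and bottom-quartile means of a read-category metric
#'
#' Within each sample, cells are ranked by the chosen fraction (ties broken
#' by barcode order for determinism); the top and bottom `ceiling(n/4)`
#' cells form the extreme quartiles and their means are reported. Samples
#' with fewer than 4 usable cells are skipped with a warning.
#'
#' @param fractions output of [read_category_fractions()] with an added
#'   `sample_id` column (flagged rows are ignored).
#' @param metric "exonic" or "intronic".
#' @return data.frame sample_id, n_cells, bottom_quartile_mean,
#'   top_quartile_mean.
#' @export
quartile_extremes <- function(fractions, metric = c("exonic", "intronic")) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_frac")
  stopifnot(col %in% names(fractions), "sample_id" %in% names(fractions))
  fr <- fractions[!fractions$flagged, ]
  out <- lapply(split(fr, fr$sample_id), function(s) {
    n <- nrow(s)
    if (n < 4) {
      warning("sample ", s$sample_id[1], " has fewer than 4 cells; skipped")
      return(NULL)
    }
    s <- s[order(s[[col]], s$barcode), ]
    k <- ceiling(n / 4)
    data.frame(sample_id = s$sample_id[1], n_cells = n,
               bottom_quartile_mean = mean(s[[col]][seq_len(k)]),
               top_quartile_mean = mean(s[[col]][(n - k + 1):n]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Compute per-cell QC covariates
#'
#' Detected genes, UMI totals and mitochondrial percentage (100 x MT UMIs /
#' total UMIs) for every column of a count matrix.
#'
#' @param counts genes x cells count matrix with feature rownames.
#' @param mt_genes character vector of mitochondrial gene names, or NULL to
#'   use all features prefixed `MT-`.
#' @return data.frame barcode, n_genes, n_counts, mt_pct.
#' @export
cell_covariates <- function(counts, mt_genes = NULL) {
  feats <- rownames(counts)
  if (is.null(feats)) stop("count matrix must have feature rownames")
  if (is.null(mt_genes)) mt_genes <- grep("^MT-", feats, value = TRUE)
  mt_genes <- intersect(mt_genes, feats)
  if (length(mt_genes) == 0) stop("mitochondrial gene set is empty or absent from features")
  n_counts <- Matrix::colSums(counts)
  mt_counts <- Matrix::colSums(counts[mt_genes, , drop = FALSE])
  data.frame(barcode = colnames(counts),
             n_genes = as.integer(Matrix::colSums(counts > 0)),
             n_counts = as.numeric(n_counts),
             mt_pct = ifelse(n_counts > 0, 100 * mt_counts / n_counts, 0),
             stringsAsFactors = FALSE)
}

#' Filter cells by gene count, UMI count and mitochondrial percentage
#'
#' A cell is kept iff its detected genes lie in `[min_genes, limit]` (limit
#' 8000 for esophagus, 5000 otherwise by default), its UMI total is at most
#' `max_umi` and its mitochondrial percentage at most `max_mt_pct`; strictly
#' greater (or strictly smaller, for `min_genes`) values are removed, so
#' boundary cells are kept. The removal log records the first rule that
#' fired for each removed cell, in the order min_genes, max_genes, max_umi,
#' max_mt_pct.
#'
#' @param counts genes x cells count matrix (feature rownames, barcode
#'   colnames).
#' @param mt_genes mitochondrial gene set (NULL: `MT-` prefix).
#' @param tissue tissue label; one of lung, esophagus, spleen unless
#'   `thresholds` overrides the esophagus rule.
#' @param thresholds a [cell_qc_thresholds()].
#' @return list with `counts` (kept columns), `cells` (covariate table of
#'   kept cells) and `removal_log` (barcode, rule).
#' @export
filter_cells <- function(counts, mt_genes = NULL, tissue,
                         thresholds = cell_qc_thresholds()) {
  stopifnot(inherits(thresholds, "cell_qc_thresholds"))
  known <- c("lung", "esophagus", "spleen")
  if (!tissue %in% known) {
    stop("unknown tissue label '", tissue, "' (expected one of ",
         paste(known, collapse = ", "), ")")
  }
  cov <- cell_covariates(counts, mt_genes)
  limit <- if (tissue == "esophagus") thresholds$max_genes_esophagus else
    thresholds$max_genes
  rule <- rep(NA_character_, nrow(cov))
  rule[is.na(rule) & cov$n_genes < thresholds$min_genes] <- "min_genes"
  rule[is.na(rule) & cov$n_genes > limit] <- "max_genes"
  rule[is.na(rule) & cov$n_counts > thresholds$max_umi] <- "max_umi"
  rule[is.na(rule) & cov$mt_pct > thresholds$max_mt_pct] <- "max_mt_pct"
  keep <- is.na(rule)
  list(counts = counts[, keep, drop = FALSE],
       cells = cov[keep, , drop = FALSE],
       removal_log = data.frame(barcode = cov$barcode[!keep],
                                rule = rule[!keep],
                                stringsAsFactors = FALSE))
}

#' Remove genes detected in too few cells
#'
#' Keeps a gene iff it has a nonzero count in at least `min_cells` cells of
#' the (tissue-pooled) matrix. Idempotent.
#'
#' @param counts genes x cells count matrix.
#' @param min_cells detection threshold (default 3).
#' @return the filtered matrix.
#' @export
filter_genes <- function(counts, min_cells = 3) {
  detected <- Matrix::rowSums(counts > 0)
  counts[detected >= min_cells, , drop = FALSE]
}

#' Per-sample fraction of high-mitochondrial cells
#'
#' Share of cells with mitochondrial percentage strictly above `cutoff`,
#' computed on the unfiltered cell table (i.e. before the MT filter removes
#' those cells). Empty samples yield NA.
#'
#' @param cells data.frame with columns sample_id and mt_pct.
#' @param cutoff percentage cutoff (default 10).
#' @return data.frame sample_id, n_cells, high_mt_rate.
#' @export
high_mito_rate <- function(cells, cutoff = 10) {
  stopifnot(all(c("sample_id", "mt_pct") %in% names(cells)))
  out <- do.call(rbind, lapply(split(cells, cells$sample_id), function(s) {
    data.frame(sample_id = s$sample_id[1], n_cells = nrow(s),
               high_mt_rate = if (nrow(s) == 0) NA_real_ else
                 mean(s$mt_pct > cutoff),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample QC metrics with time-trend tests
#'
#' Computes, per sample: number of cells, median detected genes per cell,
#' total confident reads, and the confidently-mapped-to-exon fraction of
#' those reads. For each metric and tissue, the baseline time group is
#' compared against every later time group by an unpaired two-sided t test
#' (donors differ across time points in this design), BH-corrected within
#' the metric. Groups with fewer than 2 samples on either side are skipped
#' and flagged.
#'
#' @param cells cell covariate table with a `sample_id` column.
#' @param read_categories data.frame(sample_id, barcode, exonic, intronic,
#'   intergenic).
#' @param samples sample sheet with columns sample_id, donor, tissue,
#'   time_h.
#' @return list with `metrics` (per-sample table) and `trend_tests`
#'   (tissue, metric, time_h, p_value, p_adj, status).
#' @export
sample_metrics <- function(cells, read_categories, samples) {
  stopifnot(all(c("sample_id", "n_genes") %in% names(cells)))
  if (nrow(cells) == 0) stop("no cells to summarise")
  per_sample <- lapply(split(cells, cells$sample_id), function(s) {
    data.frame(sample_id = s$sample_id[1], n_cells = nrow(s),
               median_genes = stats::median(s$n_genes),
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, per_sample)
  rc <- read_categories
  rc$total <- rc$exonic + rc$intronic + rc$intergenic
  agg <- do.call(rbind, lapply(split(rc, rc$sample_id), function(s) {
    data.frame(sample_id = s$sample_id[1],
               total_confident_reads = sum(s$total),
               conf_mapped_exonic_frac = if (sum(s$total) > 0)
                 sum(s$exonic) / sum(s$total) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  metrics <- merge(metrics, agg, by = "sample_id", all.x = TRUE)
  metrics <- merge(samples, metrics, by = "sample_id", all.x = TRUE)
  metrics <- metrics[order(metrics$sample_id), ]
  rownames(metrics) <- NULL

  metric_cols <- c("n_cells", "median_genes", "total_confident_reads",
                   "conf_mapped_exonic_frac")
  t0 <- min(samples$time_h)
  later <- sort(setdiff(unique(samples$time_h), t0))
  tests <- list()
  for (m in metric_cols) {
    for (ti in unique(metrics$tissue)) {
      sub <- metrics[metrics$tissue == ti, ]
      base <- sub[[m]][sub$time_h == t0]
      for (tl in later) {
        grp <- sub[[m]][sub$time_h == tl]
        if (sum(!is.na(base)) < 2 || sum(!is.na(grp)) < 2) {
          tests[[length(tests) + 1]] <- data.frame(
            tissue = ti, metric = m, time_h = tl, p_value = NA_real_,
            status = "skipped_single_sample", stringsAsFactors = FALSE)
          next
        }
        p <- if (stats::sd(base, na.rm = TRUE) == 0 &&
                 stats::sd(grp, na.rm = TRUE) == 0 &&
                 mean(base, na.rm = TRUE) == mean(grp, na.rm = TRUE)) 1 else
          stats::t.test(base, grp)$p.value
        tests[[length(tests) + 1]] <- data.frame(
          tissue = ti, metric = m, time_h = tl, p_value = p, status = "ok",
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, tests)
  tests$p_adj <- NA_real_
  for (m in metric_cols) {
    sel <- tests$metric == m & tests$status == "ok"
    tests$p_adj[sel] <- bh_adjust(tests$p_value[sel])
  }
  list(metrics = metrics, trend_tests = tests)
}
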