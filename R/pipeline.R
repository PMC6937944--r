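#' Load a 10x-style MTX triplet into a droplet table
#'
#' Reads a MatrixMarket coordinate file with its barcodes and features
#' sidecars, checking that the header dimensions match the sidecar line
#' counts. MTX indices are 1-based in the file; the returned sparse matrix
#' follows R's native indexing, so no further conversion is needed.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param barcodes_path one barcode per line.
#' @param features_path one feature per line.
#' @param sample_id identifier for the resulting table.
#' @return a [droplet_table()].
#' @export
load_count_matrix <- function(mtx_path, barcodes_path, features_path,
                              sample_id = basename(dirname(mtx_path))) {
  for (f in c(mtx_path, barcodes_path, features_path)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  header <- readLines(mtx_path, n = 1)
  if (!grepl("^%%MatrixMarket matrix coordinate", header)) {
    stop("format error in ", mtx_path, " line 1: not a MatrixMarket ",
         "coordinate header")
  }
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e) {
    stop("format error in ", mtx_path, ": ", conditionMessage(e))
  })
  barcodes <- readLines(barcodes_path)
  features <- readLines(features_path)
  if (nrow(m) != length(features)) {
    stop("dimension mismatch: ", mtx_path, " declares ", nrow(m),
         " rows but ", features_path, " has ", length(features), " lines")
  }
  if (ncol(m) != length(barcodes)) {
    stop("dimension mismatch: ", mtx_path, " declares ", ncol(m),
         " columns but ", barcodes_path, " has ", length(barcodes), " lines")
  }
  droplet_table(sample_id = sample_id, barcodes = barcodes,
                counts = methods::as(m, "CsparseMatrix"),
                features = features)
}

#' Pipeline configuration
#'
#' Bundles the inputs, output location, thresholds and stage toggles of a
#' full stability-assessment run over a serialized experiment directory
#' (the layout written by [write_fixture()]).
#'
#' @param input_dir experiment directory with `samples.tsv` and per-sample
#'   MTX triplets.
#' @param output_dir where report tables are written.
#' @param stages subset of droplets, cells, assign, stats, de (dependency
#'   order enforced at run time).
#' @param mt_genes mitochondrial gene set (NULL: `MT-` prefix).
#' @param thresholds a [cell_qc_thresholds()].
#' @param bulk_path optional gene x sample bulk counts TSV enabling the de
#'   stage.
#' @param alpha significance level for summary counts (default 0.05).
#' @param similarity_threshold,n_features annotation-transfer parameters.
#' @param seed integer seed for any subsampling.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            stages = c("droplets", "cells", "assign",
                                       "stats"),
                            mt_genes = NULL,
                            thresholds = cell_qc_thresholds(),
                            bulk_path = NULL, alpha = 0.05,
                            similarity_threshold = 0.7, n_features = 500,
                            seed = 1L) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  if (!file.exists(file.path(input_dir, "samples.tsv"))) {
    stop("input_dir lacks samples.tsv: ", input_dir)
  }
  known <- c("droplets", "cells", "assign", "stats", "de")
  if (!all(stages %in% known)) {
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (!is.null(bulk_path) && !file.exists(bulk_path)) {
    stop("bulk_path does not exist: ", bulk_path)
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 stages = stages, mt_genes = mt_genes,
                 thresholds = thresholds, bulk_path = bulk_path,
                 alpha = alpha,
                 similarity_threshold = similarity_threshold,
                 n_features = n_features, seed = as.integer(seed)),
            class = "pipeline_config")
}

check_stage_deps <- function(stages) {
  deps <- list(cells = "droplets", assign = "cells", stats = "assign",
               de = "cells")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages) {
      stop("stage '", s, "' requires stage '", need, "' to be enabled")
    }
  }
}

#' Run the full stability-assessment pipeline
#'
#' Executes the enabled stages in dependency order — droplet classification,
#' cell QC, high-MT annotation transfer, degradation statistics and (when a
#' bulk table is supplied) bulk vs pseudo-bulk differential expression —
#' over a serialized experiment, writing each stage's tables as TSVs plus a
#' JSON run manifest with the config hash. Re-running an identical config
#' on identical inputs reproduces the tables byte for byte. Cells entering
#' the cell stage are the droplets classified as cellular material;
#' upstream cell-type labels (for the annotation-transfer reference) are
#' taken from the experiment's truth tables, standing in for an upstream
#' annotation.
#'
#' @param config a [pipeline_config()].
#' @return a `stability_report`: list of stage outputs plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  check_stage_deps(config$stages)
  if ("de" %in% config$stages && is.null(config$bulk_path)) {
    stop("stage 'de' requires bulk_path")
  }
  exp <- load_experiment_fixture(config$input_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  log <- list()
  note <- function(...) log[[length(log) + 1]] <<- paste0(...)

  norm_list <- NULL; label_list <- NULL
  if ("droplets" %in% config$stages) {
    norm_list <- lapply(exp$samples, function(s) normalize_umi(s$droplets))
    label_list <- lapply(norm_list, classify_droplets)
    report$droplet_class_summary <- class_means(norm_list, label_list)
    ambient <- lapply(names(exp$samples), function(sid) {
      s <- exp$samples[[sid]]
      out <- tryCatch(ambient_profile(s$droplets, label_list[[sid]]),
                      error = function(e) NULL)
      if (is.null(out)) {
        note("sample ", sid, ": no ambient droplets, profile skipped")
        return(NULL)
      }
      cbind(sample_id = sid, utils::head(out, 50))
    })
    report$ambient_profiles <- do.call(rbind,
                                       ambient[!vapply(ambient, is.null,
                                                       logical(1))])
  }

  cells_all <- NULL; counts_by_tissue <- list()
  if ("cells" %in% config$stages) {
    cell_tables <- list(); removal <- list(); rc_all <- list()
    kept_counts <- list()
    for (sid in names(exp$samples)) {
      s <- exp$samples[[sid]]
      lab <- label_list[[sid]]
      is_cell <- lab == "cellular"
      if (!any(is_cell)) {
        note("sample ", sid, ": no cellular droplets")
        next
      }
      counts <- s$droplets$counts[, is_cell, drop = FALSE]
      rownames(counts) <- s$droplets$features
      colnames(counts) <- paste(sid, s$droplets$barcodes[is_cell], sep = ":")
      md <- s$metadata
      fl <- filter_cells(counts, config$mt_genes, md$tissue,
                         config$thresholds)
      if (nrow(fl$removal_log)) {
        note("sample ", sid, ": removed ", nrow(fl$removal_log),
             " cells (", paste(names(table(fl$removal_log$rule)),
                               table(fl$removal_log$rule),
                               collapse = ", "), ")")
      }
      cov_all <- cell_covariates(counts, config$mt_genes)
      cov_all$sample_id <- sid; cov_all$donor <- md$donor
      cov_all$tissue <- md$tissue; cov_all$time_h <- md$time_h
      cov_all$kept <- !cov_all$barcode %in% fl$removal_log$barcode
      cell_tables[[sid]] <- cov_all
      if (nrow(fl$removal_log)) {
        removal[[sid]] <- cbind(sample_id = sid, fl$removal_log)
      }
      kept_counts[[sid]] <- counts
      rc <- s$read_categories
      rc$barcode <- paste(sid, rc$barcode, sep = ":")
      rc <- rc[rc$barcode %in% cov_all$barcode, ]
      rc$sample_id <- sid
      rc_all[[sid]] <- rc
    }
    cells_all <- do.call(rbind, cell_tables)
    rownames(cells_all) <- NULL
    report$cells <- cells_all
    report$removal_log <- do.call(rbind, removal)
    rc_all <- do.call(rbind, rc_all)
    fr <- read_category_fractions(rc_all)
    fr$sample_id <- rc_all$sample_id
    report$quartile_exonic <- quartile_extremes(fr, "exonic")
    report$high_mt_rate <- high_mito_rate(cells_all)
    sm <- sample_metrics(cells_all[cells_all$kept, ], rc_all,
                         exp$samples_df)
    report$sample_metrics <- sm$metrics
    report$metric_trend_tests <- sm$trend_tests
    # pool kept cells per tissue and apply the gene filter
    for (ti in unique(exp$samples_df$tissue)) {
      sids <- exp$samples_df$sample_id[exp$samples_df$tissue == ti]
      sids <- intersect(sids, names(kept_counts))
      if (!length(sids)) next
      pooled <- do.call(cbind, kept_counts[sids])
      counts_by_tissue[[ti]] <- filter_genes(
        pooled, config$thresholds$min_cells_per_gene)
    }
  }

  if ("assign" %in% config$stages) {
    truth_labels <- do.call(rbind, lapply(names(exp$samples), function(sid) {
      tr <- exp$samples[[sid]]$truth$droplets
      data.frame(barcode = paste(sid, tr$barcode, sep = ":"),
                 cell_type = tr$cell_type, stringsAsFactors = FALSE)
    }))
    cells_all$cell_type <- truth_labels$cell_type[
      match(cells_all$barcode, truth_labels$barcode)]
    assignments <- list()
    for (ti in names(counts_by_tissue)) {
      sub <- cells_all[cells_all$tissue == ti, ]
      counts <- counts_by_tissue[[ti]]
      low <- sub$barcode[sub$mt_pct <= config$thresholds$max_mt_pct &
                           !is.na(sub$cell_type)]
      high <- sub$barcode[sub$mt_pct > config$thresholds$max_mt_pct]
      if (length(high) == 0) {
        note("tissue ", ti, ": no high-MT cells to assign")
        next
      }
      idx <- build_centroids(counts[, low, drop = FALSE],
                             sub$cell_type[match(low, sub$barcode)],
                             n_features = config$n_features,
                             threshold = config$similarity_threshold)
      asg <- assign_by_similarity(counts[, high, drop = FALSE], idx)
      assignments[[ti]] <- cbind(tissue = ti, asg)
      hit <- asg$assigned
      cells_all$cell_type[match(asg$barcode[hit], cells_all$barcode)] <-
        asg$label[hit]
    }
    report$assignments <- do.call(rbind, assignments)
    report$cells <- cells_all
  }

  if ("stats" %in% config$stages) {
    ann <- cells_all[!is.na(cells_all$cell_type), ]
    # high- and low-MT cells combined for the per-type MT means; cells
    # removed by the other QC rules stay excluded
    ann <- ann[ann$kept | ann$mt_pct > config$thresholds$max_mt_pct, ]
    report$fold_change <- mito_fold_change(ann)
    report$fold_change$bin <- significance_bins(report$fold_change$p_adj)
    comp <- composition_proportions(ann[ann$kept, ])
    report$composition <- comp
    report$composition_tests <- composition_time_tests(comp)
    report$donor_anova <- composition_donor_anova(comp, config$alpha)$tests
  }

  if ("de" %in% config$stages) {
    bulk <- as.matrix(read_tsv(config$bulk_path, row.names = 1))
    kept_cells <- cells_all[cells_all$kept, ]
    pseudo <- list()
    for (ti in names(counts_by_tissue)) {
      sub <- kept_cells[kept_cells$tissue == ti, ]
      pb <- make_pseudobulk(
        counts_by_tissue[[ti]][, sub$barcode, drop = FALSE], sub$sample_id)
      common_s <- intersect(colnames(pb), colnames(bulk))
      common_g <- intersect(rownames(pb), rownames(bulk))
      if (length(common_s) < 2) {
        note("tissue ", ti, ": fewer than 2 matched bulk samples, DE skipped")
        next
      }
      de <- wilcoxon_de(bulk[common_g, common_s, drop = FALSE],
                        pb[common_g, common_s, drop = FALSE], paired = TRUE)
      pseudo[[ti]] <- cbind(tissue = ti, de)
    }
    report$bulk_vs_pseudobulk <- do.call(rbind, pseudo)
  }

  report$log <- unlist(log)
  manifest <- list(package = "coldstab",
                   version = as.character(utils::packageVersion("coldstab")),
                   stages = config$stages,
                   seed = config$seed,
                   config_hash = object_hash(
                     config[setdiff(names(config), "output_dir")]))
  report$manifest <- manifest
  write_report(report, config$output_dir)
  class(report) <- "stability_report"
  report
}

# serialize every tabular stage output plus the manifest
write_report <- function(report, output_dir) {
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x)) write_tsv(x, file.path(output_dir,
                                                 paste0(nm, ".tsv")))
  }
  if (!is.null(report$log)) {
    writeLines(report$log, file.path(output_dir, "run_log.txt"))
  }
  jsonlite::write_json(report$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.stability_report <- function(x, ...) {
  tabs <- names(x)[vapply(x, is.data.frame, logical(1))]
  cat("stability_report with tables:", paste(tabs, collapse = ", "), "\n")
  invisible(x)
}
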