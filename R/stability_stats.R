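#' Cell-type groupings used for per-group time-variance summaries
#'
#' Ships the grouping of smaller or related cell types into classes
#' (Endothelial, Alveolar, Mono_macro, T_cell, NK, B_cell) used when
#' summarising the variance explained by storage time per cell-type group.
#'
#' @return named list: tissue -> list(group -> member cell types).
#' @export
cell_type_groupings <- function() {
  list(
    lung = list(
      Endothelial = c("Blood vessel", "Lymph vessel"),
      Alveolar = c("Alveolar Type 1", "Alveolar Type 2"),
      Mono_macro = c("Monocyte", "Macrophage_MARCOneg", "Macrophage_MARCOpos"),
      T_cell = c("T_CD4", "T_CD8_Cyt", "T_regulatory")),
    spleen = list(
      Mono_macro = c("Monocyte", "Macrophage"),
      NK = c("NK_FCGR3Apos", "NK_CD160pos"),
      T_cell = c("T_CD4_conv", "T_CD4_fh", "T_CD4_naive", "T_CD4_reg",
                 "T_CD8_activated", "T_CD8_CTL", "T_CD8_gd",
                 "T_CD8_MAIT-like", "T_cell_dividing"),
      B_cell = c("B_follicular", "B_Hypermutation", "B_mantle")))
}

#' Mitochondrial fold-change table per cell-type stratum
#'
#' For every (tissue, cell type, time) stratum the mean mitochondrial
#' percentage — over all cells of that stratum, including reassigned
#' high-MT cells — is compared to the same tissue and cell type at the
#' baseline time: `FC = mean(mt_pct at t) / mean(mt_pct at baseline)`.
#' Significance is a two-sided Wilcoxon rank-sum test of the per-cell
#' mt_pct values, BH-corrected across all (cell type x time) entries within
#' a tissue. Strata with fewer than `min_cells` cells on either side are
#' masked as `too_few_cells` (no FC or p reported); (tissue, time)
#' combinations without a sample are marked `missing_sample`.
#'
#' @param cells data.frame with columns tissue, cell_type, time_h, mt_pct.
#' @param min_cells masking threshold (default 5).
#' @param expected_times optional time points expected per tissue, used to
#'   emit `missing_sample` rows (default: times observed anywhere).
#' @return data.frame tissue, cell_type, time_h, n_cells, fc, p_value,
#'   p_adj, status.
#' @export
mito_fold_change <- function(cells, min_cells = 5, expected_times = NULL) {
  stopifnot(all(c("tissue", "cell_type", "time_h", "mt_pct") %in%
                  names(cells)))
  if (is.null(expected_times)) expected_times <- sort(unique(cells$time_h))
  t0 <- min(expected_times)
  rows <- list()
  for (ti in unique(cells$tissue)) {
    tis <- cells[cells$tissue == ti, ]
    present_times <- unique(tis$time_h)
    for (ct in sort(unique(tis$cell_type))) {
      base <- tis$mt_pct[tis$cell_type == ct & tis$time_h == t0]
      for (tl in expected_times) {
        cur <- tis$mt_pct[tis$cell_type == ct & tis$time_h == tl]
        n <- length(cur)
        row <- data.frame(tissue = ti, cell_type = ct, time_h = tl,
                          n_cells = n, fc = NA_real_, p_value = NA_real_,
                          p_adj = NA_real_, status = "ok",
                          stringsAsFactors = FALSE)
        if (!(tl %in% present_times)) {
          row$status <- "missing_sample"
        } else if (n < min_cells || length(base) < min_cells) {
          row$status <- "too_few_cells"
        } else if (tl == t0) {
          row$fc <- 1; row$p_value <- 1
        } else if (mean(base) == 0) {
          row$status <- "undefined_baseline"
        } else {
          row$fc <- mean(cur) / mean(base)
          row$p_value <- suppressWarnings(
            stats::wilcox.test(cur, base)$p.value)
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  for (ti in unique(out$tissue)) {
    sel <- out$tissue == ti & out$status == "ok" & !is.na(out$p_value)
    out$p_adj[sel] <- bh_adjust(out$p_value[sel])
  }
  rownames(out) <- NULL
  out
}

#' Reporting bins for adjusted p-values of fold-change strata
#'
#' Maps adjusted p-values onto the asterisk bins used for display:
#' `*` below 0.01, `**` below 1e-5, `***` below 1e-8.
#'
#' @param p_adj numeric vector of adjusted p-values.
#' @return character vector of "", "*", "**" or "***" (NA preserved).
#' @export
significance_bins <- function(p_adj) {
  ifelse(is.na(p_adj), NA_character_,
  ifelse(p_adj < 1e-8, "***",
  ifelse(p_adj < 1e-5, "**",
  ifelse(p_adj < 0.01, "*", ""))))
}

#' Cell-type composition per sample
#'
#' Proportion of each cell type among a sample's cells; types absent from a
#' sample but present in its tissue are reported as 0 so every sample covers
#' the same type set and rows sum to 1.
#'
#' @param cells data.frame with columns sample_id, donor, tissue, time_h,
#'   cell_type.
#' @return data.frame sample_id, donor, tissue, time_h, cell_type, n,
#'   proportion.
#' @export
composition_proportions <- function(cells) {
  stopifnot(all(c("sample_id", "donor", "tissue", "time_h", "cell_type")
                %in% names(cells)))
  out <- list()
  for (ti in unique(cells$tissue)) {
    tis <- cells[cells$tissue == ti, ]
    types <- sort(unique(tis$cell_type))
    for (sid in unique(tis$sample_id)) {
      s <- tis[tis$sample_id == sid, ]
      tab <- table(factor(s$cell_type, levels = types))
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid, donor = s$donor[1], tissue = ti,
        time_h = s$time_h[1], cell_type = types,
        n = as.integer(tab), proportion = as.numeric(tab) / nrow(s),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Composition change tests over storage time
#'
#' Per tissue and cell type, two-sided unpaired t tests of per-sample
#' proportions for (a) each pairwise contrast of the baseline time against a
#' later time and (b) the combined early time points (all but the last)
#' against the last time point. BH correction spans all cell types and
#' contrasts within a tissue. Contrasts with fewer than 2 samples on either
#' side are skipped.
#'
#' @param composition output of [composition_proportions()].
#' @return data.frame tissue, cell_type, contrast, p_value, p_adj, status.
#' @export
composition_time_tests <- function(composition) {
  out <- list()
  for (ti in unique(composition$tissue)) {
    tis <- composition[composition$tissue == ti, ]
    times <- sort(unique(tis$time_h))
    t0 <- times[1]; t_last <- times[length(times)]
    for (ct in sort(unique(tis$cell_type))) {
      sub <- tis[tis$cell_type == ct, ]
      contrasts <- c(lapply(times[-1], function(tl)
        list(name = sprintf("T%g_vs_T%g", t0, tl),
             a = sub$proportion[sub$time_h == t0],
             b = sub$proportion[sub$time_h == tl])),
        list(list(name = sprintf("combined_early_vs_T%g", t_last),
                  a = sub$proportion[sub$time_h != t_last],
                  b = sub$proportion[sub$time_h == t_last])))
      for (cc in contrasts) {
        if (length(cc$a) < 2 || length(cc$b) < 2) {
          out[[length(out) + 1]] <- data.frame(
            tissue = ti, cell_type = ct, contrast = cc$name,
            p_value = NA_real_, status = "skipped", stringsAsFactors = FALSE)
          next
        }
        p <- if (stats::sd(cc$a) == 0 && stats::sd(cc$b) == 0) {
          if (mean(cc$a) == mean(cc$b)) 1 else 0
        } else stats::t.test(cc$a, cc$b)$p.value
        out[[length(out) + 1]] <- data.frame(
          tissue = ti, cell_type = ct, contrast = cc$name, p_value = p,
          status = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  out$p_adj <- NA_real_
  for (ti in unique(out$tissue)) {
    sel <- out$tissue == ti & out$status == "ok"
    out$p_adj[sel] <- bh_adjust(out$p_value[sel])
  }
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of composition across donors
#'
#' Per tissue and cell type, a one-way ANOVA of per-sample proportion on
#' donor, BH-corrected across the tissue's cell types; reports the F
#' statistic, adjusted p and how many (tissue, cell type) combinations are
#' significant at `alpha`. Strata with a single donor error; strata whose
#' proportions are constant (zero residual and between variance) are
#' flagged degenerate.
#'
#' @param composition output of [composition_proportions()].
#' @param alpha significance level on adjusted p (default 0.05).
#' @return list with `tests` (tissue, cell_type, f, df1, df2, p_value,
#'   p_adj, status) and `n_significant`.
#' @export
composition_donor_anova <- function(composition, alpha = 0.05) {
  out <- list()
  for (ti in unique(composition$tissue)) {
    tis <- composition[composition$tissue == ti, ]
    if (length(unique(tis$donor)) < 2) {
      stop("tissue ", ti, " has a single donor; ANOVA needs >= 2")
    }
    for (ct in sort(unique(tis$cell_type))) {
      sub <- tis[tis$cell_type == ct, ]
      row <- data.frame(tissue = ti, cell_type = ct, f = NA_real_,
                        df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
                        p_adj = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      if (length(unique(sub$donor)) < 2 || nrow(sub) < 3) {
        row$status <- "skipped"
      } else if (stats::var(sub$proportion) == 0) {
        row$status <- "degenerate"
      } else {
        fit <- stats::aov(proportion ~ donor, data = sub)
        an <- summary(fit)[[1]]
        if (nrow(an) < 2 || an["Residuals", "Df"] == 0 ||
            is.na(an[1, "F value"])) {
          row$status <- "degenerate"
        } else {
          row$f <- an[1, "F value"]; row$df1 <- an[1, "Df"]
          row$df2 <- an["Residuals", "Df"]; row$p_value <- an[1, "Pr(>F)"]
        }
      }
      out[[length(out) + 1]] <- row
    }
  }
  out <- do.call(rbind, out)
  for (ti in unique(out$tissue)) {
    sel <- out$tissue == ti & out$status == "ok"
    out$p_adj[sel] <- bh_adjust(out$p_value[sel])
  }
  rownames(out) <- NULL
  list(tests = out,
       n_significant = sum(out$p_adj < alpha, na.rm = TRUE))
}

# marginal R^2 of one gene on one factor: SS_between / SS_total for
# categorical factors, squared Pearson correlation for continuous ones
marginal_r2_one <- function(y, f) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  if (is.numeric(f)) {
    if (stats::var(f) == 0) return(NA_real_)
    return(stats::cor(y, f)^2)
  }
  means <- tapply(y, f, mean)
  fit <- means[as.character(f)]
  1 - sum((y - fit)^2) / tss
}

#' Gene-wise marginal R-squared variance partition
#'
#' For each gene and each factor, the expression vector is fit on that
#' factor alone (group means for categorical factors, simple linear
#' regression for continuous ones such as library size or storage time);
#' marginal R² = 1 − RSS/TSS. Genes with zero variance are reported NA.
#' Optionally, donor and library-size effects can be residualized out of the
#' expression first, reproducing the per-cell-type time analysis in which
#' those confounders — but not time or the mitochondrial percentage — are
#' regressed away.
#'
#' @param expr normalized expression matrix, genes x cells.
#' @param factors data.frame of per-cell factors (each column categorical
#'   or numeric), rows aligned to cells.
#' @param residualize character vector of factor columns to regress out of
#'   expression before the partition (default none).
#' @return data.frame gene x factor in long form: gene, factor, r2.
#' @export
variance_explained <- function(expr, factors, residualize = character(0)) {
  if (ncol(expr) != nrow(factors)) stop("factors not aligned with cells")
  for (fc in names(factors)) {
    f <- factors[[fc]]
    if (!is.numeric(f) && length(unique(f)) < 2) {
      stop("constant factor '", fc, "'")
    }
  }
  expr <- as.matrix(expr)
  if (length(residualize)) {
    dn <- dimnames(expr)
    mm <- stats::model.matrix(
      ~ ., data = factors[, residualize, drop = FALSE])
    expr <- t(stats::resid(stats::lm.fit(mm, t(expr))))
    dimnames(expr) <- dn
  }
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("gene%05d", seq_len(nrow(expr)))
  }
  target <- setdiff(names(factors), residualize)
  out <- expand.grid(gene = rownames(expr), factor = target,
                     stringsAsFactors = FALSE)
  out$r2 <- NA_real_
  for (fc in target) {
    f <- factors[[fc]]
    r2 <- apply(expr, 1, marginal_r2_one, f = f)
    out$r2[out$factor == fc] <- r2
  }
  out
}

# mean-binned normalized dispersion (variable-gene ranking)
hvg_ranking <- function(expr, n_bins = 20) {
  m <- Matrix::rowMeans(expr)
  v <- apply(as.matrix(expr), 1, stats::var)
  disp <- ifelse(m > 0, v / m, 0)
  bins <- cut(rank(m, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    sel <- bins == b
    mu <- mean(disp[sel]); sdv <- stats::sd(disp[sel])
    z[sel] <- if (is.na(sdv) || sdv == 0) 0 else (disp[sel] - mu) / sdv
  }
  order(-z, rownames(expr))
}

#' Cross-organ subsampled hierarchical clustering
#'
#' Deterministically subsamples up to `n_per_stratum` cells per (cell type,
#' tissue, time, donor) stratum, selects the `n_hvg` most variable genes on
#' the subsample by mean-binned normalized dispersion, and clusters the
#' cells by average-linkage hierarchical clustering on correlation distance
#' (1 − Pearson r of log-normalized profiles).
#'
#' @param counts genes x cells count matrix.
#' @param labels data.frame with columns cell_type, tissue, time_h, donor,
#'   rows aligned to cells.
#' @param n_per_stratum cells kept per stratum (default 10).
#' @param n_hvg highly variable genes used (default 1000).
#' @param seed integer seed for the subsampling.
#' @return list with `hclust` (stats::hclust object), `leaves` (metadata of
#'   the clustered cells, in matrix column order) and `newick` (the tree in
#'   newick text).
#' @export
crossorgan_dendrogram <- function(counts, labels, n_per_stratum = 10,
                                  n_hvg = 1000, seed = 1L) {
  req <- c("cell_type", "tissue", "time_h", "donor")
  stopifnot(all(req %in% names(labels)), nrow(labels) == ncol(counts))
  stratum <- interaction(labels$cell_type, labels$tissue, labels$time_h,
                         labels$donor, drop = TRUE)
  if (nlevels(stratum) < 2) stop("need at least 2 strata to cluster")
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(stratum), stratum), function(ix) {
      if (length(ix) <= n_per_stratum) ix else
        sort(sample(ix, n_per_stratum))
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  sub <- counts[, idx, drop = FALSE]
  ln <- log_normalize(sub)
  keep <- utils::head(hvg_ranking(ln), min(n_hvg, nrow(ln)))
  ln <- ln[keep, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(ln))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  leaves <- labels[idx, req, drop = FALSE]
  leaves$cell <- colnames(sub)
  if (is.null(leaves$cell)) leaves$cell <- sprintf("cell%05d", idx)
  rownames(leaves) <- NULL
  hc$labels <- leaves$cell
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaves = leaves,
       newick = ape::write.tree(phy))
}
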