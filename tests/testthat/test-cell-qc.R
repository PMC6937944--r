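test_that("read-category fractions normalize, flag zero totals and are scale invariant", {
  rc <- data.frame(barcode = c("a", "b"), exonic = c(8, 0),
                   intronic = c(2, 0), intergenic = c(0, 0))
  fr <- read_category_fractions(rc)
  expect_equal(fr$exonic_frac[1], 0.8)
  expect_equal(fr$intronic_frac[1], 0.2)
  expect_equal(fr$intergenic_frac[1], 0)
  expect_true(fr$flagged[2])
  expect_true(is.na(fr$exonic_frac[2]))
  ok <- !fr$flagged
  expect_equal(fr$exonic_frac[ok] + fr$intronic_frac[ok] +
                 fr$intergenic_frac[ok], rep(1, sum(ok)))
  rc10 <- rc
  rc10[, 2:4] <- rc10[, 2:4] * 10L
  expect_equal(read_category_fractions(rc10)$exonic_frac, fr$exonic_frac)
  expect_error(read_category_fractions(data.frame(barcode = "a", exonic = -1,
                                                  intronic = 0,
                                                  intergenic = 0)),
               "non-negative")
})

test_that("quartile extremes use ceiling(n/4) cells with deterministic ties", {
  fr <- data.frame(barcode = sprintf("b%02d", 1:8), sample_id = "s1",
                   exonic_frac = seq(0.1, 0.8, by = 0.1), flagged = FALSE)
  qe <- quartile_extremes(fr, "exonic")
  expect_equal(qe$top_quartile_mean, mean(c(0.7, 0.8)))
  expect_equal(qe$bottom_quartile_mean, mean(c(0.1, 0.2)))

  fr2 <- data.frame(barcode = sprintf("b%02d", 1:6), sample_id = "s1",
                    exonic_frac = 0.4, flagged = FALSE)
  qe2 <- quartile_extremes(fr2, "exonic")
  expect_equal(qe2$top_quartile_mean, 0.4)
  expect_equal(qe2$bottom_quartile_mean, 0.4)

  fr3 <- data.frame(barcode = c("a", "b", "c"), sample_id = "s1",
                    exonic_frac = c(0.1, 0.2, 0.3), flagged = FALSE)
  expect_warning(quartile_extremes(fr3, "exonic"), "fewer than 4")
})

test_that("an injected intron shift moves the bottom exonic quartile by about the shift", {
  deg <- degradation_params(
    intron_shift = data.frame(tissue = "spleen", time_h = 72, shift = 0.15))
  cfg <- tiny_config(n_donors = 1, n_cells = 200, mean_umis = 500,
                     degradation = deg, seed = 14)
  exp <- generate_experiment(cfg)
  qs <- lapply(exp$samples, function(s) {
    fr <- read_category_fractions(s$read_categories)
    fr$sample_id <- s$metadata$sample_id
    cbind(quartile_extremes(fr, "exonic"), time_h = s$metadata$time_h,
          se = stats::sd(fr$exonic_frac, na.rm = TRUE) /
            sqrt(ceiling(nrow(fr) / 4)))
  })
  qs <- do.call(rbind, qs)
  drop_bottom <- qs$bottom_quartile_mean[qs$time_h == 0] -
    qs$bottom_quartile_mean[qs$time_h == 72]
  se <- sqrt(sum(qs$se^2))
  expect_lt(abs(drop_bottom - 0.15), 3 * se)
})

# dense brute-force construction used to cross-check the filters
plant_matrix <- function() {
  set.seed(31)
  genes <- c(sprintf("G%04d", 1:395), sprintf("MT-%d", 1:5))
  cases <- list(
    keep = list(n_det = 320, depth = 3000, mt = 0.05),
    low_genes = list(n_det = 250, depth = 3000, mt = 0.05),
    boundary_min = list(n_det = 300, depth = 3000, mt = 0.05),
    high_umi = list(n_det = 320, depth = 25000, mt = 0.05),
    boundary_umi = list(n_det = 320, depth = 20000, mt = 0.05),
    high_mt = list(n_det = 320, depth = 3000, mt = 0.25),
    boundary_mt = list(n_det = 320, depth = 3000, mt = 0.10))
  cols <- list(); label <- character(0)
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    for (r in 1:4) {
      v <- numeric(400)
      body <- sample(1:395, cs$n_det - 5)
      mt_total <- round(cs$depth * cs$mt)
      v[body] <- 1  # guarantee the planted detection count exactly
      extra <- tabulate(sample(body, cs$depth - mt_total - length(body),
                               replace = TRUE), nbins = 400)
      v <- v + extra
      v[396:400] <- c(mt_total - 4, 1, 1, 1, 1)
      cols[[length(cols) + 1]] <- v
      label <- c(label, nm)
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(genes, sprintf("%s_%d", label, seq_along(label)))
  Matrix::Matrix(m, sparse = TRUE)
}

test_that("cell filters match a brute-force application of the thresholds", {
  m <- plant_matrix()
  fl <- filter_cells(m, tissue = "lung")
  cov <- cell_covariates(m)
  brute_keep <- cov$n_genes >= 300 & cov$n_genes <= 5000 &
    cov$n_counts <= 20000 & cov$mt_pct <= 10
  expect_identical(sort(fl$cells$barcode), sort(cov$barcode[brute_keep]))
  expect_identical(nrow(fl$cells) + nrow(fl$removal_log), ncol(m))
  expect_true(all(grepl("^low_genes", fl$removal_log$barcode) ==
                    (fl$removal_log$rule == "min_genes")))
  # exactly the planted keepers and boundary cells survive
  expect_setequal(unique(sub("_\\d+$", "", fl$cells$barcode)),
                  c("keep", "boundary_min", "boundary_umi", "boundary_mt"))
  expect_error(filter_cells(m, tissue = "kidney"), "unknown tissue")
})

test_that("the esophagus gene ceiling is 8000 instead of 5000", {
  set.seed(32)
  genes <- c(sprintf("G%04d", 1:6995), sprintf("MT-%d", 1:5))
  v <- numeric(7000)
  v[sample(1:6995, 5995)] <- 1
  v[6996] <- 5  # modest MT content
  m <- Matrix::Matrix(cbind(big = v), sparse = TRUE)
  rownames(m) <- genes
  colnames(m) <- "big"
  expect_identical(nrow(filter_cells(m, tissue = "esophagus")$cells), 1L)
  fl <- filter_cells(m, tissue = "lung")
  expect_identical(fl$removal_log$rule, "max_genes")
})

test_that("gene filtering keeps genes detected in at least three cells and is idempotent", {
  m <- Matrix::Matrix(rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 2, 3, 0),
                            g3 = c(0, 0, 0, 0)), sparse = TRUE)
  colnames(m) <- sprintf("c%d", 1:4)
  f1 <- filter_genes(m)
  expect_identical(rownames(f1), "g2")
  expect_equal(as.matrix(filter_genes(f1)), as.matrix(f1))
  empty <- m[, 0, drop = FALSE]
  expect_identical(nrow(filter_genes(empty)), 0L)
})

test_that("high-mito rates use a strict cutoff on the unfiltered table", {
  cells <- data.frame(sample_id = "s1", mt_pct = c(5, 15, 25, 5))
  expect_equal(high_mito_rate(cells)$high_mt_rate, 0.5)
  cells2 <- data.frame(sample_id = "s1", mt_pct = rep(10, 4))
  expect_equal(high_mito_rate(cells2)$high_mt_rate, 0)
})

test_that("a strong MT fold change raises the high-MT rate at 72 h in nearly all donors", {
  deg <- degradation_params(
    mt_fold_change = data.frame(tissue = "spleen", cell_type = "*",
                                time_h = 72, fold = 3))
  hits <- 0; n_runs <- 100
  for (r in seq_len(n_runs)) {
    cfg <- tiny_config(n_donors = 1, n_cells = 60, mean_umis = 600,
                       degradation = deg, seed = 1000L + r)
    exp <- generate_experiment(cfg)
    cells <- cells_from_experiment(exp)
    hr <- high_mito_rate(cells)
    hr <- merge(hr, exp$samples_df, by = "sample_id")
    if (hr$high_mt_rate[hr$time_h == 72] > hr$high_mt_rate[hr$time_h == 0])
      hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("sample metrics report medians and flat metrics give adjusted p of 1", {
  cells <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                      barcode = sprintf("b%d", 1:4),
                      n_genes = c(100, 200, 100, 200))
  rc <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                   barcode = sprintf("b%d", 1:4),
                   exonic = c(80, 80, 80, 80), intronic = c(15, 15, 15, 15),
                   intergenic = c(5, 5, 5, 5))
  samples <- data.frame(sample_id = c("s1", "s2"), donor = c("d1", "d2"),
                        tissue = "spleen", time_h = c(0, 72))
  sm <- sample_metrics(cells, rc, samples)
  expect_equal(sm$metrics$median_genes, c(150, 150))
  expect_equal(sm$metrics$total_confident_reads, c(200, 200))
  # single sample per group: tests skipped and flagged
  expect_true(all(sm$trend_tests$status == "skipped_single_sample"))

  samples4 <- data.frame(sample_id = sprintf("s%d", 1:4),
                         donor = sprintf("d%d", 1:4), tissue = "spleen",
                         time_h = c(0, 0, 72, 72))
  cells4 <- data.frame(sample_id = rep(sprintf("s%d", 1:4), each = 2),
                       barcode = sprintf("b%d", 1:8),
                       n_genes = rep(c(100, 200), 4))
  rc4 <- data.frame(sample_id = rep(sprintf("s%d", 1:4), each = 2),
                    barcode = sprintf("b%d", 1:8), exonic = 80,
                    intronic = 15, intergenic = 5)
  sm4 <- sample_metrics(cells4, rc4, samples4)
  ok <- sm4$trend_tests$status == "ok"
  expect_true(all(sm4$trend_tests$p_adj[ok] == 1))
})
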