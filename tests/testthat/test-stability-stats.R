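fake_cells <- function(tissue, cell_type, time_h, mt_pct,
                       donor = "d1") {
  data.frame(tissue = tissue, cell_type = cell_type, time_h = time_h,
             mt_pct = mt_pct, donor = donor, stringsAsFactors = FALSE)
}

test_that("fold changes are 1 at baseline and masking follows the 5-cell rule exactly", {
  set.seed(41)
  cells <- rbind(
    fake_cells("spleen", "A", 0, rnorm(50, 5, 0.5)),
    fake_cells("spleen", "A", 12, rnorm(50, 5, 0.5)),
    fake_cells("spleen", "A", 72, rnorm(4, 15, 0.5)),    # < 5 cells: masked
    fake_cells("spleen", "B", 0, rnorm(50, 5, 0.5)),
    fake_cells("spleen", "B", 12, rnorm(50, 10, 0.5)),
    fake_cells("spleen", "B", 72, rnorm(50, 10, 0.5)))
  fc <- mito_fold_change(cells, expected_times = c(0, 12, 24, 72))
  a72 <- fc[fc$cell_type == "A" & fc$time_h == 72, ]
  expect_identical(a72$status, "too_few_cells")
  expect_true(is.na(a72$fc) && is.na(a72$p_adj))
  expect_identical(unique(fc$status[fc$time_h == 24]), "missing_sample")
  a0 <- fc[fc$cell_type == "A" & fc$time_h == 0, ]
  expect_equal(a0$fc, 1)
  expect_equal(a0$p_value, 1)
  b12 <- fc[fc$cell_type == "B" & fc$time_h == 12, ]
  expect_equal(b12$fc, 2, tolerance = 0.05)
  expect_lt(b12$p_adj, 0.01)
  expect_true(all(fc$fc[!is.na(fc$fc)] > 0))
  # masking rule is exact: n < 5 <=> too_few_cells among present samples
  present <- fc$status != "missing_sample"
  expect_identical(fc$status[present] == "too_few_cells",
                   fc$n_cells[present] < 5)
})

test_that("significance bins reproduce the asterisk thresholds", {
  expect_identical(significance_bins(c(0.02, 0.009, 1e-6, 1e-9, NA)),
                   c("", "*", "**", "***", NA))
})

test_that("an injected MT fold change of 2 is recovered within 10% at 500 cells per stratum", {
  deg <- degradation_params(
    mt_fold_change = data.frame(tissue = "spleen", cell_type = "*",
                                time_h = 72, fold = 2))
  cfg <- tiny_config(n_donors = 1, n_cells = 1000, mean_umis = 2000,
                     degradation = deg, seed = 23)
  exp <- generate_experiment(cfg)
  cells <- cells_from_experiment(exp)
  expect_gte(min(table(cells$cell_type, cells$time_h)), 400)
  fc <- mito_fold_change(cells)
  late <- fc[fc$time_h == 72, ]
  expect_true(all(late$status == "ok"))
  expect_true(all(abs(late$fc - 2) <= 0.2))
  expect_true(all(late$p_adj < 0.01))
})

test_that("composition proportions cover missing types with zeros and sum to one", {
  cells <- data.frame(sample_id = rep(c("s1", "s2"), c(4, 3)),
                      donor = "d1", tissue = "spleen",
                      time_h = rep(c(0, 72), c(4, 3)),
                      cell_type = c("A", "A", "A", "B", "A", "A", "A"))
  comp <- composition_proportions(cells)
  s1 <- comp[comp$sample_id == "s1", ]
  expect_equal(sort(s1$proportion), c(0.25, 0.75))
  s2 <- comp[comp$sample_id == "s2", ]
  expect_equal(s2$proportion[s2$cell_type == "B"], 0)
  sums <- tapply(comp$proportion, comp$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, 2))
})

test_that("composition recovery stays within multinomial 3-SE bands", {
  pi_true <- c(alpha = 0.7, beta = 0.3)
  cfg <- tiny_config(n_donors = 1, n_cells = 1000, mean_umis = 400,
                     seed = 2, cell_type_proportions = pi_true)
  exp <- generate_experiment(cfg)
  cells <- cells_from_experiment(exp)
  comp <- composition_proportions(cells)
  for (i in seq_len(nrow(comp))) {
    p <- pi_true[[comp$cell_type[i]]]
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(comp$proportion[i] - p), 3 * se)
  }
})

test_that("identical compositions across time give adjusted p of 1 and halving a type is detected", {
  comp_const <- expand.grid(sample_id = sprintf("s%d", 1:8),
                            cell_type = c("A", "B"),
                            stringsAsFactors = FALSE)
  comp_const$tissue <- "spleen"
  comp_const$donor <- rep(sprintf("d%d", 1:8), 2)
  comp_const$time_h <- rep(c(0, 12, 24, 72), 4)
  comp_const$proportion <- ifelse(comp_const$cell_type == "A", 0.6, 0.4)
  tt <- composition_time_tests(comp_const)
  expect_true(all(tt$p_adj[tt$status == "ok"] == 1))

  # power: proportion of one type halved at 72 h across 6 donors
  set.seed(99)
  hits <- 0; n_runs <- 40
  for (r in seq_len(n_runs)) {
    rows <- expand.grid(donor = sprintf("d%d", 1:6),
                        time_h = c(0, 12, 24, 72),
                        stringsAsFactors = FALSE)
    rows$sample_id <- paste0(rows$donor, "_", rows$time_h)
    rows$tissue <- "spleen"
    pa <- ifelse(rows$time_h == 72, 0.2, 0.4)
    pa <- pmin(pmax(pa + rnorm(nrow(rows), 0, 0.04), 0.01), 0.99)
    comp <- rbind(
      transform(rows, cell_type = "A", proportion = pa),
      transform(rows, cell_type = "B", proportion = 1 - pa))
    tt <- composition_time_tests(comp)
    hit <- tt$p_adj[tt$cell_type == "A" &
                      grepl("combined", tt$contrast)] < 0.05
    if (isTRUE(hit)) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.8)
})

test_that("donor ANOVA flags degenerate strata and detects a deviant donor", {
  comp <- expand.grid(donor = c("d1", "d2"), rep = 1:2,
                      stringsAsFactors = FALSE)
  comp$sample_id <- paste0(comp$donor, "_", comp$rep)
  comp$tissue <- "spleen"; comp$time_h <- 0; comp$cell_type <- "A"
  comp$proportion <- 0.5
  res <- composition_donor_anova(comp)
  expect_identical(res$tests$status, "degenerate")
  expect_identical(res$n_significant, 0L)

  one_donor <- comp[comp$donor == "d1", ]
  expect_error(composition_donor_anova(one_donor), "single donor")

  set.seed(7)
  hits <- 0; n_runs <- 40
  for (r in seq_len(n_runs)) {
    grid <- expand.grid(donor = sprintf("d%d", 1:4), rep = 1:4,
                        stringsAsFactors = FALSE)
    grid$sample_id <- paste0(grid$donor, "_", grid$rep)
    grid$tissue <- "spleen"; grid$time_h <- 0; grid$cell_type <- "A"
    mu <- ifelse(grid$donor == "d1", 0.4, 0.1)
    grid$proportion <- pmax(mu + rnorm(nrow(grid), 0, 0.02), 0.001)
    res <- composition_donor_anova(grid)
    if (res$n_significant == 1) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("marginal R2 is 1 for factor-determined genes and near 0 for independent ones", {
  set.seed(5)
  f <- rep(c("x", "y"), each = 500)
  expr <- rbind(determined = ifelse(f == "x", 1, 3),
                independent = rnorm(1000))
  vp <- variance_explained(expr, data.frame(grp = f))
  expect_equal(vp$r2[vp$gene == "determined"], 1)
  expect_lt(vp$r2[vp$gene == "independent"], 0.02)
  # zero-variance gene reported missing
  expr2 <- rbind(flat = rep(2, 1000))
  vp2 <- variance_explained(expr2, data.frame(grp = f))
  expect_true(is.na(vp2$r2))
  expect_error(variance_explained(expr, data.frame(konst = rep("z", 1000))),
               "konst")
})

test_that("marginal R2 recovers a planted donor effect and is invariant to factor relabelling", {
  set.seed(6)
  donor <- rep(sprintf("d%d", 1:4), each = 250)
  mu <- c(d1 = -1, d2 = 1, d3 = -1, d4 = 1)[donor]
  expr <- t(replicate(40, mu + rnorm(1000, 0, 1)))
  rownames(expr) <- sprintf("g%02d", 1:40)
  vp <- variance_explained(expr, data.frame(donor = donor))
  med <- median(vp$r2)
  expect_gt(med, 0.45); expect_lt(med, 0.55)
  relabelled <- c(d1 = "P", d2 = "Q", d3 = "R", d4 = "S")[donor]
  vp2 <- variance_explained(expr, data.frame(donor = relabelled))
  expect_equal(vp$r2, vp2$r2)
})

test_that("continuous factors use squared correlation and residualization removes the confounder", {
  set.seed(8)
  n <- 400
  depth <- rnorm(n)
  time <- rep(c(0, 72), each = n / 2)
  g <- 0.8 * depth + rnorm(n, 0, 0.6)
  expr <- rbind(gene = g)
  vp <- variance_explained(expr, data.frame(n_counts = depth))
  expect_equal(vp$r2, cor(g, depth)^2, tolerance = 1e-10)
  vp_res <- variance_explained(expr,
                               data.frame(n_counts = depth, time = time),
                               residualize = "n_counts")
  expect_identical(unique(vp_res$factor), "time")
  expect_lt(vp_res$r2, 0.02)
})

test_that("cross-organ dendrogram subsamples strata, merges duplicates first and recovers types", {
  exp <- generate_experiment(tiny_config(n_donors = 2, n_cells = 120,
                                         n_genes = 60, mean_umis = 2000,
                                         seed = 13))
  cells <- cells_from_experiment(exp)
  counts <- do.call(cbind, lapply(exp$samples, function(s) {
    sel <- s$truth$droplets$class == "cell"
    m <- s$droplets$counts[, sel, drop = FALSE]
    colnames(m) <- paste(s$metadata$sample_id, colnames(m), sep = ":")
    m
  }))
  labels <- cells[, c("cell_type", "tissue", "time_h", "donor")]
  res <- crossorgan_dendrogram(counts, labels, n_per_stratum = 10,
                               n_hvg = 50, seed = 3)
  per_stratum <- table(interaction(res$leaves$cell_type, res$leaves$donor,
                                   res$leaves$time_h, drop = TRUE))
  expect_true(all(per_stratum <= 10))
  expect_gt(nrow(res$leaves), 10)
  # two identical cells merge at height 0 first
  dup <- cbind(counts[, 1, drop = FALSE], counts[, 1, drop = FALSE],
               counts[, 2:6])
  colnames(dup) <- sprintf("c%d", 1:7)
  lab_dup <- labels[c(1, 1, 2:6), ]
  res_dup <- crossorgan_dendrogram(dup, lab_dup, seed = 1)
  expect_equal(res_dup$hclust$height[1], 0, tolerance = 1e-10)
  first <- abs(res_dup$hclust$merge[1, ])
  expect_setequal(first, c(1, 2))
  # cutting at the number of types recovers the type partition
  k <- length(unique(res$leaves$cell_type))
  cut <- stats::cutree(res$hclust, k = k)
  expect_gte(adjusted_rand(cut, res$leaves$cell_type), 0.9)
  expect_match(res$newick, "^\\(")
  expect_error(crossorgan_dendrogram(counts[, 1, drop = FALSE],
                                     labels[1, , drop = FALSE]),
               "2 strata")
})
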