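#' Aggregate single cells into per-sample pseudo-bulk
#'
#' Sums raw counts of all cells assigned to each sample, preserving the
#' gene universe; the provenance attribute records how many cells
#' contributed per sample.
#'
#' @param counts genes x cells count matrix.
#' @param sample_of sample identifier per cell (no NAs).
#' @return integer matrix genes x samples with attribute `n_cells`.
#' @export
make_pseudobulk <- function(counts, sample_of) {
  if (length(sample_of) != ncol(counts)) {
    stop("sample assignment not aligned with cells")
  }
  if (anyNA(sample_of)) {
    bad <- colnames(counts)[is.na(sample_of)]
    stop("unassigned cells: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  samples <- sort(unique(sample_of))
  out <- vapply(samples, function(s) {
    as.numeric(Matrix::rowSums(counts[, sample_of == s, drop = FALSE]))
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), samples))
  attr(out, "n_cells") <- stats::setNames(
    as.integer(table(sample_of)[samples]), samples)
  out
}

#' Wilcoxon differential expression between matched sample groups
#'
#' Per gene, both matrices are normalized to counts per million and compared
#' across samples by a Wilcoxon test: the signed-rank test on matched pairs
#' when `paired = TRUE` (zero-difference pairs dropped per the test's
#' convention), the rank-sum test otherwise. P-values are BH-corrected
#' across tested genes, and the effect size is the median over samples of
#' `log2((a + 1) / (b + 1))` on the CPM scale (pseudocount of one
#' normalized count). Genes with all-zero values in both groups are
#' reported untested.
#'
#' @param group_a,group_b gene x sample count matrices with identical gene
#'   universes; columns matched pairwise when `paired`.
#' @param paired logical (default TRUE: signed-rank).
#' @param normalize set FALSE if the matrices are already on a common scale.
#' @return data.frame gene, p_value, p_adj, median_log2fc, direction,
#'   n_used, status.
#' @export
wilcoxon_de <- function(group_a, group_b, paired = TRUE, normalize = TRUE) {
  if (nrow(group_a) != nrow(group_b)) stop("gene universes differ")
  if (paired && ncol(group_a) != ncol(group_b)) {
    stop("paired comparison requires matched sample columns")
  }
  a <- if (normalize) as.matrix(cpm(group_a)) else as.matrix(group_a)
  b <- if (normalize) as.matrix(cpm(group_b)) else as.matrix(group_b)
  genes <- rownames(a)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(a)))
  n <- nrow(a)
  p <- rep(NA_real_, n); med <- rep(NA_real_, n)
  n_used <- integer(n); status <- rep("ok", n)
  for (g in seq_len(n)) {
    x <- a[g, ]; y <- b[g, ]
    if (all(x == 0) && all(y == 0)) {
      status[g] <- "untested"; next
    }
    if (paired) {
      d <- x - y
      usable <- sum(d != 0)
      n_used[g] <- usable
      med[g] <- stats::median(log2((x + 1) / (y + 1)))
      if (usable == 0) { p[g] <- 1; next }  # all pairs tie: no evidence
      p[g] <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE)$p.value)
    } else {
      n_used[g] <- length(x) + length(y)
      med[g] <- stats::median(log2((x + 1) / (y + 1)))
      if (length(x) < 2 || length(y) < 2) { status[g] <- "untested"; next }
      if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) { p[g] <- 1; next }
      p[g] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
  }
  if (all(status == "untested")) stop("zero genes tested")
  out <- data.frame(gene = genes, p_value = p, p_adj = NA_real_,
                    median_log2fc = med,
                    direction = ifelse(is.na(med) | med == 0, "none",
                                       ifelse(med > 0, "up_in_a", "up_in_b")),
                    n_used = n_used, status = status,
                    stringsAsFactors = FALSE)
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- bh_adjust(out$p_value[tested])
  out
}

#' Per-cell-type storage-time expression signatures
#'
#' For every cell type with at least `min_cells` cells in both time groups,
#' each gene's log-normalized expression at the baseline time is compared
#' with the late time by a two-sided Wilcoxon rank-sum test; the signature
#' is the set of genes below `alpha` on the BH-adjusted p, ranked by
#' absolute effect (median difference of log-normalized expression). A
#' Jaccard similarity matrix over the cell-type signatures is also
#' returned, to examine whether signatures group by organ.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param cells data.frame aligned to columns with cell_type and time_h.
#' @param t0_label,late_label the two time points compared.
#' @param min_cells per-group minimum (default 20; smaller types skipped).
#' @param alpha adjusted-p cutoff defining the signature (default 0.01).
#' @return list with `tables` (per-cell-type DE data.frames), `signatures`
#'   (per-cell-type ranked gene vectors), `jaccard` (similarity matrix) and
#'   `skipped`.
#' @export
storage_signature <- function(expr, cells, t0_label = 0, late_label = 72,
                              min_cells = 20, alpha = 0.01) {
  stopifnot(ncol(expr) == nrow(cells))
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  tables <- list(); signatures <- list(); skipped <- character(0)
  for (ct in sort(unique(cells$cell_type))) {
    ia <- which(cells$cell_type == ct & cells$time_h == t0_label)
    ib <- which(cells$cell_type == ct & cells$time_h == late_label)
    if (length(ia) < min_cells || length(ib) < min_cells) {
      skipped <- c(skipped, ct); next
    }
    p <- numeric(nrow(expr)); eff <- numeric(nrow(expr))
    for (g in seq_len(nrow(expr))) {
      x <- expr[g, ib]; y <- expr[g, ia]
      eff[g] <- stats::median(x) - stats::median(y)
      p[g] <- if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) 1 else
        suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
    p_adj <- bh_adjust(p)
    tab <- data.frame(gene = genes, p_value = p, p_adj = p_adj,
                      effect = eff, stringsAsFactors = FALSE)
    sig <- tab[!is.na(tab$p_adj) & tab$p_adj < alpha, ]
    sig <- sig[order(-abs(sig$effect), sig$gene), ]
    tables[[ct]] <- tab
    signatures[[ct]] <- sig$gene
  }
  k <- length(signatures)
  jac <- matrix(NA_real_, k, k,
                dimnames = list(names(signatures), names(signatures)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    u <- union(signatures[[i]], signatures[[j]])
    jac[i, j] <- if (length(u) == 0) 0 else
      length(intersect(signatures[[i]], signatures[[j]])) / length(u)
  }
  list(tables = tables, signatures = signatures, jaccard = jac,
       skipped = skipped)
}

#' Fisher's exact overrepresentation of one gene set in another
#'
#' One-sided (enrichment) exact hypergeometric test of the overlap between
#' a signature and a reference gene set within a universe, with a
#' Haldane-corrected odds ratio when a margin cell is zero.
#'
#' @param signature,reference character gene sets, both subsets of
#'   `universe`.
#' @param universe the gene universe.
#' @return list with overlap, odds_ratio, p_value and the 2x2 table.
#' @export
signature_overlap_fisher <- function(signature, reference, universe) {
  if (length(universe) == 0) stop("empty universe")
  signature <- unique(signature); reference <- unique(reference)
  universe <- unique(universe)
  if (!all(signature %in% universe) || !all(reference %in% universe)) {
    stop("signature and reference must be subsets of the universe")
  }
  k <- length(intersect(signature, reference))
  m <- length(reference)
  n <- length(universe) - m
  s <- length(signature)
  # P(X >= k) for X ~ Hypergeometric(m, n, s)
  p <- stats::phyper(k - 1, m, n, s, lower.tail = FALSE)
  tab <- matrix(c(k, s - k, m - k, n - (s - k)), 2, 2,
                dimnames = list(c("in_ref", "out_ref"),
                                c("in_sig", "out_sig")))
  tb <- tab
  if (any(tab == 0)) tb <- tab + 0.5
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  list(overlap = k, odds_ratio = or, p_value = p, table = tab)
}

#' Default dissociation-related gene set
#'
#' The immediate-early stress genes induced by tissue dissociation that ship
#' as the default reference for overrepresentation tests; extend via
#' `extra`.
#'
#' @param extra additional gene symbols to append.
#' @return character vector of gene symbols.
#' @export
dissociation_genes <- function(extra = character(0)) {
  unique(c("FOS", "FOSB", "JUN", "JUNB", extra))
}
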