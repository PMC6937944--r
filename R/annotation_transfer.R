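#' Select informative features by dropout-vs-expression residuals
#'
#' Per gene, the dropout rate (fraction of zero cells) is regressed on log
#' mean expression; the `n_features` genes with the largest positive
#' residuals — more dropout than their expression level predicts — are
#' selected. When fewer than `n_features` genes are eligible the selection
#' falls back to the top-variance genes of the log-normalized matrix.
#'
#' @param counts genes x cells count matrix with feature rownames.
#' @param n_features number of features to select (default 500).
#' @return character vector of selected feature names.
#' @export
select_informative_features <- function(counts, n_features = 500) {
  feats <- rownames(counts)
  dropout <- 1 - Matrix::rowSums(counts > 0) / ncol(counts)
  mean_expr <- Matrix::rowSums(counts) / ncol(counts)
  eligible <- dropout > 0 & dropout < 1 & mean_expr > 0
  if (sum(eligible) >= min(n_features, length(feats))) {
    fit <- stats::lm(dropout[eligible] ~ log(mean_expr[eligible]))
    res <- stats::residuals(fit)
    ord <- order(-res, feats[eligible])
    sel <- feats[eligible][ord]
  } else {
    ln <- log_normalize(counts)
    v <- apply(ln, 1, stats::var)
    sel <- feats[order(-v, feats)]
  }
  utils::head(sel, min(n_features, length(sel)))
}

#' Build cell-type centroids from a low-mitochondrial reference
#'
#' Centroids are per-gene medians of log-normalized expression within each
#' cell type, restricted to features chosen by
#' [select_informative_features()]. Reference cells are expected to pass
#' the mitochondrial filter (at most 10% MT); the centroid index is then
#' used to place high-MT cells excluded from clustering.
#'
#' @param counts genes x cells count matrix of reference cells.
#' @param labels cell-type label per reference cell.
#' @param n_features number of features in the index (default 500).
#' @param threshold similarity threshold stored in the index (default 0.7).
#' @return object of class `centroid_index`: list with `centroids`
#'   (features x types), `features`, `threshold`, `measure`.
#' @export
build_centroids <- function(counts, labels, n_features = 500,
                            threshold = 0.7) {
  if (length(labels) != ncol(counts)) stop("labels not aligned with counts")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must lie in (0, 1]")
  empty <- setdiff(unique(labels), labels[!is.na(labels)])
  tab <- table(labels)
  if (any(tab == 0)) {
    stop("cell types with zero reference cells: ",
         paste(names(tab)[tab == 0], collapse = ", "))
  }
  feats <- select_informative_features(counts, n_features)
  ln <- log_normalize(counts)[feats, , drop = FALSE]
  types <- sort(unique(labels))
  cen <- vapply(types, function(ty) {
    apply(ln[, labels == ty, drop = FALSE], 1, stats::median)
  }, numeric(length(feats)))
  cen <- matrix(cen, nrow = length(feats),
                dimnames = list(feats, types))
  structure(list(centroids = cen, features = feats, threshold = threshold,
                 measure = "cosine"),
            class = "centroid_index")
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Assign query cells to their nearest centroid
#'
#' Cosine similarity between each query cell's log-normalized profile and
#' every centroid, on the shared feature set; the arg-max label is assigned
#' when its similarity reaches the index threshold, otherwise the cell is
#' unassigned. Exact ties go to the lexicographically first label and are
#' flagged. Requires at least 50% of the index features to be present in
#' the query matrix.
#'
#' @param counts genes x cells count matrix of query cells.
#' @param index a [build_centroids()] index.
#' @param threshold optional override of the index threshold.
#' @return data.frame barcode, label ("unassigned" below threshold),
#'   similarity, assigned, tie.
#' @export
assign_by_similarity <- function(counts, index, threshold = NULL) {
  stopifnot(inherits(index, "centroid_index"))
  if (is.null(threshold)) threshold <- index$threshold
  shared <- intersect(index$features, rownames(counts))
  if (length(shared) < 0.5 * length(index$features)) {
    stop("query features overlap index features by ",
         round(100 * length(shared) / length(index$features)), "% (< 50%)")
  }
  ln <- log_normalize(counts)[shared, , drop = FALSE]
  cen <- index$centroids[shared, , drop = FALSE]
  types <- colnames(cen)
  sims <- matrix(NA_real_, ncol(ln), length(types),
                 dimnames = list(colnames(ln), types))
  for (k in seq_along(types)) {
    sims[, k] <- apply(ln, 2, cosine_sim, b = cen[, k])
  }
  best <- apply(sims, 1, max)
  tie <- apply(sims, 1, function(s) sum(s == max(s)) > 1)
  label <- types[apply(sims, 1, which.max)]  # which.max: first = lexicographic
  assigned <- best >= threshold
  data.frame(barcode = colnames(ln),
             label = ifelse(assigned, label, "unassigned"),
             similarity = best, assigned = assigned, tie = tie,
             stringsAsFactors = FALSE)
}
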