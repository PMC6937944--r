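#' Droplet table for one sequencing run
#'
#' Per-barcode UMI totals and per-gene counts before any cell calling. The
#' UMI total of each barcode is the column sum of its gene counts; this is
#' enforced at construction.
#'
#' @param sample_id run identifier.
#' @param barcodes character vector, unique within the run.
#' @param counts sparse genes x barcodes count matrix.
#' @param features gene identifiers (rows of `counts`).
#' @return object of class `droplet_table`.
#' @export
droplet_table <- function(sample_id, barcodes, counts, features) {
  if (anyDuplicated(barcodes)) stop("barcodes must be unique within a sample")
  if (ncol(counts) != length(barcodes)) {
    stop("counts has ", ncol(counts), " columns but ", length(barcodes),
         " barcodes")
  }
  if (nrow(counts) != length(features)) {
    stop("counts has ", nrow(counts), " rows but ", length(features),
         " features")
  }
  dimnames(counts) <- list(features, barcodes)
  structure(list(sample_id = sample_id,
                 barcodes = barcodes,
                 features = features,
                 counts = counts,
                 umi_total = as.numeric(Matrix::colSums(counts))),
            class = "droplet_table")
}

#' @export
print.droplet_table <- function(x, ...) {
  cat("droplet_table", x$sample_id, ":", length(x$barcodes), "barcodes x",
      length(x$features), "genes,", sum(x$umi_total), "UMIs\n")
  invisible(x)
}

#' Droplet classification thresholds
#'
#' The three normalized-UMI intervals separating ambient RNA, debris and
#' cellular material: (0, 0.25] ambient, (0.25, 5] debris, (5, Inf)
#' cellular. Upper bounds are inclusive; barcodes at exactly 0 are
#' unclassified.
#'
#' @param upper_ambient upper (inclusive) bound of the ambient interval.
#' @param upper_debris upper (inclusive) bound of the debris interval.
#' @return object of class `droplet_class_thresholds`.
#' @export
droplet_class_thresholds <- function(upper_ambient = 0.25, upper_debris = 5) {
  if (!(0 < upper_ambient && upper_ambient < upper_debris)) {
    stop("thresholds must satisfy 0 < upper_ambient < upper_debris")
  }
  structure(list(lower_ambient = 0, upper_ambient = upper_ambient,
                 upper_debris = upper_debris),
            class = "droplet_class_thresholds")
}

#' Read-depth-normalized UMI per droplet
#'
#' Each barcode's UMI count is scaled by one million over the run's grand
#' total: `normalized UMI = UMI per droplet x 1,000,000 / UMI in all
#' droplets per run`. The values of a run therefore sum to one million.
#'
#' @param table a [droplet_table()].
#' @return numeric vector named by barcode, in the table's barcode order.
#' @export
normalize_umi <- function(table) {
  stopifnot(inherits(table, "droplet_table"))
  total <- sum(table$umi_total)
  if (total <= 0) stop("empty run: all barcodes have zero UMIs")
  stats::setNames(table$umi_total * 1e6 / total, table$barcodes)
}

#' Classify droplets by normalized UMI
#'
#' Applies the three-interval rule: `(0, upper_ambient]` ambient,
#' `(upper_ambient, upper_debris]` debris, above that cellular; exactly zero
#' is unclassified (the ambient interval is open at 0).
#'
#' @param norm normalized-UMI vector from [normalize_umi()].
#' @param thresholds a [droplet_class_thresholds()].
#' @return factor with levels ambient, debris, cellular, unclassified, in
#'   `norm`'s order (names preserved).
#' @export
classify_droplets <- function(norm, thresholds = droplet_class_thresholds()) {
  stopifnot(inherits(thresholds, "droplet_class_thresholds"))
  lab <- ifelse(norm == 0, "unclassified",
         ifelse(norm <= thresholds$upper_ambient, "ambient",
         ifelse(norm <= thresholds$upper_debris, "debris", "cellular")))
  stats::setNames(factor(lab, levels = c("ambient", "debris", "cellular",
                                         "unclassified")), names(norm))
}

#' Per-sample per-class mean normalized UMI
#'
#' Arithmetic mean of normalized UMI and droplet count for every droplet
#' class in every sample. Classes with zero droplets in a sample are
#' reported with `NA` means, not zeros.
#'
#' @param norm normalized-UMI vector (one sample) or a list of such vectors
#'   keyed by sample_id.
#' @param labels classification factor(s) aligned with `norm`.
#' @param sample_id sample identifier(s); a single string when `norm` is a
#'   vector.
#' @return data.frame with columns sample_id, class, n_droplets,
#'   mean_norm_umi.
#' @export
class_means <- function(norm, labels, sample_id = "sample") {
  if (!is.list(norm)) {
    norm <- stats::setNames(list(norm), sample_id)
    labels <- stats::setNames(list(labels), sample_id)
  }
  classes <- c("ambient", "debris", "cellular")
  out <- do.call(rbind, lapply(names(norm), function(sid) {
    v <- norm[[sid]]; l <- labels[[sid]]
    if (length(v) != length(l)) stop("labels not aligned with norm for ", sid)
    data.frame(sample_id = sid, class = classes,
               n_droplets = vapply(classes, function(cl)
                 sum(l == cl), integer(1)),
               mean_norm_umi = vapply(classes, function(cl) {
                 x <- v[l == cl]
                 if (length(x) == 0) NA_real_ else mean(x)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Student t comparison of per-donor class means between time points
#'
#' Two-sided Student t test on per-donor mean values at a baseline time
#' versus a later time. The paired variant tests within-donor differences
#' (donors matched across the two time points); the unpaired variant is a
#' classical two-sample t test with pooled variance.
#'
#' @param values data.frame with columns donor, time label column
#'   (`time_col`), and `value`.
#' @param t0_label,other_label the two time labels compared.
#' @param paired logical; pair donors across time points.
#' @param time_col name of the time label column (default "time_h").
#' @return list with statistic, df, p_value, paired, n.
#' @export
compare_time_points <- function(values, t0_label, other_label,
                                paired = FALSE, time_col = "time_h") {
  a <- values[values[[time_col]] == t0_label, ]
  b <- values[values[[time_col]] == other_label, ]
  if (paired) {
    common <- intersect(a$donor, b$donor)
    if (length(common) < 2) stop("fewer than 2 matched donors")
    x <- a$value[match(common, a$donor)]
    y <- b$value[match(common, b$donor)]
    d <- x - y
    if (stats::sd(d) == 0) stop("degenerate paired test: zero-variance differences")
    tt <- stats::t.test(x, y, paired = TRUE)
    n <- length(common)
  } else {
    if (nrow(a) < 2 || nrow(b) < 2) stop("fewer than 2 observations per group")
    if (stats::sd(a$value) == 0 && stats::sd(b$value) == 0 &&
        mean(a$value) == mean(b$value)) {
      return(list(statistic = 0, df = nrow(a) + nrow(b) - 2, p_value = 1,
                  paired = FALSE, n = c(nrow(a), nrow(b))))
    }
    tt <- stats::t.test(a$value, b$value, var.equal = TRUE)
    n <- c(nrow(a), nrow(b))
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, paired = paired, n = n)
}

#' Ambient RNA gene profile
#'
#' Per-gene share of the UMIs captured in ambient-classified droplets,
#' sorted descending: the expression profile of the soup, used to identify
#' the top genes contributing to ambient contamination.
#'
#' @param table a [droplet_table()].
#' @param labels classification factor aligned to the table's barcodes.
#' @return data.frame with columns gene, ambient_umis, fraction, sorted by
#'   fraction descending (ties by gene name); fractions sum to 1.
#' @export
ambient_profile <- function(table, labels) {
  stopifnot(inherits(table, "droplet_table"))
  if (length(labels) != length(table$barcodes)) {
    stop("labels not aligned with droplet table")
  }
  amb <- labels == "ambient"
  if (!any(amb)) stop("no ambient droplets in run ", table$sample_id)
  sums <- Matrix::rowSums(table$counts[, amb, drop = FALSE])
  total <- sum(sums)
  if (total == 0) stop("ambient droplets carry zero UMIs")
  out <- data.frame(gene = table$features, ambient_umis = as.numeric(sums),
                    fraction = as.numeric(sums) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$gene), ]
  rownames(out) <- NULL
  out
}
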