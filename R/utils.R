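#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of a family of p-values. Shared by
#' every multiple-testing step in the package so that the correction has a
#' single implementation and a single test surface. `NA` entries are carried
#' through unadjusted.
#'
#' @param p numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Counts-per-million normalization
#'
#' Scales each column (sample or cell) of a count matrix to a total of one
#' million. Zero-total columns are left at zero.
#'
#' @param counts matrix or sparse Matrix, genes x samples.
#' @return matrix of the same shape on the CPM scale.
#' @export
cpm <- function(counts) {
  totals <- Matrix::colSums(counts)
  scale_by <- ifelse(totals > 0, 1e6 / totals, 0)
  if (methods::is(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(x = scale_by)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    sweep(counts, 2, scale_by, `*`)
  }
}

#' Log-normalize a count matrix
#'
#' Counts per cell are scaled to a common total (`scale_total`) and then
#' transformed with `log(1 + x)`. This is the normalization used for centroid
#' construction and similarity assignment, stated explicitly because centroid
#' medians depend on it.
#'
#' @param counts genes x cells count matrix.
#' @param scale_total common per-cell total after scaling (default 10000).
#' @return dense matrix of log-normalized values.
#' @export
log_normalize <- function(counts, scale_total = 1e4) {
  totals <- Matrix::colSums(counts)
  scale_by <- ifelse(totals > 0, scale_total / totals, 0)
  m <- as.matrix(counts %*% Matrix::Diagonal(x = scale_by))
  dimnames(m) <- dimnames(counts)
  log1p(m)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generation is a pure function of its config.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit substream seed derived from a global seed and a string
# key (e.g. "donor|tissue|time"). Polynomial string hash, kept below 2^31.
substream_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Stable hash of an R object (config manifests): md5 of its ASCII
# serialization.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, ascii = TRUE, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# write a data.frame as TSV without quoting or row names
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
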