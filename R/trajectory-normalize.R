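# Normalization, covariate regression, HVG selection and count downsampling.

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

#' Size-factor normalize and log-transform a count matrix
#'
#' Per cell, counts are divided by the size factor (library size / median
#' library size) and transformed as `ln(x + 1)`.
#'
#' @param counts Cells-by-genes count matrix, or an `expression_bundle`.
#' @return Dense normalized matrix (log-normalized counts); for a bundle
#'   input, the bundle with its `norm` slot filled.
#' @export
normalize_log <- function(counts) {
  if (inherits(counts, "expression_bundle")) {
    counts$norm <- normalize_log(counts$counts)
    return(counts)
  }
  m <- as_dense(counts)
  lib <- rowSums(m)
  if (any(lib == 0)) stop("zero library size: cell(s) with no counts")
  sf <- lib / stats::median(lib)
  log1p(m / sf)
}

#' Regress out covariates gene-wise
#'
#' Ordinary least squares of each gene on the centred covariates (plus
#' intercept); the result is residual + fitted intercept, so gene means are
#' preserved (a gene fully explained by a covariate collapses to its mean).
#' Rank-deficient designs are handled by the pseudoinverse.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param covariates Matrix or data frame with one row per cell (e.g. total
#'   counts, spike-in percentage, cell-cycle scores).
#' @return Matrix of the same shape as `norm`.
#' @export
regress_covariates <- function(norm, covariates) {
  norm <- as_dense(norm)
  cov <- as.matrix(covariates)
  if (nrow(cov) != nrow(norm))
    stop("covariate rows must match the number of cells")
  cov <- sweep(cov, 2, colMeans(cov))
  D <- cbind(intercept = 1, cov)
  sv <- svd(D)
  pos <- sv$d > max(sv$d) * 1e-10
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  beta <- pinv %*% norm
  fitted <- D %*% beta
  out <- norm - fitted + matrix(beta[1, ], nrow(norm), ncol(norm), byrow = TRUE)
  dimnames(out) <- dimnames(norm)
  out
}

# normalized dispersion (variance/mean z-scored within mean bins), one dataset
.norm_dispersion <- function(norm, n_bins = 20) {
  e <- expm1(norm)
  mu <- colMeans(e)
  v <- apply(e, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- min(n_bins, max(1, floor(length(mu) / 10)))  # keep bins populated
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z
}

#' Select highly variable genes shared across datasets
#'
#' Ranks genes within each dataset by normalized dispersion (variance/mean,
#' z-scored within 20 mean-expression bins), takes the top `n` per dataset
#' and returns the genes shared by all datasets.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param n Genes to keep per dataset (default 4000).
#' @param datasets Optional per-cell dataset factor; `NULL` = one dataset.
#' @return Character vector of gene names (column names of `norm`).
#' @export
select_hvg <- function(norm, n = 4000, datasets = NULL) {
  norm <- as_dense(norm)
  if (is.null(colnames(norm))) colnames(norm) <- paste0("g", seq_len(ncol(norm)))
  if (ncol(norm) < 1) stop("need at least one gene")
  if (is.null(datasets)) datasets <- rep("all", nrow(norm))
  sets <- lapply(split(seq_len(nrow(norm)), datasets), function(idx) {
    z <- .norm_dispersion(norm[idx, , drop = FALSE])
    colnames(norm)[order(z, decreasing = TRUE)][seq_len(min(n, ncol(norm)))]
  })
  Reduce(intersect, sets)
}

#' Downsample counts per cell to a fixed depth
#'
#' Cells with total counts above `target` are downsampled without
#' replacement (multivariate hypergeometric over the cell's count multiset);
#' cells at or below `target` are left unchanged. Zeros are never turned
#' into counts.
#'
#' @param counts Cells-by-genes integer count matrix.
#' @param target Target counts per cell (default 2000).
#' @param seed Integer seed.
#' @return Matrix of the same class/shape with per-cell totals
#'   `min(total, target)`.
#' @export
downsample_counts <- function(counts, target = 2000, seed = 1L) {
  m <- as_dense(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != floor(m))) stop("counts must be integers")
  with_seed(seed, {
    tot <- rowSums(m)
    for (i in which(tot > target)) {
      row <- m[i, ]
      remaining_total <- tot[i]
      remaining_draw <- target
      nz <- which(row > 0)
      new_row <- numeric(length(row))
      for (g in nz) {
        if (remaining_draw == 0) break
        x <- stats::rhyper(1, m = row[g], n = remaining_total - row[g],
                           k = remaining_draw)
        new_row[g] <- x
        remaining_draw <- remaining_draw - x
        remaining_total <- remaining_total - row[g]
      }
      m[i, ] <- new_row
    }
    if (inherits(counts, "Matrix")) Matrix::Matrix(m, sparse = TRUE) else m
  })
}
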