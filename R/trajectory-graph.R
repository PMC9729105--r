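# kNN graph machinery: MAGIC-style imputation, diffusion pseudotime,
# distance-weighted label transfer.

# PCA scores (cells x n_pcs), centred, no scaling
.pca_scores <- function(x, n_pcs) {
  x <- as_dense(x)
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
}

# adaptive-bandwidth Gaussian kNN affinity -> symmetrized matrix + Markov M.
# density_norm applies the alpha = 1 diffusion-map normalization
# (A / (d_i d_j)) so sampling-density clumps do not distort the operator.
.knn_markov <- function(scores, k, density_norm = FALSE) {
  n <- nrow(scores)
  if (k >= n) stop("k must be smaller than the number of cells")
  kn <- FNN::get.knn(scores, k = k)
  sigma <- kn$nn.dist[, k]
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  i <- rep(seq_len(n), k)
  j <- as.vector(kn$nn.index)
  w <- exp(-(as.vector(kn$nn.dist)^2) / (sigma[i]^2))
  A <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  A <- (A + Matrix::t(A)) / 2
  Matrix::diag(A) <- 1  # self-affinity
  if (density_norm) {
    d <- Matrix::rowSums(A)
    A <- Matrix::t(A / d) / d
    A <- (A + Matrix::t(A)) / 2
  }
  rs <- Matrix::rowSums(A)
  M <- A / rs
  list(A = A, M = M, rs = rs)
}

# connected components of the symmetrized affinity graph
.graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  At <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  adj <- split(At@j + 1L, factor(At@i + 1L, levels = seq_len(n)))
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' MAGIC-style diffusion imputation
#'
#' Builds a kNN graph in PC space with adaptive-bandwidth Gaussian
#' affinities (`sigma_i` = distance to the k-th neighbour), symmetrizes,
#' row-normalizes to a Markov matrix `M`, and returns `M^t %*% norm`.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param k Neighbours (default 10).
#' @param t Diffusion steps (default 2); `t = 0` returns the input.
#' @param n_pcs Principal components for the graph (default 20).
#' @return Imputed dense matrix of the same shape.
#' @export
magic_impute <- function(norm, k = 10, t = 2, n_pcs = 20) {
  norm <- as_dense(norm)
  if (k >= nrow(norm)) stop("k must be smaller than the number of cells")
  if (t == 0) return(norm)
  g <- .knn_markov(.pca_scores(norm, n_pcs), k)
  out <- norm
  for (s in seq_len(t)) out <- as.matrix(g$M %*% out)
  dimnames(out) <- dimnames(norm)
  out
}

#' Diffusion pseudotime along a differentiation trajectory
#'
#' Eigen-decomposes the symmetrized diffusion operator, builds the diffusion
#' map (eigenvectors weighted by `lambda / (1 - lambda)`), and sets each
#' cell's pseudotime to its diffusion distance from the root, min-max scaled
#' to \[0, 1\]. If `anchor` (expression of a differentiation marker) is
#' given and the root is not, the root is chosen as the cell with minimal
#' anchor expression among the 5% of cells most extreme on the first
#' diffusion component, and the orientation is flipped if pseudotime
#' anticorrelates with the anchor.
#'
#' @param x Cells-by-genes matrix (normalized, optionally imputed).
#' @param root Root cell index, or `NULL` to choose via `anchor`.
#' @param anchor Optional per-cell expression of the anchor gene.
#' @param k Neighbours for the graph; `NULL` scales with the number of
#'   cells (`max(30, 0.12 n)`, capped at 100) — a one-dimensional
#'   differentiation continuum needs a well-mixed operator, and too-sparse
#'   graphs let sampling clumps dominate the leading eigenvectors.
#' @param n_pcs Principal components.
#' @param n_comps Diffusion components used for the distance.
#' @return List with `pseudotime` (length n, in \[0, 1\]), `order`
#'   (integer rank, 1 = root side), and `root`.
#' @export
diffusion_pseudotime <- function(x, root = NULL, anchor = NULL, k = NULL,
                                 n_pcs = 20, n_comps = 10) {
  x <- as_dense(x)
  n <- nrow(x)
  if (is.null(k)) k <- max(30, min(100, round(0.12 * n)))
  k <- min(k, n - 1L)
  g <- .knn_markov(.pca_scores(x, n_pcs), k, density_norm = TRUE)
  comp <- .graph_components(g$A)
  if (max(comp) > 1L)
    stop(sprintf("kNN graph is disconnected: %d components of sizes %s",
                 max(comp), paste(tabulate(comp), collapse = ", ")))
  d_half <- sqrt(g$rs)
  S <- Matrix::t(Matrix::t(g$A / d_half) / d_half)  # D^-1/2 A D^-1/2
  eig <- eigen(as.matrix(S), symmetric = TRUE)
  n_comps <- min(n_comps, n - 1L)
  lam <- eig$values[2:(n_comps + 1)]
  lam <- pmin(lam, 1 - 1e-9)
  # right eigenvectors of M, weighted for accumulated diffusion
  psi <- eig$vectors[, 2:(n_comps + 1), drop = FALSE] / d_half
  psi <- sweep(psi, 2, lam / (1 - lam), `*`)

  dpt_from <- function(r) {
    d <- sweep(psi, 2, psi[r, ], `-`)
    pt <- sqrt(rowSums(d^2))
    (pt - min(pt)) / (max(pt) - min(pt))
  }

  if (is.null(root)) {
    if (is.null(anchor)) stop("supply either `root` or `anchor`")
    # the trajectory ends are the extremes of the dominant diffusion
    # component; the root is on the end with low anchor (marker) expression
    dc1 <- psi[, 1]
    lo <- which(dc1 <= stats::quantile(dc1, 0.05))
    hi <- which(dc1 >= stats::quantile(dc1, 0.95))
    side <- if (mean(anchor[lo]) <= mean(anchor[hi])) lo else hi
    root <- side[which.min(anchor[side])]
  }
  pt <- dpt_from(root)
  if (!is.null(anchor) && stats::cor(pt, anchor) < 0) pt <- 1 - pt
  list(pseudotime = pt, order = rank(pt, ties.method = "first"), root = root)
}

#' Distance-weighted kNN label transfer
#'
#' Assigns to each query cell the label winning the `1/d`-weighted vote
#' among its `k` nearest reference cells. A zero-distance match copies that
#' reference cell's label; vote ties fall back to the single nearest
#' neighbour's label.
#'
#' @param ref_matrix Reference cells-by-genes matrix.
#' @param ref_labels Labels of the reference cells.
#' @param query_matrix Query cells-by-genes matrix in the same gene space.
#' @param k Neighbours (default 20).
#' @return Character vector of transferred labels.
#' @export
knn_transfer <- function(ref_matrix, ref_labels, query_matrix, k = 20) {
  ref <- as_dense(ref_matrix); qry <- as_dense(query_matrix)
  if (ncol(ref) != ncol(qry) ||
      (!is.null(colnames(ref)) && !is.null(colnames(qry)) &&
       !identical(colnames(ref), colnames(qry))))
    stop("reference and query gene spaces differ")
  if (k > nrow(ref)) stop("k exceeds the number of reference cells")
  ref_labels <- as.character(ref_labels)
  kn <- FNN::get.knnx(ref, qry, k = k)
  out <- character(nrow(qry))
  for (i in seq_len(nrow(qry))) {
    d <- kn$nn.dist[i, ]; lab <- ref_labels[kn$nn.index[i, ]]
    if (any(d == 0)) { out[i] <- lab[which(d == 0)[1]]; next }
    votes <- tapply(1 / d, lab, sum)
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else lab[1]
  }
  out
}
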