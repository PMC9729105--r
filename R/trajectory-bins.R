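# Delamination-point assignment, pseudotime binning, positivity calls,
# expression trends, gene-set scoring and spliced/unspliced co-expression.

#' Assign the delamination point on the ordered trajectory
#'
#' The basal-suprabasal boundary is the pseudotime rank of the
#' `ceiling(q * n_sorted)`-th sorted-basal cell along the ordering: cells at
#' or before that rank are on the basal side. With the default `q = 0.95`
#' this is the 95th percentile of sorted cells, which tolerates a small
#' suprabasal contamination of the sorted gate.
#'
#' @param order Integer pseudotime rank per cell (1 = most basal).
#' @param sorted_flags Logical per cell: member of the sorted-basal gate.
#' @param q Percentile of sorted cells defining the boundary.
#' @return Integer boundary rank.
#' @export
assign_delamination_point <- function(order, sorted_flags, q = 0.95) {
  stopifnot(length(order) == length(sorted_flags))
  if (!any(sorted_flags)) stop("no sorted cells")
  ranks <- sort(order[sorted_flags])
  ranks[ceiling(q * length(ranks))]
}

#' Group cells into equal-count pseudotime bins on each side of the boundary
#'
#' Cells at or before the boundary rank form the basal side (bins
#' `1..n_basal`), the rest the suprabasal side (bins `n_basal+1 ..
#' n_basal+n_supra`). Each side is split into equal-count bins by order;
#' remainders go to the earliest bins of that side.
#'
#' @param order Integer pseudotime rank per cell.
#' @param boundary Boundary rank from [assign_delamination_point()].
#' @param n_basal,n_supra Bins per side (defaults 6 and 4).
#' @return Integer bin id per cell (1..`n_basal + n_supra`).
#' @export
bin_cells <- function(order, boundary, n_basal = 6, n_supra = 4) {
  n <- length(order)
  if (boundary < 1 || boundary >= n) stop("boundary outside the ordering")
  side_bins <- function(m, k) {
    if (m < k) stop(sprintf("side has %d cells but %d bins requested", m, k))
    base <- m %/% k; rem <- m %% k
    rep(seq_len(k), times = base + (seq_len(k) <= rem))
  }
  basal_sizes <- side_bins(boundary, n_basal)
  supra_sizes <- side_bins(n - boundary, n_supra) + as.integer(n_basal)
  bins <- integer(n)
  bins[order(order)] <- c(basal_sizes, supra_sizes)
  as.integer(bins)
}

#' Flag cells positive for a gene
#'
#' Strict threshold on log-normalized expression; the default cutoff is the
#' mean expression over all cells (for Krt10 in the study's data this mean
#' is 1.84 log-normalized counts).
#'
#' @param expr Per-cell expression of one gene (log-normalized).
#' @param cutoff Threshold; `NULL` uses `mean(expr)`.
#' @return Logical vector, `expr > cutoff`.
#' @export
classify_positive <- function(expr, cutoff = NULL) {
  cutoff <- cutoff %||% mean(expr)
  expr > cutoff
}

#' Fitted expression trend along the ordering, relative to bin 1
#'
#' Centred rolling mean over the pseudotime-ordered cells (window
#' `max(31, window_frac * n)`, forced odd, truncated at the edges). The
#' delta column is the fitted value minus the bin-1 baseline (average raw
#' expression of bin-1 cells).
#'
#' @param x Per-cell expression of one gene.
#' @param order Integer pseudotime rank per cell.
#' @param bins Integer bin ids (bin 1 defines the baseline).
#' @param window_frac Window size as a fraction of n.
#' @return `data.frame(order, fitted, delta)` aligned with the input cells.
#' @export
fit_trend <- function(x, order, bins, window_frac = 0.05) {
  n <- length(x)
  if (n < 2) stop("need at least two cells")
  w <- max(31, round(window_frac * n))
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, n + (n %% 2 == 0))
  half <- (w - 1) / 2
  xo <- x[order(order)]
  cs <- cumsum(c(0, xo))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  fitted_o <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  fitted <- numeric(n)
  fitted[order(order)] <- fitted_o
  baseline <- mean(x[bins == 1])
  data.frame(order = order, fitted = fitted, delta = fitted - baseline)
}

#' Score cells for a gene set against matched controls
#'
#' Genes are binned by mean expression (`n_bins` equal-size rank bins); for
#' every bin occupied by set genes, `ctrl_size` control genes are sampled
#' from that bin. The score is the per-cell mean expression of the set minus
#' the mean of the control pool.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param gene_set Character vector of gene names (must exist).
#' @param n_bins Expression bins (default 25).
#' @param ctrl_size Control genes per occupied bin (default 50).
#' @param seed Integer seed for control sampling.
#' @return Numeric per-cell score.
#' @export
score_gene_set <- function(norm, gene_set, n_bins = 25, ctrl_size = 50,
                           seed = 0L) {
  norm <- as_dense(norm)
  if (!length(gene_set)) stop("empty gene set")
  missing <- setdiff(gene_set, colnames(norm))
  if (length(missing))
    stop(sprintf("gene set members absent from the matrix: %s",
                 paste(missing, collapse = ", ")))
  mu <- colMeans(norm)
  bin <- ceiling(rank(mu, ties.method = "first") / length(mu) * n_bins)
  set_idx <- match(gene_set, colnames(norm))
  with_seed(seed, {
    ctrl <- unlist(lapply(unique(bin[set_idx]), function(b) {
      pool <- which(bin == b)
      if (length(pool) <= ctrl_size) pool else sample(pool, ctrl_size)
    }))
  })
  rowMeans(norm[, set_idx, drop = FALSE]) -
    rowMeans(norm[, unique(ctrl), drop = FALSE])
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' A cell is called cycling when the larger of its two scores exceeds the
#' cutoff (default 0.05); the phase is that of the larger score (ties go to
#' S); otherwise G1.
#'
#' @param s_score,g2m_score Per-cell scores from [score_gene_set()].
#' @param cutoff Positivity cutoff (default 0.05).
#' @return Character vector in `{"G1", "S", "G2M"}`.
#' @export
assign_cycle_phase <- function(s_score, g2m_score, cutoff = 0.05) {
  stopifnot(all(is.finite(s_score)), all(is.finite(g2m_score)))
  ifelse(pmax(s_score, g2m_score) > cutoff,
         ifelse(g2m_score > s_score, "G2M", "S"),
         "G1")
}

#' Spliced/unspliced co-expression of two genes along the bins
#'
#' Log-transforms (`ln(count + 1)`) the spliced and unspliced layers for the
#' two genes, summarizes unspliced `gene_a` and spliced `gene_b` per bin,
#' and flags cells co-expressing all four species (spliced and unspliced of
#' both genes strictly positive).
#'
#' @param bundle An `expression_bundle` with spliced/unspliced layers.
#' @param bins Integer bin id per cell.
#' @param gene_a Basal-program gene (e.g. Krt14): unspliced axis.
#' @param gene_b Differentiation gene (e.g. Krt10/Krtdap): spliced axis.
#' @return List with `cells` (per-cell log layers, bin, `coexpressing`) and
#'   `per_bin` (bin summaries and co-expression counts).
#' @export
splicing_coexpression <- function(bundle, bins, gene_a, gene_b) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (is.null(bundle$spliced) || is.null(bundle$unspliced))
    stop("bundle lacks spliced/unspliced layers")
  get <- function(layer, gene) {
    if (!gene %in% colnames(layer)) stop(sprintf("gene '%s' not found", gene))
    as.numeric(layer[, gene])
  }
  sa <- get(bundle$spliced, gene_a); ua <- get(bundle$unspliced, gene_a)
  sb <- get(bundle$spliced, gene_b); ub <- get(bundle$unspliced, gene_b)
  cells <- data.frame(bin = bins,
                      log_spliced_a = log1p(sa), log_unspliced_a = log1p(ua),
                      log_spliced_b = log1p(sb), log_unspliced_b = log1p(ub),
                      coexpressing = sa > 0 & ua > 0 & sb > 0 & ub > 0)
  per_bin <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    i <- bins == b
    data.frame(bin = b, n = sum(i),
               mean_log_unspliced_a = mean(cells$log_unspliced_a[i]),
               mean_log_spliced_b = mean(cells$log_spliced_b[i]),
               n_coexpressing = sum(cells$coexpressing[i]))
  }))
  list(cells = cells, per_bin = per_bin)
}
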