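# TF-module (regulon) construction and per-cell target scoring.

#' Infer a TF-to-target adjacency list
#'
#' Desk-scale surrogate for gradient-boosted network inference: each target
#' gene is regressed (OLS) on the expression of all TFs, and the absolute
#' t-statistics serve as edge importances. The top `n_top` TF edges per
#' target are kept. An externally computed adjacency can be supplied
#' downstream instead ([expand_modules()] accepts any adjacency table).
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param tf_list Character vector of TF gene names present in `norm`.
#' @param n_top Edges kept per target (default 10).
#' @return `data.frame(tf, target, importance)`, no self-edges.
#' @export
infer_adjacency <- function(norm, tf_list, n_top = 10) {
  norm <- as_dense(norm)
  if (!length(tf_list)) stop("empty TF list")
  missing <- setdiff(tf_list, colnames(norm))
  if (length(missing))
    stop(sprintf("TFs absent from the matrix: %s", paste(missing, collapse = ", ")))
  X <- cbind(1, norm[, tf_list, drop = FALSE])
  qr_x <- qr(X)
  targets <- setdiff(colnames(norm), character(0))
  out <- vector("list", length(targets))
  XtXinv_diag <- diag(chol2inv(qr.R(qr_x)))[-1]
  df <- nrow(norm) - ncol(X)
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    tfs <- setdiff(tf_list, tg)  # no self-edges
    if (!length(tfs)) next
    y <- norm[, tg]
    if (tg %in% tf_list) {
      # refit without the target itself as a predictor
      Xi <- cbind(1, norm[, tfs, drop = FALSE])
      qi <- qr(Xi)
      beta <- qr.coef(qi, y)
      res <- y - Xi %*% beta
      s2 <- sum(res^2) / max(nrow(norm) - ncol(Xi), 1)
      vdiag <- diag(chol2inv(qr.R(qi)))[-1]
      tstat <- abs(beta[-1]) / sqrt(pmax(s2 * vdiag, 1e-300))
      names(tstat) <- tfs
    } else {
      beta <- qr.coef(qr_x, y)
      res <- y - X %*% beta
      s2 <- sum(res^2) / max(df, 1)
      tstat <- abs(beta[-1]) / sqrt(pmax(s2 * XtXinv_diag, 1e-300))
      names(tstat) <- tf_list
    }
    tstat <- tstat[is.finite(tstat)]
    keep <- head(order(tstat, decreasing = TRUE), n_top)
    if (length(keep))
      out[[ti]] <- data.frame(tf = names(tstat)[keep], target = tg,
                              importance = unname(tstat[keep]))
  }
  adj <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(adj) <- NULL
  adj
}

#' Genes correlated with the anchor during early differentiation
#'
#' Pearson correlation with the anchor gene over the cells of the earliest
#' differentiation bins (2, 3 and 4); genes with `r > r_min` (strict,
#' positive only) are kept. The anchor itself (r = 1) is always included.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param bins Integer bin id per cell.
#' @param anchor Anchor gene name (the earliest differentiation marker).
#' @param r_min Correlation cutoff (default 0.3).
#' @param early_bins Bins defining early differentiation (default 2:4).
#' @return Character vector of gene names.
#' @export
diff_correlated_genes <- function(norm, bins, anchor, r_min = 0.3,
                                  early_bins = 2:4) {
  norm <- as_dense(norm)
  if (!anchor %in% colnames(norm)) stop(sprintf("anchor '%s' not found", anchor))
  sel <- bins %in% early_bins
  if (!any(sel)) stop("early bins are empty")
  sub <- norm[sel, , drop = FALSE]
  a <- sub[, anchor]
  if (stats::sd(a) == 0) stop("anchor is constant in the early bins")
  r <- suppressWarnings(as.vector(stats::cor(sub, a)))
  r[is.na(r)] <- 0
  r[colnames(norm) == anchor] <- 1
  colnames(norm)[r > r_min]
}

#' Expand TF modules from the adjacency and the differentiation gene set
#'
#' For every TF with at least one edge into the differentiation-associated
#' gene set, the module is all of that TF's targets (co-regulated genes are
#' pulled in whether or not they are themselves differentiation-associated).
#'
#' @param adjacency `data.frame(tf, target, importance)`.
#' @param diff_genes Character vector from [diff_correlated_genes()].
#' @return Named list of character vectors (TF -> target set); empty list
#'   when no TF targets the set.
#' @export
expand_modules <- function(adjacency, diff_genes) {
  if (is.null(adjacency) || !nrow(adjacency)) stop("empty adjacency")
  hit_tfs <- unique(adjacency$tf[adjacency$target %in% diff_genes])
  mods <- lapply(hit_tfs, function(tf)
    unique(adjacency$target[adjacency$tf == tf]))
  names(mods) <- hit_tfs
  keep <- lengths(mods) > 0
  if (any(!keep)) warning("dropping empty modules: ",
                          paste(hit_tfs[!keep], collapse = ", "))
  mods[keep]
}

# vectorized two-sided Wilcoxon rank-sum (normal approximation with tie
# correction), group 1 vs group 2, per column
.ranksum_test <- function(m, in_g1) {
  n1 <- sum(in_g1); n2 <- sum(!in_g1); n <- n1 + n2
  p <- numeric(ncol(m))
  for (g in seq_len(ncol(m))) {
    r <- rank(m[, g])
    W <- sum(r[in_g1]) - n1 * (n1 + 1) / 2
    ties <- table(m[, g])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (s2 <= 0) { p[g] <- 1; next }
    z <- (W - n1 * n2 / 2) / sqrt(s2)
    p[g] <- 2 * stats::pnorm(-abs(z))
  }
  p
}

#' Genes differentially upregulated in bin 1
#'
#' Two-sided rank-sum test of bin-1 cells against all other cells per gene,
#' Benjamini-Hochberg adjustment; keeps genes with adjusted p < `alpha` and
#' log fold change (bin-1 mean minus rest mean, natural-log-normalized
#' units) > `lfc_min`. These basal-signature genes are excluded from
#' regulon scoring so scores reflect differentiation, not basal identity.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param bins Integer bin id per cell.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_min Log fold-change cutoff (default 0.5, natural log).
#' @return Character vector of gene names.
#' @export
de_genes_bin1 <- function(norm, bins, alpha = 0.05, lfc_min = 0.5) {
  norm <- as_dense(norm)
  in1 <- bins == 1
  if (!any(in1) || all(in1)) stop("bin 1 or its complement is empty")
  p <- .ranksum_test(norm, in1)
  padj <- stats::p.adjust(p, method = "BH")
  lfc <- colMeans(norm[in1, , drop = FALSE]) - colMeans(norm[!in1, , drop = FALSE])
  colnames(norm)[padj < alpha & lfc > lfc_min]
}

#' Score regulon modules per cell
#'
#' Removes excluded genes from each module, then applies
#' [score_gene_set()]. Modules emptied by the exclusion are skipped with a
#' warning.
#'
#' @param norm Cells-by-genes normalized matrix.
#' @param modules Named list of target gene sets from [expand_modules()].
#' @param excluded Genes to drop before scoring (e.g. [de_genes_bin1()]).
#' @param ... Passed to [score_gene_set()].
#' @return Cells-by-TF matrix of scores.
#' @export
score_regulons <- function(norm, modules, excluded = character(0), ...) {
  if (!length(modules)) stop("no modules supplied")
  kept <- lapply(modules, function(g) setdiff(g, excluded))
  empty <- lengths(kept) == 0
  if (all(empty)) stop("all modules emptied by the exclusion list")
  if (any(empty))
    warning("modules emptied by exclusion, skipped: ",
            paste(names(kept)[empty], collapse = ", "))
  kept <- kept[!empty]
  scores <- vapply(kept, function(g) score_gene_set(norm, g, ...),
                   numeric(nrow(as_dense(norm))))
  colnames(scores) <- names(kept)
  scores
}
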