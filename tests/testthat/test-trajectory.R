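test_that("size-factor log normalization is scale-invariant per cell", {
  m <- rbind(a = c(2, 4, 0, 6), b = c(2, 4, 0, 6), c = c(4, 8, 0, 12))
  nm <- normalize_log(m)
  expect_equal(nm["a", ], nm["b", ])
  expect_equal(nm["a", ], nm["c", ])  # c is a doubled, size factors cancel
  expect_error(normalize_log(rbind(c(1, 2), c(0, 0))), "zero library size")
})

test_that("covariate regression removes only what the design explains", {
  set.seed(4)
  n <- 100
  cov <- rnorm(n)
  g_orth <- rnorm(n)                    # independent of the covariate
  g_dep <- 2 * cov                      # exactly explained
  norm <- cbind(orth = g_orth, dep = g_dep)
  out <- regress_covariates(norm, cbind(cov))
  beta_orth <- coef(lm(g_orth ~ cov))[2]
  expect_equal(out[, "orth"], g_orth - beta_orth * (cov - mean(cov)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(out[, "dep"]), rep(mean(g_dep), n), tolerance = 1e-10)
  expect_error(regress_covariates(norm, cbind(rnorm(50))), "rows")
  # rank-deficient design falls back to the pseudoinverse without error
  out2 <- regress_covariates(norm, cbind(cov, cov))
  expect_equal(unname(out2[, "dep"]), rep(mean(g_dep), n), tolerance = 1e-8)
})

test_that("HVG selection ranks planted variable genes ahead of constants", {
  set.seed(6)
  n <- 300
  mus <- runif(60, 2, 9)
  quiet <- sapply(mus, function(mu) rpois(n, mu))
  # planted overdispersed genes with means spread among the quiet ones
  loud <- sapply(c(3, 4.5, 6, 7.5, 8.5), function(mu)
    rnbinom(n, mu = mu, size = 0.15))
  m <- cbind(quiet, loud, rep(3, n))
  colnames(m) <- c(sprintf("q%02d", 1:60), sprintf("v%d", 1:5), "const")
  nm <- normalize_log(m)
  top <- select_hvg(nm, n = 10)
  expect_true(all(sprintf("v%d", 1:5) %in% top))
  expect_identical(sort(select_hvg(nm, n = 100)), sort(colnames(m)))
  expect_false("const" %in% select_hvg(nm, n = 30))
})

test_that("HVG intersection across datasets keeps only shared genes", {
  set.seed(8)
  n <- 120
  ds <- rep(c("A", "B"), each = n / 2)
  m <- matrix(rpois(n * 20, 5), n, 20)
  colnames(m) <- sprintf("g%02d", 1:20)
  m[ds == "A", 1] <- rnbinom(n / 2, mu = 5, size = 0.2)  # variable in A only
  m[, 2] <- rnbinom(n, mu = 5, size = 0.2)               # variable in both
  top <- select_hvg(normalize_log(m), n = 3, datasets = ds)
  expect_true("g02" %in% top)
  expect_true(length(top) <= 3)
})

test_that("MAGIC imputation is the identity at t = 0 and smooths within blobs", {
  set.seed(5)
  blob1 <- matrix(rnorm(40 * 10, 0, 1), 40, 10)
  blob2 <- matrix(rnorm(40 * 10, 8, 1), 40, 10)
  m <- rbind(blob1, blob2)
  expect_identical(magic_impute(m, k = 10, t = 0), m)
  imp <- magic_impute(m, k = 10, t = 2)
  v_before <- mean(apply(m[1:40, ], 2, var))
  v_after <- mean(apply(imp[1:40, ], 2, var))
  expect_lt(v_after, v_before)
  expect_equal(colMeans(imp[1:40, ]), colMeans(m[1:40, ]), tolerance = 0.2)
  expect_equal(colMeans(imp[41:80, ]), colMeans(m[41:80, ]), tolerance = 0.2)
  expect_error(magic_impute(m, k = 80), "smaller than the number of cells")
})

test_that("strong diffusion on a tight cluster approaches the cluster mean", {
  set.seed(9)
  m <- matrix(rnorm(30 * 4), 30, 4)
  imp <- magic_impute(m, k = 29, t = 64)
  expect_lt(max(abs(sweep(imp, 2, colMeans(m)))), 0.35)
})

test_that("kNN label transfer copies exact matches and separates blobs", {
  set.seed(7)
  ref <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2), matrix(rnorm(60, 6, 0.5), 30, 2))
  labs <- rep(c("B", "DI"), each = 30)
  expect_identical(knn_transfer(ref, labs, ref[c(1, 40), , drop = FALSE], k = 5),
                   c("B", "DI"))
  qry <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2), matrix(rnorm(40, 6, 0.5), 20, 2))
  expect_identical(knn_transfer(ref, labs, qry, k = 20),
                   rep(c("B", "DI"), each = 20))
  expect_error(knn_transfer(ref, labs, qry, k = 100), "exceeds")
  expect_error(knn_transfer(ref, labs, qry[, 1, drop = FALSE]), "gene spaces")
})

test_that("downsampling caps totals, preserves zeros and smaller cells", {
  m <- rbind(c(1500, 400, 100, 0), c(800, 100, 50, 0), c(2500, 400, 100, 0))
  out <- downsample_counts(m, target = 2000, seed = 1)
  expect_equal(rowSums(out), pmin(rowSums(m), 2000))
  expect_identical(out[1, ], m[1, ])  # exactly 2000: untouched
  expect_identical(out[2, ], m[2, ])  # below target: untouched
  expect_true(all(out[, 4] == 0))
  expect_true(all(out <= m))          # never creates counts
  expect_error(downsample_counts(matrix(-1)), "non-negative")
  expect_error(downsample_counts(matrix(1.5)), "integers")
})

test_that("pseudotime is zero at the root and monotone along a 1D chain", {
  chain <- cbind(seq(0, 10, length.out = 50), 0)
  colnames(chain) <- c("f1", "f2")
  d <- diffusion_pseudotime(chain, root = 1, k = 5, n_pcs = 2)
  expect_equal(d$pseudotime[1], 0)
  expect_true(all(diff(d$pseudotime) > 0))
  expect_identical(d$order, 1:50)
})

test_that("a disconnected graph is reported with its component sizes", {
  two <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2), matrix(rnorm(40, 100, 0.1), 20, 2))
  expect_error(diffusion_pseudotime(two, root = 1, k = 3, n_pcs = 2),
               "disconnected")
})

test_that("the delamination point sits at the 95th percentile of sorted cells", {
  ord <- 1:200
  sorted <- c(rep(TRUE, 100), rep(FALSE, 100))
  expect_identical(assign_delamination_point(ord, sorted), 95L)
  # brute force on a random interleaving
  set.seed(11)
  ord2 <- sample(200)
  sorted2 <- runif(200) < 0.4
  b <- assign_delamination_point(ord2, sorted2)
  ranks <- sort(ord2[sorted2])
  expect_identical(b, ranks[ceiling(0.95 * length(ranks))])
  expect_error(assign_delamination_point(ord, rep(FALSE, 200)), "no sorted cells")
})

test_that("binning is equal-count per side with remainders to the earliest bins", {
  bins <- bin_cells(1:100, boundary = 60)
  expect_identical(as.integer(table(bins)), c(rep(10L, 6), rep(10L, 4)))
  bins2 <- bin_cells(1:101, boundary = 61)
  expect_identical(as.integer(table(bins2)[1:6]), c(11L, 10L, 10L, 10L, 10L, 10L))
  set.seed(3)
  ord <- sample(80)
  b <- bin_cells(ord, boundary = 48)
  expect_true(all(diff(b[order(ord)]) >= 0))  # non-decreasing along pseudotime
  expect_identical(sort(unique(b)), 1:10)
  expect_error(bin_cells(1:8, boundary = 5), "bins requested")
})

test_that("positivity calls use a strict cutoff defaulting to the mean", {
  expect_identical(classify_positive(c(0, 2)), c(FALSE, TRUE))
  expect_identical(classify_positive(rep(0, 5)), rep(FALSE, 5))
  expect_identical(classify_positive(c(1, 1, 3), cutoff = 1), c(FALSE, FALSE, TRUE))
  # two-component mixture: positive fraction recovers the planted share
  set.seed(13)
  x <- c(rnorm(600, 0.2, 0.15), rnorm(400, 3, 0.3))
  expect_equal(mean(classify_positive(x)), 0.4, tolerance = 0.03)
})

test_that("trend fitting reproduces ramps and the bin-1 baseline", {
  n <- 200
  ord <- 1:n
  bins <- bin_cells(ord, boundary = 120)
  const <- rep(2.5, n)
  ft <- fit_trend(const, ord, bins)
  expect_true(all(abs(ft$delta) < 1e-12))
  ramp <- 0.05 * ord
  ftr <- fit_trend(ramp, ord, bins, window_frac = 0.1)
  w <- max(31, 20); w <- w + (1 - w %% 2)
  half <- (w - 1) / 2
  interior <- (half + 1):(n - half)
  expect_equal(ftr$fitted[interior], ramp[interior], tolerance = 1e-6)
  expect_equal(unique(ftr$delta - (ftr$fitted - mean(ramp[bins == 1]))), 0)
})

test_that("gene-set scores vanish when the set is its own control pool", {
  set.seed(15)
  m <- matrix(rnorm(50 * 8, 2), 50, 8)
  colnames(m) <- sprintf("g%d", 1:8)
  sc <- score_gene_set(m, colnames(m), n_bins = 1, ctrl_size = 8, seed = 1)
  expect_true(all(abs(sc) < 1e-12))
  expect_error(score_gene_set(m, "absent"), "absent")
  expect_error(score_gene_set(m, character(0)), "empty gene set")
})

test_that("planted up-genes in a subpopulation raise that population's score", {
  set.seed(16)
  n <- 200
  m <- matrix(rpois(n * 40, 5), n, 40)
  colnames(m) <- sprintf("g%02d", 1:40)
  up <- sprintf("g%02d", 1:5)
  hot <- 1:60
  m[hot, up] <- m[hot, up] + rpois(length(hot) * 5, 6)
  sc <- score_gene_set(normalize_log(m), up, n_bins = 5, ctrl_size = 10, seed = 2)
  expect_lt(wilcox.test(sc[hot], sc[-hot], alternative = "greater")$p.value, 0.01)
})

test_that("cycle phase assignment follows the cutoff and larger-score rule", {
  expect_identical(assign_cycle_phase(0.2, 0.01), "S")
  expect_identical(assign_cycle_phase(0.04, 0.04), "G1")
  expect_identical(assign_cycle_phase(0.04, 0.2), "G2M")
  expect_identical(assign_cycle_phase(0.1, 0.1), "S")  # tie goes to S
  expect_identical(assign_cycle_phase(c(0.2, 0.01), c(0.01, 0.02)), c("S", "G1"))
})

test_that("planted cycling cells are recovered with high sensitivity and specificity", {
  # realistic phase gene sets carry ~20 genes each, like the standard
  # S/G2M lists used for cell-cycle scoring
  prog <- make_gene_programs(200, frac_cycle = 0.2)
  b <- simulate_expression(expr_sim_config(n_cells = c(ds1 = 500),
                                           depth_mean = 4000, program = prog,
                                           cycling_fraction = 0.2, seed = 19))
  norm <- normalize_log(b$counts)
  cyc_genes <- b$gene_meta$gene[b$gene_meta$class == "cycle"]
  half <- length(cyc_genes) %/% 2
  s_sc <- score_gene_set(norm, cyc_genes[1:half], n_bins = 8, seed = 1)
  g2m_sc <- score_gene_set(norm, cyc_genes[(half + 1):length(cyc_genes)],
                           n_bins = 8, seed = 2)
  phase <- assign_cycle_phase(s_sc, g2m_sc)
  called <- phase != "G1"
  truth <- b$cell_meta$cycling
  expect_gte(mean(called[truth]), 0.9)    # sensitivity
  expect_gte(mean(!called[!truth]), 0.9)  # specificity
})

test_that("spliced/unspliced co-expression matches a brute-force scan", {
  b <- small_bundle(seed = 21, n_cells = 20, n_genes = 30)
  ga <- b$gene_meta$gene[b$gene_meta$class == "basal-down"][1]
  gb <- first_diff_gene(b)
  bins <- rep(1:4, each = 5)
  res <- splicing_coexpression(b, bins, ga, gb)
  brute <- sum(as.numeric(b$spliced[, ga]) > 0 & as.numeric(b$unspliced[, ga]) > 0 &
                 as.numeric(b$spliced[, gb]) > 0 & as.numeric(b$unspliced[, gb]) > 0)
  expect_identical(sum(res$cells$coexpressing), brute)
  expect_identical(sum(res$per_bin$n_coexpressing), brute)
  # a cell with all-zero layers can never co-express
  b0 <- b
  b0$spliced[1, ] <- 0; b0$unspliced[1, ] <- 0
  expect_false(splicing_coexpression(b0, bins, ga, gb)$cells$coexpressing[1])
  b_nolayer <- b; b_nolayer$spliced <- NULL
  expect_error(splicing_coexpression(b_nolayer, bins, ga, gb), "layers")
})

test_that("the splicing lag produces mid-trajectory basal/diff co-transcription", {
  b <- simulate_expression(expr_sim_config(n_cells = c(ds1 = 400),
                                           depth_mean = 8000, n_genes = 60,
                                           splicing_lag = 0.15, seed = 23))
  ord <- rank(b$cell_meta$s, ties.method = "first")
  bins <- bin_cells(ord, boundary = floor(0.6 * 400))
  ga <- b$gene_meta$gene[b$gene_meta$class == "basal-down"][1]
  gb <- first_diff_gene(b)
  res <- splicing_coexpression(b, bins, ga, gb)
  mid <- res$cells$bin %in% 4:6
  overlap <- sum(res$cells$log_unspliced_a[mid] > 0 & res$cells$log_spliced_b[mid] > 0)
  expect_gt(overlap, 0)
})
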