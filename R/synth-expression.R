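# Negative-binomial count simulator along a latent differentiation axis,
# with staggered gene programs, a spliced/unspliced lag, a sorted-basal
# subpopulation and planted TF->target modules.

#' Default staggered gene-program table
#'
#' Gene classes: `diff-up` (differentiation genes switching on at staggered
#' onsets along the latent axis), `basal-down` (stemness genes switching off),
#' `neutral`, `cycle` (high only in cycling cells) and `tf` (transcription
#' factors with their own activity profile). Onsets are staggered so the
#' earliest differentiation marker rises first, emulating the ordered onset
#' of keratinocyte differentiation programs.
#'
#' @param n_genes Total number of genes.
#' @param frac_diff,frac_basal,frac_cycle Fractions per class (the remainder
#'   is neutral).
#' @param n_tf Number of TF genes (taken from the neutral pool).
#' @param amp Program amplitude on the natural-log scale.
#' @return `data.frame(gene, class, onset, amp)`.
#' @export
make_gene_programs <- function(n_genes, frac_diff = 0.25, frac_basal = 0.25,
                               frac_cycle = 0.05, n_tf = 0, amp = 2) {
  n_diff <- round(n_genes * frac_diff)
  n_bas <- round(n_genes * frac_basal)
  n_cyc <- round(n_genes * frac_cycle)
  n_neu <- n_genes - n_diff - n_bas - n_cyc - n_tf
  stopifnot(n_neu >= 0)
  cls <- c(rep("diff-up", n_diff), rep("basal-down", n_bas),
           rep("cycle", n_cyc), rep("tf", n_tf), rep("neutral", n_neu))
  onset <- rep(NA_real_, n_genes)
  onset[cls == "diff-up"] <- seq(0.15, 0.8, length.out = max(n_diff, 1))[seq_len(n_diff)]
  onset[cls == "basal-down"] <- seq(0.1, 0.8, length.out = max(n_bas, 1))[seq_len(n_bas)]
  onset[cls == "tf"] <- seq(0.2, 0.5, length.out = max(n_tf, 1))[seq_len(n_tf)]
  data.frame(gene = sprintf("G%03d", seq_len(n_genes)), class = cls,
             onset = onset, amp = amp)
}

#' Configuration for the expression simulator
#'
#' @param n_cells Named integer vector: cells per dataset (names become the
#'   dataset ids); a bare integer makes one dataset `"ds1"`.
#' @param depth_mean Mean library depth (counts/cell) per dataset, recycled.
#' @param n_genes Number of genes (ignored when `program` is supplied).
#' @param program Gene-program table from [make_gene_programs()].
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param splicing_lag Offset `delta s` between active transcription
#'   (unspliced) and accumulated spliced mRNA: spliced abundance follows the
#'   program at `s - splicing_lag`.
#' @param unspliced_frac Fraction of each cell's depth in unspliced counts.
#' @param sorted_threshold Latent position `s0` below which cells are truly
#'   basal; the sorted-basal flag covers these cells.
#' @param contamination Fraction of the sorted set that is actually
#'   suprabasal (default 0.05, mirroring the 95th-percentile boundary rule).
#' @param cycling_fraction Fraction of cells in S/G2/M.
#' @param tf_modules List of `list(tf =, targets =, effect =)` planting
#'   TF->target co-regulation: target log-rates shift by
#'   `effect * (activity - 0.5)` with per-cell TF activity noise.
#' @param depth_sdlog Log-normal sd of per-cell depth around the dataset mean.
#' @param seed Master seed (expression substream).
#' @return Object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_cells = c(ds1 = 400), depth_mean = 3000,
                            n_genes = 120, program = NULL,
                            nb_dispersion = 0.1, splicing_lag = 0.1,
                            unspliced_frac = 0.25,
                            sorted_threshold = 0.6, contamination = 0.05,
                            cycling_fraction = 0.2, tf_modules = NULL,
                            depth_sdlog = 0.3, seed = 1L) {
  if (is.null(names(n_cells))) names(n_cells) <- paste0("ds", seq_along(n_cells))
  stop_if_not_scalar_prob(contamination, "contamination")
  stop_if_not_positive(nb_dispersion, "nb_dispersion", strict = FALSE)
  if (is.null(program)) {
    n_tf <- length(tf_modules %||% list())
    program <- make_gene_programs(n_genes, n_tf = n_tf)
    if (n_tf > 0) {
      tf_rows <- which(program$class == "tf")
      for (i in seq_along(tf_modules)) {
        tf_modules[[i]]$tf <- tf_modules[[i]]$tf %||% program$gene[tf_rows[i]]
        program$gene[tf_rows[i]] <- tf_modules[[i]]$tf
      }
    }
  }
  if (!all(c("gene", "class", "onset", "amp") %in% names(program)))
    stop("degenerate program table: need gene/class/onset/amp columns")
  if (any(!is.na(program$onset) & (program$onset < 0 | program$onset > 1)))
    stop("program onsets must lie in [0, 1]")
  depth_mean <- rep_len(depth_mean, length(n_cells))
  structure(list(n_cells = n_cells, depth_mean = depth_mean,
                 n_genes = nrow(program), program = program,
                 nb_dispersion = nb_dispersion, splicing_lag = splicing_lag,
                 unspliced_frac = unspliced_frac,
                 sorted_threshold = sorted_threshold,
                 contamination = contamination,
                 cycling_fraction = cycling_fraction,
                 tf_modules = tf_modules, depth_sdlog = depth_sdlog,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

# program log-factor at latent position s for one gene row
program_log_factor <- function(row, s, cycling, tf_activity = NULL) {
  width <- 0.1
  switch(row$class,
         "diff-up" = row$amp * stats::plogis((s - row$onset) / width),
         "basal-down" = row$amp * (1 - stats::plogis((s - row$onset) / width)),
         "cycle" = row$amp * as.numeric(cycling),
         "tf" = row$amp * tf_activity,
         rep(0, length(s)))
}

#' Simulate a cells-by-genes expression bundle with known ground truth
#'
#' Each cell carries a latent differentiation position `s ~ U(0, 1)`.
#' Gene-wise expected expression follows the staggered program table;
#' unspliced counts follow the program at `s`, spliced counts at
#' `s - splicing_lag` (nascent transcription leads mature mRNA). Counts are
#' negative binomial with gene-level dispersion around a log-normal per-cell
#' depth. The total count matrix is the sum of the two layers.
#'
#' @param config An [expr_sim_config()].
#' @return Object of class `expression_bundle`: list with sparse integer
#'   matrices `counts`, `spliced`, `unspliced` (cells x genes), `cell_meta`
#'   (`cell_id`, `dataset`, `s`, `sorted`, `cycling`, `traced`, `depth`),
#'   `gene_meta` (program table plus `is_tf`), and `norm = NULL` (filled by
#'   [normalize_log()]).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  if (!nrow(config$program)) stop("degenerate program table")
  seeds <- derive_seeds(config$seed)
  with_seed(seeds[["expression"]], simulate_expression_impl(config))
}

simulate_expression_impl <- function(config) {
  prog <- config$program
  n_tot <- sum(config$n_cells)
  dataset <- rep(names(config$n_cells), config$n_cells)
  s <- runif(n_tot)
  cycling <- runif(n_tot) < config$cycling_fraction
  depth <- stats::rlnorm(n_tot,
                         meanlog = log(rep(config$depth_mean, config$n_cells)) -
                           config$depth_sdlog^2 / 2,
                         sdlog = config$depth_sdlog)

  # TF activities: program profile plus per-cell noise (drives targets)
  tf_act <- list()
  for (mod in config$tf_modules %||% list()) {
    row <- prog[prog$gene == mod$tf, ]
    base <- if (nrow(row) && !is.na(row$onset[1]))
      stats::plogis((s - row$onset[1]) / 0.1) else rep(0.5, n_tot)
    tf_act[[mod$tf]] <- pmin(pmax(base + rnorm(n_tot, 0, 0.15), 0), 1.5)
  }

  # base weights shared between the spliced and unspliced evaluations
  base_w <- log(stats::runif(nrow(prog), 0.3, 3))
  eval_rates <- function(ss) {
    lr <- matrix(rep(base_w, each = n_tot), n_tot, nrow(prog))
    for (g in seq_len(nrow(prog))) {
      row <- prog[g, ]
      act <- if (row$class == "tf") tf_act[[row$gene]] else NULL
      if (row$class == "tf" && is.null(act))
        act <- stats::plogis((ss - (if (is.na(row$onset)) 0.3 else row$onset)) / 0.1)
      lr[, g] <- lr[, g] + program_log_factor(row, ss, cycling, act)
    }
    for (mod in config$tf_modules %||% list()) {
      tgt <- match(mod$targets, prog$gene)
      tgt <- tgt[!is.na(tgt)]
      if (length(tgt))
        lr[, tgt] <- lr[, tgt] + mod$effect * (tf_act[[mod$tf]] - 0.5)
    }
    r <- exp(lr)
    r / rowSums(r)
  }

  p_unspliced <- eval_rates(s)
  p_spliced <- eval_rates(pmax(s - config$splicing_lag, 0))

  draw <- function(mu) {
    n <- length(mu)
    if (config$nb_dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / config$nb_dispersion, mu = mu)
  }
  mu_u <- p_unspliced * depth * config$unspliced_frac
  mu_s <- p_spliced * depth * (1 - config$unspliced_frac)
  uns <- matrix(draw(as.vector(mu_u)), n_tot, nrow(prog))
  spl <- matrix(draw(as.vector(mu_s)), n_tot, nrow(prog))

  cell_id <- sprintf("c%05d", seq_len(n_tot))
  dimnames(uns) <- dimnames(spl) <- list(cell_id, prog$gene)
  counts <- spl + uns

  sorted <- s < config$sorted_threshold
  n_basal <- sum(sorted)
  n_cont <- round(config$contamination / (1 - config$contamination) * n_basal)
  supra <- which(!sorted)
  if (n_cont > 0 && length(supra))
    sorted[sample(supra, min(n_cont, length(supra)))] <- TRUE

  traced <- s > 0.45 & runif(n_tot) > 0.1  # commitment-trace emulation

  cell_meta <- data.frame(cell_id = cell_id, dataset = dataset, s = s,
                          sorted = sorted, cycling = cycling, traced = traced,
                          depth = depth)
  gene_meta <- prog
  gene_meta$is_tf <- prog$class == "tf"

  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 spliced = Matrix::Matrix(spl, sparse = TRUE),
                 unspliced = Matrix::Matrix(uns, sparse = TRUE),
                 cell_meta = cell_meta, gene_meta = gene_meta, norm = NULL),
            class = "expression_bundle")
}
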