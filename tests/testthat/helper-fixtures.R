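# Shared fixture builders; everything is generated in code.

# minimal event table with explicit coordinates/times
toy_events <- function() {
  data.frame(
    event_id = 1:5,
    type = c("delamination", "division", "delamination", "division", "delamination"),
    time_h = c(70, 90, 95, 100, 99),
    x_um = c(5, 3, 4, 0, 30),
    y_um = c(0, 4, 3, 0, 30),
    cell_id = 11:15,
    daughter1 = c(NA, 21L, NA, 23L, NA),
    daughter2 = c(NA, 22L, NA, 24L, NA),
    cause_event_id = c(NA, NA, NA, NA, NA))
}

# stack with an ECM slab below interface h_fun(x, y) (um), rendered with
# partial-volume coverage per slice so the interface has a sub-slice position
slab_stack <- function(nx = 40, ny = 40, nz = 12, h_fun = function(x, y) 5,
                       thickness = 3, noise_sd = 0) {
  ecm <- array(0, dim = c(ny, nx, nz))
  xs <- (seq_len(nx) - 1); ys <- (seq_len(ny) - 1)
  h <- outer(ys, xs, function(yy, xx) h_fun(xx, yy) + 0 * xx + 0 * yy)
  for (z in seq_len(nz)) {
    zc <- z - 1
    cover <- pmin(zc + 0.5, h + thickness) - pmax(zc - 0.5, h)
    ecm[, , z] <- pmin(pmax(cover, 0), 1)
  }
  if (noise_sd > 0) ecm <- pmax(ecm + array(rnorm(length(ecm), 0, noise_sd),
                                            dim = dim(ecm)), 0)
  image_stack(list(ecm = ecm), voxel_size_um = c(1, 1, 1))
}

# small expression bundle with default programs
small_bundle <- function(seed = 3, n_cells = 300, n_genes = 80, ...) {
  simulate_expression(expr_sim_config(n_cells = c(ds1 = n_cells),
                                      depth_mean = 2500, n_genes = n_genes,
                                      seed = seed, ...))
}

first_diff_gene <- function(bundle)
  bundle$gene_meta$gene[bundle$gene_meta$class == "diff-up"][1]
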