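# Genotype-dependent proportion-versus-day trend simulator.

# control recovery curve: acute depletion of the differentiating basal pool
# followed by recovery over ~3 days, normalized to the day-0 value
.control_cubic <- c(b0 = 1, b1 = -0.9, b2 = 0.45, b3 = -0.06)

#' Simulate proportion-vs-day trend tables by genotype
#'
#' Control regions follow a fixed cubic recovery curve
#' `Y = 1 - 0.9 X + 0.45 X^2 - 0.06 X^3` (depletion at day 1, recovery by
#' day 3-4, normalized to day 0); mutant regions follow the same curve offset
#' downward by `effect_size`. Gaussian measurement noise is added per
#' region-day observation.
#'
#' @param effect_size Sustained downward offset of the mutant curve
#'   (proportion units; 0 simulates the null).
#' @param n_regions Regions per genotype (each contributes one observation
#'   per day).
#' @param days Numeric vector of days after perturbation.
#' @param noise_sd Gaussian noise s.d. (proportion units).
#' @param seed Integer seed (trend substream).
#' @return `data.frame(Y, X, G, region_id)` with `G` in
#'   `{"control", "mutant"}`.
#' @export
simulate_trend_data <- function(effect_size = 0, n_regions = 6,
                                days = 0:4, noise_sd = 0.1, seed = 1L) {
  if (!length(days)) stop("`days` must be non-empty")
  stop_if_not_positive(n_regions, "n_regions")
  seeds <- derive_seeds(seed)
  with_seed(seeds[["trend"]], {
    cc <- .control_cubic
    grid <- expand.grid(X = days, region = seq_len(n_regions),
                        G = c("control", "mutant"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- cc["b0"] + cc["b1"] * grid$X + cc["b2"] * grid$X^2 + cc["b3"] * grid$X^3
    mu <- mu - effect_size * (grid$G == "mutant")
    data.frame(Y = pmax(mu + rnorm(nrow(grid), 0, noise_sd), 0),
               X = grid$X, G = grid$G,
               region_id = paste0(grid$G, "_r", grid$region))
  })
}
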