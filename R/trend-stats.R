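# Nested cubic-model comparison for proportion-vs-day curves by genotype.

#' Fit the nested cubic models H0 and H1
#'
#' H0 explains the proportion by the day alone,
#' `Y ~ X + X^2 + X^3` (4 parameters); H1 adds the genotype main effect and
#' all three day-genotype interactions, `Y ~ (X + X^2 + X^3) * G`
#' (8 parameters, genotype coded 0/1).
#'
#' @param table `data.frame(Y, X, G, ...)` with `G` taking two levels.
#' @return List of class `cubic_fits` with elements `h0` and `h1`, each
#'   carrying `coefficients`, `ssr`, `df_resid`, `n` and the `lm` fit.
#' @export
fit_models <- function(table) {
  stopifnot(all(c("Y", "X", "G") %in% names(table)))
  n <- nrow(table)
  if (n <= 8) stop("need more than 8 observations to fit H1 (8 parameters)")
  g <- as.integer(factor(table$G)) - 1L
  if (length(unique(g)) < 2) stop("H1 requires both genotypes present")
  d <- data.frame(Y = table$Y, X = table$X, G = g)
  h0 <- stats::lm(Y ~ X + I(X^2) + I(X^3), data = d)
  h1 <- stats::lm(Y ~ (X + I(X^2) + I(X^3)) * G, data = d)
  wrap <- function(fit) list(coefficients = stats::coef(fit),
                             ssr = sum(stats::resid(fit)^2),
                             df_resid = stats::df.residual(fit),
                             n = n, fit = fit)
  structure(list(h0 = wrap(h0), h1 = wrap(h1)), class = "cubic_fits")
}

#' F-test comparing the nested cubic models
#'
#' `F = ((SSR0 - SSR1) / (df0 - df1)) / (SSR1 / df1)` with the p-value from
#' the F distribution on `(df0 - df1, df1)` degrees of freedom: does adding
#' genotype explain the trend better than day alone?
#'
#' @param fits A `cubic_fits` object, or `fit_h0` when the two fits are
#'   passed separately.
#' @param fit_h1 Optional H1 fit when passing fits separately.
#' @return List with `F`, `p`, `df1` (numerator), `df2` (denominator).
#' @export
compare_anova <- function(fits, fit_h1 = NULL) {
  if (inherits(fits, "cubic_fits")) { h0 <- fits$h0; h1 <- fits$h1 }
  else { h0 <- fits; h1 <- fit_h1 }
  if (h0$n != h1$n) stop("fits are not on identical data")
  if (h0$df_resid <= h1$df_resid)
    stop("fits are not nested (H1 must use more parameters)")
  if (h1$df_resid <= 0) stop("H1 has no residual degrees of freedom")
  df_num <- h0$df_resid - h1$df_resid
  Fstat <- ((h0$ssr - h1$ssr) / df_num) / (h1$ssr / h1$df_resid)
  Fstat <- max(Fstat, 0)
  list(F = Fstat, p = stats::pf(Fstat, df_num, h1$df_resid, lower.tail = FALSE),
       df1 = df_num, df2 = h1$df_resid)
}
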