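#' Cochran's Q heterogeneity test for the IVW analysis
#'
#' Tests whether the per-SNP causal estimates differ across variants more
#' than their sampling error allows: `Q = sum(w_j * (ratio_j - ivw)^2)` with
#' first-order inverse-variance weights `w_j = beta_x_j^2 / se_y_j^2`,
#' referred to a chi-square with L - 1 df. Computed in the algebraically
#' identical residual form `sum((beta_y - ivw * beta_x)^2 / se_y^2)`, which
#' is also defined for SNPs with `beta_x = 0`. Excess heterogeneity signals
#' pleiotropy or invalid instruments.
#'
#' @param h a `harmonized_set` with L >= 2.
#' @return A list with `q`, `df` and `pvalue`.
#' @export
cochran_q <- function(h) {
  L <- nrow(h)
  if (L < 2L) stop("Cochran's Q requires at least 2 instruments")
  beta <- mr_ivw(h, model = "fixed")$beta
  q <- sum((h$beta_y - beta * h$beta_x)^2 / h$se_y^2)
  list(q = q, df = L - 1L,
       pvalue = stats::pchisq(q, df = L - 1L, lower.tail = FALSE))
}

#' I2GX: adequacy of the no-measurement-error assumption for MR-Egger
#'
#' Quantifies the regression dilution of the Egger slope caused by sampling
#' error in the SNP-exposure estimates. With `v_j = 1/se_x_j^2` and `m` the
#' v-weighted mean of `|beta_x|`, `Q_GX = sum(v_j * (|beta_x_j| - m)^2)` and
#' `I2GX = max(0, (Q_GX - (L-1)) / Q_GX)`. Values near 1 mean the exposure
#' estimates are effectively error-free (NOME holds); values below 0.9
#' indicate that an unweighted SIMEX correction of the Egger fit is needed.
#' The weighted variant folds the Egger regression weights into the
#' statistic by applying the same formula to `|beta_x|/se_y` with standard
#' errors `se_x/se_y`.
#'
#' @param h a `harmonized_set` with L >= 2.
#' @param weighted use the Egger-weight composition (default `FALSE`, the
#'   unweighted variant that gates the SIMEX correction).
#' @return I2GX in [0, 1].
#' @export
i2_gx <- function(h, weighted = FALSE) {
  if (nrow(h) < 2L) stop("I2GX requires at least 2 instruments")
  if (weighted) {
    g <- abs(h$beta_x) / h$se_y
    s <- h$se_x / h$se_y
  } else {
    g <- abs(h$beta_x)
    s <- h$se_x
  }
  v <- 1 / s^2
  m <- sum(v * g) / sum(v)
  q_gx <- sum(v * (g - m)^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (nrow(h) - 1)) / q_gx)
}

#' Mean F statistic of the instrument
#'
#' Mean over SNPs of the squared exposure t-statistic `(beta_x/se_x)^2`; the
#' conventional summary of instrument strength (values above ~10 indicate a
#' strong instrument).
#'
#' @param h a `harmonized_set`.
#' @return Mean F (unitless, >= 0).
#' @export
mean_f <- function(h) {
  if (nrow(h) < 1L) stop("mean F requires at least 1 instrument")
  mean((h$beta_x / h$se_x)^2)
}

#' Combined instrument diagnostics
#'
#' @param h a `harmonized_set` with L >= 2.
#' @return A list of class `instrument_diagnostics`: `q`, `q_df`, `q_pvalue`,
#'   `i2_gx` (unweighted), `i2_gx_weighted`, `mean_f`, `l`.
#' @export
instrument_diagnostics <- function(h) {
  cq <- cochran_q(h)
  structure(list(q = cq$q, q_df = cq$df, q_pvalue = cq$pvalue,
                 i2_gx = i2_gx(h, weighted = FALSE),
                 i2_gx_weighted = i2_gx(h, weighted = TRUE),
                 mean_f = mean_f(h), l = nrow(h)),
            class = "instrument_diagnostics")
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument diagnostics (L = %d)\n", x$l))
  cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n", x$q, x$q_df, x$q_pvalue))
  cat(sprintf("  I2GX = %.3f (unweighted), %.3f (weighted)\n",
              x$i2_gx, x$i2_gx_weighted))
  cat(sprintf("  mean F = %.2f\n", x$mean_f))
  invisible(x)
}

#' Radial MR outlier detection
#'
#' First-order radial regression: `beta_y/se_y` on `beta_x/se_y` through the
#' origin (whose slope is the fixed-effect IVW estimate). Each SNP's squared
#' standardized residual is its contribution to Cochran's Q; a SNP is flagged
#' as an outlier when its contribution exceeds the upper-alpha quantile of
#' chi-square(1).
#'
#' @param h a `harmonized_set` with L >= 3.
#' @param alpha per-SNP significance level; default `0.05/L` (Bonferroni).
#' @return An object of class `radial_report`: data.frame with `rsid`,
#'   `q_contribution`, `outlier`; attributes `alpha`, `total_q`, `outliers`
#'   (rsid vector) and `slope`.
#' @export
radial_outliers <- function(h, alpha = NULL) {
  L <- nrow(h)
  if (L < 3L) stop("radial MR requires at least 3 instruments")
  if (is.null(alpha)) alpha <- 0.05 / L
  beta <- mr_ivw(h, model = "fixed")$beta
  q_j <- (h$beta_y / h$se_y - beta * h$beta_x / h$se_y)^2
  cut <- stats::qchisq(1 - alpha, df = 1)
  out <- data.frame(rsid = h$rsid, q_contribution = q_j, outlier = q_j > cut,
                    stringsAsFactors = FALSE)
  structure(out, alpha = alpha, total_q = sum(q_j),
            outliers = h$rsid[q_j > cut], slope = beta,
            class = c("radial_report", "data.frame"))
}

#' @export
print.radial_report <- function(x, ...) {
  cat(sprintf("Radial MR: total Q = %.3f over %d SNPs, alpha = %.4g\n",
              attr(x, "total_q"), nrow(x), attr(x, "alpha")))
  out <- attr(x, "outliers")
  if (length(out) > 0L) cat("  outliers:", paste(out, collapse = ", "), "\n")
  else cat("  no outliers flagged\n")
  invisible(x)
}

#' Radial plot of per-SNP contributions
#'
#' @param x a `radial_report`.
#' @param h the `harmonized_set` it was computed from.
#' @param ... passed to [plot()].
#' @export
plot.radial_report <- function(x, h, ...) {
  rx <- h$beta_x / h$se_y
  ry <- h$beta_y / h$se_y
  flag <- x$outlier[match(h$rsid, x$rsid)]
  plot(rx, ry, pch = ifelse(flag, 17, 16),
       col = ifelse(flag, "firebrick", "grey30"),
       xlab = expression(beta[x] / se[y]), ylab = expression(beta[y] / se[y]),
       ...)
  graphics::abline(0, attr(x, "slope"), col = "steelblue")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect L times, omitting one SNP each time, to
#' reveal estimates driven by a single variant.
#'
#' @param h a `harmonized_set` with L >= 2.
#' @param method estimator to refit: `"ivw"` (default), `"ivw_fixed"`,
#'   `"egger"` (slope), `"weighted_median"` or `"mbe"`.
#' @param ... passed to the estimator (e.g. `b_boot`, `seed`).
#' @return A named list of `mr_estimate` objects (names = omitted rsid), of
#'   class `mr_loo`.
#' @export
leave_one_out <- function(h, method = "ivw", ...) {
  L <- nrow(h)
  if (L < 2L) stop("leave-one-out requires at least 2 instruments")
  fit <- switch(method,
    ivw = function(hh, ...) mr_ivw(hh, model = "random"),
    ivw_fixed = function(hh, ...) mr_ivw(hh, model = "fixed"),
    egger = function(hh, ...) mr_egger(hh)$slope,
    weighted_median = mr_weighted_median,
    mbe = mr_mbe,
    stop("unknown method: ", method))
  ests <- lapply(seq_len(L), function(i) fit(h[-i, , drop = FALSE], ...))
  names(ests) <- h$rsid
  structure(ests, class = "mr_loo")
}

#' @export
print.mr_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out analysis (%d refits)\n", length(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.mr_loo <- function(x, ...) {
  tab <- estimates_table(unclass(x))
  cbind(data.frame(omitted = names(x), stringsAsFactors = FALSE), tab)
}
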