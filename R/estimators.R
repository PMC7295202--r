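#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# first-order delta-method SE of the Wald ratio; second order adds the
# contribution of the exposure-side sampling error
.ratio_se <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
}

# per-SNP ratios for ratio-based estimators; zero exposure effects cannot
# form a ratio and are excluded with a warning
.ratios <- function(h, second_order = FALSE) {
  zero <- h$beta_x == 0
  if (any(zero)) {
    warning(sum(zero), " SNP(s) with beta_x = 0 excluded from ratio-based estimate")
    h <- h[!zero, , drop = FALSE]
  }
  list(ratio = h$beta_y / h$beta_x,
       se = .ratio_se(h$beta_x, h$se_x, h$beta_y, h$se_y, second_order),
       h = h)
}

#' Wald ratio estimate for a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome association divided by the
#' SNP-exposure association, with a first-order delta-method standard error
#' `se_y / |beta_x|` (second order adds the exposure-side error term).
#'
#' @param beta_x,se_x SNP-exposure estimate and SE (`beta_x` must be nonzero).
#' @param beta_y,se_y SNP-outcome estimate and SE.
#' @param second_order use the second-order delta-method SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  stopifnot(se_x > 0, se_y > 0)
  if (beta_x == 0) stop("Wald ratio undefined: beta_x = 0")
  mr_estimate("wald_ratio", beta_y / beta_x,
              .ratio_se(beta_x, se_x, beta_y, se_y, second_order), n_snps = 1L)
}

#' Inverse-variance weighted estimate
#'
#' Pools the per-SNP Wald ratios with first-order inverse-variance weights;
#' equivalently, a weighted regression of the SNP-outcome coefficients on the
#' SNP-exposure coefficients with the intercept constrained to zero and
#' weights `1/se_y^2`. The fixed-effect SE is `1/sqrt(sum(beta_x^2/se_y^2))`;
#' the multiplicative random-effects model scales it by
#' `max(1, sqrt(Q/(L-1)))`, allowing balanced pleiotropy to widen the
#' interval without shifting the point estimate.
#'
#' @param h a `harmonized_set`.
#' @param model `"random"` (default; requires L >= 2) or `"fixed"`.
#' @return An `mr_estimate` with method `"ivw_random"` or `"ivw_fixed"`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  L <- nrow(h)
  if (all(h$beta_x == 0)) stop("all beta_x are zero: IVW undefined")
  if (model == "random" && L < 2L) stop("random-effects IVW requires L >= 2")
  w <- 1 / h$se_y^2
  beta <- sum(w * h$beta_x * h$beta_y) / sum(w * h$beta_x^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_x^2))
  if (model == "fixed") {
    return(mr_estimate("ivw_fixed", beta, se_fixed, L))
  }
  q <- sum((h$beta_y - beta * h$beta_x)^2 / h$se_y^2)
  se <- se_fixed * max(1, sqrt(q / (L - 1)))
  mr_estimate("ivw_random", beta, se, L)
}

# closed-form (weighted) least squares of beta_y on beta_x with intercept,
# under the beta_x > 0 orientation; returns coefficient estimates and
# model-based variances. Weighted fits use multiplicative overdispersion
# floored at 1; unweighted fits use the plain OLS residual variance.
.egger_fit <- function(beta_x, beta_y, se_y, weighted, floor_dispersion = FALSE) {
  flip <- beta_x < 0
  bx <- ifelse(flip, -beta_x, beta_x)
  by <- ifelse(flip, -beta_y, beta_y)
  L <- length(bx)
  w <- if (weighted) 1 / se_y^2 else rep(1, L)
  W <- sum(w); Sx <- sum(w * bx); Sy <- sum(w * by)
  Sxx <- sum(w * bx^2); Sxy <- sum(w * bx * by)
  denom <- W * Sxx - Sx^2
  if (denom <= 0) stop("degenerate Egger design: no variation in beta_x")
  slope <- (W * Sxy - Sx * Sy) / denom
  intercept <- (Sy - slope * Sx) / W
  resid <- by - intercept - slope * bx
  s2 <- sum(w * resid^2) / (L - 2)
  disp <- if (weighted && floor_dispersion) max(1, s2) else s2
  list(slope = slope, intercept = intercept,
       var_slope = disp * W / denom, var_intercept = disp * Sxx / denom)
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome on the SNP-exposure coefficients
#' with an unconstrained intercept (weights `1/se_y^2`), computed with every
#' pair oriented to the exposure-increasing allele. The slope estimates the
#' causal effect under the InSIDE assumption (pleiotropic effects independent
#' of instrument strength); the intercept estimates average directional
#' pleiotropy, so a nonzero intercept flags exclusion-restriction violations.
#' Inference uses t with L - 2 df and the estimated multiplicative
#' overdispersion, which makes the intercept test exactly calibrated under
#' the null; `floor_dispersion = TRUE` truncates the dispersion at 1 (the
#' convention of several MR toolkits), giving intervals never narrower than
#' the known-dispersion ones at the cost of a conservative test.
#'
#' @param h a `harmonized_set` with L >= 3.
#' @param weighted inverse-variance weights (default); `FALSE` gives the
#'   unweighted fit used by the SIMEX correction.
#' @param floor_dispersion truncate the residual dispersion at 1.
#' @return An object of class `egger_result` with elements `slope` and
#'   `intercept`, each an `mr_estimate`.
#' @export
mr_egger <- function(h, weighted = TRUE, floor_dispersion = FALSE) {
  L <- nrow(h)
  if (L < 3L) stop("MR-Egger requires at least 3 instruments, got ", L)
  f <- .egger_fit(h$beta_x, h$beta_y, h$se_y, weighted, floor_dispersion)
  tag <- if (weighted) "egger" else "egger_unweighted"
  structure(list(
    slope = mr_estimate(paste0(tag, "_slope"), f$slope, sqrt(f$var_slope),
                        L, df = L - 2),
    intercept = mr_estimate(paste0(tag, "_intercept"), f$intercept,
                            sqrt(f$var_intercept), L, df = L - 2)),
    class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope, ...)
  print(x$intercept, ...)
  invisible(x)
}

#' SIMEX-corrected unweighted MR-Egger
#'
#' Simulation-extrapolation correction of regression dilution in the
#' unweighted Egger fit when the no-measurement-error (NOME) assumption on
#' the SNP-exposure estimates fails (low I2GX). For each lambda >= 0 in the
#' grid, `b_reps` pseudo-datasets add independent N(0, lambda * se_x^2) noise
#' to each `beta_x`; the unweighted Egger fit is averaged per lambda and a
#' quadratic in lambda is extrapolated to lambda = -1, the no-error limit.
#' Variances follow the SIMEX jackknife construction: the mean model-based
#' variance minus the between-pseudo-dataset variance, extrapolated on the
#' same grid. A grid containing only lambda = 0 reproduces the unweighted
#' Egger fit exactly.
#'
#' @param h a `harmonized_set` with L >= 3.
#' @param lambdas added-noise multipliers; must include 0.
#' @param b_reps pseudo-datasets per positive lambda.
#' @param seed integer seed making the correction reproducible.
#' @return An `egger_result` with methods tagged `simex_egger_*`.
#' @export
simex_egger <- function(h, lambdas = c(0, 0.5, 1, 1.5, 2), b_reps = 200,
                        seed = NULL) {
  L <- nrow(h)
  if (L < 3L) stop("SIMEX Egger requires at least 3 instruments, got ", L)
  if (!any(lambdas == 0)) stop("lambda grid must include 0")
  lambdas <- sort(unique(lambdas))
  naive <- .egger_fit(h$beta_x, h$beta_y, h$se_y, weighted = FALSE)

  if (all(lambdas == 0)) {
    est <- c(slope = naive$slope, intercept = naive$intercept)
    v <- c(slope = naive$var_slope, intercept = naive$var_intercept)
  } else {
    res <- with_seed(seed, {
      lapply(lambdas, function(lam) {
        if (lam == 0) {
          return(list(mean = c(naive$slope, naive$intercept),
                      var_model = c(naive$var_slope, naive$var_intercept),
                      var_between = c(0, 0)))
        }
        fits <- vapply(seq_len(b_reps), function(b) {
          bx <- h$beta_x + stats::rnorm(L, 0, sqrt(lam) * h$se_x)
          f <- .egger_fit(bx, h$beta_y, h$se_y, weighted = FALSE)
          c(f$slope, f$intercept, f$var_slope, f$var_intercept)
        }, numeric(4))
        list(mean = rowMeans(fits[1:2, , drop = FALSE]),
             var_model = rowMeans(fits[3:4, , drop = FALSE]),
             var_between = apply(fits[1:2, , drop = FALSE], 1, stats::var))
      })
    })
    extrap <- function(y) {
      # quadratic in lambda extrapolated to -1 (linear if grid too small)
      deg <- min(2L, length(lambdas) - 1L)
      fit <- stats::lm(y ~ stats::poly(lambdas, degree = deg, raw = TRUE))
      unname(stats::predict(fit, newdata = data.frame(lambdas = -1)))
    }
    est_grid <- vapply(res, `[[`, numeric(2), "mean")
    v_grid <- vapply(res, function(r) r$var_model - r$var_between, numeric(2))
    est <- c(slope = extrap(est_grid[1, ]), intercept = extrap(est_grid[2, ]))
    v <- c(slope = max(extrap(v_grid[1, ]), 1e-12),
           intercept = max(extrap(v_grid[2, ]), 1e-12))
  }
  structure(list(
    slope = mr_estimate("simex_egger_slope", est[["slope"]],
                        sqrt(v[["slope"]]), L, df = L - 2),
    intercept = mr_estimate("simex_egger_intercept", est[["intercept"]],
                            sqrt(v[["intercept"]]), L, df = L - 2)),
    class = "egger_result")
}

# weighted median of values x with weights w: the 50% point of the cumulative
# normalized weights over sorted values, linearly interpolated
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The weighted median of the per-SNP Wald ratios with inverse-variance
#' weights `1/se(ratio)^2`: consistent when at least half of the total weight
#' comes from valid instruments. The SE is a parametric bootstrap, resampling
#' `beta_x` and `beta_y` from their normal sampling distributions.
#'
#' @param h a `harmonized_set` with L >= 2.
#' @param b_boot bootstrap resamples (default 1000; 0 skips the bootstrap and
#'   returns the point estimate with `se = NA`).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, b_boot = 1000, seed = NULL) {
  if (nrow(h) < 2L) stop("weighted median requires at least 2 instruments")
  r <- .ratios(h)
  beta <- .weighted_median(r$ratio, 1 / r$se^2)
  se <- NA_real_
  if (b_boot > 0) {
    hh <- r$h
    se <- with_seed(seed, {
      boots <- vapply(seq_len(b_boot), function(b) {
        bx <- stats::rnorm(nrow(hh), hh$beta_x, hh$se_x)
        by <- stats::rnorm(nrow(hh), hh$beta_y, hh$se_y)
        ok <- bx != 0
        .weighted_median(by[ok] / bx[ok], bx[ok]^2 / hh$se_y[ok]^2)
      }, numeric(1))
      stats::sd(boots)
    })
  }
  mr_estimate("weighted_median", beta, se, nrow(r$h))
}

#' Mode-based estimate (MBE)
#'
#' Finds the largest cluster of per-SNP Wald ratios: the argmax of a normal
#' kernel density over the ratios (inverse-variance weighted when `weighted`),
#' with bandwidth `phi * s` where `s` is the modified Silverman rule
#' `0.9 * min(sd, MAD/0.6745) * L^(-1/5)` on the ratio sample. Consistent
#' when the largest group of similar instrument estimates comes from valid
#' instruments, even if the majority are invalid. The density is maximized on
#' a 512-point grid spanning the ratio range padded by three bandwidths; an
#' exact tie is broken toward the smaller absolute effect. SE by parametric
#' bootstrap.
#'
#' @param h a `harmonized_set` with L >= 3.
#' @param phi bandwidth tuning multiplier (default 0.5).
#' @param weighted use inverse-variance weights in the density (default).
#' @inheritParams mr_weighted_median
#' @return An `mr_estimate` with method `"mbe"`.
#' @export
mr_mbe <- function(h, phi = 0.5, weighted = TRUE, b_boot = 1000, seed = NULL) {
  if (nrow(h) < 3L) stop("mode-based estimate requires at least 3 instruments")
  r <- .ratios(h)
  point <- function(ratio, se_ratio) {
    w <- if (weighted) 1 / se_ratio^2 else rep(1, length(ratio))
    w <- w / sum(w)
    s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * length(ratio)^(-1 / 5)
    if (!is.finite(s) || s <= 0) return(ratio[which.max(w)])
    bw <- phi * s
    grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512L)
    dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / bw)) / bw
    top <- which(dens >= max(dens) - 1e-12 * max(dens))
    grid[top][which.min(abs(grid[top]))]
  }
  beta <- point(r$ratio, r$se)
  se <- NA_real_
  if (b_boot > 0) {
    hh <- r$h
    se <- with_seed(seed, {
      boots <- vapply(seq_len(b_boot), function(b) {
        bx <- stats::rnorm(nrow(hh), hh$beta_x, hh$se_x)
        by <- stats::rnorm(nrow(hh), hh$beta_y, hh$se_y)
        ok <- bx != 0
        point(by[ok] / bx[ok], hh$se_y[ok] / abs(bx[ok]))
      }, numeric(1))
      stats::sd(boots)
    })
  }
  mr_estimate("mbe", beta, se, nrow(r$h))
}

#' Unweighted allele-score analysis as a fixed-effects meta-analysis
#'
#' Pools the SNP-outcome associations (aligned to the exposure-increasing
#' alleles) with an inverse-variance fixed-effects meta-analysis:
#' `beta = sum(beta_y/se_y^2) / sum(1/se_y^2)`, `se = 1/sqrt(sum(1/se_y^2))`.
#' This is the summary-data equivalent of an unweighted allele-score
#' analysis; the units are outcome change per additional effect allele, not
#' per unit of exposure.
#'
#' @param x a `harmonized_set`, or an `association_set` of SNP-outcome
#'   associations already aligned to the exposure-increasing alleles.
#' @return An `mr_estimate` with method `"allele_score_meta"`.
#' @export
allele_score_meta <- function(x) {
  if (inherits(x, "harmonized_set")) {
    by <- x$beta_y; sy <- x$se_y
  } else if (inherits(x, "association_set")) {
    by <- x$beta; sy <- x$se
  } else stop("x must be a harmonized_set or association_set")
  if (length(by) == 0L) stop("empty association set")
  w <- 1 / sy^2
  mr_estimate("allele_score_meta", sum(w * by) / sum(w), 1 / sqrt(sum(w)),
              length(by))
}
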