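# independent oracles and small builders used across the suite

mk_assoc <- function(rsid, ea, oa, beta, se, pvalue = NULL, eaf = NULL,
                     label = "trait", type = "continuous") {
  df <- data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
                   beta = beta, se = se, stringsAsFactors = FALSE)
  if (!is.null(pvalue)) df$pvalue <- pvalue
  if (!is.null(eaf)) df$eaf <- eaf
  association_set(df, trait_label = label, trait_type = type)
}

# weighted empirical quantile at 50% by dumb stepwise enumeration,
# coded independently of the package's cumulative-weight implementation
wm_oracle <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  centers <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    centers[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (centers[1] >= 0.5) return(x[1])
  if (centers[length(x)] <= 0.5) return(x[length(x)])
  for (i in seq_len(length(x) - 1L)) {
    if (centers[i] <= 0.5 && centers[i + 1] >= 0.5) {
      if (centers[i + 1] == centers[i]) return(x[i])
      return(x[i] + (x[i + 1] - x[i]) * (0.5 - centers[i]) /
               (centers[i + 1] - centers[i]))
    }
  }
  stop("unreachable")
}

# fine-grid weighted normal-kernel mode, independent of the package's
# 512-point grid search
mbe_oracle <- function(ratio, w, bw, n_grid = 20001L) {
  w <- w / sum(w)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - ratio) / bw)), numeric(1))
  grid[which.max(dens)]
}

# weighted regression through the origin / with intercept, via lm()
ivw_oracle <- function(h) {
  unname(coef(lm(beta_y ~ 0 + beta_x, data = as.data.frame(h),
                 weights = 1 / h$se_y^2)))
}

egger_oracle <- function(h, weighted = TRUE) {
  d <- as.data.frame(h)
  flip <- d$beta_x < 0
  d$beta_x[flip] <- -d$beta_x[flip]
  d$beta_y[flip] <- -d$beta_y[flip]
  w <- if (weighted) 1 / d$se_y^2 else rep(1, nrow(d))
  coef(lm(beta_y ~ beta_x, data = d, weights = w))
}

# harmonized set with ratios scattered around a truth, strong instruments
mk_h <- function(L, beta = 0.3, seed = 1, se_x = 0.003, se_y = 0.004,
                 alpha = rep(0, L)) {
  set.seed(seed)
  gamma <- runif(L, 0.02, 0.08)
  harmonized_set(beta_x = rnorm(L, gamma, se_x), se_x = rep(se_x, L),
                 beta_y = rnorm(L, beta * gamma + alpha, se_y),
                 se_y = rep(se_y, L))
}
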