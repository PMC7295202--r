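#' Causal-effect estimates
#'
#' Internal constructor for the common return value of all estimators: a
#' point estimate with uncertainty, a method tag, and direction/scale flags.
#' `direction` records whether the effect is expressed per unit *later* (the
#' internal convention, on the trait-increasing allele) or per unit *earlier*
#' (the reporting convention after [reverse_direction()]); `scale` is
#' `"linear"` until [to_odds_ratio()] exponentiates a binary-outcome estimate.
#'
#' @param method method tag (e.g. `"ivw_fixed"`, `"egger_slope"`).
#' @param beta,se point estimate and standard error (linear scale).
#' @param n_snps number of instruments used.
#' @param df if finite, CI and p use a t distribution with `df` degrees of
#'   freedom; otherwise the normal.
#' @param pvalue,ci_lower,ci_upper optional overrides of the default
#'   normal/t-based values.
#' @param direction,scale convention flags.
#' @return An object of class `mr_estimate`.
#' @keywords internal
mr_estimate <- function(method, beta, se, n_snps, df = Inf,
                        pvalue = NULL, ci_lower = NULL, ci_upper = NULL,
                        direction = "per-unit-later", scale = "linear") {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  if (is.null(ci_lower)) ci_lower <- beta - crit * se
  if (is.null(ci_upper)) ci_upper <- beta + crit * se
  if (is.null(pvalue)) {
    z <- beta / se
    pvalue <- if (is.finite(df)) 2 * stats::pt(abs(z), df, lower.tail = FALSE)
              else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 pvalue = pvalue, n_snps = n_snps, df = df,
                 direction = direction, scale = scale),
            class = "mr_estimate")
}

#' Reverse the direction convention of an estimate
#'
#' Analyses are run on the trait-increasing allele (effect per unit *later*);
#' reporting follows the opposite convention (effect per unit *earlier*).
#' Reversal negates the point estimate and swaps the negated confidence
#' bounds; the SE and p-value are unchanged. It must precede odds-ratio
#' exponentiation, and applying it twice restores the original estimate.
#'
#' @param e an `mr_estimate` on the linear scale.
#' @return The reversed `mr_estimate`.
#' @export
reverse_direction <- function(e) {
  stopifnot(inherits(e, "mr_estimate"))
  if (e$scale != "linear") {
    stop("reverse_direction must be applied on the linear scale, before to_odds_ratio")
  }
  e$beta <- -e$beta
  ci <- c(-e$ci_upper, -e$ci_lower)
  e$ci_lower <- ci[1]
  e$ci_upper <- ci[2]
  e$direction <- if (identical(e$direction, "per-unit-later"))
    "per-unit-earlier" else "per-unit-later"
  e
}

#' Express a binary-outcome estimate as an odds ratio
#'
#' Exponentiates the point estimate and confidence bounds of a log-odds-scale
#' estimate; the p-value is unchanged. Applying it twice is an error.
#'
#' @param e an `mr_estimate` with `scale = "linear"` for a binary outcome.
#' @return The `mr_estimate` on the odds-ratio scale.
#' @export
to_odds_ratio <- function(e) {
  stopifnot(inherits(e, "mr_estimate"))
  if (e$scale != "linear") stop("estimate is already on the odds-ratio scale")
  e$beta <- exp(e$beta)
  e$ci_lower <- exp(e$ci_lower)
  e$ci_upper <- exp(e$ci_upper)
  e$scale <- "odds_ratio"
  e
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  lab <- if (x$scale == "odds_ratio") "OR" else "beta"
  cat(sprintf("%s: %s = %.*f (95%% CI %.*f, %.*f), p = %.3g, L = %d [%s]\n",
              x$method, lab, digits, x$beta, digits, x$ci_lower,
              digits, x$ci_upper, x$pvalue, x$n_snps, x$direction))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$beta, object$method)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95) {
    crit <- if (is.finite(object$df)) stats::qt(1 - (1 - level) / 2, object$df)
            else stats::qnorm(1 - (1 - level) / 2)
    if (object$scale == "odds_ratio") {
      ci <- exp(log(object$beta) + c(-1, 1) * crit * object$se)
    } else {
      ci <- object$beta + c(-1, 1) * crit * object$se
    }
  } else {
    ci <- c(object$ci_lower, object$ci_upper)
  }
  m <- matrix(ci, nrow = 1, dimnames = list(object$method, c("lower", "upper")))
  m
}

#' Collect estimates into a result table
#'
#' @param ... `mr_estimate` objects (or a single list of them).
#' @return data.frame with one row per estimate, mirroring the serialized
#'   layout: method, beta_or_OR, ci_lower, ci_upper, p, n_snps, scale,
#'   direction.
#' @export
estimates_table <- function(...) {
  es <- list(...)
  if (length(es) == 1L && !inherits(es[[1]], "mr_estimate")) es <- es[[1]]
  do.call(rbind, lapply(es, function(e) {
    data.frame(method = e$method, beta_or_OR = e$beta,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper,
               p = e$pvalue, se = e$se, n_snps = e$n_snps,
               scale = e$scale, direction = e$direction,
               stringsAsFactors = FALSE)
  }))
}
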