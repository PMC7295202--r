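#' Run the full two-sample MR battery over one or more outcomes
#'
#' For each outcome: harmonize to the exposure's trait-increasing allele;
#' estimate the causal effect by random-effects IVW, MR-Egger, weighted
#' median and the weighted mode-based estimator (phi = 0.5); reverse every
#' estimate to the per-unit-*earlier* reporting convention; exponentiate
#' binary-outcome estimates (and their Egger intercepts) to odds ratios;
#' compute instrument diagnostics (Cochran's Q, unweighted and weighted
#' I2GX, mean F), radial-MR outlier contributions and a leave-one-out IVW
#' series; run the SIMEX-corrected unweighted Egger fit whenever the
#' unweighted I2GX falls below `simex_threshold`; and, when requested, the
#' unweighted allele-score fixed-effects meta-analysis. An optional
#' exclusion list (e.g. variants associated with body mass index) adds a
#' sensitivity arm with those instruments removed. A failure in one outcome
#' is recorded without aborting the others. Fully deterministic under
#' `seed`.
#'
#' @param exposure an `association_set` of SNP-exposure associations.
#' @param outcomes a named list of `association_set`s (or a single set) of
#'   SNP-outcome associations.
#' @param drop_palindromic passed to [harmonize()].
#' @param b_boot bootstrap resamples for the weighted median and MBE SEs.
#' @param phi MBE bandwidth tuning parameter.
#' @param simex_threshold unweighted I2GX below which the SIMEX-corrected
#'   unweighted Egger fit is run (default 0.9).
#' @param simex_lambdas,simex_b_reps SIMEX grid and pseudo-dataset count.
#' @param allele_score also report the allele-score meta-analysis (units per
#'   effect allele).
#' @param exclude_rsids optional rsids defining an exclusion sensitivity arm.
#' @param radial_alpha per-SNP outlier level; `NULL` = 0.05/L.
#' @param seed integer seed driving every stochastic component.
#' @return An object of class `mr_battery`.
#' @export
mr_battery <- function(exposure, outcomes, drop_palindromic = FALSE,
                       b_boot = 1000, phi = 0.5, simex_threshold = 0.9,
                       simex_lambdas = c(0, 0.5, 1, 1.5, 2),
                       simex_b_reps = 200, allele_score = FALSE,
                       exclude_rsids = NULL, radial_alpha = NULL,
                       seed = 1L) {
  stopifnot(inherits(exposure, "association_set"))
  if (inherits(outcomes, "association_set")) outcomes <- list(outcomes)
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- vapply(outcomes, attr, "", "trait_label")
  }
  stopifnot(length(outcomes) >= 1L)

  fit_one <- function(expo, outcome, oseed) {
    h <- harmonize(expo, outcome, drop_palindromic = drop_palindromic)
    binary <- identical(attr(h, "outcome_type"), "binary")
    finalize <- function(e) {
      e <- reverse_direction(e)
      if (binary) e <- to_odds_ratio(e)
      e
    }
    egger <- mr_egger(h)
    ests <- list(
      ivw = mr_ivw(h, model = "random"),
      egger = egger$slope,
      weighted_median = mr_weighted_median(h, b_boot = b_boot,
                                           seed = split_seed(oseed, "wm")),
      mbe = mr_mbe(h, phi = phi, b_boot = b_boot,
                   seed = split_seed(oseed, "mbe"))
    )
    diag <- instrument_diagnostics(h)
    simex <- NULL
    if (diag$i2_gx < simex_threshold) {
      simex <- simex_egger(h, lambdas = simex_lambdas, b_reps = simex_b_reps,
                           seed = split_seed(oseed, "simex"))
    }
    list(
      harmonized = h,
      estimates = lapply(ests, finalize),
      egger_intercept = finalize(egger$intercept),
      simex = if (!is.null(simex)) {
        list(slope = finalize(simex$slope),
             intercept = finalize(simex$intercept))
      },
      allele_score = if (allele_score) finalize(allele_score_meta(h)),
      diagnostics = diag,
      radial = radial_outliers(h, alpha = radial_alpha),
      loo = leave_one_out(h, method = "ivw"),
      error = NULL
    )
  }

  run_arm <- function(expo, arm_tag) {
    res <- lapply(seq_along(outcomes), function(i) {
      oseed <- split_seed(seed, paste0(arm_tag, "_", names(outcomes)[i]))
      tryCatch(fit_one(expo, outcomes[[i]], oseed),
               error = function(e) list(error = conditionMessage(e)))
    })
    names(res) <- names(outcomes)
    res
  }

  main <- run_arm(exposure, "main")
  excl <- NULL
  if (!is.null(exclude_rsids) && length(exclude_rsids) > 0L) {
    excl <- run_arm(suppressWarnings(exclude_snps(exposure, exclude_rsids)),
                    "excl")
  }

  structure(list(
    outcomes = main,
    exclusion_arm = excl,
    provenance = list(
      exposure_label = attr(exposure, "trait_label"),
      n_exposure_snps = nrow(exposure),
      outcome_labels = names(outcomes),
      seed = seed, phi = phi, b_boot = b_boot,
      simex_threshold = simex_threshold,
      drop_palindromic = drop_palindromic,
      exclude_rsids = exclude_rsids,
      version = as.character(utils::packageVersion("mrbattery")))),
    class = "mr_battery")
}

.battery_rows <- function(arm, arm_name) {
  do.call(rbind, lapply(names(arm), function(oc) {
    r <- arm[[oc]]
    if (!is.null(r$error)) {
      return(data.frame(arm = arm_name, outcome = oc, method = NA,
                        beta_or_OR = NA, ci_lower = NA, ci_upper = NA,
                        p = NA, se = NA, n_snps = NA, scale = NA,
                        direction = NA, error = r$error,
                        stringsAsFactors = FALSE))
    }
    es <- c(r$estimates, list(egger_intercept = r$egger_intercept))
    if (!is.null(r$simex)) {
      es <- c(es, list(simex_egger = r$simex$slope,
                       simex_egger_intercept = r$simex$intercept))
    }
    if (!is.null(r$allele_score)) es <- c(es, list(allele_score = r$allele_score))
    tab <- estimates_table(es)
    cbind(data.frame(arm = arm_name, outcome = oc,
                     stringsAsFactors = FALSE), tab, error = "")
  }))
}

#' @export
summary.mr_battery <- function(object, ...) {
  out <- .battery_rows(object$outcomes, "main")
  if (!is.null(object$exclusion_arm)) {
    out <- rbind(out, .battery_rows(object$exclusion_arm, "exclusion"))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.mr_battery <- function(x, digits = 3, ...) {
  p <- x$provenance
  cat(sprintf("MR battery: exposure %s (%d SNPs) on %d outcome(s), seed %d\n",
              p$exposure_label, p$n_exposure_snps,
              length(p$outcome_labels), p$seed))
  tab <- summary(x)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  for (oc in names(x$outcomes)) {
    r <- x$outcomes[[oc]]
    if (is.null(r$error)) {
      d <- r$diagnostics
      cat(sprintf("%s: L=%d, Q=%.2f (p=%.3g), I2GX=%.3f, mean F=%.1f%s\n",
                  oc, d$l, d$q, d$q_pvalue, d$i2_gx, d$mean_f,
                  if (!is.null(r$simex)) " [SIMEX applied]" else ""))
    } else {
      cat(sprintf("%s: FAILED (%s)\n", oc, r$error))
    }
  }
  invisible(x)
}

#' @export
coef.mr_battery <- function(object, ...) {
  tab <- .battery_rows(object$outcomes, "main")
  tab <- tab[tab$error == "", , drop = FALSE]
  methods <- unique(tab$method)
  out <- sapply(methods, function(m) {
    stats::setNames(tab$beta_or_OR[tab$method == m], tab$outcome[tab$method == m])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(unique(tab$outcome), methods))
  out
}

#' Write battery results as delimited tables and a JSON sidecar
#'
#' Emits `table2.tsv` (causal-effect estimates per outcome and method),
#' `table3.tsv` (Egger and SIMEX-Egger intercepts), `diagnostics.tsv`,
#' `radial.tsv`, `loo.tsv` and `result.json`. Table cells are rounded to 3
#' decimals; `result.json` keeps full precision.
#'
#' @param x an `mr_battery`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_battery <- function(x, dir) {
  stopifnot(inherits(x, "mr_battery"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- summary(x)
  rnd <- function(d) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], round, 3)
    d
  }
  wt <- function(d, f) utils::write.table(rnd(d), file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  is_int <- grepl("intercept", tab$method)
  wt(tab[!is_int | is.na(tab$method), , drop = FALSE], "table2.tsv")
  wt(tab[is_int & !is.na(tab$method), , drop = FALSE], "table3.tsv")

  diag_rows <- do.call(rbind, lapply(names(x$outcomes), function(oc) {
    r <- x$outcomes[[oc]]
    if (!is.null(r$error)) return(NULL)
    d <- r$diagnostics
    data.frame(outcome = oc, l = d$l, mean_f = d$mean_f, i2_gx = d$i2_gx,
               i2_gx_weighted = d$i2_gx_weighted, q = d$q, q_df = d$q_df,
               q_pvalue = d$q_pvalue, stringsAsFactors = FALSE)
  }))
  wt(diag_rows, "diagnostics.tsv")

  radial_rows <- do.call(rbind, lapply(names(x$outcomes), function(oc) {
    r <- x$outcomes[[oc]]
    if (!is.null(r$error)) return(NULL)
    cbind(data.frame(outcome = oc, stringsAsFactors = FALSE),
          as.data.frame(r$radial))
  }))
  wt(radial_rows, "radial.tsv")

  loo_rows <- do.call(rbind, lapply(names(x$outcomes), function(oc) {
    r <- x$outcomes[[oc]]
    if (!is.null(r$error)) return(NULL)
    cbind(data.frame(outcome = oc, stringsAsFactors = FALSE),
          as.data.frame(r$loo))
  }))
  wt(loo_rows, "loo.tsv")

  json <- list(provenance = x$provenance, estimates = summary(x),
               diagnostics = diag_rows)
  jsonlite::write_json(json, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
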