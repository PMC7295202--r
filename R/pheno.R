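#' Alcohol-intake frequency coding (most frequent = 1, never = 6)
#' @keywords internal
.alcohol_levels <- c("daily or almost daily" = 1L,
                     "three to four times a week" = 2L,
                     "once or twice a week" = 3L,
                     "one to three times a month" = 4L,
                     "special occasions only" = 5L,
                     "never" = 6L)

#' Derive reproductive life-history outcomes from an individual-level table
#'
#' Applies the outcome recoding rules to a raw participant table:
#' \itemize{
#'   \item age at first sexual intercourse is set missing when reported
#'     younger than age at menarche (the implausible report is taken to be
#'     the debut age; `blank_both = TRUE` blanks both fields instead);
#'   \item age at leaving education is set missing when answered with the
#'     never-attended-school sentinel;
#'   \item number of children and number of sexual partners are set missing
#'     strictly above their within-sample 99.99th percentile
#'     (linear-interpolation quantile; values equal to it are kept);
#'   \item reproductive period = age at last birth - age at first birth, for
#'     participants with more than one child only;
#'   \item childlessness = 1 for zero children;
#'   \item ever smoked = 1 if either smoking question indicates any smoking;
#'     0 only when both deny it; missing otherwise;
#'   \item alcohol intake mapped never = 6 ... daily or almost daily = 1;
#'   \item risk taking yes = 1, no = 0;
#'   \item number of sexual partners kept only for participants who reported
#'     ever having had sex.
#' }
#' Rules produce missingness, never failures.
#'
#' @param t data.frame with (any subset of) columns `age_menarche`,
#'   `age_first_sex`, `age_first_birth`, `age_last_birth`, `n_children`,
#'   `n_sexual_partners`, `age_left_education`, `education_years`,
#'   `alcohol_category`, `smoke_now`, `smoked_past`, `risk_taking`,
#'   `ever_had_sex`.
#' @param never_education_sentinel value of `age_left_education` meaning
#'   "never attended school" (default -2).
#' @param blank_both blank both ages (not just the debut age) when the debut
#'   precedes menarche.
#' @param trim_quantiles optional named list with precomputed `n_children`
#'   and/or `n_sexual_partners` 99.99th-percentile cutoffs, e.g. to reuse
#'   cutoffs across subsets.
#' @return data.frame of derived outcomes (one row per participant):
#'   `age_first_birth`, `age_last_birth`, `reproductive_period`,
#'   `n_children`, `childlessness`, `n_sexual_partners`, `ever_smoked`,
#'   `age_left_education`, `education_years`, `alcohol_intake`,
#'   `risk_taking`, `age_first_sex`.
#' @export
derive_outcomes <- function(t, never_education_sentinel = -2,
                            blank_both = FALSE, trim_quantiles = NULL) {
  stopifnot(is.data.frame(t), nrow(t) > 0L)
  n <- nrow(t)
  get <- function(col) if (col %in% names(t)) t[[col]] else rep(NA, n)

  age_menarche <- as.numeric(get("age_menarche"))
  age_first_sex <- as.numeric(get("age_first_sex"))
  implausible <- !is.na(age_first_sex) & !is.na(age_menarche) &
    age_first_sex < age_menarche
  age_first_sex[implausible] <- NA
  if (blank_both) age_menarche[implausible] <- NA

  age_left_education <- as.numeric(get("age_left_education"))
  age_left_education[!is.na(age_left_education) &
                       age_left_education == never_education_sentinel] <- NA

  trim <- function(x, precomputed) {
    if (all(is.na(x))) return(x)
    q <- if (!is.null(precomputed)) precomputed
         else stats::quantile(x, 0.9999, na.rm = TRUE, names = FALSE, type = 7)
    x[!is.na(x) & x > q] <- NA
    x
  }
  n_children <- trim(as.numeric(get("n_children")), trim_quantiles$n_children)
  n_partners <- as.numeric(get("n_sexual_partners"))
  ever_sex <- get("ever_had_sex")
  n_partners[is.na(ever_sex) | ever_sex != 1] <- NA
  n_partners <- trim(n_partners, trim_quantiles$n_sexual_partners)

  age_first_birth <- as.numeric(get("age_first_birth"))
  age_last_birth <- as.numeric(get("age_last_birth"))
  reproductive_period <- ifelse(!is.na(n_children) & n_children > 1,
                                age_last_birth - age_first_birth, NA_real_)
  childlessness <- ifelse(is.na(n_children), NA_real_,
                          as.numeric(n_children == 0))

  deny <- function(x) !is.na(x) & tolower(as.character(x)) %in% c("never", "no")
  affirm <- function(x) !is.na(x) & !deny(x)
  now <- get("smoke_now"); past <- get("smoked_past")
  ever_smoked <- ifelse(affirm(now) | affirm(past), 1,
                        ifelse(deny(now) & deny(past), 0, NA_real_))

  alc <- tolower(trimws(as.character(get("alcohol_category"))))
  alcohol_intake <- unname(.alcohol_levels[alc])

  rt <- tolower(trimws(as.character(get("risk_taking"))))
  risk_taking <- ifelse(rt == "yes", 1, ifelse(rt == "no", 0, NA_real_))

  data.frame(age_first_birth = age_first_birth,
             age_last_birth = age_last_birth,
             reproductive_period = reproductive_period,
             n_children = n_children,
             childlessness = childlessness,
             n_sexual_partners = n_partners,
             ever_smoked = ever_smoked,
             age_left_education = age_left_education,
             education_years = as.numeric(get("education_years")),
             alcohol_intake = as.numeric(alcohol_intake),
             risk_taking = risk_taking,
             age_first_sex = age_first_sex)
}

#' Covariate-adjusted per-SNP outcome associations
#'
#' Regresses a derived outcome on each SNP's dosage (additive, 0/1/2 copies
#' of the effect allele) adjusting for birth year and the top 10 genetic
#' principal components (plus genotype array when `adjust_array`). Continuous
#' outcomes use a linear model; binary outcomes a logistic model, so the
#' reported beta is the log odds ratio per effect allele. Fits are
#' complete-case per outcome; the contributing sample size is recorded per
#' SNP. A logistic fit showing separation is kept as a flagged record with
#' missing beta.
#'
#' @param t individual-level data.frame with dosage columns named by rsid,
#'   `birth_year`, `pc1`..`pc10` and optionally `array`. SNP allele labels
#'   are taken from `snp_info` (or `attr(t, "snp_info")`): a data.frame with
#'   `rsid`, `effect_allele`, `other_allele`.
#' @param d derived outcomes from [derive_outcomes()] (or any data.frame
#'   holding the outcome column), row-aligned with `t`.
#' @param outcome name of the outcome column in `d`.
#' @param adjust_array additionally adjust for genotype array.
#' @param snp_info SNP allele annotation; defaults to `attr(t, "snp_info")`.
#' @param outcome_type `"auto"` (default: binary iff the non-missing values
#'   are all 0/1), `"continuous"` or `"binary"`.
#' @return An `association_set` of SNP-outcome associations with a
#'   `fit_flag` column (`""` or `"separation"`).
#' @export
snp_outcome_assoc <- function(t, d, outcome, adjust_array = FALSE,
                              snp_info = attr(t, "snp_info"),
                              outcome_type = c("auto", "continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(is.data.frame(t), is.data.frame(d), nrow(t) == nrow(d))
  if (is.null(snp_info)) stop("snp_info annotation is required (rsid + alleles)")
  rsids <- snp_info$rsid
  missing_snps <- setdiff(rsids, names(t))
  if (length(missing_snps) > 0L) {
    stop("dosage column(s) missing: ", paste(missing_snps, collapse = ", "))
  }
  if (!outcome %in% names(d)) stop("outcome column not found: ", outcome)
  y <- d[[outcome]]
  vals <- unique(y[!is.na(y)])
  if (length(vals) < 2L) stop("outcome has fewer than 2 distinct non-missing values")
  binary <- switch(outcome_type,
                   auto = all(vals %in% c(0, 1)),
                   continuous = FALSE,
                   binary = TRUE)
  if (binary && length(setdiff(vals, c(0, 1))) > 0L) {
    stop("binary outcome must be coded 0/1")
  }

  covars <- c("birth_year", paste0("pc", 1:10),
              if (adjust_array) "array")
  missing_cov <- setdiff(covars, names(t))
  if (length(missing_cov) > 0L) {
    stop("covariate column(s) missing: ", paste(missing_cov, collapse = ", "))
  }

  rows <- lapply(rsids, function(rs) {
    df <- data.frame(y = y, g = t[[rs]], t[covars])
    df <- df[stats::complete.cases(df), , drop = FALSE]
    flag <- ""
    if (binary) {
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial()))
      est <- summary(fit)$coefficients["g", ]
      fitted_extreme <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
      if (!fit$converged || (fitted_extreme && est[["Std. Error"]] > 100)) {
        est[] <- NA_real_
        flag <- "separation"
      }
      p <- if (flag == "") 2 * stats::pnorm(abs(est[["Estimate"]] / est[["Std. Error"]]),
                                            lower.tail = FALSE) else NA_real_
    } else {
      fit <- stats::lm(y ~ ., data = df)
      est <- summary(fit)$coefficients["g", ]
      p <- est[["Pr(>|t|)"]]
    }
    data.frame(rsid = rs, beta = est[["Estimate"]], se = est[["Std. Error"]],
               pvalue = p, n = nrow(df), eaf = mean(df$g) / 2,
               fit_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$effect_allele <- snp_info$effect_allele[match(out$rsid, snp_info$rsid)]
  out$other_allele <- snp_info$other_allele[match(out$rsid, snp_info$rsid)]
  association_set(out, trait_label = outcome,
                  trait_type = if (binary) "binary" else "continuous",
                  validate = FALSE)
}
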