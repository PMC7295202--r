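#' Configuration of the generative model
#'
#' The generator emulates the statistical structure of a two-sample MR study
#' of reproductive life-history traits: independent biallelic instruments
#' drawn at realistic minor-allele frequencies, per-allele effects jointly
#' explaining a target fraction of exposure variance, an unobserved
#' confounder loading on exposure and outcome, a configurable causal effect,
#' and configurable pleiotropy and exposure-side measurement-error regimes.
#' Defaults mirror the main study arm being emulated: 116 instruments
#' explaining ~3% of exposure variance, a discovery GWAS of ~182,000 and an
#' outcome sample of ~120,000, non-overlapping.
#'
#' @param n_snps number of independent instruments.
#' @param maf_range interval in (0, 0.5] for effect-allele frequencies.
#' @param target_r2 fraction of exposure variance jointly explained by the
#'   instruments (exposure variance is normalized to 1).
#' @param beta_causal true causal effect (outcome units per unit exposure;
#'   log-odds per unit for binary outcomes).
#' @param confounder_effect_x,confounder_effect_y loadings of a shared
#'   standard-normal confounder on exposure and outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects),
#'   `"directional"` (mean `pleiotropy_mean`) or `"inside_violating"`
#'   (direct effects correlated with instrument strength, breaking InSIDE).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of per-SNP direct effects
#'   on the outcome.
#' @param inside_cor correlation between direct effects and instrument
#'   effects in the `inside_violating` mode.
#' @param nome_error_sd extra sampling error on the SNP-exposure estimates
#'   (reflected in their reported standard errors); inflating it relative to
#'   the spread of the true instrument effects degrades I2GX and dilutes the
#'   Egger slope.
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes behind the
#'   exposure and outcome standard errors (two distinct, non-overlapping
#'   samples).
#' @param n_individual participants generated by [simulate_individual()].
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param prevalence outcome prevalence for binary outcomes.
#' @param randomize_alleles randomize allele labels (including swapped,
#'   strand-complemented and palindromic representations) in
#'   [simulate_summary()] to exercise harmonization.
#' @param birth_year_effect_y,pc1_effect_y loadings of birth year (scaled)
#'   and the first principal component on the outcome; combined with
#'   `struct_effect` they create confounding that covariate adjustment
#'   removes.
#' @param struct_effect strength of a latent population-structure score that
#'   tilts genotype frequencies and loads on birth year and PC1.
#' @param seed integer seed; all randomness flows from it through a named
#'   stream splitter so each operation is reproducible in isolation.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 116, maf_range = c(0.1, 0.5), target_r2 = 0.03,
                       beta_causal = 0, confounder_effect_x = 0.3,
                       confounder_effect_y = 0.3,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violating"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                       inside_cor = 0.5, nome_error_sd = 0,
                       n_exposure_sample = 182416, n_outcome_sample = 120000,
                       n_individual = 10000,
                       outcome_type = c("continuous", "binary"),
                       prevalence = 0.4, randomize_alleles = FALSE,
                       birth_year_effect_y = 0, pc1_effect_y = 0,
                       struct_effect = 0, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            target_r2 > 0, target_r2 < 1,
            pleiotropy_sd >= 0, nome_error_sd >= 0,
            n_exposure_sample > 1, n_outcome_sample > 1,
            prevalence > 0, prevalence < 1,
            abs(inside_cor) <= 1)
  noise_var <- 1 - target_r2 - confounder_effect_x^2
  if (noise_var <= 0) {
    stop("infeasible config: target_r2 + confounder_effect_x^2 must be < 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

# deterministic sub-seed for a named random stream, kept below 2^31 - 1
#' @keywords internal
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587 + 1)
}

# instrument frequencies and per-allele effects scaled so the instruments
# jointly explain exactly target_r2 of the (unit) exposure variance
.draw_instruments <- function(cfg) {
  with_seed(split_seed(cfg$seed, "instruments"), {
    maf <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    # effect magnitudes from a half-normal truncated away from zero:
    # instruments are genome-wide significant by construction, so no
    # instrument has an effect indistinguishable from noise
    mag <- stats::qnorm(stats::runif(cfg$n_snps, stats::pnorm(0.25), 1))
    raw <- mag * sample(c(-1, 1), cfg$n_snps, replace = TRUE)
    scale <- sqrt(cfg$target_r2 / sum(2 * maf * (1 - maf) * raw^2))
    gamma <- raw * scale
    # direct (pleiotropic) effects are defined on the exposure-increasing
    # allele, so a directional mean survives orientation; stored on the
    # recorded effect allele via the sign of gamma
    alpha_inc <- switch(cfg$pleiotropy_mode,
      none = rep(0, cfg$n_snps),
      balanced = stats::rnorm(cfg$n_snps, 0, cfg$pleiotropy_sd),
      directional = stats::rnorm(cfg$n_snps, cfg$pleiotropy_mean,
                                 cfg$pleiotropy_sd),
      inside_violating = {
        z <- stats::rnorm(cfg$n_snps)
        std_str <- (abs(gamma) - mean(abs(gamma))) / stats::sd(abs(gamma))
        cfg$pleiotropy_mean + cfg$pleiotropy_sd *
          (cfg$inside_cor * std_str + sqrt(1 - cfg$inside_cor^2) * z)
      })
    alpha <- sign(gamma) * alpha_inc
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("A", "T"), c("C", "G"))
    idx <- sample.int(6, cfg$n_snps, replace = TRUE,
                      prob = c(0.225, 0.225, 0.225, 0.225, 0.05, 0.05))
    data.frame(rsid = sprintf("rs%07d", seq_len(cfg$n_snps)),
               effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2],
               maf = maf, gamma = gamma, alpha = alpha,
               stringsAsFactors = FALSE)
  })
}

#' Simulate an individual-level cohort
#'
#' Draws genotypes as binomial(2, maf) dosages (optionally tilted by a latent
#' population-structure score), a standard-normal confounder, the exposure as
#' the sum of instrument effects, confounder loading and noise (unit total
#' variance), and the outcome as causal effect times exposure plus
#' confounding, per-SNP direct (pleiotropic) effects and noise; binary
#' outcomes through a logistic link at the configured prevalence. Birth year
#' and 10 principal components are generated, with optional loadings on the
#' outcome so that covariate adjustment becomes consequential.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with dosage columns named by rsid, `birth_year`,
#'   `pc1`..`pc10`, `array`, `confounder`, `exposure`, `outcome`; SNP
#'   annotation in `attr(, "snp_info")` (rsid, alleles, maf, true `gamma`
#'   and `alpha`).
#' @export
simulate_individual <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  info <- .draw_instruments(cfg)
  n <- cfg$n_individual
  with_seed(split_seed(cfg$seed, "individual"), {
    struct <- stats::rnorm(n)
    G <- vapply(seq_len(cfg$n_snps), function(j) {
      p <- stats::plogis(stats::qlogis(info$maf[j]) + cfg$struct_effect * struct)
      stats::rbinom(n, 2L, p)
    }, numeric(n))
    colnames(G) <- info$rsid
    u <- stats::rnorm(n)
    g_centered <- sweep(G, 2, 2 * info$maf)
    x <- drop(g_centered %*% info$gamma) + cfg$confounder_effect_x * u +
      stats::rnorm(n, 0, sqrt(cfg$noise_var))
    birth_year <- round(stats::runif(n, 1939, 1970)) + 2 * cfg$struct_effect * struct
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    pcs[, 1] <- pcs[, 1] + cfg$struct_effect * struct
    by_scaled <- (birth_year - 1955) / 10
    eta <- cfg$beta_causal * x + cfg$confounder_effect_y * u +
      drop(G %*% info$alpha) +
      cfg$birth_year_effect_y * by_scaled + cfg$pc1_effect_y * pcs[, 1]
    y <- if (cfg$outcome_type == "binary") {
      stats::rbinom(n, 1L, stats::plogis(stats::qlogis(cfg$prevalence) + eta))
    } else {
      eta + stats::rnorm(n)
    }
    out <- data.frame(G, birth_year = birth_year, pcs,
                      array = stats::rbinom(n, 1L, 0.3),
                      confounder = u, exposure = x, outcome = y,
                      check.names = FALSE)
    attr(out, "snp_info") <- info
    out
  })
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates the SNP-exposure and SNP-outcome association sets directly:
#' `beta_x_j ~ N(gamma_j, se_x_j^2 + nome_error_sd^2)` with reported
#' `se_x_j` derived from the exposure GWAS sample size and allele frequency
#' (`se = 1/sqrt(2 maf (1-maf) n)` for a unit-variance trait), and
#' `beta_y_j ~ N(beta_causal * gamma_j + alpha_j, se_y_j^2)` with `se_y_j`
#' from the outcome sample (logistic information at the configured prevalence
#' for binary outcomes). Draws are independent across the two sides — the
#' two-sample, non-overlapping design. With `randomize_alleles` the outcome
#' records are re-expressed under random allele representations (swapped,
#' strand-complemented, occasionally palindromic) to exercise harmonization.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `exposure` and `outcome` (both
#'   `association_set`s) and `truth` (the instrument table with true
#'   `gamma` and `alpha`).
#' @export
simulate_summary <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  info <- .draw_instruments(cfg)
  with_seed(split_seed(cfg$seed, "summary"), {
    het <- 2 * info$maf * (1 - info$maf)
    # nome_error_sd inflates the SNP-exposure sampling error (and its
    # reported SE): the NOME-violating regime that degrades I2GX
    se_x <- sqrt(1 / (het * cfg$n_exposure_sample) + cfg$nome_error_sd^2)
    se_y <- if (cfg$outcome_type == "binary") {
      1 / sqrt(het * cfg$n_outcome_sample * cfg$prevalence * (1 - cfg$prevalence))
    } else {
      1 / sqrt(het * cfg$n_outcome_sample)
    }
    beta_x <- stats::rnorm(cfg$n_snps, info$gamma, se_x)
    beta_y <- stats::rnorm(cfg$n_snps,
                           cfg$beta_causal * info$gamma + info$alpha, se_y)
    exp_df <- data.frame(rsid = info$rsid,
                         effect_allele = info$effect_allele,
                         other_allele = info$other_allele,
                         beta = beta_x, se = se_x,
                         pvalue = 2 * stats::pnorm(abs(beta_x / se_x),
                                                   lower.tail = FALSE),
                         eaf = info$maf, n = cfg$n_exposure_sample,
                         stringsAsFactors = FALSE)
    out_df <- exp_df
    out_df$beta <- beta_y
    out_df$se <- se_y
    out_df$pvalue <- 2 * stats::pnorm(abs(beta_y / se_y), lower.tail = FALSE)
    out_df$n <- cfg$n_outcome_sample

    if (cfg$randomize_alleles) {
      comp <- function(a) chartr("ACGT", "TGCA", a)
      pal <- out_df$effect_allele == comp(out_df$other_allele)
      # representation: 1 same, 2 swapped, 3 complement, 4 complement+swapped
      rep_kind <- sample.int(4, cfg$n_snps, replace = TRUE)
      rep_kind[pal] <- sample.int(2, sum(pal), replace = TRUE)
      swap <- rep_kind %in% c(2, 4)
      strand <- rep_kind %in% c(3, 4)
      ea <- out_df$effect_allele; oa <- out_df$other_allele
      out_df$effect_allele <- ifelse(swap, oa, ea)
      out_df$other_allele <- ifelse(swap, ea, oa)
      out_df$beta <- ifelse(swap, -out_df$beta, out_df$beta)
      out_df$eaf <- ifelse(swap, 1 - out_df$eaf, out_df$eaf)
      out_df$effect_allele <- ifelse(strand, comp(out_df$effect_allele),
                                     out_df$effect_allele)
      out_df$other_allele <- ifelse(strand, comp(out_df$other_allele),
                                    out_df$other_allele)
    }
    list(exposure = association_set(exp_df, "simulated_exposure", "continuous"),
         outcome = association_set(out_df, "simulated_outcome",
                                   cfg$outcome_type),
         truth = info)
  })
}

#' Simulate raw life-history phenotype fields
#'
#' Generates the raw questionnaire-style fields consumed by
#' [derive_outcomes()]: menarche and sexual-debut ages (including a small
#' fraction of implausible debut-before-menarche reports), birth ages and
#' child counts with rare extreme values, partner counts, education fields
#' with a never-attended sentinel, alcohol-frequency labels, the two smoking
#' questions and the risk-taking item. Purely synthetic; magnitudes chosen
#' to resemble a middle-aged population cohort.
#'
#' @param n participants.
#' @param seed integer seed.
#' @param never_education_sentinel sentinel for "never attended school".
#' @return data.frame of raw phenotype fields.
#' @export
simulate_raw_phenotypes <- function(n, seed = 1L,
                                    never_education_sentinel = -2) {
  with_seed(split_seed(seed, "raw_pheno"), {
    age_menarche <- round(stats::rnorm(n, 13, 1.5))
    ever_sex <- stats::rbinom(n, 1L, 0.96)
    age_first_sex <- round(stats::rnorm(n, 18, 3))
    age_first_sex[ever_sex == 0] <- NA
    n_children <- stats::rpois(n, 1.8)
    extreme <- stats::runif(n) < 5e-4
    n_children[extreme] <- n_children[extreme] + stats::rpois(sum(extreme), 15)
    age_first_birth <- round(stats::rnorm(n, 25, 4))
    age_first_birth[n_children == 0] <- NA
    spacing <- stats::rgamma(n, shape = 2, rate = 0.5) * pmax(n_children - 1, 0)
    age_last_birth <- round(age_first_birth + spacing)
    age_last_birth[n_children == 0] <- NA
    n_partners <- pmax(1, round(stats::rlnorm(n, 1.2, 0.9)))
    big <- stats::runif(n) < 5e-4
    n_partners[big] <- n_partners[big] + round(stats::rlnorm(sum(big), 5, 0.5))
    n_partners[ever_sex == 0] <- NA
    age_left_education <- round(stats::runif(n, 14, 25))
    age_left_education[stats::runif(n) < 0.002] <- never_education_sentinel
    education_years <- pmax(0, age_left_education - 5)
    education_years[age_left_education == never_education_sentinel] <- 0
    alcohol <- sample(names(.alcohol_levels), n, replace = TRUE)
    smoke_now <- sample(c("no", "yes on most or all days", "only occasionally"),
                        n, replace = TRUE, prob = c(0.8, 0.12, 0.08))
    smoked_past <- sample(c("never", "smoked occasionally", "smoked most days"),
                          n, replace = TRUE, prob = c(0.55, 0.25, 0.2))
    risk_taking <- sample(c("yes", "no", NA), n, replace = TRUE,
                          prob = c(0.25, 0.72, 0.03))
    data.frame(age_menarche = age_menarche, age_first_sex = age_first_sex,
               ever_had_sex = ever_sex, n_children = n_children,
               age_first_birth = age_first_birth,
               age_last_birth = age_last_birth,
               n_sexual_partners = n_partners,
               age_left_education = age_left_education,
               education_years = education_years,
               alcohol_category = alcohol, smoke_now = smoke_now,
               smoked_past = smoked_past, risk_taking = risk_taking,
               stringsAsFactors = FALSE)
  })
}
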