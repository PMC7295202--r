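#' Harmonize exposure and outcome association sets to a common effect allele
#'
#' Matches variants by rsid and aligns the outcome record of each SNP to the
#' exposure's effect allele, so that `beta_x` and `beta_y` refer to the same
#' allele. Outcome records whose effect/other alleles are swapped relative to
#' the exposure have `beta_y` negated (and `eaf` reflected); alleles that match
#' neither directly nor swapped are tried on the complementary strand
#' (A<->T, C<->G) before being dropped. Palindromic (A/T or C/G) variants are
#' flagged and, optionally, dropped: for these the strand cannot be inferred
#' from the allele labels alone. Every dropped SNP is accounted for in the
#' drop report (`attr(, "drop_report")`, reasons `absent_in_outcome`,
#' `allele_mismatch`, `palindromic_dropped`).
#'
#' @param exposure,outcome `association_set` objects for the exposure and the
#'   outcome trait.
#' @param drop_palindromic drop A/T and C/G variants instead of keeping them
#'   flagged (default `FALSE`: both data sets drawn from one cohort share a
#'   strand convention, making palindromes unambiguous).
#' @param orient_beta_x_positive re-express each pair on the allele for which
#'   the exposure effect is positive (the trait-increasing allele). This is
#'   mathematically neutral for every estimator but makes Egger regression
#'   output and diagnostic plots comparable across instruments. Default `TRUE`.
#' @return An object of class `harmonized_set`: a data.frame with columns
#'   `rsid`, `effect_allele`, `other_allele`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`, `palindromic`, plus attributes `exposure_label`, `outcome_label`,
#'   `outcome_type`, `drop_report` and `complement_resolved`.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = FALSE,
                      orient_beta_x_positive = TRUE) {
  stopifnot(inherits(exposure, "association_set"),
            inherits(outcome, "association_set"))
  drops <- data.frame(rsid = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  add_drop <- function(rsid, reason) {
    if (length(rsid) > 0L) {
      drops <<- rbind(drops, data.frame(rsid = rsid, reason = reason,
                                        stringsAsFactors = FALSE))
    }
  }

  absent <- setdiff(exposure$rsid, outcome$rsid)
  add_drop(absent, "absent_in_outcome")
  common <- exposure$rsid[exposure$rsid %in% outcome$rsid]
  ex <- exposure[match(common, exposure$rsid), , drop = FALSE]
  ou <- outcome[match(common, outcome$rsid), , drop = FALSE]

  comp <- function(a) chartr("ACGT", "TGCA", a)
  same    <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele  & ou$other_allele == ex$effect_allele
  csame    <- !same & !swapped &
    comp(ou$effect_allele) == ex$effect_allele & comp(ou$other_allele) == ex$other_allele
  cswapped <- !same & !swapped &
    comp(ou$effect_allele) == ex$other_allele & comp(ou$other_allele) == ex$effect_allele
  palindromic <- ex$effect_allele == comp(ex$other_allele)

  reconciled <- same | swapped | csame | cswapped
  add_drop(common[!reconciled], "allele_mismatch")

  flip <- swapped | (cswapped & !palindromic)
  keep <- reconciled
  if (drop_palindromic) {
    add_drop(common[keep & palindromic], "palindromic_dropped")
    keep <- keep & !palindromic
  }
  if (!any(keep)) stop("no SNPs survive harmonization")

  h <- data.frame(
    rsid = common[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = ifelse(flip[keep], -ou$beta[keep], ou$beta[keep]),
    se_y = ou$se[keep],
    palindromic = palindromic[keep],
    stringsAsFactors = FALSE
  )
  if (orient_beta_x_positive) {
    neg <- h$beta_x < 0
    h$beta_x[neg] <- -h$beta_x[neg]
    h$beta_y[neg] <- -h$beta_y[neg]
    ea <- h$effect_allele[neg]
    h$effect_allele[neg] <- h$other_allele[neg]
    h$other_allele[neg] <- ea
  }
  rownames(h) <- NULL
  structure(h,
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            outcome_type = attr(outcome, "trait_type"),
            drop_report = drops,
            complement_resolved = common[csame | cswapped],
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set directly from aligned coefficients
#'
#' Convenience constructor used when exposure and outcome associations are
#' already aligned to a common effect allele (e.g. simulated coefficients).
#'
#' @param beta_x,se_x,beta_y,se_y aligned SNP-exposure and SNP-outcome
#'   estimates and standard errors.
#' @param rsid optional identifiers (defaults to `snp_1 ... snp_L`).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @inheritParams harmonize
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y, rsid = NULL,
                           outcome_type = c("continuous", "binary"),
                           orient_beta_x_positive = TRUE) {
  outcome_type <- match.arg(outcome_type)
  L <- length(beta_x)
  stopifnot(L >= 1L, length(se_x) == L, length(beta_y) == L, length(se_y) == L,
            all(se_x > 0), all(se_y > 0))
  if (is.null(rsid)) rsid <- sprintf("snp_%d", seq_len(L))
  h <- data.frame(rsid = as.character(rsid),
                  effect_allele = rep("A", L), other_allele = rep("G", L),
                  beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
                  beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                  palindromic = FALSE, stringsAsFactors = FALSE)
  if (orient_beta_x_positive) {
    neg <- h$beta_x < 0
    h$beta_x[neg] <- -h$beta_x[neg]
    h$beta_y[neg] <- -h$beta_y[neg]
  }
  structure(h, exposure_label = "exposure", outcome_label = "outcome",
            outcome_type = outcome_type,
            drop_report = data.frame(rsid = character(0), reason = character(0)),
            complement_resolved = character(0),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s (%s outcome), L = %d SNP(s)\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              attr(x, "outcome_type"), nrow(x)))
  dr <- attr(x, "drop_report")
  if (nrow(dr) > 0L) {
    tab <- table(dr$reason)
    cat("  dropped:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Write the harmonization drop report
#'
#' @param h a `harmonized_set`.
#' @param path output TSV path (columns `rsid`, `reason`).
#' @export
write_drop_report <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  utils::write.table(attr(h, "drop_report"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
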