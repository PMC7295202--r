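#' Per-SNP association sets for one trait
#'
#' An association set holds, for one trait, per-variant effect estimates from
#' a GWAS: rsid, effect allele, other allele, beta, standard error, and
#' optionally the p-value, effect-allele frequency and contributing sample
#' size. It is the container for both edges of the instrumental-variable
#' triangle: the SNP-exposure associations and the SNP-outcome associations.
#'
#' @param data data.frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, and optionally `pvalue`, `eaf`, `n`. Extra columns (e.g.
#'   chromosome/position) are carried along but never used for matching.
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"` (binary traits carry betas
#'   on the log-odds scale).
#' @param validate if `TRUE` (default) rows violating the record invariants
#'   are dropped with a per-row report attached as `attr(, "validation_log")`.
#' @return An object of class `association_set`: a data.frame with attributes
#'   `trait_label` and `trait_type`.
#' @export
association_set <- function(data, trait_label = "trait",
                            trait_type = c("continuous", "binary"),
                            validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$rsid <- as.character(data$rsid)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in intersect(c("beta", "se", "pvalue", "eaf", "n"), names(data))) {
    data[[col]] <- as.numeric(data[[col]])
  }

  log <- character(0)
  if (validate) {
    bad <- .validate_rows(data)
    if (any(bad != "")) {
      idx <- which(bad != "")
      log <- sprintf("row %d (%s): %s", idx, data$rsid[idx], bad[idx])
      data <- data[bad == "", , drop = FALSE]
    }
  }
  dup <- unique(data$rsid[duplicated(data$rsid)])
  if (length(dup) > 0L) {
    stop("duplicate rsid in association set: ", paste(dup, collapse = ", "))
  }
  rownames(data) <- NULL
  structure(data,
            trait_label = trait_label, trait_type = trait_type,
            validation_log = log,
            class = c("association_set", "data.frame"))
}

.valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")

.validate_rows <- function(data) {
  reasons <- character(nrow(data))
  add <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    ifelse(bad, ifelse(reasons == "", msg, paste(reasons, msg, sep = "; ")), reasons)
  }
  reasons <- add(is.na(data$rsid) | data$rsid == "", "missing rsid")
  reasons <- add(!.valid_allele(data$effect_allele), "invalid effect_allele")
  reasons <- add(!.valid_allele(data$other_allele), "invalid other_allele")
  same <- .valid_allele(data$effect_allele) & .valid_allele(data$other_allele) &
    data$effect_allele == data$other_allele
  reasons <- add(same, "effect_allele equals other_allele")
  reasons <- add(!is.finite(data$beta), "non-finite beta")
  reasons <- add(!is.finite(data$se) | data$se <= 0, "se not > 0")
  if ("pvalue" %in% names(data)) {
    p <- data$pvalue
    reasons <- add(!is.na(p) & (p < 0 | p > 1), "pvalue outside [0,1]")
  }
  if ("eaf" %in% names(data)) {
    f <- data$eaf
    reasons <- add(!is.na(f) & (f < 0 | f > 1), "eaf outside [0,1]")
  }
  reasons
}

#' Read per-SNP associations from a delimited text file
#'
#' Reads a TSV/CSV of GWAS summary statistics with a header row. Column names
#' can be remapped via `column_map`; `'.'` and empty fields are treated as
#' missing. Rows failing type or invariant checks (non-positive SE, invalid
#' alleles, p or EAF outside the unit interval) are rejected and reported in
#' the validation log; a duplicated rsid is an error.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`,
#'   `n`) to the file's column names, e.g. `c(pvalue = "pval")`. Canonical
#'   names already present in the file need not be mapped.
#' @param sep field separator; `NULL` (default) picks `\t` for `.tsv`/`.txt`
#'   and `,` for `.csv`.
#' @inheritParams association_set
#' @return An `association_set`.
#' @export
read_associations <- function(path, column_map = NULL, sep = NULL,
                              trait_label = NULL,
                              trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ".", ""),
                           check.names = FALSE, quote = "\"", comment.char = "")
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0L) {
      stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  if (is.null(trait_label)) {
    trait_label <- sub("\\.[^.]*$", "", basename(path))
  }
  association_set(raw, trait_label = trait_label, trait_type = trait_type)
}

#' Retain genome-wide-significant instruments
#'
#' Keeps the records whose p-value is strictly below `p_threshold` (default
#' the conventional genome-wide significance level 5e-8), preserving order.
#'
#' @param s an `association_set` in which every record has a p-value.
#' @param p_threshold strict upper bound on the instrument p-value.
#' @return The filtered `association_set`; an error if no record survives.
#' @export
filter_instruments <- function(s, p_threshold = 5e-8) {
  stopifnot(inherits(s, "association_set"))
  if (!"pvalue" %in% names(s) || anyNA(s$pvalue)) {
    stop("filter_instruments requires a pvalue for every record")
  }
  keep <- s$pvalue < p_threshold
  if (!any(keep)) stop("no instrument: all p-values at or above ", p_threshold)
  .subset_set(s, keep)
}

#' Remove listed variants from an association set
#'
#' Drops the given rsids (e.g. variants independently associated with a
#' suspected pleiotropic pathway such as body mass index). rsids not present
#' are ignored with a warning; the number removed is recorded in
#' `attr(, "n_excluded")`.
#'
#' @param s an `association_set`.
#' @param rsids character vector of variant identifiers to remove.
#' @return The reduced `association_set`.
#' @export
exclude_snps <- function(s, rsids) {
  stopifnot(inherits(s, "association_set"))
  if (length(rsids) == 0L) return(s)
  unknown <- setdiff(rsids, s$rsid)
  if (length(unknown) > 0L) {
    warning("rsid(s) not present, ignored: ", paste(unknown, collapse = ", "))
  }
  keep <- !(s$rsid %in% rsids)
  out <- .subset_set(s, keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

.subset_set <- function(s, keep) {
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("trait_label", "trait_type")] <-
    attributes(s)[c("trait_label", "trait_type")]
  class(out) <- class(s)
  out
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("Association set: %s (%s), %d variant(s)\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  log <- attr(x, "validation_log")
  if (length(log) > 0L) cat(sprintf("  %d row(s) rejected on input\n", length(log)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
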