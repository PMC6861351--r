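# Participant-level quality control and smoking-history derivation.

#' Pack-years of smoking
#'
#' Lifetime dose: cigarettes per day divided by 20 (one pack), multiplied by
#' the total years of smoking.
#'
#' @param cigs_per_day,years_smoked Non-negative numerics (vectorized).
#' @return `cigs_per_day / 20 * years_smoked`.
#' @export
compute_pack_years <- function(cigs_per_day, years_smoked) {
  if (any(cigs_per_day < 0, na.rm = TRUE) ||
      any(years_smoked < 0, na.rm = TRUE)) {
    stop("cigs_per_day and years_smoked must be non-negative")
  }
  cigs_per_day / 20 * years_smoked
}

#' Years since smoking cessation
#'
#' Current age minus the age at which the participant stopped smoking.
#'
#' @param age,age_stopped Years (vectorized); `age_stopped` must not exceed
#'   `age`.
#' @return `age - age_stopped`.
#' @export
compute_cessation <- function(age, age_stopped) {
  if (any(age < age_stopped, na.rm = TRUE)) {
    stop("age_stopped exceeds age for at least one participant")
  }
  age - age_stopped
}

#' Apply participant exclusions
#'
#' Removes, in order: (1) participants with missing smoking status,
#' (2) participants with missing beta values for any of the predictive CpGs,
#' (3) participants with an extreme outlier beta (outside mean +/- `sd_mult`
#' SD) for one or more CpGs. Outlier moments are computed per CpG on the
#' samples surviving rules 1-2, in a single pass (no re-computation after
#' removals), so the operation is idempotent.
#'
#' @param beta Samples x CpGs numeric matrix, restricted to the candidate
#'   CpGs, with sample-id rownames.
#' @param pheno Phenotype data frame with `sample_id` and `status` columns;
#'   status is missing when `NA` or `"missing"`.
#' @param sd_mult Outlier bound in SD units (default 4).
#' @return List with `beta`, `pheno` (filtered, aligned) and `log`, a data
#'   frame of exclusion counts per rule.
#' @export
apply_exclusions <- function(beta, pheno, sd_mult = 4) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  pheno <- pheno[match(rownames(beta), pheno$sample_id), , drop = FALSE]
  if (anyNA(pheno$sample_id)) {
    stop("phenotype table lacks rows for some samples in the beta matrix")
  }

  miss_status <- is.na(pheno$status) | pheno$status == "missing"
  keep1 <- !miss_status

  miss_beta <- apply(beta, 1, anyNA) & keep1
  keep2 <- keep1 & !miss_beta

  b2 <- beta[keep2, , drop = FALSE]
  mu <- colMeans(b2)
  sdv <- apply(b2, 2, stats::sd)
  lo <- mu - sd_mult * sdv
  hi <- mu + sd_mult * sdv
  out_flag <- rowSums(sweep(b2, 2, lo, "<") | sweep(b2, 2, hi, ">")) > 0
  keep <- rownames(b2)[!out_flag]
  if (length(keep) == 0) stop("no participants remain after exclusions")

  log <- data.frame(
    rule = c("missing_status", "missing_beta", "outlier_beta", "retained"),
    n = c(sum(miss_status), sum(miss_beta), sum(out_flag), length(keep))
  )
  list(
    beta = beta[keep, , drop = FALSE],
    pheno = pheno[match(keep, pheno$sample_id), , drop = FALSE],
    log = log
  )
}

#' Dichotomize a smoking-history quantity
#'
#' Codes `1` when the value is at or above the cutoff (inclusive), `0`
#' otherwise: e.g. cessation time at least 5/10/15 years, or pack-years at
#' least 10/15.
#'
#' @param values Numeric history values (cessation years or pack-years).
#' @param cutoff Inclusive threshold.
#' @return Integer 0/1 vector (`NA` propagated).
#' @export
dichotomize_history <- function(values, cutoff) {
  as.integer(values >= cutoff)
}

#' Five-category life-time smoking code
#'
#' Never smokers are coded 1; former smokers with more than 10 years of
#' cessation 2, with at most 10 years 3; current smokers below the pack-year
#' cutoff 4, at or above it 5. Note the cessation boundary here (`<= 10`
#' codes 3) intentionally differs from the standalone cessation models
#' (where `>= 10` codes 1): both conventions are implemented exactly as
#' defined.
#'
#' @param status Character vector over `current`, `former`, `never`.
#' @param pack_years Pack-years (required for current smokers).
#' @param cessation_years Years since cessation (required for former
#'   smokers).
#' @param py_cutoff Pack-year cutoff, 15 (variant 1) or 10 (variant 2).
#' @return Integer labels in 1..5.
#' @export
code_five_category <- function(status, pack_years, cessation_years,
                               py_cutoff = c(15, 10)) {
  py_cutoff <- match.arg(as.character(py_cutoff[1]), c("15", "10"))
  py_cutoff <- as.numeric(py_cutoff)
  if (!all(status %in% c("current", "former", "never"))) {
    stop("status must be one of current, former, never")
  }
  if (any(status == "current" & is.na(pack_years)) ||
      any(status == "former" & is.na(cessation_years))) {
    stop("missing smoking history for current/former participants")
  }
  ifelse(status == "never", 1L,
    ifelse(status == "former",
      ifelse(cessation_years > 10, 2L, 3L),
      ifelse(pack_years >= py_cutoff, 5L, 4L)
    )
  )
}
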