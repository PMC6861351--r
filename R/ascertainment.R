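# Candidate-marker ascertainment from tabulated EWAS evidence.

#' Select candidate CpGs from EWAS evidence
#'
#' A CpG becomes a candidate marker when it satisfies all three inclusion
#' criteria: (1) reported in at least `min_studies` distinct studies,
#' (2) an absolute beta-value difference of at least `min_abs_delta` between
#' current and never/non-smokers in at least one study, and (3) a consistent
#' direction of effect across every study reporting it. A delta of exactly
#' zero in any study has no direction and therefore fails criterion 3.
#'
#' @param evidence Data frame with columns `cpg_id`, `study_id`,
#'   `delta_beta` (signed current-minus-never beta difference, in `[-1, 1]`),
#'   one row per (CpG, study) pair.
#' @param min_studies Minimum number of distinct reporting studies.
#' @param min_abs_delta Minimum absolute beta difference, required in at
#'   least one study (inclusive bound).
#' @return A data frame of class `candidate_set`, sorted by `cpg_id`, with
#'   columns `cpg_id`, `n_studies`, `max_abs_delta`, `sign`.
#' @export
filter_candidates <- function(evidence, min_studies = 2,
                              min_abs_delta = 0.10) {
  req <- c("cpg_id", "study_id", "delta_beta")
  if (!all(req %in% names(evidence)) || nrow(evidence) == 0) {
    stop("evidence must be a non-empty table with columns ",
         paste(req, collapse = ", "))
  }
  if (anyDuplicated(evidence[, c("cpg_id", "study_id")])) {
    stop("duplicate (cpg_id, study_id) rows in evidence")
  }
  if (any(abs(evidence$delta_beta) > 1)) {
    stop("delta_beta outside [-1, 1]")
  }
  split_ev <- split(evidence, evidence$cpg_id)
  rows <- lapply(split_ev, function(e) {
    keep <- length(unique(e$study_id)) >= min_studies &&
      max(abs(e$delta_beta)) >= min_abs_delta &&
      (all(e$delta_beta > 0) || all(e$delta_beta < 0))
    if (!keep) return(NULL)
    data.frame(
      cpg_id = e$cpg_id[1],
      n_studies = length(unique(e$study_id)),
      max_abs_delta = max(abs(e$delta_beta)),
      sign = if (e$delta_beta[1] > 0) "+" else "-",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cpg_id = character(), n_studies = integer(),
                      max_abs_delta = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$cpg_id, -out$max_abs_delta), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", class(out))
  out
}
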