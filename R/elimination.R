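# Backward marker elimination: refit the current binary model, drop the
# marker with the smallest absolute z-statistic, record the reduced model's
# AUC and the nested likelihood-ratio test against the model one step
# earlier, and repeat down to a single marker. The stopping rule then walks
# the trace and keeps the set in place just before the first significant
# removal.

#' Backward elimination of methylation markers
#'
#' At every step the model on the current marker set is refit, the marker
#' with the minimal absolute z-statistic (coefficient / SE; covariates are
#' never candidates) is removed, the apparent AUC of the reduced model is
#' recorded, and the current and reduced models are compared with a
#' likelihood-ratio test (consecutive nesting). Ties in |z| are broken
#' lexicographically by marker id so the order is a pure function of the
#' data.
#'
#' @param x Samples x markers beta matrix restricted to the candidate CpGs.
#' @param y Binary outcome (current smoker vs other).
#' @param covariates Optional columns always kept in the model.
#' @return Object of class `elimination_trace`: a list with `trace` (data
#'   frame: step, removed, n_remaining, auc, chi_sq, df, p_value),
#'   `candidates` (initial marker set) and `auc_full` (apparent AUC of the
#'   model on all candidates).
#' @export
backward_eliminate <- function(x, y, covariates = NULL) {
  x <- as_design(x)
  if (ncol(x) < 2) stop("need at least 2 candidate markers")
  candidates <- colnames(x)

  fit_set <- function(markers) {
    tryCatch(
      suppressWarnings(fit_binary(x[, markers, drop = FALSE], y, covariates)),
      error = function(e) {
        stop("model fit failed for marker set {",
             paste(markers, collapse = ", "), "}: ", conditionMessage(e))
      }
    )
  }

  current <- candidates
  fit_cur <- fit_set(current)
  auc_full <- roc_auc(predict_prob(fit_cur, x), y)

  steps <- vector("list", length(candidates) - 1)
  k <- 0L
  while (length(current) > 1) {
    zm <- abs(fit_cur$z[current])
    victim <- current[order(zm, current)][1]
    reduced <- setdiff(current, victim)
    fit_red <- fit_set(reduced)
    lrt <- lr_test(fit_cur, fit_red)
    auc <- roc_auc(predict_prob(fit_red, x), y)
    k <- k + 1L
    steps[[k]] <- data.frame(
      step = k, removed = victim, n_remaining = length(reduced),
      auc = auc, chi_sq = lrt$chi_sq, df = lrt$df, p_value = lrt$p_value,
      stringsAsFactors = FALSE
    )
    current <- reduced
    fit_cur <- fit_red
  }
  structure(
    list(trace = do.call(rbind, steps), candidates = candidates,
         auc_full = auc_full),
    class = "elimination_trace"
  )
}

#' Stop backward elimination at the first significant removal
#'
#' Walks the elimination trace in removal order and returns the marker set
#' in place immediately before the first removal whose nested-model test has
#' `p_value < alpha`. If no removal is significant the final single-marker
#' set is returned with a warning.
#'
#' @param trace An [backward_eliminate()] result.
#' @param alpha Significance level of the chi-squared stopping test.
#' @return Character vector of selected marker ids.
#' @export
chisq_stop <- function(trace, alpha = 0.05) {
  stopifnot(inherits(trace, "elimination_trace"))
  tr <- trace$trace
  if (is.null(tr) || nrow(tr) == 0) stop("empty elimination trace")
  hit <- which(tr$p_value < alpha)
  if (length(hit) == 0) {
    warning("no removal reached significance; returning the final ",
            "single-marker set")
    return(setdiff(trace$candidates, tr$removed))
  }
  first <- hit[1]
  setdiff(trace$candidates, tr$removed[seq_len(first - 1)])
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("Backward elimination over %d candidates (full-model AUC %.4f)\n",
              length(x$candidates), x$auc_full))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Cumulative AUC profile of an elimination trace
#'
#' Plots apparent AUC against the number of markers retained in the model,
#' the machine-readable analogue of a cumulative AUC profile.
#'
#' @param x An `elimination_trace`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.elimination_trace <- function(x, ...) {
  n_mark <- c(length(x$candidates), x$trace$n_remaining)
  auc <- c(x$auc_full, x$trace$auc)
  graphics::plot(n_mark, auc, type = "b", pch = 19,
                 xlab = "markers in model", ylab = "apparent AUC", ...)
  invisible(x)
}
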