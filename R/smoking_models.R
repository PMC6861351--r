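# The concrete model suite: binary current-vs-non-smoker, three-category,
# cessation-horizon, pack-year and five-category life-time models, the
# cotinine cut-off rule, and application of a frozen adult model to child
# cohorts.

#' Fixed decision thresholds of the cessation-horizon models
#'
#' The three dichotomous cessation models (at least 5 / 10 / 15 years since
#' quitting) use fixed probability thresholds 0.8733, 0.7650 and 0.6397
#' instead of 0.5. They are treated as given constants and can be overridden
#' per call.
#' @export
CESSATION_THRESHOLDS <- c(`5` = 0.8733, `10` = 0.7650, `15` = 0.6397)

#' Cotinine cut-off smoker call
#'
#' Calls a participant a smoker when plasma cotinine exceeds 50 ng/mL;
#' exactly 50 ng/mL is a non-smoker call.
#'
#' @param cotinine_ng_ml Plasma cotinine concentrations (ng/mL).
#' @param cutoff Cut-off concentration (default 50).
#' @return Integer 0/1 calls.
#' @export
cotinine_classify <- function(cotinine_ng_ml, cutoff = 50) {
  as.integer(cotinine_ng_ml > cutoff)
}

new_smk_model <- function(name, fit, report, markers, outcome, family,
                          decision, threshold = NA_real_) {
  structure(
    list(name = name, fit = fit, report = report, markers = markers,
         outcome = outcome, family = family, decision = decision,
         threshold = threshold),
    class = "smk_model"
  )
}

#' @export
print.smk_model <- function(x, ...) {
  cat(sprintf("smokesig model '%s' (%s, %d markers)\n",
              x$name, x$family, length(x$markers)))
  if (inherits(x$report, "classification_report")) print(x$report)
  else print(x$report, row.names = FALSE)
  invisible(x)
}

check_markers <- function(beta, markers) {
  missing <- setdiff(markers, colnames(beta))
  if (length(missing) > 0) {
    stop("markers absent from the beta matrix: ",
         paste(missing, collapse = ", "))
  }
  beta[, markers, drop = FALSE]
}

#' Binary current-vs-non-smoker model
#'
#' Current smokers against former and never smokers combined; positive call
#' above probability 0.5.
#'
#' @param beta Samples x CpGs matrix.
#' @param pheno Phenotype table aligned to `beta` (column `status`).
#' @param markers Marker set to fit (e.g. the selected panel).
#' @param covariates Optional covariate columns (age, sex, cell
#'   proportions).
#' @param threshold Decision threshold (default 0.5).
#' @return An `smk_model` with the fit and apparent classification report.
#' @export
build_binary_smoker_model <- function(beta, pheno, markers,
                                      covariates = NULL, threshold = 0.5) {
  x <- check_markers(beta, markers)
  y <- as.integer(pheno$status == "current")
  fit <- fit_binary(x, y, covariates)
  probs <- predict_prob(fit, if (is.null(covariates)) x else
    cbind(x, as_design(covariates)))
  report <- confusion_at(probs, y, threshold)
  new_smk_model("current_vs_nonsmoker", fit, report, markers,
                "current smoker", "binomial", "threshold", threshold)
}

#' Three-category model: current vs former vs never
#'
#' Baseline-category multinomial logit with `never` as reference; predicted
#' category is the row argmax, and per-category one-vs-rest metrics are
#' reported.
#'
#' @inheritParams build_binary_smoker_model
#' @return An `smk_model` whose report has one row per category.
#' @export
build_three_category_model <- function(beta, pheno, markers,
                                       covariates = NULL) {
  keep <- pheno$status %in% c("current", "former", "never")
  x <- check_markers(beta[keep, , drop = FALSE], markers)
  y <- factor(pheno$status[keep], levels = c("never", "former", "current"))
  fit <- fit_multinomial(x, y, covariates, reference = "never")
  probs <- predict_prob(fit, x)
  report <- multiclass_report(probs, y)
  new_smk_model("current_former_never", fit, report, markers,
                "three-category smoking status", "multinomial", "argmax")
}

#' Cessation-horizon model in former smokers
#'
#' Dichotomizes former smokers at a cessation horizon of 5, 10 or 15 years
#' (at or beyond the horizon codes 1) and fits a binary model whose decision
#' threshold is the fixed constant for that horizon (see
#' [CESSATION_THRESHOLDS]), not 0.5.
#'
#' @param beta,pheno Cohort restricted (or restrictable) to former smokers;
#'   `pheno` must carry `age` and `age_stopped`.
#' @param markers Marker set.
#' @param horizon Cessation horizon in years: 5, 10 or 15.
#' @param threshold Decision threshold; defaults to the horizon constant.
#' @return An `smk_model`.
#' @export
build_cessation_model <- function(beta, pheno, markers,
                                  horizon = c(5, 10, 15),
                                  threshold = NULL) {
  horizon <- as.numeric(match.arg(as.character(horizon[1]),
                                  c("5", "10", "15")))
  if (is.null(threshold)) {
    threshold <- CESSATION_THRESHOLDS[[as.character(horizon)]]
  }
  keep <- pheno$status == "former"
  if (!any(keep)) stop("no former smokers in the cohort")
  ph <- pheno[keep, , drop = FALSE]
  x <- check_markers(beta[keep, , drop = FALSE], markers)
  cess <- compute_cessation(ph$age, ph$age_stopped)
  y <- dichotomize_history(cess, horizon)
  if (length(unique(y)) < 2) {
    stop("all former smokers fall on one side of the ", horizon,
         "-year horizon")
  }
  fit <- fit_binary(x, y)
  report <- confusion_at(predict_prob(fit, x), y, threshold)
  new_smk_model(paste0("cessation_ge", horizon, "y"), fit, report, markers,
                sprintf("cessation >= %g years", horizon), "binomial",
                "threshold", threshold)
}

#' Pack-year model in current smokers
#'
#' Dichotomizes current smokers at 10 or 15 pack-years (at or above codes 1)
#' and fits a binary model with the standard 0.5 threshold. Pack-years are
#' computed from cigarettes/day and years smoked (age minus start age).
#'
#' @param beta,pheno Cohort; `pheno` must carry `age`, `age_started`,
#'   `cigs_per_day`.
#' @param markers Marker set.
#' @param cutoff Pack-year cutoff: 10 or 15.
#' @param threshold Decision threshold (default 0.5).
#' @return An `smk_model`.
#' @export
build_packyear_model <- function(beta, pheno, markers, cutoff = c(15, 10),
                                 threshold = 0.5) {
  cutoff <- as.numeric(match.arg(as.character(cutoff[1]), c("15", "10")))
  keep <- pheno$status == "current"
  if (!any(keep)) stop("no current smokers in the cohort")
  ph <- pheno[keep, , drop = FALSE]
  x <- check_markers(beta[keep, , drop = FALSE], markers)
  py <- compute_pack_years(ph$cigs_per_day, ph$age - ph$age_started)
  y <- dichotomize_history(py, cutoff)
  if (length(unique(y)) < 2) {
    stop("all current smokers fall on one side of the ", cutoff,
         " pack-year cutoff")
  }
  fit <- fit_binary(x, y)
  report <- confusion_at(predict_prob(fit, x), y, threshold)
  new_smk_model(paste0("packyears_ge", cutoff), fit, report, markers,
                sprintf("pack-years >= %g", cutoff), "binomial",
                "threshold", threshold)
}

#' Five-category life-time smoking model
#'
#' Combines never smokers (1), former smokers by cessation time (> 10 years:
#' 2, <= 10 years: 3) and current smokers by pack-years (below the cutoff:
#' 4, at/above: 5) into one multinomial model; prediction is the row argmax.
#'
#' @param beta,pheno Cohort with complete history for current/former.
#' @param markers Marker set.
#' @param py_cutoff Pack-year cutoff: 15 (variant 1) or 10 (variant 2).
#' @return An `smk_model` with a five-row per-category report.
#' @export
build_five_category_model <- function(beta, pheno, markers,
                                      py_cutoff = c(15, 10)) {
  keep <- pheno$status %in% c("current", "former", "never")
  ph <- pheno[keep, , drop = FALSE]
  x <- check_markers(beta[keep, , drop = FALSE], markers)
  py <- compute_pack_years(ph$cigs_per_day, ph$age - ph$age_started)
  cess <- compute_cessation(ph$age, ph$age_stopped)
  y <- factor(code_five_category(ph$status, py, cess, py_cutoff),
              levels = 1:5)
  if (any(table(y) == 0)) {
    stop("at least one of the five categories is empty")
  }
  fit <- fit_multinomial(x, y, reference = "1")
  probs <- predict_prob(fit, x)
  report <- multiclass_report(probs, y)
  new_smk_model(paste0("five_category_py", as.numeric(py_cutoff[1])), fit,
                report, markers, "five-category life-time smoking",
                "multinomial", "argmax")
}

#' Apply a frozen adult model to a child cohort
#'
#' The adult model is never refit: its coefficients are applied as-is to the
#' child beta matrix. Five exposure recodings are supported:
#' \describe{
#'   \item{1}{all children coded non-smokers; reports the proportion
#'     accurately called non-smoker at the 0.5 threshold.}
#'   \item{2}{children of mothers who smoked throughout pregnancy coded 1.}
#'   \item{3}{additionally, mothers who stopped smoking on learning of the
#'     pregnancy.}
#'   \item{4}{additionally, passive household/work smoking exposure.}
#'   \item{5}{passive exposure alone, restricted to children of mothers who
#'     did not smoke during pregnancy.}
#' }
#'
#' @param adult_model An `smk_model` fitted on adults (binomial family).
#' @param child_cohort An `smk_cohort` whose phenotype carries
#'   `mother_sustained`, `mother_stopped_when_aware`, `household_passive`.
#' @param analysis Integer 1..5.
#' @param threshold Call threshold (default 0.5).
#' @return A `classification_report` (analyses 2-5) or, for analysis 1, a
#'   report against the all-non-smoker coding where `accuracy` is the
#'   proportion correctly called non-smoker.
#' @export
children_application <- function(adult_model, child_cohort, analysis,
                                 threshold = 0.5) {
  stopifnot(inherits(adult_model, "smk_model"),
            adult_model$family == "binomial")
  analysis <- as.integer(analysis)
  if (!analysis %in% 1:5) stop("analysis must be in 1..5")
  ph <- child_cohort$pheno
  req <- c("mother_sustained", "mother_stopped_when_aware",
           "household_passive")
  if (analysis > 1 && !all(req %in% names(ph))) {
    stop("child phenotype lacks exposure fields: ",
         paste(setdiff(req, names(ph)), collapse = ", "))
  }
  probs <- predict_prob(adult_model$fit,
                        check_markers(child_cohort$beta,
                                      adult_model$markers))
  if (analysis == 1) {
    return(confusion_at(probs, rep(0L, length(probs)), threshold))
  }
  keep <- rep(TRUE, nrow(ph))
  labels <- switch(as.character(analysis),
    "2" = as.integer(ph$mother_sustained),
    "3" = as.integer(ph$mother_sustained | ph$mother_stopped_when_aware),
    "4" = as.integer(ph$mother_sustained | ph$mother_stopped_when_aware |
                       ph$household_passive),
    "5" = {
      keep <- !ph$mother_sustained & !ph$mother_stopped_when_aware
      as.integer(ph$household_passive)
    }
  )
  if (anyNA(labels)) stop("missing exposure fields for analysis ", analysis)
  confusion_at(probs[keep], labels[keep], threshold)
}
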