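# Binary and multinomial logit fits behind every classifier, wrapped in a
# light container exposing coefficients, standard errors, z-statistics
# (coefficient / SE), log-likelihood and deviance, plus the nested
# likelihood-ratio test used by the marker-elimination stopping rule.

SEPARATION_COEF_BOUND <- 15

new_smk_glm <- function(coefficients, se, loglik, deviance, n, family,
                        predictors, marker_names, covariate_names,
                        levels = NULL, reference = NULL) {
  z <- coefficients / se
  structure(
    list(coefficients = coefficients, se = se, z = z,
         loglik = loglik, deviance = deviance, n = n, family = family,
         link = "logit", predictors = predictors,
         marker_names = marker_names, covariate_names = covariate_names,
         levels = levels, reference = reference,
         separation = any(abs(coefficients) > SEPARATION_COEF_BOUND,
                          na.rm = TRUE)),
    class = "smk_glm"
  )
}

#' @export
print.smk_glm <- function(x, ...) {
  cat(sprintf("%s logit model (n = %d, logLik = %.3f%s)\n",
              x$family, x$n, x$loglik,
              if (x$separation) ", SEPARATION FLAGGED" else ""))
  if (x$family == "binomial") {
    print(data.frame(coef = x$coefficients, se = x$se, z = x$z))
  } else {
    cat("reference category:", x$reference, "\n")
    print(x$coefficients)
  }
  invisible(x)
}

as_design <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x
}

check_full_rank <- function(design) {
  r <- qr(design)$rank
  if (r < ncol(design)) {
    stop("design matrix is rank deficient (constant or duplicated columns)")
  }
}

bind_covariates <- function(x, covariates) {
  if (is.null(covariates)) {
    return(list(design = x, covariate_names = character()))
  }
  cv <- as_design(covariates)
  list(design = cbind(x, cv), covariate_names = colnames(cv))
}

#' Fit a binary logistic regression
#'
#' Maximum-likelihood binomial GLM with logit link via [stats::glm()].
#' Perfect or quasi-perfect separation is detected through diverging
#' coefficients (|coef| > 15) and reported with a warning; the fit is
#' returned with `separation = TRUE` rather than silently.
#'
#' @param x Numeric predictor matrix (samples x markers) with column names.
#' @param y Binary outcome: logical, 0/1, or two-level factor (second level
#'   is the positive class).
#' @param covariates Optional matrix/data frame of additional columns (age,
#'   sex, cell proportions) appended to the design; they are never
#'   elimination candidates.
#' @return An object of class `smk_glm`.
#' @export
fit_binary <- function(x, y, covariates = NULL) {
  x <- as_design(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  d <- bind_covariates(x, covariates)
  design <- d$design
  check_full_rank(cbind(1, design))
  df <- data.frame(.y = y, design, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial("logit"),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  out <- new_smk_glm(
    coefficients = coefs, se = se[names(coefs)],
    loglik = as.numeric(stats::logLik(fit)),
    deviance = stats::deviance(fit), n = length(y), family = "binomial",
    predictors = colnames(design),
    marker_names = colnames(x), covariate_names = d$covariate_names
  )
  if (out$separation) {
    warning("possible separation: at least one |coefficient| > ",
            SEPARATION_COEF_BOUND, "; estimates flagged")
  }
  out
}

#' Fit a baseline-category multinomial logit model
#'
#' Fitted with [nnet::multinom()]. The reference (baseline) category
#' defaults to `"never"` when present, otherwise the first factor level.
#' With two categories the coefficients reproduce [fit_binary()].
#'
#' @param x Numeric predictor matrix with column names.
#' @param y Factor (or coercible) over K >= 2 categories, all non-empty.
#' @param covariates Optional additional design columns.
#' @param reference Baseline category.
#' @return An object of class `smk_glm` with a coefficient matrix of one row
#'   per non-reference category.
#' @export
fit_multinomial <- function(x, y, covariates = NULL, reference = "never") {
  x <- as_design(x)
  y <- as.factor(y)
  if (any(table(y) == 0) || nlevels(y) < 2) {
    stop("every outcome category must be non-empty (K >= 2)")
  }
  if (!reference %in% levels(y)) reference <- levels(y)[1]
  y <- stats::relevel(y, ref = reference)
  d <- bind_covariates(x, covariates)
  design <- d$design
  check_full_rank(cbind(1, design))
  df <- data.frame(.y = y, design, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 500,
                        reltol = 1e-12, Hess = TRUE)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) {  # K = 2: multinom returns a vector
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(levels(y)[2], names(cf)))
  }
  sm <- summary(fit)
  se <- sm$standard.errors
  if (is.null(dim(se))) {
    se <- matrix(se, nrow = 1, dimnames = dimnames(cf))
  }
  out <- new_smk_glm(
    coefficients = cf, se = se,
    loglik = as.numeric(stats::logLik(fit)),
    deviance = stats::deviance(fit), n = length(y), family = "multinomial",
    predictors = colnames(design),
    marker_names = colnames(x), covariate_names = d$covariate_names,
    levels = levels(y), reference = reference
  )
  if (out$separation) {
    warning("possible separation: at least one |coefficient| > ",
            SEPARATION_COEF_BOUND, "; estimates flagged")
  }
  out
}

#' Predicted class probabilities
#'
#' Binary models return the inverse-logit of the linear predictor;
#' multinomial models return a samples x K matrix of softmax probabilities
#' whose rows sum to one, columns named by category.
#'
#' @param model An `smk_glm`.
#' @param x Predictor matrix whose columns match the model's predictors
#'   (markers plus covariates, any order).
#' @return Numeric vector (binary) or matrix (multinomial).
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "smk_glm"))
  x <- as_design(x)
  if (!all(model$predictors %in% colnames(x))) {
    stop("x lacks predictor columns: ",
         paste(setdiff(model$predictors, colnames(x)), collapse = ", "))
  }
  x <- x[, model$predictors, drop = FALSE]
  if (model$family == "binomial") {
    eta <- drop(cbind(1, x) %*% model$coefficients)
    return(stats::plogis(eta))
  }
  eta <- cbind(1, x) %*% t(model$coefficients)  # n x (K-1)
  expeta <- exp(cbind(0, eta))                  # reference column first
  p <- expeta / rowSums(expeta)
  colnames(p) <- model$levels
  rownames(p) <- rownames(x)
  p
}

#' Likelihood-ratio test of nested logit models
#'
#' The statistic is twice the log-likelihood difference, referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in parameter count. Used to decide when backward marker elimination must
#' stop.
#'
#' @param full,reduced `smk_glm` fits on the same samples, with the reduced
#'   model's predictors a subset of the full model's.
#' @return List of class `smk_lrtest` with `chi_sq`, `df`, `p_value`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "smk_glm"), inherits(reduced, "smk_glm"))
  if (full$family != reduced$family || full$n != reduced$n) {
    stop("models are not comparable (different family or sample set)")
  }
  if (!all(reduced$predictors %in% full$predictors)) {
    stop("models are not nested: reduced predictors not a subset of full")
  }
  npar <- function(m) length(m$coefficients)
  df <- npar(full) - npar(reduced)
  if (df < 0) stop("reduced model has more parameters than full model")
  chi <- 2 * (full$loglik - reduced$loglik)
  chi <- max(chi, 0)  # guard vanishing negative rounding
  p <- if (df == 0) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  structure(list(chi_sq = chi, df = df, p_value = p), class = "smk_lrtest")
}

#' @export
print.smk_lrtest <- function(x, ...) {
  cat(sprintf("LRT: chi-squared = %.4f, df = %d, p = %.4g\n",
              x$chi_sq, x$df, x$p_value))
  invisible(x)
}
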