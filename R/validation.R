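# Internal validation: fivefold cross-validation and bootstrap optimism
# correction. Fitting only ever sees training slices / bootstrap resamples;
# held-out and original-sample labels enter at evaluation time only.

#' K-fold cross-validation of a smoking classifier
#'
#' The cohort is randomly partitioned into `k` equal (within one sample)
#' non-overlapping subsets; each fold's model is trained on the remaining
#' k-1 subsets and evaluated on the held-out fold. If some training fold
#' lacks a class, the partition is re-randomized (up to `max_tries` times).
#' Fold assignment is unstratified by default; `stratified = TRUE` balances
#' classes across folds.
#'
#' @param x Predictor matrix (samples x markers).
#' @param y Outcome: binary, or a factor with K >= 3 levels for the
#'   multinomial family.
#' @param k Number of folds.
#' @param seed Integer seed controlling the partition.
#' @param family `"binomial"` or `"multinomial"`.
#' @param threshold Call threshold for the binary confusion summaries.
#' @param stratified Balance class counts across folds.
#' @param covariates Optional extra design columns.
#' @param max_tries Re-randomization attempts before giving up.
#' @return Object of class `cv_report`: `folds` (per-fold metric rows),
#'   `mean`, `sd`, `k`, `seed`. For the multinomial family metrics are
#'   per-category one-vs-rest values averaged over folds.
#' @export
kfold_cv <- function(x, y, k = 5, seed = 1L, family = c("binomial",
                                                        "multinomial"),
                     threshold = 0.5, stratified = FALSE, covariates = NULL,
                     max_tries = 100) {
  family <- match.arg(family)
  x <- as_design(x)
  n <- nrow(x)
  y_chk <- if (family == "binomial") as_binary(y) else as.factor(y)
  set.seed(seed)

  assign_folds <- function() {
    if (stratified) {
      fold <- integer(n)
      for (cls in unique(y_chk)) {
        idx <- which(y_chk == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold
    } else {
      sample(rep_len(seq_len(k), n))
    }
  }
  fold <- NULL
  for (try in seq_len(max_tries)) {
    cand <- assign_folds()
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(y_chk[cand != f])) == length(unique(y_chk))
    }, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold)) {
    stop("could not build training folds containing every class after ",
         max_tries, " tries")
  }

  fold_rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    te <- !tr
    if (family == "binomial") {
      fit <- suppressWarnings(
        fit_binary(x[tr, , drop = FALSE], y_chk[tr],
                   covariates = if (is.null(covariates)) NULL else
                     covariates[tr, , drop = FALSE]))
      probs <- predict_prob(fit, x[te, , drop = FALSE])
      rep <- confusion_at(probs, y_chk[te], threshold)
      data.frame(fold = f, accuracy = rep$accuracy,
                 sensitivity = rep$sensitivity,
                 specificity = rep$specificity, auc = rep$auc)
    } else {
      fit <- suppressWarnings(
        fit_multinomial(x[tr, , drop = FALSE], y_chk[tr],
                        covariates = if (is.null(covariates)) NULL else
                          covariates[tr, , drop = FALSE]))
      probs <- predict_prob(fit, x[te, , drop = FALSE])
      rep <- multiclass_report(probs, y_chk[te])
      cbind(fold = f, rep)
    }
  })
  folds <- do.call(rbind, fold_rows)
  metric_cols <- intersect(c("accuracy", "sensitivity", "specificity", "auc"),
                           names(folds))
  if (family == "binomial") {
    mean_m <- colMeans(folds[metric_cols])
    sd_m <- apply(folds[metric_cols], 2, stats::sd)
  } else {
    mean_m <- stats::aggregate(folds[metric_cols],
                               by = list(category = folds$category), mean)
    sd_m <- stats::aggregate(folds[metric_cols],
                             by = list(category = folds$category), stats::sd)
  }
  structure(list(folds = folds, mean = mean_m, sd = sd_m, k = k,
                 seed = seed, family = family),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", x$k, x$family))
  if (x$family == "binomial") {
    m <- x$mean
    s <- x$sd
    for (nm in names(m)) cat(sprintf("  %s: %.3f +/- %.3f\n", nm, m[nm], s[nm]))
  } else {
    print(x$mean, row.names = FALSE)
  }
  invisible(x)
}

#' Bootstrap optimism correction of the apparent AUC
#'
#' For each of `B` replicates a bootstrap sample of size n is drawn with
#' replacement, a model is fit on it, and its AUC is evaluated both on the
#' replicate itself (bootstrap-apparent) and on the original cohort
#' (bootstrap-test). The optimism is the mean difference between the two,
#' and the adjusted AUC subtracts it from the apparent AUC of the original
#' fit. Replicates missing a class are redrawn (counted). Per-replicate
#' seeds are derived as `seed + b`, so shrinking `B` never changes the
#' replicates that remain.
#'
#' @param x Predictor matrix.
#' @param y Binary outcome.
#' @param B Number of bootstrap replicates.
#' @param seed Master seed.
#' @param covariates Optional extra design columns.
#' @return Object of class `optimism_report`: `apparent`, `boot_apparent`
#'   (mean), `boot_test` (mean), `optimism`, `adjusted`, `B`, `seed`,
#'   `retries`.
#' @export
bootstrap_optimism <- function(x, y, B = 1000, seed = 1L, covariates = NULL) {
  stopifnot(B >= 1)
  x <- as_design(x)
  y <- as_binary(y)
  n <- nrow(x)
  fit0 <- suppressWarnings(fit_binary(x, y, covariates))
  apparent <- roc_auc(predict_prob(fit0, x), y)

  app_b <- test_b <- numeric(B)
  retries <- 0L
  for (b in seq_len(B)) {
    set.seed(seed + b)
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
      retries <- retries + 1L
      if (retries > 100 * B) stop("bootstrap replicates keep missing a class")
    }
    cv <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    fit_b <- suppressWarnings(fit_binary(x[idx, , drop = FALSE], y[idx], cv))
    app_b[b] <- roc_auc(predict_prob(fit_b, x[idx, , drop = FALSE]), y[idx])
    test_b[b] <- roc_auc(predict_prob(fit_b, x), y)
  }
  optimism <- mean(app_b - test_b)
  structure(
    list(apparent = apparent, boot_apparent = mean(app_b),
         boot_test = mean(test_b), optimism = optimism,
         adjusted = adjusted_auc(apparent, optimism),
         B = B, seed = seed, retries = retries),
    class = "optimism_report"
  )
}

#' Optimism-adjusted AUC
#'
#' The adjustment rule of bootstrap internal validation: the apparent AUC
#' minus the estimated optimism.
#'
#' @param apparent Apparent AUC of the original fit on the original data.
#' @param optimism Mean bootstrap-apparent minus bootstrap-test AUC.
#' @return `apparent - optimism`.
#' @export
adjusted_auc <- function(apparent, optimism) apparent - optimism

#' @export
print.optimism_report <- function(x, ...) {
  cat(sprintf(
    "Bootstrap optimism (B = %d): apparent AUC %.4f, optimism %.4f, adjusted %.4f\n",
    x$B, x$apparent, x$optimism, x$adjusted))
  invisible(x)
}
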