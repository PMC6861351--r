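# Readers/writers for the one delimited dialect used throughout
# (tab-separated, header row, UTF-8, "." decimal, empty string = missing;
# samples are rows, CpGs are columns), plus the end-to-end pipeline driver.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    na.strings = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a methylation beta matrix
#'
#' Tab-separated text: first column `sample_id`, remaining columns CpG ids,
#' values numeric beta values in `[0, 1]` or empty for missing.
#'
#' @param path File path.
#' @return Numeric matrix (samples x CpGs) with sample-id rownames; missing
#'   cells are `NA`.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "sample_id") {
    stop("first column must be sample_id")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value outside [0, 1] at sample %s, CpG %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  m
}

#' Write a beta matrix in the package dialect
#' @param beta Samples x CpGs matrix with rownames.
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

PHENO_STATUS_TOKENS <- c("current", "former", "never", "missing")

#' Read a phenotype table
#'
#' Requires columns `sample_id` and `status`; recognises the optional
#' history and covariate columns (`age`, `sex`, `age_started`,
#' `age_stopped`, `cigs_per_day`, `cotinine`, cell proportions). Validates
#' the status vocabulary and the history ordering invariants
#' (`age_stopped <= age`, `age_started <= age_stopped` when both present),
#' reporting offending rows.
#'
#' @param path File path.
#' @return Data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("sample_id", "status") %in% names(df))) {
    stop("phenotype table needs sample_id and status columns")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  bad_status <- !is.na(df$status) & !(df$status %in% PHENO_STATUS_TOKENS)
  if (any(bad_status)) {
    stop("unknown status token(s) ",
         paste(unique(df$status[bad_status]), collapse = ", "),
         " (allowed: ", paste(PHENO_STATUS_TOKENS, collapse = ", "), ")")
  }
  if (all(c("age", "age_stopped") %in% names(df))) {
    bad <- which(!is.na(df$age_stopped) & df$age_stopped > df$age)
    if (length(bad) > 0) {
      stop("age_stopped > age for row(s): ", paste(bad, collapse = ", "))
    }
  }
  if (all(c("age_started", "age_stopped") %in% names(df))) {
    bad <- which(!is.na(df$age_started) & !is.na(df$age_stopped) &
                   df$age_started > df$age_stopped)
    if (length(bad) > 0) {
      stop("age_started > age_stopped for row(s): ",
           paste(bad, collapse = ", "))
    }
  }
  df
}

#' Write a phenotype table
#' @param pheno Phenotype data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(pheno, path) write_tsv_strict(pheno, path)

#' Read an EWAS evidence table (`cpg_id`, `study_id`, `delta_beta`)
#' @param path File path.
#' @return Data frame of evidence rows.
#' @export
read_ewas_evidence <- function(path) {
  df <- read_tsv_strict(path)
  req <- c("cpg_id", "study_id", "delta_beta")
  if (!all(req %in% names(df))) {
    stop("evidence table needs columns: ", paste(req, collapse = ", "))
  }
  df
}

#' Write a synthetic cohort as the three delimited inputs
#'
#' Emits `beta.tsv`, `pheno.tsv` and `truth.tsv` under `dir` in the package
#' dialect; the truth table is for evaluation only and never feeds model
#' fitting.
#'
#' @param cohort An `smk_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_tsv_strict(cohort$pheno, file.path(dir, "pheno.tsv"))
  write_tsv_strict(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in method order: candidate ascertainment from the
#' evidence table, participant QC, backward marker elimination with the
#' chi-squared stop, the binary model on the selected panel, fivefold
#' cross-validation and bootstrap optimism, and (when cotinine is present)
#' the three-way concordance against the cotinine cut-off. Every output is
#' written as a tab-separated table under `config$outdir`, with a log
#' recording package version, the config echo and the seed; rerunning with
#' the same config reproduces the outputs.
#'
#' @param config A list, or path to a YAML file, with fields: `beta_path`,
#'   `pheno_path`, `evidence_path` (optional; when absent all beta columns
#'   are candidates), `outdir`, and optional `alpha` (0.05), `k` (5), `B`
#'   (200), `threshold` (0.5), `seed` (1).
#' @return Invisibly, a list with the selected markers, the model, the CV
#'   and optimism reports, and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, k = 5, B = 200, threshold = 0.5, seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (f in c("beta_path", "pheno_path", "outdir")) {
    if (is.null(config[[f]])) stop("config missing required field: ", f)
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logfile, append = TRUE)
  }
  cat("", file = logfile)
  log_line("smokesig %s", as.character(utils::packageVersion("smokesig")))
  log_line("seed: %d", config$seed)
  log_line("config: %s", paste(deparse(config[setdiff(names(config),
                                                      "packyear_scaling")]),
                               collapse = " "))

  stage <- function(name, expr) {
    log_line("stage: %s", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  beta <- stage("read_beta", read_beta_matrix(config$beta_path))
  pheno <- stage("read_phenotypes", read_phenotypes(config$pheno_path))

  if (!is.null(config$evidence_path)) {
    evidence <- stage("read_evidence", read_ewas_evidence(config$evidence_path))
    candidates <- stage("ascertain", filter_candidates(evidence))
    write_tsv_strict(as.data.frame(candidates),
                     file.path(outdir, "candidates.tsv"))
    marker_cols <- intersect(candidates$cpg_id, colnames(beta))
  } else {
    marker_cols <- colnames(beta)
  }
  if (length(marker_cols) < 2) {
    stop("pipeline stage 'ascertain' failed: fewer than 2 candidate CpGs ",
         "present in the beta matrix")
  }

  qc <- stage("qc", apply_exclusions(beta[, marker_cols, drop = FALSE],
                                     pheno))
  write_tsv_strict(qc$log, file.path(outdir, "exclusions.tsv"))
  log_line("retained %d participants", nrow(qc$beta))

  y <- as.integer(qc$pheno$status == "current")
  trace <- stage("select", backward_eliminate(qc$beta, y))
  write_tsv_strict(trace$trace, file.path(outdir, "elimination_trace.tsv"))
  selected <- stage("stop", chisq_stop(trace, alpha = config$alpha))
  writeLines(selected, file.path(outdir, "selected_markers.txt"))
  log_line("selected %d markers", length(selected))

  model <- stage("fit", build_binary_smoker_model(
    qc$beta, qc$pheno, selected, threshold = config$threshold))
  rep <- model$report
  write_tsv_strict(
    data.frame(metric = c("accuracy", "ci_lower", "ci_upper", "sensitivity",
                          "specificity", "auc"),
               value = c(rep$accuracy, rep$ci_lower, rep$ci_upper,
                         rep$sensitivity, rep$specificity, rep$auc)),
    file.path(outdir, "binary_model_report.tsv"))

  cv <- stage("cross_validate", kfold_cv(
    qc$beta[, selected, drop = FALSE], y, k = config$k, seed = config$seed,
    threshold = config$threshold))
  write_tsv_strict(cv$folds, file.path(outdir, "cv_folds.tsv"))

  opt <- stage("bootstrap", bootstrap_optimism(
    qc$beta[, selected, drop = FALSE], y, B = config$B, seed = config$seed))
  write_tsv_strict(
    data.frame(metric = c("apparent", "optimism", "adjusted", "B"),
               value = c(opt$apparent, opt$optimism, opt$adjusted, opt$B)),
    file.path(outdir, "optimism.tsv"))

  concordance <- NULL
  if ("cotinine" %in% names(qc$pheno) && !anyNA(qc$pheno$cotinine)) {
    concordance <- stage("compare_cotinine", {
      probs <- predict_prob(model$fit, qc$beta[, selected, drop = FALSE])
      concordance_partition(
        questionnaire_calls = y,
        cotinine_calls = cotinine_classify(qc$pheno$cotinine),
        cpg_calls = as.integer(probs > config$threshold)
      )
    })
    write_tsv_strict(concordance$cells, file.path(outdir, "concordance.tsv"))
  }
  log_line("done")
  invisible(list(selected = selected, model = model, cv = cv,
                 optimism = opt, concordance = concordance,
                 trace = trace, outdir = outdir))
}
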