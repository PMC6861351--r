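# Synthetic methylation cohorts with the statistical structure the smoking
# classifiers assume: per-CpG never-smoker baselines, current-smoker beta
# shifts with fixed sign, former-smoker shifts decaying with cessation time,
# dose scaling with pack-years, non-informative decoy CpGs, and plasma
# cotinine concentrated above/below 50 ng/mL by true status.

#' Per-CpG specification for the synthetic cohort generator
#'
#' @param cpg_id Character CpG identifiers.
#' @param baseline_beta Never-smoker mean beta value, in (0, 1).
#' @param smoker_delta Signed beta-scale shift in current smokers at full
#'   dose saturation. Effects at least 0.10 in magnitude mirror the
#'   detectability floor used for marker ascertainment.
#' @param reversion_timescale Exponential time scale tau (years) on which the
#'   former-smoker shift decays back to baseline; must be positive.
#' @param informative Logical; non-informative CpGs carry no smoking effect
#'   regardless of `smoker_delta`.
#' @return A data frame with one row per CpG.
#' @export
cpg_spec <- function(cpg_id, baseline_beta, smoker_delta,
                     reversion_timescale = 10, informative = TRUE) {
  spec <- data.frame(
    cpg_id = as.character(cpg_id),
    baseline_beta = baseline_beta,
    smoker_delta = smoker_delta,
    reversion_timescale = reversion_timescale,
    informative = informative,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(spec$cpg_id)) {
    stop("duplicate cpg_id in CpG specification")
  }
  if (any(spec$baseline_beta <= 0 | spec$baseline_beta >= 1)) {
    stop("baseline_beta must lie strictly inside (0, 1)")
  }
  if (any(spec$reversion_timescale <= 0)) {
    stop("reversion_timescale must be positive")
  }
  spec
}

#' Default marker panel: 13 informative CpGs plus decoys
#'
#' The informative effects are hypomethylation shifts spanning -0.24 to
#' -0.10 on the beta scale (the ascertainment criterion requires at least a
#' 0.10 difference in at least one study), at baselines typical of smoking
#' CpGs in whole blood. `decoy_delta` lets the caller plant near-null rather
#' than exactly-null decoys.
#'
#' @param n_informative Number of smoking-responsive CpGs.
#' @param n_decoy Number of non-informative CpGs.
#' @param decoy_delta Beta-scale shift assigned to decoys (default 0).
#' @param reversion_timescale Decay time scale (years) shared by the panel.
#' @return A `cpg_spec()` data frame.
#' @export
default_cpg_panel <- function(n_informative = 13, n_decoy = 7,
                              decoy_delta = 0, reversion_timescale = 10) {
  stopifnot(n_informative >= 1, n_decoy >= 0)
  deltas <- -seq(0.24, 0.10, length.out = n_informative)
  baselines <- rep(c(0.80, 0.65, 0.50, 0.72, 0.60), length.out = n_informative)
  inf <- cpg_spec(
    cpg_id = sprintf("cgINF%03d", seq_len(n_informative)),
    baseline_beta = baselines,
    smoker_delta = deltas,
    reversion_timescale = reversion_timescale,
    informative = TRUE
  )
  if (n_decoy == 0) {
    return(inf)
  }
  dec <- cpg_spec(
    cpg_id = sprintf("cgDEC%03d", seq_len(n_decoy)),
    baseline_beta = rep(c(0.45, 0.62, 0.55, 0.70), length.out = n_decoy),
    smoker_delta = rep(decoy_delta, n_decoy),
    reversion_timescale = reversion_timescale,
    informative = abs(decoy_delta) > 0
  )
  rbind(inf, dec)
}

#' Parameters of the synthetic methylation cohort
#'
#' Defaults emulate the structure of the model-building population: 3764
#' participants, class proportions matching the three-category subset
#' (current 364 / former 1332 / never 1243 of 2939), a 13-marker panel with
#' beta shifts of at least 0.10, saturating pack-year dose response
#' PY/(PY+10), cotinine log-normal with medians 200 (true smokers) and
#' 2 ng/mL (non-smokers), and a 5% misreporting fraction among true smokers.
#' The default logit-noise SD of 0.5 calibrates the strongest single marker
#' of the default panel to a one-CpG AUC near 0.88 at these class
#' proportions, the level reported for the best smoking CpG in whole blood.
#'
#' @param n_participants Cohort size (at least 20).
#' @param class_mix Named proportions over `current`, `former`, `never`,
#'   summing to 1.
#' @param cpg_specs A `cpg_spec()` data frame.
#' @param n_decoy_cpgs Additional exactly-null decoy CpGs appended to
#'   `cpg_specs`.
#' @param noise_sd_logit Standard deviation of the Gaussian logit-scale noise.
#' @param packyear_scaling Monotone function mapping pack-years to a dose
#'   multiplier in `[0, 1]`.
#' @param cotinine_meanlog_smoker,cotinine_meanlog_nonsmoker,cotinine_sdlog
#'   Log-normal parameters of plasma cotinine (ng/mL) by true smoking status.
#' @param misreport_rate Fraction of true current smokers whose questionnaire
#'   status reads `never`.
#' @param cordblood_offset Optional per-CpG additive logit-scale shift applied
#'   by [generate_child_cohort()] for cord-blood tissue (recycled across CpGs).
#' @param seed Integer seed; identical parameters give identical cohorts.
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_participants = 3764,
                             class_mix = c(current = 364, former = 1332,
                                           never = 1243) / 2939,
                             cpg_specs = default_cpg_panel(),
                             n_decoy_cpgs = 0,
                             noise_sd_logit = 0.5,
                             packyear_scaling = function(py) py / (py + 10),
                             cotinine_meanlog_smoker = log(200),
                             cotinine_meanlog_nonsmoker = log(2),
                             cotinine_sdlog = 0.8,
                             misreport_rate = 0.05,
                             cordblood_offset = 0,
                             seed = 1L) {
  if (n_participants < 20) stop("n_participants must be at least 20")
  if (!all(sort(names(class_mix)) == c("current", "former", "never"))) {
    stop("class_mix must be named over current, former, never")
  }
  if (abs(sum(class_mix) - 1) > 1e-12) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be non-negative")
  if (noise_sd_logit <= 0) stop("noise_sd_logit must be positive")
  if (misreport_rate < 0 || misreport_rate > 1) {
    stop("misreport_rate must be in [0, 1]")
  }
  if (n_decoy_cpgs > 0) {
    dec <- cpg_spec(
      cpg_id = sprintf("cgNUL%03d", seq_len(n_decoy_cpgs)),
      baseline_beta = rep(c(0.40, 0.58, 0.66), length.out = n_decoy_cpgs),
      smoker_delta = 0,
      informative = FALSE
    )
    cpg_specs <- rbind(cpg_specs, dec)
  }
  if (!any(cpg_specs$informative)) stop("at least one informative CpG required")
  structure(
    list(
      n_participants = as.integer(n_participants),
      class_mix = class_mix[c("current", "former", "never")],
      cpg_specs = cpg_specs,
      noise_sd_logit = noise_sd_logit,
      packyear_scaling = packyear_scaling,
      cotinine_meanlog_smoker = cotinine_meanlog_smoker,
      cotinine_meanlog_nonsmoker = cotinine_meanlog_nonsmoker,
      cotinine_sdlog = cotinine_sdlog,
      misreport_rate = misreport_rate,
      cordblood_offset = cordblood_offset,
      seed = as.integer(seed)
    ),
    class = "synthetic_params"
  )
}

.BETA_EPS <- 1e-6

clip_beta <- function(x) pmin(pmax(x, .BETA_EPS), 1 - .BETA_EPS)

# Deterministic class allocation: floor(n * mix) then largest remainders.
allocate_classes <- function(n, mix) {
  base <- floor(n * mix)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * mix - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base == 0 & mix > 0)) {
    stop("n_participants too small to contain all classes in class_mix")
  }
  base
}

# Per-sample expected beta for one CpG, before logit-scale noise.
expected_beta <- function(spec_row, status, dose, decay) {
  shift <- if (spec_row$informative) {
    spec_row$smoker_delta * dose *
      ifelse(status == "current", 1,
             ifelse(status == "former", decay, 0))
  } else {
    0
  }
  clip_beta(spec_row$baseline_beta + shift)
}

#' Generate a synthetic adult cohort
#'
#' Betas are sampled logit-normally: the target group mean is set on the beta
#' scale (baseline plus `delta * g(PY)`, decayed by `exp(-cessation/tau)` in
#' former smokers), mapped through the logit, perturbed with Gaussian noise of
#' SD `noise_sd_logit`, and mapped back, so values always fall in `[0, 1]`.
#' Cotinine follows the true status (misreporters keep smoker-level
#' cotinine), and the truth table records what the questionnaire hides.
#'
#' @param params A [synthetic_params()] object.
#' @return A list of class `smk_cohort` with elements `beta` (samples x CpGs
#'   matrix), `pheno` (questionnaire-level phenotype table) and `truth`
#'   (true status, dose history, misreporting flag). The informative-CpG ids
#'   are attached as `attr(, "informative_cpgs")` of the truth table.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  n <- params$n_participants
  counts <- allocate_classes(n, params$class_mix)
  status_true <- sample(rep(names(counts), counts))

  age <- runif(n, 25, 75)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ever <- status_true != "never"
  age_started <- ifelse(ever, pmin(runif(n, 16, 22), age - 3), NA_real_)
  age_stopped <- rep(NA_real_, n)
  f <- status_true == "former"
  age_stopped[f] <- runif(sum(f), age_started[f] + 1, age[f])
  cigs_per_day <- ifelse(ever, pmax(1, round(rlnorm(n, log(15), 0.45))),
                         NA_real_)

  years_smoked <- rep(0, n)
  years_smoked[status_true == "current"] <-
    (age - age_started)[status_true == "current"]
  years_smoked[f] <- (age_stopped - age_started)[f]
  pack_years <- ifelse(ever, compute_pack_years(cigs_per_day, years_smoked), 0)
  cessation_years <- ifelse(f, compute_cessation(age, age_stopped), NA_real_)

  dose <- params$packyear_scaling(pack_years)

  specs <- params$cpg_specs
  beta <- matrix(NA_real_, n, nrow(specs),
                 dimnames = list(sprintf("S%05d", seq_len(n)), specs$cpg_id))
  for (j in seq_len(nrow(specs))) {
    dec_j <- ifelse(f, exp(-cessation_years / specs$reversion_timescale[j]), 0)
    mu_beta <- expected_beta(specs[j, ], status_true, dose, dec_j)
    beta[, j] <- clip_beta(stats::plogis(
      stats::rnorm(n, stats::qlogis(mu_beta), params$noise_sd_logit)
    ))
  }

  cot_meanlog <- ifelse(status_true == "current",
                        params$cotinine_meanlog_smoker,
                        params$cotinine_meanlog_nonsmoker)
  cotinine <- rlnorm(n, cot_meanlog, params$cotinine_sdlog)

  misreported <- status_true == "current" &
    runif(n) < params$misreport_rate
  status_rep <- status_true
  status_rep[misreported] <- "never"

  # cell proportions (granulocytes/lymphocytes/monocytes), smoking-independent
  g <- cbind(rgamma(n, 60), rgamma(n, 30), rgamma(n, 10))
  cell <- g / rowSums(g)

  pheno <- data.frame(
    sample_id = rownames(beta),
    status = status_rep,
    age = age,
    sex = sex,
    age_started = ifelse(misreported, NA_real_, age_started),
    age_stopped = age_stopped,
    cigs_per_day = ifelse(misreported, NA_real_, cigs_per_day),
    cotinine = cotinine,
    gran = cell[, 1], lymph = cell[, 2], mono = cell[, 3],
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = rownames(beta),
    true_status = status_true,
    pack_years = pack_years,
    cessation_years = cessation_years,
    misreported = misreported,
    stringsAsFactors = FALSE
  )
  attr(truth, "informative_cpgs") <- specs$cpg_id[specs$informative]
  structure(list(beta = beta, pheno = pheno, truth = truth, params = params),
            class = "smk_cohort")
}

#' @export
print.smk_cohort <- function(x, ...) {
  cat(sprintf("Synthetic methylation cohort: %d samples x %d CpGs\n",
              nrow(x$beta), ncol(x$beta)))
  print(table(x$pheno$status))
  invisible(x)
}

#' Generate a synthetic child cohort with prenatal-exposure structure
#'
#' Children are non-smokers whose methylation can carry (i) an attenuated
#' maternal smoking effect and (ii) a cord-blood tissue offset on the logit
#' scale. Exposure codings for the five downstream analyses (sustained
#' maternal smoking; stopped when aware of pregnancy; passive household
#' smoking) are carried in the phenotype table.
#'
#' @param params A [synthetic_params()] object; `n_participants` must equal
#'   the number of rows of `maternal_smoking_labels`, and `cordblood_offset`
#'   is applied when `tissue = "cord"`.
#' @param maternal_smoking_labels Data frame with logical columns
#'   `sustained`, `stopped_when_aware`, `passive` (one row per child).
#' @param tissue `"cord"` (applies the offset) or `"peripheral"`.
#' @param attenuation Named numeric multipliers of the adult current-smoker
#'   shift for each exposure class, `c(sustained=, stopped=, passive=)`.
#' @return An `smk_cohort` whose phenotype carries the exposure columns.
#' @export
generate_child_cohort <- function(params, maternal_smoking_labels,
                                  tissue = c("cord", "peripheral"),
                                  attenuation = c(sustained = 0.5,
                                                  stopped = 0.2,
                                                  passive = 0)) {
  stopifnot(inherits(params, "synthetic_params"))
  tissue <- match.arg(tissue)
  m <- maternal_smoking_labels
  req <- c("sustained", "stopped_when_aware", "passive")
  if (!all(req %in% names(m))) {
    stop("maternal_smoking_labels needs columns: ",
         paste(req, collapse = ", "))
  }
  if (nrow(m) != params$n_participants) {
    stop("n_participants must match nrow(maternal_smoking_labels)")
  }
  if (tissue == "cord" && is.null(params$cordblood_offset)) {
    stop("cordblood_offset required for cord-blood tissue")
  }
  set.seed(params$seed)
  n <- nrow(m)
  mult <- ifelse(m$sustained, attenuation[["sustained"]],
                 ifelse(m$stopped_when_aware, attenuation[["stopped"]],
                        ifelse(m$passive, attenuation[["passive"]], 0)))
  specs <- params$cpg_specs
  offset <- rep_len(if (tissue == "cord") params$cordblood_offset else 0,
                    nrow(specs))
  beta <- matrix(NA_real_, n, nrow(specs),
                 dimnames = list(sprintf("C%05d", seq_len(n)), specs$cpg_id))
  for (j in seq_len(nrow(specs))) {
    shift <- if (specs$informative[j]) specs$smoker_delta[j] * mult else 0
    mu <- stats::qlogis(clip_beta(specs$baseline_beta[j] + shift)) + offset[j]
    beta[, j] <- clip_beta(stats::plogis(
      stats::rnorm(n, mu, params$noise_sd_logit)
    ))
  }
  pheno <- data.frame(
    sample_id = rownames(beta),
    status = "never",
    age = if (tissue == "cord") 0 else 6,
    sex = sample(c("F", "M"), n, replace = TRUE),
    mother_sustained = as.logical(m$sustained),
    mother_stopped_when_aware = as.logical(m$stopped_when_aware),
    household_passive = as.logical(m$passive),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = rownames(beta),
    true_status = "never",
    exposure_multiplier = mult,
    stringsAsFactors = FALSE
  )
  attr(truth, "informative_cpgs") <- specs$cpg_id[specs$informative]
  structure(list(beta = beta, pheno = pheno, truth = truth, params = params),
            class = "smk_cohort")
}
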