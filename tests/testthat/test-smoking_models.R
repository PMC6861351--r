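cohort_for_models <- function(n = 1200, seed = 60L, noise = 0.35) {
  p <- synthetic_params(
    n_participants = n,
    class_mix = c(current = 0.25, former = 0.4, never = 0.35),
    cpg_specs = default_cpg_panel(n_informative = 4, n_decoy = 0),
    noise_sd_logit = noise, misreport_rate = 0, seed = seed)
  generate_cohort(p)
}

test_that("cotinine cut-off is strict at 50 ng/mL", {
  expect_equal(cotinine_classify(c(60, 50, 49.9, 0)), c(1L, 0L, 0L, 0L))
})

test_that("cessation models use the fixed horizon thresholds", {
  expect_equal(unname(CESSATION_THRESHOLDS),
               c(0.8733, 0.7650, 0.6397))
  coh <- cohort_for_models()
  m5 <- build_cessation_model(coh$beta, coh$pheno, colnames(coh$beta), 5)
  m10 <- build_cessation_model(coh$beta, coh$pheno, colnames(coh$beta), 10)
  m15 <- build_cessation_model(coh$beta, coh$pheno, colnames(coh$beta), 15)
  expect_equal(m5$threshold, 0.8733)
  expect_equal(m10$threshold, 0.7650)
  expect_equal(m15$threshold, 0.6397)
  expect_equal(m5$report$threshold, 0.8733)
  # degenerate cohort: every former smoker on one side of the horizon
  ph <- coh$pheno[coh$pheno$status == "former", ]
  ph$age_stopped <- ph$age - 1  # all cessation times ~1 year
  bt <- coh$beta[coh$pheno$status == "former", ]
  expect_error(build_cessation_model(bt, ph, colnames(bt), 15),
               "one side")
})

test_that("a clean planted-signal cohort gives a near-perfect binary model", {
  p <- synthetic_params(
    n_participants = 400,
    class_mix = c(current = 0.4, former = 0.2, never = 0.4),
    cpg_specs = cpg_spec("cgP", 0.8, -0.5),
    noise_sd_logit = 0.05, misreport_rate = 0,
    packyear_scaling = function(py) rep(1, length(py)), seed = 61L)
  coh <- generate_cohort(p)
  m <- suppressWarnings(
    build_binary_smoker_model(coh$beta, coh$pheno, "cgP"))
  expect_gt(m$report$auc, 0.999)
})

test_that("covariates independent of methylation barely move the AUC", {
  coh <- cohort_for_models(n = 1500, seed = 62L)
  markers <- colnames(coh$beta)
  base <- build_binary_smoker_model(coh$beta, coh$pheno, markers)
  covs <- cbind(age = coh$pheno$age,
                sex = as.integer(coh$pheno$sex == "M"))
  aug <- build_binary_smoker_model(coh$beta, coh$pheno, markers,
                                   covariates = covs)
  expect_lt(abs(aug$report$auc - base$report$auc), 0.02)
})

test_that("three-category model orders category difficulty as expected", {
  coh <- cohort_for_models(n = 2000, seed = 63L)
  m <- build_three_category_model(coh$beta, coh$pheno, colnames(coh$beta))
  rep <- m$report
  expect_setequal(rep$category, c("never", "former", "current"))
  # cessation decay makes former smokers the hardest category
  expect_lt(rep$auc[rep$category == "former"],
            rep$auc[rep$category == "current"])
  # label permutation destroys the signal
  ph_perm <- coh$pheno
  set.seed(1)
  ph_perm$status <- sample(ph_perm$status)
  m0 <- build_three_category_model(coh$beta, ph_perm, colnames(coh$beta))
  expect_true(all(abs(m0$report$auc - 0.5) < 0.08))
})

test_that("pack-year models pick up dose scaling and respect the cutoff coding", {
  coh <- cohort_for_models(n = 2500, seed = 64L)
  m15 <- build_packyear_model(coh$beta, coh$pheno, colnames(coh$beta), 15)
  expect_gt(m15$report$auc, 0.55)
  expect_equal(m15$threshold, 0.5)
  # outcome coding equals dichotomize_history on the derived pack-years
  ph <- coh$pheno[coh$pheno$status == "current", ]
  py <- compute_pack_years(ph$cigs_per_day, ph$age - ph$age_started)
  expect_equal(sum(dichotomize_history(py, 15)),
               m15$report$tp + m15$report$fn)

  # flat dose response removes the signal
  p0 <- synthetic_params(
    n_participants = 1500,
    class_mix = c(current = 0.4, former = 0.2, never = 0.4),
    cpg_specs = default_cpg_panel(n_informative = 3, n_decoy = 0),
    packyear_scaling = function(py) rep(1, length(py)),
    misreport_rate = 0, seed = 65L)
  coh0 <- generate_cohort(p0)
  m0 <- build_packyear_model(coh0$beta, coh0$pheno, colnames(coh0$beta), 15)
  expect_lt(abs(m0$report$auc - 0.5), 0.1)
})

test_that("five-category model codes labels correctly and separates heavy smokers best", {
  coh <- cohort_for_models(n = 2500, seed = 66L)
  m <- build_five_category_model(coh$beta, coh$pheno, colnames(coh$beta),
                                 py_cutoff = 15)
  rep <- m$report
  expect_setequal(rep$category, as.character(1:5))
  # argmax marginal consistency: per-category call counts sum to n
  expect_equal(sum(rep$n), sum(coh$pheno$status %in%
                                 c("current", "former", "never")))
  # heavy current smokers carry the largest dose signal
  expect_equal(rep$category[which.max(rep$auc)], "5")
})

test_that("the 10-marker variant is a refit, not a coefficient subset", {
  coh <- cohort_for_models(n = 1000, seed = 67L)
  all_m <- colnames(coh$beta)
  sub_m <- all_m[-1]
  full <- build_binary_smoker_model(coh$beta, coh$pheno, all_m)
  sub <- build_binary_smoker_model(coh$beta, coh$pheno, sub_m)
  expect_false(isTRUE(all.equal(
    sub$fit$coefficients[sub_m], full$fit$coefficients[sub_m])))
})

test_that("children application freezes the adult model and recodes exposures", {
  adult <- cohort_for_models(n = 1500, seed = 68L)
  model <- build_binary_smoker_model(adult$beta, adult$pheno,
                                     colnames(adult$beta))
  coefs_before <- model$fit$coefficients

  n <- 600
  set.seed(69)
  mat <- data.frame(
    sustained = c(rep(TRUE, 90), rep(FALSE, n - 90)),
    stopped_when_aware = c(rep(FALSE, 90), rep(TRUE, 60),
                           rep(FALSE, n - 150)),
    passive = c(rep(FALSE, 150), rep(TRUE, 120), rep(FALSE, n - 270))
  )
  p_child <- synthetic_params(
    n_participants = n,
    class_mix = c(current = 0.25, former = 0.4, never = 0.35),
    cpg_specs = default_cpg_panel(n_informative = 4, n_decoy = 0),
    noise_sd_logit = 0.35, seed = 70L)
  child <- generate_child_cohort(p_child, mat, tissue = "peripheral",
                                 attenuation = c(sustained = 0.8,
                                                 stopped = 0.3, passive = 0))

  a1 <- children_application(model, child, 1)
  expect_gt(a1$accuracy, 0.8)   # offset-free children read as non-smokers
  a2 <- children_application(model, child, 2)
  expect_gt(a2$auc, 0.5)        # sustained exposure is detectable
  a5 <- children_application(model, child, 5)
  n1 <- sum(mat$passive & !mat$sustained & !mat$stopped_when_aware)
  n0 <- sum(!mat$passive & !mat$sustained & !mat$stopped_when_aware)
  se_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a5$auc - 0.5), 3 * se_null)  # zero-effect passive exposure

  expect_identical(model$fit$coefficients, coefs_before)
  bad <- child
  bad$pheno$mother_sustained <- NULL
  expect_error(children_application(model, bad, 2), "exposure fields")
})

test_that("a smoker-shifted cord-blood cohort is mostly called smoker", {
  adult <- cohort_for_models(n = 1500, seed = 71L)
  model <- build_binary_smoker_model(adult$beta, adult$pheno,
                                     colnames(adult$beta))
  n <- 200
  mat <- data.frame(sustained = rep(FALSE, n), stopped_when_aware = FALSE,
                    passive = FALSE)
  # offset pushes every CpG toward smoker-like levels (deltas are negative)
  p_cord <- synthetic_params(
    n_participants = n,
    class_mix = c(current = 0.25, former = 0.4, never = 0.35),
    cpg_specs = default_cpg_panel(n_informative = 4, n_decoy = 0),
    noise_sd_logit = 0.35, cordblood_offset = -2.5, seed = 72L)
  cord <- generate_child_cohort(p_cord, mat, tissue = "cord")
  a1 <- children_application(model, cord, 1)
  expect_lt(a1$accuracy, 0.5)
})
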