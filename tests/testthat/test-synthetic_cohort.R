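test_that("identical parameters give identical cohorts", {
  p <- quick_params(n = 200, seed = 42L)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$beta, b$beta)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth, b$truth)
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(synthetic_params(n_participants = 10), "at least 20")
  expect_error(
    synthetic_params(class_mix = c(current = 0.5, former = 0.5, never = 0.5)),
    "sum to 1")
  expect_error(cpg_spec("cg1", 0.5, -0.1, reversion_timescale = -1),
               "positive")
  expect_error(cpg_spec("cg1", 1.2, -0.1), "inside \\(0, 1\\)")
  p20 <- synthetic_params(
    n_participants = 20,
    class_mix = c(current = 0.01, former = 0.49, never = 0.5),
    cpg_specs = cpg_spec("cg1", 0.5, -0.15))
  expect_error(generate_cohort(p20), "too small")
})

test_that("betas stay inside [0,1] and zero-delta panels carry no signal", {
  p <- quick_params(n = 600, seed = 7L, deltas = c(0, 0), n_decoy = 0)
  coh <- generate_cohort(p)
  expect_true(all(coh$beta >= 0 & coh$beta <= 1))
  cur <- coh$truth$true_status == "current"
  nev <- coh$truth$true_status == "never"
  for (j in seq_len(ncol(coh$beta))) {
    d <- mean(coh$beta[cur, j]) - mean(coh$beta[nev, j])
    se <- sqrt(stats::var(coh$beta[cur, j]) / sum(cur) +
                 stats::var(coh$beta[nev, j]) / sum(nev))
    expect_lt(abs(d), 3 * se)
  }
})

test_that("former-smoker shift vanishes in the long-cessation limit", {
  # tau = 4 with cessation around 40 years: expected shift -0.15 * e^-10 ~ 0
  panel <- cpg_spec("cgA", 0.7, -0.15, reversion_timescale = 4)
  p <- synthetic_params(
    n_participants = 2000,
    class_mix = c(current = 0.05, former = 0.55, never = 0.4),
    cpg_specs = panel, noise_sd_logit = 0.3, seed = 11L)
  coh <- generate_cohort(p)
  f <- coh$truth$true_status == "former" & coh$truth$cessation_years > 30
  nev <- coh$truth$true_status == "never"
  expect_gt(sum(f), 30)
  d <- mean(coh$beta[f, 1]) - mean(coh$beta[nev, 1])
  se <- sqrt(stats::var(coh$beta[f, 1]) / sum(f) +
               stats::var(coh$beta[nev, 1]) / sum(nev))
  expect_lt(abs(d), 3 * se + 0.01)
})

test_that("current-vs-never mean difference matches the logit-normal oracle", {
  # one CpG, delta -0.15, flat dose (g = 1), noise 0.3: compare the empirical
  # group difference against Monte-Carlo integration of the logit-normal mean
  panel <- cpg_spec("cgA", 0.7, -0.15)
  p <- synthetic_params(
    n_participants = 5000,
    class_mix = c(current = 0.3, former = 0.2, never = 0.5),
    cpg_specs = panel, noise_sd_logit = 0.3,
    packyear_scaling = function(py) rep(1, length(py)), seed = 3L)
  coh <- generate_cohort(p)
  set.seed(99)
  z <- stats::rnorm(1e6, 0, 0.3)
  oracle <- mean(stats::plogis(stats::qlogis(0.55) + z)) -
    mean(stats::plogis(stats::qlogis(0.70) + z))
  cur <- coh$truth$true_status == "current"
  nev <- coh$truth$true_status == "never"
  emp <- mean(coh$beta[cur, 1]) - mean(coh$beta[nev, 1])
  expect_lt(abs(emp - oracle), 0.02)
})

test_that("effect-size error shrinks with cohort size and decoys stay null", {
  err_at <- function(n) {
    p <- synthetic_params(
      n_participants = n,
      class_mix = c(current = 0.3, former = 0.2, never = 0.5),
      cpg_specs = cpg_spec("cgA", 0.7, -0.15),
      n_decoy_cpgs = 1, noise_sd_logit = 0.2,
      packyear_scaling = function(py) rep(1, length(py)), seed = 5L)
    coh <- generate_cohort(p)
    cur <- coh$truth$true_status == "current"
    nev <- coh$truth$true_status == "never"
    set.seed(123)
    z <- stats::rnorm(2e5, 0, 0.2)
    target <- mean(stats::plogis(stats::qlogis(0.55) + z)) -
      mean(stats::plogis(stats::qlogis(0.70) + z))
    c(err = abs(mean(coh$beta[cur, "cgA"]) - mean(coh$beta[nev, "cgA"]) -
                  target),
      decoy = mean(coh$beta[cur, 2]) - mean(coh$beta[nev, 2]))
  }
  small <- err_at(500)
  big <- err_at(5000)
  expect_lt(big["err"], small["err"] + 0.003)
  expect_lt(abs(big["decoy"]), 0.01)
})

test_that("decoy CpGs pass a permutation test of no association", {
  ok <- 0L
  for (s in 1:10) {
    p <- quick_params(n = 300, seed = 100L + s, deltas = -0.15, n_decoy = 1)
    coh <- generate_cohort(p)
    y <- coh$truth$true_status == "current"
    obs <- abs(mean(coh$beta[y, 2]) - mean(coh$beta[!y, 2]))
    set.seed(s)
    null <- replicate(200, {
      yp <- sample(y)
      abs(mean(coh$beta[yp, 2]) - mean(coh$beta[!yp, 2]))
    })
    if (mean(null >= obs) > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 7L)
})

test_that("misreporting moves questionnaire status but not cotinine", {
  p <- quick_params(n = 2000, seed = 21L)
  coh <- generate_cohort(p)
  mis <- coh$truth$misreported
  expect_gt(sum(mis), 0)
  expect_true(all(coh$pheno$status[mis] == "never"))
  expect_true(all(coh$truth$true_status[mis] == "current"))
  # cotinine concentrates above 50 ng/mL in true smokers, below in others
  expect_gt(mean(coh$pheno$cotinine[coh$truth$true_status == "current"] > 50),
            0.9)
  expect_lt(mean(coh$pheno$cotinine[coh$truth$true_status != "current"] > 50),
            0.05)
})

test_that("child cohorts carry exposure codings and attenuation by construction", {
  n <- 400
  set.seed(8)
  mat <- data.frame(
    sustained = rep(c(TRUE, FALSE), c(100, 300)),
    stopped_when_aware = FALSE,
    passive = FALSE
  )
  p <- quick_params(n = n, seed = 9L, deltas = -0.2, n_decoy = 0, noise = 0.2)
  coh <- generate_child_cohort(p, mat, tissue = "peripheral",
                               attenuation = c(sustained = 0.5,
                                               stopped = 0.2, passive = 0))
  expect_true(all(c("mother_sustained", "household_passive") %in%
                    names(coh$pheno)))
  exp_shift <- 0.5 * -0.2
  d <- mean(coh$beta[mat$sustained, 1]) - mean(coh$beta[!mat$sustained, 1])
  expect_lt(abs(d - exp_shift), 0.03)
  expect_error(generate_child_cohort(p, mat[, 1, drop = FALSE]),
               "columns")
})

test_that("offset-free children of never-smoking mothers look like adult never smokers", {
  n <- 300
  mat <- data.frame(sustained = rep(FALSE, n), stopped_when_aware = FALSE,
                    passive = FALSE)
  p <- quick_params(n = n, seed = 31L, deltas = -0.2, n_decoy = 0)
  child <- generate_child_cohort(p, mat, tissue = "peripheral")
  adult <- generate_cohort(quick_params(n = 1000, seed = 32L, deltas = -0.2,
                                        n_decoy = 0))
  nev <- adult$truth$true_status == "never"
  pv <- stats::t.test(child$beta[, 1], adult$beta[nev, 1])$p.value
  expect_gt(pv, 0.05 / ncol(child$beta))
})
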