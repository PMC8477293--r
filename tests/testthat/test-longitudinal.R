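# Mixed between/within ANOVA engine: oracle equivalence, SS conservation,
# covariate adjustment, elapsed-time and medication designs.

test_that("constant responses produce zero effect sums of squares", {
  d <- balanced_rm_fixture()
  d$value <- 7
  r <- rm_anova(d, 5)
  expect_true(all(r$sum_sq < 1e-20))
})

test_that("balanced fixture matches the cell-means oracle to 1e-8", {
  d <- balanced_rm_fixture(n_per_group = 4, k = 5, seed = 42)
  r <- rm_anova(d, 5)
  o <- cell_means_anova_oracle(d, 5)
  g <- function(e) r$sum_sq[r$effect == e]
  expect_equal(g("diagnosis"), o$diagnosis, tolerance = 1e-8)
  expect_equal(g("subjects(error)"), o$subjects, tolerance = 1e-8)
  expect_equal(g("repetition"), o$repetition, tolerance = 1e-8)
  expect_equal(g("diagnosis:repetition"), o$interaction, tolerance = 1e-8)
  expect_equal(g("repetition:subjects(error)"), o$error, tolerance = 1e-8)
})

test_that("effect table agrees with the aov error-stratum oracle", {
  for (seed in c(42, 43)) {
    d <- balanced_rm_fixture(n_per_group = 5, k = 5, seed = seed)
    r <- rm_anova(d, 5)
    a <- summary(aov(value ~ diagnosis * factor(repetition_index) +
                       Error(factor(subject_id)), data = d))
    ab <- a[[1]][[1]]; aw <- a[[2]][[1]]
    expect_equal(r$sum_sq[r$effect == "diagnosis"], ab$`Sum Sq`[1],
                 tolerance = 1e-10)
    expect_equal(r$F[r$effect == "diagnosis"], ab$`F value`[1],
                 tolerance = 1e-10)
    expect_equal(r$F[r$effect == "repetition"], aw$`F value`[1],
                 tolerance = 1e-10)
    expect_equal(r$F[r$effect == "diagnosis:repetition"], aw$`F value`[2],
                 tolerance = 1e-10)
    expect_equal(r$p[r$effect == "repetition"], aw$`Pr(>F)`[1],
                 tolerance = 1e-10)
  }
})

test_that("unbalanced group sizes still match aov and conserve SS", {
  set.seed(44)
  d <- expand.grid(subject_id = sprintf("s%02d", 1:11),
                   repetition_index = 1:5, stringsAsFactors = FALSE)
  d$diagnosis <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 4,
                        "PD", "HC")
  d$value <- rnorm(55) + 0.4 * (d$diagnosis == "PD")
  r <- rm_anova(d, 5)
  a <- summary(aov(value ~ diagnosis * factor(repetition_index) +
                     Error(factor(subject_id)), data = d))
  expect_equal(r$F[r$effect == "diagnosis"], a[[1]][[1]]$`F value`[1],
               tolerance = 1e-10)
  expect_equal(r$F[r$effect == "diagnosis:repetition"],
               a[[2]][[1]]$`F value`[2], tolerance = 1e-10)
  # SS conservation against the raw total
  ss_tot <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(r$sum_sq), ss_tot, tolerance = 1e-8 * ss_tot)
})

test_that("incomplete profiles are dropped and logged", {
  d <- balanced_rm_fixture(n_per_group = 4)
  d <- d[!(d$subject_id == "s01" & d$repetition_index == 3), ]
  r <- rm_anova(d, 5)
  expect_equal(attr(r, "dropped_subjects"), "s01")
  expect_equal(r$df[r$effect == "subjects(error)"], 5)
})

test_that("covariates orthogonal to the design leave the SS unchanged", {
  d <- balanced_rm_fixture(n_per_group = 6, k = 5, seed = 45)
  subj <- unique(d$subject_id)
  # residualize a raw covariate against diagnosis and the subject means,
  # giving a covariate exactly orthogonal to both
  sm <- tapply(d$value, d$subject_id, mean)[subj]
  diag_s <- tapply(d$diagnosis, d$subject_id, `[`, 1)[subj]
  set.seed(45)
  age_raw <- rnorm(length(subj), 55, 8)
  age_orth <- residuals(lm(age_raw ~ diag_s + sm))
  d$age <- age_orth[match(d$subject_id, subj)]
  d$sex <- rep("male", nrow(d))
  r0 <- rm_anova(d, 5)
  expect_warning(r1 <- rm_anova_covariates(d, 5, covariates = c("age", "sex")),
                 "constant")
  # sex is constant (dropped); orthogonal age changes no sum of squares
  expect_equal(r1$sum_sq[r1$effect == "repetition"],
               r0$sum_sq[r0$effect == "repetition"], tolerance = 1e-12)
  expect_equal(r1$sum_sq[r1$effect == "diagnosis"],
               r0$sum_sq[r0$effect == "diagnosis"], tolerance = 1e-6)
  expect_equal(r1$sum_sq[r1$effect == "subjects(error)"],
               r0$sum_sq[r0$effect == "subjects(error)"], tolerance = 1e-6)
})

test_that("a group difference explained by age vanishes when adjusted", {
  # constructed confound: no true diagnosis effect, response driven by
  # age, PD subjects older
  set.seed(46)
  n <- 60
  subj <- sprintf("s%03d", seq_len(2 * n))
  diagnosis <- rep(c("PD", "HC"), each = n)
  age <- ifelse(diagnosis == "PD", rnorm(2 * n, 65, 5), rnorm(2 * n, 50, 5))
  d <- expand.grid(subject_id = subj, repetition_index = 1:5,
                   stringsAsFactors = FALSE)
  d$diagnosis <- diagnosis[match(d$subject_id, subj)]
  d$age <- age[match(d$subject_id, subj)]
  d$sex <- sample(c("male", "female"), nrow(d), replace = TRUE)
  d$value <- 0.1 * d$age + rnorm(nrow(d))
  r0 <- rm_anova(d, 5)
  r1 <- rm_anova_covariates(d, 5)
  f0 <- r0$F[r0$effect == "diagnosis"]
  f1 <- r1$F[r1$effect == "diagnosis"]
  expect_lt(f1, f0 / 5)
  expect_lt(r0$p[r0$effect == "diagnosis"], 1e-6)
  # oracle: residual-based recomputation on subject means
  sm <- tapply(d$value, d$subject_id, mean)[subj]
  sex_num <- as.numeric(factor(tapply(d$sex, d$subject_id, `[`, 1)[subj]))
  fit_red <- lm(sm ~ age + sex_num)
  fit_full <- lm(sm ~ age + sex_num + diagnosis)
  ss_diag <- (deviance(fit_red) - deviance(fit_full)) * 5
  expect_equal(r1$sum_sq[r1$effect == "diagnosis"], ss_diag,
               tolerance = 1e-8)
})

test_that("elapsed-time regressor detects an injected common slope", {
  set.seed(47)
  n <- 50
  subj <- sprintf("s%03d", seq_len(2 * n))
  diagnosis <- rep(c("PD", "HC"), each = n)
  rows <- purrr::map(seq_along(subj), function(i) {
    hrs <- sort(runif(5, 0, 400))
    tibble::tibble(subject_id = subj[i], diagnosis = diagnosis[i],
                   age = 55, sex = c("male", "female")[1 + i %% 2],
                   elapsed_hours = hrs,
                   value = 0.005 * hrs + rnorm(5, 0, 0.5) + rnorm(1, 0, 0.5))
  })
  d <- dplyr::bind_rows(rows)
  d$age <- d$age + rnorm(nrow(d), 0, 3)
  r <- elapsed_time_model(d)
  expect_lt(r$p[r$effect == "time"], 1e-6)
  # slope direction recoverable from the within-stratum projection
  expect_gt(r$F[r$effect == "time"], r$F[r$effect == "diagnosis:time"])
  # null slope: F near 1 in expectation
  d0 <- d; d0$value <- rnorm(nrow(d0))
  r0 <- elapsed_time_model(d0)
  expect_lt(r0$F[r0$effect == "time"], 6)
})

test_that("medication model matches the repeated-measures aov oracle", {
  set.seed(48)
  d <- expand.grid(subject_id = sprintf("s%d", 1:5),
                   medication_state = c("before", "after", "best"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(15) + 0.6 * (d$medication_state == "after")
  r <- medication_model(d)
  a <- summary(aov(value ~ medication_state + Error(subject_id), data = d))
  expect_equal(r$F[r$effect == "medication"], a[[2]][[1]]$`F value`[1],
               tolerance = 1e-10)
  expect_equal(r$sum_sq[r$effect == "medication"],
               a[[2]][[1]]$`Sum Sq`[1], tolerance = 1e-10)
  # identical values across states: zero medication SS
  d2 <- d; d2$value <- rep(rnorm(5), 3)
  r2 <- medication_model(d2)
  expect_lt(r2$sum_sq[r2$effect == "medication"], 1e-20)
  # SS conservation
  ss_tot <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(r$sum_sq), ss_tot, tolerance = 1e-10)
  # missing state -> subject excluded and logged
  d3 <- d[!(d$subject_id == "s1" & d$medication_state == "best"), ]
  r3 <- medication_model(d3)
  expect_equal(attr(r3, "dropped_subjects"), "s1")
})

test_that("Greenhouse-Geisser epsilon is bounded and reacts to sphericity", {
  set.seed(49)
  # compound-symmetric data: epsilon near 1
  prof_cs <- matrix(rnorm(200 * 4), 200, 4) + rnorm(200)
  eps_cs <- gg_epsilon(prof_cs)
  expect_gt(eps_cs, 0.9); expect_lte(eps_cs, 1)
  # strongly heteroscedastic correlated levels: epsilon well below 1
  b <- rnorm(200)
  prof_ns <- cbind(b + rnorm(200, 0, 0.1), b + rnorm(200, 0, 0.1),
                   rnorm(200, 0, 3), rnorm(200, 0, 3))
  expect_lt(gg_epsilon(prof_ns), 0.8)
  expect_gte(gg_epsilon(prof_ns), 1 / 3)
  # for clearly significant effects the corrected p is the weaker one
  d <- balanced_rm_fixture(n_per_group = 5, seed = 50, rep_slope = 0.8)
  r <- rm_anova(d, 5)
  within <- r[r$effect %in% c("repetition", "diagnosis:repetition") &
                !is.na(r$F) & r$F > 2, ]
  expect_gt(nrow(within), 0)
  expect_true(all(within$p_gg >= within$p - 1e-12))
})
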