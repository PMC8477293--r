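# Screening statistics, redundancy filtering, ICC and pairing schemes.

test_that("Mann-Whitney handles separation, exchangeability and ties", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(rep(1, 5), rep(1, 6))$p_value, 1)
  # exact p for {1,2,3} vs {2,3,4} against the permutation oracle
  mw <- mann_whitney(c(1, 2, 3), c(2, 3, 4))
  expect_equal(mw$p_value, mw_permutation_oracle(c(1, 2, 3), c(2, 3, 4)))
})

test_that("exact enumeration agrees with oracles across small sizes", {
  set.seed(14)
  for (n1 in c(2, 4, 6, 8)) for (n2 in c(3, 5, 8)) {
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2, 0.4), 1)
    expect_equal(mann_whitney(x, y)$p_value, mw_permutation_oracle(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
  # tie-free case agrees with the exact rank-sum distribution
  x <- c(0.3, 1.7, 2.9); y <- c(0.8, 2.2, 3.6, 4.1)
  expect_equal(mann_whitney(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("large-sample approximation tracks wilcox.test", {
  set.seed(15)
  x <- rnorm(40); y <- rnorm(45, 0.3)
  expect_equal(mann_whitney(x, y)$p_value,
               wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("Cohen d matches the pooled-SD hand formula", {
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohen_d(c(0, 1), c(1, 2)), -1 / sqrt(0.5), tolerance = 1e-12)
  expect_true(is.na(cohen_d(c(1, 1), c(1, 1))))
})

test_that("redundancy filtering collapses correlated cliques", {
  set.seed(16)
  n <- 60
  base <- rnorm(n)
  m <- cbind(A = base, B = base + rnorm(n, 0, 1e-4),
             C = rank(base) + rnorm(n, 0, 1e-4),
             D = rnorm(n), E = rnorm(n), const = rep(1, n))
  kept <- dedup_features(m, rho_max = 0.95, seed = 1)
  # the {A,B,C} clique collapses to exactly one member
  expect_equal(sum(c("A", "B", "C") %in% kept), 1)
  expect_true(all(c("D", "E") %in% kept))
  # constant feature retained and logged
  expect_true("const" %in% kept)
  expect_equal(attr(kept, "constant"), "const")
  # post-hoc audit: no retained non-constant pair above the threshold
  act <- setdiff(kept, attr(kept, "constant"))
  rho <- cor(m[, act], method = "spearman")
  expect_true(all(rho[upper.tri(rho)] <= 0.95))
  # deterministic under the seed
  expect_identical(as.character(kept),
                   as.character(dedup_features(m, seed = 1)))
  # independent features all retained
  m2 <- matrix(rnorm(300), ncol = 3,
               dimnames = list(NULL, c("x", "y", "z")))
  expect_setequal(as.character(dedup_features(m2, seed = 1)),
                  c("x", "y", "z"))
})

test_that("ICC(1,1) matches the one-way ANOVA hand decomposition", {
  # distinct identical pairs: MSW = 0 -> ICC = 1
  v <- c(1, 2, 3, 4, 5)
  expect_equal(icc_1_1(v, v), 1)
  # 6-pair fixture against a hand MSB/MSW computation
  m1 <- c(7.1, 5.2, 9.8, 6.4, 8.0, 5.9)
  m2 <- c(6.8, 5.6, 9.1, 6.9, 8.4, 5.3)
  n <- 6; k <- 2
  rm_ <- (m1 + m2) / 2
  grand <- mean(c(m1, m2))
  msb <- k * sum((rm_ - grand)^2) / (n - 1)
  msw <- sum((m1 - rm_)^2 + (m2 - rm_)^2) / n
  expect_equal(icc_1_1(m1, m2), (msb - msw) / (msb + msw),
               tolerance = 1e-12)
  # independent pairs: ICC near 0
  set.seed(18)
  expect_lt(abs(icc_1_1(rnorm(2000), rnorm(2000))), 0.05)
  # degenerate cases
  expect_true(is.na(icc_1_1(c(1, 2), c(1, 2))))
  expect_true(is.na(icc_1_1(rep(1, 5), rep(1, 5))))
})

test_that("ICC approaches the Pearson correlation for exchangeable pairs", {
  set.seed(19)
  b <- rnorm(5000, 0, 1)
  m1 <- b + rnorm(5000, 0, 1)
  m2 <- b + rnorm(5000, 0, 1)
  expect_lt(abs(icc_1_1(m1, m2) - cor(m1, m2)), 0.02)
})

test_that("ICC bands follow the interpretation cut-points", {
  iccs <- c(-0.2, 0, 0.39, 0.40, 0.59, 0.60, 0.74, 0.75, 1)
  expect_equal(as.character(icc_band(iccs)),
               c("poor", "poor", "poor", "fair", "fair", "good", "good",
                 "excellent", "excellent"))
})

test_that("pairing schemes pick the first qualifying retest per window", {
  fv <- tibble::tibble(
    subject_id = c("A", "A", "A", "B"),
    value = c(10, 11, 12, 5),
    repetition_index = c(1, 2, 3, 1),
    elapsed_hours = c(0, 3, 29, 0))
  sch <- pairing_schemes()
  hour <- build_pairs(fv, sch$hour)
  expect_equal(hour$subject_id, "A")
  expect_equal(hour$m2, 11)          # record at 3 h
  day <- build_pairs(fv, sch$day)
  expect_equal(day$m2, 12)           # record at 29 h
  expect_equal(nrow(build_pairs(fv, sch$week)), 0)
  # subject with baseline only contributes nowhere
  expect_false("B" %in% hour$subject_id)
  # repetition scheme pairs baseline with the k-th repetition
  r2 <- build_pairs(fv, sch$rep2)
  expect_equal(r2$m1, 10); expect_equal(r2$m2, 11)
  # records at 0 and 3 h only: contributes to "hour" only
  fv2 <- fv[fv$subject_id == "A" & fv$repetition_index <= 2, ]
  expect_equal(nrow(build_pairs(fv2, sch$hour)), 1)
  expect_equal(nrow(build_pairs(fv2, sch$day)), 0)
})

test_that("time windows are disjoint and cover an hour to a month", {
  sch <- pairing_schemes()
  wins <- do.call(rbind, lapply(sch[c("hour", "day", "week", "month")],
                                function(s) s$window))
  expect_true(all(wins[-1, 1] == wins[-nrow(wins), 2]))
})

test_that("top-feature selection labels PD/HC/common and honours ties", {
  set.seed(20)
  feats <- sprintf("f%02d", 1:20)
  # construct per-feature median targets: PD ranks = index order;
  # HC ranks shifted so top-10 sets overlap in 8 features
  icc_pd <- seq(0.95, 0.05, length.out = 20)
  icc_hc <- icc_pd[c(3:20, 1:2)]
  rows <- list()
  for (s in names(pairing_schemes())) {
    fam <- pairing_schemes()[[s]]$family
    rows[[s]] <- tibble::tibble(
      feature = feats, group = "PD", scheme = s, family = fam,
      icc = icc_pd, n_pairs = 50)
    rows[[paste0(s, "hc")]] <- tibble::tibble(
      feature = feats, group = "HC", scheme = s, family = fam,
      icc = icc_hc, n_pairs = 50)
  }
  icc_res <- dplyr::bind_rows(rows)
  top <- select_top_features(icc_res, k = 10)
  tt <- top[top$family == "time", ]
  pd_top <- feats[1:10]
  hc_top <- feats[order(-icc_hc)][1:10]
  expect_setequal(tt$feature, union(pd_top, hc_top))
  expect_setequal(tt$feature[tt$label == "common"],
                  intersect(pd_top, hc_top))
  expect_equal(sum(tt$label == "common"), 8)
  expect_equal(nrow(tt), 12)
  # all-equal ICCs: the tie rule includes every feature
  icc_tie <- icc_res; icc_tie$icc <- 0.5
  top_tie <- select_top_features(icc_tie, k = 10)
  expect_equal(nrow(top_tie[top_tie$family == "time", ]), 20)
})

test_that("screening flags the features with true group shifts", {
  cfg <- sim_config(n_pd = 80, n_hc = 80, recordings_per_subject = 2,
                    group_shift = c(f1 = 1.2, f2 = 0), var_between = 0.5,
                    var_within = 0.5, features = c("f1", "f2"), seed = 23)
  ft <- simulate_feature_table(cfg)
  sc <- screen_features(ft)
  expect_true(sc$significant[sc$feature == "f1"])
  expect_gt(sc$cohen_d[sc$feature == "f1"], 0.6)
  expect_equal(sc$n_pd[1], 80)
})
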