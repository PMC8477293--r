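#' Mann-Whitney U test for baseline group screening
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test comparing two
#' independent groups. For small samples (both groups of size 8 or less)
#' the exact null distribution of U is enumerated over all group
#' assignments of the pooled values, which remains valid under ties; for
#' larger samples a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y numeric vectors of feature values for the two groups
#' @param exact_max largest per-group size at which the exact enumeration
#'   is used (default 8)
#' @return list with `U` (statistic for `x` relative to `y`), `p_value`,
#'   `method`, and the group sizes
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop_bad_arg("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    cum_r <- r
    u_all <- colSums(matrix(cum_r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(u_all - n1 * n2 / 2)
    p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-12)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(U = U, p_value = 1, method = "degenerate", n1 = n1, n2 = n2))
    }
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y))` divided by the pooled standard deviation
#' (degrees-of-freedom weighted, n-1 denominators).
#'
#' @param x,y numeric vectors, each with at least 2 finite values
#' @return numeric d, or `NA` when the pooled SD is zero
#' @export
cohen_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_bad_arg("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Baseline screening of a feature table
#'
#' Runs the Mann-Whitney test and Cohen's d on baseline (first-repetition)
#' values of every feature, PD versus HC.
#'
#' @param feature_table long-format tibble with columns `subject_id`,
#'   `diagnosis`, `feature`, `value`, `repetition_index`
#' @param alpha significance level for the `significant` flag (default .05,
#'   uncorrected; set `p_adjust_method` for a multiplicity correction)
#' @param p_adjust_method passed to [stats::p.adjust()]; default `"none"`
#' @return tibble with one row per feature: `feature`, `U`, `p_value`,
#'   `cohen_d`, `n_pd`, `n_hc`, `significant`
#' @export
screen_features <- function(feature_table, alpha = 0.05,
                            p_adjust_method = "none") {
  stopifnot(all(c("subject_id", "diagnosis", "feature", "value",
                  "repetition_index") %in% names(feature_table)))
  base <- dplyr::filter(feature_table, .data$repetition_index == 1L)
  res <- base |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      xs <- d$value[d$diagnosis == "PD"]
      ys <- d$value[d$diagnosis == "HC"]
      xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
      if (length(xs) < 2 || length(ys) < 2) {
        return(tibble::tibble(U = NA_real_, p_value = NA_real_,
                              cohen_d = NA_real_,
                              n_pd = length(xs), n_hc = length(ys)))
      }
      mw <- mann_whitney(xs, ys)
      tibble::tibble(U = mw$U, p_value = mw$p_value,
                     cohen_d = cohen_d(xs, ys),
                     n_pd = length(xs), n_hc = length(ys))
    }) |>
    dplyr::ungroup()
  res$p_adj <- stats::p.adjust(res$p_value, method = p_adjust_method)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Redundancy filtering of highly correlated features
#'
#' Features whose baseline values share the same variance (pairwise
#' Spearman correlation above `rho_max`) carry redundant information.
#' An undirected graph is built with an edge for every pair exceeding
#' `rho_max` (pairwise-complete observations); within each connected
#' component one member is retained, chosen by a seeded uniform draw.
#' Constant features, for which the correlation is undefined, are retained
#' and listed in the `constant` attribute of the result.
#'
#' @param baseline_matrix numeric matrix, rows = subjects (baseline
#'   records), columns = features
#' @param rho_max correlation threshold (default 0.95)
#' @param seed integer seed for the per-component draw
#' @return character vector of retained feature names, with attributes
#'   `dropped` (named by the surviving representative) and `constant`
#' @export
dedup_features <- function(baseline_matrix, rho_max = 0.95, seed = 1L) {
  stopifnot(is.matrix(baseline_matrix) || is.data.frame(baseline_matrix))
  m <- as.matrix(baseline_matrix)
  feats <- colnames(m)
  if (is.null(feats)) stop_bad_arg("baseline_matrix must have column names")
  sds <- apply(m, 2, function(v) sd(v, na.rm = TRUE))
  constant <- feats[!is.na(sds) & sds == 0 | is.na(sds)]
  active <- setdiff(feats, constant)
  if (length(active) < 2) {
    out <- feats
    attr(out, "dropped") <- character(0)
    attr(out, "constant") <- constant
    return(out)
  }
  rho <- suppressWarnings(
    cor(m[, active, drop = FALSE], method = "spearman",
        use = "pairwise.complete.obs"))
  adj <- !is.na(rho) & rho > rho_max
  diag(adj) <- FALSE
  # union-find over the thresholded correlation graph
  parent <- seq_along(active)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(active)) {
    for (j in which(adj[i, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_along(active), find, integer(1))
  keep <- character(0); dropped <- character(0)
  with_seed(child_seed(seed, "dedup"), {
    for (cid in unique(comp)) {
      members <- active[comp == cid]
      pick <- if (length(members) == 1) members else
        members[sample.int(length(members), 1)]
      keep <- c(keep, pick)
      drp <- setdiff(members, pick)
      if (length(drp)) {
        names(drp) <- rep(pick, length(drp))
        dropped <- c(dropped, drp)
      }
    }
  })
  out <- c(keep, constant)
  out <- feats[feats %in% out]  # original column order
  attr(out, "dropped") <- dropped
  attr(out, "constant") <- constant
  out
}

#' Intraclass correlation, type (1,1)
#'
#' One-way random-effects, single-measurement ICC:
#' `(MSB - MSW) / (MSB + (k-1) MSW)` with `k = 2` for test-retest pairs,
#' where MSB and MSW are the between- and within-subject mean squares of a
#' one-way ANOVA treating subjects as the random grouping factor.
#'
#' @param m1,m2 numeric vectors: first and second measurement per subject
#' @return ICC in `[-1, 1]`, or `NA` if fewer than 3 complete pairs or the
#'   data are fully degenerate (MSB = MSW = 0)
#' @export
icc_1_1 <- function(m1, m2) {
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  n <- length(m1)
  if (n < 3) return(NA_real_)
  k <- 2
  row_means <- (m1 + m2) / 2
  grand <- mean(c(m1, m2))
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m1 - row_means)^2 + (m2 - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) return(NA_real_)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' ICC interpretation band
#'
#' Maps an ICC value to the conventional qualitative band:
#' below 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good, 0.75-1.00 excellent.
#' Negative ICC values are poor.
#'
#' @param icc numeric vector of ICC values
#' @return factor with levels poor/fair/good/excellent
#' @export
icc_band <- function(icc) {
  band <- ifelse(is.na(icc), NA_character_,
          ifelse(icc < 0.40, "poor",
          ifelse(icc < 0.60, "fair",
          ifelse(icc < 0.75, "good", "excellent"))))
  factor(band, levels = c("poor", "fair", "good", "excellent"))
}

#' Pairing schemes for test-retest reliability
#'
#' The eight retest pairing schemes: four time-lag windows of elapsed hours
#' from baseline (hour `(0, 6]`, day `(6, 36]`, week `(36 h, 8 d]`, month
#' `(8 d, 45 d]`) and four repetition pairings (baseline versus repetition
#' 2, 3, 4, 5). For a time scheme a subject contributes their baseline
#' paired with their first record whose elapsed time falls in the window;
#' for a repetition scheme, the baseline paired with the k-th repetition.
#'
#' @return named list of scheme definitions with elements `name`,
#'   `family` ("time" or "repetition") and either `window` (hours,
#'   half-open `(lo, hi]`) or `rep` (repetition index)
#' @export
pairing_schemes <- function() {
  list(
    hour  = list(name = "hour",  family = "time", window = c(0, 6)),
    day   = list(name = "day",   family = "time", window = c(6, 36)),
    week  = list(name = "week",  family = "time", window = c(36, 8 * 24)),
    month = list(name = "month", family = "time", window = c(8 * 24, 45 * 24)),
    rep2  = list(name = "rep2",  family = "repetition", rep = 2L),
    rep3  = list(name = "rep3",  family = "repetition", rep = 3L),
    rep4  = list(name = "rep4",  family = "repetition", rep = 4L),
    rep5  = list(name = "rep5",  family = "repetition", rep = 5L)
  )
}

#' Build baseline/retest pairs for one feature under one scheme
#'
#' @param feature_values tibble with columns `subject_id`, `value`,
#'   `repetition_index`, `elapsed_hours` for a single feature (and group)
#' @param scheme one element of [pairing_schemes()]
#' @return tibble with columns `subject_id`, `m1` (baseline), `m2` (retest);
#'   subjects without a qualifying retest are skipped
#' @export
build_pairs <- function(feature_values, scheme) {
  stopifnot(all(c("subject_id", "value", "repetition_index",
                  "elapsed_hours") %in% names(feature_values)))
  d <- dplyr::arrange(feature_values, .data$subject_id,
                      .data$repetition_index)
  base <- d[d$repetition_index == 1L, c("subject_id", "value")]
  names(base)[2] <- "m1"
  if (identical(scheme$family, "time")) {
    lo <- scheme$window[1]; hi <- scheme$window[2]
    retest <- d |>
      dplyr::filter(.data$elapsed_hours > lo, .data$elapsed_hours <= hi) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::slice_min(.data$elapsed_hours, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    retest <- d[d$repetition_index == scheme$rep, , drop = FALSE]
  }
  retest <- retest[, c("subject_id", "value")]
  names(retest)[2] <- "m2"
  out <- dplyr::inner_join(base, retest, by = "subject_id")
  out[is.finite(out$m1) & is.finite(out$m2), , drop = FALSE]
}

#' ICC(1,1) across all pairing schemes, per feature and group
#'
#' @param feature_table long-format tibble with `subject_id`, `diagnosis`,
#'   `feature`, `value`, `repetition_index`, `elapsed_hours`
#' @param features optional character vector restricting the features
#'   (e.g. those passing the baseline screen)
#' @param min_pairs minimum number of complete pairs (default 3)
#' @return tibble: `feature`, `group`, `scheme`, `family`, `icc`,
#'   `n_pairs`, `band`
#' @export
icc_by_scheme <- function(feature_table, features = NULL, min_pairs = 3) {
  if (!is.null(features))
    feature_table <- feature_table[feature_table$feature %in% features, ]
  schemes <- pairing_schemes()
  empty <- tibble::tibble(feature = character(0), group = character(0),
                          scheme = character(0), family = character(0),
                          icc = numeric(0), n_pairs = integer(0),
                          band = icc_band(numeric(0)))
  if (!nrow(feature_table)) return(empty)
  grid <- expand.grid(feature = unique(feature_table$feature),
                      group = c("PD", "HC"),
                      scheme = names(schemes),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(feature, group, scheme) {
    sub <- feature_table[feature_table$feature == feature &
                         feature_table$diagnosis == group, ]
    pr <- build_pairs(sub, schemes[[scheme]])
    icc <- if (nrow(pr) >= min_pairs) icc_1_1(pr$m1, pr$m2) else NA_real_
    tibble::tibble(feature = feature, group = group, scheme = scheme,
                   family = schemes[[scheme]]$family,
                   icc = icc, n_pairs = nrow(pr))
  })
  out <- dplyr::bind_rows(rows)
  out$band <- icc_band(out$icc)
  out
}

#' Select the most reliable features by median ICC
#'
#' Within each scheme family (time lags, repetitions) and group, features
#' are ranked by their median ICC across the family's four schemes; the top
#' `k` per group are taken and the union across groups is labelled
#' PD-only / HC-only / common. Features tied with the k-th ranked median
#' are all included.
#'
#' @param icc_results output of [icc_by_scheme()]
#' @param k number of features per group (default 10)
#' @return tibble: `feature`, `family`, `label`, `median_icc_pd`,
#'   `median_icc_hc`
#' @export
select_top_features <- function(icc_results, k = 10) {
  empty <- tibble::tibble(feature = character(0), family = character(0),
                          label = character(0),
                          median_icc_pd = numeric(0),
                          median_icc_hc = numeric(0))
  if (!nrow(icc_results)) return(empty)
  med <- icc_results |>
    dplyr::group_by(.data$feature, .data$group, .data$family) |>
    dplyr::summarise(median_icc = median(.data$icc, na.rm = TRUE),
                     .groups = "drop")
  fams <- unique(med$family)
  out <- purrr::map(fams, function(fam) {
    m <- med[med$family == fam & is.finite(med$median_icc), ]
    top_of <- function(grp) {
      g <- m[m$group == grp, ]
      g <- g[order(-g$median_icc), ]
      if (nrow(g) <= k) return(g$feature)
      thresh <- g$median_icc[k]
      g$feature[g$median_icc >= thresh]   # ties at rank k all included
    }
    pd <- top_of("PD"); hc <- top_of("HC")
    union_f <- union(pd, hc)
    lab <- ifelse(union_f %in% pd & union_f %in% hc, "common",
                  ifelse(union_f %in% pd, "PD", "HC"))
    med_pd <- m$median_icc[match(union_f, m$feature[m$group == "PD"])]
    mp <- m[m$group == "PD", ]; mh <- m[m$group == "HC", ]
    tibble::tibble(feature = union_f, family = fam, label = lab,
                   median_icc_pd = mp$median_icc[match(union_f, mp$feature)],
                   median_icc_hc = mh$median_icc[match(union_f, mh$feature)])
  })
  dplyr::bind_rows(out)
}
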