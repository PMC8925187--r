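small_params <- function(...) {
  synthetic_params(n_participants = 120, cluster_sizes = c(3, 3),
                   n_noise = 2, ...)
}

test_that("same seed reproduces the cohort exactly", {
  c1 <- generate_cohort(small_params(seed = 7))
  c2 <- generate_cohort(small_params(seed = 7))
  expect_identical(c1$survey, c2$survey)
  expect_identical(c1$cord_table, c2$cord_table)
  expect_identical(c1$biomarker_table, c2$biomarker_table)
  c3 <- generate_cohort(small_params(seed = 8))
  expect_false(identical(c1$survey, c3$survey))
})

test_that("generated cohorts satisfy the declared invariants", {
  co <- generate_cohort(small_params(seed = 3))
  sym <- symptom_columns(co$survey)
  vals <- unlist(co$survey[, sym])
  expect_true(all(vals[!is.na(vals)] %in% 1:5))
  expect_true(any(is.na(vals)))                       # MCAR holes exist
  expect_true(all(co$biomarker_table$value > 0))
  cord <- co$cord_table$cord_hg_ugL
  expect_true(all(cord[!is.na(cord)] > 0))
  expect_setequal(names(co$truth$partition), sym)
  # configuration errors
  expect_error(synthetic_params(cluster_sizes = c(1, 5)))
  expect_error(synthetic_params(thresholds = c(0, -1, 1, 2)),
               "increasing")
})

test_that("null exposure effect leaves factors uncorrelated with mercury", {
  co <- generate_cohort(synthetic_params(n_participants = 1000,
                                         cluster_sizes = c(4, 4),
                                         n_noise = 0, beta_hg = 0,
                                         beta_mediator = 0, beta_nd = 0,
                                         covariate_effects = c(age_z = 0),
                                         seed = 11))
  z <- log10(co$truth$childhood_true)
  for (k in 1:2) {
    expect_lt(abs(cor(co$truth$factor_scores[, k], z)), 0.1)
  }
})

test_that("positive exposure effect yields positive rank correlation with scores", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_params(n_participants = 500,
                                           cluster_sizes = c(4, 4),
                                           n_noise = 0, beta_hg = 0.3,
                                           missing_rate = 0, seed = s))
    sol <- composite_scores(likert_matrix(co$survey[, symptom_columns(co$survey)]),
                            co$truth$partition)
    cor(co$truth$childhood_true, sol$composite_scores[, 1],
        method = "spearman") > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("within-cluster inter-item correlations match the one-factor closed form", {
  # continuous scores: corr(item_i, item_j) = lambda_i * lambda_j, so with
  # loadings in [0.8, 0.9] every pair lies in [0.64, 0.81]
  rs <- unlist(lapply(1:5, function(s) {
    co <- generate_cohort(synthetic_params(n_participants = 500,
                                           cluster_sizes = c(5, 5),
                                           n_noise = 0,
                                           loading_range = c(0.8, 0.9),
                                           seed = s))
    cont <- co$truth$continuous
    unlist(lapply(1:2, function(k) {
      mem <- names(co$truth$partition)[co$truth$partition == k]
      R <- cor(cont[, mem])
      R[lower.tri(R)]
    }))
  }))
  expect_gt(mean(rs), 0.64 - 0.03)
  expect_lt(mean(rs), 0.81 + 0.03)
  expect_gt(min(rs), 0.45)   # individual pairs within sampling noise
})

test_that("Likert margins follow the threshold-implied orthant probabilities", {
  # noise symptoms are standard normal, so category frequencies are the
  # differences of Phi at the cut-points
  co <- generate_cohort(synthetic_params(n_participants = 2000,
                                         cluster_sizes = c(2, 2),
                                         n_noise = 6, missing_rate = 0,
                                         seed = 5))
  th <- co$params$thresholds
  expected <- diff(pnorm(c(-Inf, th, Inf)))
  noise_cols <- names(co$truth$partition)[co$truth$partition == 0]
  obs <- table(factor(unlist(co$survey[, noise_cols]), levels = 1:5))
  obs <- as.numeric(obs) / sum(obs)
  expect_lt(max(abs(obs - expected)), 0.02)
})

test_that("cord mercury matches the anchors at the anchor years", {
  vals <- list(y1970 = c(), y1992 = c())
  for (s in 1:4) {
    co <- generate_cohort(synthetic_params(n_participants = 600,
                                           birth_year_range = c(1968, 1994),
                                           cluster_sizes = c(2, 2),
                                           n_noise = 0, cord_obs_prob = 1,
                                           seed = s))
    ct <- co$cord_table
    vals$y1970 <- c(vals$y1970, ct$cord_hg_ugL[ct$birth_year == 1970 &
                                                 !is.na(ct$cord_hg_ugL)])
    vals$y1992 <- c(vals$y1992, ct$cord_hg_ugL[ct$birth_year == 1992 &
                                                 !is.na(ct$cord_hg_ugL)])
  }
  gm <- function(x) 10^mean(log10(x))
  expect_lt(abs(log10(gm(vals$y1970)) - log10(65.7)), 0.1)
  expect_lt(abs(log10(gm(vals$y1992)) - log10(4.48)), 0.1)
})

test_that("cohorts round-trip through write_cohort and read_cohort", {
  co <- generate_cohort(small_params(seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_length(paths, 3)
  back <- read_cohort(dir)
  expect_equal(back$survey, co$survey, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$cord_table, co$cord_table, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$biomarker_table, co$biomarker_table,
               tolerance = 1e-12, ignore_attr = TRUE)
  # missing Likert cells encoded as empty fields, count preserved
  sym <- symptom_columns(co$survey)
  expect_identical(sum(is.na(back$survey[, sym])),
                   sum(is.na(co$survey[, sym])))
})
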