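test_that("yearly series keep the highest equivalent-hair value per year", {
  ydb <- build_yearly_hair(toy_biomarkers())
  expect_equal(unname(ydb[["A"]]["1975"]), 7.0)     # max of 3.0 and 7.0
  expect_equal(unname(ydb[["A"]]["1980"]), 5.0)     # blood 20 * 0.25
  expect_equal(sort(names(ydb[["B"]])), c("1972", "1980"))
  # order invariance
  shuffled <- toy_biomarkers()[c(4, 6, 1, 3, 5, 2), ]
  expect_identical(unclass(build_yearly_hair(shuffled)), unclass(ydb))
  # unknown medium rejected with count
  bad <- rbind(toy_biomarkers(),
               data.frame(participant_id = "D", year = 1980,
                          medium = "nail", value = 1))
  ydb2 <- build_yearly_hair(bad)
  expect_equal(unname(attr(ydb2, "rejected")["medium"]), 1)
  expect_false("D" %in% names(ydb2))
  # conservation: total person-years equals sum of series lengths
  co <- generate_cohort(synthetic_params(n_participants = 150,
                                         cluster_sizes = c(2, 2),
                                         n_noise = 0, seed = 21))
  ydb3 <- build_yearly_hair(co$biomarker_table)
  py <- unique(co$biomarker_table[, c("participant_id", "year")])
  expect_equal(sum(lengths(ydb3)), nrow(py))
})

test_that("childhood mean uses ages 5 to 15 inclusive", {
  s <- c("1976" = 2.0, "1980" = 4.0)
  expect_equal(childhood_mean_hair(s, 1970), 3.0)
  late <- c("1990" = 2.0)                           # age 20
  expect_true(is.na(childhood_mean_hair(late, 1970)))
  # row-filter oracle on random series
  set.seed(22)
  for (i in 1:10) {
    yrs <- sort(sample(1970:1997, 8))
    vals <- setNames(runif(8, 0.5, 10), yrs)
    by <- sample(1955:1990, 1)
    ages <- yrs - by
    keep <- ages >= 5 & ages <= 15
    expected <- if (any(keep)) mean(vals[keep]) else NA_real_
    expect_equal(childhood_mean_hair(vals, by), expected)
  }
})

test_that("period regressions recover noiseless log-linear trends", {
  by <- rep(1970:1992, each = 3)
  slope_true <- -0.05
  cord <- data.frame(birth_year = by,
                     cord_hg_ugL = 10^(2 + slope_true * (by - 1970)))
  regs <- fit_cord_regressions(cord)
  expect_equal(nrow(regs), 3)
  expect_false(any(regs$fallback))
  expect_equal(regs$slope, rep(slope_true, 3), tolerance = 1e-6)
  # flat data
  flat <- data.frame(birth_year = by, cord_hg_ugL = rep(5, length(by)))
  expect_lt(max(abs(fit_cord_regressions(flat)$slope)), 1e-10)
  # sparse period falls back
  sparse <- cord[cord$birth_year >= 1977, ]
  regs2 <- fit_cord_regressions(sparse)
  expect_true(regs2$fallback[1])
})

test_that("the cord cascade returns the published attribution constants", {
  cord <- data.frame(participant_id = "X", birth_year = 1980,
                     cord_hg_ugL = NA_real_)
  regs <- structure(data.frame(start = c(1970, 1977, 1988),
                               end = c(1976, 1987, 1992),
                               intercept = NA_real_, slope = NA_real_,
                               n = 0, fallback = TRUE),
                    log10_scale = TRUE,
                    class = c("hg_cordreg", "data.frame"))
  e <- estimate_cord(NA, 1966, "region", cord, regs)
  expect_identical(e$value, 65.7)
  expect_identical(e$source, "era_constant")
  e <- estimate_cord(NA, 1995, "region", cord, regs)
  expect_identical(e$value, 4.48)
  e <- estimate_cord(NA, 1950, "region", cord, regs)
  expect_identical(e$value, 1.0)
  e <- estimate_cord(NA, 1985, "elsewhere", cord, regs)
  expect_identical(e$value, 1.0)
  expect_identical(e$source, "elsewhere_floor")
  # measurement always wins
  e <- estimate_cord(12.3, 1950, "elsewhere", cord, regs)
  expect_identical(e$value, 12.3)
  expect_identical(e$source, "measured")
  # unknown birth year
  e <- estimate_cord(NA, NA, "region", cord, regs)
  expect_identical(e$source, "undefined")
})

test_that("the childhood cascade returns constants, year means, and undefineds", {
  ydb <- build_yearlike <- build_yearly_hair(data.frame(
    participant_id = c("p1", "p2", "p3"),
    year = c(1975, 1975, 1975),
    medium = "hair", value = c(2, 4, 6)))
  # born <= 1952: pre-discharge constant, no fish answer needed
  e <- estimate_childhood(numeric(0), 1950, NA, 0, ydb)
  expect_identical(e$value, 0.1)
  expect_identical(e$source, "era_constant")
  # age 10 after 1990: plateau constant
  e <- estimate_childhood(numeric(0), 1983, 1, 0, ydb)
  expect_identical(e$value, 0.81)
  expect_identical(e$source, "era_constant")
  # age 10 in a measured year: cohort mean
  e <- estimate_childhood(numeric(0), 1965, 0, 0, ydb)
  expect_equal(e$value, 4)
  expect_identical(e$source, "cohort_year_mean")
  # measured childhood wins, unadjusted
  s <- c("1975" = 2.5)
  e <- estimate_childhood(s, 1965, 1, 1, ydb)
  expect_equal(e$value, 2.5)
  expect_identical(e$source, "measured")
  expect_false(e$adjusted)
  # post-1952 estimate without a fish answer is undefined
  e <- estimate_childhood(numeric(0), 1965, NA, 0, ydb)
  expect_identical(e$source, "undefined")
})

test_that("exceedance indicator uses an inclusive threshold", {
  expect_false(ever_ge5(c("1980" = 4.9)))
  expect_true(ever_ge5(c("1980" = 5.0)))
  expect_true(is.na(ever_ge5(numeric(0))))
  set.seed(23)
  for (i in 1:10) {
    s <- setNames(runif(6, 0, 10), 1980:1985)
    expect_identical(ever_ge5(s), any(s >= 5))
  }
})

test_that("estimate validation computes Spearman correlations", {
  v <- validate_estimates(1:10, (1:10)^2)
  expect_equal(v$rho, 1)
  v <- validate_estimates(1:10, -(1:10))
  expect_equal(v$rho, -1)
  expect_error(validate_estimates(1:3, 1:3), "5")
  expect_error(validate_estimates(rep(1, 8), rep(2, 8)), "ties")
})

test_that("the cascade is exhaustive, exclusive and measurement-first", {
  co <- generate_cohort(synthetic_params(n_participants = 250,
                                         cluster_sizes = c(2, 2),
                                         n_noise = 0, seed = 24))
  ex <- build_exposure_profiles(co$survey, co$cord_table,
                                co$biomarker_table)
  expect_equal(nrow(ex), 250)
  # exactly one source per participant and exposure
  expect_false(any(is.na(ex$cord_source)))
  expect_false(any(is.na(ex$childhood_source)))
  # measured values never overwritten
  meas <- !is.na(co$cord_table$cord_hg_ugL)
  idx <- match(co$cord_table$participant_id[meas], ex$participant_id)
  expect_identical(ex$cord_hg[idx], co$cord_table$cord_hg_ugL[meas])
  expect_true(all(ex$cord_source[idx] == "measured"))
  # every defined cord value respects the 1.0 ug/L floor
  expect_true(all(ex$cord_hg[!is.na(ex$cord_hg)] >= 1.0 - 1e-9))
  # childhood estimates for frequent fish eaters sit above the
  # infrequent-eater stratum (direction of the adjustment)
  est <- ex$childhood_source != "measured" & !is.na(ex$childhood_hg)
  sv <- co$survey[match(ex$participant_id, co$survey$participant_id), ]
  same_era <- sv$birth_year >= 1961 & sv$birth_year <= 1980
  grp <- est & same_era & !is.na(sv$fish_childhood)
  if (sum(grp & sv$fish_childhood == 1) > 5 &&
      sum(grp & sv$fish_childhood == 0) > 5) {
    expect_gt(mean(log10(ex$childhood_hg[grp & sv$fish_childhood == 1])),
              mean(log10(ex$childhood_hg[grp & sv$fish_childhood == 0])))
  }
})

test_that("childhood estimates track measured values more closely than cord", {
  # the ordering is a property of the regime the reconstruction faces:
  # historical cord values scatter widely around their birth-year trend
  # (printed records span 1-78.5 ug/L within the monitored window), so
  # cord estimates borrow only a weak trend, while adjusted childhood
  # estimates additionally borrow the fish-consumption/residential-school
  # strata of the measured data
  rhos <- vapply(c(25, 17, 3), function(s) {
    co <- generate_cohort(synthetic_params(seed = s, cord_sd = 0.5))
    ex <- build_exposure_profiles(co$survey, co$cord_table,
                                  co$biomarker_table)
    ydb <- attr(ex, "yearly_db")
    sv <- co$survey
    by <- sv$birth_year
    meas_child <- vapply(seq_len(nrow(sv)), function(i) {
      ss <- ydb[[sv$participant_id[i]]]
      if (is.null(ss)) return(NA_real_)
      childhood_mean_hair(ss, by[i])
    }, numeric(1))
    era <- vapply(by, hgclust:::childhood_era, character(1))
    fac <- hgclust:::childhood_adjustment_factors(
      meas_child, sv$fish_childhood, sv$residential_school, era)
    m <- which(ex$childhood_source == "measured")
    est <- vapply(m, function(i) {
      estimate_childhood(numeric(0), by[i], sv$fish_childhood[i],
                         sv$residential_school[i], ydb,
                         adjust_factors = fac)$value
    }, numeric(1))
    keep <- !is.na(est)
    v_child <- validate_estimates(ex$childhood_hg[m][keep], est[keep])
    regs <- attr(ex, "regressions")
    mc <- which(ex$cord_source == "measured")
    est_c <- vapply(mc, function(i) {
      estimate_cord(NA, by[i], sv$region_pregnancy[i],
                    co$cord_table[-match(ex$participant_id[i],
                                         co$cord_table$participant_id), ],
                    regs)$value
    }, numeric(1))
    keepc <- !is.na(est_c)
    v_cord <- validate_estimates(ex$cord_hg[mc][keepc], est_c[keepc])
    c(child = v_child$rho, cord = v_cord$rho)
  }, numeric(2))
  expect_gt(mean(rhos["child", ]), mean(rhos["cord", ]))
  expect_true(all(rhos["child", ] > 0.3))
  expect_true(all(rhos["cord", ] > 0))
})
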