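#' Era constants of the exposure-attribution rules
#'
#' The rule cascade attributes fixed exposure values to birth cohorts that
#' fall outside the measured monitoring window: 1.0 ug/L cord blood for
#' births before the 1962 discharge and for mothers who spent the pregnancy
#' elsewhere; 65.7 ug/L (the 1970 mean) for births 1962-1969; 4.48 ug/L
#' (the 1992 mean) for births after 1992; 0.1 ug/g childhood hair for
#' people who were already 10 or older in 1962; and 0.81 ug/g for people
#' who turned 10 after 1990.
#'
#' @return named list of the default constants (all overridable in the
#'   estimation functions).
#' @export
era_constants <- function() {
  list(cord_pre1962_ugL = 1.0,
       cord_1962_1969_ugL = 65.7,
       cord_post1992_ugL = 4.48,
       cord_elsewhere_ugL = 1.0,
       childhood_pre1962_ugg = 0.1,
       childhood_post1990_ugg = 0.81)
}

#' Yearly equivalent-hair mercury series
#'
#' Converts blood records to equivalent hair concentrations via a fixed
#' hair:blood ratio and keeps, for each person-year, the highest equivalent
#' hair value. Records with unknown medium are rejected and counted; the
#' result is invariant to record order.
#'
#' @param records data frame with columns `participant_id`, `year`,
#'   `medium` (`"hair"` or `"blood"`), `value` (ug/g for hair, ug/L for
#'   blood); values must be positive.
#' @param blood_to_hair ug/g equivalent hair per ug/L blood (default 0.25,
#'   i.e. a 250:1 hair-to-blood concentration ratio).
#' @param monitor_years calendar window; records outside are rejected.
#' @return named list of per-person series (each a named numeric vector,
#'   year -> ug/g), class `hg_yearlyhair`; attribute `rejected` counts
#'   dropped records.
#' @export
build_yearly_hair <- function(records, blood_to_hair = 0.25,
                              monitor_years = c(1970, 1997)) {
  stopifnot(is.data.frame(records),
            all(c("participant_id", "year", "medium", "value")
                %in% names(records)))
  ok_medium <- records$medium %in% c("hair", "blood")
  ok_value <- !is.na(records$value) & records$value > 0
  ok_year <- !is.na(records$year) & records$year >= monitor_years[1] &
    records$year <= monitor_years[2]
  keep <- ok_medium & ok_value & ok_year
  rejected <- c(medium = sum(!ok_medium), value = sum(ok_medium & !ok_value),
                year = sum(ok_medium & ok_value & !ok_year))
  r <- records[keep, , drop = FALSE]
  eq <- ifelse(r$medium == "blood", r$value * blood_to_hair, r$value)
  # per person-year maximum
  keymax <- tapply(eq, list(r$participant_id, r$year), max)
  out <- lapply(rownames(keymax), function(pid) {
    v <- keymax[pid, ]
    names(v) <- colnames(keymax)   # single-year matrices drop names
    v <- v[!is.na(v)]
    setNames(as.numeric(v), names(v))
  })
  names(out) <- rownames(keymax)
  out <- out[order(names(out))]
  structure(out, rejected = rejected, class = "hg_yearlyhair")
}

#' Mean childhood hair mercury (ages 5-15)
#'
#' Arithmetic mean of the yearly equivalent-hair values recorded while the
#' person was between 5 and 15 years of age inclusive; undefined (`NA`)
#' when no value falls in that window.
#'
#' @param series named numeric vector (year -> ug/g) for one person.
#' @param birth_year the person's birth year.
#' @return scalar ug/g or `NA`.
#' @export
childhood_mean_hair <- function(series, birth_year) {
  if (is.na(birth_year) || length(series) == 0) return(NA_real_)
  ages <- as.numeric(names(series)) - birth_year
  sel <- ages >= 5 & ages <= 15
  if (!any(sel)) return(NA_real_)
  mean(series[sel])
}

#' Period regressions of cord mercury on birth year
#'
#' Ordinary least squares of log10 cord Hg on birth year, fitted separately
#' within the three exposure eras (1970-1976, 1977-1987, 1988-1992). A
#' period with fewer than 3 observations falls back to year means and is
#' flagged.
#'
#' @param cord_table data frame with `birth_year` and `cord_hg_ugL`
#'   (missing values dropped).
#' @param periods list of `c(start, end)` year pairs.
#' @param log10_scale fit on log10 scale (default) or raw scale.
#' @return data frame of class `hg_cordreg`: one row per period with
#'   `start`, `end`, `intercept`, `slope`, `n`, `fallback`.
#' @export
fit_cord_regressions <- function(cord_table,
                                 periods = list(c(1970, 1976),
                                                c(1977, 1987),
                                                c(1988, 1992)),
                                 log10_scale = TRUE) {
  d <- cord_table[!is.na(cord_table$cord_hg_ugL), , drop = FALSE]
  stopifnot(all(d$cord_hg_ugL > 0))
  y <- if (log10_scale) log10(d$cord_hg_ugL) else d$cord_hg_ugL
  rows <- lapply(periods, function(pr) {
    sel <- d$birth_year >= pr[1] & d$birth_year <= pr[2]
    n <- sum(sel)
    if (n < 3) {
      return(data.frame(start = pr[1], end = pr[2], intercept = NA_real_,
                        slope = NA_real_, n = n, fallback = TRUE))
    }
    fit <- lm(y[sel] ~ d$birth_year[sel])
    data.frame(start = pr[1], end = pr[2],
               intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2]), n = n, fallback = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "log10_scale") <- log10_scale
  class(out) <- c("hg_cordreg", "data.frame")
  out
}

# predict cord Hg (ug/L) for a birth year from the period regressions
predict_cord <- function(regressions, birth_year) {
  r <- regressions[regressions$start <= birth_year &
                     regressions$end >= birth_year, , drop = FALSE]
  if (nrow(r) == 0 || is.na(r$slope[1])) return(NA_real_)
  v <- r$intercept[1] + r$slope[1] * birth_year
  if (isTRUE(attr(regressions, "log10_scale"))) 10^v else v
}

#' Prenatal (cord) exposure for one person: measurement-first rule cascade
#'
#' A measured umbilical-cord value always wins. Otherwise, for births in
#' the monitored window (1970-1992) whose mother stayed in the region, the
#' mean measured cord value of the birth year is used when at least
#' `min_year_n` measured births exist for that year, and the period
#' regression prediction otherwise. Births before 1962 get the pre-discharge
#' floor (1.0 ug/L); births 1962-1969 get the 1970 mean (65.7 ug/L);
#' births after 1992 get the 1992 mean (4.48 ug/L); a pregnancy spent
#' elsewhere gets 1.0 ug/L regardless of year.
#'
#' @param measured the person's measured cord value (ug/L) or `NA`.
#' @param birth_year the person's birth year (`NA` leaves the exposure
#'   undefined and flags the person).
#' @param region_flag `"region"` or `"elsewhere"` (where the mother spent
#'   the pregnancy).
#' @param cord_table cohort cord table (for year means).
#' @param regressions an [fit_cord_regressions()] result.
#' @param constants era constants, see [era_constants()].
#' @param min_year_n minimum measured births for the year-mean path.
#' @return list `value` (ug/L), `source` (one of `measured`,
#'   `region_year_mean`, `regression`, `era_constant`, `elsewhere_floor`,
#'   `undefined`).
#' @export
estimate_cord <- function(measured, birth_year, region_flag, cord_table,
                          regressions, constants = era_constants(),
                          min_year_n = 3) {
  if (!is.na(measured)) {
    return(list(value = measured, source = "measured"))
  }
  if (is.na(birth_year)) {
    return(list(value = NA_real_, source = "undefined"))
  }
  if (identical(region_flag, "elsewhere")) {
    return(list(value = constants$cord_elsewhere_ugL,
                source = "elsewhere_floor"))
  }
  if (birth_year <= 1961) {
    return(list(value = constants$cord_pre1962_ugL, source = "era_constant"))
  }
  if (birth_year <= 1969) {
    return(list(value = constants$cord_1962_1969_ugL,
                source = "era_constant"))
  }
  if (birth_year >= 1993) {
    return(list(value = constants$cord_post1992_ugL,
                source = "era_constant"))
  }
  # monitored window 1970-1992: year mean if enough measured births
  meas <- cord_table[!is.na(cord_table$cord_hg_ugL) &
                       cord_table$birth_year == birth_year, , drop = FALSE]
  if (nrow(meas) >= min_year_n) {
    return(list(value = mean(meas$cord_hg_ugL), source = "region_year_mean"))
  }
  pred <- predict_cord(regressions, birth_year)
  if (!is.na(pred)) {
    return(list(value = pred, source = "regression"))
  }
  list(value = NA_real_, source = "undefined")
}

# stratum adjustment factors for childhood estimates: ratio of the
# geometric-mean measured childhood hair Hg in the person's
# fish-consumption x residential-school stratum to the overall geometric
# mean, computed within eras when enough data, else overall
childhood_adjustment_factors <- function(measured_child, fish, resschool,
                                         era, min_n = 5) {
  ok <- !is.na(measured_child) & !is.na(fish) & !is.na(resschool)
  if (sum(ok) < min_n) return(NULL)
  lg <- log10(measured_child[ok])
  strat <- interaction(fish[ok], resschool[ok], drop = FALSE)
  overall <- mean(lg)
  per_era <- NULL
  if (!is.null(era)) {
    per_era <- tapply(seq_along(lg), list(strat, era[ok]), function(ix) {
      if (length(ix) >= min_n) 10^(mean(lg[ix]) - overall) else NA_real_
    })
  }
  glob <- tapply(lg, strat, function(v) {
    if (length(v) >= min_n) 10^(mean(v) - overall) else NA_real_
  })
  list(per_era = per_era, global = glob)
}

lookup_adjustment <- function(factors, fish, resschool, era) {
  if (is.null(factors) || is.na(fish) || is.na(resschool)) return(NA_real_)
  key <- paste(fish, resschool, sep = ".")
  f <- NA_real_
  if (!is.null(factors$per_era) && !is.na(era) &&
      era %in% colnames(factors$per_era) &&
      key %in% rownames(factors$per_era)) {
    f <- factors$per_era[key, era]
  }
  if (is.na(f) && key %in% names(factors$global)) f <- factors$global[[key]]
  if (is.na(f)) f <- 1
  f
}

#' Childhood exposure for one person: measurement-first rule cascade
#'
#' The measured childhood mean (hair values at ages 5-15) always wins and
#' is returned unadjusted. Otherwise: people who were 10 or older in 1962
#' (born up to 1952) get the pre-discharge constant 0.1 ug/g; people who
#' turned 10 after 1990 (born 1981 or later) get 0.81 ug/g; everyone else
#' gets the cohort mean equivalent-hair value of the year they turned 10.
#' Post-1962 estimates (not the pre-1962 constant) are multiplied by the
#' fish-consumption x residential-school stratum factor; the estimate is
#' undefined when the childhood fish-consumption answer is missing and
#' there is no measurement.
#'
#' @param series the person's yearly series (possibly empty).
#' @param birth_year birth year.
#' @param fish_childhood 0/1 frequent childhood fish consumption (`NA`
#'   allowed).
#' @param residential_school 0/1 attended residential school (`NA` treated
#'   as 0 for adjustment purposes).
#' @param yearly_db full [build_yearly_hair()] result (for cohort year
#'   means).
#' @param adjust_factors precomputed stratum factors (see
#'   [build_exposure_profiles()]); `NULL` disables adjustment.
#' @param constants era constants.
#' @return list `value` (ug/g), `source` (`measured`, `cohort_year_mean`,
#'   `era_constant`, `undefined`), `adjusted` (logical).
#' @export
estimate_childhood <- function(series, birth_year, fish_childhood,
                               residential_school, yearly_db,
                               adjust_factors = NULL,
                               constants = era_constants()) {
  meas <- childhood_mean_hair(series, birth_year)
  if (!is.na(meas)) {
    return(list(value = meas, source = "measured", adjusted = FALSE))
  }
  if (is.na(birth_year)) {
    return(list(value = NA_real_, source = "undefined", adjusted = FALSE))
  }
  if (birth_year <= 1952) { # 10 or older in 1962, pre-discharge childhood
    return(list(value = constants$childhood_pre1962_ugg,
                source = "era_constant", adjusted = FALSE))
  }
  # estimate requires the fish-consumption answer (mirrors the unestimable
  # persons rule)
  if (is.na(fish_childhood)) {
    return(list(value = NA_real_, source = "undefined", adjusted = FALSE))
  }
  rs <- if (is.na(residential_school)) 0 else residential_school
  year10 <- birth_year + 10
  if (year10 > 1990) {
    base <- constants$childhood_post1990_ugg
    src <- "era_constant"
  } else {
    vals <- unlist(lapply(yearly_db, function(s) {
      v <- s[names(s) == as.character(year10)]
      if (length(v)) unname(v) else NULL
    }))
    if (length(vals) == 0) {
      # no cohort measurement that year: nearest monitored year's mean
      allyears <- sort(unique(as.numeric(unlist(lapply(yearly_db, names)))))
      if (length(allyears) == 0) {
        return(list(value = NA_real_, source = "undefined",
                    adjusted = FALSE))
      }
      near <- allyears[which.min(abs(allyears - year10))]
      vals <- unlist(lapply(yearly_db, function(s) {
        v <- s[names(s) == as.character(near)]
        if (length(v)) unname(v) else NULL
      }))
    }
    base <- mean(vals)
    src <- "cohort_year_mean"
  }
  era <- childhood_era(birth_year)
  f <- lookup_adjustment(adjust_factors, fish_childhood, rs, era)
  if (is.na(f)) f <- 1
  list(value = base * f, source = src, adjusted = !is.null(adjust_factors))
}

# childhood era label by the year the person turned 10
childhood_era <- function(birth_year) {
  y10 <- birth_year + 10
  if (is.na(birth_year)) return(NA_character_)
  if (y10 <= 1962) "pre1962" else if (y10 <= 1970) "1963-1970"
  else if (y10 <= 1990) "1971-1990" else "post1990"
}

#' Ever at or above the hair-mercury threshold
#'
#' @param series named numeric vector (year -> ug/g) for one person.
#' @param threshold ug/g (default 5).
#' @return `TRUE` if any yearly value is at or above the threshold, `FALSE`
#'   if none is, `NA` when the series is empty (not computable).
#' @export
ever_ge5 <- function(series, threshold = 5) {
  if (length(series) == 0) return(NA)
  any(series >= threshold)
}

#' Spearman validation of estimated against measured exposures
#'
#' @param measured,estimated paired vectors (pairs with missings dropped);
#'   at least 5 complete pairs required.
#' @return list `rho`, `p_value`, `n`.
#' @export
validate_estimates <- function(measured, estimated) {
  cc <- complete.cases(measured, estimated)
  if (sum(cc) < 5) stop("need at least 5 complete pairs")
  if (length(unique(measured[cc])) < 2 || length(unique(estimated[cc])) < 2)
    stop("ties-only input: rank correlation undefined")
  ct <- suppressWarnings(cor.test(measured[cc], estimated[cc],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(cc))
}

#' Exposure profiles for a cohort
#'
#' Runs the full measurement-first cascade for every participant: yearly
#' equivalent-hair series, prenatal (cord) exposure, childhood exposure
#' with covariate adjustment of estimates, and the ever-at-or-above-5 ug/g
#' indicator. The cascade is exhaustive and exclusive: every participant
#' with a known birth year gets exactly one (value, source) pair per
#' exposure, and measured values are never overwritten.
#'
#' @param survey survey table (needs `participant_id`, `birth_year`,
#'   `fish_childhood`, `residential_school`, `region_pregnancy`).
#' @param cord_table cord table (`participant_id`, `birth_year`,
#'   `cord_hg_ugL`).
#' @param biomarker_table long-format records for [build_yearly_hair()].
#' @param blood_to_hair hair:blood conversion (default 0.25 ug/g per ug/L).
#' @param threshold ug/g threshold for the binary indicator (default 5).
#' @param adjust apply the stratum adjustment to childhood estimates.
#' @param constants era constants, see [era_constants()].
#' @return data frame of class `hg_exposure`: per participant `cord_hg`,
#'   `cord_source`, `childhood_hg`, `childhood_source`, `adjusted`,
#'   `ever_ge5`, `n_hair_years`.
#' @export
build_exposure_profiles <- function(survey, cord_table, biomarker_table,
                                    blood_to_hair = 0.25, threshold = 5,
                                    adjust = TRUE,
                                    constants = era_constants()) {
  ydb <- build_yearly_hair(biomarker_table, blood_to_hair = blood_to_hair)
  regs <- fit_cord_regressions(cord_table)
  ids <- survey$participant_id
  by <- survey$birth_year[match(ids, survey$participant_id)]
  cord_meas <- cord_table$cord_hg_ugL[match(ids, cord_table$participant_id)]
  # measured childhood means for the adjustment factors
  meas_child <- vapply(seq_along(ids), function(i) {
    s <- ydb[[ids[i]]]
    if (is.null(s)) return(NA_real_)
    childhood_mean_hair(s, by[i])
  }, numeric(1))
  factors <- NULL
  if (adjust) {
    era <- vapply(by, childhood_era, character(1))
    factors <- childhood_adjustment_factors(meas_child,
                                            survey$fish_childhood,
                                            survey$residential_school, era)
  }
  out <- lapply(seq_along(ids), function(i) {
    s <- ydb[[ids[i]]] %||% numeric(0)
    cord <- estimate_cord(cord_meas[i], by[i], survey$region_pregnancy[i],
                          cord_table, regs, constants)
    child <- estimate_childhood(s, by[i], survey$fish_childhood[i],
                                survey$residential_school[i], ydb,
                                adjust_factors = factors,
                                constants = constants)
    data.frame(participant_id = ids[i],
               cord_hg = unname(cord$value), cord_source = cord$source,
               childhood_hg = unname(child$value),
               childhood_source = child$source,
               adjusted = child$adjusted &&
                 child$source %in% c("cohort_year_mean", "era_constant") &&
                 !is.na(child$value),
               ever_ge5 = ever_ge5(s, threshold),
               n_hair_years = length(s),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "regressions") <- regs
  attr(res, "yearly_db") <- ydb
  attr(res, "threshold") <- threshold
  class(res) <- c("hg_exposure", "data.frame")
  res
}
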