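#' Parameters for the synthetic cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults mirror
#' the statistical structure the downstream analyses assume: a survey of
#' 391 adults answering a 59-symptom battery of which 37 symptoms load on 6
#' latent factors (cluster sizes 9, 7, 6, 6, 5, 4) and 22 are noise;
#' umbilical-cord mercury declining from a geometric mean of 65.7 ug/L in
#' 1970 to 4.48 ug/L in 1992 along a piecewise log10-linear trend with
#' breaks after 1976 and 1987; sparse yearly hair-mercury series with
#' person-level heterogeneity and AR(1) within-person noise; a binary
#' diagnosed nervous-system-disorder mediator; and survey covariates (age
#' category, sex, obesity, chronic condition, childhood fish consumption,
#' residential-school attendance, region of pregnancy).
#'
#' @param n_participants cohort size.
#' @param birth_year_range earliest and latest birth year.
#' @param survey_year calendar year of the survey (for age categories).
#' @param cluster_sizes integer vector of informative-symptom counts per
#'   latent factor (each at least 2).
#' @param n_noise number of pure-noise symptom columns.
#' @param loading_range range of factor loadings for informative symptoms.
#' @param thresholds 4 increasing cut-points for 5-level discretization of
#'   the standard-normal symptom scores.
#' @param cord_anchors named vector, year -> cord Hg geometric mean (ug/L);
#'   the trend is piecewise linear in log10 between anchors.
#' @param period_breaks years delimiting the three exposure eras
#'   (1970-1976, 1977-1987, 1988-1992 by default).
#' @param cord_sd log10 ug/L person scatter around the cord trend.
#' @param cord_obs_prob probability a birth in 1970-1992 has a measured cord
#'   value.
#' @param hair_anchors named vector, year -> hair Hg geometric mean (ug/g).
#' @param hair_person_sd log10 ug/g between-person SD of the hair level.
#' @param hair_obs_sd log10 ug/g within-person observation SD.
#' @param hair_ar1 AR(1) correlation of within-person yearly deviations;
#'   the value is a modelling convenience, not an empirically grounded one.
#' @param sampling_prob_per_year mean probability that a person-year is
#'   sampled; person-level propensities are Beta-distributed around it
#'   (`sampling_shape1` controls the spread) so that a minority of people
#'   accumulate long series, as in opportunistic monitoring programmes.
#' @param sampling_shape1 first Beta shape parameter of the propensities.
#' @param monitor_years calendar window of the monitoring programme.
#' @param beta_hg per-cluster standardized effect of z(log10 childhood Hg)
#'   on the latent symptom factor (recycled to the number of clusters).
#' @param beta_mediator log-odds effect of z(log10 childhood Hg) on the
#'   diagnosed nervous-system-disorder indicator.
#' @param beta_nd standardized effect of the (centred) disorder indicator on
#'   each latent factor.
#' @param covariate_effects named vector of standardized effects of
#'   covariates on every latent factor; recognised names are `age_z`,
#'   `sex_female`, `obesity`, `chronic_condition`.
#' @param missing_rate MCAR missingness rate applied to Likert cells.
#' @param covariate_missing_rate MCAR missingness on covariates (feeds the
#'   imputation stage).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full parameter set.
#' @return list of class `hg_synthparams`.
#' @export
synthetic_params <- function(n_participants = 391,
                             birth_year_range = c(1950, 1992),
                             survey_year = 2016,
                             cluster_sizes = c(9, 7, 6, 6, 5, 4),
                             n_noise = 22,
                             loading_range = c(0.85, 0.95),
                             thresholds = c(-1.5, -0.5, 0.5, 1.5),
                             cord_anchors = c("1970" = 65.7, "1977" = 18,
                                              "1988" = 6.5, "1992" = 4.48),
                             period_breaks = c(1970, 1976, 1987, 1992),
                             cord_sd = 0.25,
                             cord_obs_prob = 0.5,
                             hair_anchors = c("1970" = 8, "1977" = 3,
                                              "1988" = 1, "1997" = 0.8),
                             hair_person_sd = 0.3,
                             hair_obs_sd = 0.2,
                             hair_ar1 = 0.3,
                             sampling_prob_per_year = 0.2,
                             sampling_shape1 = 1.2,
                             monitor_years = c(1970, 1997),
                             beta_hg = 0.3,
                             beta_mediator = 0.6,
                             beta_nd = 0.2,
                             covariate_effects = c(age_z = 0.2,
                                                   sex_female = 0.15,
                                                   obesity = 0.1,
                                                   chronic_condition = 0.15),
                             missing_rate = 0.05,
                             covariate_missing_rate = 0.03,
                             seed = 1) {
  stopifnot(all(cluster_sizes >= 2))
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  stopifnot(cord_sd >= 0, hair_person_sd >= 0, hair_obs_sd >= 0)
  if (loading_range[1] < 0 || loading_range[2] > 1 ||
      loading_range[1] > loading_range[2])
    stop("loading_range must be within [0, 1]")
  stopifnot(sampling_prob_per_year > 0, sampling_prob_per_year < 1)
  K <- length(cluster_sizes)
  beta_hg <- rep_len(beta_hg, K)
  p <- list(n_participants = n_participants,
            birth_year_range = birth_year_range, survey_year = survey_year,
            cluster_sizes = cluster_sizes, n_noise = n_noise,
            n_symptoms = sum(cluster_sizes) + n_noise,
            loading_range = loading_range, thresholds = thresholds,
            cord_anchors = cord_anchors, period_breaks = period_breaks,
            cord_sd = cord_sd, cord_obs_prob = cord_obs_prob,
            hair_anchors = hair_anchors, hair_person_sd = hair_person_sd,
            hair_obs_sd = hair_obs_sd, hair_ar1 = hair_ar1,
            sampling_prob_per_year = sampling_prob_per_year,
            sampling_shape1 = sampling_shape1,
            monitor_years = monitor_years,
            beta_hg = beta_hg, beta_mediator = beta_mediator,
            beta_nd = beta_nd, covariate_effects = covariate_effects,
            missing_rate = missing_rate,
            covariate_missing_rate = covariate_missing_rate, seed = seed)
  class(p) <- "hg_synthparams"
  p
}

# piecewise-linear interpolation in log10 between named year anchors,
# flat extrapolation outside
log_trend <- function(years, anchors) {
  ay <- as.numeric(names(anchors))
  av <- log10(anchors)
  approx(ay, av, xout = pmin(pmax(years, min(ay)), max(ay)),
         rule = 2)$y
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces a survey table (ordinal symptom battery plus covariates), an
#' umbilical-cord mercury table and a long-format biomarker table whose
#' joint distribution follows the generative model described in
#' [synthetic_params()]: each informative symptom is a thresholded
#' continuous score `lambda * f_k + N(0, 1 - lambda^2)` where the latent
#' factor `f_k` is a unit-variance combination of standardized log10
#' childhood mercury, the disorder mediator, covariates and noise.
#'
#' @param params an [synthetic_params()] object.
#' @return list of class `hg_cohort`: `survey`, `cord_table`,
#'   `biomarker_table`, and `truth` (planted partition, factor scores,
#'   effect sizes, true childhood exposure, person-level hair levels).
#' @export
generate_cohort <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "hg_synthparams"))
  set.seed(params$seed)
  n <- params$n_participants
  id <- sprintf("P%04d", seq_len(n))
  by <- sample(seq(params$birth_year_range[1], params$birth_year_range[2]),
               n, replace = TRUE)
  age <- params$survey_year - by
  age_category <- cut(age, c(17, 29, 49, Inf),
                      labels = c("18-29", "30-49", "50+"))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.54, 0.46))
  region_pregnancy <- sample(c("region", "elsewhere"), n, replace = TRUE,
                             prob = c(0.9, 0.1))

  # --- hair exposure process -------------------------------------------
  yrs <- seq(params$monitor_years[1], params$monitor_years[2])
  trend <- log_trend(yrs, params$hair_anchors)
  u <- rnorm(n, 0, params$hair_person_sd)      # person level (log10)
  resschool <- as.integer(by <= 1978 & runif(n) < 0.5)
  u <- u - 0.15 * resschool                    # attendees lived away part-year
  # latent yearly log10 hair level per person-year (only ages >= 1)
  lat_hair <- matrix(NA_real_, n, length(yrs))
  for (i in seq_len(n)) {
    ages <- yrs - by[i]
    ok <- ages >= 1
    lat_hair[i, ok] <- trend[ok] + u[i]
  }
  # true childhood exposure: geometric mean of latent level over ages 5-15
  childhood_true <- vapply(seq_len(n), function(i) {
    ages <- yrs - by[i]
    sel <- ages >= 5 & ages <= 15
    if (!any(sel)) return(NA_real_)
    10^mean(lat_hair[i, sel])
  }, numeric(1))
  # persons whose childhood predates monitoring: assign from extrapolated
  # trend at their childhood midpoint so every person has a true exposure
  miss_ct <- is.na(childhood_true)
  if (any(miss_ct)) {
    childhood_true[miss_ct] <-
      10^(log_trend(by[miss_ct] + 10, params$hair_anchors) + u[miss_ct])
  }
  z_child <- as.numeric(scale(log10(childhood_true)))

  # observed hair series: AR(1) observation noise, Beta-heterogeneous
  # sampling of person-years
  prop <- rbeta(n, params$sampling_shape1,
                params$sampling_shape1 *
                  (1 - params$sampling_prob_per_year) /
                  params$sampling_prob_per_year)
  bio <- vector("list", n)
  rho <- params$hair_ar1
  for (i in seq_len(n)) {
    ok <- which(!is.na(lat_hair[i, ]))
    if (length(ok) == 0) next
    e <- numeric(length(ok))
    e[1] <- rnorm(1, 0, params$hair_obs_sd)
    if (length(ok) > 1) {
      for (t in 2:length(ok)) {
        e[t] <- rho * e[t - 1] +
          rnorm(1, 0, params$hair_obs_sd * sqrt(1 - rho^2))
      }
    }
    obs <- runif(length(ok)) < prop[i]
    if (!any(obs)) next
    val <- 10^(lat_hair[i, ok][obs] + e[obs])
    medium <- sample(c("hair", "blood"), sum(obs), replace = TRUE,
                     prob = c(0.8, 0.2))
    val_out <- ifelse(medium == "blood", val / 0.25, val)
    bio[[i]] <- data.frame(participant_id = id[i], year = yrs[ok][obs],
                           medium = medium, value = val_out,
                           stringsAsFactors = FALSE)
  }
  biomarker_table <- do.call(rbind, bio)
  rownames(biomarker_table) <- NULL

  # --- cord table -------------------------------------------------------
  cord_ok <- by >= 1970 & by <= 1992 & region_pregnancy == "region" &
    runif(n) < params$cord_obs_prob
  cord_val <- rep(NA_real_, n)
  cord_val[cord_ok] <- 10^(log_trend(by[cord_ok], params$cord_anchors) +
                             rnorm(sum(cord_ok), 0, params$cord_sd))
  cord_table <- data.frame(participant_id = id, birth_year = by,
                           cord_hg_ugL = cord_val, stringsAsFactors = FALSE)

  # --- covariates and mediator -----------------------------------------
  age_z <- as.numeric(scale(age))
  obesity <- as.integer(runif(n) < 0.47)
  chronic <- as.integer(runif(n) < plogis(qlogis(0.6) + 0.04 * (age - 40)))
  nervous <- as.integer(runif(n) <
                          plogis(qlogis(0.24) + params$beta_mediator * z_child))
  fish_childhood <- as.integer(runif(n) < plogis(-0.2 + 0.9 * z_child))

  # --- latent factors and symptoms -------------------------------------
  K <- length(params$cluster_sizes)
  ce <- params$covariate_effects
  covpart <- (ce["age_z"] %||% 0) * age_z +
    (ce["sex_female"] %||% 0) * (sex == "F") +
    (ce["obesity"] %||% 0) * obesity +
    (ce["chronic_condition"] %||% 0) * chronic
  covpart[is.na(covpart)] <- 0
  nd_c <- nervous - mean(nervous)
  f <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    sys <- params$beta_hg[k] * z_child + params$beta_nd * nd_c + covpart
    vres <- max(1 - var(sys), 0.05)
    f[, k] <- sys + rnorm(n, 0, sqrt(vres))
    f[, k] <- f[, k] / sd(f[, k])
  }
  p_inf <- sum(params$cluster_sizes)
  p_all <- p_inf + params$n_noise
  lam <- runif(p_inf, params$loading_range[1], params$loading_range[2])
  clus <- rep(seq_len(K), params$cluster_sizes)
  cont <- matrix(NA_real_, n, p_all)
  for (s in seq_len(p_inf)) {
    cont[, s] <- lam[s] * f[, clus[s]] +
      rnorm(n, 0, sqrt(1 - lam[s]^2))
  }
  if (params$n_noise > 0) {
    cont[, (p_inf + 1):p_all] <- rnorm(n * params$n_noise)
  }
  br <- c(-Inf, params$thresholds, Inf)
  lik <- matrix(cut(cont, br, labels = FALSE), n, p_all)
  if (params$missing_rate > 0) {
    lik[matrix(runif(n * p_all) < params$missing_rate, n, p_all)] <- NA
  }
  sym_ids <- sprintf("sym_%03d", seq_len(p_all))
  colnames(lik) <- sym_ids

  survey <- data.frame(participant_id = id, sex = sex, birth_year = by,
                       age_category = as.character(age_category),
                       obesity = obesity, chronic_condition = chronic,
                       nervous_disorder = nervous,
                       fish_childhood = fish_childhood,
                       residential_school = resschool,
                       region_pregnancy = region_pregnancy,
                       stringsAsFactors = FALSE)
  if (params$covariate_missing_rate > 0) {
    for (cl in c("obesity", "chronic_condition", "fish_childhood")) {
      survey[[cl]][runif(n) < params$covariate_missing_rate] <- NA
    }
  }
  survey <- cbind(survey, as.data.frame(lik))

  truth_part <- setNames(c(clus, rep(0L, params$n_noise)), sym_ids)
  colnames(cont) <- sym_ids
  structure(list(survey = survey, cord_table = cord_table,
                 biomarker_table = biomarker_table,
                 truth = list(partition = truth_part, factor_scores = f,
                              continuous = cont,
                              loadings = setNames(lam, sym_ids[seq_len(p_inf)]),
                              beta_hg = params$beta_hg,
                              beta_mediator = params$beta_mediator,
                              childhood_true = setNames(childhood_true, id),
                              person_level = setNames(u, id)),
                 params = params),
            class = "hg_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `survey.csv`, `cord.csv` and `biomarkers.csv` in the column
#' layouts the pipeline readers expect; missing cells become empty fields.
#' Round-trips losslessly through [read_cohort()].
#'
#' @param cohort an [generate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "hg_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("survey.csv", "cord.csv", "biomarkers.csv"))
  write.csv(cohort$survey, paths[1], row.names = FALSE, na = "")
  write.csv(cohort$cord_table, paths[2], row.names = FALSE, na = "")
  write.csv(cohort$biomarker_table, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

#' Read cohort CSV files written by [write_cohort()]
#'
#' @param directory directory holding `survey.csv`, `cord.csv`,
#'   `biomarkers.csv`.
#' @return list with `survey`, `cord_table`, `biomarker_table`.
#' @export
read_cohort <- function(directory) {
  survey <- read.csv(file.path(directory, "survey.csv"),
                     stringsAsFactors = FALSE,
                     colClasses = c(participant_id = "character"))
  cord <- read.csv(file.path(directory, "cord.csv"),
                   stringsAsFactors = FALSE,
                   colClasses = c(participant_id = "character"))
  bio <- read.csv(file.path(directory, "biomarkers.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
  list(survey = survey, cord_table = cord, biomarker_table = bio)
}

#' Symptom columns of a survey table
#'
#' @param survey a survey data frame as produced by [generate_cohort()].
#' @return character vector of symptom column names (prefix `sym_`).
#' @export
symptom_columns <- function(survey) {
  grep("^sym_", names(survey), value = TRUE)
}
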