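#' Median split of composite scores
#'
#' Labels each participant `above` when the score strictly exceeds the
#' median and `below` otherwise (ties at the median go to `below`).
#'
#' @param scores named numeric vector of per-participant composite scores.
#' @return named factor with levels `below`, `above`.
#' @export
median_split <- function(scores) {
  sc <- scores[!is.na(scores)]
  if (length(sc) < 2) stop("need at least 2 participants")
  if (length(unique(sc)) == 1) stop("all scores equal: split undefined")
  med <- median(sc)
  out <- factor(ifelse(scores > med, "above", "below"),
                levels = c("below", "above"))
  names(out) <- names(scores)
  out
}

#' Assemble the longitudinal analysis dataset
#'
#' Joins per-person yearly hair series with composite-score groups and
#' covariates, keeping only persons with at least `min_measurements`
#' yearly values (and a non-missing score). Exclusion counts are recorded
#' in attributes.
#'
#' @param yearly an [build_yearly_hair()] result (or named list of
#'   year -> ug/g vectors).
#' @param scores named numeric vector of composite scores.
#' @param covariates data frame with `participant_id`, `sex`,
#'   `birth_year`.
#' @param min_measurements inclusion threshold (default 10).
#' @return data frame of class `hg_longdata`: `participant_id`, `year`,
#'   `hair_hg`, `log10_hair`, `age_at_sampling`, `sex`, `group`.
#' @export
build_long <- function(yearly, scores, covariates, min_measurements = 10) {
  counts <- vapply(yearly, length, integer(1))
  eligible <- names(yearly)[counts >= min_measurements]
  has_score <- eligible[eligible %in% names(scores) &
                          !is.na(scores[eligible])]
  dropped_score <- setdiff(eligible, has_score)
  grp <- median_split(scores[has_score])
  rows <- lapply(has_score, function(pid) {
    s <- yearly[[pid]]
    ci <- match(pid, covariates$participant_id)
    data.frame(participant_id = pid,
               year = as.numeric(names(s)),
               hair_hg = as.numeric(s),
               age_at_sampling = as.numeric(names(s)) -
                 covariates$birth_year[ci],
               sex = covariates$sex[ci],
               group = as.character(grp[pid]),
               score = unname(scores[pid]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no participants meet the inclusion threshold")
  out$log10_hair <- log10(out$hair_hg)
  out$group <- factor(out$group, levels = c("below", "above"))
  attr(out, "n_included") <- length(has_score)
  attr(out, "n_excluded_few") <- sum(counts < min_measurements)
  attr(out, "n_excluded_score") <- length(dropped_score)
  attr(out, "min_measurements") <- min_measurements
  class(out) <- c("hg_longdata", "data.frame")
  out
}

#' Longitudinal mixed-effects model of hair mercury
#'
#' REML fit of log10 hair mercury on score group, age at sampling, sex and
#' calendar year, with a participant-level random intercept (default) or
#' the alternative year-level structure (random intercepts for sampling
#' year with an age slope). The score-group coefficient estimates the
#' log10 difference in hair mercury between participants above and below
#' the median composite score, over the sampling period; it is also
#' reported back-transformed as a multiplicative ratio on the ug/g scale.
#' Model comparison against the fixed-effects-only nested model uses AIC,
#' BIC and a likelihood-ratio test.
#'
#' @param data an [build_long()] result.
#' @param random `"participant"` (random intercept per person) or
#'   `"year_nested"` (random intercept and age slope by sampling year).
#' @param min_participants warn below this number (longitudinal power
#'   analyses place the minimum around 29).
#' @return object of class `hg_lmemfit`: list with `fixed` (estimate, CI,
#'   p per fixed effect), `group_effect` (log10 and ratio scale),
#'   `varcomp`, `aic`, `bic`, `lr_test`, `fit` (the lmerMod), `singular`.
#' @export
fit_lmem <- function(data, random = c("participant", "year_nested"),
                     min_participants = 29) {
  random <- match.arg(random)
  stopifnot(inherits(data, "data.frame"))
  np <- length(unique(data$participant_id))
  if (np < min_participants)
    warning("only ", np, " participants; longitudinal power analyses ",
            "suggest at least ", min_participants)
  data$year_c <- data$year - mean(data$year)
  form <- if (random == "participant") {
    log10_hair ~ group + age_at_sampling + sex + year_c +
      (1 | participant_id)
  } else {
    log10_hair ~ group + age_at_sampling + sex + year_c +
      (1 + age_at_sampling | year)
  }
  fit <- lmerTest::lmer(form, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular && random == "year_nested") {
    # simplify: drop the age slope
    fit <- lmerTest::lmer(log10_hair ~ group + age_at_sampling + sex +
                            year_c + (1 | year), data = data, REML = TRUE)
    singular <- lme4::isSingular(fit)
  }
  sm <- summary(fit)$coefficients
  cf <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], df = sm[, "df"],
                   p = sm[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  tcrit <- qt(0.975, cf$df)
  cf$ci_lo <- cf$estimate - tcrit * cf$se
  cf$ci_hi <- cf$estimate + tcrit * cf$se
  rownames(cf) <- NULL
  gi <- grep("^groupabove$", cf$term)
  group_effect <- list(
    log10 = cf$estimate[gi], ci_log10 = c(cf$ci_lo[gi], cf$ci_hi[gi]),
    p = cf$p[gi],
    ratio = 10^cf$estimate[gi],
    ci_ratio = 10^c(cf$ci_lo[gi], cf$ci_hi[gi]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  # LR test against the no-random-effect nested model (ML refits)
  fit_ml <- lme4::refitML(fit)
  null_ml <- lm(log10_hair ~ group + age_at_sampling + sex + year_c,
                data = data)
  lr <- as.numeric(2 * (logLik(fit_ml) - logLik(null_ml)))
  lr_df <- attr(logLik(fit_ml), "df") - attr(logLik(null_ml), "df")
  # boundary-corrected reference for a single variance component
  lr_p <- if (lr_df == 1) 0.5 * pchisq(lr, 1, lower.tail = FALSE) else
    pchisq(lr, lr_df, lower.tail = FALSE)
  structure(list(fixed = cf, group_effect = group_effect, varcomp = vc,
                 aic = AIC(fit_ml), bic = BIC(fit_ml),
                 lr_test = list(statistic = lr, df = lr_df, p = lr_p,
                                aic_null = AIC(null_ml),
                                bic_null = BIC(null_ml)),
                 random = random, n_participants = np,
                 n_obs = nrow(data), singular = singular, fit = fit),
            class = "hg_lmemfit")
}

#' @export
print.hg_lmemfit <- function(x, ...) {
  cat("Longitudinal mixed-effects model:", x$n_obs, "measurements,",
      x$n_participants, "participants; random =", x$random, "\n")
  print(x$fixed, digits = 3, row.names = FALSE)
  cat(sprintf("group (above vs below median): %.3f log10 units, ratio %.2f [%.2f, %.2f], p = %.3g\n",
              x$group_effect$log10, x$group_effect$ratio,
              x$group_effect$ci_ratio[1], x$group_effect$ci_ratio[2],
              x$group_effect$p))
  invisible(x)
}

#' Residual normality diagnostics for a mixed-model fit
#'
#' Ordered conditional residuals against standard-normal quantiles plus a
#' Shapiro-Wilk statistic; flags heavy tails.
#'
#' @param fit an [fit_lmem()] result.
#' @return list with `table` (data frame `theoretical`, `observed`),
#'   `slope` (robust quantile slope), `shapiro_w`, `shapiro_p`,
#'   `flagged` (normality rejected at 0.05).
#' @export
qq_residuals <- function(fit) {
  r <- residuals(fit$fit)
  if (sd(r) < 1e-12) stop("residuals are constant: diagnostics undefined")
  rs <- sort(as.numeric(scale(r)))
  qs <- qnorm(ppoints(length(rs)))
  # slope between the quartiles, as drawn on a q-q plot
  qr_obs <- quantile(rs, c(0.25, 0.75))
  qr_th <- qnorm(c(0.25, 0.75))
  slope <- diff(qr_obs) / diff(qr_th)
  n <- length(rs)
  sw <- shapiro.test(if (n <= 5000) rs else rs[seq(1, n, length.out = 5000)])
  list(table = data.frame(theoretical = qs, observed = rs),
       slope = unname(slope), shapiro_w = unname(sw$statistic),
       shapiro_p = sw$p.value, flagged = sw$p.value < 0.05)
}
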