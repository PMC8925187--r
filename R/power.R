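#' Specification for longitudinal two-group power
#'
#' @param alpha two-tailed test level (default 0.05).
#' @param power target power (default 0.80).
#' @param effect_size standardized group difference; interpreted as
#'   Cohen's d by default, or Cohen's f (d = 2f) via `effect_type`.
#' @param effect_type `"d"` or `"f"`.
#' @param n_timepoints repeated measurements per person (default 10).
#' @param rho correlation between repeated measures (compound symmetry).
#' @return list of class `hg_longpower`.
#' @export
long_power_spec <- function(alpha = 0.05, power = 0.80, effect_size = 0.25,
                            effect_type = c("d", "f"), n_timepoints = 10,
                            rho = 0.1) {
  effect_type <- match.arg(effect_type)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, effect_size > 0,
            rho >= 0, rho < 1, n_timepoints >= 1)
  structure(list(alpha = alpha, power = power, effect_size = effect_size,
                 effect_type = effect_type, n_timepoints = n_timepoints,
                 rho = rho),
            class = "hg_longpower")
}

#' Minimum sample size for a longitudinal two-group comparison
#'
#' Compound-symmetry formula for detecting a standardized mean difference
#' `d` between two groups with `n` repeated measurements per person and
#' within-person correlation `rho`:
#' `N_per_group = 2 (z_{1-alpha/2} + z_{1-beta})^2 (1 + (n-1) rho) / (n d^2)`,
#' rounded up. With one time point and `rho = 0` this reduces to the
#' classic two-sample formula. The design factor `(1 + (n-1) rho)/n` makes
#' the requirement increase with `rho` and decrease with `n`.
#'
#' @param spec an [long_power_spec()] (or arguments via `...` forwarded to
#'   it).
#' @param ... used to build a spec when `spec` is missing.
#' @return list: `n_per_group`, `n_total`, `design_factor`, `d` (the
#'   Cohen's d actually used), `spec`.
#' @export
long_samplesize <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- long_power_spec(...)
  stopifnot(inherits(spec, "hg_longpower"))
  if (spec$rho == 1 && spec$n_timepoints > 1)
    stop("rho = 1 with repeated measures adds no information")
  d <- if (spec$effect_type == "f") 2 * spec$effect_size else
    spec$effect_size
  za <- qnorm(1 - spec$alpha / 2)
  zb <- qnorm(spec$power)
  n <- spec$n_timepoints
  df_fac <- (1 + (n - 1) * spec$rho) / n
  npg <- ceiling(2 * (za + zb)^2 * df_fac / d^2)
  list(n_per_group = npg, n_total = 2 * npg, design_factor = df_fac,
       d = d, spec = spec)
}

#' Analytic power of the longitudinal two-group comparison at a given N
#'
#' Exact finite-sample power of the two-sided two-sample t-test on person
#' means under compound symmetry, via the noncentral t distribution. The
#' closed-form sample-size formula in [long_samplesize()] uses the normal
#' approximation; this function is the sharper evaluation used to
#' cross-check it (and the Monte-Carlo oracle) at small N.
#'
#' @param spec an [long_power_spec()].
#' @param N total sample size.
#' @return power (scalar in (0, 1)).
#' @export
long_power_analytic <- function(spec, N) {
  stopifnot(inherits(spec, "hg_longpower"))
  d <- if (spec$effect_type == "f") 2 * spec$effect_size else
    spec$effect_size
  n1 <- ceiling(N / 2); n2 <- N - n1
  vmean <- (1 + (spec$n_timepoints - 1) * spec$rho) / spec$n_timepoints
  ncp <- d / sqrt(vmean * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tc <- qt(1 - spec$alpha / 2, df)
  pt(-tc, df, ncp = ncp) + pt(tc, df, ncp = ncp, lower.tail = FALSE)
}

#' Monte-Carlo power check for the longitudinal design
#'
#' Simulates compound-symmetry normal data (`n_timepoints` measurements,
#' within-person correlation `rho`, standardized group difference `d`) at
#' a given total sample size and returns the empirical rejection rate of
#' the two-group test. Under compound symmetry with balanced data, the
#' generalized-least-squares group contrast of the mixed model equals the
#' two-sample t-test on person means, which is what is used (it makes the
#' check an independent closed-form-free oracle of the analytic formula).
#'
#' @param spec an [long_power_spec()].
#' @param N total sample size (split evenly; one extra person goes to the
#'   first group when odd).
#' @param reps Monte-Carlo replicates (at least 100).
#' @param seed integer seed.
#' @return list: `power`, `ci` (binomial 95%), `reps`.
#' @export
mc_power <- function(spec, N, reps = 1000, seed = 1) {
  stopifnot(inherits(spec, "hg_longpower"), reps >= 100)
  d <- if (spec$effect_type == "f") 2 * spec$effect_size else
    spec$effect_size
  n1 <- ceiling(N / 2); n2 <- N - n1
  nt <- spec$n_timepoints
  rho <- spec$rho
  set.seed(seed)
  # person mean under CS: variance (1 + (nt-1) rho)/nt
  vmean <- (1 + (nt - 1) * rho) / nt
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    m1 <- rnorm(n1, 0, sqrt(vmean))
    m2 <- rnorm(n2, d, sqrt(vmean))
    rej[r] <- t.test(m1, m2)$p.value < spec$alpha
  }
  pw <- mean(rej)
  ci <- pw + c(-1.96, 1.96) * sqrt(pw * (1 - pw) / reps)
  list(power = pw, ci = pmin(pmax(ci, 0), 1), reps = reps)
}

#' Sample-size grid for the longitudinal design
#'
#' Evaluates [long_samplesize()] over a grid of repeated-measures
#' correlations and both effect-size interpretations, mirroring how such
#' calculations are reported when the exact software configuration behind
#' a published range is unknown.
#'
#' @param rho_values correlations to tabulate (default 0.1 and 0.2).
#' @param effect_size standardized effect (default 0.25).
#' @param ... forwarded to [long_power_spec()].
#' @return data frame: `rho`, `effect_type`, `d`, `n_per_group`,
#'   `n_total`.
#' @export
long_samplesize_grid <- function(rho_values = c(0.1, 0.2),
                                 effect_size = 0.25, ...) {
  rows <- list()
  for (rho in rho_values) for (ty in c("d", "f")) {
    sp <- long_power_spec(effect_size = effect_size, effect_type = ty,
                          rho = rho, ...)
    ss <- long_samplesize(sp)
    rows[[length(rows) + 1]] <- data.frame(rho = rho, effect_type = ty,
                                           d = ss$d,
                                           n_per_group = ss$n_per_group,
                                           n_total = ss$n_total)
  }
  do.call(rbind, rows)
}
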