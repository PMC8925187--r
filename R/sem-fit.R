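#' Fit a structural equation model by diagonally weighted least squares
#'
#' Estimates an [sem_model()] on the polychoric/polyserial/Pearson
#' correlation matrix of the data. The discrepancy is the weighted sum of
#' squared differences between sample and model-implied moments, with
#' weights equal to the inverse asymptotic variances of the correlation
#' estimates (the DWLS weight matrix). Because the sample moments are
#' correlations, the unit diagonal is included with a large fixed weight so
#' that residual variances absorb it.
#'
#' Inference does not trust the naive statistic: the reported chi-square is
#' mean-scaled using the full estimated asymptotic covariance of the
#' correlations (`T_scaled = df * T_naive / trace(U Gamma)`), and standard
#' errors are sandwich estimates under the same Gamma. Fit indices (CFI,
#' TLI, RMSEA with 90% CI, SRMR) are recomputed from the scaled chi-square,
#' its degrees of freedom and `N - 1`; the baseline is the independence
#' model. AIC/BIC are quasi versions (`chisq + 2q`, `chisq + log(N) q`)
#' meaningful only for comparing models on the same data.
#'
#' @param model an [sem_model()].
#' @param data data frame containing every observed variable of the model;
#'   complete cases are used.
#' @param mc optional precomputed [mixed_correlation()] of exactly the
#'   model's observed variables (used by the bootstrap/power internals).
#' @param diag_weight multiplier on the maximum off-diagonal weight used
#'   for the unit-diagonal moments.
#' @return object of class `hg_semfit`; see Details. Key elements:
#'   `est` (parameter table with unstandardized and standardized estimates,
#'   sandwich SEs, z and p), `fit` (named vector of fit measures),
#'   `converged`, `heywood`, `residuals` (sample minus implied moments).
#' @export
fit_sem <- function(model, data, mc = NULL, diag_weight = 20) {
  stopifnot(inherits(model, "hg_semmodel"))
  obs <- model$obs
  if (is.null(mc)) {
    miss <- setdiff(obs, names(data))
    if (length(miss)) stop("columns missing from data: ",
                           paste(miss, collapse = ", "))
    mc <- mixed_correlation(data[, obs, drop = FALSE],
                            ordinal = model$ordinal)
  }
  R <- mc$R[obs, obs]
  n <- mc$n
  p <- length(obs)
  # moment bookkeeping: lower triangle including diagonal, column-major
  lt <- which(lower.tri(R, diag = TRUE), arr.ind = TRUE)
  nmom <- nrow(lt)
  is_diag <- lt[, 1] == lt[, 2]
  r_vec <- R[lt]
  # map mixed_correlation pair index (strict lower triangle) to moments
  gamma <- matrix(0, nmom, nmom)
  offmap <- integer(nrow(mc$index))
  for (l in seq_len(nrow(mc$index))) {
    offmap[l] <- which(lt[, 1] == mc$index[l, 1] & lt[, 2] == mc$index[l, 2])
  }
  gamma[offmap, offmap] <- mc$gamma
  avar <- diag(gamma)
  w <- numeric(nmom)
  w[!is_diag] <- 1 / pmax(avar[!is_diag], 1e-10)
  w[is_diag] <- diag_weight * max(w[!is_diag])
  free <- model$ptab$free
  q <- sum(free)
  df <- nmom - q
  if (df < 0) stop("model not identified: negative degrees of freedom")
  start <- sem_start_values(model, R)
  momfun <- function(theta) sem_implied(model, theta, obs)[lt]
  objfun <- function(theta) {
    sig <- tryCatch(momfun(theta), error = function(e) NULL)
    if (is.null(sig) || any(!is.finite(sig))) return(1e10)
    sum(w * (r_vec - sig)^2)
  }
  opt <- lm_wls(momfun, r_vec, w, start)
  theta <- opt$par
  converged <- opt$converged
  Fmin <- opt$objective
  sig_hat <- momfun(theta)
  # Jacobian of moments wrt free parameters (central differences)
  Delta <- matrix(0, nmom, q)
  for (k in seq_len(q)) {
    h <- 1e-5 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    Delta[, k] <- (momfun(tp) - momfun(tm)) / (2 * h)
  }
  WD <- w * Delta
  H <- crossprod(Delta, WD)          # Delta' W Delta
  Hinv <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  # sandwich covariance of theta-hat
  B <- crossprod(WD, gamma %*% WD)   # Delta' W Gamma W Delta
  Vtheta <- Hinv %*% B %*% Hinv / n
  se <- sqrt(pmax(diag(Vtheta), 0))
  # mean-scaled test statistic
  U <- diag(w) - WD %*% Hinv %*% t(WD)
  trUG <- sum(diag(U %*% gamma))
  chisq_naive <- (n - 1) * Fmin
  scaling <- if (df > 0) trUG / df else 1
  if (!is.finite(scaling) || scaling <= 0) scaling <- 1
  chisq <- if (df > 0) chisq_naive / scaling else 0
  # baseline (independence) model: zero covariances, free variances
  base <- sem_baseline(r_vec, w, gamma, is_diag, n)
  fitidx <- sem_fit_indices(chisq, df, base$chisq, base$df, n, r_vec,
                            sig_hat, is_diag, q)
  # assemble parameter table
  est <- model$ptab
  est$est <- est$start
  est$est[free] <- theta
  est$se <- NA_real_
  est$se[free] <- se
  est$z <- est$est / est$se
  est$p <- 2 * pnorm(-abs(est$z))
  std <- sem_standardize(model, theta)
  est$std_est <- std$values
  heywood <- any(est$matrix == "S" & est$row == est$col & est$est < -1e-6) ||
    any(abs(est$std_est[est$matrix == "A"]) > 1 + 1e-6, na.rm = TRUE)
  structure(list(model = model, est = est, fit = fitidx,
                 chisq_naive = chisq_naive, scaling = scaling,
                 vcov = Vtheta, theta = theta, n = n, df = df,
                 converged = converged, iterations = opt$iterations,
                 heywood = heywood,
                 residuals = r_vec - sig_hat, moments = lt,
                 r_vec = r_vec, sig_hat = sig_hat, w = w, gamma = gamma,
                 Delta = Delta, Hinv = Hinv, mc = mc,
                 std_all = std$matrices),
            class = "hg_semfit")
}

# Levenberg-Marquardt minimizer for the weighted moment least squares:
# sigma() maps parameters to implied moments; the Jacobian is numerical
# (forward differences), and damping is adapted multiplicatively
lm_wls <- function(sigma_fun, r_vec, w, start, max_iter = 100,
                   tol = 1e-10) {
  theta <- start
  q <- length(theta)
  sig <- sigma_fun(theta)
  Fcur <- sum(w * (r_vec - sig)^2)
  lambda <- 1e-3
  conv <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    Delta <- matrix(0, length(sig), q)
    for (k in seq_len(q)) {
      h <- 1e-6 * max(1, abs(theta[k]))
      tp <- theta; tp[k] <- tp[k] + h
      Delta[, k] <- (sigma_fun(tp) - sig) / h
    }
    resid <- r_vec - sig
    g <- crossprod(Delta, w * resid)     # half the negative gradient
    H <- crossprod(Delta, w * Delta)
    accepted <- FALSE
    for (inner in 1:12) {
      Hd <- H + lambda * diag(pmax(diag(H), 1e-8), q)
      step <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + drop(step)
        sc <- tryCatch(sigma_fun(cand), error = function(e) NULL)
        if (!is.null(sc) && all(is.finite(sc))) {
          Fc <- sum(w * (r_vec - sc)^2)
          if (Fc <= Fcur) {
            accepted <- TRUE
            improve <- Fcur - Fc
            theta <- cand; sig <- sc; Fcur <- Fc
            lambda <- max(lambda / 3, 1e-10)
            break
          }
        }
      }
      lambda <- lambda * 5
    }
    if (!accepted) { conv <- TRUE; break }   # no improving step: at optimum
    if (improve < tol * max(Fcur, 1e-12) || improve < 1e-14) {
      conv <- TRUE; break
    }
  }
  list(par = theta, objective = Fcur, converged = conv, iterations = it)
}

# data-informed start values: loadings from correlations with the first
# indicator, exogenous covariances from the sample matrix
sem_start_values <- function(model, R) {
  pt <- model$ptab
  vars <- model$vars
  start <- pt$start
  isS <- pt$matrix == "S"
  # exogenous covariances start at the sample correlations
  for (k in which(isS & pt$row != pt$col)) {
    vi <- vars[pt$row[k]]; vj <- vars[pt$col[k]]
    if (vi %in% rownames(R) && vj %in% rownames(R)) {
      start[k] <- R[vi, vj]
    }
  }
  # observed endogenous residual variances: moderate
  obs_endo <- vars[unique(pt$row[pt$matrix == "A"])]
  for (k in which(isS & pt$row == pt$col)) {
    if (vars[pt$row[k]] %in% obs_endo && vars[pt$row[k]] %in% model$obs) {
      start[k] <- 0.4
    }
  }
  start[pt$free]
}

# independence baseline: implied = diag; only variance parameters, which
# match the unit diagonal exactly, so F_b = sum of weighted off-diag r^2
sem_baseline <- function(r_vec, w, gamma, is_diag, n) {
  noff <- sum(!is_diag)
  Fb <- sum(w[!is_diag] * r_vec[!is_diag]^2)
  # U_b: diagonal weights on off-diag moments (variance params span diag)
  Ub <- diag(w * as.numeric(!is_diag))
  trUG <- sum(diag(Ub %*% gamma))
  dfb <- noff
  scal <- if (dfb > 0) trUG / dfb else 1
  if (!is.finite(scal) || scal <= 0) scal <- 1
  list(chisq = (n - 1) * Fb / scal, df = dfb)
}

sem_fit_indices <- function(chisq, df, chisq_b, df_b, n, r_vec, sig_hat,
                            is_diag, q) {
  d <- max(chisq - df, 0)
  db <- max(chisq_b - df_b, 0)
  cfi <- if (max(db, d) == 0) 1 else 1 - d / max(db, d)
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1) {
    min(((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1), 1)
  } else 1
  rmsea <- if (df > 0) sqrt(d / (df * (n - 1))) else 0
  ci <- rmsea_ci(chisq, df, n)
  resid <- r_vec - sig_hat
  srmr <- sqrt(mean(resid^2))
  c(chisq = chisq, df = df, chisq_df = if (df > 0) chisq / df else NA,
    pvalue = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA,
    cfi = cfi, tli = tli, rmsea = rmsea,
    rmsea_lo = ci[1], rmsea_hi = ci[2], srmr = srmr,
    chisq_baseline = chisq_b, df_baseline = df_b,
    aic = chisq + 2 * q, bic = chisq + log(n) * q, n = n)
}

# 90% CI for RMSEA by inverting the noncentral chi-square distribution
rmsea_ci <- function(chisq, df, n, level = 0.90) {
  if (df <= 0 || !is.finite(chisq)) return(c(0, 0))
  a <- (1 - level) / 2
  lo_l <- 0
  if (pchisq(chisq, df, ncp = 0) > 1 - a) {
    f <- function(l) pchisq(chisq, df, ncp = l) - (1 - a)
    lo_l <- tryCatch(uniroot(f, c(0, max(chisq * 5, 1)))$root,
                     error = function(e) 0)
  }
  hi_l <- 0
  if (pchisq(chisq, df, ncp = 0) > a) {
    f <- function(l) pchisq(chisq, df, ncp = l) - a
    hi_l <- tryCatch(uniroot(f, c(0, max(chisq * 10, 1)))$root,
                     error = function(e) 0)
  }
  c(sqrt(lo_l / (df * (n - 1))), sqrt(hi_l / (df * (n - 1))))
}

# standardized solution: scale every path by sd(from)/sd(to), covariances
# to correlations
sem_standardize <- function(model, theta) {
  Sig <- sem_implied_all(model, theta)
  sdv <- sqrt(pmax(diag(Sig), 1e-12))
  pt <- model$ptab
  vals <- pt$start
  vals[pt$free] <- theta
  out <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k]; j <- pt$col[k]
    if (pt$matrix[k] == "A") {
      out[k] <- vals[k] * sdv[j] / sdv[i]
    } else if (i == j) {
      out[k] <- vals[k] / (sdv[i]^2)
    } else {
      out[k] <- vals[k] / (sdv[i] * sdv[j])
    }
  }
  ms <- sem_matrices(model, theta)
  Astd <- ms$A * outer(1 / sdv, sdv)
  list(values = out, matrices = list(A = Astd, sd = sdv, Sigma = Sig))
}

#' @export
print.hg_semfit <- function(x, ...) {
  cat("SEM fit (DWLS on polychoric/mixed correlations), N =", x$n, "\n")
  cat(sprintf("chisq(%d) = %.2f (scaled), chisq/df = %.2f\n",
              x$df, x$fit["chisq"], x$fit["chisq_df"]))
  cat(sprintf("CFI = %.3f  TLI = %.3f  RMSEA = %.3f [%.3f, %.3f]  SRMR = %.3f\n",
              x$fit["cfi"], x$fit["tli"], x$fit["rmsea"],
              x$fit["rmsea_lo"], x$fit["rmsea_hi"], x$fit["srmr"]))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  if (x$heywood) cat("WARNING: Heywood case flagged\n")
  free <- x$est[x$est$free, c("label", "est", "se", "z", "p", "std_est")]
  print(free, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Confirmatory factor analysis of a cluster solution
#'
#' Fits the correlated-factors measurement model implied by a symptom
#' partition: each cluster is a latent factor measured by its symptoms,
#' factors covary freely, estimation is DWLS on polychoric correlations.
#'
#' @param measurement named list: factor -> indicator columns.
#' @param data data frame with the indicator columns (ordinal 1-5).
#' @return an [fit_sem()] result.
#' @export
fit_cfa <- function(measurement, data) {
  model <- sem_model(measurement = measurement,
                     ordinal = unique(unlist(measurement)))
  fit_sem(model, data)
}
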