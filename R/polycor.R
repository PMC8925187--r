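#' Mixed ordinal/continuous correlation layer
#'
#' Estimates the correlation matrix that underlies a data frame containing
#' ordinal (integer-coded) and continuous columns: polychoric correlations
#' between two ordinal variables, polyserial between an ordinal and a
#' continuous variable, and Pearson between two continuous variables.
#' Thresholds are estimated from the marginal category proportions (two-step
#' maximum likelihood). Alongside the point estimates, the function returns
#' the estimated asymptotic covariance matrix of the unique correlations,
#' obtained from per-observation influence functions; its diagonal supplies
#' the weights of the diagonally weighted least squares discrepancy used by
#' [fit_sem()], and the full matrix feeds robust standard errors and the
#' mean-scaled test statistic.
#'
#' @param data data frame of complete cases.
#' @param ordinal character vector naming the ordinal columns; remaining
#'   columns are treated as continuous.
#' @param smooth logical; if the estimated matrix is not positive
#'   semi-definite, clip eigenvalues and renormalise (an attribute
#'   `smoothed` records whether this happened).
#' @return list with `R` (correlation matrix), `gamma` (asymptotic covariance
#'   of the vech-ordered unique correlations, per-observation scale, so
#'   `Cov(r) ~ gamma/n`), `n`, `index` (moment bookkeeping), `types`.
#' @export
mixed_correlation <- function(data, ordinal = character(), smooth = TRUE) {
  stopifnot(is.data.frame(data))
  data <- data[complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  if (n < 50) warning("mixed_correlation: n < 50; estimates may be unstable")
  vars <- names(data)
  p <- length(vars)
  is_ord <- vars %in% ordinal
  # standardize continuous columns; recode ordinal columns to 1..K
  X <- vector("list", p)
  thresholds <- vector("list", p)
  for (j in seq_len(p)) {
    v <- data[[j]]
    if (is_ord[j]) {
      lev <- sort(unique(v))
      if (length(lev) < 2) stop("ordinal column '", vars[j],
                                "' has fewer than 2 observed categories")
      vi <- match(v, lev)
      prop <- cumsum(tabulate(vi, length(lev)) / n)
      thresholds[[j]] <- qnorm(prop[-length(prop)])
      X[[j]] <- vi
    } else {
      if (sd(v) == 0) stop("continuous column '", vars[j],
                           "' has zero variance")
      X[[j]] <- as.numeric(scale(v))
    }
  }
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  pairs <- which(lower.tri(R), arr.ind = TRUE)
  npair <- nrow(pairs)
  IF <- matrix(0, n, npair) # influence functions, one column per moment
  for (l in seq_len(npair)) {
    i <- pairs[l, 1]; j <- pairs[l, 2] # i > j
    if (is_ord[i] && is_ord[j]) {
      est <- polychoric_pair(X[[j]], X[[i]], thresholds[[j]], thresholds[[i]])
    } else if (!is_ord[i] && !is_ord[j]) {
      est <- pearson_pair(X[[j]], X[[i]])
    } else if (is_ord[i]) {
      est <- polyserial_pair(X[[j]], X[[i]], thresholds[[i]])
    } else {
      est <- polyserial_pair(X[[i]], X[[j]], thresholds[[j]])
    }
    R[i, j] <- R[j, i] <- est$rho
    IF[, l] <- est$IF
  }
  gamma <- crossprod(IF) / n
  smoothed <- FALSE
  if (smooth) {
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) {
      lam <- pmax(ev$values, 1e-6)
      R2 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
      d <- sqrt(diag(R2))
      R <- R2 / tcrossprod(d)
      dimnames(R) <- list(vars, vars)
      smoothed <- TRUE
    }
  }
  structure(list(R = R, gamma = gamma, n = n,
                 index = pairs, types = ifelse(is_ord, "ordinal", "numeric"),
                 thresholds = thresholds),
            smoothed = smoothed, class = "hg_mixedcor")
}

# Polychoric correlation for two integer-coded ordinal vectors (two-step ML).
# Returns rho and the per-observation influence function (score / information).
polychoric_pair <- function(x, y, taux, tauy) {
  R1 <- max(x); R2 <- max(y)
  counts <- matrix(0, R1, R2)
  for (i in seq_along(x)) counts[x[i], y[i]] <- counts[x[i], y[i]] + 1
  opt <- optimize(function(r) polychoric_negll(r, taux, tauy, counts),
                  interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  h <- 1e-4
  lp_p <- polychoric_cell_logp(min(rho + h, 0.9995), taux, tauy, R1, R2)
  lp_m <- polychoric_cell_logp(max(rho - h, -0.9995), taux, tauy, R1, R2)
  smat <- (lp_p - lp_m) / (2 * h)
  s <- smat[cbind(x, y)]
  info <- mean(s^2)
  if (info < 1e-12) info <- 1e-12
  list(rho = rho, IF = s / info)
}

# Pearson correlation of two standardized continuous vectors with its
# classical influence function.
pearson_pair <- function(x, y) {
  r <- cor(x, y)
  IF <- x * y - (r / 2) * (x^2 + y^2)
  list(rho = r, IF = IF)
}

# Polyserial correlation: x continuous (standardized), y ordinal (1..K).
# Conditional two-step likelihood given x.
polyserial_pair <- function(x, y, tau) {
  K <- max(y)
  tau_lo <- c(-Inf, tau)[y]
  tau_hi <- c(tau, Inf)[y]
  ll <- function(r) {
    s <- sqrt(1 - r^2)
    p <- pnorm((tau_hi - r * x) / s) - pnorm((tau_lo - r * x) / s)
    sum(log(pmax(p, 1e-12)))
  }
  opt <- optimize(function(r) -ll(r), interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  h <- 1e-4
  lli <- function(r) {
    s <- sqrt(1 - r^2)
    p <- pnorm((tau_hi - r * x) / s) - pnorm((tau_lo - r * x) / s)
    log(pmax(p, 1e-12))
  }
  s_i <- (lli(min(rho + h, 0.9995)) - lli(max(rho - h, -0.9995))) / (2 * h)
  info <- mean(s_i^2)
  if (info < 1e-12) info <- 1e-12
  list(rho = rho, IF = s_i / info)
}

#' Polychoric/polyserial/Pearson correlation matrix
#'
#' Convenience wrapper around [mixed_correlation()] returning just the
#' correlation matrix together with the asymptotic covariance needed for
#' diagonally weighted least squares estimation.
#'
#' @inheritParams mixed_correlation
#' @return see [mixed_correlation()]
#' @export
polychoric_matrix <- function(data, ordinal = character(), smooth = TRUE) {
  mixed_correlation(data, ordinal = ordinal, smooth = smooth)
}
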