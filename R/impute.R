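#' Chained-equations multiple imputation of survey covariates
#'
#' Fills missing covariate cells by iterated conditional draws, column by
#' column: predictive mean matching for numeric columns, Bayesian-flavour
#' logistic draws for binary columns, and proportional-odds draws for
#' ordered factors with 3 or more levels. Observed cells are never
#' changed. The result is `m` completed copies of the table; downstream
#' estimates can be pooled by Rubin's rules ([pool_estimates()]).
#'
#' @param data data frame; columns that are character are treated as
#'   unordered categorical (sampled from conditional frequencies via a
#'   multinomial logistic approximation by PMM on scores).
#' @param m number of imputations (default 5).
#' @param seed integer seed.
#' @param maxit chained-equation sweeps per imputation (default 5).
#' @param donors predictive-mean-matching donor pool size.
#' @return list of `m` completed data frames; attribute `missing_pattern`
#'   records the per-column missing counts.
#' @export
mice_impute <- function(data, m = 5, seed = 1, maxit = 5, donors = 5) {
  stopifnot(is.data.frame(data), m >= 1)
  miss <- vapply(data, function(x) sum(is.na(x)), integer(1))
  if (any(miss == nrow(data))) {
    stop("column(s) with no observed values: ",
         paste(names(data)[miss == nrow(data)], collapse = ", "))
  }
  if (any(miss > 0.5 * nrow(data))) {
    warning("column(s) with more than 50% missingness: ",
            paste(names(data)[miss > 0.5 * nrow(data)], collapse = ", "))
  }
  targets <- names(data)[miss > 0]
  if (!length(targets)) {
    out <- replicate(m, data, simplify = FALSE)
    attr(out, "missing_pattern") <- miss
    return(out)
  }
  # numeric design matrix of predictors (always complete: current fills)
  set.seed(seed)
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    d <- data
    # initial fill: random draws from the observed margins
    for (v in targets) {
      nas <- is.na(d[[v]])
      d[[v]][nas] <- sample(d[[v]][!nas], sum(nas), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in targets) {
        nas <- is.na(data[[v]])
        X <- impute_design(d[setdiff(names(d), v)])
        d[[v]][nas] <- impute_draw(data[[v]], d[[v]], X, nas,
                                   donors = donors)
      }
    }
    out[[imp]] <- d
  }
  attr(out, "missing_pattern") <- miss
  out
}

# numeric design matrix from a mixed data frame (model.matrix-free to
# tolerate rank issues; character columns one-hot minus reference)
impute_design <- function(d) {
  cols <- lapply(names(d), function(nm) {
    x <- d[[nm]]
    if (is.numeric(x)) return(matrix(as.numeric(x), ncol = 1))
    lev <- sort(unique(as.character(x)))
    if (length(lev) < 2) return(NULL)
    sapply(lev[-1], function(l) as.numeric(as.character(x) == l))
  })
  X <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
  if (is.null(X)) X <- matrix(1, nrow(d), 1)
  X
}

# one conditional draw for the missing cells of a column
impute_draw <- function(orig, cur, X, nas, donors = 5) {
  yobs_ix <- which(!nas)
  ymis_ix <- which(nas)
  if (is.numeric(orig) && length(unique(orig[!nas])) > 2) {
    # predictive mean matching
    fit <- lm(cur[yobs_ix] ~ X[yobs_ix, , drop = FALSE])
    bhat <- coef(fit)
    bhat[is.na(bhat)] <- 0
    pr_obs <- drop(cbind(1, X[yobs_ix, , drop = FALSE]) %*% bhat)
    pr_mis <- drop(cbind(1, X[ymis_ix, , drop = FALSE]) %*% bhat)
    vapply(pr_mis, function(p) {
      dd <- abs(pr_obs - p)
      pool <- yobs_ix[order(dd)[seq_len(min(donors, length(dd)))]]
      cur[sample(pool, 1)]
    }, cur[1])
  } else if (is.numeric(orig)) {
    # binary 0/1: logistic draw
    y <- cur[yobs_ix]
    lev <- sort(unique(y))
    yb <- as.numeric(y == max(lev))
    fit <- suppressWarnings(glm(yb ~ X[yobs_ix, , drop = FALSE],
                                family = binomial()))
    bhat <- coef(fit); bhat[is.na(bhat)] <- 0
    eta <- drop(cbind(1, X[ymis_ix, , drop = FALSE]) %*% bhat)
    draw <- rbinom(length(eta), 1, plogis(eta))
    ifelse(draw == 1, max(lev), min(lev))
  } else if (is.ordered(orig) || (is.factor(orig) && nlevels(orig) > 2)) {
    # proportional-odds draw
    df <- data.frame(y = factor(cur[yobs_ix], ordered = TRUE),
                     X[yobs_ix, , drop = FALSE])
    fit <- tryCatch(MASS::polr(y ~ ., data = df, Hess = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(sample(cur[yobs_ix], length(ymis_ix), replace = TRUE))
    }
    nd <- data.frame(X[ymis_ix, , drop = FALSE])
    names(nd) <- names(df)[-1]
    pr <- predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    lev <- levels(df$y)
    vapply(seq_len(nrow(pr)), function(i) {
      sample(lev, 1, prob = pr[i, ])
    }, character(1))
  } else {
    # character / 2-level factor: frequency-weighted logistic-style draw
    y <- as.character(cur[yobs_ix])
    lev <- sort(unique(y))
    if (length(lev) == 1) return(rep(lev, length(ymis_ix)))
    yb <- as.numeric(y == lev[2])
    fit <- suppressWarnings(glm(yb ~ X[yobs_ix, , drop = FALSE],
                                family = binomial()))
    bhat <- coef(fit); bhat[is.na(bhat)] <- 0
    eta <- drop(cbind(1, X[ymis_ix, , drop = FALSE]) %*% bhat)
    ifelse(rbinom(length(eta), 1, plogis(eta)) == 1, lev[2], lev[1])
  }
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param variances numeric vector of per-imputation squared standard
#'   errors.
#' @return list: `estimate`, `se`, `t_df`, `ci` (95%).
#' @export
pool_estimates <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m == length(variances), m >= 1)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1) var(estimates) else 0
  tv <- ubar + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2 else Inf
  tcrit <- if (is.finite(df)) qt(0.975, df) else qnorm(0.975)
  list(estimate = qbar, se = sqrt(tv), t_df = df,
       ci = c(qbar - tcrit * sqrt(tv), qbar + tcrit * sqrt(tv)))
}
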