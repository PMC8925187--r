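#' Decompose standardized effects into direct and indirect parts
#'
#' Enumerates every directed path from `source` to `outcome` in the fitted
#' model's structural graph. The direct effect is the standardized
#' coefficient of the edge `source -> outcome` (0 if absent); each
#' indirect effect is the product of standardized coefficients along one
#' path of length at least two; the total is their sum. Delta-method
#' standard errors are computed from the sandwich covariance of the free
#' parameters.
#'
#' @param fit an [fit_sem()] result.
#' @param source,outcome variable names (observed or latent).
#' @return object of class `hg_effects`: data frame with one row per path
#'   (`path`, `effect`, `se`, `z`, `p`) plus rows `direct`, `indirect`
#'   (sum), `total`.
#' @export
decompose_effects <- function(fit, source, outcome) {
  model <- fit$model
  idx <- model$idx
  if (!source %in% model$vars || !outcome %in% model$vars)
    stop("unknown variable")
  paths <- enumerate_paths(fit$std_all$A, idx[source], idx[outcome])
  eff_fun <- function(theta) {
    A <- sem_standardize(model, theta)$matrices$A
    vapply(paths, function(pth) {
      prod(A[cbind(pth[-1], pth[-length(pth)])])
    }, numeric(1))
  }
  effs <- if (length(paths)) eff_fun(fit$theta) else numeric(0)
  # delta-method SEs via numeric jacobian
  q <- length(fit$theta)
  ses <- rep(NA_real_, length(paths))
  if (length(paths) && q > 0) {
    G <- matrix(0, length(paths), q)
    for (k in seq_len(q)) {
      h <- 1e-5 * max(1, abs(fit$theta[k]))
      tp <- fit$theta; tp[k] <- tp[k] + h
      tm <- fit$theta; tm[k] <- tm[k] - h
      G[, k] <- (eff_fun(tp) - eff_fun(tm)) / (2 * h)
    }
    V <- G %*% fit$vcov %*% t(G)
    ses <- sqrt(pmax(diag(V), 0))
    Gtot <- colSums(G)
    se_tot <- sqrt(max(t(Gtot) %*% fit$vcov %*% Gtot, 0))
    is_dir <- vapply(paths, length, integer(1)) == 2
    Gdir <- if (any(is_dir)) colSums(G[is_dir, , drop = FALSE]) else rep(0, q)
    Gind <- Gtot - Gdir
    se_dir <- sqrt(max(t(Gdir) %*% fit$vcov %*% Gdir, 0))
    se_ind <- sqrt(max(t(Gind) %*% fit$vcov %*% Gind, 0))
  } else {
    se_tot <- se_dir <- se_ind <- NA_real_
  }
  lab <- vapply(paths, function(pth) {
    paste(model$vars[pth], collapse = " -> ")
  }, character(1))
  is_dir <- vapply(paths, length, integer(1)) == 2
  direct <- sum(effs[is_dir])
  indirect <- sum(effs[!is_dir])
  tab <- data.frame(path = c(lab, "direct", "indirect", "total"),
                    effect = c(effs, direct, indirect, direct + indirect),
                    se = c(ses, se_dir, se_ind, se_tot),
                    stringsAsFactors = FALSE)
  tab$z <- tab$effect / tab$se
  tab$p <- 2 * pnorm(-abs(tab$z))
  class(tab) <- c("hg_effects", "data.frame")
  tab
}

# all directed paths source -> outcome in A (A[to, from] != 0), as index
# vectors c(source, ..., outcome); graph is acyclic by construction
enumerate_paths <- function(A, source, outcome) {
  out <- list()
  walk <- function(path) {
    tail <- path[length(path)]
    if (tail == outcome && length(path) > 1) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    nxt <- which(abs(A[, tail]) > 1e-12)
    for (v in nxt) walk(c(path, v))
  }
  walk(source)
  out
}

#' Modification indices
#'
#' Score-test estimates of the chi-square improvement from freeing one
#' currently fixed parameter: candidate cross-loadings (latent ->
#' indicator of another latent) and residual covariances between observed
#' endogenous variables. The index uses the quadratic expansion of the
#' DWLS discrepancy around the optimum, divided by the model's
#' mean-scaling factor so that values are on the same scale as the
#' reported chi-square. The expected parameter change (EPC) is reported
#' alongside.
#'
#' @param fit an [fit_sem()] result.
#' @return data frame (`label`, `mi`, `epc`), sorted by decreasing `mi`;
#'   rows with a singular restricted information are flagged `NA`.
#' @export
modification_indices <- function(fit) {
  model <- fit$model
  obs <- model$obs
  idx <- model$idx
  pt <- model$ptab
  existing <- paste(pt$matrix, pt$row, pt$col)
  cands <- list()
  # cross-loadings
  for (L in model$latents) {
    for (v in setdiff(unlist(model$measurement), model$measurement[[L]])) {
      key <- paste("A", idx[v], idx[L])
      if (!key %in% existing) {
        cands[[length(cands) + 1]] <- list(mat = "A", i = idx[v],
                                           j = idx[L],
                                           label = paste0(L, "=~", v))
      }
    }
  }
  # residual covariances among indicators
  ind <- unlist(model$measurement)
  if (length(ind) > 1) {
    for (a in seq_along(ind)[-1]) for (b in seq_len(a - 1)) {
      i <- idx[ind[a]]; j <- idx[ind[b]]
      key1 <- paste("S", max(i, j), min(i, j))
      key2 <- paste("S", min(i, j), max(i, j))
      if (!key1 %in% existing && !key2 %in% existing) {
        cands[[length(cands) + 1]] <- list(mat = "S", i = max(i, j),
                                           j = min(i, j),
                                           label = paste0(ind[a], "~~",
                                                          ind[b]))
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(label = character(), mi = numeric(),
                      epc = numeric()))
  }
  lt <- fit$moments
  w <- fit$w
  n <- fit$n
  resid <- fit$residuals
  sqw <- sqrt(w)
  qrX <- qr(sqw * fit$Delta)   # projection basis for the free parameters
  out <- lapply(cands, function(cd) {
    # derivative of moments wrt the candidate parameter at 0
    model2 <- model
    model2$ptab <- rbind(pt, data.frame(matrix = cd$mat, row = cd$i,
                                        col = cd$j, free = TRUE, start = 0,
                                        label = cd$label))
    th2 <- c(fit$theta, 0)
    h <- 1e-5
    tp <- th2; tp[length(th2)] <- h
    tm <- th2; tm[length(th2)] <- -h
    dc <- (sem_implied(model2, tp, obs)[lt] -
             sem_implied(model2, tm, obs)[lt]) / (2 * h)
    # robust score test: residualize the weighted moment direction against
    # the free parameters (QR projection, numerically stable), then refer
    # the score to its sampling variance under Gamma rather than to the
    # arbitrary DWLS weights
    u_perp <- qr.resid(qrX, sqw * dc)
    h_cc <- 2 * sum(w * dc * dc)
    denom <- 2 * sum(u_perp^2)
    v <- sqw * u_perp
    g_c <- -2 * sum(v * resid)
    vGv <- drop(t(v) %*% fit$gamma %*% v)
    if (!is.finite(denom) || denom < 1e-8 * max(h_cc, 1) ||
        !is.finite(vGv) || vGv < 1e-12) {
      return(data.frame(label = cd$label, mi = NA_real_, epc = NA_real_))
    }
    data.frame(label = cd$label,
               mi = n * g_c^2 / (4 * vGv),
               epc = -g_c / denom)
  })
  res <- do.call(rbind, out)
  res[order(-ifelse(is.na(res$mi), -Inf, res$mi)), , drop = FALSE]
}

#' Moderation of an exposure path by a binary variable
#'
#' Multi-group comparison: the model is fitted to both groups with all
#' parameters group-specific (free model) and refitted with the target
#' path constrained equal across groups. The comparison reports the
#' scaled chi-square difference with its degrees of freedom, the change
#' in CFI, and a sandwich Wald test of the group difference in the target
#' path (the better-calibrated of the two in moderate samples).
#'
#' @param model an [sem_model()].
#' @param data data frame including the moderator column.
#' @param moderator name of a binary column (two observed levels).
#' @param path label of the constrained path, e.g. `"cluster~exposure"`.
#' @param min_group_n warn below this group size.
#' @return list: `delta_chisq`, `delta_df`, `p_delta`, `delta_cfi`,
#'   `wald_z`, `p_wald`, `groups` (per-group fits), `estimates`.
#' @export
test_moderation <- function(model, data, moderator, path,
                            min_group_n = 50) {
  g <- data[[moderator]]
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2) stop("moderator must be binary")
  d1 <- data[!is.na(g) & g == lev[1], , drop = FALSE]
  d2 <- data[!is.na(g) & g == lev[2], , drop = FALSE]
  if (min(nrow(d1), nrow(d2)) < min_group_n)
    warning("a moderation group has fewer than ", min_group_n, " rows")
  f1 <- fit_sem(model, d1)
  f2 <- fit_sem(model, d2)
  i1 <- which(f1$est$label == path & f1$est$free)
  if (!length(i1)) stop("path label not found or not free: ", path)
  e1 <- f1$est$est[i1]; s1 <- f1$est$se[i1]
  e2 <- f2$est$est[i1]; s2 <- f2$est$se[i1]
  wald_z <- (e1 - e2) / sqrt(s1^2 + s2^2)
  p_wald <- 2 * pnorm(-abs(wald_z))
  con <- fit_sem_constrained(model, list(f1$mc, f2$mc), path)
  free_naive <- f1$chisq_naive + f2$chisq_naive
  # scale the naive difference by its own correction factor: the extra
  # restriction spans a single direction in stacked moment space, and the
  # factor is the trace of the projection difference against the stacked
  # asymptotic covariance of the moments (Satorra-Bentler-style)
  cd <- moderation_scaling(model, f1, f2, path)
  delta <- max(con$chisq_naive - free_naive, 0) / cd
  cbar <- mean(c(f1$scaling, f2$scaling))
  fitcon <- c(chisq = (con$chisq_naive) / cbar,
              df = f1$df + f2$df + 1)
  cfi_free <- mean(c(f1$fit["cfi"], f2$fit["cfi"]))
  # pooled baseline for the constrained CFI
  chib <- f1$fit["chisq_baseline"] + f2$fit["chisq_baseline"]
  dfb <- f1$fit["df_baseline"] + f2$fit["df_baseline"]
  dcon <- max(fitcon["chisq"] - fitcon["df"], 0)
  cfi_con <- if (max(chib - dfb, dcon) == 0) 1 else
    1 - dcon / max(chib - dfb, dcon)
  list(delta_chisq = delta, delta_df = 1,
       p_delta = pchisq(delta, 1, lower.tail = FALSE),
       delta_cfi = unname(cfi_free - cfi_con),
       wald_z = wald_z, p_wald = p_wald,
       estimates = data.frame(group = as.character(lev),
                              est = c(e1, e2), se = c(s1, s2)),
       groups = list(f1, f2))
}

# scaling factor for the 1-df constrained-vs-free chi-square difference:
# tr((P_free - P_con) G) over the stacked, weight-whitened moment space,
# with G the weighted asymptotic covariance of the sample moments
moderation_scaling <- function(model, f1, f2, path) {
  free_ix <- which(model$ptab$free)
  s <- which(model$ptab$label[free_ix] == path)
  B1 <- sqrt(f1$w) * f1$Delta
  B2 <- sqrt(f2$w) * f2$Delta
  m1 <- nrow(B1); q <- ncol(B1)
  # free-model span: blockdiag(B1, B2); constrained: shared column s gets
  # the sqrt(n) relative weighting across groups
  Xfree <- rbind(cbind(B1, matrix(0, m1, q)),
                 cbind(matrix(0, nrow(B2), q), B2))
  shared <- c(sqrt(f1$n) * B1[, s], sqrt(f2$n) * B2[, s])
  Xcon <- cbind(Xfree[, -c(s, q + s), drop = FALSE], shared)
  G <- rbind(cbind(sqrt(f1$w) * t(sqrt(f1$w) * t(f1$gamma)),
                   matrix(0, m1, nrow(B2))),
             cbind(matrix(0, nrow(B2), m1),
                   sqrt(f2$w) * t(sqrt(f2$w) * t(f2$gamma))))
  Qf <- qr.Q(qr(Xfree))
  Qc <- qr.Q(qr(Xcon))
  trf <- sum(Qf * (G %*% Qf))
  trc <- sum(Qc * (G %*% Qc))
  cd <- trf - trc
  if (!is.finite(cd) || cd <= 1e-8) cd <- mean(c(f1$scaling, f2$scaling))
  cd
}

# joint two-group fit with one path constrained equal; moment structures
# are stacked, parameters duplicated except the shared path
fit_sem_constrained <- function(model, mcs, path) {
  obs <- model$obs
  prep <- lapply(mcs, function(mc) {
    R <- mc$R[obs, obs]
    lt <- which(lower.tri(R, diag = TRUE), arr.ind = TRUE)
    is_diag <- lt[, 1] == lt[, 2]
    gamma <- matrix(0, nrow(lt), nrow(lt))
    offmap <- integer(nrow(mc$index))
    for (l in seq_len(nrow(mc$index))) {
      offmap[l] <- which(lt[, 1] == mc$index[l, 1] &
                           lt[, 2] == mc$index[l, 2])
    }
    gamma[offmap, offmap] <- mc$gamma
    w <- numeric(nrow(lt))
    w[!is_diag] <- 1 / pmax(diag(gamma)[!is_diag], 1e-10)
    w[is_diag] <- 20 * max(w[!is_diag])
    list(R = R, lt = lt, w = w, r_vec = R[lt], n = mc$n)
  })
  free_ix <- which(model$ptab$free)
  q <- length(free_ix)
  shared <- which(model$ptab$label[free_ix] == path)
  if (!length(shared)) stop("path not free: ", path)
  # parameter layout: group1 all free params, then group2 params minus the
  # shared one
  map2 <- seq_len(q)
  map2[-shared] <- q + seq_len(q - 1)
  nall <- 2 * q - 1
  start <- c(sem_start_values(model, prep[[1]]$R),
             sem_start_values(model, prep[[2]]$R)[-shared])
  # stacked WLS problem on the (N-1)-weighted naive chi-square scale
  r_stack <- c(prep[[1]]$r_vec, prep[[2]]$r_vec)
  w_stack <- c((prep[[1]]$n - 1) * prep[[1]]$w,
               (prep[[2]]$n - 1) * prep[[2]]$w)
  sigma_stack <- function(th) {
    th1 <- th[seq_len(q)]
    th2 <- th[map2]
    c(sem_implied(model, th1, obs)[prep[[1]]$lt],
      sem_implied(model, th2, obs)[prep[[2]]$lt])
  }
  opt <- lm_wls(sigma_stack, r_stack, w_stack, start)
  list(chisq_naive = opt$objective, converged = opt$converged,
       theta = opt$par)
}

#' Power analyses for SEM
#'
#' `sem_power()` is the RMSEA-based power to detect model misspecification:
#' with noncentrality `lambda = (N - 1) * df * epsilon^2`, the power of the
#' test of close fit (null RMSEA `rmsea_null` against alternative
#' `rmsea_alt`) is the probability that the chi-square statistic exceeds
#' the critical value computed under the null noncentrality. When the two
#' RMSEA values coincide the power equals alpha by construction.
#'
#' @param model_df model degrees of freedom (at least 1).
#' @param N sample size (at least 10).
#' @param rmsea_null,rmsea_alt RMSEA under the null and the alternative.
#' @param alpha test level.
#' @return list `power`, `ncp_null`, `ncp_alt`, `critical`, `note`.
#' @export
sem_power <- function(model_df, N, rmsea_null = 0.05, rmsea_alt = 0.08,
                      alpha = 0.05) {
  stopifnot(model_df >= 1, N >= 10)
  l0 <- (N - 1) * model_df * rmsea_null^2
  l1 <- (N - 1) * model_df * rmsea_alt^2
  crit <- qchisq(1 - alpha, model_df, ncp = l0)
  pw <- pchisq(crit, model_df, ncp = l1, lower.tail = FALSE)
  note <- NULL
  if (isTRUE(all.equal(rmsea_null, rmsea_alt))) {
    note <- "rmsea_alt equals rmsea_null: power is alpha by construction"
    pw <- alpha
  }
  list(power = pw, ncp_null = l0, ncp_alt = l1, critical = crit,
       note = note)
}

#' Monte-Carlo power for a target exposure effect
#'
#' Simulates ordinal-indicator cohorts with a planted standardized
#' exposure -> latent path, fits the SEM, and returns the rejection rate
#' of that path at level `alpha`.
#'
#' @param effect planted standardized effect.
#' @param N sample size per replicate.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @param n_indicators,loading measurement design of the latent outcome.
#' @param alpha test level.
#' @return list `power`, `ci` (binomial 95%), `reps`, `n_fail` (replicates
#'   that did not converge, excluded).
#' @export
target_effect_power <- function(effect, N, reps = 200, seed = 1,
                                n_indicators = 5, loading = 0.85,
                                alpha = 0.05) {
  stopifnot(reps >= 100)
  model <- sem_model(measurement = list(F1 = paste0("y",
                                                    seq_len(n_indicators))),
                     regressions = "F1 ~ exposure",
                     ordinal = paste0("y", seq_len(n_indicators)))
  set.seed(seed)
  seeds <- sample.int(1e7, reps)
  rej <- logical(reps); ok <- logical(reps)
  for (r in seq_len(reps)) {
    d <- simulate_sem_cohort(N, effect, seeds[r], n_indicators, loading)
    ft <- tryCatch(fit_sem(model, d), error = function(e) NULL)
    if (is.null(ft) || !ft$converged) next
    ok[r] <- TRUE
    i <- which(ft$est$label == "F1~exposure")
    rej[r] <- isTRUE(ft$est$p[i] < alpha)
  }
  pw <- mean(rej[ok])
  nok <- sum(ok)
  ci <- pw + c(-1.96, 1.96) * sqrt(pw * (1 - pw) / nok)
  list(power = pw, ci = pmin(pmax(ci, 0), 1), reps = nok,
       n_fail = reps - nok)
}

# one-factor ordinal cohort with continuous exposure regressed on latent
simulate_sem_cohort <- function(N, effect, seed, n_indicators = 5,
                                loading = 0.85,
                                thresholds = c(-1.5, -0.5, 0.5, 1.5)) {
  set.seed(seed)
  z <- rnorm(N)
  f <- effect * z + rnorm(N, 0, sqrt(max(1 - effect^2, 1e-6)))
  lat <- vapply(seq_len(n_indicators), function(j) {
    loading * f + rnorm(N, 0, sqrt(1 - loading^2))
  }, numeric(N))
  lik <- matrix(cut(lat, c(-Inf, thresholds, Inf), labels = FALSE), N,
                n_indicators)
  d <- as.data.frame(lik)
  names(d) <- paste0("y", seq_len(n_indicators))
  d$exposure <- z
  d
}
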