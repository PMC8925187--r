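onefac <- sem_model(measurement = list(F1 = paste0("y", 1:5)),
                    regressions = "F1 ~ exposure",
                    ordinal = paste0("y", 1:5))

test_that("a correctly specified model fits cleanly at large n", {
  d <- hgclust:::simulate_sem_cohort(2000, 0.3, seed = 41)
  f <- fit_sem(onefac, d)
  expect_true(f$converged)
  expect_false(f$heywood)
  expect_lt(f$fit["chisq_df"], 2)
  expect_gt(f$fit["cfi"], 0.98)
  expect_lt(f$fit["rmsea"], 0.05)
  expect_lt(f$fit["srmr"], 0.03)
  # loadings near the planted 0.85
  lam <- f$est$std_est[grepl("^F1=~y", f$est$label)]
  expect_lt(max(abs(lam - 0.85)), 0.07)
})

test_that("a saturated model reports perfect fit by convention", {
  set.seed(42)
  d <- data.frame(a = rnorm(300), b = rnorm(300))
  m <- sem_model(regressions = "b ~ a")
  f <- fit_sem(m, d)
  expect_equal(unname(f$df), 0)
  expect_equal(unname(f$fit["cfi"]), 1)
  expect_equal(unname(f$fit["rmsea"]), 0)
  # under-identified model is rejected before optimization
  m2 <- sem_model(measurement = list(L = c("a", "b")),
                  covariances = list(c("a", "b")))
  expect_error(fit_sem(m2, d), "identified")
})

test_that("the planted exposure path is recovered without material bias", {
  ests <- vapply(1:12, function(s) {
    d <- hgclust:::simulate_sem_cohort(250, 0.3, seed = 500 + s)
    f <- fit_sem(onefac, d)
    f$est$std_est[f$est$label == "F1~exposure"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3), 0.1)
  expect_lt(median(abs(ests - 0.3)), 0.1)
})

test_that("standardized effects are invariant to rescaling the exposure", {
  d <- hgclust:::simulate_sem_cohort(400, 0.3, seed = 43)
  f1 <- fit_sem(onefac, d)
  d2 <- d
  d2$exposure <- d2$exposure * 10
  f2 <- fit_sem(onefac, d2)
  i <- which(f1$est$label == "F1~exposure")
  expect_equal(f1$est$std_est[i], f2$est$std_est[i], tolerance = 1e-6)
})

test_that("effect decomposition follows the path-product rule", {
  set.seed(44)
  n <- 1500
  a <- rnorm(n)
  b <- 0.5 * a + sqrt(0.75) * rnorm(n)
  cc <- 0.4 * b + 0.3 * a + rnorm(n, 0, sqrt(1 - 0.16 - 0.09 - 2 * .3 * .4 * .5))
  d <- data.frame(a = a, b = b, c = cc)
  m <- sem_model(regressions = c("b ~ a", "c ~ b + a"))
  f <- fit_sem(m, d)
  de <- decompose_effects(f, "a", "c")
  ab <- f$est$std_est[f$est$label == "b~a"]
  bc <- f$est$std_est[f$est$label == "c~b"]
  ac <- f$est$std_est[f$est$label == "c~a"]
  ind <- de$effect[de$path == "indirect"]
  expect_equal(ind, ab * bc, tolerance = 1e-10)
  expect_equal(de$effect[de$path == "direct"], ac, tolerance = 1e-10)
  expect_equal(de$effect[de$path == "total"], ac + ab * bc,
               tolerance = 1e-10)
  expect_equal(ind, 0.5 * 0.4, tolerance = 0.08)
})

test_that("effect decomposition equals brute-force path enumeration", {
  # random DAGs on 5 observed variables
  for (s in 1:5) {
    set.seed(600 + s)
    nv <- 5
    nm <- paste0("v", 1:nv)
    # upper-triangular random adjacency guarantees acyclicity
    regs <- character(0)
    for (j in 2:nv) {
      parents <- nm[which(runif(j - 1) < 0.6)]
      if (!length(parents)) parents <- nm[sample.int(j - 1, 1)]
      regs <- c(regs, paste(nm[j], "~", paste(parents, collapse = " + ")))
    }
    n <- 500
    X <- matrix(rnorm(n * nv), n, nv, dimnames = list(NULL, nm))
    for (j in 2:nv) X[, j] <- X[, j] + 0.4 * rowSums(X[, 1:(j - 1), drop = FALSE])
    d <- as.data.frame(X)
    m <- sem_model(regressions = regs)
    f <- fit_sem(m, d)
    de <- decompose_effects(f, "v1", nm[nv])
    # oracle over the fitted standardized edges
    A <- f$std_all$A
    edges <- which(abs(A) > 1e-12, arr.ind = TRUE)
    el <- data.frame(from = f$model$vars[edges[, 2]],
                     to = f$model$vars[edges[, 1]],
                     weight = A[edges])
    oracle <- paths_oracle(el, "v1", nm[nv])
    tot_oracle <- sum(vapply(oracle, function(o) o$prod, numeric(1)))
    expect_equal(de$effect[de$path == "total"], tot_oracle,
                 tolerance = 1e-10)
    expect_equal(sum(de$path %in% c("direct", "indirect", "total")), 3)
    expect_length(oracle, nrow(de) - 3)
  }
})

test_that("modification indices localize an omitted cross-loading", {
  simx <- function(n, seed, cross) {
    set.seed(seed)
    f1 <- rnorm(n); f2 <- 0.3 * f1 + rnorm(n, 0, sqrt(0.91))
    X <- vapply(1:4, function(j) 0.85 * f1 + rnorm(n, 0, sqrt(1 - 0.7225)),
                numeric(n))
    Z <- vapply(1:3, function(j) 0.85 * f2 + rnorm(n, 0, sqrt(1 - 0.7225)),
                numeric(n))
    if (cross) {
      X[, 4] <- 0.6 * f1 + 0.5 * f2 +
        rnorm(n, 0, sqrt(max(1 - 0.36 - 0.25 - 2 * 0.6 * 0.5 * 0.3, 0.05)))
    }
    lik <- matrix(cut(cbind(X, Z), c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                      labels = FALSE), n)
    d <- as.data.frame(lik)
    names(d) <- c(paste0("x", 1:4), paste0("z", 1:3))
    d
  }
  m <- sem_model(measurement = list(F1 = paste0("x", 1:4),
                                    F2 = paste0("z", 1:3)),
                 ordinal = c(paste0("x", 1:4), paste0("z", 1:3)))
  hits <- vapply(1:8, function(s) {
    f <- fit_sem(m, simx(600, 700 + s, cross = TRUE))
    mi <- modification_indices(f)
    mi$label[which.max(mi$mi)] == "F2=~x4"
  }, logical(1))
  expect_gte(mean(hits), 0.75)
  # correct model: indices stay modest
  maxmi <- vapply(1:8, function(s) {
    f <- fit_sem(m, simx(600, 800 + s, cross = FALSE))
    max(modification_indices(f)$mi, na.rm = TRUE)
  }, numeric(1))
  expect_lt(median(maxmi), 6)
})

test_that("freeing the top modification index improves the fit", {
  set.seed(45)
  n <- 800
  f1 <- rnorm(n); f2 <- 0.3 * f1 + rnorm(n, 0, sqrt(0.91))
  X <- vapply(1:4, function(j) 0.85 * f1 + rnorm(n, 0, sqrt(1 - 0.7225)),
              numeric(n))
  Z <- vapply(1:3, function(j) 0.85 * f2 + rnorm(n, 0, sqrt(1 - 0.7225)),
              numeric(n))
  X[, 4] <- 0.6 * f1 + 0.5 * f2 +
    rnorm(n, 0, sqrt(max(1 - 0.36 - 0.25 - 2 * 0.6 * 0.5 * 0.3, 0.05)))
  lik <- matrix(cut(cbind(X, Z), c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                    labels = FALSE), n)
  d <- as.data.frame(lik)
  names(d) <- c(paste0("x", 1:4), paste0("z", 1:3))
  m0 <- sem_model(measurement = list(F1 = paste0("x", 1:4),
                                     F2 = paste0("z", 1:3)),
                  ordinal = names(d))
  f0 <- fit_sem(m0, d)
  mi <- modification_indices(f0)
  expect_equal(mi$label[1], "F2=~x4")
  m1 <- sem_model(measurement = list(F1 = paste0("x", 1:4),
                                     F2 = c(paste0("z", 1:3), "x4")),
                  ordinal = names(d))
  f1_ <- fit_sem(m1, d)
  expect_lt(f1_$fit["chisq"], f0$fit["chisq"])
  expect_gt(f0$fit["chisq"] - f1_$fit["chisq"], 0.5 * mi$mi[1] * 0.5)
})

test_that("sex moderation testing is calibrated and powered", {
  m <- sem_model(measurement = list(F1 = paste0("y", 1:4)),
                 regressions = "F1 ~ exposure",
                 ordinal = paste0("y", 1:4))
  simg <- function(n, b1, b2, seed) {
    set.seed(seed)
    g <- rep(0:1, each = n)
    z <- rnorm(2 * n)
    b <- ifelse(g == 0, b1, b2)
    f <- b * z + rnorm(2 * n, 0, sqrt(1 - b^2))
    lat <- vapply(1:4, function(j) 0.85 * f + rnorm(2 * n, 0, sqrt(1 - 0.7225)),
                  numeric(2 * n))
    lik <- matrix(cut(lat, c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                      labels = FALSE), 2 * n)
    d <- as.data.frame(lik)
    names(d) <- paste0("y", 1:4)
    d$exposure <- z
    d$sex <- g
    d
  }
  # planted group difference is detected
  det <- vapply(1:6, function(s) {
    tm <- test_moderation(m, simg(300, 0.3, 0, 900 + s), "sex",
                          "F1~exposure")
    tm$p_wald < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.7)
  # null: mostly non-significant
  nulls <- vapply(1:12, function(s) {
    tm <- test_moderation(m, simg(250, 0.3, 0.3, 950 + s), "sex",
                          "F1~exposure")
    c(tm$p_wald, tm$p_delta)
  }, numeric(2))
  expect_gte(mean(nulls[1, ] >= 0.05), 0.8)
  expect_gte(mean(nulls[2, ] >= 0.05), 0.8)
  # df bookkeeping: one extra constraint
  tm <- test_moderation(m, simg(150, 0.3, 0.3, 999), "sex", "F1~exposure")
  expect_equal(tm$delta_df, 1)
  expect_equal(nrow(tm$estimates), 2)
})

test_that("RMSEA-based power behaves like the noncentral chi-square", {
  p0 <- sem_power(40, 242, 0.05, 0.05)
  expect_equal(p0$power, 0.05)
  expect_match(p0$note, "alpha")
  # monotone in N
  pw <- vapply(c(100, 200, 400, 800), function(N) {
    sem_power(40, N, 0.05, 0.08)$power
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  # monotone in the RMSEA separation
  pw2 <- vapply(c(0.06, 0.08, 0.10), function(ra) {
    sem_power(40, 242, 0.05, ra)$power
  }, numeric(1))
  expect_true(all(diff(pw2) > 0))
  expect_error(sem_power(0, 200))
})

test_that("Monte-Carlo target-effect power increases with the effect", {
  p_small <- target_effect_power(0.2, 150, reps = 120, seed = 46)
  p_large <- target_effect_power(0.5, 150, reps = 120, seed = 46)
  expect_gt(p_large$power, p_small$power)
  expect_lte(p_large$n_fail, 10)
})
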