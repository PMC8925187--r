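test_that("cluster homogeneity equals the leading eigenvalue", {
  set.seed(1)
  x <- rnorm(200)
  expect_equal(cluster_homogeneity(cbind(x)), 1)
  # two columns: eigenvalues of [[1, r], [r, 1]] are 1 +/- r
  y <- 0.6 * x + 0.8 * rnorm(200)
  r <- cor(x, y)
  expect_equal(cluster_homogeneity(cbind(x, y)), 1 + abs(r),
               tolerance = 1e-12)
  # independent eigen-decomposition oracle on random matrices
  for (s in 1:6) {
    set.seed(100 + s)
    p <- sample(3:12, 1)
    m <- matrix(rnorm(200 * p), 200, p)
    expect_equal(cluster_homogeneity(m),
                 eigen(cor(m), symmetric = TRUE)$values[1],
                 tolerance = 1e-10)
  }
  bad <- cbind(a = rnorm(50), b = rep(2, 50))
  expect_error(cluster_homogeneity(bad), "b")
})

test_that("tree construction is greedy on the aggregation cost", {
  set.seed(2)
  x <- rnorm(150)
  m <- cbind(s1 = x, s2 = x, s3 = rnorm(150))   # s1, s2 perfectly correlated
  tr <- build_tree(m)
  expect_equal(sort(unlist(tr$merges[1, c("a", "b")])), c("s1", "s2"),
               ignore_attr = TRUE)
  expect_lt(tr$merges$d[1], 1e-10)
  expect_equal(nrow(tr$merges), 2)
  # exhaustive-search oracle for the first merge, p = 6
  for (s in 1:5) {
    set.seed(200 + s)
    m6 <- matrix(rnorm(100 * 6), 100, 6)
    colnames(m6) <- sprintf("v%d", 1:6)
    R <- cor(m6)
    best <- Inf; best_pair <- NULL
    for (i in 1:5) for (j in (i + 1):6) {
      d <- 2 - eigen(R[c(i, j), c(i, j)], symmetric = TRUE)$values[1]
      if (d < best) { best <- d; best_pair <- c(i, j) }
    }
    tr6 <- build_tree(m6)
    expect_setequal(unlist(tr6$merges[1, c("a", "b")]),
                    colnames(m6)[best_pair])
    expect_equal(tr6$merges$d[1], best, tolerance = 1e-10)
  }
})

test_that("total homogeneity is non-increasing and ends at the full eigenvalue", {
  sim <- sim_likert(200, c(3, 3), seed = 4)
  tr <- build_tree(likert_matrix(sim$likert))
  expect_true(all(diff(tr$homogeneity_path) < 1e-8))
  expect_true(all(tr$merges$d >= -1e-10))
  R <- cor(sim$likert, use = "pairwise.complete.obs")
  expect_equal(tr$homogeneity_path[length(tr$homogeneity_path)],
               eigen(R, symmetric = TRUE)$values[1], tolerance = 1e-8)
})

test_that("cutting the tree returns the requested number of clusters", {
  sim <- sim_likert(250, c(3, 3, 3), seed = 5)
  tr <- build_tree(likert_matrix(sim$likert))
  p <- ncol(sim$likert)
  expect_equal(unname(cut_tree(tr, p)), seq_len(p))
  expect_equal(length(unique(cut_tree(tr, 1))), 1)
  expect_error(cut_tree(tr, 0))
  expect_error(cut_tree(tr, p + 1))
  # planted two clusters with strong loadings are recovered
  hits <- vapply(1:20, function(s) {
    sm <- sim_likert(400, c(4, 4), loading = 0.85, seed = 300 + s)
    part <- cut_tree(build_tree(likert_matrix(sm$likert)), 2)
    adjusted_rand(part, sm$truth) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("composite scores behave like first principal components", {
  set.seed(6)
  sim <- sim_likert(500, c(4, 4), loading = 0.85, seed = 6)
  lm_ <- likert_matrix(sim$likert)
  # single-variable cluster: the standardized variable itself
  part1 <- setNames(c(1, rep(2, 7)), colnames(sim$likert))
  sol1 <- composite_scores(lm_, part1)
  z <- as.numeric(scale(sim$likert[, 1]))
  expect_equal(abs(cor(sol1$composite_scores[, 1], z)), 1,
               tolerance = 1e-10)
  expect_equal(unname(sol1$squared_loadings[1]), 1)
  # two-variable cluster: explained proportion is (1 + r)/2
  part2 <- setNames(c(1, 1, rep(2, 6)), colnames(sim$likert))
  sol2 <- composite_scores(lm_, part2)
  r12 <- cor(sim$likert[, 1], sim$likert[, 2])
  expect_equal(sol2$explained_prop[1], (1 + r12) / 2, tolerance = 1e-10)
  # full solution: explained matches the eigen oracle, orientation positive
  sol <- composite_scores(lm_, sim$truth)
  for (k in 1:2) {
    mem <- names(sim$truth)[sim$truth == k]
    lam1 <- eigen(cor(sim$likert[, mem]), symmetric = TRUE)$values[1]
    expect_equal(sol$explained_prop[k], lam1 / length(mem),
                 tolerance = 1e-10)
    im <- rowMeans(sim$likert[, mem])
    expect_gte(cor(sol$composite_scores[, k], im), 0)
  }
  expect_true(all(sol$squared_loadings >= 0 & sol$squared_loadings <= 1))
})

test_that("pruning removes weak symptoms and flags weak clusters", {
  sim <- sim_likert(400, c(5, 5), loading = 0.88, n_noise = 1, seed = 9)
  lm_ <- likert_matrix(sim$likert)
  # assign the noise symptom into cluster 1
  part <- sim$truth
  part[part == 0] <- 1
  sol <- composite_scores(lm_, part)
  pr <- prune_clusters(lm_, sol)
  noise_id <- names(sim$truth)[sim$truth == 0]
  expect_false(noise_id %in% names(pr$partition))
  expect_setequal(names(pr$partition), names(sim$truth)[sim$truth > 0])
  expect_true(all(pr$retained))
  # already-clean solution is a fixpoint
  sol_clean <- composite_scores(lm_, sim$truth)
  pr2 <- prune_clusters(lm_, sol_clean)
  expect_identical(pr2$partition, sol_clean$partition)
  expect_equal(pr2$squared_loadings, sol_clean$squared_loadings)
  # a cluster collapsing below 2 members is flagged degenerate
  sim2 <- sim_likert(300, c(4), loading = 0.9, n_noise = 1, seed = 10)
  # cluster 2 pairs the noise column with one informative symptom: after
  # pruning it cannot keep 2 strong members
  part3 <- setNames(c(rep(1, 3), 2, 2), colnames(sim2$likert))
  sol3 <- composite_scores(lm2 <- likert_matrix(sim2$likert), part3)
  pr3 <- prune_clusters(lm2, sol3)
  expect_true(any(pr3$degenerate) || any(!pr3$retained))
})

test_that("adjusted Rand index matches the contingency-table formula", {
  p1 <- setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(adjusted_rand(p1, p1), 1)
  relab <- setNames(c(9, 9, 4, 4), letters[1:4])
  expect_equal(adjusted_rand(p1, relab), 1)
  p2 <- setNames(c(1, 2, 1, 2), letters[1:4])
  expect_equal(adjusted_rand(p1, p2), -0.5)
  # brute-force oracle on random partitions; symmetry
  if (requireNamespace("mclust", quietly = TRUE)) {
    for (s in 1:10) {
      set.seed(400 + s)
      a <- sample(1:4, 30, replace = TRUE)
      b <- sample(1:3, 30, replace = TRUE)
      expect_equal(adjusted_rand(a, b), ari_oracle(a, b),
                   tolerance = 1e-12)
      expect_equal(adjusted_rand(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
      expect_equal(adjusted_rand(a, b), adjusted_rand(b, a),
                   tolerance = 1e-12)
    }
  }
  expect_error(adjusted_rand(1:3, 1:4), "same items")
})

test_that("bootstrap stability separates structure from noise", {
  sim <- sim_likert(300, c(4, 4), loading = 0.88, seed = 12)
  st <- bootstrap_stability(likert_matrix(sim$likert), K_range = 2:4,
                            B = 25, seed = 3)
  expect_gte(st$mean_ari[st$K == 2], 0.9)
  expect_true(all(st$mean_ari >= -1 & st$mean_ari <= 1))
  st_rep <- bootstrap_stability(likert_matrix(sim$likert), K_range = 2:4,
                                B = 25, seed = 3)
  expect_identical(st, st_rep)
  # pure noise: stability near zero
  set.seed(13)
  noise <- matrix(sample(1:5, 200 * 10, replace = TRUE), 200, 10)
  colnames(noise) <- sprintf("n%02d", 1:10)
  stn <- bootstrap_stability(likert_matrix(noise), K_range = 3, B = 25,
                             seed = 4)
  expect_lt(abs(stn$mean_ari), 0.2)
})

test_that("Cronbach alpha reproduces the closed forms", {
  set.seed(14)
  n <- 400
  x <- rnorm(n)
  make_items <- function(p, r) {
    its <- vapply(seq_len(p), function(i) sqrt(r) * x + sqrt(1 - r) * rnorm(n),
                  numeric(n))
    scale(its)   # unit variances: alpha = p rbar / (1 + (p-1) rbar) exactly
  }
  m2 <- make_items(2, 0.5)
  r12 <- cor(m2)[1, 2]
  expect_equal(cronbach_alpha(m2), 2 * r12 / (1 + r12), tolerance = 1e-10)
  m9 <- make_items(9, 0.5)
  R <- cor(m9)
  rbar <- mean(R[lower.tri(R)])
  expect_equal(cronbach_alpha(m9), 9 * rbar / (1 + 8 * rbar),
               tolerance = 1e-10)
  indep <- scale(matrix(rnorm(n * 5), n, 5))
  expect_lt(abs(cronbach_alpha(indep)), 0.15)
  expect_error(cronbach_alpha(cbind(x)), "2 items")
})

test_that("K selection maximizes stability with the aggregation-gap tie-break", {
  sim <- sim_likert(400, c(3, 3, 3, 3, 3, 3), loading = 0.88, seed = 15)
  lm_ <- likert_matrix(sim$likert)
  tr <- build_tree(lm_)
  st <- bootstrap_stability(lm_, K_range = 4:8, B = 25, seed = 5)
  sel <- select_k(tr, st)
  expect_equal(sel$K, 6)
  # manual tie: both K rows get the same mean ARI; gap decides
  st2 <- st
  st2$mean_ari[] <- 0.5
  sel2 <- select_k(tr, st2)
  expect_true(sel2$tie)
  gaps <- sel2$table$aggregation_gap
  expect_equal(sel2$table$aggregation_gap[sel2$table$K == sel2$K],
               max(gaps))
  expect_error(select_k(tr, st, K_range = 99), "empty")
})
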