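#' Construct a participants-by-symptoms Likert matrix
#'
#' Validates and wraps an ordinal (1-5) symptom table for variable
#' clustering. Columns with fewer than two distinct observed values are
#' rejected: a constant symptom carries no clustering information and breaks
#' the correlation-based homogeneity criterion.
#'
#' @param values matrix or data frame of integer scores in 1..5; `NA` allowed.
#' @param symptom_ids,participant_ids optional labels (default from dimnames).
#' @return object of class `hg_likert` (a validated numeric matrix).
#' @export
likert_matrix <- function(values, symptom_ids = NULL, participant_ids = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  obs <- m[!is.na(m)]
  if (length(obs) == 0) stop("no observed values")
  if (!all(obs %in% 1:5)) stop("observed Likert values must be in {1,...,5}")
  if (is.null(symptom_ids)) symptom_ids <- colnames(m)
  if (is.null(symptom_ids)) symptom_ids <- sprintf("sym_%03d", seq_len(ncol(m)))
  if (is.null(participant_ids)) participant_ids <- rownames(m)
  if (is.null(participant_ids)) participant_ids <- as.character(seq_len(nrow(m)))
  ndist <- apply(m, 2, function(x) length(unique(x[!is.na(x)])))
  if (any(ndist < 2)) {
    stop("columns with < 2 distinct observed values: ",
         paste(symptom_ids[ndist < 2], collapse = ", "))
  }
  dimnames(m) <- list(participant_ids, symptom_ids)
  structure(m, class = c("hg_likert", "matrix"))
}

# Pairwise-complete correlation matrix of the (numeric-scored) Likert data.
likert_cor <- function(data) {
  m <- unclass(data)
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0)) {
    stop("zero-variance column: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  cor(m, use = "pairwise.complete.obs")
}

#' Homogeneity of a cluster of variables
#'
#' The homogeneity criterion of a variable cluster is the leading eigenvalue
#' of the members' correlation matrix, which equals the sum of squared
#' correlations of the members with the cluster's first principal component.
#' It ranges from 1 (mutually orthogonal members) to the number of members
#' (perfectly correlated members).
#'
#' @param columns numeric matrix (columns are the cluster members), already
#'   on comparable scales; missing values handled pairwise.
#' @return largest eigenvalue of the correlation matrix of `columns`.
#' @export
cluster_homogeneity <- function(columns) {
  m <- as.matrix(columns)
  if (ncol(m) == 1) {
    if (sd(m[, 1], na.rm = TRUE) == 0)
      stop("zero-variance column: ", colnames(m)[1] %||% "1")
    return(1)
  }
  sds <- apply(m, 2, sd, na.rm = TRUE)
  if (any(sds == 0)) {
    stop("zero-variance column: ",
         paste((colnames(m) %||% as.character(seq_len(ncol(m))))[sds == 0],
               collapse = ", "))
  }
  R <- cor(m, use = "pairwise.complete.obs")
  lambda1(R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Leading eigenvalue of a symmetric matrix.
lambda1 <- function(R) {
  eigen(R, symmetric = TRUE, only.values = TRUE)$values[1]
}

#' Hierarchical variable clustering under the homogeneity criterion
#'
#' Agglomerates variables bottom-up: starting from singleton clusters, each
#' step merges the pair (A, B) whose aggregation cost
#' `d(A, B) = H(A) + H(B) - H(A union B)` is smallest, where `H` is the
#' cluster homogeneity ([cluster_homogeneity()]). Merging two clusters can
#' never increase total homogeneity, so `d >= 0`; small `d` means the two
#' clusters share a common principal direction. Ties are broken toward the
#' lexicographically smallest member label.
#'
#' @param data an [likert_matrix()] object, or any numeric matrix of
#'   comparable-scale variables.
#' @return object of class `hg_vartree`: list with `merges` (data frame of
#'   labels and heights), `homogeneity_path` (total homogeneity after each
#'   merge), `labels`, and the membership history needed by [cut_tree()].
#' @export
build_tree <- function(data) {
  m <- unclass(as.matrix(data))
  p <- ncol(m)
  if (p < 2) stop("need at least 2 columns")
  R <- if (inherits(data, "hg_likert")) likert_cor(data) else {
    sds <- apply(m, 2, sd, na.rm = TRUE)
    if (any(sds == 0)) stop("zero-variance column: ",
                            paste(colnames(m)[sds == 0], collapse = ", "))
    cor(m, use = "pairwise.complete.obs")
  }
  labels <- colnames(m) %||% sprintf("V%d", seq_len(p))
  clusters <- vector("list", 2 * p - 1)    # member column indices per slot
  clusters[seq_len(p)] <- as.list(seq_len(p))
  key <- c(labels, rep(NA_character_, p - 1)) # tie-break: smallest label
  H <- c(rep(1, p), rep(NA_real_, p - 1))  # homogeneity per slot
  active <- c(rep(TRUE, p), rep(FALSE, p - 1))
  # pairwise merge costs indexed by cluster slot (p singletons + p-1 merged),
  # NA when either slot is inactive
  D <- matrix(NA_real_, 2 * p - 1, 2 * p - 1)
  for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
    D[i, j] <- 2 - (1 + abs(R[i, j]))      # d for singletons: 1 - |r|
  }
  merges <- data.frame(a = character(0), b = character(0), d = numeric(0),
                       stringsAsFactors = FALSE)
  steps <- vector("list", p - 1)
  hom_path <- numeric(p - 1)
  slots <- p
  for (step in seq_len(p - 1)) {
    idx <- which(!is.na(D), arr.ind = TRUE)
    dvals <- D[idx]
    best <- which(dvals <= min(dvals) + 1e-12)
    if (length(best) > 1) {
      # tie-break: smallest member label among candidate pairs
      keys <- vapply(best, function(b) {
        min(key[idx[b, 1]], key[idx[b, 2]])
      }, character(1))
      best <- best[order(keys)][1]
    } else best <- best[1]
    i <- idx[best, 1]; j <- idx[best, 2]
    dmin <- D[i, j]
    newmem <- c(clusters[[i]], clusters[[j]])
    Hnew <- lambda1(R[newmem, newmem, drop = FALSE])
    # contract: merging never increases total homogeneity
    if (Hnew > H[i] + H[j] + 1e-8) {
      warning("homogeneity increased on merge; numerical issue suspected")
    }
    slots <- slots + 1
    clusters[[slots]] <- newmem
    H[slots] <- Hnew
    key[slots] <- min(key[i], key[j])
    active[c(i, j)] <- FALSE
    active[slots] <- TRUE
    merges <- rbind(merges, data.frame(a = key[i], b = key[j], d = dmin,
                                       stringsAsFactors = FALSE))
    steps[[step]] <- c(i, j, slots)
    D[c(i, j), ] <- NA; D[, c(i, j)] <- NA
    for (k in which(active)) {
      if (k == slots) next
      mem <- c(newmem, clusters[[k]])
      dval <- H[slots] + H[k] - lambda1(R[mem, mem, drop = FALSE])
      D[min(k, slots), max(k, slots)] <- max(dval, 0)
    }
    hom_path[step] <- sum(H[active])
  }
  structure(list(merges = merges, homogeneity_path = hom_path,
                 labels = labels, steps = steps, clusters = clusters,
                 p = p, R = R),
            class = "hg_vartree")
}

#' Cut a variable-clustering tree into K clusters
#'
#' Undoes the last `K - 1` merges of the tree, i.e. returns the partition
#' that was current after `p - K` merges.
#'
#' @param tree an [build_tree()] result.
#' @param K number of clusters, between 1 and the number of variables.
#' @return named integer vector mapping each variable to a cluster in 1..K.
#' @export
cut_tree <- function(tree, K) {
  p <- tree$p
  if (K < 1 || K > p) stop("K must be in 1..", p)
  active <- c(rep(TRUE, p), rep(FALSE, p - 1))
  nmerge <- p - K
  if (nmerge > 0) {
    for (s in seq_len(nmerge)) {
      st <- tree$steps[[s]]
      active[st[1:2]] <- FALSE
      active[st[3]] <- TRUE
    }
  }
  part <- integer(p)
  cl <- 0
  for (slot in which(active)) {
    cl <- cl + 1
    part[tree$clusters[[slot]]] <- cl
  }
  names(part) <- tree$labels
  part
}

#' Composite (synthetic) scores per cluster
#'
#' For each cluster, the composite variable is the first principal component
#' of its standardized members: a weighted linear combination that can be
#' read as a per-participant gradient of symptom frequency. Scores are
#' oriented so that a higher score means higher symptom frequency
#' (correlation of the composite with the mean of its items is
#' non-negative). A participant with missing items gets available-item mean
#' imputation within the cluster when at least half the items are observed;
#' otherwise the score is missing.
#'
#' @param data an [likert_matrix()] object (or numeric matrix).
#' @param partition named integer vector as from [cut_tree()].
#' @return object of class `hg_clustersolution`: list with `K`, `partition`,
#'   `composite_scores` (participants x K), `squared_loadings` (per symptom,
#'   r-squared with its own composite), `explained_prop` (per cluster,
#'   homogeneity divided by cluster size), `cronbach_alpha` (per cluster, NA
#'   for singletons), `retained` (all TRUE until [prune_clusters()]),
#'   `degenerate` (all FALSE initially), `loadings` (signed PC weights).
#' @export
composite_scores <- function(data, partition) {
  m <- unclass(as.matrix(data))
  p <- ncol(m)
  labs <- colnames(m) %||% sprintf("V%d", seq_len(p))
  if (is.null(names(partition))) names(partition) <- labs
  if (!setequal(names(partition), labs))
    stop("partition labels do not match data columns")
  partition <- partition[labs]
  K <- length(unique(partition))
  kl <- sort(unique(partition))
  Z <- scale(m)
  scores <- matrix(NA_real_, nrow(m), K)
  colnames(scores) <- paste0("cluster", seq_len(K))
  rownames(scores) <- rownames(m)
  sq <- setNames(rep(NA_real_, p), labs)
  expl <- numeric(K)
  alpha <- rep(NA_real_, K)
  loadings <- setNames(rep(NA_real_, p), labs)
  for (ki in seq_along(kl)) {
    mem <- which(partition == kl[ki])
    Zk <- Z[, mem, drop = FALSE]
    if (length(mem) == 1) {
      s <- Zk[, 1]
      expl[ki] <- 1
      sq[mem] <- 1
      loadings[mem] <- 1
    } else {
      Rk <- cor(m[, mem, drop = FALSE], use = "pairwise.complete.obs")
      e <- eigen(Rk, symmetric = TRUE)
      v <- e$vectors[, 1]
      expl[ki] <- e$values[1] / length(mem)
      # available-item handling: mean-impute standardized values when at
      # least half the items are observed for the participant
      nobs <- rowSums(!is.na(Zk))
      Zi <- Zk
      rmean <- rowMeans(Zk, na.rm = TRUE)
      for (jj in seq_len(ncol(Zi))) {
        miss <- is.na(Zi[, jj]) & nobs >= ceiling(length(mem) / 2)
        Zi[miss, jj] <- rmean[miss]
      }
      s <- as.numeric(Zi %*% v)
      s[nobs < ceiling(length(mem) / 2)] <- NA
      item_mean <- rowMeans(m[, mem, drop = FALSE], na.rm = TRUE)
      cc <- complete.cases(s, item_mean)
      if (sum(cc) > 2 && sd(s[cc]) > 0 &&
          cor(s[cc], item_mean[cc]) < 0) {
        v <- -v
        s <- -s
      }
      for (jj in seq_along(mem)) {
        ccj <- complete.cases(s, m[, mem[jj]])
        sq[mem[jj]] <- if (sum(ccj) > 2) cor(s[ccj], m[ccj, mem[jj]])^2 else NA
      }
      loadings[mem] <- v
      alpha[ki] <- cronbach_alpha(m[, mem, drop = FALSE])
    }
    sdev <- sd(s, na.rm = TRUE)
    scores[, ki] <- if (sdev > 0) s / sdev else s
  }
  part_out <- setNames(match(partition, kl), labs)
  structure(list(K = K, partition = part_out, composite_scores = scores,
                 squared_loadings = sq, explained_prop = expl,
                 cronbach_alpha = alpha,
                 retained = rep(TRUE, K), degenerate = rep(FALSE, K),
                 loadings = loadings),
            class = "hg_clustersolution")
}

#' Prune weakly attached symptoms and weak clusters
#'
#' Applies the two cluster-quality rules: a symptom must have squared
#' correlation of at least `min_sq_corr` with its own composite variable,
#' and a cluster must explain at least `min_explained` of its members'
#' variance. Symptoms failing the first rule are dropped and the composite
#' is recomputed, iterating to a fixpoint; clusters failing the second rule
#' afterwards are marked not retained. A cluster reduced below 2 members is
#' flagged degenerate rather than silently dropped.
#'
#' @param data the [likert_matrix()] the solution was computed from.
#' @param solution an [composite_scores()] result.
#' @param min_explained minimum proportion of variance explained (default 0.5).
#' @param min_sq_corr minimum squared item-composite correlation (default 0.6).
#' @param max_iter safety bound on the fixpoint iteration.
#' @return pruned `hg_clustersolution`; attribute `dropped` lists removed
#'   symptoms.
#' @export
prune_clusters <- function(data, solution, min_explained = 0.5,
                           min_sq_corr = 0.6, max_iter = 25) {
  part <- solution$partition
  dropped <- character(0)
  sol <- solution
  for (it in seq_len(max_iter)) {
    sq <- sol$squared_loadings[names(part)]
    bad <- names(part)[!is.na(sq) & sq < min_sq_corr]
    if (length(bad) == 0) break
    # never remove the last member of a cluster: a collapsing cluster is
    # flagged degenerate below, not silently dropped
    for (k in unique(part)) {
      mem <- names(part)[part == k]
      if (all(mem %in% bad)) {
        keep <- mem[which.max(sq[mem])]
        bad <- setdiff(bad, keep)
      }
    }
    if (length(bad) == 0) break
    dropped <- c(dropped, bad)
    part <- part[!names(part) %in% bad]
    sol <- composite_scores(unclass(data)[, names(part), drop = FALSE], part)
    part <- sol$partition
  }
  sizes <- as.integer(table(factor(sol$partition,
                                   levels = seq_len(sol$K))))
  sol$degenerate <- sizes < 2
  sol$retained <- !sol$degenerate & sol$explained_prop >= min_explained
  attr(sol, "dropped") <- unique(dropped)
  sol
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table of the two labelings. 1 means identical partitions (up to label
#' permutation), values near 0 mean chance-level agreement.
#'
#' @param p1,p2 vectors of cluster labels over the same items (same length;
#'   if named, names must match).
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions must cover the same items")
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) stop("partition label sets differ")
    p2 <- p2[names(p1)]
  }
  tab <- table(p1, p2)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  a <- sum_comb(tab)
  b <- sum_comb(rowSums(tab))
  c2 <- sum_comb(colSums(tab))
  tot <- choose(n, 2)
  expected <- b * c2 / tot
  maxi <- (b + c2) / 2
  if (abs(maxi - expected) < 1e-12) return(ifelse(a == expected, 1, 0))
  (a - expected) / (maxi - expected)
}

#' Bootstrap stability of the clustering across K
#'
#' For each candidate K, participants (rows) are resampled with replacement
#' B times; the tree is rebuilt on each bootstrap sample, cut at K, and the
#' resulting partition compared with the full-data partition at the same K
#' by adjusted Rand index. Replicates where a resampled column becomes
#' constant are dropped and counted.
#'
#' @param data an [likert_matrix()] object.
#' @param K_range integer vector of candidate cluster counts.
#' @param B number of bootstrap samples (default 60).
#' @param seed integer seed for reproducibility.
#' @return data frame of class `hg_stability`: `K`, `mean_ari`, `sd_ari`,
#'   `B_used`, `B`, `seed`; attribute `ari` holds the full B x K matrix.
#' @export
bootstrap_stability <- function(data, K_range, B = 60, seed = 1) {
  stopifnot(B >= 1)
  m <- unclass(as.matrix(data))
  n <- nrow(m)
  ref_tree <- build_tree(data)
  ref_parts <- lapply(K_range, function(K) cut_tree(ref_tree, K))
  set.seed(seed)
  ari <- matrix(NA_real_, B, length(K_range))
  colnames(ari) <- paste0("K", K_range)
  dropped <- 0L
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    mb <- m[rows, , drop = FALSE]
    sds <- apply(mb, 2, sd, na.rm = TRUE)
    if (any(sds == 0, na.rm = TRUE)) {
      dropped <- dropped + 1L
      next
    }
    tb <- tryCatch(build_tree(mb), error = function(e) NULL)
    if (is.null(tb)) { dropped <- dropped + 1L; next }
    for (ki in seq_along(K_range)) {
      pb <- cut_tree(tb, K_range[ki])
      ari[b, ki] <- adjusted_rand(ref_parts[[ki]], pb)
    }
  }
  if (dropped > 0)
    warning(dropped, " bootstrap replicate(s) dropped (constant column)")
  out <- data.frame(K = K_range,
                    mean_ari = colMeans(ari, na.rm = TRUE),
                    sd_ari = apply(ari, 2, sd, na.rm = TRUE),
                    B_used = colSums(!is.na(ari)), B = B, seed = seed)
  attr(out, "ari") <- ari
  class(out) <- c("hg_stability", "data.frame")
  out
}

#' Cronbach alpha of an item set
#'
#' Internal-consistency reliability `alpha = p/(p-1) * (1 - sum of item
#' variances / variance of the item sum)`, computed on complete cases.
#'
#' @param columns numeric matrix with at least two columns.
#' @return scalar alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(columns) {
  m <- as.matrix(columns)
  p <- ncol(m)
  if (p < 2) stop("Cronbach alpha needs at least 2 items")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("too few complete cases for Cronbach alpha")
  total <- rowSums(m)
  (p / (p - 1)) * (1 - sum(apply(m, 2, var)) / var(total))
}

#' Choose the number of clusters
#'
#' Returns the K in range with the highest mean bootstrap adjusted Rand
#' index; ties (within `tie_tol`) are broken toward the K sitting at the
#' largest gap of the tree's aggregation-cost path. The full diagnostic
#' table is attached for human review; automatic selection is a convenience,
#' not a substitute for inspecting aggregation levels and stability spread.
#'
#' @param tree an [build_tree()] result.
#' @param stability an [bootstrap_stability()] result.
#' @param K_range candidate K values (must be present in `stability`).
#' @param tie_tol mean-ARI difference treated as a tie (default 0.01).
#' @return list: `K` (selected), `table` (diagnostics per K), `tie` (logical).
#' @export
select_k <- function(tree, stability, K_range = stability$K,
                     tie_tol = 0.01) {
  tab <- stability[stability$K %in% K_range, , drop = FALSE]
  if (nrow(tab) == 0) stop("empty K range")
  p <- tree$p
  d <- tree$merges$d
  # gap before the merge that reduces the count from K to K-1:
  # cutting at K undoes merges p-K+1 .. p-1; the gap credited to K is the
  # cost jump between merge p-K and merge p-K+1
  gap <- vapply(tab$K, function(K) {
    i <- p - K          # last merge performed at K clusters
    if (i < 1 || i >= length(d)) return(0)
    d[i + 1] - d[i]
  }, numeric(1))
  tab$aggregation_gap <- gap
  best <- max(tab$mean_ari, na.rm = TRUE)
  cand <- which(tab$mean_ari >= best - tie_tol)
  tie <- length(cand) > 1
  pick <- cand[order(-tab$aggregation_gap[cand], tab$K[cand])][1]
  list(K = tab$K[pick], table = tab, tie = tie)
}

#' Full variable-clustering front-end
#'
#' Builds the tree, assesses bootstrap stability across `K_range`, selects
#' K, computes composite scores and prunes. The "driving symptom" reported
#' per cluster is simply the member with the highest squared loading -- an
#' interpretive convenience, not a formal test.
#'
#' @inheritParams bootstrap_stability
#' @param K_range candidate numbers of clusters.
#' @param min_explained,min_sq_corr pruning thresholds (see
#'   [prune_clusters()]).
#' @return list with `tree`, `stability`, `selection`, `solution` (pruned),
#'   `initial_solution`, `driving` (per-cluster max-r-squared symptom).
#' @export
varclust <- function(data, K_range = 2:8, B = 60, seed = 1,
                     min_explained = 0.5, min_sq_corr = 0.6) {
  data <- likert_matrix(data)
  tree <- build_tree(data)
  stab <- bootstrap_stability(data, K_range, B = B, seed = seed)
  sel <- select_k(tree, stab, K_range)
  part <- cut_tree(tree, sel$K)
  sol0 <- composite_scores(data, part)
  sol <- prune_clusters(data, sol0, min_explained = min_explained,
                        min_sq_corr = min_sq_corr)
  driving <- vapply(seq_len(sol$K), function(k) {
    mem <- names(sol$partition)[sol$partition == k]
    if (length(mem) == 0) return(NA_character_)
    mem[which.max(sol$squared_loadings[mem])]
  }, character(1))
  list(tree = tree, stability = stab, selection = sel,
       solution = sol, initial_solution = sol0, driving = driving)
}
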