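#' Specify a structural equation model
#'
#' Builds the internal representation of a SEM with latent variables
#' (reticular action model: directed-path matrix `A`, symmetric matrix `S`
#' of variances/covariances, filter onto the observed variables). Latent
#' scales are identified by fixing each latent's (residual) variance to 1
#' with all loadings free (variance-standardized identification, robust
#' when a scaling indicator would correlate weakly with the rest); fixing
#' the first loading to 1 instead is available via `identification`. The
#' standardized solution reported after fitting is identical under either
#' choice. Every pair of
#' exogenous variables (latent or observed) receives a free covariance;
#' endogenous variables receive a free residual variance. The model is fit
#' to a polychoric/polyserial/Pearson correlation matrix, so observed
#' variables are on unit scale.
#'
#' @param measurement named list: latent name -> character vector of
#'   indicator columns.
#' @param regressions character vector of structural equations, e.g.
#'   `"cluster ~ childhood_hg + nervous_disorder"`; left-hand sides and
#'   right-hand sides may be latent names or observed columns.
#' @param ordinal character vector of observed columns to treat as ordinal
#'   (Likert indicators, binary endogenous variables).
#' @param covariances optional list of 2-element character vectors naming
#'   extra free (residual) covariances.
#' @param identification `"variance"` (latent variance fixed to 1, all
#'   loadings free; default) or `"loading"` (first loading fixed to 1).
#' @return object of class `hg_semmodel`: variable bookkeeping plus a
#'   parameter table (`matrix`, `row`, `col`, `free`, `start`, `label`).
#' @export
sem_model <- function(measurement = list(), regressions = character(),
                      ordinal = character(), covariances = list(),
                      identification = c("variance", "loading")) {
  identification <- match.arg(identification)
  latents <- names(measurement)
  if (length(measurement) && (is.null(latents) || any(latents == "")))
    stop("measurement list must be fully named")
  edges <- parse_regressions(regressions)
  obs <- unique(c(unlist(measurement),
                  setdiff(c(edges$from, edges$to), latents)))
  vars <- c(obs, latents)
  if (anyDuplicated(vars)) stop("a name is used as both observed and latent")
  nv <- length(vars)
  idx <- setNames(seq_len(nv), vars)
  par <- list()
  add <- function(mat, i, j, free, start, label) {
    par[[length(par) + 1]] <<- data.frame(matrix = mat, row = i, col = j,
                                          free = free, start = start,
                                          label = label,
                                          stringsAsFactors = FALSE)
  }
  # loadings
  for (L in latents) {
    ind <- measurement[[L]]
    if (length(ind) < 1) stop("latent '", L, "' has no indicators")
    for (k in seq_along(ind)) {
      fr <- if (identification == "variance") TRUE else k > 1
      add("A", idx[ind[k]], idx[L], free = fr,
          start = if (identification == "variance") 0.7 else 1,
          label = paste0(L, "=~", ind[k]))
    }
  }
  # structural paths
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      add("A", idx[edges$to[k]], idx[edges$from[k]], free = TRUE, start = 0,
          label = paste0(edges$to[k], "~", edges$from[k]))
    }
  }
  ptab <- do.call(rbind, par)
  if (is.null(ptab)) ptab <- data.frame(matrix = character(), row = integer(),
                                        col = integer(), free = logical(),
                                        start = numeric(), label = character())
  # acyclicity of the directed graph
  Adj <- matrix(0, nv, nv)
  Arows <- ptab[ptab$matrix == "A", , drop = FALSE]
  Adj[cbind(Arows$row, Arows$col)] <- 1
  if (has_cycle(Adj)) stop("structural graph is cyclic")
  has_incoming <- colSums(t(Adj)) > 0   # variable receives a path
  exo <- !has_incoming
  # S entries
  spar <- list()
  sadd <- function(i, j, free, start, label) {
    spar[[length(spar) + 1]] <<- data.frame(matrix = "S", row = i, col = j,
                                            free = free, start = start,
                                            label = label,
                                            stringsAsFactors = FALSE)
  }
  for (i in seq_len(nv)) {
    is_lat <- vars[i] %in% latents
    if (is_lat && identification == "variance") {
      sadd(i, i, FALSE, 1, paste0(vars[i], "~~", vars[i]))
    } else {
      sadd(i, i, TRUE, if (is_lat) 0.5 else if (exo[i]) 1 else 0.5,
           paste0(vars[i], "~~", vars[i]))
    }
  }
  exo_ix <- which(exo)
  if (length(exo_ix) > 1) {
    for (a in seq_along(exo_ix)[-1]) for (b in seq_len(a - 1)) {
      i <- exo_ix[a]; j <- exo_ix[b]
      sadd(i, j, TRUE, 0, paste0(vars[i], "~~", vars[j]))
    }
  }
  for (cv in covariances) {
    stopifnot(length(cv) == 2)
    i <- idx[cv[1]]; j <- idx[cv[2]]
    if (exo[i] && exo[j]) next # already free
    sadd(max(i, j), min(i, j), TRUE, 0, paste0(cv[1], "~~", cv[2]))
  }
  ptab <- rbind(ptab, do.call(rbind, spar))
  rownames(ptab) <- NULL
  structure(list(vars = vars, obs = obs, latents = latents, idx = idx,
                 ptab = ptab, measurement = measurement,
                 ordinal = intersect(ordinal, obs), edges = edges),
            class = "hg_semmodel")
}

parse_regressions <- function(regressions) {
  out <- list()
  for (r in regressions) {
    parts <- strsplit(r, "~", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("bad regression string: ", r)
    to <- trimws(parts[1])
    rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    for (fr in rhs) out[[length(out) + 1]] <- data.frame(from = fr, to = to)
  }
  if (!length(out)) return(data.frame(from = character(), to = character()))
  do.call(rbind, out)
}

has_cycle <- function(Adj) {
  nv <- nrow(Adj)
  indeg <- rowSums(Adj)   # Adj[to, from] = 1
  active <- rep(TRUE, nv)
  repeat {
    leaf <- which(active & indeg == 0)
    if (!length(leaf)) break
    for (l in leaf) {
      active[l] <- FALSE
      out <- which(Adj[, l] > 0 & active)
      indeg[out] <- indeg[out] - 1
    }
  }
  any(active)
}

# Assemble A and S matrices from a parameter vector (free params only).
sem_matrices <- function(model, theta) {
  nv <- length(model$vars)
  A <- matrix(0, nv, nv)
  S <- matrix(0, nv, nv)
  pt <- model$ptab
  vals <- pt$start
  vals[pt$free] <- theta
  isA <- pt$matrix == "A"
  A[cbind(pt$row[isA], pt$col[isA])] <- vals[isA]
  iS <- which(!isA)
  for (k in iS) {
    S[pt$row[k], pt$col[k]] <- vals[k]
    S[pt$col[k], pt$row[k]] <- vals[k]
  }
  list(A = A, S = S)
}

# Model-implied covariance of all variables (latents included).
sem_implied_all <- function(model, theta) {
  ms <- sem_matrices(model, theta)
  Ti <- solve(diag(length(model$vars)) - ms$A)
  Ti %*% ms$S %*% t(Ti)
}

# Model-implied covariance of the observed variables, in `order` (names).
sem_implied <- function(model, theta, order = model$obs) {
  Sig <- sem_implied_all(model, theta)
  ix <- model$idx[order]
  Sig[ix, ix, drop = FALSE]
}
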