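## Synthetic mixed data from known MGM parameters: ground-truth generation,
## Gibbs sampling, and edge-support recovery scoring.

#' Generate a random sparse ground-truth MGM
#'
#' Edges are drawn independently with probability \code{density}; nonzero
#' edge weights are uniform on \code{-[hi, lo] union [lo, hi]}. For
#' continuous-categorical and categorical-categorical edges every free
#' (non-reference) entry of the block receives an independent draw. The
#' continuous diagonal is set to \code{beta_ss = -(1 + sum_t |beta_st|)},
#' which makes beta strictly diagonally dominant with negative diagonal, so
#' every conditional precision stays positive along any Gibbs sweep
#' (conservative but sufficient).
#'
#' @param p number of continuous variables.
#' @param q number of categorical variables.
#' @param levels integer vector of level counts (length q, default all 2),
#'   or a named list of level labels.
#' @param density edge probability in (0, 1].
#' @param weightRange numeric (lo, hi), 0 < lo < hi.
#' @param seed integer seed.
#' @return a \code{\linkS4class{GroundTruthModel}}.
#' @export
makeGroundTruth <- function(p, q, levels = rep(2L, q), density = 0.1,
                            weightRange = c(0.3, 0.6), seed = 1L) {
  stopifnot(density >= 0, density <= 1, weightRange[1] < weightRange[2],
            weightRange[1] >= 0)
  contNames <- if (p > 0) sprintf("x%02d", seq_len(p)) else character(0)
  if (!is.list(levels)) {
    catNames <- if (q > 0) sprintf("y%02d", seq_len(q)) else character(0)
    levels <- setNames(lapply(levels, function(L) as.character(seq_len(L) - 1)),
                       catNames)
  }
  params <- emptyMGMParameters(contNames, levels)
  nv <- p + q
  support <- matrix(FALSE, nv, nv,
                    dimnames = list(c(contNames, names(levels)),
                                    c(contNames, names(levels))))
  withSeed(seed, {
    rw <- function(k) sample(c(-1, 1), k, replace = TRUE) *
      runif(k, weightRange[1], weightRange[2])
    for (a in seq_len(nv - 1)) for (b in (a + 1):nv) {
      if (runif(1) > density) next
      support[a, b] <- support[b, a] <- TRUE
      if (a <= p && b <= p) {
        params@beta[a, b] <- params@beta[b, a] <- rw(1)
      } else if (a <= p) {
        j <- b - p
        L <- length(levels[[j]])
        params@rho[[j]][a, -1] <- rw(L - 1)
      } else {
        r <- a - p; j <- b - p
        B <- params@phi[[phiKey(r, j)]]
        B[-1, -1] <- rw((nrow(B) - 1) * (ncol(B) - 1))
        params@phi[[phiKey(r, j)]] <- B
      }
    }
  })
  if (p > 0) {
    offAbs <- rowSums(abs(params@beta)) - abs(diag(params@beta))
    diag(params@beta) <- -(1 + offAbs)
  }
  validObject(params)
  new("GroundTruthModel", params = params, support = support,
      recipe = list(p = p, q = q, levels = lengths(levels),
                    density = density, weightRange = weightRange,
                    seed = seed))
}

#' Gibbs-sample a mixed dataset from known MGM parameters
#'
#' Systematic-scan Gibbs sampling: in fixed variable order, each continuous
#' node is redrawn from its Gaussian conditional and each categorical node
#' from its softmax conditional. The first \code{burnIn} sweeps are
#' discarded and every \code{thin}-th retained state becomes one sample.
#' Deterministic given \code{seed}.
#'
#' @param truth a \code{\linkS4class{GroundTruthModel}} (or
#'   \code{\linkS4class{MGMParameters}}).
#' @param n number of samples to return.
#' @param burnIn warm-up sweeps to discard (default 500).
#' @param thin keep every thin-th sweep (default 2).
#' @param seed integer seed.
#' @return a \code{\linkS4class{MixedDataset}} (layer "synthetic").
#' @export
gibbsSample <- function(truth, n, burnIn = 500L, thin = 2L, seed = 1L) {
  stopifnot(burnIn >= 0, thin >= 1)
  params <- if (is(truth, "GroundTruthModel")) truth@params else truth
  p <- length(params@contNames); q <- length(params@catNames)
  Ls <- lengths(params@levels)
  tau <- if (p > 0) -diag(params@beta) else numeric(0)
  csd <- sqrt(1 / tau)
  X <- matrix(0, n, p, dimnames = list(NULL, params@contNames))
  Y <- matrix(1L, n, q, dimnames = list(NULL, params@catNames))
  withSeed(seed, {
    x <- numeric(p)
    y <- rep(1L, q)
    kept <- 0L; sinceKeep <- 0L; sweeps <- 0L
    repeat {
      sweeps <- sweeps + 1L
      for (s in seq_len(p)) {
        eta <- params@alpha[s]
        if (p > 1) eta <- eta + sum(params@beta[s, -s] * x[-s])
        for (j in seq_len(q)) eta <- eta + params@rho[[j]][s, y[j]]
        x[s] <- rnorm(1, eta / tau[s], csd[s])
      }
      for (j in seq_len(q)) {
        pr <- conditionalCategorical(params, j, x, y)
        y[j] <- sample.int(Ls[j], 1, prob = pr)
      }
      if (sweeps <= burnIn) next
      sinceKeep <- sinceKeep + 1L
      if (sinceKeep == thin) {
        sinceKeep <- 0L
        kept <- kept + 1L
        if (p > 0) X[kept, ] <- x
        if (q > 0) Y[kept, ] <- y
        if (kept == n) break
      }
    }
  })
  d <- mixedDataset(continuous = if (p > 0) X else NULL,
                    categorical = if (q > 0) Y else NULL,
                    levels = params@levels, layer = "synthetic")
  validObject(d)
  d
}

#' Score edge-support recovery against a ground truth
#'
#' An estimated edge counts as positive when its absolute collapsed weight
#' exceeds \code{threshold}. Precision is NA-flagged when nothing is
#' predicted; F1 is 0 in that case unless the truth is also empty.
#'
#' @param truth a \code{\linkS4class{GroundTruthModel}}.
#' @param fitted an \code{\linkS4class{EdgeNetwork}} over the same variables.
#' @param threshold absolute-weight threshold (default 0: any nonzero edge).
#' @return named numeric vector: precision, recall, f1, tp, fp, fn.
#' @export
edgeRecoveryMetrics <- function(truth, fitted, threshold = 0) {
  vars <- rownames(truth@support)
  if (!setequal(vars, fitted@nodes$name))
    stop("truth and fitted network must share the same variables")
  est <- matrix(FALSE, length(vars), length(vars),
                dimnames = list(vars, vars))
  e <- fitted@edges
  keep <- abs(e$weight) > threshold
  for (i in which(keep)) {
    est[e$source[i], e$target[i]] <- TRUE
    est[e$target[i], e$source[i]] <- TRUE
  }
  ut <- upper.tri(truth@support)
  tp <- sum(est[ut] & truth@support[ut])
  fp <- sum(est[ut] & !truth@support[ut])
  fn <- sum(!est[ut] & truth@support[ut])
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else if (tp + fp + fn == 0) 1 else 0
  c(precision = precision, recall = recall, f1 = f1,
    tp = tp, fp = fp, fn = fn)
}
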