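## Pairwise mixed graphical model: potentials, conditionals, joint negative
## pseudo-log-likelihood and its exact gradient. All losses are averaged over
## samples so the penalty weight lambda is comparable across sample sizes.

#' Create an all-zero (edge-free) parameter set
#'
#' Node potentials are zero, conditional precisions are 1 (beta_ss = -1), and
#' every edge block is zero.
#'
#' @param contNames names of the continuous variables.
#' @param levels named list of level labels per categorical variable (the
#'   names define the categorical variables and their order).
#' @param epsilon lower bound on conditional precisions, default 1e-4.
#' @return an \code{\linkS4class{MGMParameters}} object.
#' @export
emptyMGMParameters <- function(contNames = character(),
                               levels = list(), epsilon = 1e-4) {
  p <- length(contNames); q <- length(levels)
  catNames <- names(levels)
  if (q > 0 && is.null(catNames)) stop("levels must be a named list")
  beta <- diag(-1, p)
  dimnames(beta) <- list(contNames, contNames)
  rho <- lapply(levels, function(lv)
    matrix(0, p, length(lv), dimnames = list(contNames, lv)))
  theta <- lapply(levels, function(lv) setNames(numeric(length(lv)), lv))
  phi <- list()
  if (q > 1) {
    for (j in 2:q) for (r in 1:(j - 1)) {
      phi[[phiKey(r, j)]] <- matrix(0, length(levels[[r]]), length(levels[[j]]),
                                    dimnames = list(levels[[r]], levels[[j]]))
    }
  }
  new("MGMParameters", beta = beta, alpha = setNames(numeric(p), contNames),
      rho = rho, theta = theta, phi = phi,
      contNames = as.character(contNames), catNames = as.character(catNames),
      levels = levels, epsilon = epsilon)
}

phiKey <- function(r, j) paste(r, j, sep = "|")

## phi block oriented as (r rows, j cols) for arbitrary r != j
phiBlock <- function(params, r, j) {
  if (r < j) params@phi[[phiKey(r, j)]] else t(params@phi[[phiKey(j, r)]])
}

#' Count free parameters under reference-level coding
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @return named integer vector with elements \code{total}, \code{edge}
#'   (penalized edge parameters) and \code{node} (unpenalized node
#'   potentials, including the precision diagonal).
#' @export
parameterCount <- function(params) {
  p <- length(params@contNames)
  Ls <- lengths(params@levels)
  edge <- p * (p - 1) / 2 + sum(p * (Ls - 1))
  if (length(Ls) > 1) {
    for (j in 2:length(Ls)) for (r in 1:(j - 1))
      edge <- edge + (Ls[r] - 1) * (Ls[j] - 1)
  }
  node <- 2 * p + sum(Ls - 1)
  c(total = as.integer(edge + node), edge = as.integer(edge),
    node = as.integer(node))
}

#' Unnormalized log joint density
#'
#' Evaluates the exponent of the pairwise density:
#' \code{1/2 sum_st beta_st x_s x_t + sum_s alpha_s x_s +
#' sum_sj rho_sj(y_j) x_s + sum_j theta_j(y_j) +
#' sum_{r<j} phi_rj(y_r, y_j)}.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @param x numeric vector of length p.
#' @param y integer vector of length q of level indices (1-based; 1 =
#'   reference level).
#' @return the unnormalized log density (a scalar).
#' @export
logPotential <- function(params, x = numeric(), y = integer()) {
  p <- length(params@contNames); q <- length(params@catNames)
  stopifnot(length(x) == p, length(y) == q)
  if (q > 0) {
    Ls <- lengths(params@levels)
    if (any(y < 1 | y > Ls)) stop("level index out of range")
  }
  val <- 0
  if (p > 0)
    val <- val + 0.5 * drop(x %*% params@beta %*% x) + sum(params@alpha * x)
  for (j in seq_len(q)) {
    val <- val + params@theta[[j]][y[j]]
    if (p > 0) val <- val + sum(params@rho[[j]][, y[j]] * x)
  }
  if (q > 1) {
    for (j in 2:q) for (r in 1:(j - 1))
      val <- val + params@phi[[phiKey(r, j)]][y[r], y[j]]
  }
  unname(val)
}

#' Conditional distribution of a continuous node
#'
#' Given all other variables, node s is Gaussian with precision
#' \code{tau = -beta_ss}, mean \code{(alpha_s + sum_{t != s} beta_st x_t +
#' sum_j rho_sj(y_j)) / tau} and variance \code{1 / tau}.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @param s index (or name) of the continuous node.
#' @param x numeric vector of length p (the entry at s is ignored).
#' @param y integer vector of level indices.
#' @return list with elements \code{mean} and \code{variance}.
#' @export
conditionalContinuous <- function(params, s, x, y = integer()) {
  if (is.character(s)) s <- match(s, params@contNames)
  tau <- -params@beta[s, s]
  if (tau < params@epsilon)
    stop("degenerate conditional: -beta_ss below epsilon")
  eta <- params@alpha[s] + sum(params@beta[s, -s] * x[-s])
  for (j in seq_along(params@catNames))
    eta <- eta + params@rho[[j]][s, y[j]]
  list(mean = unname(eta / tau), variance = 1 / tau)
}

#' Conditional distribution of a categorical node
#'
#' Softmax over the levels l of
#' \code{theta_j(l) + sum_s rho_sj(l) x_s + sum_{r != j} phi_rj(y_r, l)}.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @param j index (or name) of the categorical node.
#' @param x numeric vector of length p.
#' @param y integer vector of level indices (entry at j ignored).
#' @return probability vector over the levels of node j (sums to 1).
#' @export
conditionalCategorical <- function(params, j, x = numeric(), y) {
  if (is.character(j)) j <- match(j, params@catNames)
  eta <- params@theta[[j]]
  if (length(params@contNames))
    eta <- eta + drop(x %*% params@rho[[j]])
  for (r in seq_along(params@catNames)) {
    if (r == j) next
    eta <- eta + phiBlock(params, r, j)[y[r], ]
  }
  eta <- eta - max(eta)
  w <- exp(eta)
  w / sum(w)
}

## Precomputed design: value matrices plus one-hot indicators per categorical.
mgmDesign <- function(d) {
  X <- d@continuous
  Y <- d@categorical
  q <- ncol(Y)
  D <- vector("list", q)
  for (j in seq_len(q)) {
    L <- length(d@levels[[j]])
    Dj <- matrix(0, nrow(Y), L)
    Dj[cbind(seq_len(nrow(Y)), Y[, j])] <- 1
    D[[j]] <- Dj
  }
  list(X = X, Y = Y, D = D, n = nrow(X), p = ncol(X), q = q,
       levels = d@levels)
}

## Core engine: loss (and optionally gradient) in one pass.
## Returns list(loss, grad) where grad mirrors the MGMParameters slots; tied
## edge parameters carry the accumulated (both-conditionals) derivative, with
## beta kept symmetric and reference entries forced to zero.
pllEngine <- function(params, des, wantGrad = TRUE) {
  X <- des$X; D <- des$D; n <- des$n; p <- des$p; q <- des$q
  loss <- 0
  grad <- NULL
  if (wantGrad)
    grad <- list(beta = matrix(0, p, p), alpha = numeric(p),
                 rho = lapply(params@rho, function(m) m * 0),
                 theta = lapply(params@theta, function(v) v * 0),
                 phi = lapply(params@phi, function(m) m * 0))
  R <- NULL
  if (p > 0) {
    tau <- -diag(params@beta)
    if (any(tau < params@epsilon))
      stop("degenerate conditional: -beta_ss below epsilon")
    Eta <- X %*% params@beta
    Eta <- Eta - sweep(X, 2, diag(params@beta), "*")   # drop self term
    Eta <- sweep(Eta, 2, params@alpha, "+")
    for (j in seq_len(q)) Eta <- Eta + D[[j]] %*% t(params@rho[[j]])
    Mu <- sweep(Eta, 2, tau, "/")
    R <- X - Mu
    loss <- loss + sum(sweep(R^2, 2, tau / 2, "*")) / n +
      sum(-0.5 * log(tau)) + p * 0.5 * log(2 * pi)
    if (wantGrad) {
      M <- crossprod(R, X) / n                 # M[s,t] = mean(r_s x_t)
      G <- -(M + t(M))
      diag(G) <- 0
      # d loss / d tau_s, then beta_ss = -tau_s
      gTau <- colMeans(0.5 * X^2) - colMeans(Eta^2) / (2 * tau^2) -
        1 / (2 * tau)
      grad$beta <- G
      diag(grad$beta) <- -gTau
      grad$alpha <- -colMeans(R)
    }
  }
  for (j in seq_len(q)) {
    EtaJ <- matrix(params@theta[[j]], n, length(params@theta[[j]]),
                   byrow = TRUE)
    if (p > 0) EtaJ <- EtaJ + X %*% params@rho[[j]]
    for (r in seq_len(q)) {
      if (r == j) next
      EtaJ <- EtaJ + D[[r]] %*% phiBlock(params, r, j)
    }
    mx <- apply(EtaJ, 1, max)
    W <- exp(EtaJ - mx)
    P <- W / rowSums(W)
    loss <- loss - sum(log(pmax(rowSums(P * D[[j]]), 1e-300))) / n
    if (wantGrad) {
      E <- (P - D[[j]]) / n                    # n x L_j
      grad$theta[[j]] <- grad$theta[[j]] + colSums(E)
      if (p > 0) {
        grad$rho[[j]] <- grad$rho[[j]] + crossprod(X, E) -
          crossprod(R, D[[j]]) / n
      }
      for (r in seq_len(q)) {
        if (r == j) next
        inc <- crossprod(D[[r]], E)            # L_r x L_j
        if (r < j) grad$phi[[phiKey(r, j)]] <- grad$phi[[phiKey(r, j)]] + inc
        else grad$phi[[phiKey(j, r)]] <- grad$phi[[phiKey(j, r)]] + t(inc)
      }
    }
  }
  if (wantGrad) {
    for (j in seq_len(q)) {
      if (p > 0) grad$rho[[j]][, 1] <- 0
      grad$theta[[j]][1] <- 0
    }
    for (key in names(grad$phi)) {
      grad$phi[[key]][1, ] <- 0
      grad$phi[[key]][, 1] <- 0
    }
  }
  list(loss = loss, grad = grad)
}

#' Negative pseudo-log-likelihood
#'
#' The sample average over rows of the summed per-node conditional negative
#' log-densities: Gaussian for continuous nodes, categorical (softmax) for
#' discrete nodes. Averaging over n makes the penalty weight lambda
#' comparable across sample sizes; multiply by n to match summed conventions.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @param d a \code{\linkS4class{MixedDataset}} whose variables match
#'   \code{params}.
#' @return a finite scalar.
#' @export
negPseudoLoglik <- function(params, d) {
  pllEngine(params, mgmDesign(d), wantGrad = FALSE)$loss
}

#' Exact gradient of the negative pseudo-log-likelihood
#'
#' Tied (symmetric) edge parameters accumulate the contributions of both
#' node conditionals once per unordered pair; reference-level entries are
#' forced to zero so the gradient lives in the same constrained space as the
#' parameters.
#'
#' @inheritParams negPseudoLoglik
#' @return a list shaped like the \code{MGMParameters} slots
#'   (\code{beta}, \code{alpha}, \code{rho}, \code{theta}, \code{phi}).
#' @export
gradNegPseudoLoglik <- function(params, d) {
  pllEngine(params, mgmDesign(d), wantGrad = TRUE)$grad
}

## ---- flat parameterization -------------------------------------------------
## Fixed order: alpha (p) | diag(beta) (p) | upper-tri beta (col-major) |
## for each categorical j: rho_j free columns (p x (L_j - 1)) | theta_j free |
## for each pair r < j (canonical key order): free block (L_r-1) x (L_j-1).

flatTemplate <- function(params) {
  p <- length(params@contNames); q <- length(params@catNames)
  Ls <- lengths(params@levels)
  idx <- list(); at <- 0L
  take <- function(k) { v <- at + seq_len(k); at <<- at + k; v }
  idx$alpha <- take(p)
  idx$diag <- take(p)
  idx$betaUT <- take(p * (p - 1) / 2)
  idx$rho <- idx$theta <- vector("list", q)
  for (j in seq_len(q)) {
    idx$rho[[j]] <- take(p * (Ls[j] - 1))
    idx$theta[[j]] <- take(Ls[j] - 1)
  }
  idx$phi <- list()
  for (key in names(params@phi)) {
    rj <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    idx$phi[[key]] <- take((Ls[rj[1]] - 1) * (Ls[rj[2]] - 1))
  }
  idx$length <- at
  idx
}

#' Flatten parameters (or a gradient) to a numeric vector
#'
#' @param params an \code{\linkS4class{MGMParameters}} defining the shapes.
#' @param obj the object to flatten: \code{params} itself (default) or a
#'   gradient list from \code{\link{gradNegPseudoLoglik}}.
#' @return numeric vector of the free parameters; tied/reference entries
#'   appear exactly once.
#' @export
flattenMGM <- function(params, obj = params) {
  if (is(obj, "MGMParameters"))
    obj <- list(beta = obj@beta, alpha = obj@alpha, rho = obj@rho,
                theta = obj@theta, phi = obj@phi)
  p <- length(params@contNames)
  v <- c(obj$alpha, diag(obj$beta), obj$beta[upper.tri(obj$beta)])
  for (j in seq_along(params@catNames)) {
    Lj <- length(params@levels[[j]])
    v <- c(v, if (p > 0 && Lj > 1) obj$rho[[j]][, -1] else numeric(0),
           obj$theta[[j]][-1])
  }
  for (key in names(params@phi))
    v <- c(v, obj$phi[[key]][-1, -1])
  unname(v)
}

#' Rebuild MGMParameters from a flat vector
#'
#' @param v numeric vector as produced by \code{\link{flattenMGM}}.
#' @param skeleton an \code{\linkS4class{MGMParameters}} providing names,
#'   levels and epsilon.
#' @return an \code{\linkS4class{MGMParameters}} with symmetry and
#'   reference-zero constraints imposed exactly.
#' @export
unflattenMGM <- function(v, skeleton) {
  idx <- flatTemplate(skeleton)
  stopifnot(length(v) == idx$length)
  p <- length(skeleton@contNames)
  out <- skeleton
  beta <- matrix(0, p, p, dimnames = dimnames(skeleton@beta))
  beta[upper.tri(beta)] <- v[idx$betaUT]
  beta <- beta + t(beta)
  diag(beta) <- v[idx$diag]
  out@beta <- beta
  out@alpha <- setNames(v[idx$alpha], skeleton@contNames)
  for (j in seq_along(skeleton@catNames)) {
    Lj <- length(skeleton@levels[[j]])
    m <- skeleton@rho[[j]] * 0
    if (p > 0 && Lj > 1) m[, -1] <- v[idx$rho[[j]]]
    out@rho[[j]] <- m
    th <- skeleton@theta[[j]] * 0
    th[-1] <- v[idx$theta[[j]]]
    out@theta[[j]] <- th
  }
  for (key in names(skeleton@phi)) {
    m <- skeleton@phi[[key]] * 0
    m[-1, -1] <- v[idx$phi[[key]]]
    out@phi[[key]] <- m
  }
  out
}

#' Penalty mask and penalty groups over the flat parameterization
#'
#' Edge parameters (off-diagonal beta, all free rho entries, all free phi
#' entries) are penalized; node potentials (alpha, theta, diagonal beta) are
#' not. \code{groups} assigns one id per edge parameter block for the
#' optional group-L2 penalty: each beta edge is its own group, each rho_sj
#' vector is one group, each phi block is one group; 0 marks unpenalized
#' entries.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @return list with logical \code{mask} and integer \code{groups}, both of
#'   the flat length.
#' @export
penaltyMask <- function(params) {
  idx <- flatTemplate(params)
  mask <- logical(idx$length)
  groups <- integer(idx$length)
  g <- 0L
  mask[idx$betaUT] <- TRUE
  for (k in idx$betaUT) { g <- g + 1L; groups[k] <- g }
  p <- length(params@contNames)
  for (j in seq_along(params@catNames)) {
    ii <- idx$rho[[j]]
    mask[ii] <- TRUE
    if (length(ii)) {
      Lfree <- length(params@levels[[j]]) - 1
      # entries are column-major over (s, l>1); group by s
      sIdx <- rep(seq_len(p), Lfree)
      for (s in seq_len(p)) { g <- g + 1L; groups[ii[sIdx == s]] <- g }
    }
  }
  for (key in names(params@phi)) {
    ii <- idx$phi[[key]]
    mask[ii] <- TRUE
    g <- g + 1L
    groups[ii] <- g
  }
  list(mask = mask, groups = groups)
}

## ---- JSON round-trip -------------------------------------------------------

#' Serialize MGMParameters to JSON
#'
#' Writes an explicit-shape JSON document (names, level labels, epsilon and
#' all blocks) whose decimal representation round-trips bit-stably through
#' \code{\link{readMGMParameters}}.
#'
#' @param params an \code{\linkS4class{MGMParameters}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMGMParameters <- function(params, path) {
  doc <- list(
    contNames = params@contNames,
    catNames = params@catNames,
    levels = params@levels,
    epsilon = params@epsilon,
    alpha = unname(params@alpha),
    beta = unname(params@beta),
    rho = lapply(params@rho, unname),
    theta = lapply(params@theta, unname),
    phi = lapply(params@phi, unname)
  )
  # 17 significant digits: the shortest representation that round-trips
  # IEEE doubles exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read MGMParameters from JSON
#'
#' @param path a file written by \code{\link{writeMGMParameters}}.
#' @return an \code{\linkS4class{MGMParameters}}.
#' @export
readMGMParameters <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lv <- lapply(as.list(doc$levels), as.character)
  if (length(lv) == 0) lv <- setNames(list(), character(0))
  out <- emptyMGMParameters(as.character(doc$contNames), lv,
                            epsilon = doc$epsilon)
  p <- length(out@contNames)
  if (p > 0) {
    out@beta[] <- doc$beta
    out@alpha[] <- doc$alpha
  }
  for (j in seq_along(out@catNames)) {
    if (p > 0) out@rho[[j]][] <- doc$rho[[j]]
    out@theta[[j]][] <- doc$theta[[j]]
  }
  for (key in names(out@phi)) out@phi[[key]][] <- doc$phi[[key]]
  validObject(out)
  out
}
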