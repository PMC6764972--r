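## L1-penalized minimization of the negative pseudo-log-likelihood:
## FISTA (proximal gradient with Nesterov momentum), backtracking line
## search, and adaptive restarts in the sense of O'Donoghue & Candes.

#' Fit configuration
#'
#' @param lambda L1 weight on edge parameters (>= 0).
#' @param maxIter maximum number of iterations.
#' @param tol relative change of the penalized objective at which to stop.
#' @param stepInit initial step size for backtracking (> 0).
#' @param backtrackFactor step-shrink factor in (0, 1).
#' @param restart momentum restart rule: \code{"function"} (reset when the
#'   objective increases; default), \code{"gradient"}, or \code{"none"}.
#' @param momentum logical; \code{FALSE} gives plain ISTA.
#' @param penalty \code{"l1"} (default) or \code{"group"} (group-L2 over
#'   rho vectors and phi blocks; see \code{\link{penaltyMask}}).
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @return a validated list of class \code{mgmFitControl}.
#' @export
fitControl <- function(lambda = 0, maxIter = 10000L, tol = 1e-6,
                       stepInit = 1.0, backtrackFactor = 0.5,
                       restart = c("function", "gradient", "none"),
                       momentum = TRUE, penalty = c("l1", "group"),
                       seed = 1L) {
  restart <- match.arg(restart)
  penalty <- match.arg(penalty)
  stopifnot(lambda >= 0, maxIter >= 1, tol > 0, stepInit > 0,
            backtrackFactor > 0, backtrackFactor < 1)
  structure(list(lambda = lambda, maxIter = as.integer(maxIter), tol = tol,
                 stepInit = stepInit, backtrackFactor = backtrackFactor,
                 restart = restart, momentum = momentum, penalty = penalty,
                 seed = as.integer(seed)),
            class = "mgmFitControl")
}

#' Soft-thresholding operator
#'
#' \code{sign(v) * max(|v| - t, 0)}: the proximal operator of the L1 norm.
#'
#' @param v numeric vector.
#' @param t threshold (>= 0).
#' @return the shrunk vector.
#' @export
softThreshold <- function(v, t) {
  stopifnot(all(t >= 0))
  sign(v) * pmax(abs(v) - t, 0)
}

## prox of step * lambda * penalty on the flat vector; diagonal entries are
## projected to <= -epsilon. `pm` is the penaltyMask() list, `dIdx` the flat
## positions of diag(beta).
proxFlat <- function(v, stepLambda, pm, dIdx, epsilon, penalty = "l1") {
  if (stepLambda > 0) {
    if (penalty == "l1") {
      v[pm$mask] <- softThreshold(v[pm$mask], stepLambda)
    } else {
      for (g in unique(pm$groups[pm$groups > 0])) {
        ii <- which(pm$groups == g)
        nrm <- sqrt(sum(v[ii]^2))
        v[ii] <- if (nrm <= stepLambda) 0 else v[ii] * (1 - stepLambda / nrm)
      }
    }
  }
  v[dIdx] <- pmin(v[dIdx], -epsilon)
  v
}

#' One proximal-gradient step
#'
#' Takes a gradient step of size \code{step} from \code{params}, applies
#' soft-thresholding with threshold \code{step * lambda} to the penalized
#' (edge) parameters only, and re-imposes the structural constraints
#' (symmetry, reference zeros, \code{beta_ss <= -epsilon}) exactly.
#'
#' @param params current \code{\linkS4class{MGMParameters}}.
#' @param gradient gradient list from \code{\link{gradNegPseudoLoglik}} (or a
#'   flat vector).
#' @param step step size (> 0).
#' @param lambda penalty weight.
#' @param penalty \code{"l1"} or \code{"group"}.
#' @return the updated \code{\linkS4class{MGMParameters}}.
#' @export
proxStep <- function(params, gradient, step, lambda, penalty = "l1") {
  stopifnot(step > 0)
  v <- flattenMGM(params)
  g <- if (is.numeric(gradient)) gradient else flattenMGM(params, gradient)
  pm <- penaltyMask(params)
  idx <- flatTemplate(params)
  out <- proxFlat(v - step * g, step * lambda, pm, idx$diag, params@epsilon,
                  penalty)
  unflattenMGM(out, params)
}

#' Fit a mixed graphical model by accelerated proximal gradient
#'
#' Minimizes \code{negPseudoLoglik + lambda * ||edge parameters||_1} by FISTA
#' with backtracking line search (the step is halved until the quadratic
#' upper bound holds) and adaptive restarts. With the default function-value
#' restart the momentum is reset whenever the objective would increase and
#' the step is retaken without momentum, so the recorded objective is
#' non-increasing. Continuous variables are expected in standard units; a
#' warning (not an error) is issued otherwise.
#'
#' @param d a complete \code{\linkS4class{MixedDataset}}.
#' @param control a \code{\link{fitControl}} list.
#' @param init optional \code{\linkS4class{MGMParameters}} warm start.
#' @return an \code{\linkS4class{MGMFit}}.
#' @export
fitMGM <- function(d, control = fitControl(), init = NULL) {
  X <- d@continuous
  if (ncol(X)) {
    mns <- colMeans(X); sds <- apply(X, 2, sd)
    if (any(abs(mns) > 0.01) || any(abs(sds - 1) > 0.01))
      warning("continuous variables do not look standardized (|mean| > 0.01 or |sd - 1| > 0.01)")
  }
  skel <- if (is.null(init))
    emptyMGMParameters(colnames(d@continuous), d@levels) else init
  des <- mgmDesign(d)
  pm <- penaltyMask(skel)
  idx <- flatTemplate(skel)
  lambda <- control$lambda
  fOf <- function(v) pllEngine(unflattenMGM(v, skel), des, FALSE)$loss
  gOf <- function(v) {
    gr <- pllEngine(unflattenMGM(v, skel), des, TRUE)$grad
    flattenMGM(skel, gr)
  }
  penOf <- function(v) {
    if (lambda == 0) return(0)
    if (control$penalty == "l1") lambda * sum(abs(v[pm$mask]))
    else {
      s <- 0
      for (g in unique(pm$groups[pm$groups > 0]))
        s <- s + sqrt(sum(v[pm$groups == g]^2))
      lambda * s
    }
  }

  x <- flattenMGM(skel)
  y <- x
  fx <- fOf(x)
  if (!is.finite(fx)) stop("non-finite objective at the starting point")
  Fx <- fx + penOf(x)
  step <- control$stepInit
  tk <- 1
  xPrev <- x
  trace <- vector("list", control$maxIter)
  converged <- FALSE

  for (it in seq_len(control$maxIter)) {
    step <- min(step * 1.1, control$stepInit * 10)  # mild growth between iters
    restarted <- FALSE
    repeat {
      fy <- fOf(y)
      gy <- gOf(y)
      # backtracking on the proximal-gradient sufficient-decrease bound
      repeat {
        z <- proxFlat(y - step * gy, step * lambda, pm, idx$diag,
                      skel@epsilon, control$penalty)
        dz <- z - y
        fz <- fOf(z)
        if (!is.finite(fz)) {
          step <- step * control$backtrackFactor
          if (step < 1e-14)
            stop("objective diverged; try a smaller stepInit")
          next
        }
        if (fz <= fy + sum(gy * dz) + sum(dz^2) / (2 * step)) break
        step <- step * control$backtrackFactor
        if (step < 1e-14) stop("line search failed; try a smaller stepInit")
      }
      Fz <- fz + penOf(z)
      doRestart <- switch(control$restart,
        "function" = Fz > Fx + 1e-15,
        "gradient" = sum((y - z) * (z - x)) > 0,
        "none" = FALSE)
      if (doRestart && control$momentum && !restarted && any(y != x)) {
        # reset momentum and retake the step from the last accepted iterate
        tk <- 1
        y <- x
        restarted <- TRUE
        next
      }
      break
    }
    if (restarted && Fz > Fx) { # numerically flat: keep the current iterate
      z <- x
      Fz <- Fx
    }
    xPrev <- x
    x <- z
    FxPrev <- Fx
    Fx <- Fz
    if (control$momentum) {
      tkNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
      mom <- (tk - 1) / tkNew
      y <- x + mom * (x - xPrev)
      tk <- tkNew
    } else {
      mom <- 0
      y <- x
    }
    trace[[it]] <- c(iter = it, objective = Fx, step = step,
                     restart = as.numeric(restarted), momentum = mom)
    if (abs(FxPrev - Fx) <= control$tol * max(1, abs(FxPrev))) {
      converged <- TRUE
      break
    }
  }
  tr <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)]))
  tr$restart <- as.logical(tr$restart)
  params <- unflattenMGM(x, skel)
  validObject(params)
  new("MGMFit", params = params, trace = tr, lambda = lambda,
      control = unclass(control), converged = converged)
}

#' Smallest penalty that yields an empty edge set
#'
#' Computes the node-potential-only optimum in closed form (Gaussian moment
#' matching for continuous nodes, multinomial log-frequencies for categorical
#' nodes) and returns the maximum absolute gradient over the penalized edge
#' parameters at that point: for any \code{lambda >= lambdaMax} the edge-free
#' model is stationary and the fitted graph is empty.
#'
#' @param d a complete \code{\linkS4class{MixedDataset}}.
#' @return a non-negative scalar.
#' @export
lambdaMax <- function(d) {
  params <- nodewiseOptimum(d)
  g <- gradNegPseudoLoglik(params, d)
  v <- abs(flattenMGM(params, g))
  pm <- penaltyMask(params)
  if (!any(pm$mask)) return(0)
  max(v[pm$mask])
}

## Closed-form optimum of the edge-free model: tau_s = 1/varML, alpha_s =
## tau_s * mean, theta_jl = log(n_l / n_1).
nodewiseOptimum <- function(d) {
  params <- emptyMGMParameters(colnames(d@continuous), d@levels)
  X <- d@continuous
  n <- nSamples(d)
  for (s in seq_len(ncol(X))) {
    m <- mean(X[, s]); vml <- mean((X[, s] - m)^2)
    if (vml < 1e-12) stop(sprintf("variable '%s' is constant", colnames(X)[s]))
    params@beta[s, s] <- -1 / vml
    params@alpha[s] <- m / vml
  }
  for (j in seq_along(params@catNames)) {
    cnt <- tabulate(d@categorical[, j], nbins = length(d@levels[[j]]))
    if (any(cnt == 0))
      stop(sprintf("level '%s' of '%s' absent from the data",
                   d@levels[[j]][which(cnt == 0)[1]], params@catNames[j]))
    params@theta[[j]] <- log(cnt / cnt[1])
    names(params@theta[[j]]) <- d@levels[[j]]
  }
  params
}

#' Warm-started regularization path
#'
#' Fits a strictly decreasing sequence of penalties, warm-starting each fit
#' from the previous solution (momentum resets at every new lambda).
#'
#' @param d a complete \code{\linkS4class{MixedDataset}}.
#' @param lambdas strictly decreasing positive penalties.
#' @param control a \code{\link{fitControl}} list (its \code{lambda} is
#'   ignored).
#' @return list of \code{\linkS4class{MGMFit}} objects, one per lambda.
#' @export
regularizationPath <- function(d, lambdas, control = fitControl()) {
  if (any(diff(lambdas) >= 0) || any(lambdas <= 0))
    stop("lambdas must be strictly decreasing and positive")
  fits <- vector("list", length(lambdas))
  init <- NULL
  for (k in seq_along(lambdas)) {
    ctl <- control
    ctl$lambda <- lambdas[k]
    fits[[k]] <- fitMGM(d, ctl, init = init)
    init <- fits[[k]]@params
  }
  fits
}

#' Select the penalty by EBIC or cross-validation
#'
#' EBIC scores each path fit by \code{n * pseudoLoss + k * log(n) +
#' 2 * gamma * k * log(P)} with \code{k} the number of nonzero penalized
#' parameters and \code{P} the total number of penalized parameters.
#' Cross-validation minimizes the mean held-out negative pseudo-log-likelihood
#' over \code{folds} folds (deterministic given \code{seed}); a fold whose
#' training part loses a categorical level is refused with an error.
#'
#' @param d a complete \code{\linkS4class{MixedDataset}}.
#' @param lambdas strictly decreasing positive penalties (default: a
#'   log-spaced path from \code{lambdaMax(d)} down to 5 percent of it).
#' @param method \code{"ebic"} (default) or \code{"cv"}.
#' @param folds number of folds for \code{"cv"} (>= 2).
#' @param gamma EBIC density parameter in [0, 1], default 0.5.
#' @param seed integer seed (used by \code{"cv"} only; EBIC is seed-free).
#' @param control a \code{\link{fitControl}} list.
#' @return list with \code{lambda} (the chosen value), \code{fit} (the
#'   corresponding \code{\linkS4class{MGMFit}} on all of \code{d}),
#'   \code{scores} (per-lambda criterion values) and \code{lambdas}.
#' @export
selectLambda <- function(d, lambdas = NULL, method = c("ebic", "cv"),
                         folds = 5L, gamma = 0.5, seed = 1L,
                         control = fitControl()) {
  method <- match.arg(method)
  if (is.null(lambdas)) {
    lmax <- lambdaMax(d)
    lambdas <- exp(seq(log(lmax * 0.999), log(lmax * 0.05), length.out = 15))
  }
  fits <- regularizationPath(d, lambdas, control)
  n <- nSamples(d)
  pm <- penaltyMask(fits[[1]]@params)
  P <- sum(pm$mask)
  if (method == "ebic") {
    scores <- vapply(fits, function(f) {
      v <- flattenMGM(f@params)
      k <- sum(v[pm$mask] != 0)
      n * negPseudoLoglik(f@params, d) + k * log(n) +
        2 * gamma * k * log(max(P, 1))
    }, numeric(1))
  } else {
    if (folds < 2) stop("folds must be >= 2")
    fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
    scores <- numeric(length(lambdas))
    for (fd in seq_len(folds)) {
      trIdx <- which(fold != fd)
      dTr <- subsetSamples(d, trIdx)
      for (j in seq_along(d@levels)) {
        L <- length(d@levels[[j]])
        if (any(tabulate(dTr@categorical[, j], nbins = L) == 0))
          stop(sprintf("fold %d drops a level of '%s'; use fewer folds",
                       fd, colnames(d@categorical)[j]))
      }
      dTe <- subsetSamples(d, which(fold == fd))
      # fold subsets keep the full-data units, so the standardization
      # reminder does not apply to them
      pfits <- withCallingHandlers(
        regularizationPath(dTr, lambdas, control),
        warning = function(w) {
          if (grepl("standardized", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      scores <- scores + vapply(pfits, function(f)
        negPseudoLoglik(f@params, dTe), numeric(1)) / folds
    }
  }
  best <- which.min(scores)
  list(lambda = lambdas[best], fit = fits[[best]], scores = scores,
       lambdas = lambdas)
}
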