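test_that("soft thresholding follows its definition", {
  expect_equal(softThreshold(1.5, 1.0), 0.5)
  expect_equal(softThreshold(-0.3, 0.5), 0)
  v <- c(-2, -0.1, 0, 0.4, 3)
  expect_equal(softThreshold(v, 0), v)
})

test_that("prox step reduces to a gradient step at lambda 0 and matches an
           elementwise oracle otherwise", {
  params <- randomParams(3, 2, seed = 1, scale = 0.5)
  sm <- smallMixed(n = 40, p = 3, q = 2, seed = 2)
  g <- gradNegPseudoLoglik(params, sm$data)
  step <- 0.3
  # lambda = 0: plain gradient step (up to the precision projection)
  out0 <- proxStep(params, g, step, 0)
  v <- flattenMGM(params); gv <- flattenMGM(params, g)
  idx <- mgmix:::flatTemplate(params)
  expect0 <- v - step * gv
  expect0[idx$diag] <- pmin(expect0[idx$diag], -params@epsilon)
  expect_equal(flattenMGM(out0), expect0, tolerance = 1e-14)
  # huge lambda from zero-ish params: all masked parameters exactly 0
  outBig <- proxStep(params, g, step, 1e6)
  pm <- penaltyMask(params)
  expect_true(all(flattenMGM(outBig)[pm$mask] == 0))
  # elementwise oracle at a generic lambda
  lam <- 0.07
  outL <- proxStep(params, g, step, lam)
  oracle <- v - step * gv
  for (k in which(pm$mask)) oracle[k] <- softThreshold(oracle[k], step * lam)
  oracle[idx$diag] <- pmin(oracle[idx$diag], -params@epsilon)
  expect_equal(flattenMGM(outL), oracle, tolerance = 1e-14)
})

test_that("unpenalized Gaussian fit recovers the negated inverse covariance", {
  d <- gaussData(500, 5, seed = 11)
  fit <- suppressWarnings(
    fitMGM(d, fitControl(lambda = 0, tol = 1e-14, maxIter = 50000)))
  X <- continuousValues(d)
  K <- solve(crossprod(sweep(X, 2, colMeans(X))) / nrow(X))
  # node-wise OLS oracle: beta_st = -K_st, and beta_st / (-beta_ss) equals
  # the OLS coefficient of x_t in the regression of x_s on the rest
  expect_lt(max(abs(fittedParams(fit)@beta + K)), 1e-6)
  s <- 1
  ols <- coef(lm(X[, 1] ~ X[, -1]))[-1]
  b <- fittedParams(fit)@beta
  expect_equal(unname(b[1, -1] / (-b[1, 1])), unname(ols), tolerance = 1e-6)
})

test_that("two-binary-node fit matches logistic regression exactly", {
  set.seed(21)
  n <- 400
  y1 <- rbinom(n, 1, 0.5)
  y2 <- rbinom(n, 1, plogis(-0.4 + 1.1 * y1))
  d <- mixedDataset(categorical = cbind(a = y1 + 1L, b = y2 + 1L),
                    levels = list(a = c("0", "1"), b = c("0", "1")))
  fit <- fitMGM(d, fitControl(lambda = 0, tol = 1e-14, maxIter = 50000))
  gl <- glm(y2 ~ y1, family = binomial())
  expect_lt(abs(fittedParams(fit)@phi[["1|2"]][2, 2] - coef(gl)[2]), 1e-6)
  expect_lt(abs(fittedParams(fit)@theta[[2]][[2]] - coef(gl)[1]), 1e-6)
  # symmetric direction
  gl2 <- glm(y1 ~ y2, family = binomial())
  expect_lt(abs(fittedParams(fit)@phi[["1|2"]][2, 2] - coef(gl2)[2]), 1e-6)
})

test_that("bivariate Gaussian edge matches the partial-correlation estimate", {
  set.seed(31)
  n <- 1000
  x1 <- rnorm(n); x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  d <- applyTransforms(mixedDataset(continuous = cbind(a = x1, b = x2)))
  fit <- fitMGM(d, fitControl(lambda = 0, tol = 1e-12, maxIter = 20000))
  X <- continuousValues(d)
  K <- solve(crossprod(sweep(X, 2, colMeans(X))) / n)
  expect_equal(fittedParams(fit)@beta[1, 2], -K[1, 2], tolerance = 1e-3)
})

test_that("identical configuration and data give bit-identical fits", {
  sm <- smallMixed(n = 150, p = 3, q = 2, seed = 41)
  d <- suppressWarnings(applyTransforms(sm$data))
  ctl <- fitControl(lambda = 0.05, tol = 1e-8)
  f1 <- fitMGM(d, ctl)
  f2 <- fitMGM(d, ctl)
  expect_identical(flattenMGM(fittedParams(f1)), flattenMGM(fittedParams(f2)))
})

test_that("objective is non-increasing under function restarts", {
  sm <- smallMixed(n = 200, p = 4, q = 2, seed = 51)
  d <- suppressWarnings(applyTransforms(sm$data))
  for (lam in c(0, 0.02, 0.2)) {
    fit <- fitMGM(d, fitControl(lambda = lam, tol = 1e-9))
    expect_true(all(diff(fitTrace(fit)$objective) <= 1e-12))
  }
})

test_that("KKT conditions hold at convergence", {
  sm <- smallMixed(n = 300, p = 4, q = 2, seed = 61)
  d <- suppressWarnings(applyTransforms(sm$data))
  lam <- 0.05
  fit <- fitMGM(d, fitControl(lambda = lam, tol = 1e-12, maxIter = 50000))
  params <- fittedParams(fit)
  v <- flattenMGM(params)
  g <- flattenMGM(params, gradNegPseudoLoglik(params, d))
  pm <- penaltyMask(params)
  zero <- pm$mask & v == 0
  act <- pm$mask & v != 0
  if (any(zero)) expect_lt(max(abs(g[zero])), lam + 1e-4)
  if (any(act)) expect_lt(max(abs(g[act] + lam * sign(v[act]))), 1e-4)
  # unpenalized node potentials (alpha, theta) are stationary at convergence
  idx <- mgmix:::flatTemplate(params)
  nodePot <- which(!pm$mask)
  nodePot <- setdiff(nodePot, idx$diag)
  expect_lt(max(abs(g[nodePot])), 1e-4)
})

test_that("lambda at or above lambdaMax yields an empty edge set", {
  sm <- smallMixed(n = 250, p = 3, q = 2, seed = 71)
  d <- suppressWarnings(applyTransforms(sm$data))
  lmax <- lambdaMax(d)
  fit <- fitMGM(d, fitControl(lambda = 1.01 * lmax, tol = 1e-10))
  expect_equal(nrow(networkEdges(collapseEdges(fittedParams(fit)))), 0L)
})

test_that("lambdaMax on a duplicated standardized variable matches the
           hand-computed tied gradient", {
  set.seed(81)
  x <- rnorm(400)
  d <- applyTransforms(mixedDataset(continuous = cbind(a = x, b = x + 0)))
  X <- continuousValues(d)
  n <- nrow(X)
  # tied edge gradient at the edge-free optimum, computed from first
  # principles: -(mean(r_a x_b) + mean(r_b x_a)) with r = x - mean(x),
  # precisions at their ML values (they do not enter the beta entry)
  ra <- X[, 1] - mean(X[, 1]); rb <- X[, 2] - mean(X[, 2])
  expected <- abs(mean(ra * X[, 2]) + mean(rb * X[, 1]))
  expect_equal(lambdaMax(d), expected, tolerance = 1e-10)
  # duplicated standardized columns: the entry is twice the ML correlation
  expect_equal(expected, 2 * (n - 1) / n, tolerance = 1e-12)
})

test_that("lambdaMax of pure noise shrinks with sample size", {
  lm1 <- lambdaMax(gaussData(100, 4, seed = 91, rho = 0))
  lm2 <- lambdaMax(gaussData(4000, 4, seed = 92, rho = 0))
  expect_lt(lm2, lm1)
  expect_lt(lm2, 0.15)
})

test_that("FISTA and ISTA agree in objective; FISTA needs no more iterations", {
  sm <- smallMixed(n = 250, p = 4, q = 2, seed = 101)
  d <- suppressWarnings(applyTransforms(sm$data))
  lam <- 0.03
  # converged solutions agree in objective
  fista <- fitMGM(d, fitControl(lambda = lam, tol = 1e-10, maxIter = 50000))
  ista <- fitMGM(d, fitControl(lambda = lam, tol = 1e-10, maxIter = 50000,
                               momentum = FALSE, restart = "none"))
  oF <- min(fitTrace(fista)$objective)
  oI <- min(fitTrace(ista)$objective)
  expect_lt(abs(oF - oI), 1e-5)
  # acceleration: no more iterations than ISTA at the default tolerance
  fF6 <- fitMGM(d, fitControl(lambda = lam, tol = 1e-6, maxIter = 50000))
  fI6 <- fitMGM(d, fitControl(lambda = lam, tol = 1e-6, maxIter = 50000,
                              momentum = FALSE, restart = "none"))
  expect_lte(nrow(fitTrace(fF6)), nrow(fitTrace(fI6)))
})

test_that("permuting variable order permutes the solution identically", {
  sm <- smallMixed(n = 200, p = 3, q = 2, seed = 111)
  d <- suppressWarnings(applyTransforms(sm$data))
  ctl <- fitControl(lambda = 0.04, tol = 1e-10)
  f1 <- fitMGM(d, ctl)
  # permute continuous columns (3, 1, 2) and categorical columns (2, 1)
  perm <- new("MixedDataset",
              continuous = d@continuous[, c(3, 1, 2)],
              categorical = d@categorical[, c(2, 1)],
              specs = d@specs[c(3, 1, 2, 5, 4), ],
              levels = d@levels[c(2, 1)],
              sampleIds = d@sampleIds)
  f2 <- fitMGM(perm, ctl)
  b1 <- fittedParams(f1)@beta
  b2 <- fittedParams(f2)@beta
  expect_equal(b2, b1[c(3, 1, 2), c(3, 1, 2)], tolerance = 1e-9)
  # a continuous-categorical block maps to the permuted positions
  r1 <- fittedParams(f1)@rho[[2]]       # cat var 2 in original order
  r2 <- fittedParams(f2)@rho[[1]]       # same variable, now first
  expect_equal(r2, r1[c(3, 1, 2), ], tolerance = 1e-9)
})

test_that("warm-started paths match cold starts and nest by sparsity", {
  sm <- smallMixed(n = 300, p = 4, q = 2, seed = 121)
  d <- suppressWarnings(applyTransforms(sm$data))
  lmax <- lambdaMax(d)
  lambdas <- lmax * c(0.8, 0.4, 0.2)
  ctl <- fitControl(tol = 1e-9)
  path <- regularizationPath(d, lambdas, ctl)
  for (k in seq_along(lambdas)) {
    cold <- fitMGM(d, fitControl(lambda = lambdas[k], tol = 1e-9))
    warmObj <- min(fitTrace(path[[k]])$objective)
    coldObj <- min(fitTrace(cold)$objective)
    expect_lt(warmObj, coldObj + 1e-6)
  }
  nEdges <- vapply(path, function(f)
    nrow(networkEdges(collapseEdges(fittedParams(f)))), integer(1))
  expect_true(all(diff(nEdges) >= 0))
  # single-lambda path is just fitMGM
  single <- regularizationPath(d, lambdas[1], ctl)
  expect_equal(flattenMGM(fittedParams(single[[1]])),
               flattenMGM(fittedParams(fitMGM(d, fitControl(lambda = lambdas[1],
                                                            tol = 1e-9)))))
})

test_that("EBIC selection is seed-free and near-empty on pure noise", {
  d <- gaussData(1000, 10, seed = 131, rho = 0)
  sel1 <- selectLambda(d, method = "ebic", seed = 1)
  sel2 <- selectLambda(d, method = "ebic", seed = 99)
  expect_identical(sel1$lambda, sel2$lambda)
  nFalse <- nrow(networkEdges(collapseEdges(fittedParams(sel1$fit))))
  expect_lte(nFalse, 2L)
})

test_that("cross-validation selects a workable lambda and guards folds", {
  sm <- smallMixed(n = 240, p = 3, q = 1, seed = 141)
  d <- suppressWarnings(applyTransforms(sm$data))
  lmax <- lambdaMax(d)
  sel <- selectLambda(d, lambdas = lmax * c(0.7, 0.35, 0.15), method = "cv",
                      folds = 3, seed = 7, control = fitControl(tol = 1e-7))
  expect_true(sel$lambda %in% (lmax * c(0.7, 0.35, 0.15)))
  # degenerate fold: a nearly-constant categorical level must be refused
  dBad <- d
  dBad@categorical[, 1] <- c(2L, rep(1L, nSamples(d) - 1))
  expect_error(selectLambda(dBad, lambdas = lmax * c(0.5, 0.25), method = "cv",
                            folds = 5, seed = 1,
                            control = fitControl(tol = 1e-6)),
               "level")
})
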