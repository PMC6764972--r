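test_that("log potential matches hand arithmetic and vanishes at zero", {
  params <- emptyMGMParameters("x1", list(y1 = c("a", "b")))
  params@beta[1, 1] <- -1
  expect_equal(logPotential(params, 2, 1L), -2)   # 1/2 * (-1) * 4
  zero <- emptyMGMParameters(character(0), list(y1 = c("a", "b"),
                                                y2 = c("a", "b")))
  for (y in list(c(1L, 1L), c(2L, 1L), c(2L, 2L)))
    expect_equal(logPotential(zero, numeric(0), y), 0)
})

test_that("discrete-only joint enumeration matches the stated potentials", {
  params <- randomParams(0, 2, Ls = c(2L, 2L), seed = 4, scale = 0.8)
  enum <- enumerateJoint(params)
  # direct hand computation of the 4 cell potentials
  th1 <- params@theta[[1]]; th2 <- params@theta[[2]]
  B <- params@phi[["1|2"]]
  lp <- c(th1[1] + th2[1] + B[1, 1], th1[2] + th2[1] + B[2, 1],
          th1[1] + th2[2] + B[1, 2], th1[2] + th2[2] + B[2, 2])
  pr <- exp(lp) / sum(exp(lp))
  # expand.grid enumerates y1 fastest: (1,1), (2,1), (1,2), (2,2)
  expect_equal(unname(enum$prob), unname(pr), tolerance = 1e-12)
})

test_that("continuous conditionals have the closed-form mean and variance", {
  params <- emptyMGMParameters(c("x1", "x2"), list())
  cc <- conditionalContinuous(params, 1, c(0, 0))
  expect_equal(cc, list(mean = 0, variance = 1))
  params@beta[1, 2] <- params@beta[2, 1] <- 0.5
  cc <- conditionalContinuous(params, 1, c(0, 2))
  expect_equal(cc$mean, 1)      # (0.5 * 2) / 1
  expect_equal(cc$variance, 1)
  params@beta[1, 1] <- -1e-6
  expect_error(conditionalContinuous(params, 1, c(0, 2)), "degenerate")
})

test_that("continuous conditional equals the joint-density ratio (quadrature)", {
  params <- randomParams(2, 1, Ls = 3L, seed = 9, scale = 0.4)
  x <- c(NA, 0.6); y <- 2L
  cc <- conditionalContinuous(params, 1, c(0, x[2]), y)
  grid <- seq(cc$mean - 8 * sqrt(cc$variance),
              cc$mean + 8 * sqrt(cc$variance), length.out = 4001)
  lp <- vapply(grid, function(g) logPotential(params, c(g, x[2]), y),
               numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  qMean <- sum(grid * w)
  qVar <- sum((grid - qMean)^2 * w)
  expect_equal(qMean, cc$mean, tolerance = 1e-6)
  expect_equal(qVar, cc$variance, tolerance = 1e-4)
})

test_that("categorical conditionals are softmax probabilities", {
  params <- emptyMGMParameters(character(0), list(y1 = c("a", "b", "c")))
  expect_equal(conditionalCategorical(params, 1, y = 1L),
               setNames(rep(1/3, 3), c("a", "b", "c")))
  bin <- emptyMGMParameters(character(0), list(y1 = c("0", "1")))
  bin@theta[[1]][2] <- 2
  pr <- conditionalCategorical(bin, 1, y = 1L)
  expect_equal(unname(pr), c(1 / (1 + exp(2)), 1 / (1 + exp(-2))),
               tolerance = 1e-12)
})

test_that("categorical conditional matches enumeration over a mixed model", {
  params <- randomParams(1, 2, Ls = c(2L, 3L), seed = 12, scale = 0.5)
  xv <- 0.8; yOther <- 2L
  # p(y2 = l | x, y1) by quadrature-free enumeration: x is conditioned on,
  # so the ratio needs only the discrete states of y2
  lp <- vapply(1:3, function(l)
    logPotential(params, xv, c(yOther, l)), numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  got <- conditionalCategorical(params, 2, xv, c(yOther, 1L))
  expect_equal(unname(got), unname(pr), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("pseudo-log-likelihood matches per-node baselines", {
  # standard-normal node: per-row contribution x^2/2 + log(2*pi)/2
  d <- mixedDataset(continuous = cbind(x = c(-1, 0, 2)))
  params <- emptyMGMParameters("x", list())
  expect_equal(negPseudoLoglik(params, d),
               mean(c(1, 0, 4) / 2) + 0.5 * log(2 * pi))
  # uniform binary node: log 2 per row
  d2 <- mixedDataset(categorical = cbind(y = c(1L, 2L, 1L)),
                     levels = list(y = c("0", "1")))
  expect_equal(negPseudoLoglik(emptyMGMParameters(character(0),
                                                  list(y = c("0", "1"))), d2),
               log(2))
})

test_that("pseudo-log-likelihood equals an independent per-node summation", {
  sm <- smallMixed(n = 60, p = 2, q = 2, seed = 21)
  params <- randomParams(2, 2, seed = 22, scale = 0.4)
  d <- sm$data
  # oracle: loop rows and nodes, using only the conditional functions
  X <- continuousValues(d); Y <- categoricalValues(d)
  tot <- 0
  for (i in seq_len(nSamples(d))) {
    for (s in 1:2) {
      cc <- conditionalContinuous(params, s, X[i, ], Y[i, ])
      tot <- tot - dnorm(X[i, s], cc$mean, sqrt(cc$variance), log = TRUE)
    }
    for (j in 1:2) {
      pr <- conditionalCategorical(params, j, X[i, ], Y[i, ])
      tot <- tot - log(pr[Y[i, j]])
    }
  }
  expect_equal(negPseudoLoglik(params, d), unname(tot / nSamples(d)),
               tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  cases <- expand.grid(p = c(0L, 1L, 4L), q = c(0L, 1L, 3L))
  cases <- cases[cases$p + cases$q > 0, ]
  for (k in seq_len(nrow(cases))) {
    p <- cases$p[k]; q <- cases$q[k]
    Ls <- if (q > 0) rep_len(c(2L, 3L, 4L), q) else integer(0)
    gt <- makeGroundTruth(p, q, levels = Ls, density = 0.6,
                          weightRange = c(0.2, 0.5), seed = 30 + k)
    d <- gibbsSample(gt, 50, burnIn = 100, thin = 1, seed = 40 + k)
    params <- randomParams(p, q, Ls = Ls, seed = 50 + k, scale = 0.3)
    g <- flattenMGM(params, gradNegPseudoLoglik(params, d))
    fd <- numericGradient(params, d)
    relErr <- max(abs(g - fd) / pmax(abs(fd), 1e-6))
    expect_lt(relErr, 1e-6)
  }
})

test_that("gradient vanishes at a moment-matched separable optimum", {
  d <- gaussData(200, 3, seed = 61)
  X <- continuousValues(d)
  K <- solve(crossprod(sweep(X, 2, colMeans(X))) / nrow(X))
  params <- emptyMGMParameters(colnames(X), list())
  params@beta <- -K
  params@alpha <- drop(K %*% colMeans(X))
  g <- flattenMGM(params, gradNegPseudoLoglik(params, d))
  expect_lt(max(abs(g)), 1e-8)
})

test_that("gradient of alpha is zero at zero parameters on zero data", {
  d <- mixedDataset(continuous = cbind(a = numeric(10), b = numeric(10)) + 0)
  params <- emptyMGMParameters(c("a", "b"), list())
  g <- gradNegPseudoLoglik(params, d)
  expect_equal(unname(g$alpha), c(0, 0))
})

test_that("flat vector round-trips and respects tied storage of phi", {
  params <- randomParams(3, 3, Ls = c(2L, 3L, 2L), seed = 71, scale = 0.6)
  v <- flattenMGM(params)
  back <- unflattenMGM(v, params)
  expect_equal(back@beta, params@beta)
  expect_equal(back@rho, params@rho)
  expect_equal(back@phi, params@phi)
  # transpose-consistent storage: evaluating with phi accessed in either
  # orientation gives the same potential
  y <- c(2L, 3L, 1L)
  x <- c(0.1, -0.2, 0.5)
  direct <- logPotential(params, x, y)
  manual <- 0.5 * drop(x %*% params@beta %*% x) + sum(params@alpha * x) +
    sum(vapply(1:3, function(j) params@theta[[j]][y[j]] +
                 sum(params@rho[[j]][, y[j]] * x), numeric(1))) +
    sum(vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(rj)
      t(mgmix:::phiBlock(params, rj[2], rj[1]))[y[rj[1]], y[rj[2]]],
      numeric(1)))
  expect_equal(direct, manual, tolerance = 1e-12)
})

test_that("JSON serialization round-trips bit-stably", {
  params <- randomParams(2, 2, Ls = c(2L, 3L), seed = 81, scale = 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  writeMGMParameters(params, path)
  back <- readMGMParameters(path)
  expect_identical(back@beta, params@beta)
  expect_identical(back@rho, params@rho)
  expect_identical(back@theta, params@theta)
  expect_identical(back@phi, params@phi)
  expect_identical(back@levels, params@levels)
})

test_that("parameter counting distinguishes edge and node parameters", {
  params <- emptyMGMParameters(c("x1", "x2"), list(y1 = c("a", "b"),
                                                   y2 = c("a", "b", "c")))
  cnt <- parameterCount(params)
  # edges: 1 beta + 2*1 rho(y1) + 2*2 rho(y2) + 1*2 phi = 9
  expect_equal(unname(cnt["edge"]), 9L)
  # nodes: 2 alpha + 2 diag + 1 theta(y1) + 2 theta(y2) = 7
  expect_equal(unname(cnt["node"]), 7L)
  expect_equal(unname(cnt["total"]), 16L)
})
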