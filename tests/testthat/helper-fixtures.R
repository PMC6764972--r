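# fixtures are generated in code; no data files

## standardized multivariate Gaussian data with a known precision structure
gaussData <- function(n, p, seed = 1, rho = 0.4) {
  set.seed(seed)
  S <- outer(1:p, 1:p, function(i, j) rho^abs(i - j))
  X <- matrix(rnorm(n * p), n) %*% chol(S)
  colnames(X) <- sprintf("g%02d", 1:p)
  applyTransforms(mixedDataset(continuous = X))
}

## a small mixed dataset drawn from a known sparse truth
smallMixed <- function(n = 300, p = 3, q = 2, seed = 1, density = 0.5) {
  gt <- makeGroundTruth(p, q, density = density, seed = seed)
  list(truth = gt, data = gibbsSample(gt, n, burnIn = 200, thin = 1,
                                      seed = seed + 1000))
}

## random parameters with every block populated (for gradient checks)
randomParams <- function(p, q, Ls = rep(2L, q), seed = 1, scale = 0.3) {
  lv <- setNames(lapply(Ls, function(L) as.character(seq_len(L) - 1)),
                 if (q > 0) sprintf("y%02d", seq_len(q)) else character(0))
  params <- emptyMGMParameters(
    if (p > 0) sprintf("x%02d", seq_len(p)) else character(0), lv)
  set.seed(seed)
  v <- flattenMGM(params)
  idx <- mgmix:::flatTemplate(params)
  v <- rnorm(length(v), sd = scale)
  v[idx$diag] <- -runif(p, 0.8, 2)   # keep precisions well away from epsilon
  unflattenMGM(v, params)
}

## central finite differences of the negative pseudo-log-likelihood
numericGradient <- function(params, d, h = 1e-5) {
  v <- flattenMGM(params)
  vapply(seq_along(v), function(k) {
    vp <- v; vp[k] <- vp[k] + h
    vm <- v; vm[k] <- vm[k] - h
    (negPseudoLoglik(unflattenMGM(vp, params), d) -
       negPseudoLoglik(unflattenMGM(vm, params), d)) / (2 * h)
  }, numeric(1))
}

## enumerate the joint distribution of a discrete-only model
enumerateJoint <- function(params) {
  Ls <- lengths(params@levels)
  states <- as.matrix(expand.grid(lapply(Ls, seq_len)))
  lp <- apply(states, 1, function(y)
    logPotential(params, numeric(0), as.integer(y)))
  pr <- exp(lp - max(lp))
  list(states = states, prob = pr / sum(pr))
}

## write a small data+meta CSV pair for loader tests; returns the two paths
writeTinyTables <- function(dir, mutate = identity) {
  dataPath <- file.path(dir, "data.csv")
  metaPath <- file.path(dir, "meta.csv")
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   bmi = c(21.5, 27.3, 24.0),
                   smoker = c("no", "yes", "no"),
                   stringsAsFactors = FALSE)
  df <- mutate(df)
  write.csv(df, dataPath, row.names = FALSE)
  write.csv(data.frame(name = c("bmi", "smoker"),
                       kind = c("continuous", "categorical"),
                       levels = c("", "no|yes"),
                       layer = c("clinical_chemistry", "demographic"),
                       log2 = c(0L, 0L)),
            metaPath, row.names = FALSE)
  list(data = dataPath, meta = metaPath)
}
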