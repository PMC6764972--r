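## Univariate association screening and the post-hoc confounder-adjustment
## comparison between univariate "top associations" and MGM "top neighbors".

## p-values are floored before -log10 so perfect fits stay finite
P_FLOOR <- 1e-300

## linear or logistic regression of `response` on predictor + confounders;
## returns the focal predictor's coefficient, p-value (strongest column for
## a multi-level factor predictor), and a separation flag.
regressP <- function(df, response, predictor, confounders = character(),
                     binaryResponse) {
  terms <- c(predictor, confounders)
  fml <- stats::as.formula(paste0("`", response, "` ~ ",
                                  paste0("`", terms, "`", collapse = " + ")))
  fit <- if (binaryResponse)
    suppressWarnings(glm(fml, df, family = binomial()))
  else lm(fml, df)
  mm <- stats::model.matrix(fit)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("rank-deficient design for response '%s': collinear column(s) %s",
                 response, paste(aliased, collapse = ", ")))
  }
  focalCols <- colnames(mm)[attr(mm, "assign") == 1]  # term 1 = predictor
  sm <- summary(fit)$coefficients[focalCols, , drop = FALSE]
  ridx <- which.min(sm[, 4])
  co <- sm[ridx, 1]; pv <- sm[ridx, 4]
  flagged <- FALSE
  if (binaryResponse &&
      (!fit$converged || abs(co) > 15 || sm[ridx, 2] > 100)) {
    # (quasi-)separation: fall back to a ridge-stabilized logistic fit
    flagged <- TRUE
    yy <- stats::model.response(stats::model.frame(fit))
    if (is.factor(yy)) yy <- as.integer(yy) - 1L
    rl <- ridgeLogistic(mm, yy, lambda = 1e-2)
    k <- match(focalCols[ridx], colnames(mm))
    co <- rl$coef[k]
    pv <- 2 * pnorm(-abs(co / rl$se[k]))
  }
  list(coef = unname(co), p = max(pv, P_FLOOR), flagged = flagged)
}

## small-L2 penalized logistic fit with Wald standard errors
ridgeLogistic <- function(X, y, lambda = 1e-2, maxIter = 100) {
  b <- numeric(ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (i in seq_len(maxIter)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - mu) - pen %*% b
    db <- solve(H, g)
    b <- b + drop(db)
    if (max(abs(db)) < 1e-8) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(X, X * (mu * (1 - mu))) + pen
  list(coef = b, se = sqrt(diag(solve(H))))
}

isBinaryVar <- function(d, v) {
  v %in% colnames(d@categorical) && length(d@levels[[v]]) == 2
}

#' Univariate association screen over all variable pairs
#'
#' Regresses each variable on every single remaining variable: simple linear
#' regression (two-sided t-test on the slope) for continuous responses,
#' logistic regression (Wald test) for binary responses. Responses that are
#' categorical with more than two levels are skipped as responses but still
#' serve as predictors (entered as factors). For each response, predictors
#' are ranked by decreasing -log10 p, ties broken by |coefficient| then
#' name. Separated logistic fits fall back to a ridge-stabilized fit and are
#' flagged.
#'
#' @param d a complete \code{\linkS4class{MixedDataset}}.
#' @param responses optional subset of response variables to screen
#'   (default: all continuous and binary variables).
#' @return a \code{\linkS4class{ScreeningResult}}.
#' @export
univariateScreen <- function(d, responses = NULL) {
  df <- datasetAsDataFrame(d)
  vars <- d@specs$name
  if (is.null(responses)) {
    responses <- vars[vapply(vars, function(v)
      v %in% colnames(d@continuous) || isBinaryVar(d, v), logical(1))]
  }
  rows <- list()
  for (r in responses) {
    bin <- isBinaryVar(d, r)
    if (bin && length(unique(d@categorical[, r])) < 2)
      stop(sprintf("binary response '%s' has a single class", r))
    for (pr in setdiff(vars, r)) {
      res <- regressP(df, r, pr, character(), bin)
      rows[[length(rows) + 1]] <- data.frame(
        response = r, predictor = pr, coefficient = res$coef,
        pvalue = res$p, neglog10p = -log10(res$p), flagged = res$flagged,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  ranking <- lapply(split(pairs, pairs$response), function(tab) {
    tab <- tab[order(-tab$neglog10p, -abs(tab$coefficient), tab$predictor), ]
    tab$predictor
  })
  new("ScreeningResult", pairs = pairs, ranking = ranking[responses])
}

#' Confounder-adjusted -log10 p-value
#'
#' Fits the multivariate linear or logistic model of \code{response} on
#' \code{predictor} plus \code{confounders} simultaneously and returns the
#' predictor's -log10 p in that joint model. With an empty confounder list
#' this equals the univariate screen result exactly.
#'
#' @param d a complete \code{\linkS4class{MixedDataset}}.
#' @param response response variable name (continuous or binary).
#' @param predictor focal predictor name.
#' @param confounders character vector of adjustment variables (disjoint
#'   from response and predictor).
#' @return the -log10 p-value of \code{predictor} in the joint model.
#' @export
adjustedPvalue <- function(d, response, predictor, confounders = character()) {
  stopifnot(!predictor %in% confounders, !response %in% c(predictor, confounders))
  res <- regressP(datasetAsDataFrame(d), response, predictor,
                  confounders, isBinaryVar(d, response))
  -log10(res$p)
}

#' Top-k neighbors of a response in the fitted network
#'
#' Predictors ranked by decreasing absolute collapsed edge weight.
#'
#' @param net an \code{\linkS4class{EdgeNetwork}}.
#' @param response node name.
#' @param k number of neighbors to return (fewer if the neighborhood is
#'   smaller).
#' @return character vector of neighbor names, strongest first.
#' @export
mgmTopNeighbors <- function(net, response, k = 5L) {
  nb <- firstOrderNeighborhood(net, response)
  head(nb@neighbors$node, k)
}

#' Compare univariate top associations with MGM top neighbors under
#' confounder adjustment
#'
#' For every screened response, records the unadjusted -log10 p of (i) the
#' univariate top association and (ii) the MGM top neighbor, then the
#' adjusted versions under the chosen scheme: \code{"top5"} adjusts each
#' method's pick for the next five variables of that method's own ranking;
#' \code{"random5"} adjusts both picks for the same five variables drawn
#' uniformly without replacement from univariate ranks 2-11. Differences are
#' MGM minus univariate, with rank-percentile columns (most negative
#' difference at 0, most positive at 1).
#'
#' @param d the training \code{\linkS4class{MixedDataset}} (the same data the
#'   network was fitted on).
#' @param net the fitted \code{\linkS4class{EdgeNetwork}}.
#' @param scheme \code{"top5"} or \code{"random5"}.
#' @param seed integer seed for the random draw.
#' @param screen optional precomputed \code{\linkS4class{ScreeningResult}}.
#' @return list with \code{table} (one row per response: top picks, their
#'   unadjusted/adjusted -log10 p, differences and rank percentiles),
#'   \code{excluded} (responses with fewer than 6 candidate predictors or no
#'   MGM neighbors), and \code{summary} (fractions of positive, negative and
#'   zero unadjusted and adjusted differences).
#' @export
compareScreens <- function(d, net, scheme = c("top5", "random5"), seed = 1L,
                           screen = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(screen)) screen <- univariateScreen(d)
  responses <- names(screen@ranking)
  rows <- list(); excluded <- character(0)
  rng <- withSeed(seed, lapply(responses, function(r)
    sample(2:11, 5)))      # per-response random ranks, shared by both methods
  names(rng) <- responses
  for (r in responses) {
    rk <- screen@ranking[[r]]
    nbs <- mgmTopNeighbors(net, r, k = 6L)
    if (length(rk) < 11 || !length(nbs)) {
      excluded <- c(excluded, r)
      next
    }
    topAssoc <- rk[1]
    topNeigh <- nbs[1]
    pu <- screen@pairs
    puR <- pu[pu$response == r, ]
    unadjAssoc <- puR$neglog10p[puR$predictor == topAssoc]
    unadjNeigh <- puR$neglog10p[puR$predictor == topNeigh]
    if (scheme == "top5") {
      confAssoc <- rk[2:6]
      confNeigh <- setdiff(nbs, topNeigh)[1:5]
      confNeigh <- confNeigh[!is.na(confNeigh)]
      if (length(confNeigh) < 5) {
        # pad with the response's next univariate predictors not already used
        pad <- setdiff(rk, c(topNeigh, confNeigh))
        confNeigh <- c(confNeigh, pad[seq_len(5 - length(confNeigh))])
      }
    } else {
      confAssoc <- confNeigh <- rk[rng[[r]]]
    }
    adjAssoc <- adjustedPvalue(d, r, topAssoc, setdiff(confAssoc, topAssoc))
    adjNeigh <- adjustedPvalue(d, r, topNeigh, setdiff(confNeigh, topNeigh))
    rows[[length(rows) + 1]] <- data.frame(
      response = r, topAssoc = topAssoc, topNeigh = topNeigh,
      unadjAssoc = unadjAssoc, unadjNeigh = unadjNeigh,
      adjAssoc = adjAssoc, adjNeigh = adjNeigh,
      diffUnadj = unadjNeigh - unadjAssoc,
      diffAdj = adjNeigh - adjAssoc,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab) && nrow(tab)) {
    tab$rankPctUnadj <- (rank(tab$diffUnadj) - 1) / max(nrow(tab) - 1, 1)
    tab$rankPctAdj <- (rank(tab$diffAdj) - 1) / max(nrow(tab) - 1, 1)
  }
  summary <- if (!is.null(tab)) c(
    fracPosUnadj = mean(tab$diffUnadj > 0), fracNegUnadj = mean(tab$diffUnadj < 0),
    fracZeroUnadj = mean(tab$diffUnadj == 0),
    fracPosAdj = mean(tab$diffAdj > 0), fracNegAdj = mean(tab$diffAdj < 0),
    fracZeroAdj = mean(tab$diffAdj == 0)) else NULL
  list(table = tab, excluded = excluded, summary = summary)
}

#' Benjamini-Hochberg adjusted p-values for a screen (supplementary output)
#'
#' @param screen a \code{\linkS4class{ScreeningResult}}.
#' @return the pair table with an extra \code{pAdjustBH} column.
#' @export
screenWithBH <- function(screen) {
  tab <- screen@pairs
  tab$pAdjustBH <- stats::p.adjust(tab$pvalue, method = "BH")
  tab
}
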