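## Out-of-sample validation of first-order neighborhoods: linear prediction
## for continuous centers, logistic prediction for binary centers, with
## Pearson correlation and ROC/AUC summaries.

#' Predict a center node from its first-order neighborhood
#'
#' Uses the fitted edge weights directly as a linear (continuous center) or
#' logistic (categorical center) signature; nothing is refit. For a
#' continuous center the per-sample score is the conditional mean
#' \code{(alpha_s + sum_{t in N} beta_st x_t + sum_{j in N} rho_sj(y_j)) /
#' (-beta_ss)}; for a binary center it is the conditional probability of the
#' non-reference level; for a multi-level center the full conditional
#' probability matrix is returned. Test data must be transformed with the
#' TRAINING center/scale (see \code{\link{applyTransforms}}).
#'
#' @param model a \code{\linkS4class{NeighborhoodModel}} (used for its center
#'   and neighbor set).
#' @param params the fitted \code{\linkS4class{MGMParameters}}.
#' @param dTest a \code{\linkS4class{MixedDataset}} containing every neighbor
#'   variable.
#' @param refit logical; if TRUE, re-estimate the linear/logistic model on
#'   the neighborhood variables of \code{dTest} before scoring (comparison
#'   mode; default FALSE).
#' @return numeric vector of per-sample scores (or a probability matrix for
#'   a multi-level categorical center).
#' @export
predictFromNeighborhood <- function(model, params, dTest, refit = FALSE) {
  need <- model@neighbors$node
  have <- c(colnames(dTest@continuous), colnames(dTest@categorical))
  if (length(missing <- setdiff(need, have)))
    stop("neighbor variable(s) absent from test data: ",
         paste(missing, collapse = ", "))
  n <- nSamples(dTest)
  X <- dTest@continuous
  Y <- dTest@categorical
  center <- model@center
  if (refit) return(refitNeighborhood(model, dTest))
  if (model@centerKind == "continuous") {
    s <- match(center, params@contNames)
    tau <- -params@beta[s, s]
    eta <- rep(params@alpha[s], n)
    for (t in seq_along(params@contNames)) {
      if (t == s) next
      if (params@beta[s, t] != 0)
        eta <- eta + params@beta[s, t] * X[, params@contNames[t]]
    }
    for (j in seq_along(params@catNames)) {
      rv <- params@rho[[j]][s, ]
      if (any(rv != 0))
        eta <- eta + rv[Y[, params@catNames[j]]]
    }
    return(unname(eta / tau))
  }
  j <- match(center, params@catNames)
  L <- length(params@levels[[j]])
  Eta <- matrix(params@theta[[j]], n, L, byrow = TRUE)
  for (s in seq_along(params@contNames)) {
    rv <- params@rho[[j]][s, ]
    if (any(rv != 0))
      Eta <- Eta + outer(X[, params@contNames[s]], rv)
  }
  for (r in seq_along(params@catNames)) {
    if (r == j) next
    B <- phiBlock(params, r, j)
    if (any(B != 0))
      Eta <- Eta + B[Y[, params@catNames[r]], , drop = FALSE]
  }
  Eta <- Eta - apply(Eta, 1, max)
  P <- exp(Eta)
  P <- P / rowSums(P)
  colnames(P) <- params@levels[[j]]
  if (L == 2) unname(P[, 2]) else P
}

## comparison mode: ordinary lm/glm on the neighborhood variables
refitNeighborhood <- function(model, d) {
  df <- datasetAsDataFrame(d)
  nb <- model@neighbors$node
  if (!length(nb)) return(rep(NA_real_, nSamples(d)))
  fml <- stats::as.formula(paste0("`", model@center, "` ~ ",
                                  paste0("`", nb, "`", collapse = " + ")))
  if (model@centerKind == "continuous")
    unname(stats::fitted(lm(fml, df)))
  else
    unname(stats::fitted(glm(fml, df, family = binomial())))
}

## continuous columns as-is; categorical as factors (reference level first)
datasetAsDataFrame <- function(d) {
  df <- as.data.frame(d@continuous)
  for (v in colnames(d@categorical))
    df[[v]] <- factor(d@levels[[v]][d@categorical[, v]],
                      levels = d@levels[[v]])
  rownames(df) <- d@sampleIds
  df
}

#' Pearson correlation between truth and prediction
#'
#' @param truth numeric vector (n >= 3, nonzero variance).
#' @param pred numeric vector of equal length (nonzero variance).
#' @return the Pearson correlation coefficient in [-1, 1].
#' @export
pearsonCorrelation <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) < 3) stop("need at least 3 observations")
  if (sd(truth) == 0 || sd(pred) == 0)
    stop("zero variance in truth or prediction")
  cor(truth, pred)
}

#' ROC curve and AUC
#'
#' Thresholds sweep from +Inf downward over the distinct score values; tied
#' scores share a threshold, and the AUC is the trapezoidal area under the
#' (FPR, TPR) curve, which equals the normalized Mann-Whitney U statistic
#' with ties counted 1/2.
#'
#' @param labels binary vector (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @param scores numeric scores, larger meaning more positive.
#' @return list with \code{curve} (data.frame fpr, tpr, threshold) and
#'   \code{auc}.
#' @export
rocAuc <- function(labels, scores) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  stopifnot(length(labels) == length(scores))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  nPos <- sum(l == 1); nNeg <- sum(l == 0)
  # collapse tied thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l == 1); fp <- cumsum(l == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  curve <- data.frame(
    fpr = c(0, fp[last] / nNeg),
    tpr = c(0, tp[last] / nPos),
    threshold = c(Inf, s[last]))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

#' Validate every first-order neighborhood on test data
#'
#' One row per node: Pearson correlation between truth and neighborhood
#' prediction for continuous centers, AUC for binary centers; multi-level
#' categorical centers get one one-vs-rest AUC per level plus a macro
#' average. Nodes whose metric is undefined (empty neighborhood giving a
#' constant continuous prediction) are flagged with NA.
#'
#' @param params fitted \code{\linkS4class{MGMParameters}}.
#' @param net the collapsed \code{\linkS4class{EdgeNetwork}}.
#' @param dTest test \code{\linkS4class{MixedDataset}} in training units.
#' @return data.frame with columns \code{node}, \code{kind}, \code{metric},
#'   \code{level}, \code{value}, \code{nNeighbors}.
#' @export
validateAllNeighborhoods <- function(params, net, dTest) {
  rows <- list()
  for (v in net@nodes$name) {
    nb <- firstOrderNeighborhood(net, v, params)
    sc <- predictFromNeighborhood(nb, params, dTest)
    kind <- nb@centerKind
    if (kind == "continuous") {
      truth <- dTest@continuous[, v]
      val <- if (is.numeric(sc) && sd(sc) > 0 && sd(truth) > 0)
        pearsonCorrelation(truth, sc) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        node = v, kind = kind, metric = "correlation", level = NA,
        value = val, nNeighbors = nrow(nb@neighbors))
    } else {
      j <- match(v, params@catNames)
      L <- length(params@levels[[j]])
      yv <- dTest@categorical[, v]
      if (L == 2) {
        val <- if (length(unique(yv)) == 2) rocAuc(yv == 2, sc)$auc else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          node = v, kind = kind, metric = "auc",
          level = params@levels[[j]][2], value = val,
          nNeighbors = nrow(nb@neighbors))
      } else {
        aucs <- rep(NA_real_, L)
        for (l in seq_len(L)) {
          if (length(unique(yv == l)) == 2)
            aucs[l] <- rocAuc(yv == l, sc[, l])$auc
        }
        for (l in seq_len(L))
          rows[[length(rows) + 1]] <- data.frame(
            node = v, kind = kind, metric = "auc_onevsrest",
            level = params@levels[[j]][l], value = aucs[l],
            nNeighbors = nrow(nb@neighbors))
        rows[[length(rows) + 1]] <- data.frame(
          node = v, kind = kind, metric = "auc_macro", level = NA,
          value = mean(aucs, na.rm = TRUE), nNeighbors = nrow(nb@neighbors))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
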