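#' @import methods
#' @importFrom stats rnorm runif sd var cor lm glm binomial coef pnorm setNames
#' @importFrom utils read.csv read.delim write.table head
NULL

## Central S4 containers. Categorical values are stored as integer level
## indices 1..L_j; index 1 is always the declared reference level, so every
## free effect parameter of a binary variable is a single signed scalar.

#' MixedDataset: a complete sample-by-variable table of mixed type
#'
#' Holds a complete (no missing entries) data matrix split into its continuous
#' and categorical parts, together with per-variable metadata. Continuous
#' values are real; categorical values are integer level indices in
#' \code{1..L_j} with level 1 the reference level. Completeness, finiteness
#' and level-range validity are enforced by the class validity method.
#'
#' @slot continuous numeric matrix, n samples x p continuous variables.
#' @slot categorical integer matrix, n samples x q categorical variables.
#' @slot specs data.frame with one row per variable (in model order):
#'   \code{name}, \code{kind} ("continuous"/"categorical"), \code{layer},
#'   \code{transformLog2}, \code{center}, \code{scale}. \code{center} and
#'   \code{scale} record the training-set affine map once
#'   \code{\link{applyTransforms}} has run, so the identical map can be
#'   applied to held-out data.
#' @slot levels named list: for each categorical variable, the ordered
#'   character vector of level labels (first = reference).
#' @slot sampleIds character vector of sample identifiers.
#'
#' @seealso \code{\link{mixedDataset}}, \code{\link{loadMixedDataset}}
#' @export
setClass("MixedDataset",
  representation(
    continuous  = "matrix",
    categorical = "matrix",
    specs       = "data.frame",
    levels      = "list",
    sampleIds   = "character"
  )
)

setValidity("MixedDataset", function(object) {
  msgs <- character()
  n <- length(object@sampleIds)
  X <- object@continuous
  Y <- object@categorical
  if (nrow(X) != n || nrow(Y) != n)
    msgs <- c(msgs, "continuous/categorical row counts must equal length(sampleIds)")
  if (anyNA(X) || anyNA(Y)) {
    bad <- which(is.na(X), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(Y), arr.ind = TRUE)
    msgs <- c(msgs, sprintf("missing value at sample '%s', variable '%s'",
                            object@sampleIds[bad[1, 1]],
                            colnames(if (anyNA(X)) X else Y)[bad[1, 2]]))
  } else {
    if (length(X) && any(!is.finite(X)))
      msgs <- c(msgs, "non-finite continuous value")
    for (v in colnames(Y)) {
      L <- length(object@levels[[v]])
      if (L < 2) msgs <- c(msgs, sprintf("categorical '%s' needs >= 2 levels", v))
      if (length(Y) && (any(Y[, v] < 1) || any(Y[, v] > L)))
        msgs <- c(msgs, sprintf("level index out of range for '%s'", v))
    }
  }
  sp <- object@specs
  need <- c("name", "kind", "layer", "transformLog2", "center", "scale")
  if (!all(need %in% names(sp)))
    msgs <- c(msgs, "specs must have columns name, kind, layer, transformLog2, center, scale")
  else {
    if (anyDuplicated(sp$name)) msgs <- c(msgs, "duplicate variable names")
    if (!setequal(sp$name[sp$kind == "continuous"], colnames(X)))
      msgs <- c(msgs, "specs/continuous column mismatch")
    if (!setequal(sp$name[sp$kind == "categorical"], colnames(Y)))
      msgs <- c(msgs, "specs/categorical column mismatch")
    if (!setequal(names(object@levels), colnames(Y)))
      msgs <- c(msgs, "levels list must be keyed by categorical variable names")
    for (v in names(object@levels))
      if (anyDuplicated(object@levels[[v]]))
        msgs <- c(msgs, sprintf("duplicate level labels for '%s'", v))
  }
  if (length(msgs)) msgs else TRUE
})

#' MGMParameters: the full parameter set of a pairwise mixed graphical model
#'
#' The joint density over p continuous variables x and q categorical variables
#' y is proportional to
#' \code{exp(1/2 sum_st beta_st x_s x_t + sum_s alpha_s x_s +
#' sum_sj rho_sj(y_j) x_s + sum_j theta_j(y_j) + sum_{r<j} phi_rj(y_r, y_j))}.
#' Reference-level coding pins the first entry of every rho and theta vector
#' and the first row/column of every phi block to exactly zero, so binary
#' edges collapse to single signed scalars. The diagonal of beta is strictly
#' negative (the conditional precision of node s is -beta_ss) and bounded
#' away from zero by \code{epsilon}.
#'
#' @slot beta symmetric p x p matrix of continuous-continuous couplings;
#'   strictly negative diagonal.
#' @slot alpha length-p numeric of continuous node potentials.
#' @slot rho named list (one per categorical variable) of p x L_j matrices of
#'   continuous-categorical couplings; first column zero.
#' @slot theta named list of length-L_j numeric node potentials; first entry zero.
#' @slot phi named list, keys \code{"r|j"} for categorical pair indices r < j,
#'   of L_r x L_j coupling matrices; first row and first column zero.
#' @slot contNames,catNames character vectors of variable names.
#' @slot levels named list of level labels per categorical variable.
#' @slot epsilon lower bound on conditional precisions (-beta_ss >= epsilon).
#' @export
setClass("MGMParameters",
  representation(
    beta = "matrix", alpha = "numeric",
    rho = "list", theta = "list", phi = "list",
    contNames = "character", catNames = "character",
    levels = "list", epsilon = "numeric"
  )
)

setValidity("MGMParameters", function(object) {
  p <- length(object@contNames); q <- length(object@catNames)
  msgs <- character()
  if (!identical(dim(object@beta), c(p, p)))
    msgs <- c(msgs, "beta must be p x p")
  else if (p > 0) {
    if (max(abs(object@beta - t(object@beta))) > 1e-10)
      msgs <- c(msgs, "beta must be symmetric")
    if (any(diag(object@beta) > -object@epsilon + 1e-12))
      msgs <- c(msgs, "diag(beta) must be <= -epsilon")
  }
  if (length(object@alpha) != p) msgs <- c(msgs, "alpha length != p")
  if (length(object@levels) != q || length(object@rho) != q ||
      length(object@theta) != q)
    msgs <- c(msgs, "rho/theta/levels must have one entry per categorical variable")
  else if (q > 0) {
    for (j in seq_len(q)) {
      L <- length(object@levels[[j]])
      if (!identical(dim(object@rho[[j]]), c(p, L)))
        msgs <- c(msgs, sprintf("rho[[%d]] must be p x L_j", j))
      else if (p > 0 && any(object@rho[[j]][, 1] != 0))
        msgs <- c(msgs, sprintf("rho[[%d]] reference column must be zero", j))
      if (length(object@theta[[j]]) != L || object@theta[[j]][1] != 0)
        msgs <- c(msgs, sprintf("theta[[%d]] must have length L_j and zero reference", j))
    }
    if (q > 1) {
      for (key in names(object@phi)) {
        idx <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
        B <- object@phi[[key]]
        Lr <- length(object@levels[[idx[1]]]); Lj <- length(object@levels[[idx[2]]])
        if (idx[1] >= idx[2]) msgs <- c(msgs, sprintf("phi key '%s' must have r < j", key))
        if (!identical(dim(B), c(Lr, Lj)))
          msgs <- c(msgs, sprintf("phi[['%s']] must be L_r x L_j", key))
        else if (any(B[1, ] != 0) || any(B[, 1] != 0))
          msgs <- c(msgs, sprintf("phi[['%s']] reference row/column must be zero", key))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EdgeNetwork: collapsed signed weighted conditional-independence network
#'
#' Each surviving parameter block of a fitted model becomes one undirected
#' edge with a scalar signed weight (the single free parameter for
#' continuous-continuous, continuous-binary and binary-binary edges; the
#' signed maximum-magnitude entry for larger blocks) and the L2 norm of the
#' whole block. Exact-zero blocks have no edge.
#'
#' @slot nodes data.frame: \code{name}, \code{kind}, \code{layer}.
#' @slot edges data.frame: \code{source}, \code{target}, \code{weight},
#'   \code{norm}, \code{block} (one of "beta", "rho", "phi").
#' @export
setClass("EdgeNetwork",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("EdgeNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (nrow(e)) {
    if (any(e$source == e$target)) msgs <- c(msgs, "self-edges are not allowed")
    key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
    if (anyDuplicated(key)) msgs <- c(msgs, "at most one edge per node pair")
    if (any(e$weight == 0)) msgs <- c(msgs, "zero-weight edges must be absent")
    if (!all(c(e$source, e$target) %in% object@nodes$name))
      msgs <- c(msgs, "edge endpoint not among nodes")
  }
  if (length(msgs)) msgs else TRUE
})

#' NeighborhoodModel: a node and its directly connected neighbors
#'
#' The first-order neighborhood of a center node: all nodes joined to it by
#' exactly one edge, ordered by decreasing absolute collapsed weight (ties
#' broken by node name), plus the center's own node potentials so the
#' neighborhood can be used as a linear or logistic predictor without
#' refitting.
#'
#' @slot center center node name.
#' @slot centerKind "continuous" or "categorical".
#' @slot neighbors data.frame: \code{node}, \code{weight}, \code{norm},
#'   \code{block}, sorted by decreasing |weight|.
#' @slot intercept list: for a continuous center, \code{alpha} and \code{tau}
#'   (= -beta_ss); for a categorical center, \code{theta}.
#' @export
setClass("NeighborhoodModel",
  representation(center = "character", centerKind = "character",
                 neighbors = "data.frame", intercept = "list")
)

#' MGMFit: result of a penalized pseudo-likelihood fit
#'
#' @slot params fitted \code{\linkS4class{MGMParameters}}.
#' @slot trace data.frame with one row per iteration: \code{iter},
#'   \code{objective} (penalized), \code{step}, \code{restart},
#'   \code{momentum}.
#' @slot lambda penalty weight used.
#' @slot control the fit control list (see \code{\link{fitControl}}).
#' @slot converged logical.
#' @export
setClass("MGMFit",
  representation(params = "MGMParameters", trace = "data.frame",
                 lambda = "numeric", control = "list", converged = "logical")
)

#' GroundTruthModel: a known sparse MGM for simulation benchmarks
#'
#' @slot params true \code{\linkS4class{MGMParameters}}.
#' @slot support symmetric logical adjacency matrix over all variables
#'   (continuous then categorical) marking true edges.
#' @slot recipe list recording the generation settings (p, q, levels,
#'   density, weightRange, seed).
#' @export
setClass("GroundTruthModel",
  representation(params = "MGMParameters", support = "matrix", recipe = "list")
)

#' ScreeningResult: univariate association screen over all variable pairs
#'
#' @slot pairs data.frame with one row per (response, predictor) pair:
#'   \code{response}, \code{predictor}, \code{coefficient}, \code{pvalue},
#'   \code{neglog10p}, \code{flagged} (TRUE where a separated logistic fit
#'   fell back to a ridge-stabilized fit).
#' @slot ranking named list: per response, predictors ordered by decreasing
#'   -log10 p (ties by |coefficient|, then name).
#' @export
setClass("ScreeningResult",
  representation(pairs = "data.frame", ranking = "list")
)

## -- show methods ------------------------------------------------------------

setMethod("show", "MixedDataset", function(object) {
  cat(sprintf("MixedDataset: %d samples, %d continuous + %d categorical variables\n",
              length(object@sampleIds), ncol(object@continuous), ncol(object@categorical)))
  ly <- table(object@specs$layer)
  cat("  layers:", paste(sprintf("%s (%d)", names(ly), ly), collapse = ", "), "\n")
})

setMethod("show", "MGMParameters", function(object) {
  cat(sprintf("MGMParameters: p = %d continuous, q = %d categorical\n",
              length(object@contNames), length(object@catNames)))
  cnt <- parameterCount(object)
  cat(sprintf("  free parameters: %d (of which %d edge parameters)\n",
              cnt["total"], cnt["edge"]))
})

setMethod("show", "EdgeNetwork", function(object) {
  cat(sprintf("EdgeNetwork: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
})

setMethod("show", "MGMFit", function(object) {
  cat(sprintf("MGMFit: lambda = %g, %d iterations, converged = %s\n",
              object@lambda, nrow(object@trace), object@converged))
  show(object@params)
})

setMethod("show", "NeighborhoodModel", function(object) {
  cat(sprintf("NeighborhoodModel: center '%s' (%s), %d neighbors\n",
              object@center, object@centerKind, nrow(object@neighbors)))
  if (nrow(object@neighbors)) print(head(object@neighbors, 10))
})

setMethod("show", "GroundTruthModel", function(object) {
  cat(sprintf("GroundTruthModel: %d true edges over %d variables (density %.3g)\n",
              sum(object@support[upper.tri(object@support)]),
              nrow(object@support), object@recipe$density))
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult: %d responses, %d pairs\n",
              length(object@ranking), nrow(object@pairs)))
})

## -- accessors ---------------------------------------------------------------

#' Accessors for MixedDataset
#'
#' @param x a \code{\linkS4class{MixedDataset}}.
#' @return \code{continuousValues}/\code{categoricalValues}: the value
#'   matrices; \code{variableSpecs}: the metadata data.frame;
#'   \code{sampleIds}: sample identifiers; \code{catLevels}: named list of
#'   level labels; \code{nSamples}: number of rows.
#' @name MixedDataset-accessors
NULL

#' @rdname MixedDataset-accessors
#' @export
continuousValues <- function(x) x@continuous

#' @rdname MixedDataset-accessors
#' @export
categoricalValues <- function(x) x@categorical

#' @rdname MixedDataset-accessors
#' @export
variableSpecs <- function(x) x@specs

#' @rdname MixedDataset-accessors
#' @export
sampleIds <- function(x) x@sampleIds

#' @rdname MixedDataset-accessors
#' @export
catLevels <- function(x) x@levels

#' @rdname MixedDataset-accessors
#' @export
nSamples <- function(x) length(x@sampleIds)

#' Accessors for fits and networks
#'
#' @param x an \code{\linkS4class{MGMFit}} or \code{\linkS4class{EdgeNetwork}}.
#' @return \code{fittedParams}: the \code{MGMParameters} of a fit;
#'   \code{fitTrace}: its iteration trace; \code{networkNodes} /
#'   \code{networkEdges}: node and edge tables.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
fittedParams <- function(x) x@params

#' @rdname fit-accessors
#' @export
fitTrace <- function(x) x@trace

#' @rdname fit-accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname fit-accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname fit-accessors
#' @export
screenPairs <- function(x) x@pairs

#' @rdname fit-accessors
#' @export
screenRanking <- function(x) x@ranking
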