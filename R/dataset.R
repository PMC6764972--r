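#' Construct a MixedDataset from matrices
#'
#' @param continuous numeric matrix (n x p) with column names; may have zero
#'   columns.
#' @param categorical matrix of level labels (character) or level indices
#'   (integer, 1-based) with column names; may have zero columns.
#' @param levels named list of ordered level labels per categorical variable;
#'   the first label is the reference level. Required when \code{categorical}
#'   holds labels; inferred (sorted unique values) otherwise if missing.
#' @param layer named character vector or single string assigning each
#'   variable to a layer (default "other").
#' @param sampleIds sample identifiers (default from rownames, else 1..n).
#' @return a validated \code{\linkS4class{MixedDataset}}.
#' @export
mixedDataset <- function(continuous = NULL, categorical = NULL, levels = NULL,
                         layer = "other", sampleIds = NULL) {
  n <- if (!is.null(continuous)) nrow(continuous) else nrow(categorical)
  if (is.null(n)) stop("at least one of continuous/categorical is required")
  if (is.null(continuous))
    continuous <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.null(categorical))
    categorical <- matrix(integer(0), nrow = n, ncol = 0)
  if (is.null(sampleIds)) {
    sampleIds <- rownames(continuous)
    if (is.null(sampleIds)) sampleIds <- rownames(categorical)
    if (is.null(sampleIds)) sampleIds <- as.character(seq_len(n))
  }
  storage.mode(continuous) <- "double"
  if (is.character(categorical) || is.factor(categorical)) {
    if (is.null(levels))
      levels <- lapply(as.data.frame(categorical, stringsAsFactors = FALSE),
                       function(v) sort(unique(v)))
    lab <- categorical
    categorical <- matrix(0L, n, ncol(lab), dimnames = dimnames(lab))
    for (v in colnames(lab)) {
      idx <- match(lab[, v], levels[[v]])
      if (anyNA(idx) && !anyNA(lab[, v]))
        stop(sprintf("value '%s' of variable '%s' is not a declared level",
                     lab[which(is.na(idx))[1], v], v))
      categorical[, v] <- idx
    }
  }
  storage.mode(categorical) <- "integer"
  if (is.null(levels)) levels <- list()
  levels <- levels[colnames(categorical)]
  nm <- c(colnames(continuous), colnames(categorical))
  if (length(layer) == 1 && is.null(names(layer)))
    layer <- setNames(rep(layer, length(nm)), nm)
  specs <- data.frame(
    name = nm,
    kind = c(rep("continuous", ncol(continuous)),
             rep("categorical", ncol(categorical))),
    layer = unname(layer[nm]),
    transformLog2 = FALSE, center = NA_real_, scale = NA_real_,
    stringsAsFactors = FALSE
  )
  new("MixedDataset", continuous = continuous, categorical = categorical,
      specs = specs, levels = levels, sampleIds = as.character(sampleIds))
}

#' Load a mixed dataset from a data table and a variable-metadata table
#'
#' The data file must have a header row of variable names and a sample-id
#' column (first column, or named \code{sample_id}). The metadata file has one
#' row per variable with columns \code{name}, \code{kind}
#' ("continuous"/"categorical"), \code{levels} (|-separated labels, empty for
#' continuous), \code{layer}, and optionally \code{log2} (0/1). Variable order
#' in the returned object follows the metadata file. Any missing cell, any
#' categorical value outside its declared levels, and any variable present in
#' only one of the two files is rejected with an informative error.
#'
#' @param dataPath path to the CSV/TSV data file.
#' @param metaPath path to the CSV/TSV metadata file.
#' @param sep field separator; inferred from the file extension by default.
#' @return a validated \code{\linkS4class{MixedDataset}}. Variables flagged
#'   \code{log2 = 1} in the metadata have \code{transformLog2 = TRUE} in the
#'   specs (the transform itself is applied by \code{\link{applyTransforms}}).
#' @export
loadMixedDataset <- function(dataPath, metaPath, sep = NULL) {
  readTab <- function(path) {
    s <- sep
    if (is.null(s)) s <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
    read.csv(path, sep = s, check.names = FALSE, stringsAsFactors = FALSE,
             colClasses = NA)
  }
  dat <- readTab(dataPath)
  meta <- readTab(metaPath)
  need <- c("name", "kind", "layer")
  if (!all(need %in% names(meta)))
    stop("metadata file must have columns name, kind, levels, layer")
  idCol <- if ("sample_id" %in% names(dat)) "sample_id" else names(dat)[1]
  ids <- as.character(dat[[idCol]])
  dat <- dat[, setdiff(names(dat), idCol), drop = FALSE]
  extra <- setdiff(names(dat), meta$name)
  miss <- setdiff(meta$name, names(dat))
  if (length(extra)) stop("variable(s) in data but not metadata: ",
                          paste(extra, collapse = ", "))
  if (length(miss)) stop("variable(s) in metadata but not data: ",
                         paste(miss, collapse = ", "))
  dat <- dat[, meta$name, drop = FALSE]
  for (v in meta$name) {
    bad <- which(is.na(dat[[v]]) | (is.character(dat[[v]]) & dat[[v]] == ""))
    if (length(bad))
      stop(sprintf("missing value at sample '%s', variable '%s'", ids[bad[1]], v))
  }
  isCat <- meta$kind == "categorical"
  lv <- list()
  if (any(isCat)) {
    lvRaw <- if ("levels" %in% names(meta)) meta$levels else rep("", nrow(meta))
    for (k in which(isCat)) {
      labs <- strsplit(as.character(lvRaw[k]), "|", fixed = TRUE)[[1]]
      if (length(labs) < 2)
        stop(sprintf("categorical variable '%s' must declare >= 2 levels", meta$name[k]))
      lv[[meta$name[k]]] <- labs
    }
  }
  cont <- as.matrix(dat[, meta$name[!isCat], drop = FALSE])
  if (length(cont) && !is.numeric(cont)) storage.mode(cont) <- "double"
  catLab <- as.matrix(dat[, meta$name[isCat], drop = FALSE])
  storage.mode(catLab) <- "character"
  d <- mixedDataset(continuous = cont, categorical = catLab, levels = lv,
                    layer = setNames(meta$layer, meta$name), sampleIds = ids)
  if ("log2" %in% names(meta))
    d@specs$transformLog2 <- as.logical(as.integer(meta$log2))[
      match(d@specs$name, meta$name)]
  validObject(d)
  d
}

#' Apply log2 and standard-unit transforms
#'
#' Applies \code{log2} to the named continuous variables first, then centers
#' and scales every continuous variable to mean 0 and sample standard
#' deviation 1 (n-1 denominator). The (center, scale) pair of each variable is
#' recorded in its spec so the identical affine map can be applied to
#' held-out data by passing the transformed training dataset as
#' \code{reference} -- held-out statistics are never used.
#'
#' @param d a \code{\linkS4class{MixedDataset}}.
#' @param log2Vars character vector of continuous variables to log2-transform;
#'   defaults to those flagged \code{transformLog2} in the specs.
#' @param standardize logical; scale to standard units after any log2.
#' @param reference optional transformed training \code{MixedDataset} whose
#'   stored (center, scale) and log2 flags are reused verbatim.
#' @return the transformed dataset, with transform parameters recorded.
#' @export
applyTransforms <- function(d, log2Vars = NULL, standardize = TRUE,
                            reference = NULL) {
  sp <- d@specs
  X <- d@continuous
  if (!is.null(reference)) {
    rsp <- reference@specs
    if (!all(colnames(X) %in% rsp$name))
      stop("reference is missing transform parameters for some variables")
    for (v in colnames(X)) {
      k <- match(v, rsp$name)
      if (isTRUE(rsp$transformLog2[k])) {
        if (any(X[, v] <= 0))
          stop(sprintf("non-positive value in log2 variable '%s'", v))
        X[, v] <- log2(X[, v])
      }
      if (!is.na(rsp$center[k]))
        X[, v] <- (X[, v] - rsp$center[k]) / rsp$scale[k]
      sp[sp$name == v, c("transformLog2", "center", "scale")] <-
        rsp[k, c("transformLog2", "center", "scale")]
    }
  } else {
    if (is.null(log2Vars)) log2Vars <- sp$name[sp$transformLog2 & sp$kind == "continuous"]
    if (length(bad <- setdiff(log2Vars, colnames(X))))
      stop("log2 variables not continuous variables of the dataset: ",
           paste(bad, collapse = ", "))
    for (v in log2Vars) {
      if (any(X[, v] <= 0))
        stop(sprintf("non-positive value in log2 variable '%s'", v))
      X[, v] <- log2(X[, v])
      sp$transformLog2[sp$name == v] <- TRUE
    }
    if (standardize && ncol(X)) {
      for (v in colnames(X)) {
        ctr <- mean(X[, v]); scl <- sd(X[, v])
        if (!is.finite(scl) || scl <= 0)
          stop(sprintf("variable '%s' has zero variance; cannot standardize", v))
        X[, v] <- (X[, v] - ctr) / scl
        sp[sp$name == v, c("center", "scale")] <- c(ctr, scl)
      }
    }
  }
  d@continuous <- X
  d@specs <- sp
  validObject(d)
  d
}

#' Invert the recorded affine transform
#'
#' Maps standardized values back to the (possibly log2) scale using the
#' stored (center, scale); used for reporting predictions in original units.
#'
#' @param d a transformed \code{\linkS4class{MixedDataset}}.
#' @return dataset with continuous values de-standardized.
#' @export
invertTransforms <- function(d) {
  sp <- d@specs
  X <- d@continuous
  for (v in colnames(X)) {
    k <- match(v, sp$name)
    if (!is.na(sp$center[k]))
      X[, v] <- X[, v] * sp$scale[k] + sp$center[k]
  }
  d@continuous <- X
  sp$center <- NA_real_; sp$scale <- NA_real_
  d@specs <- sp
  d
}

#' Deterministic train/test split by rows
#'
#' Draws a random disjoint partition of the samples with
#' \code{floor(trainFraction * n)} training rows; with \code{n = 3705} and
#' fraction 2/3 this yields the 2470/1235 split used for cohort-scale work.
#'
#' @param d a \code{\linkS4class{MixedDataset}}.
#' @param trainFraction fraction of samples in the training part (0 < f < 1).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
splitTrainTest <- function(d, trainFraction = 2/3, seed = 1L) {
  n <- nSamples(d)
  if (n < 3) stop("need at least 3 samples to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  nTrain <- floor(trainFraction * n)
  idx <- withSeed(seed, sample.int(n, nTrain))
  list(train = subsetSamples(d, sort(idx)),
       test  = subsetSamples(d, sort(setdiff(seq_len(n), idx))))
}

#' Subset a MixedDataset by sample index
#'
#' @param d a \code{\linkS4class{MixedDataset}}.
#' @param i integer or logical row index.
#' @return the row-subset dataset.
#' @export
subsetSamples <- function(d, i) {
  new("MixedDataset",
      continuous = d@continuous[i, , drop = FALSE],
      categorical = d@categorical[i, , drop = FALSE],
      specs = d@specs, levels = d@levels,
      sampleIds = d@sampleIds[i])
}

#' Count variables by kind
#'
#' @param specs a variable-spec data.frame (or a
#'   \code{\linkS4class{MixedDataset}}).
#' @return named integer vector \code{c(total, continuous, discrete)}.
#' @export
countVariables <- function(specs) {
  if (is(specs, "MixedDataset")) specs <- specs@specs
  c(total = nrow(specs),
    continuous = sum(specs$kind == "continuous"),
    discrete = sum(specs$kind == "categorical"))
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
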