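#' Column scaling for multivariate models
#'
#' @param centering logical, mean-center columns.
#' @param scaling one of `"uv"` (unit variance), `"pareto"`, `"none"`.
#' @return a named list used by the model fitters.
#' @export
scalingSpec <- function(centering = TRUE, scaling = c("uv", "pareto", "none")) {
  scaling <- match.arg(scaling)
  list(centering = centering, scaling = scaling)
}

# Apply (or reuse) column centering/weighting; returns the scaled matrix with
# the means and weights attached.
.scaleMatrix <- function(x, spec, center = NULL, wt = NULL) {
  x <- as.matrix(x)
  if (is.null(center))
    center <- if (spec$centering) colMeans(x) else rep(0, ncol(x))
  if (is.null(wt)) {
    s <- apply(x, 2, sd)
    wt <- switch(spec$scaling,
      uv = ifelse(s > 0, s, 1),
      pareto = ifelse(s > 0, sqrt(s), 1),
      none = rep(1, ncol(x))
    )
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, wt, "/")
  attr(xs, "center") <- center
  attr(xs, "wt") <- wt
  xs
}

# Fix component signs so the largest-|loading| element is positive.
.fixSigns <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of a bucket matrix
#'
#' Thin wrapper over the singular value decomposition of the scaled matrix,
#' with a deterministic sign convention (largest-|loading| element positive)
#' and per-component explained-variance fractions.
#'
#' @param x samples-by-variables matrix or an [NMRBucketMatrix-class].
#' @param n_components number of components (<= min(samples - 1, variables)).
#' @param scaling a [scalingSpec()].
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(x, n_components = 2, scaling = scalingSpec()) {
  if (is(x, "NMRBucketMatrix")) x <- bucketValues(x)
  x <- as.matrix(x)
  if (n_components > min(nrow(x) - 1L, ncol(x)))
    stop("n_components must be <= min(samples - 1, variables)")
  xs <- .scaleMatrix(x, scaling)
  if (all(abs(xs) < 1e-14)) stop("degenerate input: matrix has zero variance")
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  totvar <- sum(pc$sdev^2)
  k <- seq_len(n_components)
  fx <- .fixSigns(pc$x[, k, drop = FALSE], pc$rotation[, k, drop = FALSE])
  new("PCAModel",
    scores = fx$scores, loadings = fx$loadings,
    R2X = pc$sdev[k]^2 / totvar,
    center = attr(xs, "center"), scale = attr(xs, "wt"),
    varnames = colnames(x) %||% as.character(seq_len(ncol(x)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Core O-PLS decomposition on an already-scaled matrix and centered y.
# Returns weights/loadings for orthogonal components plus the final
# predictive component fitted on the deflated matrix.
.oplsCore <- function(xs, yc, n_orth) {
  w <- drop(crossprod(xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-300) stop("degenerate input: y is uncorrelated with every variable")
  w <- w / nw
  p_orth <- w_orth <- matrix(0, ncol(xs), 0)
  t_orth <- matrix(0, nrow(xs), 0)
  xd <- xs
  for (k in seq_len(n_orth)) {
    t <- drop(xd %*% w)
    p <- drop(crossprod(xd, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("n_orth too large: no orthogonal variation left at component ", k)
    wo <- wo / nwo
    to <- drop(xd %*% wo)
    po <- drop(crossprod(xd, to)) / sum(to^2)
    xd <- xd - tcrossprod(to, po)
    w_orth <- cbind(w_orth, wo)
    p_orth <- cbind(p_orth, po)
    t_orth <- cbind(t_orth, to)
  }
  t <- drop(xd %*% w)
  p <- drop(crossprod(xd, t)) / sum(t^2)
  list(w = w, t = t, p = p, w_orth = w_orth, p_orth = p_orth, t_orth = t_orth,
       xd = xd)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis: the
#' predictive weight is the class-covariance direction of the scaled matrix;
#' each orthogonal component removes the part of the X-loading orthogonal to
#' that weight before the final predictive component is fitted on the deflated
#' matrix. Class labels are coded 0/1 and centered.
#'
#' @param x samples-by-variables matrix or [NMRBucketMatrix-class].
#' @param y two-level factor/character vector of class labels.
#' @param n_orth number of orthogonal components (default 1).
#' @param scaling a [scalingSpec()].
#' @return an [OPLSDAModel-class] (Q2 slot is `NA` until
#'   [crossValidateQ2()] is used).
#' @export
fitOPLSDA <- function(x, y, n_orth = 1, scaling = scalingSpec()) {
  if (is(x, "NMRBucketMatrix")) {
    if (missing(y)) y <- groupLabels(x)
    x <- bucketValues(x)
  }
  x <- as.matrix(x)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two classes")
  if (n_orth < 0) stop("n_orth must be >= 0")
  y01 <- as.numeric(yf) - 1
  ym <- mean(y01)
  yc <- y01 - ym
  xs <- .scaleMatrix(x, scaling)
  fit <- .oplsCore(xs, yc, n_orth)
  ssx <- sum(xs^2)
  r2x_pred <- sum(fit$t^2) * sum(fit$p^2) / ssx
  r2x_orth <- if (n_orth > 0)
    colSums(fit$t_orth^2) * colSums(fit$p_orth^2) / ssx else numeric(0)
  cc <- sum(yc * fit$t) / sum(fit$t^2)
  r2y <- 1 - sum((yc - cc * fit$t)^2) / sum(yc^2)
  scores <- matrix(fit$t, ncol = 1, dimnames = list(rownames(x), "tp1"))
  loadings <- matrix(fit$p, ncol = 1,
                     dimnames = list(colnames(x), "pp1"))
  new("OPLSDAModel",
    scores = scores, loadings = loadings,
    R2X = c(pred = r2x_pred, if (n_orth > 0) setNames(r2x_orth,
      paste0("orth", seq_len(n_orth)))),
    center = attr(xs, "center"), scale = attr(xs, "wt"),
    varnames = colnames(x) %||% as.character(seq_len(ncol(x))),
    scoresOrth = if (n_orth > 0) fit$t_orth else matrix(0, nrow(x), 0),
    weights = fit$w, weightsOrth = fit$w_orth, loadingsOrth = fit$p_orth,
    coef = cc, yMean = ym, y = yc, classes = levels(yf),
    R2Y = r2y, Q2 = NA_real_, nOrth = as.integer(n_orth)
  )
}

#' Predict class values for new samples
#'
#' Applies the stored scaling, strips the model's orthogonal components, and
#' projects on the predictive weight.
#'
#' @param object an [OPLSDAModel-class].
#' @param newdata samples-by-variables matrix on the training variables.
#' @return list with `t` (predictive scores) and `y` (predicted class values
#'   on the 0/1 scale).
#' @export
predictOPLSDA <- function(object, newdata) {
  xs <- .scaleMatrix(as.matrix(newdata), list(centering = TRUE, scaling = "uv"),
                     center = object@center, wt = object@scale)
  for (k in seq_len(object@nOrth)) {
    to <- drop(xs %*% object@weightsOrth[, k])
    xs <- xs - tcrossprod(to, object@loadingsOrth[, k])
  }
  t <- drop(xs %*% object@weights)
  list(t = t, y = t * object@coef + object@yMean)
}

#' Cross-validated Q2 for OPLS-DA
#'
#' K-fold cross-validation with folds assigned round-robin after a seeded
#' shuffle; Q2 = 1 - PRESS / SS over held-out class predictions, with SS the
#' total centered sum of squares of the class coding.
#'
#' @param x samples-by-variables matrix or [NMRBucketMatrix-class].
#' @param y two-level class labels.
#' @param n_orth orthogonal components.
#' @param folds number of folds (default 7).
#' @param scaling a [scalingSpec()].
#' @param seed integer seed for the fold shuffle.
#' @return Q2 value; fold assignment in `attr(, "folds")`.
#' @export
crossValidateQ2 <- function(x, y, n_orth = 1, folds = 7,
                            scaling = scalingSpec(), seed = 1) {
  if (is(x, "NMRBucketMatrix")) {
    if (missing(y)) y <- groupLabels(x)
    x <- bucketValues(x)
  }
  x <- as.matrix(x)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly two classes")
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(x)
  y01 <- as.numeric(yf) - 1
  ord <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(folds), n)
  press <- 0
  for (k in sort(unique(fold))) {
    tr <- fold != k
    if (length(unique(y01[tr])) < 2)
      stop("stratification error: fold ", k, " leaves a single class in training")
    m <- fitOPLSDA(x[tr, , drop = FALSE], yf[tr], n_orth = n_orth,
                   scaling = scaling)
    pr <- predictOPLSDA(m, x[!tr, , drop = FALSE])
    yhat <- pr$y
    if (m@classes[1] != levels(yf)[1]) yhat <- 1 - yhat
    press <- press + sum((y01[!tr] - yhat)^2)
  }
  q2 <- 1 - press / sum((y01 - mean(y01))^2)
  attr(q2, "folds") <- fold
  q2
}

#' Critical Pearson |r| for a given sample size
#'
#' The two-tailed critical value of the Pearson correlation coefficient under
#' the null, from the t transform: r* = t* / sqrt(t*^2 + df), df = n - 2. At
#' n = 8 and alpha = 0.05 this is the conventional 0.707 biomarker cutoff.
#'
#' @param n number of samples (>= 3).
#' @param alpha two-tailed significance level.
#' @return critical |r| in (0, 1).
#' @export
criticalR <- function(n, alpha = 0.05) {
  if (n < 3) stop("n must be >= 3")
  df <- n - 2
  tstar <- qt(1 - alpha / 2, df)
  tstar / sqrt(tstar^2 + df)
}

#' Correlation loadings of an OPLS-DA model
#'
#' Per variable: the Pearson correlation r between the predictive score vector
#' and the scaled variable, and the covariance back-scaled to the variable's
#' original units (the height in a coefficient plot). Variables with zero
#' variance get r = 0 with a warning. The selection threshold is the critical
#' |r| for the number of samples.
#'
#' @param model an [OPLSDAModel-class].
#' @param x the matrix the model was fitted on (or [NMRBucketMatrix-class]).
#' @param alpha two-tailed level for the critical |r|.
#' @param n sample size used for the critical-|r| threshold. Defaults to the
#'   number of fitted samples; pass the per-group n to follow the convention
#'   of quoting the threshold at the group size (n = 8 gives 0.707).
#' @return data.frame with columns `variable`, `ppm` (NA when names are not
#'   ppm), `r`, `covariance`, `selected`; threshold and n in attributes.
#' @export
correlationLoadings <- function(model, x, alpha = 0.05, n = NULL) {
  if (is(x, "NMRBucketMatrix")) x <- bucketValues(x)
  x <- as.matrix(x)
  t <- model@scores[, 1]
  if (is.null(n)) n <- length(t)
  xs <- .scaleMatrix(x, list(centering = TRUE, scaling = "uv"),
                     center = model@center, wt = model@scale)
  sds <- apply(x, 2, sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant variable(s): r set to 0")
  r <- rep(0, ncol(x))
  r[!const] <- drop(cor(t, xs[, !const, drop = FALSE]))
  covar <- drop(cov(t, sweep(x, 2, model@center, "-")))
  thr <- criticalR(n, alpha)
  vn <- model@varnames
  ppm <- suppressWarnings(as.numeric(vn))
  out <- data.frame(
    variable = vn, ppm = ppm, r = r, covariance = covar,
    selected = abs(r) >= thr, stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  attr(out, "n") <- n
  out
}

#' Lift bucket-level selections to metabolites
#'
#' Buckets with |r| at or above the critical threshold are grouped by the
#' metabolite annotation covering their ppm; a metabolite is called when more
#' than half of its annotated buckets pass. Direction is the sign of the mean
#' covariance over the metabolite's annotated buckets. Selected buckets
#' covered by no annotation are reported as `"unassigned"` rather than
#' dropped.
#'
#' @param loadings output of [correlationLoadings()].
#' @param bucket_map data.frame with columns `metabolite`, `lo`, `hi`
#'   (annotation ppm windows; a metabolite may have several rows).
#' @return data.frame with one row per called metabolite (plus `"unassigned"`
#'   rows for orphan buckets): `metabolite`, `n_buckets`, `n_selected`,
#'   `direction` (`"up"`/`"down"`), `max_abs_r`.
#' @export
selectBiomarkers <- function(loadings, bucket_map) {
  stopifnot(all(c("metabolite", "lo", "hi") %in% names(bucket_map)))
  ppm <- loadings$ppm
  rows <- list()
  covered <- rep(FALSE, nrow(loadings))
  for (m in unique(bucket_map$metabolite)) {
    win <- bucket_map[bucket_map$metabolite == m, , drop = FALSE]
    inm <- rep(FALSE, nrow(loadings))
    for (j in seq_len(nrow(win)))
      inm <- inm | (ppm >= win$lo[j] & ppm <= win$hi[j])
    covered <- covered | inm
    if (!any(inm)) next
    nsel <- sum(loadings$selected[inm])
    if (nsel > sum(inm) / 2) {
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, n_buckets = sum(inm), n_selected = nsel,
        direction = if (mean(loadings$covariance[inm]) >= 0) "up" else "down",
        max_abs_r = max(abs(loadings$r[inm])), stringsAsFactors = FALSE
      )
    }
  }
  orphan <- loadings$selected & !covered
  if (any(orphan)) {
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = "unassigned", n_buckets = sum(orphan),
      n_selected = sum(orphan),
      direction = if (mean(loadings$covariance[orphan]) >= 0) "up" else "down",
      max_abs_r = max(abs(loadings$r[orphan])), stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    metabolite = character(0), n_buckets = integer(0), n_selected = integer(0),
    direction = character(0), max_abs_r = numeric(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
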