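#' Principal-component latent factor with varimax rotation
#'
#' Derives a latent factor (e.g. future orientation from CFC, ZTPI-future
#' and PFE scores, or dispositional negativity from BDI, STAI and ATQ-NA)
#' by SVD-based principal component analysis of the standardized
#' indicators, with varimax rotation when more than one component is
#' retained (rotation of a single component is the identity). Indicators
#' are standardized to mean 0, SD 1 before decomposition, so mixed scales
#' (a 12-60 sum, a 1-5 mean, a 0-1 ratio) contribute equally. Loadings are
#' reported as indicator-component correlations; each component's variance
#' proportion is its sum of squared loadings over the number of
#' indicators. The first component is sign-oriented so the anchor
#' indicator (by default the first column) loads positively.
#'
#' @param scores Data frame or matrix, participants x indicators, complete
#'   (apply exclusions first).
#' @param n_components Number of components to retain (default 1).
#' @param anchor Column name or index whose loading on each component is
#'   oriented positive (default 1).
#' @return A `pca_factor` object with elements `loadings`, `var_prop`,
#'   `scores` (fitting-sample factor scores, mean 0, SD 1), `center`,
#'   `scale`, `weights`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(50); m <- cbind(a = x + rnorm(50), b = x + rnorm(50))
#' fit_pca_factor(m)$var_prop
fit_pca_factor <- function(scores, n_components = 1, anchor = 1) {
  X <- as.matrix(scores)
  if (is.null(colnames(X))) colnames(X) <- paste0("ind", seq_len(ncol(X)))
  if (nrow(X) < 3) abort("Need at least 3 participants.")
  if (anyNA(X)) abort("Indicators must be complete; apply exclusions first.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant indicator(s): ",
                 paste(colnames(X)[sds == 0], collapse = ", "), "."))
  }
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  sv <- svd(Z)
  p <- ncol(X)
  if (n_components < 1 || n_components > p) {
    abort("`n_components` must lie between 1 and the number of indicators.")
  }
  comp_sd <- sv$d / sqrt(nrow(X) - 1)
  A <- sv$v[, seq_len(n_components), drop = FALSE] %*%
    diag(comp_sd[seq_len(n_components)], n_components)
  if (n_components > 1) {
    vm <- varimax(A)
    A <- A %*% vm$rotmat
  }
  anchor_i <- if (is.character(anchor)) match(anchor, colnames(X)) else anchor
  flip <- ifelse(A[anchor_i, ] < 0, -1, 1)
  A <- sweep(A, 2, flip, `*`)
  dimnames(A) <- list(colnames(X), paste0("PC", seq_len(n_components)))
  # unit-variance scores by projecting standardized data on the rotated axes
  raw <- Z %*% A
  score_sd <- apply(raw, 2, sd)
  structure(
    list(loadings = A,
         var_prop = colSums(A^2) / p,
         scores = sweep(raw, 2, score_sd, `/`),
         center = ctr, scale = sds,
         weights = sweep(A, 2, score_sd, `/`),
         anchor = colnames(X)[anchor_i],
         n_components = n_components),
    class = "pca_factor")
}

#' @export
print.pca_factor <- function(x, ...) {
  cat("<pca_factor> ", x$n_components, " component(s) over ",
      nrow(x$loadings), " indicators\n", sep = "")
  print(round(x$loadings, 3))
  cat("variance proportion:", round(x$var_prop, 3), "\n")
  invisible(x)
}

#' Factor scores for (new) participants
#'
#' Projects standardized indicator values onto the fitted (rotated) first
#' components, using the fitting sample's centering, scaling and score
#' variance, so a participant at the fitting-sample indicator means scores
#' 0 and the fitting sample has SD 1.
#'
#' @param model A [fit_pca_factor()] result.
#' @param scores Data frame or matrix with the same indicator columns as
#'   the fitted model.
#' @return Matrix of factor scores (participants x components).
#' @export
factor_scores <- function(model, scores) {
  stopifnot(inherits(model, "pca_factor"))
  X <- as.matrix(scores)
  if (is.null(colnames(X))) colnames(X) <- rownames(model$loadings)
  if (!all(rownames(model$loadings) %in% colnames(X))) {
    abort("`scores` must contain the fitted model's indicator columns.")
  }
  X <- X[, rownames(model$loadings), drop = FALSE]
  Z <- scale(X, center = model$center, scale = model$scale)
  Z %*% model$weights
}

#' @describeIn fit_pca_factor Loadings and variance proportions as a long
#'   tibble.
#' @param x A `pca_factor`.
#' @param ... Unused.
#' @method tidy pca_factor
#' @export
tidy.pca_factor <- function(x, ...) {
  tibble::tibble(
    indicator = rep(rownames(x$loadings), x$n_components),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings),
    var_prop = rep(x$var_prop, each = nrow(x$loadings))
  )
}

#' @describeIn fit_pca_factor One-row summary (variance explained by the
#'   retained components).
#' @method glance pca_factor
#' @export
glance.pca_factor <- function(x, ...) {
  tibble::tibble(n_indicators = nrow(x$loadings),
                 n_components = x$n_components,
                 var_prop_total = sum(x$var_prop))
}
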