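#' Principal components of a reference genotype panel
#'
#' Mean-imputes missing dosages per locus, centers columns (optionally
#' scales by per-locus standard deviation) and eigendecomposes the sample
#' covariance. The sign of each component is fixed so that its largest-
#' magnitude loading is positive, making scores reproducible. Query samples
#' are later projected onto these axes with [project_queries()] without
#' altering them.
#'
#' @param panel A `genotype_matrix` of reference samples.
#' @param n_components Number of components to retain
#'   (<= `min(n_ref - 1, L)`).
#' @param scale Scale loci to unit variance before decomposition? Default
#'   `FALSE`: dosages already share a common 0-2 scale.
#' @return An object of class `pca_model`: list with `locus_means` (and
#'   `locus_sds` when scaling), `loadings` (L x C, orthonormal columns),
#'   `reference_scores` (n_ref x C), `explained_variance` (eigenvalues) and
#'   `marker_ids`.
#' @export
fit_reference_pca <- function(panel, n_components = 2, scale = FALSE) {
  X <- if (inherits(panel, "genotype_matrix")) panel$dosage else
    as.matrix(panel)
  n <- nrow(X); L <- ncol(X)
  if (n_components > min(n - 1, L))
    stop("n_components must be <= min(n_ref - 1, L)")
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0                      # all-missing locus: impute 0
  miss <- which(is.na(X))
  if (length(miss)) X[miss] <- mu[(miss - 1) %/% n + 1]
  Xc <- sweep(X, 2, mu)
  sds <- NULL
  if (scale) {
    sds <- apply(Xc, 2, stats::sd)
    sds[sds == 0] <- 1
    Xc <- sweep(Xc, 2, sds, "/")
  }
  if (all(abs(Xc) < 1e-12)) stop("panel has zero variance")
  sv <- svd(Xc, nu = 0, nv = n_components)
  ev <- (sv$d^2) / (n - 1)
  loadings <- sv$v
  # sign convention: largest-magnitude loading positive per component
  for (c in seq_len(n_components)) {
    i <- which.max(abs(loadings[, c]))
    if (loadings[i, c] < 0) loadings[, c] <- -loadings[, c]
  }
  scores <- Xc %*% loadings
  ids <- if (inherits(panel, "genotype_matrix")) panel$markers$marker_id else
    colnames(X)
  rownames(scores) <- if (inherits(panel, "genotype_matrix"))
    panel$samples$sample_id else rownames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(locus_means = mu, locus_sds = sds, loadings = loadings,
                 reference_scores = scores,
                 explained_variance = ev[seq_len(n_components)],
                 total_variance = sum(ev), marker_ids = ids, scale = scale),
            class = "pca_model")
}

#' Project query genotypes onto reference-defined principal components
#'
#' Missing query dosages are imputed with the model's per-locus means (never
#' the queries' own means), columns are centered by the model means (and
#' scaled by the model SDs when the model was fit with scaling), and the
#' result is multiplied by the reference loadings. Queries never alter the
#' axes: projecting a reference sample reproduces its stored score.
#'
#' @param model A `pca_model` from [fit_reference_pca()].
#' @param queries A `genotype_matrix` (markers matched to the model by id)
#'   or a bare dosage matrix already in model locus order.
#' @return Scores matrix (queries x components).
#' @export
project_queries <- function(model, queries) {
  if (inherits(queries, "genotype_matrix")) {
    j <- match(model$marker_ids, queries$markers$marker_id)
    if (anyNA(j)) stop("query markers do not cover the model's loci")
    X <- queries$dosage[, j, drop = FALSE]
    rn <- queries$samples$sample_id
  } else {
    X <- as.matrix(queries)
    if (ncol(X) != length(model$locus_means))
      stop("query markers do not match the model's loci")
    rn <- rownames(X)
  }
  n <- nrow(X)
  miss <- which(is.na(X))
  if (length(miss)) X[miss] <- model$locus_means[(miss - 1) %/% n + 1]
  Xc <- sweep(X, 2, model$locus_means)
  if (!is.null(model$locus_sds)) Xc <- sweep(Xc, 2, model$locus_sds, "/")
  scores <- Xc %*% model$loadings
  rownames(scores) <- rn
  scores
}

#' @export
print.pca_model <- function(x, ...) {
  pct <- 100 * x$explained_variance / x$total_variance
  cat("<pca_model> ", nrow(x$reference_scores), " reference samples, ",
      length(x$locus_means), " loci, ", ncol(x$loadings), " components\n",
      "  variance explained: ",
      paste0(colnames(x$loadings), "=", sprintf("%.1f%%", pct),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  project_queries(object, newdata)
}

#' Two-panel scatter of reference and projected query scores
#'
#' Draws the reference samples as triangles and projected queries as
#' circles on the first two components, colored by group, to the active
#' graphics device (or a PNG/SVG file when `file` is given).
#'
#' @param x A `pca_model`.
#' @param queries Optional query `genotype_matrix` (or scores matrix from
#'   [project_queries()]).
#' @param ref_groups Optional group labels for the reference samples.
#' @param query_groups Optional group labels for the queries.
#' @param file Optional output path ending in `.png` or `.svg`.
#' @param ... Passed to [graphics::plot()].
#' @return The query scores, invisibly.
#' @export
plot.pca_model <- function(x, queries = NULL, ref_groups = NULL,
                           query_groups = NULL, file = NULL, ...) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file)
    else grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  rs <- x$reference_scores
  qs <- NULL
  if (!is.null(queries)) {
    qs <- if (is.matrix(queries)) queries else project_queries(x, queries)
  }
  allx <- rbind(rs[, 1:2, drop = FALSE],
                if (!is.null(qs)) qs[, 1:2, drop = FALSE])
  rg <- factor(if (is.null(ref_groups)) rep("reference", nrow(rs)) else
    ref_groups)
  pal <- grDevices::hcl.colors(max(3, nlevels(rg)), "Dark 3")
  graphics::plot(allx[, 1], allx[, 2], type = "n",
                 xlab = colnames(rs)[1], ylab = colnames(rs)[2], ...)
  graphics::points(rs[, 1], rs[, 2], pch = 17, col = pal[as.integer(rg)])
  if (!is.null(qs)) {
    qg <- factor(if (is.null(query_groups)) rep("query", nrow(qs)) else
      query_groups)
    qpal <- grDevices::hcl.colors(max(3, nlevels(qg)), "Set 2")
    graphics::points(qs[, 1], qs[, 2], pch = 21,
                     bg = qpal[as.integer(qg)])
  }
  invisible(qs)
}
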