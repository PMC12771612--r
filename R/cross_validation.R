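#' Masked-genotype cross-validation error for an admixture model
#'
#' Partitions the non-missing genotype entries into `folds` folds; each fold
#' is masked in turn, the model refit on the remaining entries, and the
#' masked genotypes scored by their binomial deviance against the predicted
#' allele-B frequency `p_il = sum_k q_ik f_kl`. Loci left with no
#' observations by the masking are skipped in that fold (and counted in the
#' result's `n_skipped_loci` attribute). Returns the mean deviance per
#' masked genotype, averaged over folds.
#'
#' @param g A `genotype_matrix` (or dosage matrix).
#' @param K Number of clusters.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed fixing both the fold assignment and the EM
#'   starts; identical input and seed give identical error.
#' @param n_restarts,tol,max_iter Passed to [unsupervised_fit()].
#' @return Mean held-out binomial deviance (scalar), with attributes
#'   `per_fold` and `n_skipped_loci`.
#' @export
cross_validation_error <- function(g, K, folds = 5, seed = 1L,
                                   n_restarts = 1, tol = 1e-6,
                                   max_iter = 2000) {
  if (folds < 2) stop("folds must be >= 2")
  G <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  obs <- which(!is.na(G))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs)))
  fold_err <- numeric(folds)
  skipped <- 0L
  for (f in seq_len(folds)) {
    Gtrain <- G
    masked <- obs[fold_of == f]
    Gtrain[masked] <- NA
    keep <- colSums(!is.na(Gtrain)) > 0
    skipped <- skipped + sum(!keep)
    fit <- unsupervised_fit(Gtrain[, keep, drop = FALSE], K,
                            seed = seed + f, tol = tol,
                            max_iter = max_iter, n_restarts = n_restarts)
    P <- matrix(NA_real_, nrow(G), ncol(G))
    P[, keep] <- fit$Q %*% fit$F
    gm <- G[masked]; pm <- P[masked]
    ok <- !is.na(pm)
    gm <- gm[ok]; pm <- pm[ok]
    # binomial deviance, saturated model as reference; 0*log(0) := 0
    t1 <- ifelse(gm > 0, gm * log(gm / (2 * pm)), 0)
    t2 <- ifelse(gm < 2, (2 - gm) * log((2 - gm) / (2 - 2 * pm)), 0)
    fold_err[f] <- mean(2 * (t1 + t2))
  }
  out <- mean(fold_err)
  attr(out, "per_fold") <- fold_err
  attr(out, "n_skipped_loci") <- skipped
  out
}

#' Consolidate reference groups into genetic clusters
#'
#' Runs an unsupervised admixture fit over a range of candidate cluster
#' numbers `K`, scores each by masked-genotype cross-validation, computes
#' each labelled reference group's mean membership vector, and assigns every
#' group to its argmax cluster. The choice of `K` is ultimately the
#' analyst's; when `k_select` is not supplied the CV-minimizing `K` is used
#' as a default, and the full CV curve is always returned so the choice can
#' be revisited.
#'
#' @param panel A `genotype_matrix` or [reference_panel()] whose samples
#'   carry `group_label`s.
#' @param k_range Integer vector of candidate `K` values (each between 1 and
#'   the number of groups).
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @param k_select Optional user-selected `K` (must lie in `k_range`).
#' @param n_restarts Restarts per unsupervised fit.
#' @return An object of class `cluster_assignment`: list with `assignment`
#'   (named vector group -> cluster id at the selected `K`),
#'   `mean_membership` (groups x K matrix), `chosen_k`, and `cv_curve`
#'   (data frame `K`, `cv_error`, `converged`).
#' @export
consolidate_reference_groups <- function(panel, k_range, folds = 5,
                                         seed = 1L, k_select = NULL,
                                         n_restarts = 1) {
  groups <- panel$samples$group_label
  if (all(is.na(groups))) stop("panel samples carry no group labels")
  n_groups <- length(unique(groups))
  if (any(k_range < 1) || any(k_range > n_groups))
    stop("k_range must lie within [1, number of groups]")
  curve <- data.frame(K = k_range, cv_error = NA_real_, converged = NA)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    fit <- tryCatch(
      unsupervised_fit(panel, K, seed = seed, n_restarts = n_restarts),
      error = function(e) e)
    if (inherits(fit, "error")) {
      curve$converged[i] <- FALSE           # recorded, not fatal
      next
    }
    fits[[i]] <- fit
    curve$converged[i] <- fit$converged
    curve$cv_error[i] <- as.numeric(
      cross_validation_error(panel, K, folds = folds, seed = seed,
                             n_restarts = n_restarts))
  }
  if (is.null(k_select)) {
    ok <- which(!is.na(curve$cv_error))
    k_select <- curve$K[ok[which.min(curve$cv_error[ok])]]
  }
  if (!k_select %in% k_range) stop("k_select must be one of k_range")
  fit <- fits[[match(k_select, k_range)]]
  mm <- rowsum(fit$Q, groups)
  mm <- mm / as.vector(table(factor(groups, levels = rownames(mm))))
  assignment <- max.col(mm, ties.method = "first")
  names(assignment) <- rownames(mm)
  structure(list(assignment = assignment, mean_membership = mm,
                 chosen_k = k_select, cv_curve = curve),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$assignment), " groups -> K = ",
      x$chosen_k, " clusters\n", sep = "")
  print(x$cv_curve, row.names = FALSE)
  invisible(x)
}

#' Write a cross-validation curve as CSV
#'
#' @param x A `cluster_assignment` (or its `cv_curve` data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cv_curve <- function(x, path) {
  curve <- if (inherits(x, "cluster_assignment")) x$cv_curve else x
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
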