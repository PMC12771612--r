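FREQ_EPS <- 1e-6

## Shared EM kernel for the admixture model.
##
## G: n x L dosage matrix (NA = missing); Q: n x K ancestry rows (simplex);
## F: K x L cluster allele-B frequencies. Rows listed in `fixed_q_rows`
## keep their Q fixed (supervised reference samples). Each iteration does a
## single E-step and a joint M-step over the free Q rows and (optionally) F,
## so the log-likelihood is non-decreasing.
admixture_em <- function(G, K, F_init, Q_init, fixed_q_rows = integer(0),
                         update_F = TRUE, tol = 1e-6, max_iter = 2000,
                         eps = FREQ_EPS, keep_trace = FALSE) {
  G <- as.matrix(G)
  n <- nrow(G); L <- ncol(G)
  M <- !is.na(G)
  if (!any(M)) stop("non-finite likelihood: all genotypes missing")
  Gz <- G; Gz[!M] <- 0
  G2 <- 2 - G; G2[!M] <- 0
  lobs <- rowSums(M)
  if (any(lobs == 0)) stop("non-finite likelihood: a sample has no observed loci")
  const <- log(2) * sum(Gz == 1)          # binomial coefficients, observed hets
  Q <- Q_init; F <- pmin(pmax(F_init, eps), 1 - eps)
  free <- setdiff(seq_len(n), fixed_q_rows)

  ll_of <- function(Q, F) {
    P <- Q %*% F
    sum(Gz * log(P)) + sum(G2 * log1p(-P)) + const
  }

  em_step <- function(Q, F) {
    P <- Q %*% F
    W1 <- Gz / P
    W2 <- G2 / (1 - P)
    if (length(free)) {
      Qnum <- Q[free, , drop = FALSE] *
        (W1[free, , drop = FALSE] %*% t(F) +
         W2[free, , drop = FALSE] %*% t(1 - F))
      Q[free, ] <- Qnum / rowSums(Qnum)
    }
    if (update_F) {
      Nb <- F * crossprod(Q, W1)          # expected allele-B count per (k, l)
      Na <- (1 - F) * crossprod(Q, W2)    # expected allele-A count
      D <- Nb + Na
      F <- ifelse(D > 0, Nb / D, F)
      F <- pmin(pmax(F, eps), 1 - eps)
    }
    list(Q = Q, F = F)
  }

  ll <- ll_of(Q, F)
  trace <- if (keep_trace) ll else NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # squared-extrapolation (SQUAREM) acceleration of the EM map, with a
    # likelihood safeguard so each accepted cycle is non-decreasing
    p1 <- em_step(Q, F)
    p2 <- em_step(p1$Q, p1$F)
    rQ <- p1$Q - Q; vQ <- p2$Q - 2 * p1$Q + Q
    rF <- p1$F - F; vF <- p2$F - 2 * p1$F + F
    r2 <- sum(rQ^2) + if (update_F) sum(rF^2) else 0
    v2 <- sum(vQ^2) + if (update_F) sum(vF^2) else 0
    accepted <- FALSE
    if (v2 > 0 && r2 > 0) {
      alpha <- -sqrt(r2 / v2)
      Qx <- Q - 2 * alpha * rQ + alpha^2 * vQ
      Qx[Qx < 0] <- 0
      if (length(free))
        Qx[free, ] <- Qx[free, , drop = FALSE] /
          rowSums(Qx[free, , drop = FALSE])
      Fx <- if (update_F)
        pmin(pmax(F - 2 * alpha * rF + alpha^2 * vF, eps), 1 - eps) else F
      if (all(is.finite(Qx)) ) {
        llx <- ll_of(Qx, Fx)
        ll2 <- ll_of(p2$Q, p2$F)
        if (is.finite(llx) && llx >= ll2) {
          Q <- Qx; F <- Fx; ll_new <- llx; accepted <- TRUE
        }
      }
    }
    if (!accepted) {
      Q <- p2$Q; F <- p2$F
      ll_new <- ll_of(Q, F)
    }
    if (keep_trace) trace <- c(trace, ll_new)
    if (is.finite(ll_new) && ll_new - ll < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(Q = Q, F = F, loglik = ll, iterations = iter, converged = converged,
       trace = trace)
}

#' Admixture model log-likelihood
#'
#' Exact log-likelihood of dosage data under the admixture model: genotype
#' `g_il ~ Binomial(2, p_il)` with `p_il = sum_k q_ik f_kl`. Includes the
#' binomial coefficient term; missing entries contribute 0.
#'
#' @param Q Ancestry proportions: a simplex vector (one sample) or an
#'   `n x K` matrix.
#' @param F `K x L` matrix of cluster allele-B frequencies, entries strictly
#'   inside (0, 1).
#' @param genotypes Dosage vector (one sample) or `n x L` matrix, entries
#'   0/1/2/NA.
#' @return The log-likelihood (a scalar).
#' @examples
#' log_likelihood(1, matrix(0.5), 1)  # log(2 * 0.5 * 0.5)
#' @export
log_likelihood <- function(Q, F, genotypes) {
  F <- as.matrix(F)
  if (any(F <= 0 | F >= 1)) stop("frequencies must lie strictly in (0, 1)")
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  G <- as.matrix(genotypes)
  M <- !is.na(G)
  if (!any(M)) return(0)
  Gz <- G; Gz[!M] <- 0
  G2 <- 2 - G; G2[!M] <- 0
  P <- Q %*% F
  sum(Gz * log(P)) + sum(G2 * log1p(-P)) + log(2) * sum(Gz == 1)
}

#' Estimate per-cluster allele frequencies from a reference panel
#'
#' Frequency of allele B in cluster `k` at locus `l` is the smoothed count
#' `(b_kl + pseudocount) / (2 n_kl + 2 pseudocount)` where `b_kl` is the
#' observed allele-B count and `n_kl` the number of non-missing genotypes;
#' the result is clamped to `[1e-6, 1 - 1e-6]`. Loci with no observations in
#' a cluster fall back to the prior mean 0.5 and are flagged.
#'
#' @param panel A [reference_panel()].
#' @param pseudocount Non-negative smoothing constant (default 0.5,
#'   Jeffreys-style).
#' @return An object of class `allele_freq_model`: list with `cluster_ids`,
#'   `frequencies` (K x L), `counts` (K x L non-missing genotype counts) and
#'   `low_count` (logical K x L, TRUE where a cluster had no data).
#' @export
estimate_cluster_frequencies <- function(panel, pseudocount = 0.5) {
  if (!inherits(panel, "reference_panel")) stop("panel must be a reference_panel")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  cl <- panel$cluster
  if (any(table(cl) < 1)) stop("every cluster needs at least one member")
  d <- panel$dosage
  K <- nlevels(cl); L <- ncol(d)
  freqs <- counts <- matrix(0, K, L,
                            dimnames = list(levels(cl), panel$markers$marker_id))
  for (k in seq_len(K)) {
    rows <- which(cl == levels(cl)[k])
    dk <- d[rows, , drop = FALSE]
    nobs <- colSums(!is.na(dk))
    b <- colSums(dk, na.rm = TRUE)
    freqs[k, ] <- (b + pseudocount) / (2 * nobs + 2 * pseudocount)
    counts[k, ] <- nobs
  }
  if (pseudocount == 0 && any(counts == 0))
    freqs[counts == 0] <- 0.5
  freqs <- pmin(pmax(freqs, FREQ_EPS), 1 - FREQ_EPS)
  structure(list(cluster_ids = levels(cl), frequencies = freqs,
                 counts = counts, low_count = counts == 0,
                 pseudocount = pseudocount),
            class = "allele_freq_model")
}

#' @export
print.allele_freq_model <- function(x, ...) {
  cat("<allele_freq_model> ", length(x$cluster_ids), " clusters x ",
      ncol(x$frequencies), " loci (pseudocount ", x$pseudocount, ")\n",
      sep = "")
  invisible(x)
}

align_query <- function(query, panel) {
  if (inherits(query, "genotype_matrix")) {
    j <- match(panel$markers$marker_id, query$markers$marker_id)
    if (anyNA(j)) stop("query markers are not aligned to the panel")
    id <- query$samples$sample_id[1]
    list(g = as.numeric(query$dosage[1, j]), id = id)
  } else {
    if (length(query) != ncol(panel$dosage))
      stop("query length must match the panel's marker count")
    list(g = as.numeric(query), id = "query")
  }
}

#' Supervised single-query ancestry estimation
#'
#' Maximizes the admixture log-likelihood over the query's ancestry vector
#' `q` against the panel's reference clusters, by EM from a uniform start.
#' In `"joint"` mode (the default) the cluster frequencies `F` are
#' re-estimated together with the query — reference members keep fixed unit
#' ancestry vectors, so a single query perturbs `F` only marginally. In
#' `"fixed_frequencies"` mode `F` comes from
#' [estimate_cluster_frequencies()] and only `q` is updated (the fast path).
#'
#' @param query A dosage vector aligned to the panel's markers, or a
#'   `genotype_matrix` holding one sample (markers matched by id).
#' @param panel A [reference_panel()] with at least two clusters.
#' @param mode `"joint"` or `"fixed_frequencies"`.
#' @param tol Absolute log-likelihood improvement at which EM stops.
#' @param max_iter Maximum EM iterations.
#' @param pseudocount Passed to [estimate_cluster_frequencies()].
#' @param keep_trace Keep the per-iteration log-likelihood trace.
#' @return An object of class `ancestry_fit` with elements `sample_id`,
#'   `q` (named simplex vector), `loglik`, `iterations`, `converged`,
#'   `mode`, and `trace` (when requested). Standard errors are added by
#'   [bootstrap_standard_errors()].
#' @seealso [bootstrap_standard_errors()], [unsupervised_fit()]
#' @export
supervised_query <- function(query, panel,
                             mode = c("joint", "fixed_frequencies"),
                             tol = 1e-6, max_iter = 2000, pseudocount = 0.5,
                             keep_trace = FALSE) {
  mode <- match.arg(mode)
  aligned <- align_query(query, panel)
  g <- aligned$g
  if (all(is.na(g))) stop("non-finite likelihood: all query loci missing")
  afm <- estimate_cluster_frequencies(panel, pseudocount)
  K <- length(afm$cluster_ids)
  if (K < 2) stop("panel must define at least two clusters")
  if (mode == "fixed_frequencies") {
    fit <- admixture_em(matrix(g, 1), K,
                        F_init = afm$frequencies,
                        Q_init = matrix(1 / K, 1, K),
                        update_F = FALSE, tol = tol, max_iter = max_iter,
                        keep_trace = keep_trace)
    q <- fit$Q[1, ]
  } else {
    G <- rbind(panel$dosage, g)
    n_ref <- nrow(panel$dosage)
    Q0 <- matrix(0, n_ref + 1, K)
    Q0[cbind(seq_len(n_ref), as.integer(panel$cluster))] <- 1
    Q0[n_ref + 1, ] <- 1 / K
    fit <- admixture_em(G, K, F_init = afm$frequencies, Q_init = Q0,
                        fixed_q_rows = seq_len(n_ref), update_F = TRUE,
                        tol = tol, max_iter = max_iter,
                        keep_trace = keep_trace)
    q <- fit$Q[n_ref + 1, ]
  }
  names(q) <- afm$cluster_ids
  structure(list(sample_id = aligned$id, q = q, se = NULL,
                 significant = NULL, n_boot = 0L, loglik = fit$loglik,
                 iterations = fit$iterations, converged = fit$converged,
                 mode = mode, trace = fit$trace),
            class = "ancestry_fit")
}

#' Locus-bootstrap standard errors for a supervised ancestry estimate
#'
#' Reruns [supervised_query()] on `n_boot` resamples of the loci (drawn
#' uniformly with replacement) and reports, per cluster, the standard
#' deviation of the resampled ancestry proportions. The reported point
#' estimate is the full-data fit, not the bootstrap mean. A cluster is
#' flagged significant when its ancestry proportion minus
#' `significance_multiplier` standard errors stays above zero — the
#' "standard error does not overlap 0" rule; the multiplier defaults to 1,
#' with 1.96 available for a stricter confidence-interval reading.
#'
#' @inheritParams supervised_query
#' @param n_boot Number of bootstrap replicates (>= 2; 100 is the
#'   conventional choice).
#' @param seed Integer seed for the resampling.
#' @param significance_multiplier SE multiplier in the significance rule.
#' @return An `ancestry_fit` with `se`, `significant`, `n_boot` and
#'   `n_boot_failed` (non-convergent replicates, excluded) filled in.
#' @export
bootstrap_standard_errors <- function(query, panel, n_boot = 100, seed = 1L,
                                      mode = c("joint", "fixed_frequencies"),
                                      significance_multiplier = 1,
                                      tol = 1e-6, max_iter = 2000,
                                      pseudocount = 0.5) {
  mode <- match.arg(mode)
  if (n_boot < 2) stop("n_boot must be >= 2")
  fit <- supervised_query(query, panel, mode = mode, tol = tol,
                          max_iter = max_iter, pseudocount = pseudocount)
  g <- align_query(query, panel)$g
  L <- length(g)
  K <- length(fit$q)
  set.seed(seed)
  qb <- matrix(NA_real_, n_boot, K)
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- panel                                  # resampled loci, same samples
    sub$dosage <- panel$dosage[, idx, drop = FALSE]
    sub$markers <- panel$markers[idx, , drop = FALSE]
    sub$markers$marker_id <- sprintf("b%06d", seq_len(L))
    rfit <- supervised_query(g[idx], sub, mode = mode, tol = tol,
                             max_iter = max_iter, pseudocount = pseudocount)
    qb[b, ] <- rfit$q
    ok[b] <- rfit$converged
  }
  se <- apply(qb[ok, , drop = FALSE], 2, stats::sd)
  names(se) <- names(fit$q)
  fit$se <- se
  fit$significant <- fit$q - significance_multiplier * se > 0
  fit$n_boot <- sum(ok)
  fit$n_boot_failed <- sum(!ok)
  fit$significance_multiplier <- significance_multiplier
  fit
}

#' Unsupervised admixture fit
#'
#' Joint EM estimation of all samples' ancestry proportions `Q` and the
#' cluster frequencies `F` at a chosen number of clusters `K`, from seeded
#' Dirichlet(1) starting proportions; the best of `n_restarts` runs by
#' log-likelihood is returned. The per-iteration log-likelihood is
#' non-decreasing and frequencies are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param g A `genotype_matrix` (or bare dosage matrix).
#' @param K Number of clusters (>= 1, <= number of samples).
#' @param seed Integer seed for the restarts.
#' @param tol,max_iter EM stopping rule.
#' @param n_restarts Independent random restarts.
#' @param keep_trace Keep the best run's log-likelihood trace.
#' @return An object of class `admixture_fit`: list with `Q` (n x K), `F`
#'   (K x L), `loglik`, `iterations`, `converged`, `restart_logliks` and
#'   `trace`.
#' @export
unsupervised_fit <- function(g, K, seed = 1L, tol = 1e-6, max_iter = 2000,
                             n_restarts = 3, keep_trace = FALSE) {
  G <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  n <- nrow(G)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  set.seed(seed)
  best <- NULL; lls <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    Q0 <- matrix(stats::rexp(n * K), n, K)
    Q0 <- Q0 / rowSums(Q0)
    F0 <- matrix(stats::runif(K * ncol(G), 0.05, 0.95), K, ncol(G))
    fit <- admixture_em(G, K, F_init = F0, Q_init = Q0, update_F = TRUE,
                        tol = tol, max_iter = max_iter,
                        keep_trace = keep_trace)
    lls[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  sample_ids <- if (inherits(g, "genotype_matrix")) g$samples$sample_id else
    rownames(G)
  dimnames(best$Q) <- list(sample_ids, paste0("K", seq_len(K)))
  structure(list(Q = best$Q, F = best$F, loglik = best$loglik,
                 iterations = best$iterations, converged = best$converged,
                 restart_logliks = lls, K = K, trace = best$trace),
            class = "admixture_fit")
}

## ---- methods --------------------------------------------------------------

#' @export
print.ancestry_fit <- function(x, digits = 3, ...) {
  cat("<ancestry_fit> sample ", x$sample_id, " (", x$mode, " mode, ",
      x$iterations, " EM iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  top <- sort(x$q, decreasing = TRUE)
  top <- top[top > 0.005]
  cat("  q: ", paste0(names(top), "=", format(round(top, digits)),
                      collapse = ", "), "\n", sep = "")
  if (!is.null(x$se))
    cat("  ", x$n_boot, " bootstrap replicates; significant clusters: ",
        paste(names(x$q)[x$significant], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.ancestry_fit <- function(object, ...) object$q

#' @export
logLik.ancestry_fit <- function(object, ...) object$loglik

#' Summarize a supervised ancestry fit
#'
#' @param object An `ancestry_fit`.
#' @param ... Ignored.
#' @return Data frame with one row per reference cluster: ancestry
#'   proportion `q`, bootstrap `se` and `significant` flag (NA before
#'   bootstrapping).
#' @export
summary.ancestry_fit <- function(object, ...) {
  data.frame(
    cluster = names(object$q),
    q = unname(object$q),
    se = if (is.null(object$se)) NA_real_ else unname(object$se),
    significant = if (is.null(object$significant)) NA else
      unname(object$significant),
    row.names = NULL
  )
}

#' @export
print.admixture_fit <- function(x, digits = 3, ...) {
  cat("<admixture_fit> K = ", x$K, ", ", nrow(x$Q), " samples, loglik ",
      format(x$loglik, digits = 10), if (x$converged) " (converged)\n"
      else " (NOT converged)\n", sep = "")
  cat("  mean Q: ", paste(format(round(colMeans(x$Q), digits)),
                          collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' @export
logLik.admixture_fit <- function(object, ...) object$loglik
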