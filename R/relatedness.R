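#' Method-of-moments pairwise IBD estimation
#'
#' Classical moments estimator of the identity-by-descent state
#' probabilities `(z0, z1, z2)` from identity-by-state sharing counts: for
#' each pair, the observed counts of loci where the two samples share 0, 1
#' or 2 alleles are compared with their expectations under each IBD state
#' given the population allele frequencies, solved sequentially
#' (z0 from IBS0, z1 from IBS1, z2 as the remainder), clamped to `[0, 1]`
#' and renormalized. `pi_hat = z1/2 + z2`.
#'
#' Allele frequencies are clamped to `[0.01, 0.99]` before use; pairs with
#' fewer than `min_joint_loci` jointly observed loci are flagged
#' (`pi_hat = NA`) rather than estimated.
#'
#' @param g A `genotype_matrix`.
#' @param freqs Per-marker allele-B frequency vector (defaults to the
#'   observed frequencies in `g`).
#' @param min_joint_loci Minimum jointly non-missing loci per pair.
#' @param pairs Optional 2-column matrix of sample indices restricting which
#'   pairs are estimated; default all pairs.
#' @return Data frame of class `relatedness_table`, one row per pair:
#'   `id1`, `id2`, `n_joint`, `ibs0`, `ibs1`, `ibs2`, `z0`, `z1`, `z2`,
#'   `pi_hat`.
#' @export
estimate_pairwise_ibd <- function(g, freqs = NULL, min_joint_loci = 100,
                                  pairs = NULL) {
  validate_genotype_matrix(g)
  d <- g$dosage
  n <- nrow(d); L <- ncol(d)
  if (is.null(freqs)) freqs <- colMeans(d, na.rm = TRUE) / 2
  p <- pmin(pmax(as.numeric(freqs), 0.01), 0.99)   # allele-B frequency
  q <- 1 - p
  # expected per-locus IBS-state probabilities conditional on IBD state
  e0_z0 <- 2 * p^2 * q^2
  e1_z0 <- 4 * p^3 * q + 4 * p * q^3
  e2_z0 <- 1 - e0_z0 - e1_z0
  e1_z1 <- 2 * p^2 * q + 2 * p * q^2
  e2_z1 <- 1 - e1_z1
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  }
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    gi <- d[i, ]; gj <- d[j, ]
    obs <- !is.na(gi) & !is.na(gj)
    nj <- sum(obs)
    if (nj < min_joint_loci) {
      out[[r]] <- data.frame(id1 = g$samples$sample_id[i],
                             id2 = g$samples$sample_id[j],
                             n_joint = nj, ibs0 = NA_integer_,
                             ibs1 = NA_integer_, ibs2 = NA_integer_,
                             z0 = NA_real_, z1 = NA_real_, z2 = NA_real_,
                             pi_hat = NA_real_)
      next
    }
    diffs <- abs(gi[obs] - gj[obs])
    ibs0 <- sum(diffs == 2)
    ibs1 <- sum(diffs == 1)
    ibs2 <- nj - ibs0 - ibs1
    E0 <- sum(e0_z0[obs]); E1_0 <- sum(e1_z0[obs]); E2_0 <- sum(e2_z0[obs])
    E1_1 <- sum(e1_z1[obs]); E2_1 <- sum(e2_z1[obs])
    z0 <- ibs0 / E0
    z1 <- (ibs1 - z0 * E1_0) / E1_1
    z2 <- (ibs2 - z0 * E2_0 - z1 * E2_1) / nj
    z <- pmin(pmax(c(z0, z1, z2), 0), 1)
    z <- z / sum(z)
    out[[r]] <- data.frame(id1 = g$samples$sample_id[i],
                           id2 = g$samples$sample_id[j],
                           n_joint = nj, ibs0 = ibs0, ibs1 = ibs1,
                           ibs2 = ibs2, z0 = z[1], z1 = z[2], z2 = z[3],
                           pi_hat = z[2] / 2 + z[3])
  }
  res <- do.call(rbind, out)
  class(res) <- c("relatedness_table", "data.frame")
  res
}

#' Prune duplicate and closely related samples
#'
#' Greedy pruning of pairs at or above the `pi_hat` threshold: while any
#' retained pair remains related, remove the member with more
#' high-relatedness partners (ties broken by higher missingness when
#' available, then by the lexicographically later id). Applying the pruning
#' twice equals applying it once.
#'
#' @param estimates A `relatedness_table` from [estimate_pairwise_ibd()].
#' @param threshold Pairs with `pi_hat >= threshold` trigger a removal
#'   (default 0.70).
#' @param missingness Optional named vector (by sample id) of missing
#'   fractions used in tie-breaking.
#' @return List with `retained` (character vector of kept sample ids) and
#'   `removals` (data frame: removed id and the pair that triggered it).
#' @export
prune_duplicates_and_relatives <- function(estimates, threshold = 0.70,
                                           missingness = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  ids <- unique(c(estimates$id1, estimates$id2))
  flagged <- estimates[!is.na(estimates$pi_hat) &
                         estimates$pi_hat >= threshold, , drop = FALSE]
  active <- rep(TRUE, nrow(flagged))
  removed <- character(0)
  trigger <- list()
  repeat {
    if (!any(active)) break
    live <- flagged[active, , drop = FALSE]
    deg <- table(c(live$id1, live$id2))
    miss_of <- function(id) {
      if (is.null(missingness)) 0 else
        ifelse(is.na(missingness[id]), 0, missingness[id])
    }
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      mm <- vapply(cand, miss_of, 0)
      cand <- cand[mm == max(mm)]
    }
    victim <- sort(cand, decreasing = TRUE)[1]  # lexicographically later id
    hit <- which(active & (flagged$id1 == victim | flagged$id2 == victim))
    trigger[[length(trigger) + 1L]] <- data.frame(
      removed = victim,
      partner = ifelse(flagged$id1[hit[1]] == victim,
                       flagged$id2[hit[1]], flagged$id1[hit[1]]),
      pi_hat = flagged$pi_hat[hit[1]], stringsAsFactors = FALSE)
    removed <- c(removed, victim)
    active[hit] <- FALSE
  }
  list(
    retained = setdiff(ids, removed),
    removals = if (length(trigger)) do.call(rbind, trigger) else
      data.frame(removed = character(), partner = character(),
                 pi_hat = numeric(), stringsAsFactors = FALSE)
  )
}
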