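# Independent oracles used to validate the package's estimators. These are
# deliberately naive, direct transcriptions of the underlying definitions,
# kept structurally separate from the package's optimized implementations.

# Weir & Cockerham (1984) multi-population theta, averaged over loci
# (ratio-of-sums form). geno: dosage matrix; pop: factor of cluster labels.
wc_fst <- function(geno, pop) {
  pop <- factor(pop)
  r <- nlevels(pop)
  num <- den <- 0
  for (l in seq_len(ncol(geno))) {
    g <- geno[, l]
    ok <- !is.na(g)
    ni <- tapply(ok, pop, sum)
    pi <- tapply(g, pop, function(x) mean(x, na.rm = TRUE) / 2)
    hi <- tapply(g == 1, pop, function(x) mean(x, na.rm = TRUE))
    if (any(is.na(pi))) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Exhaustive grid search over the K = 2 simplex (step 0.001) maximizing the
# admixture log-likelihood of a single genotype row against fixed F.
grid_search_q2 <- function(g, F) {
  grid <- seq(0, 1, by = 0.001)
  ok <- !is.na(g)
  g1 <- g[ok]; f1 <- F[1, ok]; f2 <- F[2, ok]
  ll <- vapply(grid, function(q1) {
    p <- q1 * f1 + (1 - q1) * f2
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(g1 * log(p) + (2 - g1) * log(1 - p))
  }, 0)
  grid[which.max(ll)]
}

# Naive per-genotype admixture likelihood, multiplied in log space.
naive_loglik <- function(q, F, g) {
  total <- 0
  for (l in seq_along(g)) {
    if (is.na(g[l])) next
    p <- sum(q * F[, l])
    total <- total + log(choose(2, g[l]) * p^g[l] * (1 - p)^(2 - g[l]))
  }
  total
}

# O(n^2) ROH enumeration oracle: computes feasibility of EVERY interval
# directly from the constraint definitions, takes intervals whose one-marker
# extensions (within the current marker window) are infeasible, keeps the
# longest (ties leftmost), and recurses on the marker ranges left and right
# of the kept segment.
roh_oracle <- function(d, pos, max_het = 1, max_missing = 2,
                       max_gap_bp = 600000, max_kb_per_snp = 80,
                       min_snps = 25, min_kb = 500) {
  n <- length(d)
  het <- !is.na(d) & d == 1
  mis <- is.na(d)
  feasible <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    js <- i:n
    nh <- cumsum(het[js])
    nm <- cumsum(mis[js])
    mg <- if (n > i) cummax(c(0, diff(pos)[i:(n - 1)])) else 0
    span_kb <- (pos[js] - pos[i] + 1) / 1000
    nsnp <- js - i + 1
    feasible[i, js] <- nh <= max_het & nm <= max_missing & mg <= max_gap_bp &
      span_kb / nsnp <= max_kb_per_snp & nsnp >= min_snps & span_kb >= min_kb
  }
  pick <- function(lo, hi) {
    if (hi < lo) return(NULL)
    sub <- which(feasible[lo:hi, lo:hi, drop = FALSE], arr.ind = TRUE)
    if (!nrow(sub)) return(NULL)
    i <- sub[, 1] + lo - 1L; j <- sub[, 2] + lo - 1L
    ok <- i <= j
    i <- i[ok]; j <- j[ok]
    if (!length(i)) return(NULL)
    right_ok <- j == hi | !feasible[cbind(i, pmin(j + 1L, n))]
    left_ok <- i == lo | !feasible[cbind(pmax(i - 1L, 1L), j)]
    cand <- cbind(i, j)[right_ok & left_ok, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    len <- pos[cand[, 2]] - pos[cand[, 1]] + 1
    best <- order(-len, pos[cand[, 1]])[1]
    i <- cand[best, 1]; j <- cand[best, 2]
    rbind(pick(lo, i - 1), c(i, j), pick(j + 1, hi))
  }
  kept <- pick(1, n)
  if (is.null(kept))
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_kb = numeric()))
  kept <- kept[order(kept[, 1]), , drop = FALSE]
  data.frame(
    start_bp = pos[kept[, 1]], end_bp = pos[kept[, 2]],
    n_snps = kept[, 2] - kept[, 1] + 1L,
    n_het = vapply(seq_len(nrow(kept)),
                   function(r) sum(het[kept[r, 1]:kept[r, 2]]), 0L),
    n_missing = vapply(seq_len(nrow(kept)),
                       function(r) sum(mis[kept[r, 1]:kept[r, 2]]), 0L),
    length_kb = (pos[kept[, 2]] - pos[kept[, 1]] + 1) / 1000
  )
}

# Random ROH test chromosome exercising the constraint boundaries:
# spacings straddle the 600 kb gap rule and the 80 kb/SNP density rule,
# genotype mix includes runs of homozygotes with isolated hets/missing.
random_roh_chromosome <- function(n = 200) {
  spacing_pool <- c(20000, 50000, 79000, 80000, 81000, 120000,
                    599999, 600000, 600001, 700000)
  gaps <- sample(spacing_pool, n - 1, replace = TRUE,
                 prob = c(0.25, 0.25, 0.08, 0.08, 0.08, 0.1,
                          0.04, 0.04, 0.04, 0.04))
  pos <- cumsum(c(sample(1e6, 1), gaps))
  state <- sample(c("hom", "het", "mis"), n, replace = TRUE,
                  prob = c(0.82, 0.12, 0.06))
  d <- ifelse(state == "hom", sample(c(0, 2), n, replace = TRUE),
              ifelse(state == "het", 1, NA))
  list(d = d, pos = pos)
}

# Single-sample genotype matrix on an explicit position vector.
roh_matrix <- function(d, pos, chrom = "1") {
  genotype_matrix(matrix(d, 1), marker_table(sprintf("m%05d", seq_along(d)),
                                             chrom, pos, "A", "G"),
                  sample_table("s1"))
}

# Small random genotype matrix helper (polymorphic columns, A<G alleles so
# the text PLINK format round-trips exactly).
random_genotype_matrix <- function(n, L, missing_rate = 0, seed = 1) {
  set.seed(seed)
  repeat {
    d <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
    if (missing_rate > 0) d[runif(n * L) < missing_rate] <- NA
    poly <- apply(d, 2, function(x) {
      x <- x[!is.na(x)]
      length(x) > 0 && any(x > 0) && any(x < 2)
    })
    if (all(poly)) break
  }
  genotype_matrix(d,
                  marker_table(sprintf("m%04d", 1:L), "1",
                               seq(10000, by = 10000, length.out = L),
                               "A", "G"),
                  sample_table(sprintf("s%03d", 1:n)))
}
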