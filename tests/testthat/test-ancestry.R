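toy_panel <- function(freqs, n_per = 20, seed = 1) {
  # reference panel whose members are drawn from the given K x L frequencies
  K <- nrow(freqs); L <- ncol(freqs)
  set.seed(seed)
  cl <- rep(seq_len(K), each = n_per)
  d <- matrix(rbinom(K * n_per * L, 2, freqs[cl, ]), K * n_per, L)
  g <- genotype_matrix(d,
                       marker_table(sprintf("m%05d", 1:L), "1", 1:L * 1000,
                                    "A", "G"),
                       sample_table(sprintf("r%03d", seq_len(K * n_per)),
                                    role = "reference"))
  reference_panel(g, paste0("C", cl))
}

test_that("cluster frequency estimation follows the smoothed-count formula", {
  g <- genotype_matrix(matrix(c(0, 0, 2), 3, 1),
                       marker_table("m1", "1", 100, "A", "G"),
                       sample_table(c("a", "b", "c")))
  p <- reference_panel(g, rep("C1", 3))
  afm <- estimate_cluster_frequencies(p, pseudocount = 0.5)
  expect_equal(unname(afm$frequencies[1, 1]), 2.5 / 7)
  # all-missing locus falls back to the prior mean and is flagged
  g2 <- genotype_matrix(matrix(c(1, NA, 0, NA), 2, 2),
                        marker_table(c("m1", "m2"), "1", c(1, 2), "A", "G"),
                        sample_table(c("a", "b")))
  p2 <- reference_panel(g2, c("C1", "C2"))
  afm2 <- estimate_cluster_frequencies(p2, pseudocount = 0.5)
  expect_equal(unname(afm2$frequencies[2, 1]), 0.5)
  expect_true(afm2$low_count[2, 1])
  expect_error(estimate_cluster_frequencies(p, pseudocount = -1))
})

test_that("estimated frequencies concentrate around the truth", {
  sim <- simulate_reference_panel(3, 0.15, 3000, 200, seed = 21)
  afm <- estimate_cluster_frequencies(sim$panel)
  dev <- abs(afm$frequencies - pmin(pmax(sim$frequencies, 1e-6), 1 - 1e-6))
  expect_gte(mean(dev <= 0.1), 0.99)
})

test_that("log-likelihood matches closed forms and the naive oracle", {
  expect_equal(log_likelihood(1, matrix(0.5), 1), log(0.5))
  expect_equal(log_likelihood(c(0.5, 0.5), matrix(c(0.3, 0.7), 2, 1), NA), 0)
  set.seed(22)
  K <- 3; L <- 40
  F <- matrix(runif(K * L, 0.05, 0.95), K, L)
  q <- c(0.2, 0.5, 0.3)
  g <- sample(c(0, 1, 2, NA), L, replace = TRUE)
  expect_equal(log_likelihood(q, F, g), naive_loglik(q, F, g),
               tolerance = 1e-9)
  expect_error(log_likelihood(q, matrix(0, K, L), g), "strictly")
})

test_that("supervised estimates hit analytic optima in corner cases", {
  eps <- 1e-6
  # fully separated frequencies, query fixed for cluster 1
  F <- rbind(rep(1 - eps, 200), rep(eps, 200))
  pan <- toy_panel(F, n_per = 30, seed = 2)
  fit <- supervised_query(rep(2, 200), pan, mode = "fixed_frequencies")
  expect_gt(fit$q["C1"], 0.99)
  # single heterozygous locus against separated frequencies: q = (1/2, 1/2)
  g1 <- genotype_matrix(matrix(c(2, 0), 2, 1),
                        marker_table("m1", "1", 100, "A", "G"),
                        sample_table(c("a", "b")))
  pan1 <- reference_panel(g1, c("C1", "C2"))
  fit1 <- supervised_query(1, pan1, mode = "fixed_frequencies",
                           pseudocount = 0)
  expect_equal(unname(fit1$q), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("supervised estimates match the exhaustive K = 2 grid oracle", {
  for (s in 1:5) {
    sim <- simulate_reference_panel(2, 0.2, 500, 50, seed = 100 + s)
    qtrue <- c(0.2 + 0.12 * s, 0.8 - 0.12 * s)
    qs <- simulate_admixed_queries(sim$frequencies, list(qtrue), seed = s)
    fit <- supervised_query(qs$genotypes[1, ], sim$panel,
                            mode = "fixed_frequencies", tol = 1e-9)
    afm <- estimate_cluster_frequencies(sim$panel)
    q1_grid <- grid_search_q2(qs$genotypes$dosage[1, ], afm$frequencies)
    expect_lt(abs(fit$q[1] - q1_grid), 0.002)
  }
})

test_that("supervised fit is invariant to locus permutation", {
  sim <- simulate_reference_panel(3, 0.2, 400, 30, seed = 31)
  qs <- simulate_admixed_queries(sim$frequencies, list(c(0.5, 0.3, 0.2)),
                                 seed = 32)
  fit <- supervised_query(qs$genotypes[1, ], sim$panel,
                          mode = "fixed_frequencies", tol = 1e-9)
  set.seed(33)
  perm <- sample(400)
  pp <- sim$panel
  pp$dosage <- pp$dosage[, perm]
  pp$markers <- pp$markers[perm, ]
  fit_p <- supervised_query(qs$genotypes$dosage[1, perm], pp,
                            mode = "fixed_frequencies", tol = 1e-9)
  expect_equal(fit$q, fit_p$q, tolerance = 1e-6)
})

test_that("joint and fixed-frequency modes agree for well-populated panels", {
  # agreement within 0.01 per component requires clusters whose frequency
  # vectors are not nearly collinear; at low divergence the ancestry
  # problem is ill-conditioned and the two F estimates can move q more
  for (s in c(41, 141, 241)) {
    sim <- simulate_reference_panel(3, 0.3, 1000, 50, seed = s)
    qs <- simulate_admixed_queries(sim$frequencies, list(c(0.6, 0.3, 0.1)),
                                   seed = s + 1)
    fj <- supervised_query(qs$genotypes[1, ], sim$panel, mode = "joint")
    ff <- supervised_query(qs$genotypes[1, ], sim$panel,
                           mode = "fixed_frequencies")
    expect_lt(max(abs(fj$q - ff$q)), 0.01)
  }
})

test_that("bootstrap SEs vanish when all loci are identical copies", {
  g_locus <- c(rep(0, 10), rep(2, 10))          # one informative locus
  d <- matrix(rep(g_locus, 50), 20, 50)
  g <- genotype_matrix(d, marker_table(sprintf("m%02d", 1:50), "1",
                                       1:50 * 1000, "A", "G"),
                       sample_table(sprintf("s%02d", 1:20)))
  pan <- reference_panel(g, rep(c("C1", "C2"), each = 10))
  fit <- bootstrap_standard_errors(rep(1, 50), pan, n_boot = 10, seed = 4,
                                   mode = "fixed_frequencies")
  expect_equal(unname(fit$se), c(0, 0))
})

test_that("bootstrap significance flags follow the q - m*se > 0 rule", {
  sim <- simulate_reference_panel(3, 0.2, 1500, 40, seed = 51)
  qs <- simulate_admixed_queries(sim$frequencies, list(c(0.7, 0.3, 0)),
                                 seed = 52)
  fit <- bootstrap_standard_errors(qs$genotypes[1, ], sim$panel,
                                   n_boot = 30, seed = 53,
                                   mode = "fixed_frequencies")
  expect_identical(unname(fit$significant), unname(fit$q - fit$se > 0))
  expect_true(all(fit$se >= 0))
  expect_true(all(fit$q[fit$significant] > 0))
  expect_equal(fit$n_boot + fit$n_boot_failed, 30)
  # the reported point estimate is the full-data fit
  full <- supervised_query(qs$genotypes[1, ], sim$panel,
                           mode = "fixed_frequencies")
  expect_equal(fit$q, full$q)
})

test_that("unsupervised K = 1 reduces to pooled frequencies in closed form", {
  g <- random_genotype_matrix(10, 50, missing_rate = 0.05, seed = 61)
  fit <- unsupervised_fit(g, 1, seed = 1, n_restarts = 1)
  expect_true(all(fit$Q == 1))
  pooled <- colMeans(g$dosage, na.rm = TRUE) / 2
  expect_equal(unname(fit$F[1, ]), pooled, tolerance = 1e-6)
  expect_equal(fit$loglik, log_likelihood(matrix(1, 10, 1),
                                          matrix(pooled, 1), g$dosage),
               tolerance = 1e-6)
})

test_that("unsupervised K = 2 recovers two simulated lineages", {
  sim <- simulate_reference_panel(2, 0.2, 3000, 50, seed = 71)
  fit <- unsupervised_fit(sim$panel, 2, seed = 2, n_restarts = 2)
  lab <- as.integer(sim$panel$cluster)
  expect_gte(abs(cor(fit$Q[, 1], lab)), 0.95)
  expect_error(unsupervised_fit(sim$panel, 1000), "exceeds")
})

test_that("EM log-likelihood is non-decreasing in every mode", {
  sim <- simulate_reference_panel(3, 0.15, 500, 20, seed = 81)
  qs <- simulate_admixed_queries(sim$frequencies, list(c(0.4, 0.4, 0.2)),
                                 seed = 82)
  ff <- supervised_query(qs$genotypes[1, ], sim$panel,
                         mode = "fixed_frequencies", keep_trace = TRUE)
  fj <- supervised_query(qs$genotypes[1, ], sim$panel, mode = "joint",
                         keep_trace = TRUE)
  fu <- unsupervised_fit(sim$panel, 2, seed = 3, n_restarts = 1,
                         keep_trace = TRUE)
  for (tr in list(ff$trace, fj$trace, fu$trace))
    expect_true(all(diff(tr) >= -1e-9))
})

test_that("degenerate queries are rejected", {
  sim <- simulate_reference_panel(2, 0.2, 100, 10, seed = 91)
  expect_error(supervised_query(rep(NA_real_, 100), sim$panel), "missing")
  expect_error(supervised_query(rep(1, 99), sim$panel), "match")
})
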