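test_that("a constructed homozygous run is found as a single long segment", {
  pos <- seq(50000, by = 50000, length.out = 300)  # span ~ 14.95 Mb
  g <- roh_matrix(rep(2, 300), pos)
  segs <- detect_roh_segments(g)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 300)
  expect_equal(segs$n_het, 0)
  expect_gt(segs$length_kb, 10000)
  # with two interior heterozygotes no reported segment contains both
  d2 <- rep(2, 300); d2[c(100, 200)] <- 1
  segs2 <- detect_roh_segments(roh_matrix(d2, pos))
  expect_true(all(segs2$n_het <= 1))
  expect_gt(nrow(segs2), 1)
  for (i in seq_len(nrow(segs2)))
    expect_false(segs2$start_bp[i] <= pos[100] & segs2$end_bp[i] >= pos[200])
})

test_that("gap and density rules break segments where expected", {
  # a > 600 kb gap splits an otherwise perfect run
  pos <- c(seq(50000, by = 50000, length.out = 100),
           seq(50000 * 100 + 700000, by = 50000, length.out = 100))
  segs <- detect_roh_segments(roh_matrix(rep(0, 200), pos),
                              min_snps = 0, min_kb = 0)
  expect_equal(nrow(segs), 2)
  # at exactly 80 kb/SNP the density constraint is satisfied (<=)
  pos80 <- cumsum(rep(80000, 50))
  segs80 <- detect_roh_segments(roh_matrix(rep(2, 50), pos80),
                                min_snps = 0, min_kb = 0)
  expect_equal(nrow(segs80), 1)
  expect_equal(segs80$n_snps, 50)
  # unsorted markers are rejected
  bad <- roh_matrix(rep(0, 3), c(100, 50, 200))
  expect_error(detect_roh_segments(bad), "sorted")
})

test_that("scanner output is identical to the brute-force oracle", {
  set.seed(1234)
  for (case in 1:150) {
    ch <- random_roh_chromosome(60)
    for (params in list(list(min_snps = 0, min_kb = 0),
                        list(min_snps = 5, min_kb = 400))) {
      got <- do.call(detect_roh_segments,
                     c(list(roh_matrix(ch$d, ch$pos)), params))
      want <- do.call(roh_oracle, c(list(ch$d, ch$pos), params))
      expect_equal(got[, names(want)], want, ignore_attr = TRUE)
    }
  }
})

test_that("multi-chromosome scans respect chromosome boundaries", {
  set.seed(9)
  pos <- seq(50000, by = 50000, length.out = 60)
  g <- genotype_matrix(
    matrix(rep(2, 120), 1),
    marker_table(sprintf("m%03d", 1:120), rep(c("1", "2"), each = 60),
                 c(pos, pos), "A", "G"),
    sample_table("s1"))
  segs <- detect_roh_segments(g, min_snps = 0, min_kb = 0)
  expect_equal(nrow(segs), 2)
  expect_setequal(segs$chromosome, c("1", "2"))
})

test_that("fROH arithmetic matches its definition exactly", {
  empty <- detect_roh_segments(roh_matrix(rep(1, 30),
                                          seq(50000, by = 50000,
                                              length.out = 30)))
  prof0 <- summarize_froh(empty, sample_ids = "s1")
  expect_equal(prof0$froh, 0)
  expect_equal(prof0$n_long, 0)
  # one segment of exactly a tenth of the autosome
  seg <- data.frame(sample_id = "s1", chromosome = "1", start_bp = 1,
                    end_bp = 226577500, n_snps = 100, n_het = 0,
                    n_missing = 0, length_kb = 226577.5)
  expect_equal(summarize_froh(seg)$froh, 0.1)
  expect_equal(summarize_froh(seg)$n_long, 1)
})

test_that("a planted segment is recovered end to end", {
  lay <- chromosome_layout("1", 500, 50000)
  pl <- data.frame(chromosome = "1", start_bp = 4e6, end_bp = 16e6)
  ri <- simulate_roh_individual(lay, pl, background_het = 0.3, seed = 17)
  segs <- detect_roh_segments(ri$genotypes)
  long <- segs[segs$length_kb > 10000, ]
  expect_equal(nrow(long), 1)
  expect_lt(long$start_bp, 4e6 + 1e6)
  expect_gt(long$end_bp, 16e6 - 1e6)
  # dense heterozygosity with no planting yields no segment at all
  ri0 <- simulate_roh_individual(chromosome_layout("1", 2000, 50000),
                                 NULL, background_het = 0.5, seed = 18)
  expect_equal(nrow(detect_roh_segments(ri0$genotypes)), 0)
})

test_that("scanning is deterministic across a PLINK round-trip", {
  lay <- chromosome_layout("1", 300, 50000)
  pl <- data.frame(chromosome = "1", start_bp = 2e6, end_bp = 13e6)
  ri <- simulate_roh_individual(lay, pl, background_het = 0.25, seed = 19)
  prefix <- file.path(withr::local_tempdir(), "roh")
  write_genotypes(ri$genotypes, prefix, "plink_binary")
  g2 <- read_genotypes(prefix, "plink_binary")
  expect_identical(detect_roh_segments(ri$genotypes),
                   detect_roh_segments(g2))
})

test_that("group comparison summarizes fROH descriptively", {
  lay <- chromosome_layout("1", 400, 50000)
  pl <- data.frame(chromosome = "1", start_bp = 3e6, end_bp = 15e6)
  planted <- lapply(1:4, function(s)
    simulate_roh_individual(lay, pl, background_het = 0.3, seed = 20 + s))
  clean <- lapply(1:4, function(s)
    simulate_roh_individual(lay, NULL, background_het = 0.4, seed = 30 + s))
  segs <- do.call(rbind, lapply(seq_along(c(planted, clean)), function(i) {
    x <- c(planted, clean)[[i]]
    x$genotypes$samples$sample_id <- paste0("s", i)
    s <- detect_roh_segments(x$genotypes)
    if (nrow(s)) s$sample_id <- paste0("s", i)
    s
  }))
  prof <- summarize_froh(segs, sample_ids = paste0("s", 1:8))
  cmp <- compare_groups(prof, rep(c("planted", "clean"), each = 4))
  expect_gt(cmp$mean_froh[cmp$group == "planted"],
            cmp$mean_froh[cmp$group == "clean"])
  # two identical groups give identical summary rows
  cmp2 <- compare_groups(prof[c(1:4, 1:4), ], rep(c("g1", "g2"), each = 4))
  expect_equal(cmp2$mean_froh[1], cmp2$mean_froh[2])
  expect_equal(cmp2$mean_n_long[1], cmp2$mean_n_long[2])
  # a single-sample group's mean is that sample's froh
  cmp3 <- compare_groups(prof, c("solo", rep("rest", 7)))
  expect_equal(cmp3$mean_froh[cmp3$group == "solo"], prof$froh[1])
  # froh is monotone in planted segment length
  pl_short <- data.frame(chromosome = "1", start_bp = 3e6, end_bp = 8e6)
  short <- simulate_roh_individual(lay, pl_short, background_het = 0.3,
                                   seed = 21)
  fr_short <- summarize_froh(detect_roh_segments(short$genotypes),
                             "roh_sample")$froh
  fr_long <- prof$froh[1]
  expect_gt(fr_long, fr_short)
})
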