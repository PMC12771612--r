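test_that("PLINK binary fileset round-trips dosages and metadata exactly", {
  g <- random_genotype_matrix(10, 100, missing_rate = 0.05, seed = 42)
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_genotypes(g, prefix, "plink_binary")
  g2 <- read_genotypes(prefix, "plink_binary")
  expect_equal(g2$dosage, g$dosage)
  expect_equal(g2$markers, g$markers, ignore_attr = TRUE)
  expect_equal(g2$samples$sample_id, g$samples$sample_id)
})

test_that("PLINK text fileset round-trips dosages and metadata", {
  g <- random_genotype_matrix(10, 100, missing_rate = 0.05, seed = 7)
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_genotypes(g, prefix, "plink_text")
  g2 <- read_genotypes(prefix, "plink_text")
  expect_equal(g2$dosage, g$dosage)
  expect_equal(g2$markers, g$markers, ignore_attr = TRUE)
  # a 3 x 5 matrix with an explicit "0 0" missing call at marker 2
  g3 <- genotype_matrix(
    rbind(c(0, NA, 1, 2, 1), c(1, 1, 0, 0, 2), c(2, 0, 2, 1, 1)),
    marker_table(paste0("mk", 1:5), "2", c(100, 200, 300, 400, 500), "A", "C"),
    sample_table(c("x", "y", "z"))
  )
  write_genotypes(g3, prefix, "plink_text")
  ped <- readLines(paste0(prefix, ".ped"))
  expect_match(ped[1], "^x x 0 0 0 -9 A A 0 0 A C C C A C$")
  g4 <- read_genotypes(prefix, "plink_text")
  expect_identical(g4$dosage[1, 2], NA_real_)
  expect_equal(g4$dosage, g3$dosage)
})

test_that("binary decoder matches a hand-decoded SNP-major fixture", {
  # 4 samples x 6 markers, 2 bits per genotype packed LSB-first per byte:
  # 00 = hom allele_a, 01 = missing, 10 = het, 11 = hom allele_b.
  # One byte per marker (4 samples). Bytes written literally below; the
  # expected dosages are decoded from the bit layout by hand.
  bytes <- as.raw(c(
    0xE4,  # 11 10 01 00 -> samples 1..4 = 00,01,10,11 -> 0, NA, 1, 2
    0x1B,  # 00 01 10 11 -> 2, 1, NA, 0
    0xFF,  # all 11 -> 2, 2, 2, 2
    0x00,  # all 00 -> 0, 0, 0, 0
    0x55,  # all 01 -> NA x4
    0xAA   # all 10 -> 1, 1, 1, 1
  ))
  expected <- cbind(c(0, NA, 1, 2), c(2, 1, NA, 0), c(2, 2, 2, 2),
                    c(0, 0, 0, 0), c(NA, NA, NA, NA), c(1, 1, 1, 1))
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(bytes, con)
  close(con)
  writeLines(paste("1", paste0("snp", 1:6), 0, 1:6 * 1000, "A", "G"),
             paste0(prefix, ".bim"))
  writeLines(paste("f", paste0("ind", 1:4), 0, 0, 0, -9),
             paste0(prefix, ".fam"))
  g <- read_genotypes(prefix, "plink_binary")
  expect_equal(unname(g$dosage), expected)
})

test_that("text and binary outputs of the same matrix read back equal", {
  g <- random_genotype_matrix(9, 60, missing_rate = 0.1, seed = 3)
  dir <- withr::local_tempdir()
  write_genotypes(g, file.path(dir, "t"), "plink_text")
  write_genotypes(g, file.path(dir, "b"), "plink_binary")
  gt <- read_genotypes(file.path(dir, "t"), "plink_text")
  gb <- read_genotypes(file.path(dir, "b"), "plink_binary")
  expect_equal(gt$dosage, gb$dosage)
  expect_equal(gt$markers$allele_b, gb$markers$allele_b)
})

test_that("degenerate and malformed filesets are handled", {
  dir <- withr::local_tempdir()
  allmiss <- genotype_matrix(
    matrix(NA_real_, 3, 4),
    marker_table(paste0("m", 1:4), "1", 1:4 * 100, "A", "G"),
    sample_table(paste0("s", 1:3))
  )
  for (fmt in c("plink_text", "plink_binary")) {
    write_genotypes(allmiss, file.path(dir, fmt), fmt)
    back <- read_genotypes(file.path(dir, fmt), fmt)
    expect_true(all(is.na(back$dosage)))
  }
  # corrupt magic bytes
  bad <- file.path(dir, "bad")
  write_genotypes(random_genotype_matrix(3, 4, seed = 1), bad, "plink_binary")
  raw <- readBin(paste0(bad, ".bed"), "raw", 100)
  raw[1] <- as.raw(0x00)
  writeBin(raw, paste0(bad, ".bed"))
  expect_error(read_genotypes(bad, "plink_binary"), "magic")
  # truncated body -> sample/marker consistency error
  write_genotypes(random_genotype_matrix(5, 8, seed = 2), bad, "plink_binary")
  raw <- readBin(paste0(bad, ".bed"), "raw", 1000)
  writeBin(raw[1:(length(raw) - 2)], paste0(bad, ".bed"))
  expect_error(read_genotypes(bad, "plink_binary"), "consistency")
})

make_panel <- function(ids, chrom, pos, aa, ab, dosage, sample_ids) {
  genotype_matrix(dosage, marker_table(ids, chrom, pos, aa, ab),
                  sample_table(sample_ids))
}

test_that("marker intersection keeps shared ids and reconciles orientation", {
  p1 <- make_panel(c("a", "b", "c"), "1", c(10, 20, 30), "A", "G",
                   rbind(c(0, 1, 2), c(2, 2, 0)), c("s1", "s2"))
  p2 <- make_panel(c("b", "c", "d"), "1", c(20, 30, 40),
                   c("G", "A", "A"), c("A", "G", "G"),
                   rbind(c(2, 1, 0)), "s3")
  m <- merge_on_shared_markers(list(p1, p2))
  expect_equal(m$markers$marker_id, c("b", "c"))
  expect_equal(nrow(m$dosage), 3)
  # marker b has swapped alleles in p2: dosage 2 recoded to 0
  expect_equal(m$dosage[3, ], c(0, 1))
  log <- attr(m, "merge_log")
  expect_true("recoded_swap" %in% log$action)
})

test_that("irreconcilable and ambiguous-conflicting markers are dropped", {
  p1 <- make_panel(c("a", "b", "c"), "1", c(10, 20, 30),
                   c("A", "A", "C"), c("G", "T", "G"),
                   rbind(c(0, 1, 2)), "s1")
  p2 <- make_panel(c("a", "b", "c"), "1", c(10, 20, 30),
                   c("A", "T", "G"), c("C", "A", "C"),
                   rbind(c(0, 1, 2)), "s2")
  # a: A/G vs A/C -> irreconcilable; b: A/T ambiguous, pair swapped ->
  # dropped, not flipped; c: C/G ambiguous, swapped -> dropped
  expect_error(merge_on_shared_markers(list(p1, p2)),
               "empty marker intersection")
  # non-ambiguous strand flip is resolved by complementing: A/G vs T/C
  p3 <- make_panel("a", "1", 10, "T", "C", rbind(c(2)), "s3")
  p1a <- make_panel("a", "1", 10, "A", "G", rbind(c(0)), "s1")
  m <- merge_on_shared_markers(list(p1a, p3))
  expect_equal(unname(m$dosage[, 1]), c(0, 2))
})

test_that("merging errors on duplicate samples and is order-invariant", {
  p1 <- random_genotype_matrix(3, 10, seed = 5)
  p2 <- random_genotype_matrix(2, 10, seed = 6)
  p2$samples$sample_id <- c("t1", "t2")
  expect_error(merge_on_shared_markers(list(p1, p1)), "duplicate sample_id")
  m12 <- merge_on_shared_markers(list(p1, p2))
  m21 <- merge_on_shared_markers(list(p2, p1))
  ids <- m12$samples$sample_id
  reord <- match(ids, m21$samples$sample_id)
  expect_equal(m12$dosage, m21$dosage[reord, ])
})

test_that("allele-flip recoding is an involution", {
  d <- sample(c(0, 1, 2, NA), 50, replace = TRUE)
  expect_equal(2 - (2 - d), d)
})

test_that("call-rate filters remove the right individuals and markers", {
  set.seed(11)
  d <- matrix(sample(0:2, 10 * 100, replace = TRUE), 10, 100)
  d[1, 1:6] <- NA  # 6% missing
  g <- genotype_matrix(d, marker_table(sprintf("m%03d", 1:100), "1",
                                       1:100 * 1000, "A", "G"),
                       sample_table(sprintf("s%02d", 1:10)))
  res <- apply_callrate_filters(g, max_individual_missing = 0.05)
  expect_equal(nrow(res$genotypes$dosage), 9)
  expect_equal(res$report$removed_samples, "s01")
  # fully observed matrix is unchanged under any thresholds
  g0 <- random_genotype_matrix(5, 20, seed = 2)
  res0 <- apply_callrate_filters(g0, 0, 0.99)
  expect_equal(res0$genotypes$dosage, g0$dosage)
})

test_that("filtering matches an exhaustive recount and never raises missingness", {
  set.seed(21)
  d <- matrix(sample(0:2, 40 * 200, replace = TRUE), 40, 200)
  d[runif(length(d)) < 0.02] <- NA
  g <- genotype_matrix(d, marker_table(sprintf("m%03d", 1:200), "1",
                                       1:200 * 1000, "A", "G"),
                       sample_table(sprintf("s%02d", 1:40)))
  res <- apply_callrate_filters(g, 0.05, 0.95, order = "markers_first")
  # independent recount: markers first, then individuals, straight loops
  keep_m <- logical(200)
  for (l in 1:200) keep_m[l] <- mean(!is.na(d[, l])) >= 0.95
  keep_s <- logical(40)
  for (s in 1:40) keep_s[s] <- mean(is.na(d[s, keep_m])) <= 0.05
  expect_equal(res$genotypes$markers$marker_id,
               g$markers$marker_id[keep_m])
  expect_equal(res$genotypes$samples$sample_id,
               g$samples$sample_id[keep_s])
  # every retained sample satisfies the missingness threshold afterwards
  after <- rowMeans(is.na(res$genotypes$dosage))
  expect_true(all(after <= 0.05))
  # the individual filter alone never changes a retained sample's missingness
  res_i <- apply_callrate_filters(g, 0.05, NULL)
  kept <- g$samples$sample_id %in% res_i$genotypes$samples$sample_id
  expect_equal(rowMeans(is.na(res_i$genotypes$dosage)),
               rowMeans(is.na(d))[kept])
})
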