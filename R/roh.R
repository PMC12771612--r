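#' Autosome length constant (kb) used for fROH
#'
#' Total autosomal genetic material of the Sscrofa11.1 genome assembly, in
#' kilobases; the denominator of the genomic inbreeding fraction fROH.
#' @export
AUTOSOME_KB <- 2265775

#' Detect runs of homozygosity
#'
#' Finds, per sample and chromosome, all maximal marker intervals that
#' satisfy every segment constraint: at most `max_het` heterozygous and
#' `max_missing` missing calls, every adjacent-marker gap at most
#' `max_gap_bp`, whole-segment density at most `max_kb_per_snp` kilobases
#' per SNP, and at least `min_snps` markers spanning at least `min_kb`
#' kilobases. Maximal means the interval cannot be extended by one marker
#' left or right without violating a constraint. Overlapping maximal
#' candidates are resolved by keeping the longer segment (ties broken
#' leftmost) and iterating on the remainder; the result is deterministic.
#'
#' Segment endpoints are the positions of the first and last SNP of the run
#' (1-based, inclusive) and `length_kb = (end_bp - start_bp + 1) / 1000`.
#'
#' @param g A `genotype_matrix`; markers must be sorted by chromosome and
#'   position (an error otherwise). All samples are scanned.
#' @param max_het Maximum heterozygous calls per segment (default 1).
#' @param max_missing Maximum missing calls per segment (default 2).
#' @param max_gap_bp Maximum adjacent-marker gap inside a segment (default
#'   600000).
#' @param max_kb_per_snp Maximum segment span per marker, in kb/SNP
#'   (default 80, i.e. a minimum density of 1 SNP per 80 kb).
#' @param min_snps Minimum markers per segment (default 25; set 0 to test
#'   pure density/gap logic).
#' @param min_kb Minimum segment span in kb (default 500; set 0 likewise).
#' @return Data frame with one row per segment: `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_kb`.
#' @export
detect_roh_segments <- function(g, max_het = 1, max_missing = 2,
                                max_gap_bp = 600000, max_kb_per_snp = 80,
                                min_snps = 25, min_kb = 500) {
  validate_genotype_matrix(g)
  mk <- g$markers
  chr_rle <- rle(mk$chromosome)
  if (any(duplicated(chr_rle$values)))
    stop("markers are not sorted: chromosome blocks are not contiguous")
  for (ch in chr_rle$values) {
    pos <- mk$position_bp[mk$chromosome == ch]
    if (is.unsorted(pos, strictly = TRUE))
      stop("markers are not sorted by position on chromosome ", ch)
  }
  out <- list()
  for (s in seq_len(nrow(g$dosage))) {
    sid <- g$samples$sample_id[s]
    d <- g$dosage[s, ]
    for (ch in chr_rle$values) {
      j <- which(mk$chromosome == ch)
      segs <- scan_chromosome(d[j], mk$position_bp[j], max_het, max_missing,
                              max_gap_bp, max_kb_per_snp, min_snps, min_kb)
      if (nrow(segs)) {
        segs$sample_id <- sid
        segs$chromosome <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  cols <- c("sample_id", "chromosome", "start_bp", "end_bp", "n_snps",
            "n_het", "n_missing", "length_kb")
  if (!length(out))
    return(stats::setNames(
      data.frame(character(), character(), integer(), integer(), integer(),
                 integer(), integer(), numeric()), cols))
  res <- do.call(rbind, out)[, cols]
  rownames(res) <- NULL
  res
}

## One chromosome of one sample. Maximal feasible intervals are found by a
## two-pointer pass over the monotone constraints (het, missing, gap) plus a
## vectorized density/size check per start; overlaps are resolved by keeping
## the longest candidate (tie: leftmost) and re-scanning the marker ranges
## left and right of it, recursively.
scan_chromosome <- function(d, pos, max_het, max_missing, max_gap_bp,
                            max_kb_per_snp, min_snps, min_kb) {
  n <- length(d)
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_kb = numeric())
  if (n == 0) return(empty)
  H <- cumsum(c(0L, !is.na(d) & d == 1))     # prefix het counts
  Mi <- cumsum(c(0L, as.integer(is.na(d))))  # prefix missing counts
  gap_break <- if (n > 1) which(diff(pos) > max_gap_bp) else integer(0)

  # reach(i): furthest j satisfying the monotone constraints from start i
  r_het <- findInterval(H[seq_len(n)] + max_het, H[-1])
  r_mis <- findInterval(Mi[seq_len(n)] + max_missing, Mi[-1])
  r_gap <- rep(n, n)
  if (length(gap_break)) {
    nb <- c(gap_break, Inf)
    r_gap <- vapply(seq_len(n), function(i) {
      b <- nb[nb >= i][1]
      as.integer(min(b, n))
    }, 0L)
  }
  reach <- pmin(r_het, r_mis, r_gap)

  dens_ok <- function(i, j)                  # whole-segment density rule
    (pos[j] - pos[i] + 1) / 1000 <= max_kb_per_snp * (j - i + 1)

  # maximal feasible intervals restricted to the marker window [lo, hi]
  candidates_in <- function(lo, hi) {
    cand <- list()
    for (i in lo:hi) {
      r <- min(reach[i], hi)
      if (r < i) next
      js <- i:r
      span_kb <- (pos[js] - pos[i] + 1) / 1000
      feas <- span_kb <= max_kb_per_snp * (js - i + 1) &
        (js - i + 1) >= min_snps & span_kb >= min_kb
      if (!any(feas)) next
      js <- js[feas]
      right_max <- (js == r) | (js < r & !dens_ok(i, pmin(js + 1L, n)))
      js <- js[right_max]
      if (!length(js)) next
      if (i > lo) {
        left_inf <- js > reach[i - 1] | !dens_ok(i - 1, js)
        js <- js[left_inf]
      }
      for (j in js)
        cand[[length(cand) + 1L]] <- c(i, j)
    }
    if (!length(cand)) return(NULL)
    do.call(rbind, cand)
  }

  pick_segments <- function(lo, hi) {
    if (hi < lo) return(NULL)
    cm <- candidates_in(lo, hi)
    if (is.null(cm)) return(NULL)
    len <- pos[cm[, 2]] - pos[cm[, 1]] + 1
    best <- order(-len, pos[cm[, 1]])[1]
    i <- cm[best, 1]; j <- cm[best, 2]
    rbind(pick_segments(lo, i - 1L), c(i, j), pick_segments(j + 1L, hi))
  }

  kept <- pick_segments(1L, n)
  if (is.null(kept)) return(empty)
  kept <- kept[order(kept[, 1]), , drop = FALSE]
  data.frame(
    start_bp = pos[kept[, 1]], end_bp = pos[kept[, 2]],
    n_snps = kept[, 2] - kept[, 1] + 1L,
    n_het = H[kept[, 2] + 1L] - H[kept[, 1]],
    n_missing = Mi[kept[, 2] + 1L] - Mi[kept[, 1]],
    length_kb = (pos[kept[, 2]] - pos[kept[, 1]] + 1) / 1000
  )
}

#' Summarize per-sample fROH and long-segment counts
#'
#' fROH is the fraction of the autosomal genome covered by detected runs of
#' homozygosity: total segment length divided by `autosome_kb`. Long
#' segments are those spanning strictly more than 10 Mb.
#'
#' @param segments Segment table from [detect_roh_segments()].
#' @param sample_ids Sample ids to report (so samples with zero segments
#'   appear with `froh = 0`); defaults to the ids present in `segments`.
#' @param autosome_kb Autosome length denominator in kb (default
#'   [AUTOSOME_KB]).
#' @return Data frame of class `roh_profile`: `sample_id`, `n_segments`,
#'   `total_kb`, `froh`, `n_long`.
#' @export
summarize_froh <- function(segments, sample_ids = NULL,
                           autosome_kb = AUTOSOME_KB) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  prof <- data.frame(sample_id = sample_ids, n_segments = 0L, total_kb = 0,
                     froh = 0, n_long = 0L, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    agg <- stats::aggregate(
      cbind(total_kb = length_kb, n_long = length_kb > 10000,
            n_segments = rep(1L, length(length_kb))) ~ sample_id,
      data = segments, FUN = sum)
    i <- match(agg$sample_id, prof$sample_id)
    prof$n_segments[i] <- agg$n_segments
    prof$total_kb[i] <- agg$total_kb
    prof$n_long[i] <- agg$n_long
    prof$froh <- prof$total_kb / autosome_kb
  }
  class(prof) <- c("roh_profile", "data.frame")
  attr(prof, "autosome_kb") <- autosome_kb
  prof
}

#' @export
print.roh_profile <- function(x, ...) {
  cat("<roh_profile> ", nrow(x), " samples; mean froh ",
      format(mean(x$froh), digits = 4), ", mean long (>10 Mb) segments ",
      format(mean(x$n_long), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Compare ROH profiles between groups
#'
#' Descriptive comparison of genomic inbreeding across sample groups: mean
#' and quartiles of fROH and the mean count of long (> 10 Mb) segments per
#' group. No inferential statistics are computed.
#'
#' @param profiles A `roh_profile` data frame from [summarize_froh()].
#' @param groups Group label per profile row (named vector by `sample_id`
#'   or parallel vector).
#' @return Data frame: `group`, `n`, `mean_froh`, `q25_froh`,
#'   `median_froh`, `q75_froh`, `mean_n_long`. Empty groups are excluded
#'   with a warning.
#' @export
compare_groups <- function(profiles, groups) {
  if (!is.null(names(groups))) groups <- groups[profiles$sample_id]
  if (length(groups) != nrow(profiles))
    stop("groups must be parallel to profiles (or named by sample_id)")
  gf <- factor(groups)
  empty <- levels(gf)[tabulate(gf, nlevels(gf)) == 0]
  if (length(empty) || anyNA(groups)) {
    warning("excluding empty/unlabelled groups: ",
            paste(c(empty, if (anyNA(groups)) "<NA>"), collapse = ", "))
  }
  split_idx <- split(seq_len(nrow(profiles)), gf, drop = TRUE)
  rows <- lapply(names(split_idx), function(grp) {
    fr <- profiles$froh[split_idx[[grp]]]
    data.frame(group = grp, n = length(fr), mean_froh = mean(fr),
               q25_froh = unname(stats::quantile(fr, 0.25)),
               median_froh = unname(stats::median(fr)),
               q75_froh = unname(stats::quantile(fr, 0.75)),
               mean_n_long = mean(profiles$n_long[split_idx[[grp]]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
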