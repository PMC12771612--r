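#' Read genotypes from PLINK files
#'
#' Reads a PLINK text fileset (`<prefix>.ped` + `<prefix>.map`) or binary
#' fileset (`<prefix>.bed` + `<prefix>.bim` + `<prefix>.fam`, SNP-major
#' v1.00) into a [genotype_matrix()]. Dosages count copies of `allele_b`,
#' the second allele column of the `.bim` file; the missing genotype
#' (`0 0` in text, code `01` in binary) maps to `NA`.
#'
#' The text format does not record allele orientation. Unless `markers_ref`
#' is supplied, alleles observed at each marker are assigned so that
#' `allele_a` sorts before `allele_b` (ASCII); markers where a single allele
#' is observed treat it as `allele_b` with `allele_a = "0"`, and fully
#' missing markers get placeholder alleles `"0"`/`"N"`.
#'
#' @param prefix File path prefix (without extension).
#' @param format `"plink_text"` or `"plink_binary"`.
#' @param markers_ref Optional marker table (as in [marker_table()]) fixing
#'   marker metadata and allele orientation for the text format; dosages are
#'   recoded to count its `allele_b`.
#' @return A `genotype_matrix`.
#' @seealso [write_genotypes()]
#' @export
read_genotypes <- function(prefix, format = c("plink_binary", "plink_text"),
                           markers_ref = NULL) {
  format <- match.arg(format)
  switch(format,
    plink_text = read_plink_text(prefix, markers_ref),
    plink_binary = read_plink_binary(prefix)
  )
}

#' Write genotypes to PLINK files
#'
#' Writes a [genotype_matrix()] as a PLINK text (`.ped`/`.map`) or binary
#' (`.bed`/`.bim`/`.fam`, SNP-major magic `6C 1B 01`) fileset. Output is
#' readable by [read_genotypes()] with exact round-trip of dosages; binary
#' output also round-trips all marker metadata.
#'
#' @param g A `genotype_matrix`.
#' @param prefix Output path prefix (without extension).
#' @param format `"plink_text"` or `"plink_binary"`.
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(g, prefix, format = c("plink_binary", "plink_text")) {
  format <- match.arg(format)
  validate_genotype_matrix(g)
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  switch(format,
    plink_text = write_plink_text(g, prefix),
    plink_binary = write_plink_binary(g, prefix)
  )
  invisible(prefix)
}

## ---- text format ----------------------------------------------------------

read_plink_text <- function(prefix, markers_ref = NULL) {
  ped <- paste0(prefix, ".ped"); map <- paste0(prefix, ".map")
  for (f in c(ped, map)) if (!file.exists(f)) stop("missing file: ", f)
  mp <- utils::read.table(map, header = FALSE, colClasses = "character")
  if (ncol(mp) < 4) stop("malformed .map: expected 4 columns")
  L <- nrow(mp)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  bad <- which(vapply(toks, length, 1L) != 6 + 2 * L)
  if (length(bad))
    stop("consistency error: .ped line ", bad[1], " has ",
         length(toks[[bad[1]]]), " fields, expected ", 6 + 2 * L)
  fam <- t(vapply(toks, function(x) x[1:6], character(6)))
  al1 <- t(vapply(toks, function(x) x[6 + 2 * seq_len(L) - 1], character(L)))
  al2 <- t(vapply(toks, function(x) x[6 + 2 * seq_len(L)], character(L)))
  if (L == 1) { al1 <- matrix(al1, ncol = 1); al2 <- matrix(al2, ncol = 1) }
  al1[al1 == "0"] <- NA; al2[al2 == "0"] <- NA

  if (!is.null(markers_ref)) {
    if (nrow(markers_ref) != L) stop("markers_ref has wrong number of markers")
    aa <- markers_ref$allele_a; ab <- markers_ref$allele_b
  } else {
    aa <- ab <- character(L)
    for (l in seq_len(L)) {
      obs <- sort(unique(c(al1[, l], al2[, l])))
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0) { aa[l] <- "0"; ab[l] <- "N" }
      else if (length(obs) == 1) { aa[l] <- "0"; ab[l] <- obs }
      else if (length(obs) == 2) { aa[l] <- obs[1]; ab[l] <- obs[2] }
      else stop("marker ", mp[l, 2], " has >2 alleles in .ped")
    }
  }
  dos <- matrix(NA_real_, n, L)
  for (l in seq_len(L)) {
    d <- (al1[, l] == ab[l]) + (al2[, l] == ab[l])
    d[!is.na(al1[, l]) & al1[, l] != ab[l] & al1[, l] != aa[l]] <- NA
    d[!is.na(al2[, l]) & al2[, l] != ab[l] & al2[, l] != aa[l]] <- NA
    dos[, l] <- d
  }
  markers <- if (is.null(markers_ref)) {
    marker_table(mp[, 2], mp[, 1], as.integer(mp[, 4]), aa, ab)
  } else as.data.frame(markers_ref, stringsAsFactors = FALSE)
  genotype_matrix(dos, markers,
                  sample_table(fam[, 2], group_label = fam[, 1]))
}

write_plink_text <- function(g, prefix) {
  d <- g$dosage; m <- g$markers; s <- g$samples
  n <- nrow(d); L <- ncol(d)
  aam <- matrix(rep(m$allele_a, each = n), n, L)
  abm <- matrix(rep(m$allele_b, each = n), n, L)
  # genotype -> two allele calls; NA -> "0 0"
  a1 <- matrix("0", n, L); a2 <- matrix("0", n, L)
  hom_a <- !is.na(d) & d == 0; hom_b <- !is.na(d) & d == 2
  het <- !is.na(d) & d == 1
  a1[hom_a] <- aam[hom_a]; a2[hom_a] <- aam[hom_a]
  a1[hom_b] <- abm[hom_b]; a2[hom_b] <- abm[hom_b]
  a1[het] <- aam[het]; a2[het] <- abm[het]
  geno <- matrix(paste(a1, a2), n, L)
  grp <- ifelse(is.na(s$group_label), s$sample_id, s$group_label)
  lines <- paste(grp, s$sample_id, 0, 0, 0, -9,
                 apply(geno, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  writeLines(paste(m$chromosome, m$marker_id, 0, m$position_bp),
             paste0(prefix, ".map"))
}

## ---- binary format --------------------------------------------------------

plink_magic <- as.raw(c(0x6C, 0x1B, 0x01))

read_plink_binary <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bm <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bm) < 6) stop("malformed .bim: expected 6 columns")
  fm <- utils::read.table(fam, header = FALSE, colClasses = "character")
  L <- nrow(bm); n <- nrow(fm)
  bpm <- ceiling(n / 4)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], plink_magic))
    stop("format error: bad .bed magic bytes (expected SNP-major v1.00)")
  body <- raw[-(1:3)]
  if (length(body) != bpm * L)
    stop("consistency error: .bed has ", length(body),
         " data bytes; expected ", bpm * L, " for ", n, " samples x ", L,
         " markers")
  b <- as.integer(body)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4L * bpm, L)
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> hom allele_a, 01 -> missing, 10 -> het, 11 -> hom allele_b
  lut <- c(0, NA, 1, 2)
  dos <- matrix(lut[codes + 1L], n, L)
  genotype_matrix(
    dos,
    marker_table(bm[, 2], bm[, 1], as.integer(bm[, 4]), bm[, 5], bm[, 6]),
    sample_table(fm[, 2], group_label = fm[, 1])
  )
}

write_plink_binary <- function(g, prefix) {
  d <- g$dosage; m <- g$markers; s <- g$samples
  n <- nrow(d); L <- ncol(d); bpm <- ceiling(n / 4)
  code <- matrix(1L, 4L * bpm, L)          # pad + missing code 01
  lut <- c(0L, 2L, 3L)                     # dosage 0/1/2 -> 00/10/11
  obs <- !is.na(d)
  cd <- matrix(1L, n, L); cd[obs] <- lut[d[obs] + 1L]
  code[seq_len(n), ] <- cd
  dim(code) <- c(4L, bpm * L)
  bytes <- as.raw(colSums(code * c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(plink_magic, con)
  writeBin(bytes, con)
  writeLines(paste(m$chromosome, m$marker_id, 0, m$position_bp,
                   m$allele_a, m$allele_b), paste0(prefix, ".bim"))
  grp <- ifelse(is.na(s$group_label), s$sample_id, s$group_label)
  writeLines(paste(grp, s$sample_id, 0, 0, 0, -9), paste0(prefix, ".fam"))
}

## ---- merging and filters --------------------------------------------------

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Merge genotype panels on their shared markers
#'
#' Intersects marker sets by `marker_id` across two or more panels and
#' concatenates all samples. Markers whose `allele_a`/`allele_b` are swapped
#' relative to the first panel are recoded (`d -> 2 - d`); non-ambiguous
#' strand flips are resolved by base complementing; strand-ambiguous (A/T,
#' C/G) markers with conflicting allele pairs, irreconcilable allele pairs,
#' and markers whose chromosome/position disagree between panels are dropped
#' and logged.
#'
#' @param panels List of two or more `genotype_matrix` objects.
#' @return A `genotype_matrix` on the shared, reconciled markers (orientation
#'   of the first panel), with attribute `"merge_log"`: a data frame of
#'   dropped/recoded markers and the action taken.
#' @export
merge_on_shared_markers <- function(panels) {
  if (!is.list(panels) || length(panels) < 2)
    stop("need a list of >= 2 panels")
  lapply(panels, validate_genotype_matrix)
  ids <- lapply(panels, function(p) p$markers$marker_id)
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0) stop("empty marker intersection")
  all_samples <- unlist(lapply(panels, function(p) p$samples$sample_id))
  if (anyDuplicated(all_samples))
    stop("duplicate sample_id across panels: ",
         paste(utils::head(unique(all_samples[duplicated(all_samples)]), 5),
               collapse = ", "))

  ref <- panels[[1]]$markers
  ref <- ref[match(shared, ref$marker_id), , drop = FALSE]
  log <- list()
  keep <- rep(TRUE, length(shared))
  flip <- matrix(FALSE, length(shared), length(panels))  # per panel recode

  for (p in seq_along(panels)[-1]) {
    mk <- panels[[p]]$markers
    mk <- mk[match(shared, mk$marker_id), , drop = FALSE]
    pos_conflict <- mk$chromosome != ref$chromosome |
      mk$position_bp != ref$position_bp
    pair_ref <- paste0(ref$allele_a, "/", ref$allele_b)
    same <- mk$allele_a == ref$allele_a & mk$allele_b == ref$allele_b
    swap <- mk$allele_a == ref$allele_b & mk$allele_b == ref$allele_a
    ca <- unname(COMPLEMENT[mk$allele_a]); cb <- unname(COMPLEMENT[mk$allele_b])
    comp_same <- !is.na(ca) & !is.na(cb) & ca == ref$allele_a & cb == ref$allele_b
    comp_swap <- !is.na(ca) & !is.na(cb) & ca == ref$allele_b & cb == ref$allele_a
    # for A/T and C/G markers a swapped pair could equally be a strand
    # flip, so only an exact orientation match is accepted for them
    ambiguous <- pair_ref %in% STRAND_AMBIGUOUS
    resolved_same <- same | (!ambiguous & comp_same)
    resolved_swap <- !ambiguous & !resolved_same & (swap | comp_swap)
    drop <- pos_conflict | !(resolved_same | resolved_swap)
    flip[, p] <- resolved_swap & !drop
    if (any(drop)) {
      log[[length(log) + 1L]] <- data.frame(
        marker_id = shared[drop], panel = p,
        action = ifelse(pos_conflict[drop], "dropped_position_conflict",
                        "dropped_irreconcilable_alleles"),
        stringsAsFactors = FALSE)
      keep <- keep & !drop
    }
    if (any(flip[, p])) {
      log[[length(log) + 1L]] <- data.frame(
        marker_id = shared[flip[, p]], panel = p, action = "recoded_swap",
        stringsAsFactors = FALSE)
    }
  }
  if (!any(keep)) stop("empty marker intersection after allele reconciliation")
  shared <- shared[keep]; ref <- ref[keep, , drop = FALSE]
  flip <- flip[keep, , drop = FALSE]

  dmats <- vector("list", length(panels))
  smeta <- vector("list", length(panels))
  for (p in seq_along(panels)) {
    j <- match(shared, panels[[p]]$markers$marker_id)
    d <- panels[[p]]$dosage[, j, drop = FALSE]
    fl <- which(flip[, p])
    if (length(fl)) d[, fl] <- 2 - d[, fl]
    dmats[[p]] <- d
    smeta[[p]] <- panels[[p]]$samples
  }
  out <- genotype_matrix(do.call(rbind, dmats), ref, do.call(rbind, smeta))
  attr(out, "merge_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(marker_id = character(), panel = integer(),
               action = character(), stringsAsFactors = FALSE)
  out
}

#' Apply call-rate quality filters
#'
#' Removes markers whose call rate falls below `min_marker_callrate` and
#' individuals whose missing-genotype fraction exceeds
#' `max_individual_missing`. Either threshold may be `NULL` to skip that
#' filter (marker call-rate filtering is typically applied only ahead of ROH
#' scanning, while the individual-missingness filter applies panel-wide).
#'
#' @param g A `genotype_matrix`.
#' @param max_individual_missing Maximum tolerated per-individual missing
#'   fraction, in `[0, 1]`, or `NULL`.
#' @param min_marker_callrate Minimum tolerated per-marker call rate, in
#'   `[0, 1]`, or `NULL`.
#' @param order `"markers_first"` (default) or `"individuals_first"`.
#' @return List with `genotypes` (the filtered `genotype_matrix`) and
#'   `report` (removed ids, counts, thresholds and filter order).
#' @export
apply_callrate_filters <- function(g, max_individual_missing = 0.05,
                                   min_marker_callrate = NULL,
                                   order = c("markers_first", "individuals_first")) {
  order <- match.arg(order)
  validate_genotype_matrix(g)
  for (th in c(max_individual_missing, min_marker_callrate))
    if (!is.null(th) && (th < 0 || th > 1)) stop("thresholds must lie in [0, 1]")

  drop_markers <- function(x) {
    if (is.null(min_marker_callrate)) return(list(x, character(0)))
    cr <- marker_callrate(x)
    bad <- cr < min_marker_callrate
    list(if (any(bad)) x[, !bad] else x, x$markers$marker_id[bad])
  }
  drop_samples <- function(x) {
    if (is.null(max_individual_missing)) return(list(x, character(0)))
    ms <- sample_missingness(x)
    bad <- ms > max_individual_missing
    if (all(bad)) stop("call-rate filtering removed every sample")
    list(if (any(bad)) x[!bad, ] else x, x$samples$sample_id[bad])
  }
  if (order == "markers_first") {
    a <- drop_markers(g); b <- drop_samples(a[[1]])
    out <- b[[1]]; rm_m <- a[[2]]; rm_s <- b[[2]]
  } else {
    a <- drop_samples(g); b <- drop_markers(a[[1]])
    out <- b[[1]]; rm_m <- b[[2]]; rm_s <- a[[2]]
  }
  list(
    genotypes = out,
    report = list(
      removed_markers = rm_m, removed_samples = rm_s,
      n_markers_removed = length(rm_m), n_samples_removed = length(rm_s),
      max_individual_missing = max_individual_missing,
      min_marker_callrate = min_marker_callrate, order = order
    )
  )
}

#' Write a call-rate filter report as tab-separated text
#'
#' @param report The `report` element returned by [apply_callrate_filters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  rows <- rbind(
    if (length(report$removed_markers))
      data.frame(type = "marker", id = report$removed_markers),
    if (length(report$removed_samples))
      data.frame(type = "sample", id = report$removed_samples)
  )
  if (is.null(rows)) rows <- data.frame(type = character(), id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
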