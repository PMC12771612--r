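#' Construct a genotype matrix
#'
#' The universal data container of the package: a samples-by-markers table of
#' allele-B dosages together with a marker map and a sample registry. Dosages
#' count copies of `allele_b` and take values 0, 1, 2 or `NA` (missing).
#'
#' @param dosage Numeric matrix, samples in rows, markers in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @param markers Data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`; one row per dosage column.
#' @param samples Data frame with columns `sample_id` (unique), `group_label`
#'   (optional, `NA` allowed) and `role` (`"reference"` or `"query"`); one row
#'   per dosage row.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `markers`, `samples`.
#'
#' @examples
#' g <- genotype_matrix(
#'   dosage  = matrix(c(0, 1, 2, NA), 2, 2),
#'   markers = marker_table(c("m1", "m2"), "1", c(100L, 200L), "A", "G"),
#'   samples = sample_table(c("s1", "s2"))
#' )
#' dim(g)
#' @export
genotype_matrix <- function(dosage, markers, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$group_label)) samples$group_label <- NA_character_
  if (is.null(samples$role)) samples$role <- "query"
  g <- structure(
    list(dosage = dosage, markers = markers, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
  g
}

validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (nrow(d) != nrow(g$samples))
    stop("dosage rows (", nrow(d), ") != samples (", nrow(g$samples), ")")
  if (ncol(d) != nrow(g$markers))
    stop("dosage columns (", ncol(d), ") != markers (", nrow(g$markers), ")")
  need_m <- c("marker_id", "chromosome", "position_bp", "allele_a", "allele_b")
  miss <- setdiff(need_m, names(g$markers))
  if (length(miss)) stop("markers lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "group_label", "role") %in% names(g$samples)))
    stop("samples must have sample_id, group_label, role")
  if (anyDuplicated(g$samples$sample_id))
    stop("duplicate sample_id in panel")
  if (anyDuplicated(g$markers$marker_id))
    stop("duplicate marker_id in panel")
  bad <- !(is.na(d) | d == 0 | d == 1 | d == 2)
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (any(!is.na(g$markers$allele_a) & !is.na(g$markers$allele_b) &
          g$markers$allele_a == g$markers$allele_b))
    stop("allele_a must differ from allele_b")
  if (any(g$markers$position_bp < 1)) stop("position_bp must be >= 1 (1-based)")
  invisible(g)
}

#' Build a marker map data frame
#'
#' @param marker_id Character vector of unique marker ids.
#' @param chromosome Chromosome labels (recycled).
#' @param position_bp 1-based physical positions (recycled).
#' @param allele_a,allele_b Allele letters (recycled); dosage counts copies
#'   of `allele_b`.
#' @return Data frame suitable for [genotype_matrix()].
#' @export
marker_table <- function(marker_id, chromosome, position_bp,
                         allele_a = "A", allele_b = "G") {
  data.frame(
    marker_id = as.character(marker_id),
    chromosome = rep_len(as.character(chromosome), length(marker_id)),
    position_bp = rep_len(as.integer(position_bp), length(marker_id)),
    allele_a = rep_len(as.character(allele_a), length(marker_id)),
    allele_b = rep_len(as.character(allele_b), length(marker_id)),
    stringsAsFactors = FALSE
  )
}

#' Build a sample registry data frame
#'
#' @param sample_id Character vector of unique sample ids.
#' @param group_label Optional group / island / breed labels (recycled).
#' @param role `"reference"` or `"query"` (recycled).
#' @return Data frame suitable for [genotype_matrix()].
#' @export
sample_table <- function(sample_id, group_label = NA_character_, role = "query") {
  data.frame(
    sample_id = as.character(sample_id),
    group_label = rep_len(as.character(group_label), length(sample_id)),
    role = rep_len(as.character(role), length(sample_id)),
    stringsAsFactors = FALSE
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  miss <- mean(is.na(d))
  cat("<genotype_matrix> ", nrow(d), " samples x ", ncol(d), " markers",
      sprintf(" (%.1f%% missing)\n", 100 * miss), sep = "")
  chroms <- unique(x$markers$chromosome)
  cat("  chromosomes: ", paste(utils::head(chroms, 8), collapse = ", "),
      if (length(chroms) > 8) ", ..." else "", "\n", sep = "")
  roles <- table(x$samples$role)
  cat("  roles: ", paste(names(roles), roles, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or markers
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (integer, logical or sample_id character).
#' @param j Marker index (integer, logical or marker_id character).
#' @param ... Ignored.
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$markers$marker_id)
  genotype_matrix(
    dosage = x$dosage[i, j, drop = FALSE],
    markers = x$markers[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE]
  )
}

#' Construct a reference panel
#'
#' A reference panel is a [genotype_matrix()] whose samples carry an
#' assignment to named reference clusters — the genetically cohesive groups
#' (breeds, wild-boar regions, sister taxa) that supervised ancestry
#' estimation conditions on.
#'
#' @param genotypes A `genotype_matrix`.
#' @param cluster Either a character vector of cluster labels parallel to the
#'   samples, or a named vector mapping `sample_id` to cluster label.
#' @return An object of class `reference_panel` (inherits `genotype_matrix`)
#'   with an extra `cluster` factor.
#' @export
reference_panel <- function(genotypes, cluster) {
  validate_genotype_matrix(genotypes)
  ids <- genotypes$samples$sample_id
  if (!is.null(names(cluster))) {
    miss <- setdiff(ids, names(cluster))
    if (length(miss)) stop("no cluster assignment for: ", paste(utils::head(miss, 5), collapse = ", "))
    cluster <- cluster[ids]
  }
  if (length(cluster) != length(ids))
    stop("cluster length must match number of samples")
  genotypes$cluster <- factor(as.character(cluster))
  genotypes$samples$role <- "reference"
  class(genotypes) <- c("reference_panel", "genotype_matrix")
  genotypes
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " markers, ", nlevels(x$cluster), " clusters\n", sep = "")
  tab <- table(x$cluster)
  cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# per-sample and per-marker missingness helpers used by QC and pruning
sample_missingness <- function(g) rowMeans(is.na(g$dosage))
marker_callrate <- function(g) colMeans(!is.na(g$dosage))
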