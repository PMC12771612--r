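#' Chromosome layout for simulated genomes
#'
#' Describes where simulated markers sit: for each chromosome, a number of
#' markers placed at fixed spacing (marker `i` at `i * spacing_bp`). Fixed
#' spacing keeps density and gap rules of the ROH scanner analytically
#' checkable.
#'
#' @param chromosome Chromosome labels.
#' @param n_markers Markers per chromosome (recycled).
#' @param spacing_bp Inter-marker spacing in bp (recycled).
#' @return Data frame with columns `chromosome`, `n_markers`, `spacing_bp`.
#' @export
chromosome_layout <- function(chromosome, n_markers, spacing_bp = 50000) {
  data.frame(
    chromosome = as.character(chromosome),
    n_markers = rep_len(as.integer(n_markers), length(chromosome)),
    spacing_bp = rep_len(as.integer(spacing_bp), length(chromosome)),
    stringsAsFactors = FALSE
  )
}

layout_markers <- function(layout, prefix = "m") {
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    n <- layout$n_markers[i]
    data.frame(
      chromosome = rep(layout$chromosome[i], n),
      position_bp = layout$spacing_bp[i] * seq_len(n),
      stringsAsFactors = FALSE
    )
  })
  mk <- do.call(rbind, pieces)
  marker_table(sprintf("%s%06d", prefix, seq_len(nrow(mk))),
               mk$chromosome, mk$position_bp, "A", "G")
}

default_layout <- function(n_markers, spacing_bp = 10000) {
  chromosome_layout("1", n_markers, spacing_bp)
}

#' Simulate a reference panel under the Balding-Nichols model
#'
#' Draws per-locus ancestral allele frequencies uniformly from
#' `ancestral_freq_range`, diverges them into `n_clusters` cluster
#' frequencies with a Beta distribution parameterized by `fst`
#' (`f_kl ~ Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`), and samples unlinked
#' genotypes of cluster members as `Binomial(2, f_kl)` (Hardy-Weinberg
#' within cluster).
#'
#' @param n_clusters Number of divergent clusters `K`.
#' @param fst Divergence parameter, in the open interval (0, 1).
#' @param n_markers Number of unlinked biallelic markers `L` (ignored when
#'   `layout` is given).
#' @param n_per_cluster Samples per cluster.
#' @param ancestral_freq_range Interval for ancestral frequencies; the
#'   default (0.05, 0.95) avoids monomorphic loci.
#' @param seed Integer seed; identical seed and configuration give identical
#'   output.
#' @param layout Optional [chromosome_layout()] for marker placement;
#'   default is a single chromosome at 10 kb spacing.
#' @return List with `panel` (a [reference_panel()] with clusters
#'   `C1..CK`), `frequencies` (the true K x L cluster frequency matrix) and
#'   `ancestral_freq` (length-L vector).
#' @export
simulate_reference_panel <- function(n_clusters, fst, n_markers,
                                     n_per_cluster,
                                     ancestral_freq_range = c(0.05, 0.95),
                                     seed = 1L, layout = NULL) {
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  if (n_clusters < 1 || n_per_cluster < 1) stop("counts must be >= 1")
  if (is.null(layout)) layout <- default_layout(n_markers)
  markers <- layout_markers(layout)
  L <- nrow(markers)
  set.seed(seed)
  p <- stats::runif(L, ancestral_freq_range[1], ancestral_freq_range[2])
  scale <- (1 - fst) / fst
  K <- n_clusters
  freqs <- matrix(stats::rbeta(K * L, rep(p * scale, each = K),
                               rep((1 - p) * scale, each = K)), K, L)
  n <- K * n_per_cluster
  cl <- rep(seq_len(K), each = n_per_cluster)
  dos <- matrix(stats::rbinom(n * L, 2L, freqs[cl, ]), n, L)
  cluster <- paste0("C", cl)
  g <- genotype_matrix(
    dos, markers,
    sample_table(sprintf("ref_%s_%03d", cluster,
                         sequence(rep(n_per_cluster, K))),
                 group_label = cluster, role = "reference")
  )
  rownames(freqs) <- paste0("C", seq_len(K))
  list(panel = reference_panel(g, cluster), frequencies = freqs,
       ancestral_freq = p)
}

#' Simulate a two-level hierarchical reference panel
#'
#' Emulates a wild-domestic species complex with deep divergence between a
#' few lineages (e.g. Asian vs European) and shallower divergence among the
#' clusters within each lineage: lineage frequencies diverge from a common
#' ancestral frequency at `fst_between`, and each cluster's frequencies
#' diverge from its lineage frequency at `fst_within` (Balding-Nichols at
#' both levels). Genotypes are Hardy-Weinberg binomial draws as in
#' [simulate_reference_panel()].
#'
#' @param n_lineages Number of deep lineages.
#' @param clusters_per_lineage Clusters nested within each lineage.
#' @param fst_between,fst_within Divergence at the two levels, each in
#'   (0, 1); the default 0.25 / 0.08 makes the lineage split the dominant
#'   axis of variation.
#' @inheritParams simulate_reference_panel
#' @return List with `panel` (clusters labelled `L<i>C<j>`), `frequencies`
#'   (clusters x L), `lineage_frequencies` (lineages x L), `lineage_of`
#'   (named cluster -> lineage map) and `ancestral_freq`.
#' @export
simulate_hierarchical_panel <- function(n_lineages = 2,
                                        clusters_per_lineage = 2,
                                        fst_between = 0.25,
                                        fst_within = 0.08,
                                        n_markers = 1000,
                                        n_per_cluster = 25,
                                        ancestral_freq_range = c(0.05, 0.95),
                                        seed = 1L, layout = NULL) {
  for (fst in c(fst_between, fst_within))
    if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  if (is.null(layout)) layout <- default_layout(n_markers)
  markers <- layout_markers(layout)
  L <- nrow(markers)
  set.seed(seed)
  p <- stats::runif(L, ancestral_freq_range[1], ancestral_freq_range[2])
  s1 <- (1 - fst_between) / fst_between
  lin_f <- matrix(stats::rbeta(n_lineages * L, rep(p * s1, each = n_lineages),
                               rep((1 - p) * s1, each = n_lineages)),
                  n_lineages, L)
  lin_f <- pmin(pmax(lin_f, 1e-4), 1 - 1e-4)   # keep Beta shapes proper
  K <- n_lineages * clusters_per_lineage
  lin_of_cluster <- rep(seq_len(n_lineages), each = clusters_per_lineage)
  s2 <- (1 - fst_within) / fst_within
  anc <- lin_f[lin_of_cluster, , drop = FALSE]      # K x L, column-major
  freqs <- matrix(stats::rbeta(K * L, anc * s2, (1 - anc) * s2), K, L)
  n <- K * n_per_cluster
  cl <- rep(seq_len(K), each = n_per_cluster)
  dos <- matrix(stats::rbinom(n * L, 2L, freqs[cl, ]), n, L)
  cluster <- sprintf("L%dC%d", lin_of_cluster[cl],
                     ((cl - 1) %% clusters_per_lineage) + 1)
  g <- genotype_matrix(
    dos, markers,
    sample_table(sprintf("ref_%s_%03d", cluster,
                         sequence(rep(n_per_cluster, K))),
                 group_label = cluster, role = "reference")
  )
  cluster_ids <- sprintf("L%dC%d", lin_of_cluster,
                         rep(seq_len(clusters_per_lineage), n_lineages))
  rownames(freqs) <- cluster_ids
  rownames(lin_f) <- paste0("L", seq_len(n_lineages))
  list(panel = reference_panel(g, cluster), frequencies = freqs,
       lineage_frequencies = lin_f,
       lineage_of = stats::setNames(paste0("L", lin_of_cluster), cluster_ids),
       ancestral_freq = p)
}

#' Simulate admixed query genotypes with known ancestry
#'
#' For each query with ancestry vector `q` on the K-simplex, the
#' individual-specific allele frequency at locus `l` is
#' `pi_l = sum_k q_k f_kl` and the genotype is drawn `Binomial(2, pi_l)`,
#' independently across loci — the generative model matched by the
#' supervised admixture likelihood.
#'
#' @param frequencies K x L matrix of cluster allele frequencies.
#' @param q_list List of simplex vectors (length K, non-negative, summing to
#'   1 within 1e-9).
#' @param seed Integer seed.
#' @param markers Optional marker table (defaults to a 10 kb-spaced single
#'   chromosome).
#' @param missing_rate Per-cell probability of masking a genotype as
#'   missing (default 0, i.e. fully observed).
#' @return List with `genotypes` (a `genotype_matrix` of queries) and
#'   `truth` (data frame: `sample_id` plus the true `q` matrix).
#' @export
simulate_admixed_queries <- function(frequencies, q_list, seed = 1L,
                                     markers = NULL, missing_rate = 0) {
  K <- nrow(frequencies); L <- ncol(frequencies)
  for (q in q_list) {
    if (length(q) != K) stop("each q must have length K = ", K)
    if (any(q < -1e-9) || abs(sum(q) - 1) > 1e-9)
      stop("q is off the simplex beyond 1e-9")
  }
  if (is.null(markers)) markers <- layout_markers(default_layout(L))
  set.seed(seed)
  n <- length(q_list)
  Q <- do.call(rbind, q_list)
  Pi <- Q %*% frequencies                      # n x L mixed frequencies
  dos <- matrix(stats::rbinom(n * L, 2L, Pi), n, L)
  if (missing_rate > 0)
    dos[matrix(stats::runif(n * L) < missing_rate, n, L)] <- NA
  ids <- sprintf("query_%03d", seq_len(n))
  truth <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  truth$q <- Q
  list(
    genotypes = genotype_matrix(dos, markers,
                                sample_table(ids, role = "query")),
    truth = truth
  )
}

#' Simulate a related pair of genotype rows
#'
#' Fixture generator for the relatedness-based reference pruning rule:
#' `duplicate` returns identical rows, `parent_offspring` transmits one
#' allele from the parent and draws the other from the population frequency,
#' and `unrelated` draws both rows independently.
#'
#' @param frequencies Per-locus population allele-B frequency vector.
#' @param relationship One of `"duplicate"`, `"parent_offspring"`,
#'   `"unrelated"`.
#' @param seed Integer seed.
#' @return A 2 x L dosage matrix with rows `id1`, `id2`.
#' @export
simulate_related_pair <- function(frequencies,
                                  relationship = c("duplicate",
                                                   "parent_offspring",
                                                   "unrelated"),
                                  seed = 1L) {
  relationship <- match.arg(relationship)
  f <- as.numeric(frequencies); L <- length(f)
  set.seed(seed)
  g1 <- stats::rbinom(L, 2L, f)
  g2 <- switch(relationship,
    duplicate = g1,
    unrelated = stats::rbinom(L, 2L, f),
    parent_offspring = {
      transmitted <- stats::rbinom(L, 1L, g1 / 2)   # allele copied from parent
      transmitted + stats::rbinom(L, 1L, f)         # other from population
    }
  )
  out <- rbind(id1 = g1, id2 = g2)
  out
}

#' Simulate one genome with planted runs of homozygosity
#'
#' Outside planted segments, each marker is heterozygous with probability
#' `background_het` and otherwise homozygous (allele chosen at random);
#' inside a planted segment every genotype is homozygous, except for up to
#' `n_het_errors` heterozygous genotyping errors injected at random
#' positions within each segment.
#'
#' @param layout A [chromosome_layout()].
#' @param planted Data frame of planted segments with columns `chromosome`,
#'   `start_bp`, `end_bp`; segments must not overlap within a chromosome and
#'   must each contain at least one marker.
#' @param background_het Heterozygosity rate outside planted segments.
#' @param seed Integer seed.
#' @param n_het_errors Heterozygous errors injected per planted segment.
#' @return List with `genotypes` (1 x L `genotype_matrix`) and `truth`
#'   (the planted-segment data frame).
#' @export
simulate_roh_individual <- function(layout, planted = NULL,
                                    background_het = 0.3, seed = 1L,
                                    n_het_errors = 0L) {
  markers <- layout_markers(layout, "r")
  L <- nrow(markers)
  if (is.null(planted))
    planted <- data.frame(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(planted)) {
    for (ch in unique(planted$chromosome)) {
      seg <- planted[planted$chromosome == ch, , drop = FALSE]
      seg <- seg[order(seg$start_bp), , drop = FALSE]
      if (nrow(seg) > 1 &&
          any(seg$start_bp[-1] <= seg$end_bp[-nrow(seg)]))
        stop("planted segments overlap on chromosome ", ch)
    }
  }
  set.seed(seed)
  het <- stats::runif(L) < background_het
  hom <- 2L * stats::rbinom(L, 1L, 0.5)
  dos <- ifelse(het, 1L, hom)
  inside <- rep(FALSE, L)
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      idx <- which(markers$chromosome == planted$chromosome[i] &
                   markers$position_bp >= planted$start_bp[i] &
                   markers$position_bp <= planted$end_bp[i])
      if (length(idx) == 0)
        stop("planted segment ", i, " contains no markers")
      inside[idx] <- TRUE
      dos[idx] <- 2L * stats::rbinom(length(idx), 1L, 0.5)
      if (n_het_errors > 0) {
        err <- sample(idx, min(n_het_errors, length(idx)))
        dos[err] <- 1L
      }
    }
  }
  g <- genotype_matrix(matrix(dos, 1L, L), markers,
                       sample_table("roh_sample"))
  list(genotypes = g, truth = planted)
}
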