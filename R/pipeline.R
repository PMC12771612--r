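#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end ancestry workflow with the
#' conventional defaults: relatedness pruning at `pi_hat >= 0.70`, a 5%
#' individual-missingness ceiling panel-wide, ROH-stage call-rate filters
#' (markers >= 95%, individuals >= 90%), 100 locus-bootstrap replicates,
#' and the segment constraints of the ROH scanner.
#'
#' @param ibd_threshold Relatedness pruning threshold on `pi_hat`.
#' @param max_individual_missing Individual missingness ceiling.
#' @param roh_marker_callrate,roh_individual_callrate Call-rate filters
#'   applied only ahead of the ROH scan.
#' @param n_boot Bootstrap replicates per query.
#' @param mode Supervised estimation mode, `"joint"` or
#'   `"fixed_frequencies"`.
#' @param significance_multiplier SE multiplier in the significance rule
#'   (1 = literal "does not overlap 0"; 1.96 = 95% CI reading).
#' @param tol,max_iter EM stopping rule.
#' @param seed Master seed; every stage derives its seeds from it.
#' @param k2_per_query Refit the unsupervised two-lineage model once per
#'   query (mirroring single-sample querying) instead of once jointly.
#' @param asian_clusters,european_clusters Cluster labels declaring the
#'   two-lineage super-groups (and, combined, the PCA reference subset).
#' @param n_pca_components Principal components to retain.
#' @param roh List of ROH scanner parameters (see [detect_roh_segments()]).
#' @param autosome_kb fROH denominator (default [AUTOSOME_KB]).
#' @param exclusions Sample ids excluded from reported island ancestry
#'   ranges (e.g. known domestic escapees).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ibd_threshold = 0.70,
                            max_individual_missing = 0.05,
                            roh_marker_callrate = 0.95,
                            roh_individual_callrate = 0.90,
                            n_boot = 100, mode = "joint",
                            significance_multiplier = 1,
                            tol = 1e-6, max_iter = 2000, seed = 1L,
                            k2_per_query = FALSE,
                            asian_clusters = character(),
                            european_clusters = character(),
                            n_pca_components = 2,
                            roh = list(), autosome_kb = AUTOSOME_KB,
                            exclusions = character()) {
  roh_defaults <- list(max_het = 1, max_missing = 2, max_gap_bp = 600000,
                       max_kb_per_snp = 80, min_snps = 25, min_kb = 500)
  roh <- utils::modifyList(roh_defaults, roh)
  cfg <- list(ibd_threshold = ibd_threshold,
              max_individual_missing = max_individual_missing,
              roh_marker_callrate = roh_marker_callrate,
              roh_individual_callrate = roh_individual_callrate,
              n_boot = n_boot, mode = mode,
              significance_multiplier = significance_multiplier,
              tol = tol, max_iter = max_iter, seed = as.integer(seed),
              k2_per_query = k2_per_query,
              asian_clusters = asian_clusters,
              european_clusters = european_clusters,
              n_pca_components = n_pca_components, roh = roh,
              autosome_kb = autosome_kb, exclusions = exclusions)
  for (th in c("ibd_threshold", "max_individual_missing",
               "roh_marker_callrate", "roh_individual_callrate"))
    if (cfg[[th]] < 0 || cfg[[th]] > 1)
      stop(th, " must lie in [0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full ancestry pipeline
#'
#' Executes the analysis end to end: merge reference and query panels on
#' their shared markers, apply the individual-missingness filter to the
#' queries, prune duplicate/related reference samples, build the cluster
#' allele-frequency model, estimate every query's ancestry one sample at a
#' time with locus-bootstrap standard errors, fit the unsupervised
#' two-lineage (K = 2) partition over the declared Asian/European
#' super-groups, fit a reference-only PCA and project the queries, scan for
#' runs of homozygosity under the configured call-rate filters, and compile
#' an ancestry report. A query whose estimation fails is recorded and does
#' not abort the batch. Fixed seeds give identical reports.
#'
#' @param reference A `genotype_matrix` of reference samples.
#' @param cluster_table Named vector mapping reference `sample_id` to
#'   reference cluster label.
#' @param queries A `genotype_matrix` of query samples.
#' @param metadata Optional data frame with columns `sample_id` and
#'   `island` for the island summaries.
#' @param config A [pipeline_config()].
#' @return An object of class `ancestry_report`: list with `q_matrix`,
#'   `se_matrix`, `significant`, `significance_counts`, `island_summary`,
#'   `k2` (two-lineage fractions, when super-groups are declared), `pca`
#'   (model and query scores), `roh` (profiles and group comparison),
#'   `pruning`, `qc`, `failed_queries` and `config`.
#' @export
run_full_pipeline <- function(reference, cluster_table, queries,
                              metadata = NULL, config = pipeline_config()) {
  if (is.null(cluster_table) || !length(cluster_table))
    stop("a cluster table mapping reference samples to clusters is required")
  merged <- merge_on_shared_markers(list(reference, queries))
  n_ref <- nrow(reference$dosage)
  ref_g <- merged[seq_len(n_ref), ]
  qry_g <- merged[-seq_len(n_ref), ]

  qc <- apply_callrate_filters(qry_g, config$max_individual_missing, NULL)
  qry_g <- qc$genotypes

  ibd <- estimate_pairwise_ibd(ref_g)
  pruned <- prune_duplicates_and_relatives(
    ibd, config$ibd_threshold,
    missingness = stats::setNames(sample_missingness(ref_g),
                                  ref_g$samples$sample_id))
  ref_g <- ref_g[ref_g$samples$sample_id %in% pruned$retained, ]
  panel <- reference_panel(ref_g, cluster_table[ref_g$samples$sample_id])
  clusters <- levels(panel$cluster)

  n_q <- nrow(qry_g$dosage)
  qids <- qry_g$samples$sample_id
  K <- length(clusters)
  qmat <- semat <- matrix(NA_real_, n_q, K, dimnames = list(qids, clusters))
  sig <- matrix(NA, n_q, K, dimnames = list(qids, clusters))
  failed <- character(0)
  for (i in seq_len(n_q)) {               # one query per iteration
    fit <- tryCatch(
      bootstrap_standard_errors(
        qry_g[i, ], panel, n_boot = config$n_boot,
        seed = config$seed + i, mode = config$mode,
        significance_multiplier = config$significance_multiplier,
        tol = config$tol, max_iter = config$max_iter),
      error = function(e) e)
    if (inherits(fit, "error")) { failed <- c(failed, qids[i]); next }
    qmat[i, ] <- fit$q; semat[i, ] <- fit$se; sig[i, ] <- fit$significant
  }
  ok <- !rownames(qmat) %in% failed
  sig_counts <- data.frame(
    cluster = clusters,
    n_significant = colSums(sig[ok, , drop = FALSE], na.rm = TRUE),
    n_queries = sum(ok),
    row.names = NULL)
  sig_counts$label <- paste0(sig_counts$n_significant, "/",
                             sig_counts$n_queries)

  island_summary <- if (!is.null(metadata))
    summarize_by_island(qmat[ok, , drop = FALSE], metadata,
                        exclusions = config$exclusions) else NULL

  super <- c(config$asian_clusters, config$european_clusters)
  k2 <- NULL
  if (length(config$asian_clusters) && length(config$european_clusters)) {
    sub <- panel$cluster %in% super
    ref_sub <- ref_g[which(sub), ]
    asian_ref <- panel$cluster[sub] %in% config$asian_clusters
    k2 <- fit_two_lineage(ref_sub, asian_ref, qry_g, config)
  }

  pca <- NULL
  if (length(super)) {
    sub <- which(panel$cluster %in% super)
    model <- fit_reference_pca(ref_g[sub, ], config$n_pca_components)
    pca <- list(model = model, query_scores = project_queries(model, qry_g),
                ref_clusters = as.character(panel$cluster[sub]))
  }

  roh <- run_roh_stage(ref_g, panel$cluster, qry_g, config)

  structure(list(
    q_matrix = qmat, se_matrix = semat, significant = sig,
    significance_counts = sig_counts, island_summary = island_summary,
    k2 = k2, pca = pca, roh = roh,
    pruning = pruned, qc = qc$report, failed_queries = failed,
    config = config, n_markers = ncol(qry_g$dosage)
  ), class = "ancestry_report")
}

## Unsupervised K = 2 partition of the declared Asian/European super-groups.
fit_two_lineage <- function(ref_sub, asian_ref, qry_g, config) {
  n_q <- nrow(qry_g$dosage)
  asian_frac <- function(fit, query_rows) {
    ref_rows <- seq_len(length(asian_ref))
    asian_col <- which.max(colMeans(fit$Q[ref_rows, , drop = FALSE][asian_ref,
                                                                    , drop = FALSE]))
    fit$Q[query_rows, asian_col]
  }
  if (config$k2_per_query) {
    out <- numeric(n_q)
    for (i in seq_len(n_q)) {
      G <- rbind(ref_sub$dosage, qry_g$dosage[i, , drop = FALSE])
      fit <- unsupervised_fit(G, 2, seed = config$seed + i, tol = config$tol,
                              max_iter = config$max_iter, n_restarts = 1)
      out[i] <- asian_frac(fit, nrow(G))
    }
  } else {
    G <- rbind(ref_sub$dosage, qry_g$dosage)
    fit <- unsupervised_fit(G, 2, seed = config$seed, tol = config$tol,
                            max_iter = config$max_iter, n_restarts = 1)
    out <- asian_frac(fit, nrow(ref_sub$dosage) + seq_len(n_q))
  }
  data.frame(sample_id = qry_g$samples$sample_id, q_asian = out,
             q_european = 1 - out, stringsAsFactors = FALSE)
}

run_roh_stage <- function(ref_g, ref_clusters, qry_g, config) {
  scan_one <- function(g) {
    f <- apply_callrate_filters(
      g, 1 - config$roh_individual_callrate, config$roh_marker_callrate)
    segs <- do.call(detect_roh_segments, c(list(f$genotypes), config$roh))
    summarize_froh(segs, f$genotypes$samples$sample_id, config$autosome_kb)
  }
  qprof <- scan_one(qry_g)
  rprof <- scan_one(ref_g)
  labels <- c(stats::setNames(rep("reference", nrow(rprof)), rprof$sample_id),
              stats::setNames(rep("query", nrow(qprof)), qprof$sample_id))
  cl <- stats::setNames(as.character(ref_clusters), ref_g$samples$sample_id)
  labels[names(cl)] <- cl
  both <- rbind(rprof, qprof)
  list(profiles = both,
       comparison = compare_groups(both, labels[both$sample_id]))
}

#' @export
print.ancestry_report <- function(x, digits = 3, ...) {
  n_q <- nrow(x$q_matrix)
  cat("<ancestry_report> ", n_q, " queries x ", ncol(x$q_matrix),
      " reference clusters (", x$n_markers, " markers)\n", sep = "")
  cat("  mean ancestry: ",
      paste0(colnames(x$q_matrix), "=",
             format(round(colMeans(x$q_matrix, na.rm = TRUE), digits)),
             collapse = ", "), "\n", sep = "")
  if (length(x$failed_queries))
    cat("  failed queries: ", length(x$failed_queries), "\n", sep = "")
  invisible(x)
}

#' Summarize ancestry estimates by island
#'
#' Per-island arithmetic means of the ancestry vectors, plus min-max
#' ancestry ranges per cluster computed twice: over all island members and
#' after removing the configured exclusion list. Samples with more than
#' `outlier_threshold` ancestry from any single cluster are flagged as
#' candidate outliers (e.g. escaped purebred domestics). Samples without
#' island metadata are grouped as `"unassigned"` with a warning.
#'
#' @param q_matrix Numeric matrix of ancestry vectors, rows named by
#'   sample id, columns by cluster.
#' @param metadata Data frame with columns `sample_id` and `island`.
#' @param exclusions Sample ids excluded from the post-exclusion ranges.
#' @param outlier_threshold Single-cluster ancestry above which a sample is
#'   flagged (default 0.9).
#' @return List with `means` (island x cluster matrix, plus `n`), `ranges`
#'   (data frame: island, cluster, min/max over all samples and after
#'   exclusions) and `outliers` (flagged sample ids).
#' @export
summarize_by_island <- function(q_matrix, metadata, exclusions = character(),
                                outlier_threshold = 0.9) {
  q_matrix <- as.matrix(q_matrix)
  island <- metadata$island[match(rownames(q_matrix), metadata$sample_id)]
  if (anyNA(island)) {
    warning(sum(is.na(island)), " sample(s) lack island metadata; ",
            "grouped as 'unassigned'")
    island[is.na(island)] <- "unassigned"
  }
  isl <- factor(island)
  counts <- tabulate(isl, nlevels(isl))
  means <- rowsum(q_matrix, isl) / counts
  rng <- do.call(rbind, lapply(levels(isl), function(iv) {
    rows <- which(isl == iv)
    keep <- rows[!rownames(q_matrix)[rows] %in% exclusions]
    do.call(rbind, lapply(colnames(q_matrix), function(cl) {
      data.frame(island = iv, cluster = cl,
                 min = min(q_matrix[rows, cl]),
                 max = max(q_matrix[rows, cl]),
                 min_after_exclusion = if (length(keep))
                   min(q_matrix[keep, cl]) else NA_real_,
                 max_after_exclusion = if (length(keep))
                   max(q_matrix[keep, cl]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  outliers <- rownames(q_matrix)[apply(q_matrix, 1, max) > outlier_threshold]
  list(means = cbind(as.data.frame(means), n = counts), ranges = rng,
       outliers = outliers)
}

#' Export an ancestry report to files
#'
#' Writes the Q-matrix (ancestry proportions, bootstrap SEs and
#' significance flags) as CSV, the island summary as CSV, the significance
#' counts as CSV, a JSON run manifest (effective configuration, seed and
#' package version) and a human-readable markdown summary.
#'
#' @param report An `ancestry_report` from [run_full_pipeline()].
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json", "markdown")`.
#' @return Named character vector of the files written, invisibly.
#' @export
export_report <- function(report, dir,
                          formats = c("csv", "json", "markdown")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  qdf <- data.frame(sample_id = rownames(report$q_matrix),
                    report$q_matrix,
                    stats::setNames(as.data.frame(report$se_matrix),
                                    paste0("se_", colnames(report$se_matrix))),
                    stats::setNames(as.data.frame(report$significant),
                                    paste0("sig_", colnames(report$significant))),
                    row.names = NULL, check.names = FALSE)
  if ("csv" %in% formats) {
    f <- file.path(dir, "q_matrix.csv")
    utils::write.csv(qdf, f, row.names = FALSE)
    written["q_matrix"] <- f
    f <- file.path(dir, "significance_counts.csv")
    utils::write.csv(report$significance_counts, f, row.names = FALSE)
    written["significance_counts"] <- f
    if (!is.null(report$island_summary)) {
      f <- file.path(dir, "island_means.csv")
      utils::write.csv(cbind(island = rownames(report$island_summary$means),
                             report$island_summary$means), f,
                       row.names = FALSE)
      written["island_means"] <- f
      f <- file.path(dir, "island_ranges.csv")
      utils::write.csv(report$island_summary$ranges, f, row.names = FALSE)
      written["island_ranges"] <- f
    }
    if (!is.null(report$roh)) {
      f <- file.path(dir, "roh_profiles.csv")
      utils::write.csv(as.data.frame(report$roh$profiles), f,
                       row.names = FALSE)
      written["roh_profiles"] <- f
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "manifest.json")
    cfg <- unclass(report$config)
    jsonlite::write_json(
      list(config = cfg,
           package_version = as.character(utils::packageVersion("feralmix")),
           n_markers = report$n_markers,
           n_queries = nrow(report$q_matrix),
           failed_queries = report$failed_queries),
      f, auto_unbox = TRUE, digits = NA, null = "null")
    written["manifest"] <- f
  }
  if ("markdown" %in% formats) {
    f <- file.path(dir, "report.md")
    lines <- c("# Ancestry report", "",
               paste0("Queries: ", nrow(report$q_matrix), "; reference clusters: ",
                      ncol(report$q_matrix), "; markers: ", report$n_markers), "",
               "## Mean ancestry by cluster", "",
               paste0("- ", colnames(report$q_matrix), ": ",
                      sprintf("%.4f", colMeans(report$q_matrix, na.rm = TRUE)),
                      " (significant for ", report$significance_counts$label,
                      " queries)"))
    if (!is.null(report$island_summary)) {
      m <- report$island_summary$means
      hdr <- paste0("| island | n | ",
                    paste(setdiff(colnames(m), "n"), collapse = " | "), " |")
      sep <- gsub("[^|]", "-", hdr)
      rows <- vapply(seq_len(nrow(m)), function(i)
        paste0("| ", rownames(m)[i], " | ", m$n[i], " | ",
               paste(sprintf("%.4f", unlist(m[i, setdiff(colnames(m), "n")])),
                     collapse = " | "), " |"), "")
      lines <- c(lines, "", "## Island summary", "", hdr, sep, rows)
    }
    writeLines(lines, f)
    written["markdown"] <- f
  }
  invisible(written)
}
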