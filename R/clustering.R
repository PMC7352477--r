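#' Row-wise Z-score transform
#'
#' Per transcript: \code{(x - mean) / sd} with the sample (n-1) standard
#' deviation; constant transcripts map to an all-zero row. This is the
#' matrix displayed in expression heatmaps.
#'
#' @param norm A \code{tep_norm} object (or a plain numeric matrix).
#' @return Numeric matrix of the same shape.
#' @export
zscore_rows <- function(norm) {
  v <- if (inherits(norm, "tep_norm")) norm$values else norm
  if (ncol(v) < 2) stop("need at least 2 samples to Z-score")
  mu <- rowMeans(v)
  sd_ <- sqrt(row_vars(v))
  z <- (v - mu) / ifelse(sd_ > 0, sd_, 1)
  z[sd_ == 0, ] <- 0
  z
}

#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of samples with distance
#' \code{1 - Pearson correlation} between Z-scored columns and complete
#' linkage, cut into exactly two clusters. Deterministic.
#'
#' @param z Z-scored matrix (transcripts x samples), as from
#'   [zscore_rows()]; >= 4 samples.
#' @return List of class \code{"cluster_result"}: \code{tree} (hclust),
#'   \code{cut} (named integer cluster 1/2 per sample), \code{dist}
#'   (the distance matrix), \code{order} (leaf order).
#' @export
hier_cluster <- function(z) {
  if (ncol(z) < 4) stop("need at least 4 samples to cluster")
  cors <- suppressWarnings(stats::cor(z))
  cors[is.na(cors)] <- 0
  diag(cors) <- 1
  d <- stats::as.dist(1 - cors)
  tree <- stats::hclust(d, method = "complete")
  cut <- stats::cutree(tree, k = 2)
  structure(list(tree = tree, cut = cut, dist = d, order = tree$order),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Hierarchical 2-cut of %d samples: cluster sizes %s\n",
              length(x$cut), paste(table(x$cut), collapse = "/")))
  invisible(x)
}

#' Cluster-group association p-value
#'
#' Two-sided Fisher exact test on the 2x2 table of cluster membership
#' against class label — how strongly the unsupervised 2-cut separates
#' sarcoma from control. An empty cluster yields p = 1 with a warning.
#'
#' @param cut Integer/character 2-cluster assignment per sample.
#' @param labels Class labels per sample.
#' @return The two-sided Fisher exact p-value.
#' @export
cluster_association_p <- function(cut, labels) {
  tab <- table(factor(cut), factor(labels))
  if (nrow(tab) < 2 || any(rowSums(tab) == 0)) {
    warning("a cluster is empty; association p = 1")
    return(1)
  }
  if (ncol(tab) < 2) stop("need 2 classes for the association test")
  stats::fisher.test(tab)$p.value
}

#' Swarm-tuned FDR threshold for the clustering heatmap panel
#'
#' Particle-swarm search over the FDR threshold alone (the other three
#' selection parameters stay at their defaults) with fitness
#' \code{-log10} of the cluster-group association p-value of the resulting
#' panel's unsupervised 2-cut. Published default budget: 200 particles for
#' 12 iterations. One particle is pinned to FDR = 0.05 so the search never
#' does worse than the default selection.
#'
#' @param norm \code{tep_norm} of the samples to cluster.
#' @param labels Class labels (used only in the association fitness, not in
#'   the clustering itself).
#' @param fdr_bounds Search range of the FDR threshold.
#' @param n_particles,n_iterations Swarm budget (published defaults 200, 12).
#' @param libsize_cor_lo Fixed library-size correlation floor.
#' @param seed Integer seed.
#' @return List of class \code{"cluster_panel"}: \code{transcripts} (best
#'   panel), \code{fdr} (chosen threshold), \code{p} (association p-value),
#'   \code{cluster} (the [hier_cluster()] result), \code{z} (Z-matrix of the
#'   panel), \code{trace}.
#' @export
pso_cluster_panel <- function(norm, labels, fdr_bounds = c(1e-5, 1.0),
                              n_particles = 200L, n_iterations = 12L,
                              libsize_cor_lo = -0.1, seed = 1L) {
  kept <- libsize_correlation_filter(norm, lo = libsize_cor_lo, hi = 1.0)
  sub <- subset_norm(norm, transcripts = kept)
  diff_tab <- anova_per_transcript(sub, labels)

  panel_for <- function(fdr) select_by_fdr(diff_tab, fdr)
  fitness_raw <- function(fdr) {
    sel <- panel_for(fdr)
    if (length(sel) < 2) return(0)
    cl <- hier_cluster(zscore_rows(subset_norm(sub, transcripts = sel)))
    -log10(cluster_association_p(cl$cut, labels))
  }
  # swarm flies in 1-D; reuse the 4-D machinery with frozen extra dims
  bounds <- list(libsize_cor = c(libsize_cor_lo, libsize_cor_lo),
                 fdr = fdr_bounds, cor = c(0, 0),
                 n_ranked = c(nrow(sub$values), nrow(sub$values)))
  state <- init_swarm(bounds, n_particles, derive_seed(seed, "cluster-swarm"))
  scale_fit <- function(raw) raw / (1 + raw)  # monotone map into [0, 1)
  fitness_fn <- function(params) scale_fit(fitness_raw(params$fdr_threshold))
  trace <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    evaluated <- state$position[, 2]
    state <- swarm_step(state, fitness_fn)
    trace[[it]] <- data.frame(iteration = it, particle = seq_len(n_particles),
                              fdr = evaluated, fitness = state$last_fitness)
  }
  best_fdr <- state$gbest[2]
  sel <- panel_for(best_fdr)
  z <- zscore_rows(subset_norm(sub, transcripts = sel))
  cl <- hier_cluster(z)
  structure(list(transcripts = sel, fdr = best_fdr,
                 p = cluster_association_p(cl$cut, labels),
                 cluster = cl, z = z, trace = do.call(rbind, trace)),
            class = "cluster_panel")
}

#' Export the ordered heatmap matrix and dendrogram
#'
#' Writes the Z-scored matrix with samples in dendrogram leaf order (TSV)
#' and the sample tree in Newick format; rendering is left to standard
#' heatmap tooling.
#'
#' @param cluster_panel A [pso_cluster_panel()] result (or any list with
#'   \code{z} and \code{cluster}).
#' @param path_matrix TSV output path for the ordered Z-matrix.
#' @param path_tree Optional Newick output path for the sample dendrogram.
#' @return Invisibly, \code{path_matrix}.
#' @export
export_heatmap <- function(cluster_panel, path_matrix, path_tree = NULL) {
  z <- cluster_panel$z[, cluster_panel$cluster$order, drop = FALSE]
  df <- data.frame(transcript_id = rownames(z), z, check.names = FALSE)
  utils::write.table(df, path_matrix, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_tree)) {
    dend <- stats::as.dendrogram(cluster_panel$cluster$tree)
    writeLines(dendrogram_newick(dend), path_tree)
  }
  invisible(path_matrix)
}

dendrogram_newick <- function(node) {
  render <- function(nd) {
    if (is.leaf(nd)) return(attr(nd, "label"))
    paste0("(", paste(vapply(nd, render, character(1)), collapse = ","), ")")
  }
  paste0(render(node), ";")
}
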