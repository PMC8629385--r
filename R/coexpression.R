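#' Select dynamically expressed genes by coefficient of variation
#'
#' Keeps genes whose CV (sample sd over mean across time points) strictly
#' exceeds `cv_min` — the variance filter applied before co-expression
#' clustering. Order of the input is preserved.
#'
#' @param stats a [gene_stats()] result.
#' @param cv_min CV threshold (default 0.5; strict inequality, so CV = 0.5
#'   exactly is excluded).
#' @return character vector of gene ids.
#' @export
select_high_cv <- function(stats, cv_min = 0.5) {
  stopifnot(inherits(stats, "gene_stats"))
  stats$summary$gene_id[stats$summary$cv > cv_min]
}

#' Figure of merit for choosing the number of k-means clusters
#'
#' Leave-one-condition-out predictive error of a clustering: for each k and
#' each left-out column, genes are clustered on the remaining columns and
#' the figure of merit is the root-mean-square deviation of the left-out
#' column's values from their cluster means, summed over all left-out
#' columns and multiplied by the small-cluster adjustment
#' `sqrt(n / (n - k))`. A flattening of the curve marks the point where
#' extra clusters stop predicting unseen conditions; the suggested k is
#' the elbow, i.e. the interior k maximizing the second difference of the
#' curve.
#'
#' @param z numeric matrix of gene Z-score trajectories (genes x columns,
#'   typically both conditions' time points).
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart restarts per k-means fit (default 5).
#' @return data.frame `k, fom` with attribute `suggested_k`.
#' @export
figure_of_merit <- function(z, k_range = 2:10, seed = 1, nstart = 5) {
  z <- as.matrix(z)
  n <- nrow(z); p <- ncol(z)
  if (p < 3L) stopf("need at least 3 columns for leave-one-out FOM")
  if (max(k_range) >= n) stopf("k (%d) must be smaller than the number of genes (%d)",
                               max(k_range), n)
  fom <- with_seed(seed, vapply(k_range, function(k) {
    acc <- 0
    for (j in seq_len(p)) {
      cl <- if (k == 1L) rep(1L, n) else
        kmeans(z[, -j, drop = FALSE], centers = k, nstart = nstart,
               iter.max = 50)$cluster
      mu <- ave(z[, j], cl)
      acc <- acc + sqrt(mean((z[, j] - mu)^2))
    }
    acc * sqrt(n / (n - k))
  }, 0))
  out <- data.frame(k = k_range, fom = fom)
  sugg <- if (length(k_range) >= 3L) {
    d2 <- diff(fom, differences = 2)        # fom[k-1] - 2 fom[k] + fom[k+1]
    k_range[which.max(d2) + 1L]
  } else k_range[which.min(fom)]
  attr(out, "suggested_k") <- sugg
  out
}

#' k-means co-expression modules on Z-score trajectories
#'
#' Clusters gene Z-score trajectories with `stats::kmeans` (Hartigan-Wong,
#' `nstart` random restarts under a fixed seed; the restart with the
#' smallest within-cluster sum of squares wins). Module ids are relabelled
#' 1..k by decreasing module size so output is stable, and a per-module
#' median Z trajectory is computed.
#'
#' @param z numeric matrix of gene Z scores (genes x columns), rows named
#'   by gene id.
#' @param k number of modules.
#' @param seed RNG seed (recorded in the result).
#' @param nstart number of restarts (default 10).
#' @param biotype,tf optional per-gene annotations for module tallies.
#' @return object of class `module_assignment`: data.frame `assignment`
#'   (`gene_id, module`), matrix `median_trajectory` (k x columns),
#'   `tallies` (genes/TFs/lincRNAs per module), `tot_withinss`, `k`, `seed`.
#' @export
kmeans_modules <- function(z, k, seed = 1, nstart = 10,
                           biotype = NULL, tf = NULL) {
  z <- as.matrix(z)
  if (nrow(z) == 0L) stopf("empty input matrix")
  if (!is_count(k) || k > nrow(z)) stopf("k must be a count <= number of genes")
  km <- with_seed(seed, kmeans(z, centers = k, nstart = nstart, iter.max = 100))
  # relabel by decreasing size (ties: original label) for stable output
  sizes <- km$size
  relabel <- order(order(-sizes, seq_along(sizes)))
  cl <- relabel[km$cluster]
  med <- t(vapply(seq_len(k), function(m)
    apply(z[cl == m, , drop = FALSE], 2L, median), numeric(ncol(z))))
  rownames(med) <- paste0("M", seq_len(k))
  tallies <- data.frame(module = seq_len(k),
                        n_genes = as.vector(table(factor(cl, seq_len(k)))))
  if (!is.null(biotype)) {
    tallies$n_lincRNA <- vapply(seq_len(k), function(m)
      sum(biotype[cl == m] == "lincRNA"), 0L)
  }
  if (!is.null(tf)) {
    tallies$n_tf <- vapply(seq_len(k), function(m) sum(tf[cl == m]), 0L)
  }
  structure(list(assignment = data.frame(gene_id = rownames(z), module = cl,
                                         row.names = NULL,
                                         stringsAsFactors = FALSE),
                 median_trajectory = med, tallies = tallies,
                 tot_withinss = km$tot.withinss, k = k, seed = seed),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d genes in %d modules (seed %d, SSE %.4g)\n",
              nrow(x$assignment), x$k, x$seed, x$tot_withinss))
  invisible(x)
}
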