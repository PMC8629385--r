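#' Linkage-disequilibrium decay in distance bins
#'
#' Computes composite (genotype) r-squared — the squared Pearson
#' correlation of alt-allele dosage vectors, pairwise-complete over
#' missing genotypes — for every intra-chromosome SNP pair at distance
#' at most `max_dist`, then averages r-squared within `bin_bp`-wide
#' distance bins. Pairs involving a SNP monomorphic in the population
#' (r-squared undefined) are skipped and counted. Genotype r-squared is
#' used because phasing is out of scope; it tracks haplotype r-squared
#' closely at these sample sizes.
#'
#' @param g a `genotype_matrix`.
#' @param pop population label.
#' @param max_dist maximum pair distance in bp (default 300000).
#' @param bin_bp bin width in bp (default 100).
#' @return data.frame `bin_lo, bin_hi, mean_r2, n_pairs` (bins are
#'   `(bin_lo, bin_hi]`), with attribute `n_skipped` (monomorphic pairs).
#' @export
ld_decay <- function(g, pop, max_dist = 300000, bin_bp = 100) {
  stopifnot(inherits(g, "genotype_matrix"))
  cols <- names(g$pop)[g$pop == pop]
  if (length(cols) < 4L) stopf("population '%s' needs at least 4 individuals", pop)
  n_bins <- ceiling(max_dist / bin_bp)
  sum_r2 <- cnt <- numeric(n_bins)
  skipped <- 0L
  block <- 1000L
  for (ch in unique(g$chrom)) {
    sel <- which(g$chrom == ch)
    pos <- g$pos[sel]
    d <- t(g$dosage[sel, cols, drop = FALSE])  # individuals x SNPs
    ns <- length(sel)
    for (lo in seq(1L, ns, by = block)) {
      hi <- min(lo + block - 1L, ns)
      rng_hi <- min(ns, findInterval(pos[hi] + max_dist, pos))
      ii <- lo:hi
      jj <- lo:rng_hi
      r <- suppressWarnings(cor(d[, ii, drop = FALSE], d[, jj, drop = FALSE],
                                use = "pairwise.complete.obs"))
      dist <- outer(pos[ii], pos[jj], function(a, b) b - a)
      usable <- dist > 0 & dist <= max_dist
      r2 <- r[usable]^2
      bin <- ceiling(dist[usable] / bin_bp)
      na <- is.na(r2)
      skipped <- skipped + sum(na)
      if (any(!na)) {
        tab_s <- tapply(r2[!na], bin[!na], sum)
        tab_n <- tapply(r2[!na], bin[!na], length)
        idx <- as.integer(names(tab_s))
        sum_r2[idx] <- sum_r2[idx] + tab_s
        cnt[idx] <- cnt[idx] + tab_n
      }
    }
  }
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1) * bin_bp,
                    bin_hi = seq_len(n_bins) * bin_bp,
                    mean_r2 = ifelse(cnt > 0, sum_r2 / cnt, NA_real_),
                    n_pairs = as.integer(cnt))
  attr(out, "n_skipped") <- skipped
  out
}

#' Genotype principal component analysis
#'
#' Standard genotype PCA: per-SNP centering by twice the allele frequency
#' and scaling by `sqrt(2p(1-p))` (the drift-variance normalization),
#' missing genotypes imputed at the mean (zero after centering),
#' monomorphic and all-missing SNPs dropped, then eigendecomposition of
#' the individual x individual covariance matrix.
#'
#' @param g a `genotype_matrix`.
#' @param n_components number of components to return (default 2).
#' @return list with `scores` (data.frame: individual, pop, PC1..),
#'   `eigenvalues`, `var_explained`, and `n_snps_used`.
#' @export
genotype_pca <- function(g, n_components = 2) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$dosage) < 3L) stopf("need at least 3 individuals")
  d <- g$dosage
  p <- rowMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  x <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  cov_ind <- crossprod(x) / nrow(x)
  eig <- eigen(cov_ind, symmetric = TRUE)
  k <- min(n_components, ncol(cov_ind))
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = data.frame(individual = colnames(g$dosage),
                           pop = unname(g$pop[colnames(g$dosage)]),
                           scores, stringsAsFactors = FALSE),
       eigenvalues = eig$values,
       var_explained = eig$values[seq_len(k)] / sum(pmax(eig$values, 0)),
       n_snps_used = nrow(d))
}

# 1 - identity-by-state distance over jointly called sites:
# mean(|g_i - g_j|) / 2. Errors if a pair shares no called site.
ibs_dist <- function(dosage) {
  n <- ncol(dosage)
  dm <- matrix(0, n, n, dimnames = list(colnames(dosage), colnames(dosage)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(dosage[, i]) & !is.na(dosage[, j])
    if (!any(ok))
      stopf("individuals '%s' and '%s' share no called site",
            colnames(dosage)[i], colnames(dosage)[j])
    dm[i, j] <- dm[j, i] <- mean(abs(dosage[ok, i] - dosage[ok, j])) / 2
  }
  stats::as.dist(dm)
}

# Clamp negative branch lengths to zero, transferring the excess onto the
# sister edge(s) at the same parent node so leaf-to-leaf paths through the
# parent keep their length.
clamp_negative_edges <- function(phy) {
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    excess <- -phy$edge.length[e]
    phy$edge.length[e] <- 0
    sisters <- which(phy$edge[, 1] == phy$edge[e, 1])
    sisters <- setdiff(sisters, e)
    if (length(sisters))
      phy$edge.length[sisters] <- phy$edge.length[sisters] +
        excess / length(sisters)
  }
  phy
}

#' Neighbor-joining tree of individuals from allele-sharing distances
#'
#' Builds the Saitou-Nei neighbor-joining tree on the pairwise
#' 1 - identity-by-state distance (proportion of jointly called alleles
#' that differ). Negative branch lengths are clamped to zero with the
#' excess transferred to the sister edge. Optional bootstrap over SNP
#' columns attaches percentage support to internal edges (node labels).
#' On any additive distance matrix, NJ recovers the generating topology
#' and branch lengths exactly.
#'
#' @param g a `genotype_matrix`, or a symmetric distance matrix / `dist`
#'   (in which case IBS computation is skipped).
#' @param bootstrap number of bootstrap replicates over SNPs (0 = none;
#'   only available when `g` is a `genotype_matrix`).
#' @param seed RNG seed for the bootstrap.
#' @return an [ape::phylo] tree; node labels carry bootstrap percentages
#'   when requested.
#' @export
nj_tree <- function(g, bootstrap = 0, seed = 1) {
  from_geno <- inherits(g, "genotype_matrix")
  d <- if (from_geno) ibs_dist(g$dosage) else stats::as.dist(g)
  if (attr(d, "Size") < 3L) stopf("need at least 3 individuals")
  phy <- clamp_negative_edges(ape::nj(d))
  if (bootstrap > 0) {
    if (!from_geno) stopf("bootstrap needs genotype data, not a distance matrix")
    x <- t(g$dosage)  # individuals x SNPs; boot.phylo resamples columns
    bp <- with_seed(seed,
      ape::boot.phylo(phy, x,
                      function(m) clamp_negative_edges(ape::nj(ibs_dist(t(m)))),
                      B = bootstrap, quiet = TRUE))
    phy$node.label <- round(100 * bp / bootstrap)
  }
  phy
}
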