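#' Two-group differential expression by Welch's t-test on log2(x + 1)
#'
#' Expression is log2(x + 1)-transformed; the fold change is the difference
#' of group means on that scale (group A minus group B); P-values come from
#' Welch's unequal-variance t-test and are Benjamini-Hochberg adjusted
#' across all tested genes. Genes below `expr_floor` in every column of
#' both groups are excluded before testing (their count is recorded in the
#' `n_floor_excluded` attribute). Groups with zero variance receive a
#' variance floor equal to the 5th percentile of the positive per-gene
#' pooled variances, so perfectly separated genes get finite statistics;
#' genes identical in both groups get FC = 0 and P = 1.
#'
#' @param m an `expr_matrix`, or a plain numeric abundance matrix, or a
#'   list of `expr_matrix` objects whose columns are combined.
#' @param groupA_cols,groupB_cols column names (or indices) of the two
#'   groups; each needs at least 2 columns.
#' @param lfc_cut,fdr_cut significance thresholds: `|log2 FC| >= lfc_cut`
#'   and `FDR <= fdr_cut` (defaults 1 and 0.05).
#' @param expr_floor abundance floor for the pre-test expression filter.
#' @return data.frame of class `de_result` with columns `gene_id, log2FC,
#'   pvalue, fdr, direction, significant`.
#' @export
two_group_de <- function(m, groupA_cols, groupB_cols, lfc_cut = 1,
                         fdr_cut = 0.05, expr_floor = 0.1) {
  x <- combine_expr(m)
  ga <- resolve_cols(x, groupA_cols, "group A")
  gb <- resolve_cols(x, groupB_cols, "group B")
  if (length(ga) < 2L) stopf("group A has %d column(s); need at least 2", length(ga))
  if (length(gb) < 2L) stopf("group B has %d column(s); need at least 2", length(gb))
  keep <- apply(x[, c(ga, gb), drop = FALSE], 1L, max) > expr_floor
  n_floor <- sum(!keep)
  y <- log2(x[keep, , drop = FALSE] + 1)
  a <- y[, ga, drop = FALSE]; b <- y[, gb, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  pooled <- (va + vb) / 2
  floor_v <- if (any(pooled > 0))
    quantile(pooled[pooled > 0], 0.05, names = FALSE) else 1e-8
  if (!is.finite(floor_v) || floor_v <= 0) floor_v <- 1e-8
  va_f <- ifelse(va == 0, floor_v, va)
  vb_f <- ifelse(vb == 0, floor_v, vb)
  se2 <- va_f / na + vb_f / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va_f / na)^2 / (na - 1) + (vb_f / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[ma == mb] <- 1  # identical means: null by construction
  fdr <- p.adjust(p, method = "BH")
  fc <- ma - mb
  res <- data.frame(gene_id = rownames(y), log2FC = fc, pvalue = p, fdr = fdr,
                    direction = ifelse(fc > 0, "up", ifelse(fc < 0, "down", "none")),
                    significant = abs(fc) >= lfc_cut & fdr <= fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "n_floor_excluded") <- n_floor
  class(res) <- c("de_result", class(res))
  res
}

# Accept an expr_matrix, a list of them, or a bare matrix.
combine_expr <- function(m) {
  if (inherits(m, "expr_matrix")) return(m$expr)
  if (is.list(m) && all(vapply(m, inherits, TRUE, "expr_matrix"))) {
    ids <- Reduce(intersect, lapply(m, function(e) rownames(e$expr)))
    return(do.call(cbind, lapply(m, function(e) e$expr[ids, , drop = FALSE])))
  }
  as.matrix(m)
}

resolve_cols <- function(x, cols, what) {
  if (is.character(cols)) {
    bad <- setdiff(cols, colnames(x))
    if (length(bad)) stopf("%s column '%s' not found", what, bad[1L])
    return(match(cols, colnames(x)))
  }
  as.integer(cols)
}

#' Phase-specific genes: one phase versus the other three
#'
#' For each developmental phase, runs [two_group_de()] of that phase's
#' columns (both conditions pooled by default) against all remaining
#' columns and keeps genes significantly *higher* in the phase
#' (FDR <= `fdr_cut` and log2 FC >= `lfc_cut`, i.e. linear fold change >= 2
#' at the default). A gene passing for several phases is assigned only to
#' the phase with the largest fold change, so the per-phase lists are
#' disjoint.
#'
#' @param mA,mB the two conditions' `expr_matrix` objects (set `mB = NULL`
#'   for a single-condition analysis).
#' @param fdr_cut,lfc_cut thresholds (defaults 0.05 and 1).
#' @return named list of per-phase gene-id vectors, with the full
#'   assignment table in attribute `table`.
#' @export
phase_specific_genes <- function(mA, mB = NULL, fdr_cut = 0.05, lfc_cut = 1) {
  mats <- if (is.null(mB)) list(mA) else list(mA, mB)
  x <- combine_expr(mats)
  phase_by_col <- unlist(lapply(mats, function(m) m$meta$phase))
  phases <- rle(mats[[1]]$meta$phase)$values
  res <- list()
  for (ph in phases) {
    in_ph <- which(phase_by_col == ph)
    if (length(in_ph) < 2L)
      stopf("phase '%s' has fewer than 2 columns", ph)
    de <- two_group_de(x, in_ph, setdiff(seq_len(ncol(x)), in_ph),
                       lfc_cut = lfc_cut, fdr_cut = fdr_cut)
    hit <- de[de$significant & de$log2FC >= lfc_cut, c("gene_id", "log2FC")]
    if (nrow(hit)) hit$phase <- ph
    res[[ph]] <- hit
  }
  tab <- do.call(rbind, res[vapply(res, nrow, 0L) > 0])
  if (is.null(tab)) tab <- data.frame(gene_id = character(), log2FC = numeric(),
                                      phase = character())
  # enforce phase uniqueness: keep the phase with the larger fold change
  tab <- tab[order(tab$gene_id, -tab$log2FC), ]
  tab <- tab[!duplicated(tab$gene_id), ]
  rownames(tab) <- NULL
  out <- lapply(setNames(phases, phases),
                function(ph) sort(tab$gene_id[tab$phase == ph]))
  attr(out, "table") <- tab
  out
}

#' Test for different developmental trajectories between two conditions
#'
#' Per gene, fits the linear model
#' `log2(x+1) ~ condition + time_index + condition:time_index` over both
#' conditions' time courses (time as ordinal index 1..T) and F-tests the
#' interaction term against the nested no-interaction model. Genes whose
#' trajectories differ in slope between conditions are flagged at
#' BH-adjusted FDR <= `fdr_cut`.
#'
#' @param mA,mB `expr_matrix` objects sharing time points.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return data.frame of class `de_result`: `gene_id, fstat, df1, df2,
#'   pvalue, fdr, significant`.
#' @export
trajectory_interaction_test <- function(mA, mB, fdr_cut = 0.05) {
  shared <- intersect(mA$meta$timepoint, mB$meta$timepoint)
  if (length(shared) < 4L)
    stopf("need at least 4 shared time points, found %d", length(shared))
  ids <- intersect(rownames(mA$expr), rownames(mB$expr))
  ia <- match(shared, mA$meta$timepoint); ib <- match(shared, mB$meta$timepoint)
  y <- cbind(log2(mA$expr[ids, ia, drop = FALSE] + 1),
             log2(mB$expr[ids, ib, drop = FALSE] + 1))
  tt <- length(shared)
  cond <- rep(c(0, 1), each = tt)
  tind <- rep(seq_len(tt), 2)
  x_full <- cbind(1, cond, tind, cond * tind)
  x_red <- x_full[, 1:3]
  rss <- function(x) {
    q <- qr.Q(qr(x))
    rowSums((y - (y %*% q) %*% t(q))^2)
  }
  rss_f <- rss(x_full); rss_r <- rss(x_red)
  df2 <- 2 * tt - ncol(x_full)
  fstat <- pmax(rss_r - rss_f, 0) / (rss_f / df2)
  p <- pf(fstat, 1, df2, lower.tail = FALSE)
  p[rss_f <= .Machine$double.eps * rowSums(y^2) &
      (rss_r - rss_f) <= .Machine$double.eps * rowSums(y^2)] <- 1
  fdr <- p.adjust(p, method = "BH")
  res <- data.frame(gene_id = ids, fstat = fstat, df1 = 1, df2 = df2,
                    pvalue = p, fdr = fdr, significant = fdr <= fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", class(res))
  res
}
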