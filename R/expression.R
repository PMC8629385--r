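#' Construct an expression matrix object
#'
#' The central container for one condition's gene x time-point abundance
#' grid (RPKM for genes/lincRNAs, TPM for miRNAs) together with per-gene
#' biotypes and the ordered time-point metadata.
#'
#' @param expr numeric matrix, genes x time points, nonnegative. Row names
#'   are gene ids; column names are `<condition>_<timepoint>`.
#' @param biotype character vector per gene, one of `"pcg"`, `"lincRNA"`,
#'   `"miRNA"`.
#' @param condition single condition label (e.g. a breed).
#' @param meta data.frame with columns `timepoint`, `day_numeric`, `phase`,
#'   in column order of `expr`.
#' @param tf logical per gene: transcription-factor flag.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(expr, biotype, condition, meta,
                              tf = rep(FALSE, nrow(expr))) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expression matrix needs gene ids as row names")
  if (anyDuplicated(rownames(expr)))
    stopf("duplicate gene id: %s", rownames(expr)[duplicated(rownames(expr))][1L])
  if (any(expr < 0, na.rm = TRUE)) stopf("negative abundance values are not allowed")
  if (length(biotype) != nrow(expr)) stopf("biotype length != number of genes")
  if (nrow(meta) != ncol(expr))
    stopf("metadata has %d time points but matrix has %d columns",
          nrow(meta), ncol(expr))
  want <- paste0(condition, "_", meta$timepoint)
  if (is.null(colnames(expr))) colnames(expr) <- want
  if (!identical(colnames(expr), want)) {
    if (!all(want %in% colnames(expr)))
      stopf("column '%s' absent from the expression matrix",
            setdiff(want, colnames(expr))[1L])
    expr <- expr[, want, drop = FALSE]  # reorder to metadata order
  }
  validate_phase_scheme(meta)
  structure(list(expr = expr, biotype = as.character(biotype),
                 tf = as.logical(tf), condition = condition, meta = meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d time points, condition '%s'\n",
              nrow(x$expr), ncol(x$expr), x$condition))
  cat(sprintf("  biotypes: %s\n",
              paste(sprintf("%s=%d", names(table(x$biotype)), table(x$biotype)),
                    collapse = ", ")))
  cat(sprintf("  phases: %s\n", paste(rle(x$meta$phase)$values, collapse = " -> ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$expr)

#' Read an expression matrix and its time-point metadata from TSV
#'
#' Expression TSV layout: columns `gene_id`, `biotype`, `tf`, then one
#' abundance column per time point named `<condition>_<timepoint>`.
#' Metadata TSV layout: `timepoint`, `day_numeric`, `phase`. Columns are
#' reordered to metadata order; duplicate gene ids, unknown columns and
#' negative abundances are rejected with named errors.
#'
#' @param expr_path path to the expression TSV.
#' @param meta_path path to the time-point metadata TSV.
#' @return An [expression_matrix()] object.
#' @export
load_expression <- function(expr_path, meta_path) {
  tab <- read_tsv(expr_path)
  meta <- read_tsv(meta_path)
  need <- c("gene_id", "biotype")
  if (!all(need %in% names(tab)))
    stopf("expression TSV must start with columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stopf("duplicate gene id: %s", tab$gene_id[duplicated(tab$gene_id)][1L])
  tf <- if ("tf" %in% names(tab)) as.logical(tab$tf) else rep(FALSE, nrow(tab))
  val_cols <- setdiff(names(tab), c("gene_id", "biotype", "tf"))
  cond <- unique(sub("_.*$", "", val_cols))
  if (length(cond) != 1L)
    stopf("expression columns must share one condition prefix, found: %s",
          paste(cond, collapse = ", "))
  tps <- sub("^[^_]+_", "", val_cols)
  extra <- setdiff(tps, meta$timepoint)
  if (length(extra))
    stopf("column '%s_%s' absent from metadata", cond, extra[1L])
  missing_tp <- setdiff(meta$timepoint, tps)
  if (length(missing_tp))
    stopf("metadata time point '%s' has no expression column", missing_tp[1L])
  m <- as.matrix(tab[, val_cols, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric abundance values in %s", expr_path)
  if (any(m < 0, na.rm = TRUE)) stopf("negative abundance values are not allowed")
  rownames(m) <- tab$gene_id
  expression_matrix(m, tab$biotype, cond, meta, tf = tf)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' Inverse of [load_expression()]: `load -> write -> load` is an identity.
#'
#' @param m an `expr_matrix`.
#' @param expr_path output path for the expression TSV.
#' @param meta_path optional output path for the metadata TSV.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(m, expr_path, meta_path = NULL) {
  df <- data.frame(gene_id = rownames(m$expr), biotype = m$biotype,
                   tf = m$tf, m$expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, expr_path)
  if (!is.null(meta_path)) write_tsv(m$meta, meta_path)
  invisible(expr_path)
}

#' Per-gene summary statistics: mean, sd, CV, Z scores, expressed flag
#'
#' CV is sample sd (n-1) over mean across time points; genes with zero mean
#' get CV = 0 and are flagged rather than propagating NaN. Z scores are
#' computed on the raw abundance scale within the condition (per gene across
#' time points, `(x - mean)/sd`); constant genes get Z = 0 everywhere. A
#' gene is flagged expressed when its abundance exceeds
#' `expressed_threshold` at one or more time points.
#'
#' @param m an `expr_matrix`.
#' @param expressed_threshold abundance floor (default 0.1 RPKM/TPM).
#' @return An object of class `gene_stats`: data.frame `summary` with
#'   columns `gene_id, mean, sd, cv, expressed, zero_mean`, and matrix `z`.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(5, 5, 5, 5, 1, 3, 2, 4), 2, 4, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), NULL)),
#'   biotype = c("pcg", "pcg"), condition = "A",
#'   meta = data.frame(timepoint = c("t1", "t2", "t3", "t4"),
#'                     day_numeric = 1:4, phase = "Embryonic"))
#' gene_stats(m)$summary
#' @export
gene_stats <- function(m, expressed_threshold = 0.1) {
  x <- m$expr
  if (nrow(x) == 0L) stopf("empty expression matrix")
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  zero_mean <- mu == 0
  cv <- ifelse(zero_mean, 0, s / mu)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  structure(list(
    summary = data.frame(gene_id = rownames(x), mean = mu, sd = s, cv = cv,
                         expressed = apply(x, 1L, max) > expressed_threshold,
                         zero_mean = zero_mean, row.names = NULL,
                         stringsAsFactors = FALSE),
    z = z, condition = m$condition,
    expressed_threshold = expressed_threshold), class = "gene_stats")
}

#' @export
print.gene_stats <- function(x, ...) {
  cat(sprintf("gene_stats: %d genes (%d expressed > %.3g), condition '%s'\n",
              nrow(x$summary), sum(x$summary$expressed),
              x$expressed_threshold, x$condition))
  invisible(x)
}

#' Classical MDS ordination of expression samples
#'
#' Computes pairwise Euclidean distances between samples (columns) on
#' log2(x + 1) abundances over the genes shared by all input matrices, then
#' embeds them by classical (Torgerson) multidimensional scaling. By
#' default only genes expressed (> `expressed_threshold` somewhere) in at
#' least one matrix enter the distance; set `genes = "all"` to use all
#' shared genes.
#'
#' @param matrices a single `expr_matrix` or a list of them (conditions are
#'   ordinated jointly by concatenating their columns).
#' @param dims number of output dimensions (default 2).
#' @param genes `"expressed"` (default) or `"all"`.
#' @param expressed_threshold abundance floor used when `genes = "expressed"`.
#' @return list with `points` (samples x dims coordinate matrix), `eig`
#'   (eigenvalues), and `distortion` (max absolute difference between input
#'   and embedded distances).
#' @export
classical_mds <- function(matrices, dims = 2, genes = c("expressed", "all"),
                          expressed_threshold = 0.1) {
  genes <- match.arg(genes)
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  ids <- Reduce(intersect, lapply(matrices, function(m) rownames(m$expr)))
  if (length(ids) == 0L) stopf("no shared gene ids across matrices")
  x <- do.call(cbind, lapply(matrices, function(m) m$expr[ids, , drop = FALSE]))
  if (genes == "expressed") {
    keep <- apply(x, 1L, max) > expressed_threshold
    x <- x[keep, , drop = FALSE]
  }
  d <- dist(t(log2(x + 1)))
  n <- ncol(x)
  if (dims > n - 1)
    stopf("dims = %d exceeds the embedding rank (%d samples)", dims, n)
  fit <- suppressWarnings(cmdscale(d, k = dims, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < dims) {  # rank-deficient configuration: pad null directions
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
    rownames(pts) <- attr(d, "Labels")
  }
  emb <- dist(pts)
  list(points = pts, eig = fit$eig,
       distortion = max(abs(as.vector(d) - as.vector(emb))))
}
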