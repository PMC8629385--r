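#' Selective-sweep scan from windowed FST and diversity tracks
#'
#' Joins the per-window FST track and the two populations' theta-pi tracks
#' (which must share window frames), computes the log2 diversity ratio
#' `log2(pi_A / pi_B)` per window, and calls candidate sweep windows that
#' are simultaneously in the top `1 - fst_quantile` tail of FST and in an
#' extreme tail of the ratio: ratio at or below its `ratio_tail` quantile
#' is a sweep in population A (diversity depressed in A), ratio at or
#' above the `1 - ratio_tail` quantile a sweep in population B. All
#' thresholds are empirical quantiles of the analyzed (included) windows;
#' published per-dataset cutoffs are properties of a particular data set
#' and are never hard-coded. Windows excluded upstream (too few SNPs) or
#' with zero diversity in either population are dropped from both the
#' quantiles and the calls (counts in `attr(, "excluded")`). A window whose
#' ratio falls in both tails simultaneously (possible only when the tails
#' collapse onto one value, e.g. all windows identical) is ambiguous and
#' receives no call. Overlapping or book-ended candidate windows of the
#' same population are merged into sweep regions.
#'
#' @param pi_a,pi_b [windowed_pi()] tables for populations A and B.
#' @param fst [windowed_fst()] table on the same frames.
#' @param fst_quantile FST quantile defining the high tail (default 0.95).
#' @param ratio_tail tail mass for the log2 ratio (default 0.05 per side).
#' @return list with `windows` (per-window statistics and calls; class
#'   `window_stats`), `regions` (merged `sweep_regions` data.frame:
#'   `chrom, start, end, pop, n_windows`), and `thresholds`.
#' @export
sweep_scan <- function(pi_a, pi_b, fst, fst_quantile = 0.95,
                       ratio_tail = 0.05) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  if (!identical(key(pi_a), key(fst)) || !identical(key(pi_b), key(fst)))
    stopf("pi and FST tracks must share identical window frames")
  w <- data.frame(chrom = fst$chrom, start = fst$start, end = fst$end,
                  n_snps = fst$n_snps, fst = fst$fst,
                  pi_a = pi_a$pi, pi_b = pi_b$pi, stringsAsFactors = FALSE)
  zero_pi <- w$pi_a == 0 | w$pi_b == 0
  included <- !fst$excluded & !zero_pi & !is.na(w$fst)
  if (!any(included)) stopf("no windows left after exclusions")
  w$log2_ratio <- ifelse(included, log2(w$pi_a / w$pi_b), NA_real_)
  q_fst <- quantile(w$fst[included], fst_quantile, names = FALSE)
  q_lo <- quantile(w$log2_ratio[included], ratio_tail, names = FALSE)
  q_hi <- quantile(w$log2_ratio[included], 1 - ratio_tail, names = FALSE)
  in_lo <- included & w$fst >= q_fst & w$log2_ratio <= q_lo
  in_hi <- included & w$fst >= q_fst & w$log2_ratio >= q_hi
  ambiguous <- in_lo & in_hi  # collapsed tails: no directional call
  w$sweep_call <- ifelse(!included | ambiguous, "none",
                         ifelse(in_lo, "sweep-in-A",
                                ifelse(in_hi, "sweep-in-B", "none")))
  w$included <- included
  class(w) <- c("window_stats", class(w))
  regions <- merge_sweep_windows(w[w$sweep_call != "none", , drop = FALSE])
  attr(w, "excluded") <- c(upstream = sum(fst$excluded),
                           zero_pi = sum(zero_pi & !fst$excluded))
  list(windows = w, regions = regions,
       thresholds = c(fst = q_fst, ratio_lo = q_lo, ratio_hi = q_hi))
}

# Merge overlapping/adjacent candidate windows of the same population into
# sweep regions. Idempotent: merging the output changes nothing.
merge_sweep_windows <- function(cand) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), pop = character(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) {
    class(empty) <- c("sweep_regions", class(empty))
    return(empty)
  }
  cand$pop <- sub("sweep-in-", "", cand$sweep_call)
  cand <- cand[order(cand$pop, cand$chrom, cand$start), ]
  out <- list()
  cur <- NULL
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    if (!is.null(cur) && cur$pop == row$pop && cur$chrom == row$chrom &&
        row$start <= cur$end + 1) {
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- data.frame(chrom = row$chrom, start = row$start, end = row$end,
                        pop = row$pop, n_windows = 1L,
                        stringsAsFactors = FALSE)
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$pop), ]
  rownames(res) <- NULL
  class(res) <- c("sweep_regions", class(res))
  res
}

#' Genes overlapping sweep regions
#'
#' Reads a gene annotation (BED, 0-based half-open, or GFF3, 1-based
#' inclusive; coordinate conversion is exact), intersects it with the
#' sweep regions, and lists every gene with at least 1 bp of overlap. A
#' gene spanning several regions appears once per region; the deduplicated
#' selected-gene list is in attribute `selected_genes`.
#'
#' @param regions a `sweep_regions` data.frame.
#' @param genes_path path to the annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param feature GFF3 feature type to keep (default `"gene"`).
#' @return data.frame `chrom, start, end, pop, gene_id, gene_start,
#'   gene_end` (one row per region-gene overlap).
#' @export
annotate_regions <- function(regions, genes_path, format = c("auto", "bed", "gff3"),
                             feature = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", genes_path, ignore.case = TRUE)) "bed"
    else if (grepl("\\.gff3?$", genes_path, ignore.case = TRUE)) "gff3"
    else stopf("cannot infer annotation format from '%s'", genes_path)
  }
  genes <- if (format == "bed") read_bed_genes(genes_path)
  else read_gff3_genes(genes_path, feature)
  if (nrow(regions) == 0L || nrow(genes) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      pop = character(), gene_id = character(),
                      gene_start = numeric(), gene_end = numeric())
    attr(out, "selected_genes") <- character()
    return(out)
  }
  gr_reg <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_gene, minoverlap = 1L)
  ri <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(chrom = regions$chrom[ri], start = regions$start[ri],
                    end = regions$end[ri], pop = regions$pop[ri],
                    gene_id = genes$gene_id[gi],
                    gene_start = genes$start[gi], gene_end = genes$end[gi],
                    stringsAsFactors = FALSE)
  attr(out, "selected_genes") <- sort(unique(out$gene_id))
  out
}

# BED: 0-based half-open -> 1-based inclusive (start + 1, end unchanged).
read_bed_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3L)
      stopf("malformed BED line %d in %s: fewer than 3 fields", i, path)
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stopf("malformed BED line %d in %s: bad interval [%s, %s)", i, path, f[2], f[3])
    data.frame(chrom = f[1], start = s + 1, end = e,
               gene_id = if (length(f) >= 4L) f[4] else sprintf("bed_%d", i),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), gene_id = character()))
  do.call(rbind, rows)
}

# GFF3: already 1-based inclusive; gene_id from ID= or Name= attribute.
read_gff3_genes <- function(path, feature = "gene") {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != 9L)
      stopf("malformed GFF3 line %d in %s: expected 9 fields, found %d",
            i, path, length(f))
    if (f[3] != feature) return(NULL)
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s < 1 || e < s)
      stopf("malformed GFF3 line %d in %s: bad interval [%s, %s]", i, path, f[4], f[5])
    id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", f[9])
    if (identical(id, f[9])) id <- sub(".*(?:^|;)Name=([^;]+).*", "\\1", f[9])
    if (identical(id, f[9])) id <- sprintf("gff_%d", i)
    data.frame(chrom = f[1], start = s, end = e, gene_id = id,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), gene_id = character()))
  do.call(rbind, rows)
}
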