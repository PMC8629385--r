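#' Construct a genotype matrix object
#'
#' Container for biallelic SNP genotypes of two (or more) populations:
#' per-SNP records plus a SNP x individual alt-allele dosage matrix
#' (0/1/2, NA for missing) and a population label per individual.
#'
#' @param chrom,pos,ref,alt per-SNP vectors (`pos` 1-based, strictly
#'   increasing within each chromosome).
#' @param dosage integer matrix SNP x individual, entries 0/1/2/NA.
#' @param pop named character vector: population label per individual id
#'   (names must match `colnames(dosage)`).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, dosage, pop) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) stopf("dosage needs individual ids as colnames")
  if (!all(colnames(dosage) %in% names(pop)))
    stopf("every individual needs a population label")
  pop <- pop[colnames(dosage)]
  if (any(!dosage %in% c(0L, 1L, 2L) & !is.na(dosage)))
    stopf("dosages must be 0, 1, 2 or NA")
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  dosage <- dosage[o, , drop = FALSE]
  for (ch in unique(chrom)) {
    pc <- pos[chrom == ch]
    if (any(diff(pc) <= 0))
      stopf("positions must be strictly increasing within chromosome '%s'", ch)
  }
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 dosage = dosage, pop = pop), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals (%s)\n",
              length(x$pos), ncol(x$dosage),
              paste(sprintf("%s=%d", names(table(x$pop)), table(x$pop)),
                    collapse = ", ")))
  invisible(x)
}

#' Load a VCF and filter to analysis-ready biallelic SNPs
#'
#' Reads a VCF v4.2 (GT field required), drops multiallelic records and
#' indels, then drops SNPs with call rate below `call_rate_min` or overall
#' minor allele frequency below `maf_min`. Exclusion counts are kept in
#' the `filter_log` attribute.
#'
#' @param vcf_path path to the VCF.
#' @param pops named list mapping population label to the sample ids in
#'   that population; every id must be present in the VCF.
#' @param call_rate_min minimum fraction of called genotypes per SNP
#'   (default 0.9).
#' @param maf_min minimum overall minor allele frequency (default 0.05).
#' @return a [genotype_matrix()] restricted to the listed samples.
#' @export
load_and_filter <- function(vcf_path, pops, call_rate_min = 0.9,
                            maf_min = 0.05) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  want <- unlist(pops, use.names = FALSE)
  missing <- setdiff(want, colnames(gt_raw))
  if (length(missing))
    stopf("sample '%s' not present in %s", missing[1L], vcf_path)
  gt_raw <- gt_raw[, want, drop = FALSE]
  dosage <- gt_to_dosage(gt_raw)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep1 <- !multi & !indel
  call_rate <- rowMeans(!is.na(dosage))
  n_alleles <- 2 * rowSums(!is.na(dosage))
  alt_f <- rowSums(dosage, na.rm = TRUE) / pmax(n_alleles, 1)
  maf <- pmin(alt_f, 1 - alt_f)
  low_call <- keep1 & call_rate < call_rate_min
  low_maf <- keep1 & !low_call & maf < maf_min
  keep <- keep1 & !low_call & !low_maf
  log <- c(input = nrow(dosage), multiallelic = sum(multi),
           indel = sum(indel), low_call_rate = sum(low_call),
           low_maf = sum(low_maf), retained = sum(keep))
  pop <- setNames(rep(names(pops), lengths(pops)), unlist(pops))
  g <- genotype_matrix(chrom = fix[keep, "CHROM"],
                       pos = as.integer(fix[keep, "POS"]),
                       ref = ref[keep], alt = alt[keep],
                       dosage = dosage[keep, , drop = FALSE], pop = pop)
  attr(g, "filter_log") <- log
  g
}

# "0/1", "0|1", "./." etc. -> alt dosage 0/1/2/NA.
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

# Per-site nucleotide diversity within one population: average pairwise
# difference 2 * c_ref * c_alt / (n * (n - 1)) over called alleles n.
# Sites with fewer than 2 called alleles contribute 0 and are flagged.
site_pi <- function(dosage_pop) {
  n_alleles <- 2 * rowSums(!is.na(dosage_pop))
  c_alt <- rowSums(dosage_pop, na.rm = TRUE)
  c_ref <- n_alleles - c_alt
  ok <- n_alleles >= 2
  pi <- numeric(nrow(dosage_pop))
  pi[ok] <- 2 * c_ref[ok] * c_alt[ok] / (n_alleles[ok] * (n_alleles[ok] - 1))
  list(pi = pi, ok = ok)
}

# Sliding-window frames anchored at position 1, fixed span and step.
window_frames <- function(chrom_len, window, step) {
  starts <- seq(1, max(chrom_len - step + 1, 1), by = step)
  data.frame(start = starts, end = starts + window - 1)
}

# Sum `values` (aligned with sorted positions `pos`) over each window.
window_sums <- function(pos, values, frames) {
  cs <- c(0, cumsum(values))
  hi <- findInterval(frames$end, pos)
  lo <- findInterval(frames$start - 1, pos)
  cs[hi + 1] - cs[lo + 1]
}

#' Windowed nucleotide diversity (theta-pi) for one population
#'
#' Per-site pi is the average pairwise difference among called alleles,
#' `2 * c_ref * c_alt / (n * (n-1))`; the window statistic is the sum of
#' per-site pi over the window divided by the full window span (per-bp,
#' the sliding-window convention of standard VCF tooling). Windows are
#' anchored at position 1 and advance by `step`; trailing windows that
#' extend past the last position are kept and flagged `partial`.
#'
#' @param g a `genotype_matrix`.
#' @param pop population label.
#' @param window,step window span and step in bp (defaults 50000, 10000).
#' @param chrom_length optional chromosome length(s); defaults to the last
#'   SNP position per chromosome.
#' @return data.frame `chrom, start, end, n_snps, pi, partial`.
#' @export
windowed_pi <- function(g, pop, window = 50000, step = 10000,
                        chrom_length = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  cols <- names(g$pop)[g$pop == pop]
  if (length(cols) == 0L) stopf("population '%s' has no individuals", pop)
  res <- lapply(unique(g$chrom), function(ch) {
    sel <- g$chrom == ch
    sp <- site_pi(g$dosage[sel, cols, drop = FALSE])
    len <- if (is.null(chrom_length)) max(g$pos[sel]) else chrom_length
    fr <- window_frames(len, window, step)
    data.frame(chrom = ch, start = fr$start, end = fr$end,
               n_snps = window_sums(g$pos[sel], as.numeric(sp$ok), fr),
               pi = window_sums(g$pos[sel], sp$pi, fr) / window,
               partial = fr$end > len, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Weir & Cockerham (1984) per-site variance components a, b, c for two
# populations. Returns NA rows for sites skipped for insufficient calls.
wc_components <- function(dA, dB) {
  n1 <- rowSums(!is.na(dA)); n2 <- rowSums(!is.na(dB))
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2  # need nbar > 1
  p1 <- rowSums(dA, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- rowSums(dB, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- rowSums(dA == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- rowSums(dB == 1L, na.rm = TRUE) / pmax(n2, 1)
  r <- 2
  nbar <- (n1 + n2) / r
  ntot <- n1 + n2
  nc <- ntot - (n1^2 + n2^2) / ntot  # = (sum n - sum n^2 / sum n) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / ntot
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / ntot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc, ok = ok)
}

#' Windowed Weir-Cockerham FST between two populations
#'
#' Computes the 1984 per-site variance components (a: between-population,
#' b: between individuals within populations, c: within individuals) from
#' the two population samples and reports the weighted window estimate
#' `sum(a) / sum(a + b + c)`. Negative estimates are retained unclamped.
#' Windows with fewer than `min_snps` usable SNPs, or with a zero
#' denominator, are flagged excluded (`exclude_reason`).
#'
#' @param g a `genotype_matrix`.
#' @param popA,popB population labels.
#' @param window,step window span and step in bp.
#' @param min_snps minimum SNPs per window (default 10).
#' @param chrom_length optional chromosome length(s).
#' @return data.frame `chrom, start, end, n_snps, fst, excluded,
#'   exclude_reason, partial`.
#' @export
windowed_fst <- function(g, popA, popB, window = 50000, step = 10000,
                         min_snps = 10, chrom_length = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ca <- names(g$pop)[g$pop == popA]; cb <- names(g$pop)[g$pop == popB]
  if (length(ca) < 2L || length(cb) < 2L)
    stopf("both populations need at least 2 individuals")
  res <- lapply(unique(g$chrom), function(ch) {
    sel <- g$chrom == ch
    wc <- wc_components(g$dosage[sel, ca, drop = FALSE],
                        g$dosage[sel, cb, drop = FALSE])
    a <- ifelse(wc$ok, wc$a, 0)
    abc <- ifelse(wc$ok, wc$a + wc$b + wc$c, 0)
    len <- if (is.null(chrom_length)) max(g$pos[sel]) else chrom_length
    fr <- window_frames(len, window, step)
    num <- window_sums(g$pos[sel], a, fr)
    den <- window_sums(g$pos[sel], abc, fr)
    n_snps <- window_sums(g$pos[sel], as.numeric(wc$ok), fr)
    fst <- ifelse(den > 0, num / den, NA_real_)
    reason <- ifelse(n_snps < min_snps, "too_few_snps",
                     ifelse(den <= 0, "zero_denominator", ""))
    data.frame(chrom = ch, start = fr$start, end = fr$end, n_snps = n_snps,
               fst = fst, excluded = reason != "", exclude_reason = reason,
               partial = fr$end > len, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Genome-wide weighted Weir-Cockerham FST
#'
#' The ratio-of-sums estimate `sum(a) / sum(a + b + c)` over all usable
#' sites — the statistic used for parameter recovery against a simulated
#' differentiation level.
#'
#' @inheritParams windowed_fst
#' @return a single numeric value.
#' @export
global_fst <- function(g, popA, popB) {
  ca <- names(g$pop)[g$pop == popA]; cb <- names(g$pop)[g$pop == popB]
  wc <- wc_components(g$dosage[, ca, drop = FALSE],
                      g$dosage[, cb, drop = FALSE])
  sum(wc$a[wc$ok]) / sum((wc$a + wc$b + wc$c)[wc$ok])
}
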