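# Shared fixtures and independent oracles, built in code at test time.

# Minimal time-point metadata: n points split evenly over the given phases.
tiny_meta <- function(n, phases = "Embryonic") {
  k <- length(phases)
  per <- rep(ceiling(n / k), k)[seq_len(k)]
  ph <- rep(phases, per)[seq_len(n)]
  data.frame(timepoint = paste0("t", seq_len(n)), day_numeric = seq_len(n),
             phase = ph, stringsAsFactors = FALSE)
}

# Expression matrix from a plain numeric matrix (genes x time points).
make_expr <- function(x, condition = "A", biotype = NULL, meta = NULL,
                      tf = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(biotype)) biotype <- rep("pcg", nrow(x))
  if (is.null(meta)) meta <- tiny_meta(ncol(x))
  if (is.null(tf)) tf <- rep(FALSE, nrow(x))
  colnames(x) <- NULL
  expression_matrix(x, biotype, condition, meta, tf = tf)
}

# Exhaustive staircase-path maximum: enumerates every monotone path from
# (1,1) to (nr,nc) by plain recursion. Independent of the DP implementation.
brute_max_trace <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rec <- function(i, j) {
    if (i == nr && j == nc) return(m[i, j])
    best <- -Inf
    if (i < nr) best <- max(best, rec(i + 1, j))
    if (j < nc) best <- max(best, rec(i, j + 1))
    if (i < nr && j < nc) best <- max(best, rec(i + 1, j + 1))
    m[i, j] + best
  }
  rec(1L, 1L)
}

# Upper-tail hypergeometric P(X >= k) by direct log-PMF summation.
hyper_upper_oracle <- function(k, n_b, n_univ, n_a) {
  xs <- seq(k, min(n_a, n_b))
  if (k <= 0) return(1)
  if (length(xs) == 0L) return(0)
  sum(exp(lchoose(n_b, xs) + lchoose(n_univ - n_b, n_a - xs) -
            lchoose(n_univ, n_a)))
}

# Benjamini-Hochberg step-up by definition: q_i = min_{j >= rank(i)} p_(j)*m/j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Adjusted Rand index from first principles.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- sa * sb / n2
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}

# Per-site nucleotide diversity by brute-force pairwise allele comparison.
pi_site_oracle <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)],
                           function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(0)
  pairs <- combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# Write a small VCF from explicit field vectors (for parser edge cases).
write_vcf_text <- function(path, chrom, pos, ref, alt, gt_rows, samples) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t"), "")
  writeLines(c(header, body), path)
  path
}

# Two-population genotype fixture straight from dosage matrices.
make_geno <- function(dosA, dosB, pos = NULL, chrom = "1") {
  d <- cbind(dosA, dosB)
  colnames(d) <- c(paste0("A", seq_len(ncol(dosA))),
                   paste0("B", seq_len(ncol(dosB))))
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 10L
  genotype_matrix(chrom = rep(chrom, nrow(d)), pos = pos,
                  ref = rep("A", nrow(d)), alt = rep("G", nrow(d)),
                  dosage = d,
                  pop = setNames(rep(c("A", "B"), c(ncol(dosA), ncol(dosB))),
                                 colnames(d)))
}
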