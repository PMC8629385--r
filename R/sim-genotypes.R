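#' Configuration for the two-population genotype simulator
#'
#' The generator draws biallelic SNPs at uniform-random positions on one
#' chromosome and gives each population Balding-Nichols allele
#' frequencies: for ancestral frequency p and differentiation parameter F,
#' per-population frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F), so the
#' expected Weir-Cockerham FST between the populations is close to F.
#' Inside a sweep interval the swept population's frequencies are pushed
#' to within `sweep_push` of fixation of the nearer allele, which depresses
#' its nucleotide diversity and inflates FST — the summary-statistic
#' signature a sweep scan looks for.
#'
#' @param n_snps number of SNPs.
#' @param n_individuals_per_pop diploid individuals per population.
#' @param chrom_length chromosome length in bp.
#' @param fst_target Balding-Nichols differentiation parameter, in (0, 1).
#' @param sweep_intervals data.frame `start, end, pop` (1-based inclusive
#'   bp; `pop` is `"A"` or `"B"`), or NULL. Intervals must lie within the
#'   chromosome and must not overlap.
#' @param ancestral_freq_range range of the uniform ancestral frequency.
#' @param sweep_push maximum distance from fixation after the push
#'   (default 0.02, i.e. swept frequencies land in \[0.98, 1\] of the
#'   nearer allele).
#' @param chrom chromosome name in the emitted VCF.
#' @param seed master RNG seed.
#' @return A validated list of class `geno_sim_config`.
#' @export
geno_sim_config <- function(n_snps = 20000, n_individuals_per_pop = 20,
                            chrom_length = 2e7, fst_target = 0.2,
                            sweep_intervals = NULL,
                            ancestral_freq_range = c(0.1, 0.9),
                            sweep_push = 0.02, chrom = "1", seed = 1) {
  if (!is_count(n_snps)) stopf("n_snps must be a positive count")
  if (!is_count(n_individuals_per_pop)) stopf("n_individuals_per_pop must be a positive count")
  if (fst_target <= 0 || fst_target >= 1) stopf("fst_target must lie in (0, 1)")
  if (!is.null(sweep_intervals)) {
    si <- sweep_intervals
    if (!all(c("start", "end", "pop") %in% names(si)))
      stopf("sweep_intervals needs columns start, end, pop")
    if (any(si$start < 1 | si$end > chrom_length | si$start > si$end))
      stopf("sweep interval outside [1, %d]", as.integer(chrom_length))
    si <- si[order(si$start), ]
    if (nrow(si) > 1L && any(si$start[-1] <= si$end[-nrow(si)]))
      stopf("sweep intervals must not overlap")
    if (!all(si$pop %in% c("A", "B")))
      stopf("sweep populations must be 'A' or 'B'")
  }
  structure(list(n_snps = as.integer(n_snps),
                 n_individuals_per_pop = as.integer(n_individuals_per_pop),
                 chrom_length = chrom_length, fst_target = fst_target,
                 sweep_intervals = sweep_intervals,
                 ancestral_freq_range = ancestral_freq_range,
                 sweep_push = sweep_push, chrom = chrom,
                 seed = as.integer(seed)), class = "geno_sim_config")
}

#' Simulate two-population genotypes (with optional VCF output)
#'
#' Draws the Balding-Nichols panel described in [geno_sim_config()],
#' applies the configured sweep pushes, samples diploid genotypes
#' Binomial(2, freq) per individual, and returns the genotype container
#' used by the popgen functions plus the ground truth (ancestral and
#' per-population frequencies, sweep intervals). If `vcf_path` is given,
#' a VCF v4.2 file with GT fields is also written; the body is
#' byte-deterministic under a fixed seed.
#'
#' @param cfg a [geno_sim_config()].
#' @param vcf_path optional output path for the VCF.
#' @return list with `genotypes` (class `genotype_matrix`, see
#'   [load_and_filter()]), `truth` (ancestral/per-pop frequencies and
#'   sweep table), and `vcf_path` (or NULL).
#' @export
simulate_genotypes <- function(cfg, vcf_path = NULL) {
  stopifnot(inherits(cfg, "geno_sim_config"))
  n <- cfg$n_individuals_per_pop
  sim <- with_seed(sub_seed(cfg$seed, "genotypes"), {
    pos <- sort(sample.int(cfg$chrom_length, cfg$n_snps, replace = FALSE))
    p_anc <- runif(cfg$n_snps, cfg$ancestral_freq_range[1],
                   cfg$ancestral_freq_range[2])
    f <- cfg$fst_target
    shape <- (1 - f) / f
    freq <- list(A = rbeta(cfg$n_snps, shape * p_anc, shape * (1 - p_anc)),
                 B = rbeta(cfg$n_snps, shape * p_anc, shape * (1 - p_anc)))
    if (!is.null(cfg$sweep_intervals)) {
      for (r in seq_len(nrow(cfg$sweep_intervals))) {
        iv <- cfg$sweep_intervals[r, ]
        in_iv <- pos >= iv$start & pos <= iv$end
        fr <- freq[[iv$pop]][in_iv]
        near_one <- fr >= 0.5
        push <- runif(sum(in_iv), 1 - cfg$sweep_push, 1)
        freq[[iv$pop]][in_iv] <- ifelse(near_one, push, 1 - push)
      }
    }
    gA <- matrix(rbinom(cfg$n_snps * n, 2, freq$A), cfg$n_snps, n)
    gB <- matrix(rbinom(cfg$n_snps * n, 2, freq$B), cfg$n_snps, n)
    ref_alt <- t(vapply(seq_len(cfg$n_snps), function(i)
      sample(c("A", "C", "G", "T"), 2L), c("", "")))
    list(pos = pos, p_anc = p_anc, freq = freq, g = cbind(gA, gB),
         ref = ref_alt[, 1], alt = ref_alt[, 2])
  })
  ids <- c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n)))
  colnames(sim$g) <- ids
  geno <- genotype_matrix(chrom = rep(cfg$chrom, cfg$n_snps), pos = sim$pos,
                          ref = sim$ref, alt = sim$alt, dosage = sim$g,
                          pop = setNames(rep(c("A", "B"), each = n), ids))
  truth <- list(ancestral_freq = sim$p_anc, pop_freq = sim$freq,
                sweeps = cfg$sweep_intervals, fst_target = cfg$fst_target)
  if (!is.null(vcf_path)) write_vcf(geno, vcf_path)
  list(genotypes = geno, truth = truth,
       vcf_path = if (is.null(vcf_path)) NULL else vcf_path)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Minimal VCF v4.2 writer: CHROM, POS (1-based), ID, REF, ALT, QUAL,
#' FILTER, INFO and FORMAT=GT columns, unphased diploid genotypes, missing
#' dosage written as `./.`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L],
               nrow(g$dosage), ncol(g$dosage))
  gt[is.na(g$dosage)] <- "./."
  body <- cbind(g$chrom, g$pos, ".", g$ref, g$alt, ".", "PASS", ".", "GT", gt)
  header <- c("##fileformat=VCFv4.2",
              "##source=devomap simulate_genotypes",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(g$dosage)), collapse = "\t"))
  con <- file(path, "wb")  # binary mode: stable line endings
  on.exit(close(con))
  writeLines(c(header, apply(body, 1L, paste, collapse = "\t")), con)
  invisible(path)
}
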