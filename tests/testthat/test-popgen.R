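test_that("VCF loading drops multiallelic, indel, low-call and low-MAF records", {
  samples <- c(paste0("A", 1:10), paste0("B", 1:10))
  gt_ok <- rep("0/1", 20)                      # MAF 0.5, full call
  gt_low_maf <- c(rep("0/1", 2), rep("0/0", 18))  # MAF 0.05 exactly: kept
  gt_below <- c("0/1", rep("0/0", 19))            # MAF 0.025: dropped
  gt_half <- c(rep("./.", 11), rep("0/1", 9))     # call rate 45%: dropped
  f <- tempfile(fileext = ".vcf")
  write_vcf_text(f, chrom = rep("1", 5), pos = c(100, 200, 300, 400, 500),
                 ref = c("A", "A", "AT", "A", "A"),
                 alt = c("G", "G,T", "A", "G", "G"),
                 gt_rows = list(gt_ok, gt_ok, gt_ok, gt_below, gt_half),
                 samples = samples)
  g <- load_and_filter(f, pops = list(A = paste0("A", 1:10),
                                      B = paste0("B", 1:10)))
  log <- attr(g, "filter_log")
  expect_equal(unname(log["multiallelic"]), 1)
  expect_equal(unname(log["indel"]), 1)
  expect_equal(unname(log["low_maf"]), 1)
  expect_equal(unname(log["low_call_rate"]), 1)
  expect_equal(g$pos, 100)
  expect_error(load_and_filter(f, pops = list(A = "ghost")), "ghost")

  # boundary: MAF exactly 0.05 and call rate exactly 0.9 are retained
  f2 <- tempfile(fileext = ".vcf")
  gt_cr90 <- c(rep("./.", 2), rep("0/1", 18))
  write_vcf_text(f2, "1", c(10, 20), c("A", "A"), c("G", "G"),
                 list(gt_low_maf, gt_cr90), samples)
  g2 <- load_and_filter(f2, pops = list(A = paste0("A", 1:10),
                                        B = paste0("B", 1:10)))
  expect_equal(length(g2$pos), 2)
})

test_that("windowed pi matches hand arithmetic and the pairwise oracle", {
  # 2 diploids, dosages (1,1): 2 ref + 2 alt alleles -> pi = 2/3 per site
  g <- make_geno(matrix(c(1, 1), 1, 2), matrix(c(0, 0), 1, 2), pos = 50L)
  pw <- windowed_pi(g, "A", window = 100, step = 100, chrom_length = 100)
  expect_equal(pw$pi, (2 * 2 * 2 / (4 * 3)) / 100)
  expect_equal(pw$pi, 0.006667, tolerance = 1e-4)
  # doubling the span halves the per-bp value
  pw2 <- windowed_pi(g, "A", window = 200, step = 200, chrom_length = 200)
  expect_equal(pw2$pi[1], pw$pi[1] / 2)
  # monomorphic window
  expect_equal(windowed_pi(g, "B", window = 100, step = 100,
                           chrom_length = 100)$pi, 0)

  # brute-force pairwise-difference oracle, missing-aware
  set.seed(10)
  dosA <- matrix(sample(c(0:2, NA), 50 * 6, TRUE, prob = c(.3, .3, .3, .1)),
                 50, 6)
  g2 <- make_geno(dosA, matrix(0L, 50, 4), pos = sort(sample(1:1000, 50)))
  pw3 <- windowed_pi(g2, "A", window = 1000, step = 1000, chrom_length = 1000)
  oracle <- sum(apply(dosA, 1, pi_site_oracle)) / 1000
  expect_equal(pw3$pi[1], oracle, tolerance = 1e-12)
})

test_that("Weir-Cockerham components match hand-worked fixtures", {
  # opposite fixation: FST = 1
  g1 <- make_geno(matrix(2L, 5, 10), matrix(0L, 5, 10))
  expect_equal(global_fst(g1, "A", "B"), 1)
  # 2 diploids per pop: pop A = {0,2} (p=0.5, h=0), pop B = {1,1} (p=0.5, h=1)
  # nbar=2, nc=2, pbar=0.5, s2=0, hbar=0.5:
  # a = -(0.25 - 0.125) = -0.125; b = 2*(0.25 - 0.1875) = 0.125; c = 0.25
  # FST = -0.125 / 0.25 = -0.5 (negative estimates retained)
  g2 <- make_geno(matrix(c(0L, 2L), 1, 2), matrix(c(1L, 1L), 1, 2))
  expect_equal(global_fst(g2, "A", "B"), -0.5)
  wc <- devomap:::wc_components(matrix(c(0L, 2L), 1, 2),
                                matrix(c(1L, 1L), 1, 2))
  expect_equal(wc$a, -0.125)
  expect_equal(wc$b, 0.125)
  expect_equal(wc$c, 0.25)
})

test_that("panmictic samples give near-zero FST; BN simulation recovers its target", {
  set.seed(2)
  freq <- runif(4000, 0.1, 0.9)
  dos <- function(n) matrix(rbinom(4000 * n, 2, freq), 4000, n)
  g <- make_geno(dos(15), dos(15), pos = sort(sample(1:1e6, 4000)))
  expect_equal(global_fst(g, "A", "B"), 0, tolerance = 0.02)

  gs <- simulate_genotypes(geno_sim_config(n_snps = 8000,
                                           n_individuals_per_pop = 20,
                                           chrom_length = 8e6,
                                           fst_target = 0.2, seed = 1))
  expect_equal(global_fst(gs$genotypes, "A", "B"), 0.2, tolerance = 0.05)
})

test_that("windows with too few SNPs are excluded from the FST track", {
  set.seed(3)
  dosA <- matrix(rbinom(30 * 8, 2, 0.4), 30, 8)
  dosB <- matrix(rbinom(30 * 8, 2, 0.6), 30, 8)
  g <- make_geno(dosA, dosB, pos = c(seq(100, 3000, length.out = 25),
                                     seq(60000, 61000, length.out = 5)))
  fst <- windowed_fst(g, "A", "B", window = 50000, step = 50000,
                      min_snps = 10, chrom_length = 1e5)
  expect_false(fst$excluded[1])
  expect_true(fst$excluded[2])
  expect_equal(fst$exclude_reason[2], "too_few_snps")
})

test_that("sweep scan recovers an injected sweep with the right population", {
  sw <- data.frame(start = 8e6 + 1, end = 9e6, pop = "B")
  cfg <- geno_sim_config(n_snps = 20000, n_individuals_per_pop = 20,
                         chrom_length = 2e7, fst_target = 0.2,
                         sweep_intervals = sw, seed = 1)
  g <- simulate_genotypes(cfg)$genotypes
  pa <- windowed_pi(g, "A", chrom_length = 2e7)
  pb <- windowed_pi(g, "B", chrom_length = 2e7)
  fst <- windowed_fst(g, "A", "B", chrom_length = 2e7)
  scan <- sweep_scan(pa, pb, fst)
  reg <- scan$regions
  hitB <- reg$pop == "B" & reg$start <= sw$end & reg$end >= sw$start
  hitA <- reg$pop == "A" & reg$start <= sw$end & reg$end >= sw$start
  expect_true(any(hitB))   # the injected interval is called, population B
  expect_false(any(hitA))  # and never attributed to population A
})

test_that("degenerate identical windows produce no sweep candidates", {
  frames <- data.frame(chrom = "1", start = seq(1, 1e5, 1e4))
  frames$end <- frames$start + 49999
  pi_a <- data.frame(frames, n_snps = 50, pi = 0.001, partial = FALSE)
  pi_b <- data.frame(frames, n_snps = 50, pi = 0.002, partial = FALSE)
  fst <- data.frame(frames, n_snps = 50, fst = 0.3, excluded = FALSE,
                    exclude_reason = "", partial = FALSE)
  scan <- sweep_scan(pi_a, pi_b, fst)
  expect_equal(nrow(scan$regions), 0)
  expect_true(all(scan$windows$sweep_call == "none"))
})

test_that("overlapping candidate windows of one population merge into one region", {
  cand <- data.frame(chrom = "1", start = c(1, 10001), end = c(50000, 60000),
                     sweep_call = "sweep-in-B")
  merged <- devomap:::merge_sweep_windows(cand)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 1)
  expect_equal(merged$end, 60000)
  expect_equal(merged$pop, "B")
  # idempotent: re-merging the merged region is a no-op
  again <- devomap:::merge_sweep_windows(
    data.frame(chrom = merged$chrom, start = merged$start, end = merged$end,
               sweep_call = paste0("sweep-in-", merged$pop)))
  expect_equal(again$start, merged$start)
  expect_equal(again$end, merged$end)
})

test_that("region annotation converts BED and GFF3 coordinates exactly", {
  regions <- data.frame(chrom = "1", start = c(150, 1000), end = c(300, 2000),
                        pop = "A", n_windows = 1L)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tgeneX",     # 1-based 101-200: overlaps 150-300
               "1\t300\t400\tgeneY",     # 1-based 301-400: outside both
               "1\t100\t2100\tgeneZ"),   # spans both regions
             bed)
  ann <- annotate_regions(regions, bed)
  expect_setequal(ann$gene_id[ann$start == 150], c("geneX", "geneZ"))
  expect_false("geneY" %in% ann$gene_id)
  expect_equal(sum(ann$gene_id == "geneZ"), 2)  # once per region
  expect_equal(attr(ann, "selected_genes"), c("geneX", "geneZ"))  # deduplicated
  expect_equal(ann$gene_start[ann$gene_id == "geneX"][1], 101)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t150\t200\t.\t+\t.\tID=gA",
               "1\tsrc\tmRNA\t150\t200\t.\t+\t.\tID=gA.1",
               "1\tsrc\tgene\t301\t400\t.\t+\t.\tID=gB"), gff)
  ann2 <- annotate_regions(regions, gff)
  expect_equal(ann2$gene_id, "gA")   # boundary 301 does not touch end 300

  bad <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tok", "1\tnot_a_number\t300\tbad"), bad)
  expect_error(annotate_regions(regions, bad), "line 2")
})

test_that("LD decay sees perfect LD for duplicated SNPs and the null level for independent ones", {
  set.seed(4)
  base <- rbinom(30, 2, 0.5)
  dos <- rbind(base, base, rbinom(30, 2, 0.5))
  g <- make_geno(dos[, 1:15], dos[, 16:30], pos = c(100L, 250L, 300400L))
  ld <- ld_decay(g, "A", max_dist = 3e5, bin_bp = 100)
  expect_equal(ld$mean_r2[ld$bin_lo == 100 & ld$bin_hi == 200], 1)
  # pairs at distances 300150 and 300300 exceed max_dist and are excluded
  expect_equal(sum(ld$n_pairs), 1)

  set.seed(5)
  n_ind <- 50
  dos2 <- matrix(rbinom(400 * n_ind, 2, 0.5), 400, n_ind)
  g2 <- make_geno(dos2[, 1:25], dos2[, 26:50],
                  pos = sort(sample(1:50000, 400)))
  # pool both populations as one panmictic sample of 50
  g2$pop[] <- "A"
  ld2 <- ld_decay(g2, "A", max_dist = 5e4, bin_bp = 5e4)
  expect_equal(weighted.mean(ld2$mean_r2, ld2$n_pairs, na.rm = TRUE),
               1 / (n_ind - 1), tolerance = 0.01)
})

test_that("genotype PCA separates simulated populations and respects symmetry", {
  gs <- simulate_genotypes(geno_sim_config(n_snps = 4000,
                                           n_individuals_per_pop = 15,
                                           chrom_length = 4e6,
                                           fst_target = 0.2, seed = 1))
  pca <- genotype_pca(gs$genotypes)
  s <- pca$scores
  a_rng <- range(s$PC1[s$pop == "A"]); b_rng <- range(s$PC1[s$pop == "B"])
  expect_true(a_rng[2] < b_rng[1] || b_rng[2] < a_rng[1])  # zero overlap
  # identical individuals: identical coordinates
  dup <- matrix(rep(rbinom(25, 2, 0.5), 4), 25, 4)
  g <- make_geno(dup, matrix(rbinom(50, 2, .5), 25, 2))
  p2 <- genotype_pca(g)
  expect_equal(p2$scores$PC1[1], p2$scores$PC1[2], tolerance = 1e-9)
})

test_that("NJ recovers additive distances exactly, including the 3-taxon closed form", {
  dm <- matrix(c(0, 3, 7, 8,
                 3, 0, 6, 7,
                 7, 6, 0, 3,
                 8, 7, 3, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  phy <- nj_tree(dm)
  expect_true(ape::is.monophyletic(phy, c("a", "b")))
  expect_equal(as.matrix(ape::cophenetic.phylo(phy))[letters[1:4], letters[1:4]],
               dm, tolerance = 1e-9)

  d3 <- matrix(c(0, 0.4, 0.6, 0.4, 0, 0.8, 0.6, 0.8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  phy3 <- nj_tree(d3)
  lens <- setNames(phy3$edge.length, phy3$tip.label[phy3$edge[, 2]])
  expect_equal(lens[c("x", "y", "z")], c(x = 0.1, y = 0.3, z = 0.5))
})

test_that("NJ reconstructs random additive topologies and clusters simulated populations", {
  set.seed(6)
  for (trial in 1:20) {
    tree <- ape::rtree(8, br = function(n) runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(tree)
    rec <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
  gs <- simulate_genotypes(geno_sim_config(n_snps = 1500,
                                           n_individuals_per_pop = 6,
                                           chrom_length = 2e6,
                                           fst_target = 0.2, seed = 1))
  phy <- nj_tree(gs$genotypes, bootstrap = 99, seed = 1)
  expect_true(ape::is.monophyletic(phy, paste0("A0", 1:6)))
  expect_true(ape::is.monophyletic(phy, paste0("B0", 1:6)))
  # support on the population split
  root_label <- max(phy$node.label[!is.na(phy$node.label)], na.rm = TRUE)
  expect_gte(root_label, 95)
})
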