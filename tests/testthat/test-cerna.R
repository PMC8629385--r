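test_that("seed matcher finds canonical sites and rejects bad alphabets", {
  # positions 2-8 of the miRNA are GGAAUGU; reverse complement ACAUUCC
  hit <- seed_match_targets(c(miR1 = "UGGAAUGUAAAGAAGUAUGUA"),
                            c(t1 = "GGGACAUUCCGG"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$site_types, "7mer-m8")
  # trailing A upgrades the site to an 8mer
  hit8 <- seed_match_targets(c(miR1 = "UGGAAUGUAAAGAAGUAUGUA"),
                             c(t1 = "GGGACAUUCCAGG"))
  expect_equal(hit8$site_types, "8mer")
  # no complementary seed: no pair
  none <- seed_match_targets(c(miR1 = "UGGAAUGUAAAGAAGUAUGUA"),
                             c(t1 = "GGGGGGGGGGGGGG"))
  expect_equal(nrow(none), 0)
  # full reverse complement contains the site; U/T and case are equivalent
  full <- seed_match_targets(c(miR1 = "UGGAAUGUAAAGAAGUAUGUA"),
                             c(t1 = tolower("TACATACTTCTTTACATTCCA")))
  expect_equal(nrow(full), 1)
  expect_error(seed_match_targets(c(m = "UGGAAUGUXAAGAAGUAUGUA"),
                                  c(t = "ACGT")), "outside A/C/G/T/U")
})

test_that("non-overlapping occurrences are counted once each", {
  mir <- c(m = "UGGAAUGUAAAGAAGUAUGUA")     # m8 site ACAUUCC
  two <- seed_match_targets(mir, c(t = "ACAUUCCGGGGGGACAUUCC"))
  expect_equal(two$site_count, 2)
  overlapping <- seed_match_targets(mir, c(t = "ACAUUCCAUUCC"))
  expect_equal(overlapping$site_count, 1)
})

test_that("seed matcher agrees with a regex oracle on random sequences", {
  set.seed(5)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  for (trial in 1:100) {
    mir <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    tgt <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    res <- seed_match_targets(setNames(mir, "m"), setNames(tgt, "t"))
    seed <- chartr("U", "T", toupper(substr(mir, 2, 8)))
    m8 <- paste(rev(rc[strsplit(seed, "")[[1]]]), collapse = "")
    a1 <- paste0(substr(m8, 2, 7), "A")
    expected <- grepl(m8, tgt, fixed = TRUE) | grepl(a1, tgt, fixed = TRUE)
    expect_equal(nrow(res) == 1, expected,
                 label = sprintf("trial %d (%s vs %s)", trial, mir, tgt))
  }
})

# deterministic expression rows with exactly the correlation structure asked for
cor_fixture <- function() {
  n <- 20
  set.seed(2)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))                 # orthogonal to x
  x <- as.vector(scale(x)); z <- as.vector(scale(z))
  mk <- function(r) r * x + sqrt(1 - r^2) * z   # sample cor(x, .) == r
  rows <- rbind(mir = x, t_neg6 = mk(-0.6), t_neg4 = mk(-0.4),
                lnc_pos7 = mk(0.7), strong = mk(-0.95))
  abs_rows <- rows - min(rows) + 0.1        # nonnegative abundances
  abs_rows
}

test_that("correlation filter enforces the sign and threshold contract", {
  rows <- cor_fixture()
  expect_equal(cor(rows["mir", ], rows["t_neg6", ]), -0.6, tolerance = 1e-10)
  pairs <- data.frame(mirna_id = "mir",
                      target_id = c("t_neg6", "t_neg4", "strong"),
                      target_class = "mRNA")
  flt <- correlation_filter(pairs, rows)
  expect_setequal(flt$pairs$target_id, c("t_neg6", "strong"))  # -0.4 dropped
  expect_true(all(flt$edges$p[flt$edges$target_id == "t_neg6"] < 0.05))
  bad <- data.frame(mirna_id = "mir", target_id = "ghost", target_class = "mRNA")
  expect_error(correlation_filter(bad, rows), "ghost")
})

test_that("triplet join equals a nested-loop oracle and satisfies all three arms", {
  cfg <- expr_sim_config(n_genes = 400, n_mirnas = 24, noise_sd = 0.05, seed = 6)
  sim <- simulate_expression(cfg)
  cl <- simulate_cerna_layer(cfg, sim)
  exprs <- list(sim$a, sim$b, cl$mirna_a, cl$mirna_b)
  flt <- correlation_filter(cl$pairs, exprs)
  kept <- flt$pairs
  lnc <- kept[kept$target_class == "lincRNA", ]
  mrna <- kept[kept$target_class == "mRNA", ]
  tri <- build_triplets(lnc, mrna, exprs)

  # independent nested-loop join over the same surviving pairs
  expr <- devomap:::stack_expr(exprs)
  oracle <- 0L
  for (mi in unique(lnc$mirna_id)) {
    for (l in lnc$target_id[lnc$mirna_id == mi]) {
      for (m in mrna$target_id[mrna$mirna_id == mi]) {
        ct <- cor.test(expr[l, ], expr[m, ])
        if (!is.na(ct$estimate) && ct$estimate > 0.5 && ct$p.value < 0.05)
          oracle <- oracle + 1L
      }
    }
  }
  expect_equal(nrow(tri), oracle)
  expect_true(all(tri$r_mir_lnc < -0.5 & tri$p_mir_lnc < 0.05))
  expect_true(all(tri$r_mir_mrna < -0.5 & tri$p_mir_mrna < 0.05))
  expect_true(all(tri$r_lnc_mrna > 0.5 & tri$p_lnc_mrna < 0.05))

  # duplicated input pairs do not duplicate triplets
  tri2 <- build_triplets(rbind(lnc, lnc), rbind(mrna, mrna), exprs)
  expect_equal(nrow(tri2), nrow(tri))
  # a miRNA without mRNA partners contributes nothing
  tri3 <- build_triplets(lnc, mrna[0, ], exprs)
  expect_equal(nrow(tri3), 0)
})

test_that("trend partitioning assigns opposing networks and leaves flat triplets out", {
  tt <- 20
  up <- seq(1, 5, length.out = tt)
  x <- rbind(lnc_dn = rev(up), mrna_dn = rev(up) * 2 + 0.5,
             lnc_up = up, mrna_up = up * 3,
             lnc_flat = rep(2, tt), mrna_flat = rep(3, tt),
             mir = up)
  tri <- data.frame(lincRNA = c("lnc_dn", "lnc_up", "lnc_flat"),
                    mirna_id = "mir",
                    mRNA = c("mrna_dn", "mrna_up", "mrna_flat"))
  out <- partition_networks(tri, x, n_timepoints = tt)
  expect_equal(out$network, c("I", "II", "unassigned"))
  tallies <- attr(out, "tallies")
  expect_equal(unname(tallies$I["triplets"]), 1)
})

test_that("true triplets land in the network matching their generated direction", {
  cfg <- expr_sim_config(n_genes = 500, n_mirnas = 30, noise_sd = 0.1, seed = 1)
  sim <- simulate_expression(cfg)
  cl <- simulate_cerna_layer(cfg, sim)
  exprs <- list(sim$a, sim$b, cl$mirna_a, cl$mirna_b)
  kept <- correlation_filter(cl$pairs[cl$pairs$is_true, ], exprs)$pairs
  tri <- build_triplets(kept[kept$target_class == "lincRNA", ],
                        kept[kept$target_class == "mRNA", ], exprs)
  tri <- partition_networks(tri, exprs, n_timepoints = nrow(sim$a$meta))
  dir <- sim$truth$genes$archetype[match(tri$mRNA, sim$truth$genes$gene_id)]
  expect_true(all(tri$network[dir == "down"] == "I"))
  expect_true(all(tri$network[dir == "up"] == "II"))
  expect_gt(nrow(tri), 5)
})

test_that("guilt-by-association lists strongly co-expressed partners only", {
  rows <- cor_fixture()
  gba <- guilt_by_association("lnc_pos7", rows, r_min = 0.5, p_max = 0.05)
  expect_true("mir" %in% rownames(rows))
  expect_false("t_neg6" %in% gba$gene_id)
  expect_true(all(gba$r > 0.5))
})
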