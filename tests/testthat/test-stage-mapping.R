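test_that("DAG calling applies both the abundance and the Z arm", {
  # gene rows engineered so thresholds bind one arm at a time
  x <- rbind(high_spike = c(5, 0.2, 0.2, 0.2, 0.2, 0.2),
             low_spike = c(0.5, 0.01, 0.01, 0.01, 0.01, 0.01),
             constant = c(5, 5, 5, 5, 5, 5))
  m <- make_expr(x, meta = tiny_meta(6))
  gs <- gene_stats(m)
  expect_gt(gs$z["high_spike", 1], 2)  # spike well above Z threshold
  dags <- call_dags(m, gs)
  expect_true("high_spike" %in% dags$sets$t1)       # RPKM 5, Z > 1.5
  expect_false("low_spike" %in% dags$sets$t1)       # Z high, RPKM 0.5 fails
  expect_false("constant" %in% unlist(dags$sets))   # Z = 0 everywhere
})

test_that("mapping scores match exact hypergeometric arithmetic", {
  # N = 20, |A| = |B| = 5, full overlap: raw P = 1/choose(20, 5)
  universe <- paste0("g", 1:20)
  setA <- universe[1:5]
  dagsA <- structure(list(sets = rep(list(setA), 27), condition = "A"),
                     class = "dag_sets")
  dagsB <- structure(list(sets = rep(list(setA), 27), condition = "B"),
                     class = "dag_sets")
  msm <- mapping_score_matrix(dagsA, dagsB, universe)
  expect_equal(msm$raw_p[1, 1], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(msm$m, 729)
  expect_equal(msm$score[1, 1], -log10(min(1, 729 / choose(20, 5))),
               tolerance = 1e-9)
  expect_equal(msm$score[1, 1], 1.3278, tolerance = 1e-4)
})

test_that("empty draws score zero and foreign ids are rejected", {
  universe <- paste0("g", 1:10)
  empty <- structure(list(sets = list(t1 = character()), condition = "A"),
                     class = "dag_sets")
  full <- structure(list(sets = list(t1 = universe[1:3]), condition = "B"),
                    class = "dag_sets")
  msm <- mapping_score_matrix(empty, full, universe)
  expect_equal(msm$raw_p[1, 1], 1)
  expect_equal(msm$score[1, 1], 0)
  alien <- structure(list(sets = list(t1 = "not_a_gene"), condition = "B"),
                     class = "dag_sets")
  expect_error(mapping_score_matrix(alien, full, universe), "outside the universe")
})

test_that("raw P matches an independent PMF-summation oracle", {
  set.seed(7)
  for (trial in 1:200) {
    n_univ <- sample(20:200, 1)
    na <- sample.int(n_univ, 1); nb <- sample.int(n_univ, 1)
    k <- sample.int(min(na, nb), 1)
    p_impl <- phyper(k - 1, nb, n_univ - nb, na, lower.tail = FALSE)
    p_orac <- hyper_upper_oracle(k, nb, n_univ, na)
    expect_equal(p_impl, p_orac, tolerance = 1e-12)
  }
})

test_that("identical DAG courses put the row maximum on the diagonal", {
  set.seed(21)
  universe <- paste0("g", 1:200)
  sets <- lapply(1:4, function(i) sample(universe, 30))
  mk <- function(cond) structure(list(sets = setNames(sets, paste0("t", 1:4)),
                                      condition = cond), class = "dag_sets")
  msm <- mapping_score_matrix(mk("A"), mk("B"), universe)
  for (i in 1:4)
    expect_equal(msm$score[i, i], max(msm$score[i, ]))
})

test_that("maximum trace solves the base case and a hand-enumerated 3x3", {
  tr1 <- maximum_trace(matrix(7, 1, 1))
  expect_equal(tr1$path, cbind(i = 1L, j = 1L))
  expect_equal(tr1$total, 7)

  m <- rbind(c(1, 0, 0), c(0, 5, 0), c(9, 0, 1))
  tr <- maximum_trace(m)
  expect_equal(tr$total, 11)  # exhaustive enumeration over all 13 paths
  expect_equal(brute_max_trace(m), 11)
  expect_equal(tr$path,
               cbind(i = c(1L, 2L, 3L, 3L, 3L), j = c(1L, 1L, 1L, 2L, 3L)))

  diag10 <- diag(10, 5)
  trd <- maximum_trace(diag10)
  expect_equal(trd$path, cbind(i = 1:5, j = 1:5), ignore_attr = TRUE)
  expect_equal(trd$total, 50)
})

test_that("DP total equals brute-force enumeration on random matrices", {
  set.seed(99)
  for (trial in 1:300) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    m <- matrix(round(runif(nr * nc, 0, 10), 2), nr, nc)
    expect_equal(maximum_trace(m)$total, brute_max_trace(m))
  }
})

test_that("trace is transpose-symmetric and shifts additively", {
  set.seed(17)
  m <- matrix(runif(36, 0, 5), 6, 6)
  tr <- maximum_trace(m)
  trt <- maximum_trace(t(m))
  expect_equal(trt$total, tr$total)
  # the transposed optimum is the coordinate-swapped path set; totals agree
  swapped <- tr$path[, c(2, 1), drop = FALSE]
  expect_equal(sum(t(m)[swapped]), tr$total)
  # adding a constant c raises the total by c * path length
  c0 <- 3.5
  tr2 <- maximum_trace(m + c0)
  expect_equal(tr2$total, tr$total + c0 * nrow(tr$path))
  expect_equal(tr2$path, tr$path)
})

test_that("traceback tie rule prefers diagonal, then vertical", {
  m <- matrix(0, 3, 3)  # all paths tie
  tr <- maximum_trace(m)
  expect_equal(tr$path, cbind(i = 1:3, j = 1:3), ignore_attr = TRUE)
  m2 <- rbind(c(0, 0), c(0, 0), c(0, 0))  # 3x2: diagonal then vertical
  tr2 <- maximum_trace(m2)
  expect_equal(tr2$path, cbind(i = c(1L, 2L, 3L), j = c(1L, 1L, 2L)),
               ignore_attr = TRUE)
})

test_that("scores are finite, nonnegative and capped", {
  universe <- paste0("g", seq_len(2000))
  setA <- universe[1:800]
  dagsA <- structure(list(sets = list(t1 = setA), condition = "A"),
                     class = "dag_sets")
  dagsB <- structure(list(sets = list(t1 = setA), condition = "B"),
                     class = "dag_sets")
  msm <- mapping_score_matrix(dagsA, dagsB, universe)
  expect_true(is.finite(msm$score[1, 1]))
  expect_lte(msm$score[1, 1], 300)
  expect_gte(min(msm$score), 0)
})

test_that("diagonal traces summarize as synchronous; off-diagonal cells flag lag", {
  trd <- maximum_trace(diag(10, 5))
  sm <- summarize_mapping(trd)
  expect_true(all(sm$class == "synchronous"))
  expect_true(all(sm$lag == 0))
  expect_equal(attr(sm, "modal_interior_lag"), 0)

  # a path visiting (2,1): A time 2 maps to earlier B time -> A is behind
  m <- rbind(c(5, 0, 0), c(5, 0, 0), c(0, 5, 5))
  sm2 <- summarize_mapping(maximum_trace(m))
  expect_equal(sm2$lag[2], -1)
  expect_equal(sm2$class[2], "A-lags")
})

test_that("injected developmental lag is recovered as the modal interior lag", {
  cfg <- expr_sim_config(n_genes = 2000, lag_steps = 2, frac_lagged = 0.6,
                         noise_sd = 0.2, seed = 1)
  sim <- simulate_expression(cfg)
  msm <- mapping_score_matrix(call_dags(sim$a, gene_stats(sim$a)),
                              call_dags(sim$b, gene_stats(sim$b)),
                              rownames(sim$a$expr))
  sm <- summarize_mapping(maximum_trace(msm), sim$a$meta, sim$b$meta)
  expect_equal(attr(sm, "modal_interior_lag"), 2)
  # positive lag: A maps to later B time points, so condition B lags
  expect_gt(sum(sm$class == "B-lags"), sum(sm$class == "A-lags"))
})
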