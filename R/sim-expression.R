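#' Configuration for the expression time-course simulator
#'
#' Defines the study conditions the generator emulates: a two-condition
#' developmental time course (default: the 27-stage design of
#' [pig_timepoints()]) with per-gene trajectory archetypes, log-scale
#' Gaussian noise, and an optional integer developmental lag injected into
#' condition B.
#'
#' Archetypes (mean trajectories):
#' * `up` / `down`: abundance-affine monotone ramps `b + a*s(t)` with
#'   `s(t) = (t-1)/(T-1)` (so same-direction genes are exactly collinear in
#'   the noise-free limit — the property the ceRNA layer builds on);
#' * `bump-<Phase>`: phase-specific expression on the log2 scale — a
#'   plateau of `bump_amp / 2` log2 units across the phase (the
#'   phase-level signal that one-vs-rest testing detects) plus a Gaussian
#'   peak of another `bump_amp / 2` units at a random time point inside
#'   the phase (width `bump_sd` indices). After the exponential
#'   back-transform the peak dominates the trajectory's variance, so the
#'   gene exceeds the DAG Z threshold only at its centre time point — the
#'   resolution required for stage-level alignment;
#' * `flat`: constant.
#'
#' @param n_genes number of genes (pcg + lincRNA rows).
#' @param n_mirnas number of miRNAs for [simulate_cerna_layer()].
#' @param timepoints metadata data.frame (`timepoint, day_numeric, phase`).
#' @param lag_steps integer time-point shift applied to condition B for
#'   lagged genes (B's mean trajectory equals A's shifted right, edges
#'   clamped); must be < number of time points.
#' @param frac_lagged proportion of genes receiving the lag, in \[0, 1\].
#' @param noise_sd sd of Gaussian noise on the log2 abundance scale.
#' @param module_archetypes archetype labels to draw from; bump archetypes
#'   are written `bump-<Phase>`.
#' @param archetype_weights sampling weights, same length.
#' @param bump_amp,bump_sd bump amplitude (log2 units) and width (indices).
#' @param frac_lincRNA,frac_tf fraction of genes that are lincRNAs, and of
#'   protein-coding genes flagged as transcription factors.
#' @param conditions labels for the two conditions.
#' @param seed master RNG seed; every generator substream derives from it.
#' @return A validated list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 2000, n_mirnas = 60,
                            timepoints = pig_timepoints(),
                            lag_steps = 0, frac_lagged = 0, noise_sd = 0.2,
                            module_archetypes = NULL,
                            archetype_weights = NULL,
                            bump_amp = 6, bump_sd = 0.7,
                            frac_lincRNA = 0.2, frac_tf = 0.1,
                            conditions = c("A", "B"), seed = 1) {
  if (!is_count(n_genes)) stopf("n_genes must be a positive count")
  if (!(length(n_mirnas) == 1 && n_mirnas >= 0)) stopf("n_mirnas must be >= 0")
  validate_phase_scheme(timepoints)
  tt <- nrow(timepoints)
  if (!(lag_steps == as.integer(lag_steps) && lag_steps >= 0))
    stopf("lag_steps must be a nonnegative integer")
  if (lag_steps >= tt)
    stopf("lag_steps (%d) must be smaller than the number of time points (%d)",
          lag_steps, tt)
  if (frac_lagged < 0 || frac_lagged > 1) stopf("frac_lagged must lie in [0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  phases <- rle(timepoints$phase)$values
  if (is.null(module_archetypes)) {
    module_archetypes <- c("up", "down", "flat", paste0("bump-", phases))
    archetype_weights <- c(0.15, 0.15, 0.10, rep(0.60 / length(phases),
                                                 length(phases)))
  }
  if (is.null(archetype_weights))
    archetype_weights <- rep(1 / length(module_archetypes),
                             length(module_archetypes))
  if (length(archetype_weights) != length(module_archetypes))
    stopf("archetype_weights must match module_archetypes")
  structure(list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
                 timepoints = timepoints, lag_steps = as.integer(lag_steps),
                 frac_lagged = frac_lagged, noise_sd = noise_sd,
                 module_archetypes = module_archetypes,
                 archetype_weights = archetype_weights,
                 bump_amp = bump_amp, bump_sd = bump_sd,
                 frac_lincRNA = frac_lincRNA, frac_tf = frac_tf,
                 conditions = conditions, seed = as.integer(seed)),
            class = "expr_sim_config")
}

# Mean abundance trajectories for all genes (rows) over time indices 1..T.
# Returns list(mean = matrix, pars = per-gene parameter data.frame).
sim_mean_trajectories <- function(cfg) {
  tt <- nrow(cfg$timepoints)
  idx <- seq_len(tt)
  s <- (idx - 1) / (tt - 1)
  arch <- sample(cfg$module_archetypes, cfg$n_genes, replace = TRUE,
                 prob = cfg$archetype_weights)
  base_log2 <- runif(cfg$n_genes, -1, 2)
  amp_ramp <- 2^runif(cfg$n_genes, 2, 7)
  center <- rep(NA_integer_, cfg$n_genes)
  mu <- matrix(0, cfg$n_genes, tt)
  phase_of <- cfg$timepoints$phase
  for (g in seq_len(cfg$n_genes)) {
    a <- arch[g]
    if (a == "up") {
      mu[g, ] <- 2^base_log2[g] + amp_ramp[g] * s
    } else if (a == "down") {
      mu[g, ] <- 2^base_log2[g] + amp_ramp[g] * (1 - s)
    } else if (a == "flat") {
      mu[g, ] <- 2^runif(1, -1, 5)
    } else {  # bump-<Phase>: phase-wide plateau plus a peak at the centre
      ph <- sub("^bump-", "", a)
      cand <- idx[phase_of == ph]
      center[g] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      half <- cfg$bump_amp / 2
      mu[g, ] <- 2^(base_log2[g] + half * (phase_of == ph) +
                      half * exp(-(idx - center[g])^2 / (2 * cfg$bump_sd^2)))
    }
  }
  list(mean = mu,
       pars = data.frame(archetype = arch, bump_center = center,
                         stringsAsFactors = FALSE))
}

# Shift a trajectory matrix right by `lag` steps, clamping at the left edge.
shift_right <- function(mu, lag) {
  if (lag == 0) return(mu)
  tt <- ncol(mu)
  src <- pmax(seq_len(tt) - lag, 1L)
  mu[, src, drop = FALSE]
}

#' Simulate two-condition expression time courses with known ground truth
#'
#' Draws per-gene mean trajectories from the configured archetypes, injects
#' an integer developmental lag into condition B for a random subset of
#' genes (`frac_lagged`), multiplies by `2^N(0, noise_sd)` noise, and
#' returns both condition matrices plus a `sim_truth` record (per-gene
#' archetype, bump centre, lag status, and the noise-free mean trajectories
#' of both conditions).
#'
#' @param cfg an [expr_sim_config()].
#' @return list with elements `a`, `b` (both [expression_matrix()]) and
#'   `truth` (class `sim_truth`).
#' @examples
#' sim <- simulate_expression(expr_sim_config(n_genes = 50, noise_sd = 0,
#'                                            seed = 7))
#' all(sim$a$expr == sim$b$expr)  # no lag, no noise: conditions agree
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  tt <- nrow(cfg$timepoints)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  traj <- with_seed(sub_seed(cfg$seed, "expression"), sim_mean_trajectories(cfg))
  mu_a <- traj$mean
  lagged <- with_seed(sub_seed(cfg$seed, "lag"), {
    n_lag <- round(cfg$frac_lagged * cfg$n_genes)
    sort(sample(cfg$n_genes, n_lag))
  })
  mu_b <- mu_a
  if (cfg$lag_steps > 0 && length(lagged))
    mu_b[lagged, ] <- shift_right(mu_a[lagged, , drop = FALSE], cfg$lag_steps)
  noise <- function(seed_tag, mu) {
    if (cfg$noise_sd == 0) return(mu)
    with_seed(sub_seed(cfg$seed, seed_tag),
              mu * 2^matrix(rnorm(length(mu), 0, cfg$noise_sd),
                            nrow(mu), ncol(mu)))
  }
  xa <- noise("noise_a", mu_a)
  xb <- noise("noise_b", mu_b)
  biotype <- with_seed(sub_seed(cfg$seed, "expression") + 1L, {
    bt <- ifelse(runif(cfg$n_genes) < cfg$frac_lincRNA, "lincRNA", "pcg")
    tf <- bt == "pcg" & runif(cfg$n_genes) < cfg$frac_tf
    list(bt = bt, tf = tf)
  })
  dimnames(xa) <- list(gene_ids, paste0(cfg$conditions[1], "_",
                                        cfg$timepoints$timepoint))
  dimnames(xb) <- list(gene_ids, paste0(cfg$conditions[2], "_",
                                        cfg$timepoints$timepoint))
  rownames(mu_a) <- rownames(mu_b) <- gene_ids
  truth <- structure(list(
    genes = data.frame(gene_id = gene_ids,
                       archetype = traj$pars$archetype,
                       bump_center = traj$pars$bump_center,
                       lagged = seq_len(cfg$n_genes) %in% lagged,
                       biotype = biotype$bt, tf = biotype$tf,
                       stringsAsFactors = FALSE),
    lag_steps = cfg$lag_steps,
    mean_a = mu_a, mean_b = mu_b,
    mirna_targets = NULL, sweeps = NULL), class = "sim_truth")
  list(a = expression_matrix(xa, biotype$bt, cfg$conditions[1],
                             cfg$timepoints, tf = biotype$tf),
       b = expression_matrix(xb, biotype$bt, cfg$conditions[2],
                             cfg$timepoints, tf = biotype$tf),
       truth = truth)
}

#' Simulate the miRNA layer of a ceRNA experiment
#'
#' Adds miRNA (TPM) time courses on top of a simulated gene layer. Half of
#' the miRNAs (rounded up) are "true" regulators: each picks a trajectory
#' direction, lincRNA and mRNA targets of that same direction and the same
#' lag status, and receives a mean trajectory that is a negative affine
#' transform of its targets' mean trajectory — so in the noise-free limit
#' Pearson R(miRNA, target) is exactly -1 for every true pair. The
#' remaining miRNAs are decoys with randomized trajectories, paired with
#' random genes; downstream correlation filters should discard them.
#'
#' @param cfg the [expr_sim_config()] used for the gene layer.
#' @param sim the result of [simulate_expression()] (list `a`, `b`, `truth`).
#' @return list with `mirna_a`, `mirna_b` ([expression_matrix()] of TPM),
#'   `pairs` (data.frame `mirna_id, target_id, target_class, is_true`), and
#'   the updated `truth`.
#' @export
simulate_cerna_layer <- function(cfg, sim) {
  stopifnot(inherits(cfg, "expr_sim_config"), inherits(sim$truth, "sim_truth"))
  tt <- nrow(cfg$timepoints)
  if (cfg$n_mirnas == 0L) {
    warnf("n_mirnas = 0: returning an empty miRNA layer")
    empty <- matrix(numeric(0), 0, tt,
                    dimnames = list(NULL, paste0(cfg$conditions[1], "_",
                                                 cfg$timepoints$timepoint)))
    return(list(mirna_a = NULL, mirna_b = NULL,
                pairs = data.frame(mirna_id = character(),
                                   target_id = character(),
                                   target_class = character(),
                                   is_true = logical()),
                truth = sim$truth))
  }
  g <- sim$truth$genes
  out <- with_seed(sub_seed(cfg$seed, "cerna"), {
    n_true <- ceiling(cfg$n_mirnas / 2)
    n_decoy <- cfg$n_mirnas - n_true
    ids <- sprintf("miR%03d", seq_len(cfg$n_mirnas))
    mu_a <- matrix(0, cfg$n_mirnas, tt)
    mu_b <- matrix(0, cfg$n_mirnas, tt)
    pairs <- list()
    for (i in seq_len(n_true)) {
      dir <- sample(c("up", "down"), 1L)
      lag_status <- sample(c(TRUE, FALSE), 1L,
                           prob = c(cfg$frac_lagged, 1 - cfg$frac_lagged))
      pool <- g[g$archetype == dir & g$lagged == lag_status, , drop = FALSE]
      if (nrow(pool) < 3L)  # fall back on direction only
        pool <- g[g$archetype == dir, , drop = FALSE]
      n_lnc <- min(sum(pool$biotype == "lincRNA"), sample(1:2, 1L))
      n_m <- min(sum(pool$biotype == "pcg"), sample(2:4, 1L))
      lnc <- sample(pool$gene_id[pool$biotype == "lincRNA"], n_lnc)
      mrna <- sample(pool$gene_id[pool$biotype == "pcg"], n_m)
      tgt <- c(lnc, mrna)
      if (length(tgt) == 0L) next
      b_m <- 2^runif(1, 0, 2); a_m <- 2^runif(1, 4, 9)
      for (cond in c("a", "b")) {
        tbar <- colMeans(sim$truth[[paste0("mean_", cond)]][tgt, , drop = FALSE])
        rng <- max(tbar) - min(tbar)
        if (rng == 0) rng <- 1
        traj <- b_m + a_m * (max(tbar) - tbar) / rng
        if (cond == "a") mu_a[i, ] <- traj else mu_b[i, ] <- traj
      }
      pairs[[length(pairs) + 1L]] <-
        data.frame(mirna_id = ids[i], target_id = tgt,
                   target_class = ifelse(tgt %in% lnc, "lincRNA", "mRNA"),
                   is_true = TRUE, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_decoy) + n_true) {
      mu_a[i, ] <- 2^(runif(1, 2, 8) + rnorm(tt, 0, 1))
      mu_b[i, ] <- 2^(runif(1, 2, 8) + rnorm(tt, 0, 1))
      tgt <- sample(g$gene_id, sample(2:4, 1L))
      pairs[[length(pairs) + 1L]] <-
        data.frame(mirna_id = ids[i], target_id = tgt,
                   target_class = ifelse(
                     g$biotype[match(tgt, g$gene_id)] == "lincRNA",
                     "lincRNA", "mRNA"),
                   is_true = FALSE, stringsAsFactors = FALSE)
    }
    list(ids = ids, mu_a = mu_a, mu_b = mu_b,
         pairs = do.call(rbind, pairs))
  })
  noise <- function(tag, mu) {
    if (cfg$noise_sd == 0) return(mu)
    with_seed(sub_seed(cfg$seed, "cerna") + match(tag, c("a", "b")),
              mu * 2^matrix(rnorm(length(mu), 0, cfg$noise_sd),
                            nrow(mu), ncol(mu)))
  }
  xa <- noise("a", out$mu_a); xb <- noise("b", out$mu_b)
  dimnames(xa) <- list(out$ids, paste0(cfg$conditions[1], "_",
                                       cfg$timepoints$timepoint))
  dimnames(xb) <- list(out$ids, paste0(cfg$conditions[2], "_",
                                       cfg$timepoints$timepoint))
  truth <- sim$truth
  truth$mirna_targets <- out$pairs
  list(mirna_a = expression_matrix(xa, rep("miRNA", nrow(xa)),
                                   cfg$conditions[1], cfg$timepoints),
       mirna_b = expression_matrix(xb, rep("miRNA", nrow(xb)),
                                   cfg$conditions[2], cfg$timepoints),
       pairs = out$pairs, truth = truth)
}
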