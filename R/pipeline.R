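#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], with
#' every stage threshold at its documented default. The list round-trips
#' losslessly through YAML ([yaml::write_yaml()] / [yaml::read_yaml()]).
#'
#' @param seed master seed for every stage (default 1).
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    # synthetic expression layer
    n_genes = 2000L, n_mirnas = 60L, lag_steps = 0L, frac_lagged = 0,
    noise_sd = 0.2,
    # expression thresholds
    expressed_threshold = 0.1, rpkm_min = 1.0, z_min = 1.5,
    # differential expression
    lfc_cut = 1.0, fdr_cut = 0.05,
    # co-expression
    cv_min = 0.5, k = 12L, k_range = c(2L, 10L),
    # ceRNA
    r_cut = 0.5, p_cut = 0.05, rho_min = 0.3,
    # genotype layer
    n_snps = 20000L, n_individuals_per_pop = 20L, chrom_length = 2e7,
    fst_target = 0.2, sweep_start = numeric(), sweep_end = numeric(),
    sweep_pop = character(),
    # sweep scan
    window = 50000L, step = 10000L, min_snps = 10L,
    fst_quantile = 0.95, ratio_tail = 0.05,
    # LD / structure
    max_dist = 300000L, bin_bp = 100L, n_components = 2L, bootstrap = 0L,
    # optional external inputs
    expr_a = NULL, expr_b = NULL, expr_meta = NULL, vcf = NULL,
    pop_a_samples = NULL, pop_b_samples = NULL, genes_annotation = NULL),
    class = "run_config")
}

#' Read or resolve a pipeline configuration
#'
#' @param config NULL (defaults), a path to a YAML file, or a named list of
#'   overrides; unknown keys are rejected.
#' @return a complete `run_config` list.
#' @export
read_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), names(base))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  base[names(config)] <- config
  base$seed <- as.integer(base$seed)
  base
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on either synthetic
#' or user-supplied inputs, writes each stage's outputs as TSV (plus
#' newick for the tree) into `out_dir`, echoes the fully resolved
#' configuration as `config.yaml`, and returns a manifest of all written
#' files with their MD5 checksums. Identical configuration and seed give
#' byte-identical outputs.
#'
#' Stages: `simulate` (expression + miRNA layer), `stats`, `mds`, `de`
#' (per-phase two-group tests between conditions), `phase-specific`,
#' `trajectory-de`, `stage-map`, `coexpress`, `cerna`, `simulate-geno`,
#' `sweep`, `ld`, `pca`, `tree`. A stage whose upstream inputs are neither
#' scheduled nor configured fails with an error naming the stage to run
#' first.
#'
#' @param config NULL, YAML path, or named list of overrides (see
#'   [read_config()]).
#' @param stages character vector of stage names (default: a standard
#'   expression run `simulate, stats, stage-map`).
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest (`stage, file, md5`), invisibly.
#' @export
run_pipeline <- function(config = NULL, stages = c("simulate", "stats", "stage-map"),
                         out_dir = tempfile("devomap_run_")) {
  cfg <- read_config(config)
  all_stages <- c("simulate", "stats", "mds", "de", "phase-specific",
                  "trajectory-de", "stage-map", "coexpress", "cerna",
                  "simulate-geno", "sweep", "ld", "pca", "tree")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]  # dependency order
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  manifest <- list()
  emit <- function(stage, name, df) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name, md5 = unname(tools::md5sum(path)),
      stringsAsFactors = FALSE)
  }

  need_expr <- function(stage) {
    if (!is.null(st$sim)) return(invisible())
    if (!is.null(cfg$expr_a) && !is.null(cfg$expr_b) && !is.null(cfg$expr_meta)) {
      st$sim <- list(a = load_expression(cfg$expr_a, cfg$expr_meta),
                     b = load_expression(cfg$expr_b, cfg$expr_meta),
                     truth = NULL)
      return(invisible())
    }
    stopf("stage '%s' needs expression data: run stage 'simulate' first or set expr_a/expr_b/expr_meta",
          stage)
  }
  need_geno <- function(stage) {
    if (!is.null(st$geno)) return(invisible())
    if (!is.null(cfg$vcf)) {
      st$geno <- load_and_filter(cfg$vcf, pops = list(A = cfg$pop_a_samples,
                                                      B = cfg$pop_b_samples))
      return(invisible())
    }
    stopf("stage '%s' needs genotypes: run stage 'simulate-geno' first or set vcf",
          stage)
  }
  need_stats <- function(stage) {
    need_expr(stage)
    if (is.null(st$stats_a)) {
      st$stats_a <- gene_stats(st$sim$a, cfg$expressed_threshold)
      st$stats_b <- gene_stats(st$sim$b, cfg$expressed_threshold)
    }
  }

  for (stage in stages) {
    switch(stage,
      "simulate" = {
        ecfg <- expr_sim_config(n_genes = cfg$n_genes, n_mirnas = cfg$n_mirnas,
                                lag_steps = cfg$lag_steps,
                                frac_lagged = cfg$frac_lagged,
                                noise_sd = cfg$noise_sd, seed = cfg$seed)
        st$sim <- simulate_expression(ecfg)
        if (cfg$n_mirnas > 0) {
          st$cerna_sim <- simulate_cerna_layer(ecfg, st$sim)
          st$sim$truth <- st$cerna_sim$truth
        }
        for (side in c("a", "b")) {
          write_expression(st$sim[[side]],
                           file.path(out_dir, sprintf("expr_%s.tsv", side)),
                           if (side == "a") file.path(out_dir, "timepoints.tsv"))
          manifest[[length(manifest) + 1L]] <- data.frame(
            stage = stage, file = sprintf("expr_%s.tsv", side),
            md5 = unname(tools::md5sum(file.path(out_dir, sprintf("expr_%s.tsv", side)))),
            stringsAsFactors = FALSE)
        }
        emit(stage, "sim_truth_genes.tsv", st$sim$truth$genes)
      },
      "stats" = {
        need_stats(stage)
        emit(stage, "gene_stats_a.tsv", st$stats_a$summary)
        emit(stage, "gene_stats_b.tsv", st$stats_b$summary)
      },
      "mds" = {
        need_expr(stage)
        fit <- classical_mds(list(st$sim$a, st$sim$b),
                             expressed_threshold = cfg$expressed_threshold)
        emit(stage, "mds_coordinates.tsv",
             data.frame(sample = rownames(fit$points),
                        dim1 = fit$points[, 1], dim2 = fit$points[, 2]))
      },
      "de" = {
        need_expr(stage)
        phases <- rle(st$sim$a$meta$phase)$values
        res <- lapply(phases, function(ph) {
          ga <- paste0(st$sim$a$condition, "_",
                       st$sim$a$meta$timepoint[st$sim$a$meta$phase == ph])
          gb <- paste0(st$sim$b$condition, "_",
                       st$sim$b$meta$timepoint[st$sim$b$meta$phase == ph])
          de <- two_group_de(list(st$sim$a, st$sim$b), ga, gb,
                             lfc_cut = cfg$lfc_cut, fdr_cut = cfg$fdr_cut)
          de$comparison <- paste0("A_vs_B_", ph)
          de
        })
        emit(stage, "de_between_conditions.tsv", do.call(rbind, res))
      },
      "phase-specific" = {
        need_expr(stage)
        ps <- phase_specific_genes(st$sim$a, st$sim$b,
                                   fdr_cut = cfg$fdr_cut, lfc_cut = cfg$lfc_cut)
        emit(stage, "phase_specific_genes.tsv", attr(ps, "table"))
      },
      "trajectory-de" = {
        need_expr(stage)
        emit(stage, "trajectory_de.tsv",
             trajectory_interaction_test(st$sim$a, st$sim$b,
                                         fdr_cut = cfg$fdr_cut))
      },
      "stage-map" = {
        need_stats(stage)
        dags_a <- call_dags(st$sim$a, st$stats_a, cfg$rpkm_min, cfg$z_min)
        dags_b <- call_dags(st$sim$b, st$stats_b, cfg$rpkm_min, cfg$z_min)
        universe <- intersect(rownames(st$sim$a$expr), rownames(st$sim$b$expr))
        msm <- mapping_score_matrix(dags_a, dags_b, universe)
        trace <- maximum_trace(msm)
        summ <- summarize_mapping(trace, st$sim$a$meta, st$sim$b$meta)
        emit(stage, "mapping_scores.tsv",
             data.frame(a_timepoint = rownames(msm$score), msm$score,
                        check.names = FALSE))
        emit(stage, "maximum_trace.tsv",
             data.frame(a_timepoint = trace$labels$a, b_timepoint = trace$labels$b,
                        score = trace$scores))
        emit(stage, "mapping_summary.tsv", summ)
        st$mapping_summary <- summ
      },
      "coexpress" = {
        need_stats(stage)
        ids <- intersect(select_high_cv(st$stats_a, cfg$cv_min),
                         select_high_cv(st$stats_b, cfg$cv_min))
        z <- cbind(st$stats_a$z[ids, , drop = FALSE],
                   st$stats_b$z[ids, , drop = FALSE])
        fom <- figure_of_merit(z, k_range = seq(cfg$k_range[1], cfg$k_range[2]),
                               seed = cfg$seed)
        mods <- kmeans_modules(z, cfg$k, seed = cfg$seed,
                               biotype = st$sim$a$biotype[match(ids, rownames(st$sim$a$expr))],
                               tf = st$sim$a$tf[match(ids, rownames(st$sim$a$expr))])
        emit(stage, "fom_curve.tsv", fom)
        emit(stage, "modules.tsv", mods$assignment)
        emit(stage, "module_summary.tsv", mods$tallies)
      },
      "cerna" = {
        need_expr(stage)
        if (is.null(st$cerna_sim))
          stopf("stage 'cerna' needs a miRNA layer: run stage 'simulate' with n_mirnas > 0")
        exprs <- list(st$sim$a, st$sim$b, st$cerna_sim$mirna_a, st$cerna_sim$mirna_b)
        pairs <- st$cerna_sim$pairs
        flt <- correlation_filter(pairs, exprs, cfg$r_cut, cfg$p_cut)
        kept <- flt$pairs
        tri <- build_triplets(kept[kept$target_class == "lincRNA", ],
                              kept[kept$target_class == "mRNA", ],
                              exprs, cfg$r_cut, cfg$p_cut)
        tri <- partition_networks(tri, exprs,
                                  n_timepoints = nrow(st$sim$a$meta),
                                  rho_min = cfg$rho_min)
        emit(stage, "cerna_edges.tsv", flt$edges)
        emit(stage, "cerna_triplets.tsv", as.data.frame(tri))
      },
      "simulate-geno" = {
        sw <- if (length(cfg$sweep_start))
          data.frame(start = cfg$sweep_start, end = cfg$sweep_end,
                     pop = cfg$sweep_pop) else NULL
        gcfg <- geno_sim_config(n_snps = cfg$n_snps,
                                n_individuals_per_pop = cfg$n_individuals_per_pop,
                                chrom_length = cfg$chrom_length,
                                fst_target = cfg$fst_target,
                                sweep_intervals = sw, seed = cfg$seed)
        vcf <- file.path(out_dir, "genotypes.vcf")
        gs <- simulate_genotypes(gcfg, vcf_path = vcf)
        st$geno <- gs$genotypes
        st$geno_truth <- gs$truth
        manifest[[length(manifest) + 1L]] <- data.frame(
          stage = stage, file = "genotypes.vcf",
          md5 = unname(tools::md5sum(vcf)), stringsAsFactors = FALSE)
      },
      "sweep" = {
        need_geno(stage)
        pa <- windowed_pi(st$geno, "A", cfg$window, cfg$step, cfg$chrom_length)
        pb <- windowed_pi(st$geno, "B", cfg$window, cfg$step, cfg$chrom_length)
        fst <- windowed_fst(st$geno, "A", "B", cfg$window, cfg$step,
                            cfg$min_snps, cfg$chrom_length)
        scan <- sweep_scan(pa, pb, fst, cfg$fst_quantile, cfg$ratio_tail)
        emit(stage, "window_stats.tsv", as.data.frame(scan$windows))
        emit(stage, "sweep_regions.tsv", as.data.frame(scan$regions))
        if (!is.null(cfg$genes_annotation)) {
          ann <- annotate_regions(scan$regions, cfg$genes_annotation)
          emit(stage, "selected_genes.tsv", ann)
        }
        st$scan <- scan
      },
      "ld" = {
        need_geno(stage)
        emit(stage, "ld_decay_A.tsv", ld_decay(st$geno, "A", cfg$max_dist, cfg$bin_bp))
        emit(stage, "ld_decay_B.tsv", ld_decay(st$geno, "B", cfg$max_dist, cfg$bin_bp))
      },
      "pca" = {
        need_geno(stage)
        emit(stage, "pca_scores.tsv", genotype_pca(st$geno, cfg$n_components)$scores)
      },
      "tree" = {
        need_geno(stage)
        phy <- nj_tree(st$geno, bootstrap = cfg$bootstrap, seed = cfg$seed)
        path <- file.path(out_dir, "nj_tree.nwk")
        ape::write.tree(phy, path)
        manifest[[length(manifest) + 1L]] <- data.frame(
          stage = stage, file = "nj_tree.nwk", md5 = unname(tools::md5sum(path)),
          stringsAsFactors = FALSE)
      })
  }
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  man <- do.call(rbind, manifest)
  write_tsv(man, file.path(out_dir, "manifest.tsv"))
  invisible(man)
}
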