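#' Call development-associated genes (DAGs) per time point
#'
#' A gene is a DAG at time point t when its abundance exceeds `rpkm_min`
#' (distinguishable from background) AND its within-gene Z score at t
#' exceeds `z_min` (highly expressed at t relative to the rest of the time
#' course). Defaults follow the RPKM > 1.0, Z > 1.5 rule.
#'
#' @param m an `expr_matrix`.
#' @param stats the matching [gene_stats()] result (Z on the raw abundance
#'   scale within this condition).
#' @param rpkm_min,z_min the two thresholds (strict inequalities).
#' @return object of class `dag_sets`: named list `sets` of gene-id vectors
#'   (one per time point) plus the condition label.
#' @export
call_dags <- function(m, stats, rpkm_min = 1.0, z_min = 1.5) {
  if (nrow(m$expr) == 0L) stopf("empty expression matrix")
  stopifnot(inherits(stats, "gene_stats"))
  if (!identical(rownames(stats$z), rownames(m$expr)))
    stopf("stats were not computed on this matrix")
  hit <- m$expr > rpkm_min & stats$z > z_min
  sets <- lapply(seq_len(ncol(hit)), function(j) rownames(hit)[hit[, j]])
  names(sets) <- m$meta$timepoint
  structure(list(sets = sets, condition = m$condition,
                 rpkm_min = rpkm_min, z_min = z_min), class = "dag_sets")
}

#' @export
print.dag_sets <- function(x, ...) {
  n <- lengths(x$sets)
  cat(sprintf("dag_sets: condition '%s', %d time points, %d-%d DAGs per point\n",
              x$condition, length(n), min(n), max(n)))
  invisible(x)
}

#' Hypergeometric mapping-score matrix between two DAG time courses
#'
#' For every time-point pair (i, j), tests whether the overlap of
#' condition A's DAG set at i and condition B's at j is larger than
#' expected for independent draws from the shared gene universe, with the
#' upper-tail hypergeometric probability P(X >= k). Raw P-values are
#' Bonferroni-corrected (factor `m = T_A * T_B` by default) and the mapping
#' score is `-log10(corrected P)`, clamped to \[0, 300\] (corrected P floored
#' at 1e-300). High scores mark transcriptionally similar stage pairs.
#'
#' @param dagsA,dagsB `dag_sets` for the two conditions.
#' @param universe gene-id vector of the shared universe (or its size).
#'   Every DAG set must be a subset when ids are given.
#' @param bonferroni_m correction factor; default `T_A * T_B`.
#' @param score_cap upper clamp for scores (default 300).
#' @return object of class `mapping_score_matrix`: matrices `score`, `k`
#'   (shared DAG counts), `raw_p`, vectors `size_a`, `size_b`, scalars
#'   `m`, `universe_n`.
#' @export
mapping_score_matrix <- function(dagsA, dagsB, universe,
                                 bonferroni_m = NULL, score_cap = 300) {
  stopifnot(inherits(dagsA, "dag_sets"), inherits(dagsB, "dag_sets"))
  if (is.character(universe)) {
    n_univ <- length(universe)
    for (s in c(dagsA$sets, dagsB$sets))
      if (length(setdiff(s, universe)))
        stopf("DAG set contains ids outside the universe (e.g. '%s')",
              setdiff(s, universe)[1L])
  } else {
    n_univ <- as.integer(universe)
  }
  ta <- length(dagsA$sets); tb <- length(dagsB$sets)
  if (ta == 0L || tb == 0L) stopf("empty DAG list")
  size_a <- lengths(dagsA$sets); size_b <- lengths(dagsB$sets)
  if (n_univ < max(size_a, size_b))
    stopf("universe size %d smaller than the largest DAG set", n_univ)
  m_corr <- if (is.null(bonferroni_m)) ta * tb else bonferroni_m
  k <- raw_p <- matrix(0, ta, tb,
                       dimnames = list(names(dagsA$sets), names(dagsB$sets)))
  for (i in seq_len(ta)) for (j in seq_len(tb)) {
    kij <- length(intersect(dagsA$sets[[i]], dagsB$sets[[j]]))
    k[i, j] <- kij
    # upper tail P(X >= k); k = 0 gives P = 1 by convention
    raw_p[i, j] <- phyper(kij - 1, size_b[j], n_univ - size_b[j], size_a[i],
                          lower.tail = FALSE)
  }
  corrected <- pmax(pmin(m_corr * raw_p, 1), 1e-300)
  score <- pmin(pmax(-log10(corrected), 0), score_cap)
  score[corrected >= 1] <- 0  # avoid IEEE negative zero in output
  structure(list(score = score, k = k, raw_p = raw_p,
                 size_a = size_a, size_b = size_b,
                 m = m_corr, universe_n = n_univ), class = "mapping_score_matrix")
}

#' @export
print.mapping_score_matrix <- function(x, ...) {
  cat(sprintf("mapping_score_matrix: %d x %d, Bonferroni m = %d, universe %d\n",
              nrow(x$score), ncol(x$score), x$m, x$universe_n))
  cat(sprintf("  score range [%.3g, %.3g]\n", min(x$score), max(x$score)))
  invisible(x)
}

#' Maximum trace through a mapping-score matrix by dynamic programming
#'
#' Finds the monotone staircase path from cell (1, 1) to (T_A, T_B) —
#' moves restricted to right, down and diagonal — that maximizes the sum
#' of mapping scores over the cells it passes through (both endpoints
#' included). The recurrence accumulates, for each cell (i, j), the largest
#' attainable sum from (1, 1), then traces back from (T_A, T_B).
#' Tie-breaking during traceback is deterministic: diagonal is preferred,
#' then vertical (advance the row condition), then horizontal.
#'
#' @param m a `mapping_score_matrix`, or a plain numeric matrix of scores.
#' @return object of class `trace_result`: `path` (two-column matrix of
#'   (i, j) cells in order), `labels` (time-point labels when available),
#'   `total` (sum of scores on the path), `scores` (per-cell score).
#' @export
maximum_trace <- function(m) {
  sc <- if (inherits(m, "mapping_score_matrix")) m$score else as.matrix(m)
  ta <- nrow(sc); tb <- ncol(sc)
  if (ta == 0L || tb == 0L) stopf("empty score matrix")
  best <- matrix(-Inf, ta, tb)
  best[1, 1] <- sc[1, 1]
  for (i in seq_len(ta)) for (j in seq_len(tb)) {
    if (i == 1L && j == 1L) next
    pred <- -Inf
    if (i > 1L) pred <- max(pred, best[i - 1L, j])
    if (j > 1L) pred <- max(pred, best[i, j - 1L])
    if (i > 1L && j > 1L) pred <- max(pred, best[i - 1L, j - 1L])
    best[i, j] <- sc[i, j] + pred
  }
  # traceback, preferring diagonal, then vertical, then horizontal
  path <- list(c(ta, tb))
  i <- ta; j <- tb
  while (!(i == 1L && j == 1L)) {
    diag <- if (i > 1L && j > 1L) best[i - 1L, j - 1L] else -Inf
    vert <- if (i > 1L) best[i - 1L, j] else -Inf
    horz <- if (j > 1L) best[i, j - 1L] else -Inf
    mv <- max(diag, vert, horz)
    if (diag == mv) {
      i <- i - 1L; j <- j - 1L
    } else if (vert == mv) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    path[[length(path) + 1L]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  colnames(path) <- c("i", "j")
  labels <- if (!is.null(dimnames(sc)))
    data.frame(a = rownames(sc)[path[, 1]], b = colnames(sc)[path[, 2]],
               stringsAsFactors = FALSE) else NULL
  structure(list(path = path, labels = labels, total = best[ta, tb],
                 scores = sc[path]), class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("trace_result: %d cells, total score %.4g\n",
              nrow(x$path), x$total))
  invisible(x)
}

#' Summarize a maximum trace into per-time-point mapping spans and lags
#'
#' For each row-condition (A) time point, reports the span of column (B)
#' time points sharing trace cells with it and the lag
#' `median(B index) - A index`. Sign convention: positive lag means the
#' row condition maps to LATER column time points (the row condition is
#' developmentally ahead; the column condition lags). Classification per
#' time point: `synchronous` (lag 0), `B-lags` (lag > 0), `A-lags`
#' (lag < 0). The modal lag over interior time points (endpoints are
#' forced to (1,1) and (T_A,T_B)) summarizes the global offset.
#'
#' @param trace a `trace_result`.
#' @param metaA,metaB optional time-point metadata for label output.
#' @return data.frame (one row per A time point) with columns `a_index,
#'   a_timepoint, b_span, lag, class`; attributes `modal_interior_lag` and
#'   `class_counts`.
#' @export
summarize_mapping <- function(trace, metaA = NULL, metaB = NULL) {
  stopifnot(inherits(trace, "trace_result"))
  p <- trace$path
  ta <- max(p[, 1])
  rows <- lapply(seq_len(ta), function(i) {
    js <- p[p[, 1] == i, 2]
    lag <- median(js) - i
    data.frame(a_index = i,
               a_timepoint = if (!is.null(metaA)) metaA$timepoint[i] else
                 as.character(i),
               b_span = paste0(min(js), "-", max(js)),
               lag = lag,
               class = if (lag == 0) "synchronous" else
                 if (lag > 0) "B-lags" else "A-lags",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(metaB)) {
    span <- strsplit(out$b_span, "-")
    out$b_span <- vapply(span, function(s)
      paste0(metaB$timepoint[as.integer(s[1])], "-",
             metaB$timepoint[as.integer(s[2])]), "")
  }
  interior <- out$lag[-c(1L, nrow(out))]
  attr(out, "modal_interior_lag") <- modal_int(interior)
  attr(out, "class_counts") <- table(out$class)
  out
}
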