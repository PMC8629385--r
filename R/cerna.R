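#' Predict miRNA targets by canonical seed matching
#'
#' A built-in, tool-free target predictor: a target transcript is paired
#' with a miRNA when it contains at least one canonical seed site —
#' 7mer-m8 (exact reverse complement of miRNA positions 2-8), 7mer-A1
#' (reverse complement of positions 2-7 followed by an A opposite
#' position 1), or their union, the 8mer. Matching is case-insensitive and
#' treats U and T as equivalent. Overlapping site hits are merged
#' greedily left-to-right so each non-overlapping occurrence counts once.
#' Externally predicted pair lists (e.g. the intersection of dedicated
#' prediction tools) can be supplied to [correlation_filter()] instead.
#'
#' @param mirna_seqs miRNA sequences: a named character vector, a
#'   [Biostrings::RNAStringSet]/[Biostrings::DNAStringSet], or a FASTA path.
#' @param target_seqs candidate target sequences, same accepted forms.
#' @param target_class target class per sequence (`"mRNA"` or `"lincRNA"`),
#'   recycled.
#' @return data.frame of class `target_pairs`: `mirna_id, target_id,
#'   target_class, site_count, site_types, source`.
#' @examples
#' seed_match_targets(c(miR1 = "UGGAAUGUAAAGAAGUAUGUA"),
#'                    c(t1 = "GGGACAUUCCAGG"))  # 7mer-m8 site ACAUUCC
#' @export
seed_match_targets <- function(mirna_seqs, target_seqs, target_class = "mRNA") {
  mir <- normalize_seqs(mirna_seqs, "miRNA")
  tgt <- normalize_seqs(target_seqs, "target")
  target_class <- rep_len(target_class, length(tgt))
  out <- list()
  for (mi in seq_along(mir)) {
    s <- mir[[mi]]
    if (nchar(s) < 8L) stopf("miRNA '%s' shorter than 8 nt", names(mir)[mi])
    m8 <- revcomp_dna(substr(s, 2L, 8L))
    a1 <- paste0(revcomp_dna(substr(s, 2L, 7L)), "A")
    mer8 <- paste0(m8, "A")
    for (ti in seq_along(tgt)) {
      hits <- site_hits(tgt[[ti]], mer8, m8, a1)
      if (nrow(hits) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = names(mir)[mi], target_id = names(tgt)[ti],
        target_class = target_class[ti], site_count = nrow(hits),
        site_types = paste(hits$type, collapse = ","),
        source = "builtin-seed-match", stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character(), site_count = integer(),
               site_types = character(), source = character())
  class(res) <- c("target_pairs", class(res))
  res
}

# Uppercase DNA-alphabet sequences (U -> T) from the accepted input forms.
normalize_seqs <- function(x, what) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x)))
    x <- Biostrings::readBStringSet(x)
  if (inherits(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x) || is.null(names(x)))
    stopf("%s sequences must be named (or a FASTA path)", what)
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stopf("%s sequence '%s' contains characters outside A/C/G/T/U",
          what, names(x)[bad][1L])
  as.list(x)
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Non-overlapping canonical site occurrences in one target sequence.
# Preference at a given start: 8mer > 7mer-m8 > 7mer-A1.
site_hits <- function(target, mer8, m8, a1) {
  subj <- Biostrings::DNAString(target)
  starts <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
    BiocGenerics::start(m)
  }
  cand <- rbind(
    if (length(s <- starts(mer8))) data.frame(start = s, width = 8L, type = "8mer"),
    if (length(s <- starts(m8))) data.frame(start = s, width = 7L, type = "7mer-m8"),
    if (length(s <- starts(a1))) data.frame(start = s, width = 7L, type = "7mer-A1"))
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.frame(start = integer(), width = integer(), type = character()))
  pref <- match(cand$type, c("8mer", "7mer-m8", "7mer-A1"))
  cand <- cand[order(cand$start, pref), ]
  kept <- list(); last_end <- 0L
  for (r in seq_len(nrow(cand))) {
    if (cand$start[r] > last_end) {
      kept[[length(kept) + 1L]] <- cand[r, ]
      last_end <- cand$start[r] + cand$width[r] - 1L
    }
  }
  do.call(rbind, kept)
}

#' Filter miRNA-target pairs by expression anticorrelation
#'
#' Computes the Pearson correlation of each miRNA-target pair across the
#' concatenated time courses of both conditions (two-sided P from the
#' t-distribution on n-2 df) and keeps pairs satisfying the repression
#' signature R < -`r_cut` with P < `p_cut`.
#'
#' @param pairs a `target_pairs` data.frame (built-in or external; needs
#'   columns `mirna_id, target_id, target_class`).
#' @param exprs named list of `expr_matrix` objects covering every id in
#'   `pairs` (gene and miRNA layers of both conditions); columns are
#'   concatenated per id.
#' @param r_cut,p_cut thresholds (defaults 0.5 and 0.05).
#' @return list with `edges` (all pairs with `r` and `p`) and `pairs`
#'   (the surviving subset).
#' @export
correlation_filter <- function(pairs, exprs, r_cut = 0.5, p_cut = 0.05) {
  expr <- stack_expr(exprs)
  need <- unique(c(pairs$mirna_id, pairs$target_id))
  missing <- setdiff(need, rownames(expr))
  if (length(missing))
    stopf("no expression rows for: %s",
          paste(head(missing, 5L), collapse = ", "))
  rp <- pair_cor(expr, pairs$mirna_id, pairs$target_id)
  edges <- cbind(pairs, r = rp$r, p = rp$p)
  keep <- !is.na(rp$r) & rp$r < -r_cut & rp$p < p_cut
  list(edges = edges, pairs = pairs[keep, , drop = FALSE])
}

# Row-bind expression matrices by condition, cbind conditions; returns a
# plain id x sample abundance matrix over the union of ids.
stack_expr <- function(exprs) {
  if (inherits(exprs, "expr_matrix")) return(exprs$expr)
  if (is.matrix(exprs)) return(exprs)
  conds <- unique(vapply(exprs, function(m) m$condition, ""))
  blocks <- lapply(conds, function(cd) {
    ms <- Filter(function(m) m$condition == cd, exprs)
    do.call(rbind, lapply(ms, function(m) m$expr))
  })
  ids <- Reduce(intersect, lapply(blocks, rownames))
  do.call(cbind, lapply(blocks, function(b) b[ids, , drop = FALSE]))
}

# Pearson r and two-sided t-distribution P for paired rows of `expr`.
pair_cor <- function(expr, id1, id2) {
  n <- ncol(expr)
  r <- vapply(seq_along(id1), function(i)
    suppressWarnings(cor(expr[id1[i], ], expr[id2[i], ])), 0)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[is.na(r)] <- NA_real_
  list(r = r, p = p)
}

#' Assemble ceRNA triplets from filtered miRNA-target pairs
#'
#' For each miRNA, forms the cross product of its surviving lincRNA
#' partners and mRNA partners and retains a lincRNA-miRNA-mRNA triplet iff
#' the lincRNA-mRNA expression correlation passes the positive arm
#' (R > `r_cut`, P < `p_cut`). Duplicate input pairs are deduplicated, so
#' triplets are unique. Each emitted triplet therefore satisfies all
#' three sign/threshold constraints: miRNA-lincRNA R < -`r_cut`,
#' miRNA-mRNA R < -`r_cut`, lincRNA-mRNA R > `r_cut`, each with
#' P < `p_cut`.
#'
#' @param lnc_pairs,mrna_pairs surviving miRNA-lincRNA and miRNA-mRNA
#'   pairs (from [correlation_filter()]).
#' @param exprs expression input as in [correlation_filter()].
#' @param r_cut,p_cut thresholds for the lincRNA-mRNA positive arm.
#' @return data.frame of class `cerna_triplets`: `lincRNA, mirna_id, mRNA,
#'   r_mir_lnc, p_mir_lnc, r_mir_mrna, p_mir_mrna, r_lnc_mrna, p_lnc_mrna`.
#' @export
build_triplets <- function(lnc_pairs, mrna_pairs, exprs, r_cut = 0.5,
                           p_cut = 0.05) {
  expr <- stack_expr(exprs)
  lnc_pairs <- unique(lnc_pairs[, c("mirna_id", "target_id")])
  mrna_pairs <- unique(mrna_pairs[, c("mirna_id", "target_id")])
  mirnas <- intersect(unique(lnc_pairs$mirna_id), unique(mrna_pairs$mirna_id))
  rows <- list()
  for (mi in mirnas) {
    lncs <- lnc_pairs$target_id[lnc_pairs$mirna_id == mi]
    mrnas <- mrna_pairs$target_id[mrna_pairs$mirna_id == mi]
    grid <- expand.grid(lincRNA = lncs, mRNA = mrnas,
                        stringsAsFactors = FALSE)
    if (nrow(grid) == 0L) next
    lm <- pair_cor(expr, grid$lincRNA, grid$mRNA)
    keep <- !is.na(lm$r) & lm$r > r_cut & lm$p < p_cut
    if (!any(keep)) next
    grid <- grid[keep, , drop = FALSE]
    ml <- pair_cor(expr, rep(mi, nrow(grid)), grid$lincRNA)
    mm <- pair_cor(expr, rep(mi, nrow(grid)), grid$mRNA)
    rows[[length(rows) + 1L]] <- data.frame(
      lincRNA = grid$lincRNA, mirna_id = mi, mRNA = grid$mRNA,
      r_mir_lnc = ml$r, p_mir_lnc = ml$p,
      r_mir_mrna = mm$r, p_mir_mrna = mm$p,
      r_lnc_mrna = lm$r[keep], p_lnc_mrna = lm$p[keep],
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lincRNA = character(), mirna_id = character(),
               mRNA = character(), r_mir_lnc = numeric(),
               p_mir_lnc = numeric(), r_mir_mrna = numeric(),
               p_mir_mrna = numeric(), r_lnc_mrna = numeric(),
               p_lnc_mrna = numeric())
  rownames(res) <- NULL
  class(res) <- c("cerna_triplets", class(res))
  res
}

#' Partition ceRNA triplets into the two opposing-trend networks
#'
#' Network I collects triplets whose lincRNA and mRNA are down-regulated
#' over development (Spearman rho against the time index <= -`rho_min` for
#' both, miRNA consequently up); network II collects the up-regulated
#' counterparts (both rho >= `rho_min`); everything else is unassigned.
#' The time index runs 1..T within each condition's block of columns.
#'
#' @param triplets a `cerna_triplets` data.frame.
#' @param exprs expression input as in [correlation_filter()].
#' @param n_timepoints number of time points per condition block (used to
#'   build the time index; defaults to all columns as one block).
#' @param rho_min trend threshold (default 0.3).
#' @return `triplets` with an added `network` column (`"I"`, `"II"`,
#'   `"unassigned"`) and attribute `tallies` (nodes per class per network).
#' @export
partition_networks <- function(triplets, exprs, n_timepoints = NULL,
                               rho_min = 0.3) {
  expr <- stack_expr(exprs)
  tt <- if (is.null(n_timepoints)) ncol(expr) else n_timepoints
  tindex <- rep_len(seq_len(tt), ncol(expr))
  rho_of <- function(ids) {
    u <- unique(ids)
    r <- vapply(u, function(g)
      suppressWarnings(cor(expr[g, ], tindex, method = "spearman")), 0)
    r[is.na(r)] <- 0  # flat transcript: no trend
    r[match(ids, u)]
  }
  rho_l <- rho_of(triplets$lincRNA)
  rho_m <- rho_of(triplets$mRNA)
  net <- ifelse(rho_l <= -rho_min & rho_m <= -rho_min, "I",
                ifelse(rho_l >= rho_min & rho_m >= rho_min, "II",
                       "unassigned"))
  triplets$network <- net
  tallies <- lapply(split(triplets, net), function(d)
    c(lincRNAs = length(unique(d$lincRNA)),
      miRNAs = length(unique(d$mirna_id)),
      mRNAs = length(unique(d$mRNA)),
      triplets = nrow(d)))
  attr(triplets, "tallies") <- tallies
  triplets
}

#' Co-expressed partners of a lincRNA (guilt-by-association annotation)
#'
#' Lists the protein-coding genes whose expression correlates with a given
#' lincRNA above `r_min` at P < `p_max` across the concatenated time
#' courses — the association list used to transfer functional annotation
#' onto uncharacterized lincRNAs.
#'
#' @param lincrna_id lincRNA id.
#' @param exprs expression input as in [correlation_filter()].
#' @param candidate_ids ids to screen (default: all other rows).
#' @param r_min,p_max thresholds (defaults 0.5 and 0.001).
#' @return data.frame `gene_id, r, p`, sorted by decreasing r.
#' @export
guilt_by_association <- function(lincrna_id, exprs, candidate_ids = NULL,
                                 r_min = 0.5, p_max = 0.001) {
  expr <- stack_expr(exprs)
  if (!lincrna_id %in% rownames(expr)) stopf("no expression row for '%s'", lincrna_id)
  if (is.null(candidate_ids))
    candidate_ids <- setdiff(rownames(expr), lincrna_id)
  rp <- pair_cor(expr, rep(lincrna_id, length(candidate_ids)), candidate_ids)
  keep <- !is.na(rp$r) & rp$r > r_min & rp$p < p_max
  out <- data.frame(gene_id = candidate_ids[keep], r = rp$r[keep],
                    p = rp$p[keep], stringsAsFactors = FALSE)
  out[order(-out$r), , drop = FALSE]
}
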