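# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a deterministic sub-seed for a named operation from a master seed.
# Keeps every generator on its own substream while staying reproducible.
sub_seed <- function(seed, what) {
  offsets <- c(expression = 11L, lag = 23L, cerna = 37L, decoy = 41L,
               genotypes = 53L, sweep = 67L, noise_a = 71L, noise_b = 83L)
  off <- offsets[[what]]
  if (is.null(off)) stop("unknown substream: ", what)
  (as.integer(seed) * 101L + off) %% .Machine$integer.max
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x > 0
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Modal value of a numeric vector; ties broken toward the value of smallest
# absolute magnitude, then the smaller value, so results are deterministic.
modal_int <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  vals <- as.numeric(names(tab))
  best <- vals[tab == max(tab)]
  best[order(abs(best), best)][1L]
}
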