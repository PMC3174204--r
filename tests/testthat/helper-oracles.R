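# Independent oracles used to cross-check the package implementations.
# These deliberately use only base R and naive algorithms.

# Textbook pooled-variance two-sample t-test.
oracle_ttest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# Exhaustive every-window substring scan for one pattern (0-based intervals).
oracle_window_scan <- function(utr, pattern) {
  utr <- chartr("Tt", "Uu", toupper(utr)); pattern <- chartr("T", "U", toupper(pattern))
  k <- nchar(pattern); L <- nchar(utr)
  if (k > L) return(integer())
  starts <- integer()
  for (i in seq_len(L - k + 1L)) {
    if (substr(utr, i, i + k - 1L) == pattern) starts <- c(starts, i - 1L)
  }
  starts
}

# Brute-force all-ordered-triples feed-forward-loop scan.
oracle_ffl_scan <- function(edges) {
  nodes <- unique(c(edges$source, edges$target))
  has <- function(a, b) any(edges$source == a & edges$target == b)
  sgn <- function(a, b) edges$sign[edges$source == a & edges$target == b]
  rows <- list()
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (x == y || y == z || x == z) next
    if (has(x, y) && has(y, z) && has(x, z)) {
      rows[[length(rows) + 1L]] <- data.frame(
        x = x, y = y, z = z,
        sign_xy = sgn(x, y), sign_yz = sgn(y, z), sign_xz = sgn(x, z),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$x, out$y, out$z), , drop = FALSE]
}

# Shared miRNA object (miR-125b mature sequence; seed-binding CUCAGGG).
test_mirna <- function() mirna_sequence("miR-125b", "UCCCUGAGACCCUAACUUGUGA")

# Random RNA sequence.
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
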