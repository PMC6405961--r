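# internal helpers shared across the package

# the 20 standard amino acids
AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

# residues counted as charged (His excluded by convention)
CHARGED <- c("D","E","K","R")

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

.pkg_cache <- new.env(parent = emptyenv())

# BLOSUM62 as shipped with Biostrings, cached after first use
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# derive a stream-specific child seed, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# windowed fraction of positions whose character is in `set`;
# the window at position i is [i - before, i + after] clipped to the string
windowed_fraction <- function(xchars, set, before = 7L, after = 7L) {
  n <- length(xchars)
  ind <- as.numeric(xchars %in% set)
  cs <- c(0, cumsum(ind))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
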