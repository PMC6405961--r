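# shared fixtures, built once per test run

# a small balanced dataset covering every splice version of every class
fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_balanced_dataset(12L, seed = 42L, make_cdnas = FALSE)
    cache
  }
})

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force all-substring motif scan used as an oracle
scan_motif_oracle <- function(protein, motif) {
  n <- nchar(protein); m <- nchar(motif)
  if (m > n) return(integer(0))
  out <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    seg <- substr(protein, i, i + m - 1L)
    if (seg == motif && !grepl("X", seg, fixed = TRUE))
      out <- c(out, i - 1L)
  }
  out
}

# a random additive tree on n leaves and its exact leaf-to-leaf distances
random_additive_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = d[order(rownames(d)), order(colnames(d))])
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
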