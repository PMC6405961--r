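# Synthetic seroin generator.
#
# The generator emulates the sequence features the classification rules key
# on: a ~20-residue signal peptide (module A), charged/Ala-Ser-Glu-Asp-rich
# B modules carrying short class-conserved anchor blocks, Pro-rich C
# linkers, class-diagnostic motifs (Sn1: Trp ~20 residues after the initial
# Met in a charged context; Sn2: Gly-rich 20-50 stretch with an RYGG motif;
# Sn3: Trp near position 35 plus a VYGE motif), and splice versions that
# drop or truncate modules relative to the long AB1C1B2C2B3 form.

.norm_comp <- function(x) x / sum(x)

# class parameterization: module length ranges (residues), module
# compositions, conserved anchor blocks, allowed splice versions
sn_params <- local({
  sn1_b <- .norm_comp(c(A = .18, S = .15, E = .14, D = .13, K = .09, R = .07,
                        T = .06, G = .05, Q = .04, N = .03, V = .02, L = .02,
                        I = .01, F = .01, Y = .01, H = .01, M = .01))
  sn2_b <- .norm_comp(c(S = .20, E = .16, A = .12, G = .10, D = .10, K = .06,
                        R = .05, T = .06, Q = .04, N = .03, V = .02, L = .02,
                        Y = .01, I = .01, F = .01, H = .005, M = .005))
  sn2_b1 <- .norm_comp(c(G = .36, S = .14, A = .12, E = .08, D = .06,
                         Y = .05, K = .04, R = .04, T = .04, N = .03,
                         Q = .02, V = .01, L = .005, I = .005))
  sn3_b <- .norm_comp(c(D = .16, E = .14, A = .14, S = .12, T = .08, K = .08,
                        R = .06, N = .05, G = .04, Q = .04, V = .03, L = .02,
                        I = .01, F = .01, Y = .01, H = .005, M = .005))
  sn1_c <- .norm_comp(c(P = .55, S = .10, A = .08, T = .07, Q = .06, V = .05,
                        N = .04, G = .03, E = .02))
  sn2_c <- .norm_comp(c(P = .50, G = .09, S = .09, A = .08, T = .07, Q = .06,
                        N = .04, V = .04, E = .03))
  sn3_c <- .norm_comp(c(P = .50, A = .11, S = .09, T = .08, N = .07, Q = .06,
                        V = .04, G = .03, E = .02))
  function() list(
    Sn1 = list(
      a_range = c(18L, 20L),
      ranges = list(B1 = c(12L, 18L), C1 = c(28L, 38L), B2 = c(46L, 58L),
                    C2 = c(9L, 14L), B3 = c(52L, 68L)),
      b_comp = list(B1 = sn1_b, B2 = sn1_b, B3 = sn1_b),
      c_comp = sn1_c,
      anchors = list(B1 = "EWEDKKRDE", B2 = "DAEKSAEEA", B3 = "EDKAASEEKA"),
      versions = c("L", "N", "C")),
    Sn2 = list(
      a_range = c(18L, 22L),
      ranges = list(B1 = c(34L, 46L), C1 = c(9L, 14L), B2 = c(30L, 44L),
                    C2 = c(27L, 32L), B3 = c(90L, 108L)),
      b_comp = list(B1 = sn2_b1, B2 = sn2_b, B3 = sn2_b),
      c_comp = sn2_c,
      anchors = list(B1 = "GSGRYGGYGGAGG", B2 = "SSEEGAGES",
                     B3 = "AGSEESAGSE"),
      versions = c("L", "C", "T1", "T2")),
    Sn3 = list(
      a_range = c(18L, 22L),
      ranges = list(B1 = c(38L, 42L), C1 = c(10L, 20L), B2 = c(98L, 110L),
                    C2 = c(28L, 34L), B3 = c(55L, 62L)),
      b_comp = list(B1 = sn3_b, B2 = sn3_b, B3 = sn3_b),
      c_comp = sn3_c,
      anchors = list(B1 = "NWAEVYGESDK", B2 = "DSTEAKDST", B3 = "EASDKTESDA"),
      versions = c("L", "T"))
  )
})

# canonical module subsets per splice version; names give the modules kept,
# TRUE marks a module generated complete, FALSE one truncated (incomplete)
version_patterns <- function(seroin_class) {
  pats <- list(
    Sn1 = list(L = c(A = TRUE, B1 = TRUE, C1 = TRUE, B2 = TRUE, C2 = TRUE,
                     B3 = TRUE),
               N = c(A = TRUE, B1 = TRUE, C1 = TRUE, B2 = TRUE),
               C = c(A = TRUE, B1 = TRUE, C2 = TRUE, B3 = TRUE)),
    Sn2 = list(L = c(A = TRUE, B1 = TRUE, C1 = TRUE, B2 = TRUE, C2 = TRUE,
                     B3 = TRUE),
               C = c(A = TRUE, B1 = TRUE, C2 = TRUE, B3 = TRUE),
               T1 = c(A = TRUE, B1 = TRUE, C1 = TRUE, B2 = FALSE, C2 = FALSE,
                      B3 = TRUE),
               T2 = c(A = TRUE, B1 = FALSE, C1 = FALSE, B2 = TRUE, C2 = TRUE,
                      B3 = TRUE)),
    Sn3 = list(L = c(A = TRUE, B1 = TRUE, C1 = TRUE, B2 = TRUE, C2 = TRUE,
                     B3 = TRUE),
               T = c(A = TRUE, B1 = TRUE, C1 = TRUE, B3 = TRUE))
  )
  if (missing(seroin_class)) return(pats)
  pats[[match.arg(seroin_class, names(pats))]]
}

# default (midpoint) module lengths used for completeness judgements
module_defaults <- function(seroin_class) {
  p <- sn_params()[[match.arg(seroin_class, c("Sn1", "Sn2", "Sn3"))]]
  c(A = mean(p$a_range),
    vapply(p$ranges, mean, numeric(1)))
}

# truncation factor for modules marked incomplete in a splice pattern
INCOMPLETE_FACTOR <- 0.35

.sample_comp <- function(n, comp) {
  if (n <= 0) return(character(0))
  sample(names(comp), n, replace = TRUE, prob = comp)
}

.plant <- function(x, motif, at) {
  # overwrite x (character vector) with motif starting at 1-based `at`
  m <- chars(motif)
  if (at < 1 || at + length(m) - 1L > length(x))
    stop("motif offset outside its module")
  x[at:(at + length(m) - 1L)] <- m
  x
}

#' Construct a synthetic seroin specification
#'
#' A specification is the ground-truth recipe for one generated seroin:
#' class, splice version, per-module lengths and the seed that makes the
#' sequence reproducible. Module lengths are sampled from class-specific
#' ranges unless supplied.
#'
#' @param seroin_class one of \code{"Sn1"}, \code{"Sn2"}, \code{"Sn3"}.
#' @param version a splice version allowed for the class (Sn1: L, N, C;
#'   Sn2: L, C, T1, T2; Sn3: L, T).
#' @param seed integer seed controlling all sequence randomness.
#' @param module_lengths optional named integer vector with entries
#'   \code{A, B1, C1, B2, C2, B3} overriding the sampled full-length sizes.
#' @return an object of class \code{"seroin_spec"}.
#' @export
seroin_spec <- function(seroin_class, version = "L", seed = 1L,
                        module_lengths = NULL) {
  seroin_class <- match.arg(seroin_class, c("Sn1", "Sn2", "Sn3"))
  p <- sn_params()[[seroin_class]]
  if (!version %in% p$versions)
    stop("version ", version, " is not defined for class ", seroin_class)
  if (is.null(module_lengths)) {
    module_lengths <- with_seed(derive_seed(seed, 1L), {
      lens <- c(A = sample(p$a_range[1]:p$a_range[2], 1L),
                vapply(p$ranges, function(r) sample(r[1]:r[2], 1L),
                       numeric(1)))
      if (seroin_class == "Sn1")            # keep the diagnostic Trp < 25
        lens["A"] <- sample(18:20, 1L)
      # mature length capped at 250 residues
      excess <- sum(lens) - lens["A"] - 250
      if (excess > 0) lens["B2"] <- lens["B2"] - excess
      lens
    })
  }
  structure(list(seroin_class = seroin_class, version = version,
                 module_lengths = module_lengths, seed = as.integer(seed)),
            class = "seroin_spec")
}

# generate the full-length module sequences for one gene (shared by all of
# its splice isoforms); returns a named list of character vectors
.gene_modules <- function(spec) {
  p <- sn_params()[[spec$seroin_class]]
  lens <- spec$module_lengths
  with_seed(derive_seed(spec$seed, 2L), {
    # module A: Met + hydrophobic core + short polar tail
    core <- sample(c("L", "V", "A", "I", "F", "S", "T", "G"), 14L,
                   replace = TRUE,
                   prob = c(.22, .20, .18, .15, .10, .05, .05, .05))
    hyd <- core %in% c("L", "V", "A", "I", "F")
    while (sum(hyd) < 10L) {                 # guarantee a hydrophobic core
      k <- which(!hyd)[1]
      core[k] <- sample(c("L", "V", "A", "I"), 1L)
      hyd <- core %in% c("L", "V", "A", "I", "F")
    }
    tail_n <- lens["A"] - 15L
    a <- c("M", core,
           sample(c("S", "T", "N", "Q", "G", "A"), tail_n, replace = TRUE))
    mods <- list(A = a)
    for (b in c("B1", "B2", "B3")) {
      x <- .sample_comp(lens[[b]], p$b_comp[[b]])
      if (b == "B1" && spec$seroin_class == "Sn3") {
        # anchor carries the diagnostic Trp at protein position 34 (0-based)
        off <- 34L - lens[["A"]]            # 1-based offset within B1
        x <- .plant(x, p$anchors$B1, off)
      } else {
        x <- .plant(x, p$anchors[[b]], 1L)
      }
      mods[[b]] <- x
    }
    for (cc in c("C1", "C2")) {
      x <- .sample_comp(lens[[cc]], p$c_comp)
      n <- length(x)
      x[c(1L, 2L, n - 1L, n)] <- "P"        # crisp Pro edges
      mods[[cc]] <- x
    }
    if (spec$seroin_class == "Sn2") {
      # guarantee the Gly-rich 20-50 stretch for every splice version:
      # >= 9 Gly within B1[1..16] and >= 4 Gly within B1[17..30]
      b1 <- mods$B1
      anchor_span <- seq_len(nchar(p$anchors$B1))
      fix_gly <- function(b1, idx, need) {
        have <- sum(b1[idx] == "G")
        free <- setdiff(idx[b1[idx] != "G"], anchor_span)
        while (have < need && length(free)) {
          b1[free[1]] <- "G"
          free <- free[-1]
          have <- have + 1L
        }
        b1
      }
      b1 <- fix_gly(b1, 1:16, 9L)
      b1 <- fix_gly(b1, 17:min(30L, length(b1)), 4L)
      mods$B1 <- b1
    }
    mods
  })
}

#' Generate one synthetic seroin protein with its ground truth
#'
#' Builds the full set of modules for the gene encoded by \code{spec},
#' applies the splice version (dropping absent modules and truncating
#' incomplete ones to a fixed fraction of their full length), and returns
#' the protein together with its true architecture.
#'
#' Diagnostic features planted by construction: Sn1 proteins carry a Trp at
#' 0-based position \code{A+1} (19-21) inside a charged anchor block and a
#' Pro-rich C module downstream; Sn2 proteins carry the RYGG motif near the
#' start of a Gly-rich B1 whose residues 20-50 have Gly fraction >= 0.25;
#' Sn3 proteins carry a Trp at position 34 followed by the VYGE motif.
#'
#' @param spec a [seroin_spec()] object.
#' @param id record identifier (default derived from class/version/seed).
#' @param genus,species species binomial attached to the record.
#' @return a list of class \code{"seroin_truth"} with elements \code{id},
#'   \code{spec}, \code{protein}, \code{cdna} (\code{NULL} until
#'   [make_cdna()] is called), \code{true_architecture} (data frame with
#'   columns label/start/end/complete, 0-based half-open spans) and
#'   \code{species}.
#' @examples
#' r <- make_protein(seroin_spec("Sn2", "L", seed = 7))
#' grepl("RYGG", r$protein)
#' @export
make_protein <- function(spec, id = NULL,
                         genus = "Synthetica", species = "exemplaris") {
  stopifnot(inherits(spec, "seroin_spec"))
  mods <- .gene_modules(spec)
  pat <- version_patterns(spec$seroin_class)[[spec$version]]
  keep <- names(pat)
  parts <- list()
  for (m in keep) {
    x <- mods[[m]]
    if (!pat[[m]]) {                        # incomplete: keep a prefix
      full <- length(x)
      ln <- max(8L, round(INCOMPLETE_FACTOR * full))
      p <- sn_params()[[spec$seroin_class]]
      if (startsWith(m, "B"))                 # stay above window resolution
        ln <- max(ln, nchar(p$anchors[[m]]) + 1L, 16L)
      x <- x[seq_len(ln)]
      if (startsWith(m, "C")) {             # keep the linker Pro-dense
        x[c(length(x) - 1L, length(x))] <- "P"
        n_p <- sum(x == "P")
        need <- ceiling(0.6 * length(x))
        free <- which(x != "P")
        if (n_p < need && length(free))
          x[free[seq_len(min(need - n_p, length(free)))]] <- "P"
      }
    }
    parts[[m]] <- x
  }
  lens <- vapply(parts, length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  arch <- data.frame(label = keep, start = as.integer(starts),
                     end = as.integer(ends),
                     complete = as.logical(pat[keep]),
                     stringsAsFactors = FALSE)
  if (is.null(id))
    id <- sprintf("%s_%s_s%d", spec$seroin_class, spec$version, spec$seed)
  structure(list(id = id, spec = spec,
                 protein = paste(unlist(parts), collapse = ""),
                 cdna = NULL, true_architecture = arch,
                 species = c(genus = genus, species = species)),
            class = "seroin_truth")
}

# codon table for back-translation, built from the standard genetic code
.codons_by_aa <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons
}

#' Back-translate a synthetic seroin into a cDNA
#'
#' Chooses uniformly random synonymous codons for each residue, appends a
#' single stop codon, and attaches random untranslated regions. The 5' UTR
#' is constrained to contain no ATG so that the planted ORF remains the
#' longest one.
#'
#' @param record a \code{"seroin_truth"} record from [make_protein()].
#' @param utr5,utr3 UTR lengths in nucleotides.
#' @param seed integer seed.
#' @return the record with its \code{cdna} field filled in.
#' @export
make_cdna <- function(record, utr5 = 30L, utr3 = 50L, seed = 1L) {
  stopifnot(inherits(record, "seroin_truth"))
  tab <- .codons_by_aa()
  # resample until the planted ORF is the unambiguous longest one (a
  # chance reverse-strand ORF can otherwise outrun a short coding region)
  for (try in 1:50) {
    cdna <- with_seed(derive_seed(seed, 3L + 1000L * (try - 1L)), {
      aa <- chars(record$protein)
      codons <- vapply(aa, function(a) {
        cs <- tab[[a]]
        if (is.null(cs)) stop("cannot back-translate residue ", a)
        cs[sample.int(length(cs), 1L)]
      }, character(1))
      stop_codon <- sample(tab[["*"]], 1L)
      rand_utr <- function(n, forbid_atg) {
        if (n <= 0) return("")
        repeat {
          u <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = "")
          if (!forbid_atg || !grepl("ATG", u, fixed = TRUE)) return(u)
        }
      }
      paste0(rand_utr(utr5, TRUE),
             paste(codons, collapse = ""), stop_codon,
             rand_utr(utr3, FALSE))
    })
    orf <- longest_orf(cdna)
    if (!is.null(orf) && identical(orf$protein, record$protein)) {
      record$cdna <- cdna
      return(record)
    }
  }
  stop("could not back-translate '", record$id,
       "' into a cDNA whose longest ORF is the planted one")
}

#' Generate a ground-truthed synthetic seroin dataset
#'
#' Records are requested per (class, version) cell and assigned to species
#' round-robin. All records of one (species, class) pair are splice
#' isoforms of a single synthetic gene: they share the same underlying
#' module sequences and differ only in which modules the version retains,
#' mirroring alternative splicing. With \code{genes_per_species = 2} the
#' records of a cell alternate between two independently generated paralog
#' genes.
#'
#' @param n_per_cell a data frame with columns \code{class}, \code{version},
#'   \code{n}, or a named integer vector with names like \code{"Sn1:L"}.
#' @param species_pool data frame with columns \code{genus} and
#'   \code{species}; defaults to ten synthetic moth species.
#' @param seed integer master seed.
#' @param genes_per_species 1 or 2 synthetic paralog genes per
#'   (species, class).
#' @param make_cdnas also back-translate every record (default TRUE).
#' @return a list with \code{records} (list of \code{"seroin_truth"}) and
#'   \code{truth} (data frame: id, genus, species, class, version, gene,
#'   protein length, module spans serialized as \code{label:start-end}).
#' @export
make_dataset <- function(n_per_cell, species_pool = NULL, seed = 42L,
                         genes_per_species = 1L, make_cdnas = TRUE) {
  if (!is.data.frame(n_per_cell)) {
    nm <- strsplit(names(n_per_cell), ":", fixed = TRUE)
    n_per_cell <- data.frame(class = vapply(nm, `[`, "", 1L),
                             version = vapply(nm, `[`, "", 2L),
                             n = as.integer(n_per_cell),
                             stringsAsFactors = FALSE)
  }
  if (is.null(species_pool)) {
    species_pool <- data.frame(
      genus = c("Synthetica", "Synthetica", "Fictilis", "Fictilis",
                "Textoria", "Textoria", "Neratia", "Neratia",
                "Bombytes", "Bombytes"),
      species = c("exemplaris", "altera", "prima", "secunda", "sericea",
                  "glandis", "modularis", "versicolor", "simulans",
                  "fabricata"),
      stringsAsFactors = FALSE)
  }
  records <- list()
  rows <- list()
  sp_i <- 0L
  n_sp <- nrow(species_pool)
  counter <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(n_per_cell))) {
    cl <- n_per_cell$class[r]
    ver <- n_per_cell$version[r]
    for (k in seq_len(n_per_cell$n[r])) {
      sp_i <- sp_i + 1L
      sp <- species_pool[((sp_i - 1L) %% n_sp) + 1L, ]
      cell <- paste(sp$genus, sp$species, cl, sep = "|")
      cnt <- (counter[[cell]] %||% 0L) + 1L
      counter[[cell]] <- cnt
      gene <- if (genes_per_species > 1L) ((cnt - 1L) %% genes_per_species) + 1L
              else 1L
      # one seed per (species, class, gene): isoforms share their modules
      sp_idx <- ((sp_i - 1L) %% n_sp) + 1L
      gene_seed <- derive_seed(seed, sp_idx * 100L +
                                 match(cl, c("Sn1", "Sn2", "Sn3")) * 10L +
                                 gene)
      spec <- seroin_spec(cl, ver, seed = gene_seed)
      id <- sprintf("%s%s_%s_%s_g%d_%d",
                    substr(sp$genus, 1, 2), substr(sp$species, 1, 1),
                    cl, ver, gene, cnt)
      rec <- make_protein(spec, id = id, genus = sp$genus,
                          species = sp$species)
      if (make_cdnas)
        rec <- make_cdna(rec, seed = derive_seed(seed, sp_i * 13L + r))
      rec$gene <- gene
      records[[length(records) + 1L]] <- rec
      spans <- paste(sprintf("%s:%d-%d", rec$true_architecture$label,
                             rec$true_architecture$start,
                             rec$true_architecture$end), collapse = ",")
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, genus = sp$genus, species = sp$species,
                   class = cl, version = ver, gene = gene,
                   protein_length = nchar(rec$protein),
                   module_spans = spans, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows)
           else data.frame(id = character(), genus = character(),
                           species = character(), class = character(),
                           version = character(), gene = integer(),
                           protein_length = integer(),
                           module_spans = character(),
                           stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' A balanced synthetic seroin dataset covering all splice versions
#'
#' Convenience wrapper around [make_dataset()] requesting \code{n_per_class}
#' records per class spread over that class's splice versions (Sn1: L, N,
#' C; Sn2: L, C, T1, T2; Sn3: L, T).
#'
#' @param n_per_class records per class (default 100).
#' @param seed master seed (default 42).
#' @param ... passed on to [make_dataset()].
#' @return see [make_dataset()].
#' @export
make_balanced_dataset <- function(n_per_class = 100L, seed = 42L, ...) {
  cells <- list()
  for (cl in c("Sn1", "Sn2", "Sn3")) {
    vers <- sn_params()[[cl]]$versions
    base <- n_per_class %/% length(vers)
    extra <- n_per_class %% length(vers)
    n <- rep(base, length(vers))
    if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
    cells[[cl]] <- data.frame(class = cl, version = vers, n = n,
                              stringsAsFactors = FALSE)
  }
  make_dataset(do.call(rbind, cells), seed = seed, ...)
}

#' Simulate short reads from a set of cDNAs
#'
#' Reads are sampled with the source transcript chosen proportionally to
#' its abundance weight, a uniformly random start position, a uniformly
#' random strand, and independent per-base substitution errors.
#'
#' @param cdnas data frame with columns \code{id} and \code{sequence}.
#' @param abundances named numeric vector of non-negative weights, one per
#'   cDNA id; defaults to uniform.
#' @param read_len read length in nucleotides (default 150).
#' @param n_reads number of reads to draw.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a list with \code{reads} (data frame id/sequence) and
#'   \code{origin} (data frame read id, source id, start, strand).
#' @export
make_reads <- function(cdnas, abundances = NULL, read_len = 150L,
                       n_reads = 1000L, error_rate = 0, seed = 1L) {
  if (is.null(abundances))
    abundances <- stats::setNames(rep(1, nrow(cdnas)), cdnas$id)
  abundances <- abundances[cdnas$id]
  if (any(is.na(abundances) | abundances < 0) || sum(abundances) <= 0)
    stop("abundances must be non-negative weights covering every cDNA")
  if (read_len > min(nchar(cdnas$sequence)))
    stop("read_len exceeds the shortest cDNA")
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, 5L), {
    src <- sample.int(nrow(cdnas), n_reads, replace = TRUE,
                      prob = abundances)
    starts <- integer(n_reads)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- cdnas$sequence[src[i]]
      start <- sample.int(nchar(s) - read_len + 1L, 1L)
      frag <- substr(s, start, start + read_len - 1L)
      if (strands[i] == "-") frag <- reverse_complement(frag)
      if (error_rate > 0) {
        fc <- chars(frag)
        hit <- which(stats::runif(read_len) < error_rate)
        for (h in hit) fc[h] <- sample(setdiff(bases, fc[h]), 1L)
        frag <- paste(fc, collapse = "")
      }
      starts[i] <- start
      seqs[i] <- frag
    }
    read_ids <- sprintf("read%06d", seq_len(n_reads))
    list(reads = data.frame(id = read_ids, sequence = seqs,
                            stringsAsFactors = FALSE),
         origin = data.frame(read = read_ids, source = cdnas$id[src],
                             start = starts - 1L, strand = strands,
                             stringsAsFactors = FALSE))
  })
}

#' Write a synthetic dataset to FASTA and TSV files
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- data.frame(
    id = vapply(dataset$records, `[[`, "", "id"),
    sequence = vapply(dataset$records, `[[`, "", "protein"),
    stringsAsFactors = FALSE)
  paths <- c(proteins = file.path(dir, "proteins.fasta"),
             cdnas = file.path(dir, "cdnas.fasta"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(prot, paths["proteins"])
  has_cdna <- !vapply(dataset$records, function(r) is.null(r$cdna), TRUE)
  if (any(has_cdna)) {
    cd <- data.frame(
      id = vapply(dataset$records[has_cdna], `[[`, "", "id"),
      sequence = vapply(dataset$records[has_cdna], `[[`, "", "cdna"),
      stringsAsFactors = FALSE)
    write_fasta(cd, paths["cdnas"])
  }
  con <- file(paths["truth"], "w")
  writeLines(paste("# synthetic seroin truth table;",
                   "module compositions are generator stand-ins"), con)
  close(con)
  suppressWarnings(utils::write.table(dataset$truth, paths["truth"],
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(paths)
}
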