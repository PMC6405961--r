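#' Read sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a plain data frame with one row per
#' record. Sequences are uppercased and validated against the declared
#' molecule alphabet: \code{"dna"} allows \code{A,C,G,T,N}; \code{"protein"}
#' allows the 20 standard amino acids plus \code{X} (unknown) and \code{*}
#' (stop). Gap characters and any other symbol are rejected with an error
#' naming the offending line.
#'
#' @param path path to a FASTA file.
#' @param molecule either \code{"dna"} or \code{"protein"}.
#' @return a data frame with columns \code{id}, \code{description} and
#'   \code{sequence}. An empty file yields a zero-row data frame.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgt"), tf)
#' read_fasta(tf, "dna")
#' @export
read_fasta <- function(path, molecule = c("dna", "protein")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(set))
  if (anyDuplicated(id))
    stop("duplicate record id in ", path, ": ",
         id[duplicated(id)][1])
  allowed <- if (molecule == "dna") c("A", "C", "G", "T", "N")
             else c(AA20, "X", "*")
  pat <- paste0("[^", paste(gsub("\\*", "\\\\*", allowed), collapse = ""), "]")
  bad <- grepl(pat, sequence)
  if (any(bad)) {
    # locate the first offending line for the error message
    upl <- toupper(lines)
    is_seq <- !startsWith(trimws(upl), ">") & nzchar(trimws(upl))
    badline <- which(is_seq & grepl(pat, trimws(upl)))[1]
    stop(sprintf("illegal %s character in record '%s' (line %d)",
                 molecule, id[bad][1], badline))
  }
  if (any(!nzchar(sequence)))
    stop("empty sequence for record '", id[!nzchar(sequence)][1], "'")
  data.frame(id = unname(id), description = unname(description),
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records a data frame with columns \code{id}, \code{sequence} and
#'   optionally \code{description}.
#' @param path output file path.
#' @param width line-wrapping width (columns) for the sequence, default 60.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records) &&
                nzchar(records$description[i]))
      paste0(" ", records$description[i]) else ""
    writeLines(paste0(">", records$id[i], desc), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read short reads from a FASTA or FASTQ file
#'
#' Quality strings in FASTQ input are ignored; only identifiers and
#' sequences are retained.
#'
#' @param path path to a FASTA or FASTQ file; the format is taken from the
#'   first non-empty character (\code{@} means FASTQ).
#' @return a data frame with columns \code{id}, \code{description},
#'   \code{sequence}.
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(first, "@")) {
    set <- Biostrings::readDNAStringSet(path, format = "fastq")
    headers <- names(set)
    data.frame(id = sub("\\s.*$", "", headers),
               description = ifelse(grepl("\\s", headers),
                                    sub("^\\S+\\s+", "", headers), ""),
               sequence = toupper(as.character(set)),
               stringsAsFactors = FALSE)
  } else {
    read_fasta(path, "dna")
  }
}

#' Reverse complement of a nucleotide string
#'
#' @param x a nucleotide string over \code{A,C,G,T,N}.
#' @return the reverse complement as a string.
#' @export
reverse_complement <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(chars(flipped)), collapse = "")
}

#' Translate a cDNA in one of six frames
#'
#' Frames 0-2 read the forward strand with offsets 0-2; frames 3-5 read the
#' reverse complement with offsets 0-2. Translation uses the standard
#' genetic code; stop codons are rendered \code{*}, codons containing
#' \code{N} become \code{X}, and a trailing partial codon is dropped.
#'
#' @param cdna nucleotide string.
#' @param frame integer 0-5.
#' @return amino-acid string (possibly empty for very short inputs).
#' @examples
#' translate_cdna("ATGAAATAA", 0)   # "MK*"
#' translate_cdna("CATGGG", 1)      # "M" (partial codon dropped)
#' @export
translate_cdna <- function(cdna, frame = 0L) {
  if (length(frame) != 1 || is.na(frame) || !(frame %in% 0:5))
    stop("frame must be a single integer in 0..5")
  s <- toupper(cdna)
  if (frame >= 3) {
    s <- reverse_complement(s)
    frame <- frame - 3L
  }
  s <- substr(s, frame + 1L, nchar(s))
  keep <- nchar(s) - nchar(s) %% 3L
  if (keep < 3L) return("")
  starts <- seq.int(1L, keep, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"                       # ambiguous codons (N etc.)
  paste(aa, collapse = "")
}

# standard genetic code as a codon -> residue lookup, cached
.codon_table <- function() {
  if (is.null(.pkg_cache$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codon_table <- stats::setNames(unname(gc), names(gc))
  }
  .pkg_cache$codon_table
}

#' Six-frame translation
#'
#' @param cdna nucleotide string.
#' @return character vector of six translations, named \code{frame0} to
#'   \code{frame5}.
#' @export
six_frame <- function(cdna) {
  out <- vapply(0:5, function(f) translate_cdna(cdna, f), character(1))
  names(out) <- paste0("frame", 0:5)
  out
}

#' Find the longest open reading frame across six frames
#'
#' An ORF is a Met-initiated, stop-terminated coding span. The longest ORF
#' over all six frames is returned; ties are broken by lower frame index,
#' then lower start coordinate. Coordinates are 0-based half-open on the
#' input sequence and include the stop codon; for frames 3-5 they delimit
#' the region whose reverse complement encodes the protein.
#'
#' @param cdna nucleotide string of length at least 6.
#' @return \code{NULL} if no ORF exists, otherwise a list with elements
#'   \code{start}, \code{end}, \code{frame} and \code{protein} (without the
#'   terminal stop).
#' @examples
#' longest_orf("ATGAAATAA")
#' @export
longest_orf <- function(cdna) {
  if (nchar(cdna) < 6) stop("sequence shorter than 6 nt")
  L <- nchar(cdna)
  best <- NULL
  for (f in 0:5) {
    prot <- translate_cdna(cdna, f)
    if (!nzchar(prot)) next
    pc <- chars(prot)
    stops <- which(pc == "*")
    ms <- which(pc == "M")
    if (!length(stops) || !length(ms)) next
    # for each stop, the earliest M in the preceding stop-free stretch
    prev_stop <- c(0L, stops)
    for (k in seq_along(stops)) {
      lo <- prev_stop[k] + 1L
      hi <- stops[k] - 1L
      if (hi < lo) next
      m0 <- ms[ms >= lo & ms <= hi]
      if (!length(m0)) next
      m0 <- m0[1]
      plen <- stops[k] - m0            # residues, stop excluded
      off <- if (f >= 3) f - 3L else f
      nt_start <- off + (m0 - 1L) * 3L          # on the translated strand
      nt_end <- off + stops[k] * 3L             # half-open, stop included
      if (f >= 3) {
        s <- L - nt_end
        e <- L - nt_start
      } else {
        s <- nt_start
        e <- nt_end
      }
      better <- is.null(best) || plen > nchar(best$protein) ||
        (plen == nchar(best$protein) &&
         (f < best$frame || (f == best$frame && s < best$start)))
      if (better)
        best <- list(start = s, end = e, frame = f,
                     protein = substr(prot, m0, stops[k] - 1L))
    }
  }
  best
}

#' Re-translate an ORF call from its coordinates
#'
#' Utility to recover the protein encoded by an ORF call on the original
#' sequence; used to verify round-trip consistency.
#'
#' @param cdna the original nucleotide string.
#' @param orf an ORF call as returned by [longest_orf()].
#' @return amino-acid string without the terminal stop.
#' @export
orf_protein <- function(cdna, orf) {
  region <- substr(cdna, orf$start + 1L, orf$end)
  if (orf$frame >= 3) region <- reverse_complement(region)
  p <- translate_cdna(region, 0L)
  sub("\\*$", "", p)
}
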