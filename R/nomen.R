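# Seroin nomenclature.
#
# A seroin name is the concatenation of
#   <species abbreviation>  "Sn"  <class digit 1-3>
#   [ "-" <gene number 1|2> ]        only for species with two genes
#   [ <splice letter A-Z> [ <minor-variant digit >= 2> ] ]
# e.g. BmSn1-2 (Bombyx mori, class 1, gene 2), GmSn1B2 (Galleria
# mellonella, class 1, splice version B, minor variant 2), HasSn3.

#' Create an empty species-abbreviation registry
#'
#' The registry maintains a bijective map between species binomials and
#' their abbreviations. Abbreviations default to the genus initial plus the
#' first letter of the species epithet; collisions are resolved by
#' extending with further epithet letters (never by reusing an
#' abbreviation).
#'
#' @return an environment of class \code{"abbrev_registry"}.
#' @export
abbrev_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$by_species <- list()   # "Genus species" -> abbrev
  e$by_abbrev <- list()    # abbrev -> "Genus species"
  class(e) <- "abbrev_registry"
  e
}

#' @export
print.abbrev_registry <- function(x, ...) {
  if (!length(x$by_species)) {
    cat("empty species-abbreviation registry\n")
  } else {
    for (sp in names(x$by_species))
      cat(sprintf("%-6s %s\n", x$by_species[[sp]], sp))
  }
  invisible(x)
}

#' Abbreviate a species binomial
#'
#' @param genus,species alphabetic genus and species epithet.
#' @param registry an [abbrev_registry()]; updated in place.
#' @return the abbreviation (e.g. \code{"Bm"} for \emph{Bombyx mori};
#'   \code{"Has"} for \emph{Helicoverpa assulta} when \code{"Ha"} is
#'   already taken by \emph{Helicoverpa armigera}).
#' @export
species_abbrev <- function(genus, species, registry = abbrev_registry()) {
  if (!grepl("^[A-Za-z]+$", genus) || !grepl("^[A-Za-z]+$", species))
    stop("genus and species must be alphabetic")
  key <- paste(genus, species)
  if (!is.null(registry$by_species[[key]]))
    return(registry$by_species[[key]])
  g <- toupper(substr(genus, 1, 1))
  ep <- tolower(species)
  for (take in 1:nchar(ep)) {
    ab <- paste0(g, substr(ep, 1, take))
    owner <- registry$by_abbrev[[ab]]
    if (is.null(owner)) {
      registry$by_species[[key]] <- ab
      registry$by_abbrev[[ab]] <- key
      return(ab)
    }
    if (owner == key) return(ab)
  }
  stop("cannot derive a unique abbreviation for ", key)
}

#' Build a seroin name from its parts
#'
#' @param abbrev species abbreviation (capital genus initial followed by
#'   lowercase letters).
#' @param seroin_class class digit 1, 2 or 3.
#' @param gene_number optional gene number (1 or 2); include only for
#'   species carrying two genes of the class.
#' @param splice_letter optional capital splice-version letter.
#' @param minor_variant optional integer >= 2 (requires a splice letter).
#' @return the name string, e.g. \code{"BmSn1-2"}, \code{"GmSn1B2"}.
#' @export
build_name <- function(abbrev, seroin_class, gene_number = NULL,
                       splice_letter = NULL, minor_variant = NULL) {
  if (!grepl("^[A-Z][a-z]+$", abbrev) || nchar(abbrev) < 2)
    stop("invalid species abbreviation: ", abbrev)
  if (!seroin_class %in% 1:3) stop("class must be 1, 2 or 3")
  if (!is.null(gene_number) && !gene_number %in% 1:2)
    stop("gene number must be 1 or 2")
  if (!is.null(splice_letter) && !grepl("^[A-Z]$", splice_letter))
    stop("splice letter must be a single capital letter")
  if (!is.null(minor_variant)) {
    if (is.null(splice_letter))
      stop("a minor-variant digit requires a splice letter")
    if (minor_variant < 2) stop("minor-variant digits start at 2")
  }
  paste0(abbrev, "Sn", seroin_class,
         if (!is.null(gene_number)) paste0("-", gene_number) else "",
         splice_letter %||% "",
         if (!is.null(minor_variant)) minor_variant else "")
}

#' Parse a seroin name
#'
#' Exact inverse of [build_name()]. The en-dash sometimes found in print
#' is normalized to the ASCII hyphen-minus before parsing.
#'
#' @param name a seroin name string.
#' @param registry optional [abbrev_registry()]; when supplied, the parsed
#'   abbreviation is resolved to its binomial.
#' @return a list with \code{abbrev}, \code{seroin_class},
#'   \code{gene_number}, \code{splice_letter}, \code{minor_variant} (absent
#'   parts are \code{NULL}) and, with a registry, \code{species}.
#' @export
parse_name <- function(name, registry = NULL) {
  if (!nzchar(name)) stop("empty name")
  x <- gsub("–", "-", name)
  fail <- function(pos, what)
    stop(sprintf("cannot parse '%s': expected %s at position %d",
                 name, what, pos))
  m <- regexpr("^[A-Z][a-z]+", x)
  if (m == -1) fail(1L, "a species abbreviation ([A-Z][a-z]+)")
  # the abbreviation is the shortest prefix such that 'Sn' follows; the
  # lowercase run before 'Sn' belongs to the abbreviation
  sn <- regexpr("Sn[123]", x)
  if (sn == -1) fail(attr(m, "match.length") + 1L, "'Sn' and a class digit")
  abbrev <- substr(x, 1, sn - 1L)
  if (!grepl("^[A-Z][a-z]+$", abbrev) || nchar(abbrev) < 2)
    fail(1L, "a species abbreviation ([A-Z][a-z]+)")
  seroin_class <- as.integer(substr(x, sn + 2L, sn + 2L))
  rest <- substr(x, sn + 3L, nchar(x))
  pos <- sn + 3L
  gene_number <- NULL
  if (startsWith(rest, "-")) {
    if (!grepl("^-[12]", rest)) fail(pos + 1L, "a gene number 1 or 2")
    gene_number <- as.integer(substr(rest, 2, 2))
    rest <- substr(rest, 3, nchar(rest))
    pos <- pos + 2L
  }
  splice_letter <- NULL
  minor_variant <- NULL
  if (nzchar(rest)) {
    if (!grepl("^[A-Z]", rest)) fail(pos, "a capital splice letter")
    splice_letter <- substr(rest, 1, 1)
    rest <- substr(rest, 2, nchar(rest))
    pos <- pos + 1L
    if (nzchar(rest)) {
      if (!grepl("^[2-9][0-9]*$", rest))
        fail(pos, "a minor-variant number (>= 2)")
      minor_variant <- as.integer(rest)
    }
  }
  out <- list(abbrev = abbrev, seroin_class = seroin_class,
              gene_number = gene_number, splice_letter = splice_letter,
              minor_variant = minor_variant)
  if (!is.null(registry)) out$species <- registry$by_abbrev[[abbrev]]
  out
}

#' Generate names for an annotated dataset
#'
#' Applies the nomenclature to a table of classified, version-called and
#' gene-grouped records. Within each gene, distinct splice versions
#' receive letters A, B, C, ... ordered by the lexicographically smallest
#' member id (a deterministic stand-in for expression evidence); further
#' members of an already-lettered version get minor-variant digits 2, 3,
#' .... A gene represented by a single record carries no splice letter,
#' and the hyphenated gene number appears only when the species has two
#' genes of the class.
#'
#' @param annot data frame with columns \code{id}, \code{genus},
#'   \code{species}, \code{class} (\code{"Sn1"}-style or 1-3),
#'   \code{version} and \code{gene} (gene number within species/class).
#' @param registry an [abbrev_registry()]; updated in place.
#' @return \code{annot} with an added \code{name} column.
#' @export
name_dataset <- function(annot, registry = abbrev_registry()) {
  cls_digit <- function(cl) {
    if (is.numeric(cl)) as.integer(cl)
    else as.integer(sub("^Sn", "", cl))
  }
  annot$name <- NA_character_
  key <- paste(annot$genus, annot$species, annot$class)
  for (cell in unique(key)) {
    rows <- which(key == cell)
    sub <- annot[rows, , drop = FALSE]
    ab <- species_abbrev(sub$genus[1], sub$species[1], registry)
    n_genes <- length(unique(sub$gene))
    for (g in unique(sub$gene)) {
      grows <- rows[sub$gene == g]
      gsub_ <- annot[grows, , drop = FALSE]
      gene_number <- if (n_genes > 1L) g else NULL
      if (nrow(gsub_) == 1L) {
        annot$name[grows] <- build_name(ab, cls_digit(gsub_$class[1]),
                                        gene_number)
        next
      }
      vers <- unique(gsub_$version[order(gsub_$id)])
      letters_map <- stats::setNames(LETTERS[seq_along(vers)], vers)
      for (v in vers) {
        vrows <- grows[gsub_$version == v]
        vids <- order(annot$id[vrows])
        for (q in seq_along(vids)) {
          annot$name[vrows[vids[q]]] <-
            build_name(ab, cls_digit(annot$class[vrows[vids[q]]]),
                       gene_number, letters_map[[v]],
                       if (q > 1L) q else NULL)
        }
      }
    }
  }
  annot
}
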