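# End-to-end annotation pipeline: sequences -> ORFs -> signal peptide ->
# module segmentation -> class call -> splice version -> gene grouping ->
# nomenclature, with optional similarity/tree and read-count stages.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default.
#' Identical configuration, inputs and seed yield byte-identical reports.
#'
#' @param molecule \code{"dna"} (ORFs are called and translated) or
#'   \code{"protein"}.
#' @param window,pro_threshold,min_run,smooth_window segmentation
#'   parameters (see [segment_modules()]).
#' @param min_score,min_margin classification thresholds (see
#'   [assign_class()]).
#' @param gene_k,gene_id_threshold gene-grouping parameters (see
#'   [group_genes()]).
#' @param gap_open,gap_extend alignment gap penalties.
#' @param evalue_max,query_len read-counting threshold and query length.
#' @param tree compute the similarity matrix, NJ tree and monophyly flags.
#' @param seed integer seed recorded in the provenance block (the
#'   annotation stages themselves are deterministic).
#' @return a list of class \code{"seroin_config"}.
#' @export
pipeline_config <- function(molecule = c("protein", "dna"),
                            window = 15L, pro_threshold = 0.20,
                            min_run = 5L, smooth_window = 7L,
                            min_score = 0.5, min_margin = 0.15,
                            gene_k = 25L, gene_id_threshold = 0.95,
                            gap_open = 10, gap_extend = 1,
                            evalue_max = 1e-20, query_len = 80L,
                            tree = FALSE, seed = 1L) {
  structure(list(molecule = match.arg(molecule), window = window,
                 pro_threshold = pro_threshold, min_run = min_run,
                 smooth_window = smooth_window, min_score = min_score,
                 min_margin = min_margin, gene_k = gene_k,
                 gene_id_threshold = gene_id_threshold,
                 gap_open = gap_open, gap_extend = gap_extend,
                 evalue_max = evalue_max, query_len = query_len,
                 tree = tree, seed = as.integer(seed)),
            class = "seroin_config")
}

#' Run the seroin annotation pipeline
#'
#' @param sequences data frame with columns \code{id} and \code{sequence}
#'   (cDNAs or proteins according to \code{config$molecule}), e.g. from
#'   [read_fasta()].
#' @param species optional data frame with columns \code{id},
#'   \code{genus}, \code{species}; records without species metadata are
#'   named under a placeholder binomial.
#' @param config a [pipeline_config()].
#' @param reads optional data frame of short reads (\code{id},
#'   \code{sequence}) to count per class.
#' @return an object of class \code{"seroin_report"}: \code{rows} (one row
#'   per input record: id, species, class, per-class scores, margin,
#'   version, gene, name, module spans), \code{architectures},
#'   \code{summaries} (class counts, similarity table, monophyly flags,
#'   read counts when requested) and \code{provenance}.
#' @export
run_pipeline <- function(sequences, species = NULL,
                         config = pipeline_config(), reads = NULL) {
  stopifnot(is.data.frame(sequences))
  n <- nrow(sequences)
  rows <- vector("list", n)
  arches <- list()
  proteins <- character(0)

  for (i in seq_len(n)) {
    id <- sequences$id[i]
    prot <- if (config$molecule == "dna") {
      orf <- longest_orf(sequences$sequence[i])
      if (is.null(orf)) NA_character_ else orf$protein
    } else sequences$sequence[i]
    row <- data.frame(id = id, genus = NA_character_,
                      species = NA_character_, class = "unclassified",
                      score_Sn1 = NA_real_, score_Sn2 = NA_real_,
                      score_Sn3 = NA_real_, margin = NA_real_,
                      version = NA_character_, gene = NA_integer_,
                      name = NA_character_, a_end = NA_integer_,
                      module_spans = NA_character_, flag = "",
                      stringsAsFactors = FALSE)
    if (is.null(species)) {
      row$genus <- "Incertae"; row$species <- "sedis"
    } else {
      k <- match(id, species$id)
      row$genus <- if (is.na(k)) "Incertae" else species$genus[k]
      row$species <- if (is.na(k)) "sedis" else species$species[k]
    }
    if (is.na(prot)) {
      row$flag <- "no ORF"
      rows[[i]] <- row
      next
    }
    if (substr(prot, 1, 1) != "M" || nchar(prot) < 50) {
      row$flag <- "no initiator Met or too short"
      rows[[i]] <- row
      next
    }
    sig <- detect_signal(prot)
    call <- assign_class(prot, config$min_score, config$min_margin)
    row$class <- call$seroin_class
    row$score_Sn1 <- call$scores[["Sn1"]]
    row$score_Sn2 <- call$scores[["Sn2"]]
    row$score_Sn3 <- call$scores[["Sn3"]]
    row$margin <- call$margin
    row$a_end <- sig$end
    arch <- segment_modules(prot, sig$end,
                            class_hint = if (call$seroin_class %in%
                                             c("Sn1", "Sn2", "Sn3"))
                              call$seroin_class else NULL,
                            window = config$window,
                            pro_threshold = config$pro_threshold,
                            min_run = config$min_run,
                            smooth_window = config$smooth_window)
    if (call$seroin_class %in% c("Sn1", "Sn2", "Sn3")) {
      ver <- call_version(arch, call$seroin_class)
      row$version <- ver$code
      arch <- ver$canonical
    }
    arches[[id]] <- arch
    row$module_spans <- paste(sprintf("%s:%d-%d", arch$label, arch$start,
                                      arch$end), collapse = ",")
    proteins[id] <- prot
    rows[[i]] <- row
  }
  rows <- do.call(rbind, rows) %||%
    data.frame(id = character(), stringsAsFactors = FALSE)

  # gene grouping within each (species, class) cell
  if (nrow(rows)) {
    rows$gene <- NA_integer_
    cell <- paste(rows$genus, rows$species, rows$class)
    for (cl in unique(cell)) {
      k <- which(cell == cl & rows$class %in% c("Sn1", "Sn2", "Sn3"))
      if (!length(k)) next
      recs <- data.frame(id = rows$id[k], protein = proteins[rows$id[k]],
                         a_end = rows$a_end[k], stringsAsFactors = FALSE)
      groups <- group_genes(recs, k = config$gene_k,
                            id_threshold = config$gene_id_threshold)
      for (g in groups)
        rows$gene[rows$id %in% g$members] <- g$gene_number
    }
    # nomenclature
    classified <- rows$class %in% c("Sn1", "Sn2", "Sn3")
    if (any(classified)) {
      named <- name_dataset(rows[classified, c("id", "genus", "species",
                                               "class", "version", "gene")])
      rows$name[classified] <- named$name[match(rows$id[classified],
                                                named$id)]
    }
  }

  summaries <- list(
    class_counts = if (nrow(rows)) table(rows$class) else NULL)
  if (isTRUE(config$tree) && length(proteins) >= 3) {
    classified <- rows$class %in% c("Sn1", "Sn2", "Sn3")
    prots <- proteins[rows$id[classified]]
    ident <- pairwise_identity(prots, gap_open = config$gap_open,
                               gap_extend = config$gap_extend)
    cls <- rows$class[classified]
    summaries$similarity <- class_similarity_summary(prots, cls,
                                                     identity = ident)
    tr <- nj_tree(identity_distance(ident))
    summaries$newick <- write_newick(tr)
    summaries$monophyletic <-
      is_class_monophyletic(tr, stats::setNames(cls, names(prots)))
  }
  if (!is.null(reads) && nrow(rows)) {
    refs <- .class_reference_queries(rows, proteins, config$query_len)
    if (length(refs))
      summaries$read_counts <- count_class_reads(
        reads, refs, evalue_max = config$evalue_max,
        gap_open = config$gap_open, gap_extend = config$gap_extend)
  }

  structure(list(rows = rows, architectures = arches,
                 summaries = summaries,
                 provenance = list(config = unclass(config),
                                   n_input = n,
                                   package = "seroscan",
                                   version = as.character(
                                     utils::packageVersion("seroscan")))),
            class = "seroin_report")
}

# one C-terminal query per class, from the longest classified record
.class_reference_queries <- function(rows, proteins, query_len) {
  refs <- character(0)
  for (cl in c("Sn1", "Sn2", "Sn3")) {
    k <- which(rows$class == cl)
    if (!length(k)) next
    prots <- proteins[rows$id[k]]
    ref <- prots[which.max(nchar(prots))]
    refs[cl] <- cterm_query(ref, query_len)$query
  }
  refs
}

#' @export
print.seroin_report <- function(x, ...) {
  cat("Seroin annotation report:", nrow(x$rows), "records\n")
  if (!is.null(x$summaries$class_counts)) {
    cat("  class counts:\n")
    print(x$summaries$class_counts)
  }
  invisible(x)
}

#' @method summary seroin_report
#' @export
summary.seroin_report <- function(object, ...) {
  cat("Seroin annotation report\n")
  cat("  records:", nrow(object$rows), "\n")
  print(object$summaries$class_counts)
  if (!is.null(object$summaries$similarity)) {
    cat("  similarity (percent identity):\n")
    print(object$summaries$similarity, row.names = FALSE)
  }
  if (!is.null(object$summaries$monophyletic)) {
    cat("  class monophyly in NJ tree:\n")
    print(object$summaries$monophyletic)
  }
  if (!is.null(object$summaries$read_counts))
    print(object$summaries$read_counts)
  invisible(object)
}

#' Write a report to disk
#'
#' Writes the per-record table as TSV, the full report as JSON, and the
#' Newick tree when present.
#'
#' @param report a \code{"seroin_report"}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rows = file.path(dir, "annotation.tsv"),
             json = file.path(dir, "report.json"))
  utils::write.table(report$rows, paths["rows"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json <- list(rows = report$rows,
               summaries = lapply(report$summaries, function(s) {
                 if (inherits(s, "class_counts"))
                   list(counts = as.list(s$counts),
                        unassigned = s$unassigned, total = s$total)
                 else if (inherits(s, "table")) as.list(s)
                 else s
               }),
               provenance = report$provenance)
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  if (!is.null(report$summaries$newick)) {
    paths["newick"] <- file.path(dir, "tree.nwk")
    writeLines(report$summaries$newick, paths["newick"])
  }
  invisible(paths)
}

#' Validate a written report against the shipped schema
#'
#' The schema (a JSON document under \code{inst/extdata}) lists the
#' required top-level blocks and per-record fields of a report JSON file.
#'
#' @param path path to a \code{report.json} written by [write_report()].
#' @return \code{TRUE} (invisibly) or an error describing the first
#'   missing field.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report-schema.json",
                                            package = "seroscan"))
  doc <- jsonlite::read_json(path)
  for (block in schema$required) {
    if (is.null(doc[[block]])) stop("report is missing block: ", block)
  }
  if (length(doc$rows)) {
    for (f in unlist(schema$row_fields)) {
      if (!f %in% names(doc$rows[[1]]))
        stop("report rows are missing field: ", f)
    }
  }
  invisible(TRUE)
}
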