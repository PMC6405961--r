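# Splice-version calling and gene grouping.
#
# Splice versions are defined relative to the long AB1C1B2C2B3 isoform:
#   L  - full module set (all classes)
#   N  - AB1C1B2            (Sn1)
#   C  - AB1C2B3            (Sn1, Sn2)
#   T1 - AB1C1[B2C2]B3      (Sn2; bracketed modules incomplete)
#   T2 - A[B1C1]B2C2B3      (Sn2)
#   T  - AB1C1B3            (Sn3)
# The positional labels produced by segmentation (first B run = B1, ...)
# are re-mapped onto these canonical patterns by the best-matching version.

# expected canonical module lengths for a (class, version) pattern
.pattern_expectation <- function(seroin_class, pattern) {
  def <- module_defaults(seroin_class)
  exp_len <- def[names(pattern)]
  exp_len[!pattern] <- pmax(8, INCOMPLETE_FACTOR * exp_len[!pattern])
  exp_len
}

#' Call the splice version of a segmented architecture
#'
#' The observed run structure (number and order of B and C runs, their
#' measured lengths and completeness) is matched against every splice
#' pattern allowed for the class. Pattern cost = presence mismatches
#' (1 each) + completeness mismatches (0.5 each); measured-length deviation
#' from the pattern's expected module sizes (complete modules only) breaks
#' ties. An exact canonical match returns its code directly; when no
#' pattern comes within 1 mismatch the version is \code{"unrecognized"}.
#'
#' @param architecture a \code{"seroin_architecture"} from
#'   [segment_modules()].
#' @param seroin_class \code{"Sn1"}, \code{"Sn2"} or \code{"Sn3"}.
#' @return a list of class \code{"splice_version"} with elements
#'   \code{code}, \code{pattern} (named completeness vector),
#'   \code{canonical} (the architecture relabelled with canonical module
#'   names) and \code{cost}.
#' @export
call_version <- function(architecture, seroin_class) {
  seroin_class <- match.arg(seroin_class, c("Sn1", "Sn2", "Sn3"))
  arch <- as.data.frame(architecture)
  if (nrow(arch) == 0L) stop("empty architecture")
  mature <- arch[arch$label != "A", , drop = FALSE]
  obs_type <- substr(mature$label, 1, 1)
  obs_len <- mature$end - mature$start
  # correct for the compositional-window smear: the sliding Pro window
  # systematically extends detected C runs ~3 residues into each
  # neighbouring B run, so measured C lengths are inflated and B lengths
  # deflated by 3 per B/C boundary
  smear <- 3L
  n_runs <- length(obs_type)
  adj_len <- obs_len
  for (o in seq_len(n_runs)) {
    nb <- c(if (o > 1L) obs_type[o - 1L], if (o < n_runs) obs_type[o + 1L])
    edges <- sum(nb != obs_type[o])
    adj_len[o] <- obs_len[o] +
      (if (obs_type[o] == "C") -1L else 1L) * smear * edges
  }
  defaults <- module_defaults(seroin_class)
  pats <- version_patterns(seroin_class)

  score_pattern <- function(pat) {
    slots <- setdiff(names(pat), "A")
    slot_type <- substr(slots, 1, 1)
    # map observed B runs to pattern B slots in order, likewise C runs
    cost_presence <- 0
    cost_complete <- 0
    len_dev <- 0
    mapping <- rep(NA_character_, length(obs_type))
    for (tp in c("B", "C")) {
      oi <- which(obs_type == tp)
      si <- which(slot_type == tp)
      cost_presence <- cost_presence + abs(length(oi) - length(si))
      k <- min(length(oi), length(si))
      if (k == 0) next
      for (q in seq_len(k)) {
        o <- oi[q]; s <- si[q]
        slot <- slots[s]
        mapping[o] <- slot
        obs_complete <- adj_len[o] >= 0.5 * defaults[[slot]]
        if (obs_complete != pat[[slot]])
          cost_complete <- cost_complete + 0.5
        if (pat[[slot]]) {                  # length deviation, complete only
          dev <- abs(adj_len[o] - defaults[[slot]]) / defaults[[slot]]
          len_dev <- len_dev + min(dev, 1)
        }
      }
    }
    list(cost = cost_presence + cost_complete,
         tiebreak = 0.05 * len_dev, mapping = mapping)
  }

  scored <- lapply(pats, score_pattern)
  total <- vapply(scored, function(s) s$cost + s$tiebreak, numeric(1))
  best <- names(pats)[which.min(total)]
  res <- scored[[best]]
  code <- if (res$cost > 1) "unrecognized" else best

  canonical <- arch
  canonical$label[arch$label != "A"] <- res$mapping
  canonical <- canonical[!is.na(canonical$label), , drop = FALSE]
  adj_by_label <- stats::setNames(adj_len, res$mapping)
  canonical$complete <- ifelse(
    canonical$label == "A", TRUE,
    adj_by_label[canonical$label] >= 0.5 * defaults[canonical$label])

  structure(list(code = code, pattern = if (code %in% names(pats))
                   pats[[code]] else NULL,
                 canonical = canonical, cost = res$cost),
            class = "splice_version")
}

#' @export
print.splice_version <- function(x, ...) {
  cat("Splice version:", x$code, sprintf("(cost %.2f)\n", x$cost))
  print.data.frame(x$canonical, row.names = FALSE)
  invisible(x)
}

#' Group same-species isoforms into genes
#'
#' Two isoforms of one species and class are linked when their first
#' \code{k} mature residues are identical and the identity over the
#' overlapping (both-aligned) region of a global alignment reaches
#' \code{id_threshold}; single-linkage clusters of this relation are the
#' gene groups. At most two genes per class and species are reported:
#' excess clusters are merged into the nearest one with a warning. Groups
#' are numbered by descending member count, ties by the lexicographically
#' smallest member id.
#'
#' @param records data frame with columns \code{id} and \code{protein}
#'   (optionally \code{a_end}; signal peptides are detected when absent)
#'   for one species and class.
#' @param k prefix length in mature residues (default 25).
#' @param id_threshold identity required over the overlapping aligned
#'   region (default 0.95).
#' @param genomic_split optional list of character vectors of ids; when
#'   supplied it overrides sequence evidence and fixes the grouping
#'   (evidence \code{"genomic"}).
#' @return a list of gene groups, each with \code{gene_number},
#'   \code{members} and \code{evidence} (\code{"n_terminal_identity"},
#'   \code{"genomic"} or \code{"default"}).
#' @export
group_genes <- function(records, k = 25L, id_threshold = 0.95,
                        genomic_split = NULL) {
  n <- nrow(records)
  if (n < 1L) stop("at least one record required")
  if (!is.null(genomic_split)) {
    groups <- genomic_split
  } else {
    if (!"a_end" %in% names(records))
      records$a_end <- vapply(records$protein,
                              function(p) detect_signal(p)$end, integer(1))
    prefix <- substr(records$protein, records$a_end + 1L,
                     records$a_end + k)
    linked <- matrix(FALSE, n, n)
    diag(linked) <- TRUE
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        if (prefix[i] != prefix[j]) next
        al <- global_align(records$protein[i], records$protein[j])
        a <- chars(al$aligned_a); b <- chars(al$aligned_b)
        both <- a != "-" & b != "-"
        ov_id <- if (any(both)) mean(a[both] == b[both]) else 0
        if (ov_id >= id_threshold) linked[i, j] <- linked[j, i] <- TRUE
      }
    }
    # single-linkage components
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (linked[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    groups <- split(records$id, comp)
  }
  # enforce at most two genes: merge smallest clusters into the largest
  while (length(groups) > 2L) {
    warning("more than two gene clusters; merging the smallest")
    sizes <- lengths(groups)
    ord <- order(sizes)
    groups[[ord[2]]] <- c(groups[[ord[2]]], groups[[ord[1]]])
    groups[[ord[1]]] <- NULL
  }
  sizes <- lengths(groups)
  first_id <- vapply(groups, function(g) min(sort(g)), character(1))
  ord <- order(-sizes, first_id)
  groups <- groups[ord]
  evidence <- if (!is.null(genomic_split)) "genomic"
              else if (n == 1L) "default" else "n_terminal_identity"
  lapply(seq_along(groups), function(g)
    list(gene_number = g, members = sort(groups[[g]]),
         evidence = evidence))
}
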