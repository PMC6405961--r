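# Pairwise similarity, class summaries and a neighbor-joining sanity tree.
#
# Percent identity here is matches / all alignment columns (gap columns
# included) from a global affine-gap alignment - the conservative
# denominator; within/between-class similarity statements are therefore
# qualitative orderings, not calibrated percentages.

#' Global pairwise protein alignment (Gotoh, affine gaps)
#'
#' Optimal global alignment with affine gap costs (a gap of length L costs
#' \code{gap_open + L * gap_extend}). Traceback tie-breaking is
#' deterministic: match/mismatch over a gap in \code{a} over a gap in
#' \code{b}.
#'
#' @param a,b non-empty protein strings.
#' @param matrix substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend gap penalties (defaults 10 and 1).
#' @return a list of class \code{"seroin_alignment"}: \code{aligned_a},
#'   \code{aligned_b}, \code{score}, \code{identity_pct} (100 x matches /
#'   alignment columns).
#' @examples
#' global_align("MKVLL", "MKV")$identity_pct  # 60
#' @export
global_align <- function(a, b, matrix = NULL, gap_open = 10,
                         gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (is.null(matrix)) matrix <- blosum62()
  res <- .gotoh_global_cpp(a, b, matrix, gap_open, gap_extend)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score,
                 identity_pct = 100 * res$matches / res$columns),
            class = "seroin_alignment")
}

#' @export
print.seroin_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %.1f, identity %.1f%%\n", x$score, x$identity_pct))
  invisible(x)
}

#' All-pairs percent identity
#'
#' @param proteins named character vector of protein sequences.
#' @inheritParams global_align
#' @return a symmetric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
pairwise_identity <- function(proteins, matrix = NULL, gap_open = 10,
                              gap_extend = 1) {
  if (is.null(matrix)) matrix <- blosum62()
  m <- .pairwise_identity_cpp(unname(proteins), matrix, gap_open,
                              gap_extend)
  dimnames(m) <- list(names(proteins), names(proteins))
  m
}

#' Identity-based distance matrix
#'
#' @param identity a percent-identity matrix from [pairwise_identity()].
#' @return a symmetric distance matrix \code{1 - identity/100} with zero
#'   diagonal.
#' @export
identity_distance <- function(identity) {
  d <- 1 - identity / 100
  diag(d) <- 0
  d
}

#' Within- and between-class similarity summary
#'
#' @param proteins named character vector of sequences.
#' @param classes character vector of class labels aligned with
#'   \code{proteins}.
#' @param identity optional precomputed identity matrix.
#' @return a data frame with one row per unordered class pair (within-class
#'   rows have \code{class_a == class_b}) and columns \code{mean},
#'   \code{min}, \code{max}, \code{n_pairs}; classes with fewer than two
#'   members yield an \code{NA} within-class row.
#' @export
class_similarity_summary <- function(proteins, classes, identity = NULL) {
  if (is.null(identity)) identity <- pairwise_identity(proteins)
  cls <- sort(unique(classes))
  out <- list()
  for (i in seq_along(cls)) for (j in i:length(cls)) {
    ia <- which(classes == cls[i])
    ib <- which(classes == cls[j])
    if (i == j) {
      if (length(ia) < 2) {
        vals <- NA_real_
        np <- 0L
      } else {
        m <- identity[ia, ia, drop = FALSE]
        vals <- m[upper.tri(m)]
        np <- length(vals)
      }
    } else {
      vals <- as.vector(identity[ia, ib, drop = FALSE])
      np <- length(vals)
    }
    out[[length(out) + 1L]] <- data.frame(
      class_a = cls[i], class_b = cls[j],
      mean = if (np) mean(vals) else NA_real_,
      min = if (np) min(vals) else NA_real_,
      max = if (np) max(vals) else NA_real_,
      n_pairs = np, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}), with any negative branch
#' lengths clamped to zero and the deficit moved to the sibling branch so
#' that path lengths are preserved.
#'
#' @param d a symmetric distance matrix with labelled rows/columns, at
#'   least 3 taxa.
#' @return an \pkg{ape} \code{phylo} tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative branch lengths, compensating on the sibling branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] +
        tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Test class monophyly on an unrooted tree
#'
#' A class is monophyletic when some edge bipartition of the unrooted tree
#' separates exactly that class's leaves from everything else. The test is
#' performed by rooting the tree at a leaf outside the class and checking
#' for a clade.
#'
#' @param tree a \code{phylo} tree.
#' @param class_labels named character vector mapping every leaf label to
#'   its class.
#' @return a named logical vector, one entry per class.
#' @export
is_class_monophyletic <- function(tree, class_labels) {
  tips <- tree$tip.label
  unknown <- setdiff(tips, names(class_labels))
  if (length(unknown))
    stop("leaf without class label: ", unknown[1])
  out <- logical(0)
  for (cl in sort(unique(class_labels[tips]))) {
    members <- tips[class_labels[tips] == cl]
    others <- setdiff(tips, members)
    if (!length(others)) {
      out[cl] <- TRUE
      next
    }
    rooted <- ape::root(tree, outgroup = others[1], resolve.root = TRUE)
    out[cl] <- ape::is.monophyletic(rooted, members)
  }
  out
}

#' Serialize a tree to Newick
#'
#' @param tree a \code{phylo} tree.
#' @param path optional file to write; when missing the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
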