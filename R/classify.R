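# Rule-based seroin class assignment.
#
# The three classes are recognized by explicit diagnostic clauses
# transcribed from the features that distinguish them in alignments:
#   Sn1 - a Trp located ~20 residues after the initial Met (window
#         [15, 25)), a high charged fraction in its vicinity, and a
#         Pro-rich region following downstream;
#   Sn2 - a Gly-rich stretch within residues 20-50 and the RYGG motif;
#   Sn3 - a Trp ~35 residues from the initial Met (window [30, 40)) and
#         the VYGE motif.
# Motif matches carry double weight: they are the sharpest evidence.

#' Exact motif scan
#'
#' Returns all (possibly overlapping) 0-based start positions of an exact
#' motif match. The unknown residue \code{X} never matches.
#'
#' @param protein amino-acid string.
#' @param motif non-empty uppercase motif.
#' @return integer vector of 0-based match positions, ascending.
#' @examples
#' scan_motif("GGRYGGRYGG", "RYGG")  # 2 6
#' @export
scan_motif <- function(protein, motif) {
  if (!nzchar(motif)) stop("empty motif")
  if (grepl("X", protein, fixed = TRUE) || grepl("X", motif, fixed = TRUE)) {
    # X must not match anything, including another X
    n <- nchar(protein); m <- nchar(motif)
    if (m > n) return(integer(0))
    pc <- chars(protein); mc <- chars(motif)
    out <- integer(0)
    for (i in seq_len(n - m + 1L)) {
      seg <- pc[i:(i + m - 1L)]
      if (all(seg == mc) && !any(seg == "X")) out <- c(out, i - 1L)
    }
    return(out)
  }
  hits <- gregexpr(paste0("(?=", motif, ")"), protein, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

#' The registered class signatures
#'
#' Returns the diagnostic rule parameters for the three seroin classes:
#' motif (or none), the window in which the diagnostic Trp must fall
#' (0-based, counted from the initial Met at position 0), the
#' compositional context clauses and the clause weights.
#'
#' @return a named list with one entry per class.
#' @export
class_signatures <- function() {
  list(
    Sn1 = list(seroin_class = "Sn1", motif = NULL, trp_window = c(15L, 25L),
               charged_min = 0.25, downstream_pro_min = 0.20,
               weights = c(trp = 1, charged_context = 1, downstream_pro = 1)),
    Sn2 = list(seroin_class = "Sn2", motif = "RYGG",
               gly_window = c(20L, 50L), gly_min = 0.20,
               weights = c(motif = 2, gly = 1)),
    Sn3 = list(seroin_class = "Sn3", motif = "VYGE",
               trp_window = c(30L, 40L),
               weights = c(trp = 1, motif = 2))
  )
}

# fraction of charged residues in the +/- flank around 0-based position w
.charged_context <- function(x, w, flank = 10L) {
  lo <- max(0L, w - flank)
  hi <- min(length(x) - 1L, w + flank)
  mean(x[(lo + 1L):(hi + 1L)] %in% CHARGED)
}

# does any 30-residue window starting within (w, w + 45] reach the given
# Pro fraction?  (the "distinct Pro-rich region that follows" clause)
.downstream_pro <- function(x, w, min_frac = 0.20, span = 45L,
                            width = 30L) {
  n <- length(x)
  first <- w + 2L                            # 1-based start after the Trp
  last <- min(w + 1L + span, n - width + 1L)
  if (last < first) return(FALSE)
  ind <- cumsum(c(0, x == "P"))
  for (s in first:last) {
    if ((ind[s + width] - ind[s]) / width >= min_frac) return(TRUE)
  }
  FALSE
}

#' Per-class diagnostic scores
#'
#' Evaluates every clause of every class signature on one protein and
#' returns the weighted fraction of satisfied clauses per class. Clauses
#' that reference positions beyond the protein length simply evaluate
#' false.
#'
#' @param protein amino-acid string starting with Met (classification is
#'   anchored at the initial Met).
#' @return a list with \code{scores} (named numeric, one per class) and
#'   \code{satisfied} (named list of satisfied clause names).
#' @export
class_scores <- function(protein) {
  if (substr(protein, 1, 1) != "M")
    stop("classification requires an initiator Met")
  x <- chars(protein)
  sig <- class_signatures()
  scores <- numeric(0)
  satisfied <- list()

  # Sn1: Trp in [15,25) + charged context + downstream Pro-rich window
  s1 <- sig$Sn1
  wpos <- which(x == "W") - 1L
  w1 <- wpos[wpos >= s1$trp_window[1] & wpos < s1$trp_window[2]]
  cl1 <- c(trp = FALSE, charged_context = FALSE, downstream_pro = FALSE)
  if (length(w1)) {
    cl1["trp"] <- TRUE
    best <- w1[1]
    for (w in w1) {   # any qualifying Trp may satisfy the context clauses
      if (.charged_context(x, w) >= s1$charged_min) {
        cl1["charged_context"] <- TRUE
        best <- w
      }
    }
    cl1["downstream_pro"] <- any(vapply(
      w1, function(w) .downstream_pro(x, w, s1$downstream_pro_min),
      logical(1)))
  }
  scores["Sn1"] <- sum(s1$weights[cl1]) / sum(s1$weights)
  satisfied$Sn1 <- names(cl1)[cl1]

  # Sn2: RYGG motif + Gly-rich 20-50
  s2 <- sig$Sn2
  cl2 <- c(motif = length(scan_motif(protein, s2$motif)) > 0, gly = FALSE)
  gw <- s2$gly_window
  if (length(x) >= gw[2]) {
    seg <- x[(gw[1] + 1L):gw[2]]
    cl2["gly"] <- mean(seg == "G") >= s2$gly_min
  }
  scores["Sn2"] <- sum(s2$weights[cl2]) / sum(s2$weights)
  satisfied$Sn2 <- names(cl2)[cl2]

  # Sn3: Trp in [30,40) + VYGE motif
  s3 <- sig$Sn3
  cl3 <- c(trp = any(wpos >= s3$trp_window[1] & wpos < s3$trp_window[2]),
           motif = length(scan_motif(protein, s3$motif)) > 0)
  scores["Sn3"] <- sum(s3$weights[cl3]) / sum(s3$weights)
  satisfied$Sn3 <- names(cl3)[cl3]

  list(scores = scores, satisfied = satisfied)
}

#' Assign a seroin class
#'
#' The class with the highest score is called when it reaches
#' \code{min_score} and leads the runner-up by at least \code{min_margin};
#' otherwise the protein is reported unclassified. Ties at the best score
#' are always unclassified, with both classes listed.
#'
#' @param protein amino-acid string starting with Met.
#' @param min_score minimum winning score (default 0.5).
#' @param min_margin minimum lead over the second-best class (default
#'   0.15).
#' @return a list of class \code{"seroin_call"} with elements
#'   \code{seroin_class} (\code{"Sn1"}, \code{"Sn2"}, \code{"Sn3"} or
#'   \code{"unclassified"}), \code{scores}, \code{margin},
#'   \code{satisfied_clauses} and \code{tied} (classes sharing the best
#'   score, when tied).
#' @export
assign_class <- function(protein, min_score = 0.5, min_margin = 0.15) {
  cs <- class_scores(protein)
  sc <- cs$scores
  ord <- order(sc, decreasing = TRUE)
  best <- sc[ord[1]]
  second <- sc[ord[2]]
  margin <- best - second
  tied <- names(sc)[sc == best]
  call <- if (best < min_score || margin < min_margin) "unclassified"
          else names(sc)[ord[1]]
  structure(list(seroin_class = call, scores = sc, margin = margin,
                 satisfied_clauses = cs$satisfied,
                 tied = if (length(tied) > 1L) tied else NULL),
            class = "seroin_call")
}

#' @export
print.seroin_call <- function(x, ...) {
  cat("Seroin class call:", x$seroin_class, "\n")
  cat("  scores:", paste(sprintf("%s=%.3f", names(x$scores), x$scores),
                         collapse = "  "), "\n")
  cat("  margin:", sprintf("%.3f", x$margin), "\n")
  invisible(x)
}
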