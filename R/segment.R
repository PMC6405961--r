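# Signal-peptide detection and B/C module segmentation.
#
# The mature part of a seroin alternates between conserved blocks rich in
# Ala, Ser, Glu and Asp (B modules, which also carry most of the charged
# residues) and shorter Pro-rich linkers (C modules). Segmentation is
# purely compositional: a sliding-window Pro fraction is thresholded,
# smoothed, and the resulting runs are numbered from the N-terminus.

#' Windowed composition profile of a protein
#'
#' Computes, for every position, the fraction of Pro, Gly, charged
#' (D, E, K, R) and A+S+E+D residues within a centred window (clipped at
#' the ends of the protein).
#'
#' @param protein amino-acid string.
#' @param window odd window width (default 15).
#' @return a data frame with columns \code{pro_frac}, \code{gly_frac},
#'   \code{charged_frac}, \code{ased_frac}, one row per residue.
#' @export
composition_profile <- function(protein, window = 15L) {
  if (window %% 2L != 1L) stop("window must be odd")
  n <- nchar(protein)
  if (n < window) stop("protein shorter than the window")
  x <- chars(protein)
  half <- (window - 1L) %/% 2L
  data.frame(
    pro_frac = windowed_fraction(x, "P", half, half),
    gly_frac = windowed_fraction(x, "G", half, half),
    charged_frac = windowed_fraction(x, CHARGED, half, half),
    ased_frac = windowed_fraction(x, c("A", "S", "E", "D"), half, half))
}

#' Detect the signal peptide (module A)
#'
#' The signal peptide is located as the N-terminal hydrophobic stretch:
#' Kyte-Doolittle means over 8-residue windows are scanned within residues
#' 1-28 (0-based, after the initial Met), and the module-A end is the end
#' of the last window with mean hydropathy above 1.5, plus 3 residues,
#' clamped to \[15, 30\]. When no window qualifies the conventional length
#' 20 is used and flagged.
#'
#' @param protein amino-acid string starting with Met, length >= 30.
#' @return a list with \code{label = "A"}, \code{start = 0}, \code{end}
#'   (0-based half-open), \code{complete = TRUE} and \code{default}
#'   (TRUE when the fallback length was used).
#' @export
detect_signal <- function(protein) {
  if (substr(protein, 1, 1) != "M") stop("no initiator Met")
  if (nchar(protein) < 30) stop("protein too short for signal detection")
  x <- chars(protein)
  kd <- unname(KD_SCALE[x])
  kd[is.na(kd)] <- 0                         # X and friends count as neutral
  w <- 8L
  ends <- integer(0)
  for (j in 2:22) {                          # 0-based starts 1..21
    hi <- j + w - 1L
    if (hi > min(29L, length(kd))) break
    if (mean(kd[j:hi]) > 1.5) ends <- c(ends, hi)  # 0-based end = hi
  }
  if (length(ends)) {
    cend <- min(max(15L, max(ends) + 3L), 30L)
    default <- FALSE
  } else {
    cend <- 20L
    default <- TRUE
  }
  list(label = "A", start = 0L, end = cend, complete = TRUE,
       default = default)
}

# label runs of a logical vector; returns data frame of (value, start, end)
.runs <- function(v) {
  r <- rle(v)
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = c(0L, end[-length(end)]),
             end = end)
}

# sliding majority vote over a logical vector (clipped windows)
.majority_smooth <- function(v, window = 7L) {
  half <- (window - 1L) %/% 2L
  frac <- windowed_fraction(ifelse(v, "C", "B"), "C", half, half)
  frac > 0.5
}

#' Segment the mature protein into B and C modules
#'
#' Positions after the signal peptide are labelled C where the windowed
#' Pro fraction reaches \code{pro_threshold} and B otherwise; labels are
#' smoothed with a sliding majority filter, short runs are merged into
#' their longer neighbour, and surviving runs are numbered positionally
#' (first B run = B1, first C run = C1, ...). If more than 3 B or 2 C runs
#' survive, the shortest internal run is absorbed until the counts fit.
#'
#' Positional labels are later re-mapped to canonical module names by
#' [call_version()], which knows the splice patterns of each class.
#'
#' @param protein amino-acid string.
#' @param a_end 0-based end of module A from [detect_signal()].
#' @param class_hint optional class (\code{"Sn1"}..\code{"Sn3"}) used for
#'   the completeness judgement; when missing, per-class defaults are
#'   averaged.
#' @param window,pro_threshold,min_run,smooth_window segmentation
#'   parameters (defaults 15, 0.20, 5, 7).
#' @return an object of class \code{"seroin_architecture"}: a data frame
#'   with columns \code{label}, \code{start}, \code{end}, \code{complete}
#'   plus attributes \code{protein_length} and \code{degenerate}.
#' @export
segment_modules <- function(protein, a_end, class_hint = NULL,
                            window = 15L, pro_threshold = 0.20,
                            min_run = 5L, smooth_window = 7L) {
  n <- nchar(protein)
  if (n - a_end < 20L) stop("mature region shorter than 20 residues")
  prof <- composition_profile(protein, window)
  is_c <- prof$pro_frac >= pro_threshold
  mat <- seq.int(a_end + 1L, n)              # 1-based mature positions
  lab <- .majority_smooth(is_c[mat], smooth_window)

  runs <- .runs(lab)
  # merge runs shorter than min_run into the longer neighbour
  repeat {
    len <- runs$end - runs$start
    if (nrow(runs) <= 1L || all(len >= min_run)) break
    k <- which.min(ifelse(len < min_run, len, Inf))
    nb <- c(k - 1L, k + 1L)
    nb <- nb[nb >= 1L & nb <= nrow(runs)]
    tgt <- nb[which.max(len[nb])]
    runs$value[k] <- runs$value[tgt]
    # re-collapse equal neighbours
    v <- rep.int(runs$value, runs$end - runs$start)
    runs <- .runs(v)
  }
  # enforce at most 3 B and 2 C runs by absorbing the shortest internal run
  repeat {
    nb_runs <- sum(!runs$value)
    nc_runs <- sum(runs$value)
    if ((nb_runs <= 3L && nc_runs <= 2L) || nrow(runs) <= 2L) break
    internal <- 2:(nrow(runs) - 1L)
    len <- runs$end - runs$start
    k <- internal[which.min(len[internal])]
    runs$value[k] <- !runs$value[k]
    v <- rep.int(runs$value, runs$end - runs$start)
    runs <- .runs(v)
  }

  degenerate <- nrow(runs) == 1L
  bi <- 0L; ci <- 0L
  labels <- character(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    if (runs$value[k]) { ci <- ci + 1L; labels[k] <- paste0("C", ci) }
    else { bi <- bi + 1L; labels[k] <- paste0("B", bi) }
  }
  mods <- data.frame(label = c("A", labels),
                     start = c(0L, a_end + runs$start),
                     end = c(a_end, a_end + runs$end),
                     stringsAsFactors = FALSE)
  defaults <- .completeness_defaults(class_hint)
  mods$complete <- mods$end - mods$start >=
    0.5 * defaults[ifelse(mods$label %in% names(defaults), mods$label, "B1")]
  mods$complete[1] <- TRUE
  structure(mods, class = c("seroin_architecture", "data.frame"),
            protein_length = n, degenerate = degenerate)
}

# default module lengths used for completeness tests; positional labels
# share the defaults of the same-named canonical module
.completeness_defaults <- function(class_hint = NULL) {
  if (!is.null(class_hint)) return(module_defaults(class_hint))
  m <- sapply(c("Sn1", "Sn2", "Sn3"), module_defaults)
  rowMeans(m)
}

#' @export
print.seroin_architecture <- function(x, ...) {
  cat("Seroin module architecture (", attr(x, "protein_length"),
      " residues)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Tabulate architectures as a module table
#'
#' @param architectures named list of \code{"seroin_architecture"} objects.
#' @return a data frame with columns \code{id}, \code{label}, \code{start},
#'   \code{end}, \code{complete} mirroring per-protein module box diagrams.
#' @export
module_table <- function(architectures) {
  do.call(rbind, lapply(names(architectures), function(id) {
    a <- architectures[[id]]
    cbind(data.frame(id = id, stringsAsFactors = FALSE),
          as.data.frame(a))
  }))
}
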