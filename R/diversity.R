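#' Alpha diversity at a taxonomic rank
#'
#' Observed richness (taxa with non-zero abundance), Shannon's index
#' (\eqn{-\sum p \ln p}, natural log by default) and Simpson's index in its
#' Gini-Simpson form (\eqn{1 - \sum p^2}, the probability that two random
#' draws differ), computed per sample after collapsing taxa to \code{rank}.
#' Taxa unresolved at the analysis rank are pooled into an unassigned bin and
#' excluded.
#'
#' @param x An [AbundanceTable-class] (any mode; the indices depend only on
#'   within-sample proportions).
#' @param rank Analysis rank (default \code{"species"}).
#' @param base Logarithm base for Shannon's index (default \code{exp(1)}).
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{observed}, \code{shannon}, \code{simpson}.
#' @examples
#' at <- AbundanceTable(matrix(c(25, 25, 25, 25), 4,
#'                             dimnames = list(NULL, "s1")),
#'                      sprintf("g__G%d;s__sp%d", 1:4, 1:4), mode = "counts")
#' alphaDiversity(at)
#' @export
alphaDiversity <- function(x, rank = "species", base = exp(1)) {
  m <- collapseAtRank(x, rank = rank, include_unassigned = FALSE)
  empty <- which(colSums(m) <= 0)
  if (length(empty))
    stop("sample '", colnames(m)[empty[1]],
         "' has no abundance at rank '", rank, "'", call. = FALSE)
  comm <- t(m)
  data.frame(
    sample_id = colnames(m),
    observed = as.integer(rowSums(comm > 0)),
    shannon = as.numeric(vegan::diversity(comm, index = "shannon",
                                          base = base)),
    simpson = as.numeric(vegan::diversity(comm, index = "simpson")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Beta diversity distance matrix
#'
#' Bray-Curtis dissimilarity
#' \eqn{d(x, y) = \sum |x_i - y_i| / \sum (x_i + y_i)} on relative
#' abundances, or Jaccard distance \eqn{1 - |A \cap B| / |A \cup B|} on
#' presence/absence. Both are bounded in [0, 1], are 0 for identical columns
#' and 1 for disjoint supports.
#'
#' @param x An [AbundanceTable-class] in relative or percent mode (Jaccard,
#'   being presence-based, is unaffected by the scale; Bray-Curtis on closed
#'   columns equals Bray-Curtis on counts with equal library sizes).
#' @param metric \code{"bray_curtis"} or \code{"jaccard"}.
#' @param rank Optional rank at which to collapse taxa first (default: use
#'   the table as is).
#' @return A \code{stats::dist} object over samples.
#' @export
betaDiversity <- function(x, metric = c("bray_curtis", "jaccard"),
                          rank = NULL) {
  supported <- c("bray_curtis", "jaccard")
  if (!is.character(metric) || !metric[1] %in% supported)
    stop("unknown metric '", metric[1], "'; supported metrics: ",
         paste(supported, collapse = ", "), call. = FALSE)
  metric <- metric[1]
  stopifnot(is(x, "AbundanceTable"))
  if (ncol(x) < 2L)
    stop("beta diversity requires at least two samples", call. = FALSE)
  m <- if (is.null(rank)) .asProportions(x)
       else {
         cm <- collapseAtRank(x, rank = rank, include_unassigned = FALSE)
         sweep(cm, 2, colSums(cm), "/")
       }
  comm <- t(m)
  if (metric == "bray_curtis") {
    vegan::vegdist(comm, method = "bray")
  } else {
    vegan::vegdist(comm, method = "jaccard", binary = TRUE)
  }
}
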