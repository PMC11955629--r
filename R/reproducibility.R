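#' Paired sample design
#'
#' Pairs of samples to be compared: technical replicates (within-run or
#' between-run) or stool/rectal-swab pairs from the same subject. No sample
#' may belong to two pairs.
#'
#' @slot pairs \code{data.frame} with columns \code{sample_a},
#'   \code{sample_b}, \code{pair_id}.
#' @slot scope One of \code{"within_run"}, \code{"between_run"},
#'   \code{"stool_swab"}.
#' @export
setClass("PairedDesign",
         representation(pairs = "data.frame", scope = "character"))

setValidity("PairedDesign", function(object) {
  p <- object@pairs
  if (!all(c("sample_a", "sample_b", "pair_id") %in% colnames(p)))
    return("pairs needs columns sample_a, sample_b, pair_id")
  if (!object@scope %in% c("within_run", "between_run", "stool_swab"))
    return("scope must be within_run, between_run or stool_swab")
  members <- c(p$sample_a, p$sample_b)
  if (anyDuplicated(members))
    return("a sample may not appear in more than one pair")
  if (anyDuplicated(p$pair_id)) return("pair ids must be unique")
  TRUE
})

#' @describeIn PairedDesign Constructor.
#' @param sample_a,sample_b Character vectors of paired sample ids.
#' @param pair_id Optional pair labels (defaults to \code{pair_1..n}).
#' @param scope Pairing scope.
#' @export
pairedDesign <- function(sample_a, sample_b, pair_id = NULL,
                         scope = c("within_run", "between_run",
                                   "stool_swab")) {
  scope <- match.arg(scope)
  if (is.null(pair_id)) pair_id <- sprintf("pair_%d", seq_along(sample_a))
  new("PairedDesign",
      pairs = data.frame(sample_a = as.character(sample_a),
                         sample_b = as.character(sample_b),
                         pair_id = as.character(pair_id),
                         stringsAsFactors = FALSE),
      scope = scope)
}

#' @describeIn PairedDesign Number of pairs.
#' @param design A [PairedDesign-class].
#' @export
nPairs <- function(design) {
  stopifnot(is(design, "PairedDesign"))
  nrow(design@pairs)
}

#' @describeIn PairedDesign The pair table.
#' @export
designPairs <- function(design) {
  stopifnot(is(design, "PairedDesign"))
  design@pairs
}

setMethod("show", "PairedDesign", function(object) {
  cat("PairedDesign (", object@scope, ") with ", nrow(object@pairs),
      " pairs\n", sep = "")
})

#' Build a paired design from sample metadata
#'
#' Uses the \code{replicate_pair_id} column; negative controls are excluded
#' from pairing by metadata validation. When \code{scope} is
#' \code{"within_run"} or \code{"between_run"} and a \code{replicate_scope}
#' column exists, only pairs with that scope are kept.
#'
#' @param meta Sample metadata \code{data.frame}.
#' @param scope Pairing scope to extract.
#' @return A [PairedDesign-class].
#' @export
designFromMetadata <- function(meta,
                               scope = c("within_run", "between_run",
                                         "stool_swab")) {
  scope <- match.arg(scope)
  meta <- validateSampleMetadata(meta)
  if (!"replicate_pair_id" %in% colnames(meta))
    stop("metadata has no replicate_pair_id column", call. = FALSE)
  sub <- meta[!is.na(meta$replicate_pair_id), , drop = FALSE]
  if ("replicate_scope" %in% colnames(sub))
    sub <- sub[!is.na(sub$replicate_scope) & sub$replicate_scope == scope, ,
               drop = FALSE]
  if (nrow(sub) == 0L) stop("no pairs with scope '", scope, "'", call. = FALSE)
  split_ids <- split(sub$sample_id, sub$replicate_pair_id)
  pairedDesign(vapply(split_ids, `[`, character(1), 1L),
               vapply(split_ids, `[`, character(1), 2L),
               pair_id = names(split_ids), scope = scope)
}

#' Paired Wilcoxon signed-rank test with Hodges-Lehmann interval
#'
#' Two-sided signed-rank test on the paired differences of a per-sample
#' statistic (an alpha-diversity measure, typically), with the 95%
#' Hodges-Lehmann confidence interval for the median paired difference
#' computed from Walsh averages. Zero differences are dropped (Wilcoxon's
#' original treatment); the exact null distribution is used for up to 25
#' non-zero untied differences, otherwise the normal approximation with
#' continuity correction. When every difference is zero the result is
#' degenerate and flagged: p = 1 and the interval collapses at 0.
#'
#' @param values Named numeric vector of the per-sample statistic (names =
#'   sample ids).
#' @param design A [PairedDesign-class]; both members of every pair must
#'   appear in \code{values}.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with \code{n_pairs}, \code{statistic}, \code{p_value},
#'   \code{estimate} (Hodges-Lehmann), \code{ci_low}, \code{ci_high},
#'   \code{exact} and \code{degenerate}.
#' @export
pairedWilcoxon <- function(values, design, conf_level = 0.95) {
  stopifnot(is(design, "PairedDesign"))
  p <- design@pairs
  missing <- setdiff(c(p$sample_a, p$sample_b), names(values))
  if (length(missing))
    stop("values missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  va <- values[p$sample_a]
  vb <- values[p$sample_b]
  d <- va - vb
  if (length(d) < 1L) stop("at least one pair is required", call. = FALSE)
  if (all(d == 0)) {
    return(list(n_pairs = length(d), statistic = NA_real_, p_value = 1,
                estimate = 0, ci_low = 0, ci_high = 0, exact = TRUE,
                degenerate = TRUE))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  ht <- suppressWarnings(
    stats::wilcox.test(nz, conf.int = TRUE, conf.level = conf_level,
                       exact = exact, correct = TRUE))
  list(n_pairs = length(d),
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       estimate = unname(ht$estimate),
       ci_low = unname(ht$conf.int[1]),
       ci_high = unname(ht$conf.int[2]),
       exact = exact,
       degenerate = FALSE)
}

#' Distance-based intraclass correlation coefficient (dICC)
#'
#' Method-of-moments estimator on squared distances: with
#' \eqn{MS_w} the mean of \eqn{d(a, b)^2} over the designated pairs and
#' \eqn{MS_t} the mean of \eqn{d(u, v)^2} over all cross-pair sample pairs
#' (members of different pair ids),
#' \deqn{dICC = 1 - MS_w / MS_t.}
#' Perfectly duplicated pairs give 1; under a random (exchangeable) pairing
#' the estimator is centred at 0; and with Euclidean distances on data from a
#' Gaussian variance-components model with between-subject variance
#' \eqn{\sigma_b^2} and within-pair variance \eqn{\sigma_w^2} it estimates
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}, the classical ICC(1).
#' Sampling noise can push the estimate slightly negative; values are
#' reported unclipped.
#'
#' @param dist A \code{stats::dist} object or symmetric distance matrix whose
#'   labels include every sample of the design.
#' @param design A [PairedDesign-class] with at least two pairs (the total
#'   term is undefined otherwise).
#' @return A list with \code{dicc}, \code{n_pairs}, \code{mean_sq_within},
#'   \code{mean_sq_total}.
#' @export
dicc <- function(dist, design) {
  stopifnot(is(design, "PairedDesign"))
  m <- as.matrix(dist)
  p <- design@pairs
  if (nrow(p) < 2L)
    stop("dICC requires at least two pairs", call. = FALSE)
  ids <- c(p$sample_a, p$sample_b)
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("distance matrix lacks sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  msw <- mean(m[cbind(p$sample_a, p$sample_b)]^2)
  pair_of <- stats::setNames(rep(p$pair_id, 2L), ids)
  sub <- m[ids, ids]^2
  cross <- outer(pair_of[ids], pair_of[ids], "!=")
  mst <- mean(sub[upper.tri(sub)][cross[upper.tri(cross)]])
  if (mst == 0)
    stop("all between-sample distances are zero; dICC is undefined ",
         "for this metric on these samples", call. = FALSE)
  list(dicc = 1 - msw / mst,
       n_pairs = nrow(p),
       mean_sq_within = msw,
       mean_sq_total = mst)
}

#' Qualitative interpretation of an ICC value
#'
#' Standard reliability bands: below 0.5 poor, 0.5 to below 0.75 moderate,
#' 0.75 and above good.
#'
#' @param x A dICC result from [dicc()] or a bare number.
#' @return \code{"poor"}, \code{"moderate"} or \code{"good"}.
#' @examples
#' interpretDicc(0.94)   # good
#' interpretDicc(0.597)  # moderate
#' interpretDicc(0.31)   # poor
#' @export
interpretDicc <- function(x) {
  v <- if (is.list(x)) x$dicc else x
  stopifnot(is.numeric(v), length(v) == 1L)
  if (v < 0.5) "poor" else if (v < 0.75) "moderate" else "good"
}
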