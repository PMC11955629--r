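#' Confusion counts for a mock-control profile
#'
#' True positives (expected species detected at species rank), false
#' positives (species-rank taxa not matching any expected species) and false
#' negatives (expected species not detected). By construction
#' \code{tp + fn} equals the number of reference species.
#'
#' @slot tp,fp,fn Non-negative integer counts.
#' @export
setClass("ConfusionCounts",
         representation(tp = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn)
  if (length(v) != 3L || anyNA(v) || any(v < 0))
    return("tp, fp, fn must be single non-negative integers")
  TRUE
})

#' @describeIn ConfusionCounts Constructor from raw counts.
#' @param tp,fp,fn Non-negative integers.
#' @export
confusionCounts <- function(tp, fp, fn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d FN=%d\n",
              object@tp, object@fp, object@fn))
})

#' Precision, sensitivity and F-score
#'
#' @slot precision,sensitivity,f_score Numbers in [0, 1], kept at full
#'   precision; rendering to 2 decimals happens only at the report boundary.
#' @slot precision_undefined \code{TRUE} when tp + fp = 0, in which case
#'   precision is reported as 0 with this flag set.
#' @export
setClass("PerformanceScores",
         representation(precision = "numeric", sensitivity = "numeric",
                        f_score = "numeric", precision_undefined = "logical"))

setValidity("PerformanceScores", function(object) {
  v <- c(object@precision, object@sensitivity, object@f_score)
  if (any(v < 0 | v > 1)) return("scores must lie in [0, 1]")
  TRUE
})

setMethod("show", "PerformanceScores", function(object) {
  cat(sprintf("PerformanceScores: precision=%.4f sensitivity=%.4f F=%.4f%s\n",
              object@precision, object@sensitivity, object@f_score,
              if (object@precision_undefined) " (precision undefined: tp+fp=0)"
              else ""))
})

#' Match a mock-control profile against the expected community
#'
#' A reference species is \emph{detected} when a species-rank taxon
#' alias-resolves to it with relative abundance above \code{floor}.
#' Species-rank taxa above \code{floor} that resolve to no reference species
#' are \emph{spurious}. A reference species missed at species rank whose
#' genus is observed at genus rank (abundance above \code{floor}) is a
#' \emph{genus rescue}; rescues are reported but never counted as true
#' positives, since scoring is strictly at species rank.
#'
#' @param x An [AbundanceTable-class] in relative or percent mode.
#' @param ref A [MockReference-class].
#' @param control_id Sample id of the control column.
#' @param floor Relative-abundance detection floor (proportion scale;
#'   default 0 keeps all rare taxa).
#' @return A list with character vectors \code{detected}, \code{spurious}
#'   (canonical lineage strings) and \code{genus_rescues}.
#' @export
matchSpecies <- function(x, ref, control_id, floor = 0) {
  stopifnot(is(x, "AbundanceTable"), is(ref, "MockReference"))
  if (!control_id %in% sampleIDs(x))
    stop("unknown control id: '", control_id, "'", call. = FALSE)
  p <- .asProportions(x)[, control_id]
  rd <- SummarizedExperiment::rowData(x)
  sp_rows <- which(rd$resolved_rank %in% "species" & p > floor)
  resolved <- resolveAlias(ref, rd$species_label[sp_rows])
  detected <- unique(resolved[!is.na(resolved)])
  spurious <- rownames(x)[sp_rows[is.na(resolved)]]

  missed <- setdiff(referenceSpecies(ref), detected)
  rescues <- character(0)
  if (length(missed)) {
    genus_rows <- which(rd$resolved_rank %in% "genus" & p > floor)
    seen_genera <- rd$genus[genus_rows]
    for (sp in missed) {
      labels <- c(sp, names(ref@aliases)[ref@aliases == sp])
      genera <- unique(sub(" [^ ]*$", "", labels))
      if (any(genera %in% seen_genera)) rescues <- c(rescues, sp)
    }
  }
  list(detected = detected, spurious = spurious, genus_rescues = rescues)
}

#' Confusion counts from a match result
#'
#' @param detected Character vector of detected reference species.
#' @param spurious Character vector of spurious species-rank taxa.
#' @param ref A [MockReference-class].
#' @return A [ConfusionCounts-class] with \code{tp = |detected|},
#'   \code{fn = |ref| - |detected|}, \code{fp = |spurious|}.
#' @export
confusion <- function(detected, spurious, ref) {
  stopifnot(is(ref, "MockReference"))
  n_ref <- length(referenceSpecies(ref))
  tp <- length(unique(detected))
  if (tp > n_ref)
    stop("more detected species than reference species", call. = FALSE)
  confusionCounts(tp, length(unique(spurious)), n_ref - tp)
}

#' Performance scores from confusion counts
#'
#' Precision = TP / (TP + FP); sensitivity = TP / (TP + FN);
#' F-score = 2 * precision * sensitivity / (precision + sensitivity), with
#' F = 0 when precision + sensitivity = 0. When TP + FP = 0 precision is
#' undefined and reported as 0 with \code{precision_undefined} set.
#'
#' @param counts A [ConfusionCounts-class].
#' @return A [PerformanceScores-class].
#' @examples
#' performance(confusionCounts(7, 15, 1))
#' @export
performance <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn
  if (tp + fp + fn == 0L)
    stop("confusion counts are all zero; nothing to score", call. = FALSE)
  undef <- (tp + fp) == 0L
  precision <- if (undef) 0 else tp / (tp + fp)
  sensitivity <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  new("PerformanceScores", precision = precision, sensitivity = sensitivity,
      f_score = f, precision_undefined = undef)
}

## Observed percent of each reference species in each control column.
.observedPercent <- function(x, ref) {
  pct <- .asProportions(x) * 100
  rd <- SummarizedExperiment::rowData(x)
  sp_rows <- which(rd$resolved_rank %in% "species")
  resolved <- resolveAlias(ref, rd$species_label[sp_rows])
  species <- referenceSpecies(ref)
  obs <- matrix(0, length(species), ncol(x),
                dimnames = list(species, sampleIDs(x)))
  hit <- !is.na(resolved)
  if (any(hit)) {
    contrib <- rowsum(pct[sp_rows[hit], , drop = FALSE],
                      group = resolved[hit])
    obs[rownames(contrib), ] <- contrib
  }
  obs
}

#' Observed/Expected abundance ratios across mock controls
#'
#' For each reference species, the observed percentage in every control is
#' divided by its theoretical percentage; a species undetected in a control
#' contributes a ratio of exactly 0, and zeros are included in the median and
#' range, matching how dropout shows up in published mock-control tables.
#'
#' @param x An [AbundanceTable-class] (relative or percent mode) whose
#'   columns are the mock controls.
#' @param ref A [MockReference-class].
#' @return A \code{data.frame} with one row per reference species
#'   (\code{species_label}, \code{theoretical_percent}, \code{median_ratio},
#'   \code{min_ratio}, \code{max_ratio}) and attributes
#'   \code{"observed_percent"} and \code{"ratios"} (species x control
#'   matrices).
#' @export
oeRatios <- function(x, ref) {
  stopifnot(is(x, "AbundanceTable"), is(ref, "MockReference"))
  if (ncol(x) < 1L) stop("at least one control is required", call. = FALSE)
  obs <- .observedPercent(x, ref)
  theo <- theoreticalPercent(ref)
  ratios <- obs / theo[rownames(obs)]
  out <- data.frame(species_label = rownames(obs),
                    theoretical_percent = unname(theo[rownames(obs)]),
                    median_ratio = apply(ratios, 1, stats::median),
                    min_ratio = apply(ratios, 1, min),
                    max_ratio = apply(ratios, 1, max),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "observed_percent") <- obs
  attr(out, "ratios") <- ratios
  out
}

#' Percent of a control correctly classified
#'
#' Sum of species-rank relative abundances that alias-resolve to a reference
#' species, expressed as a percentage. Genus-rescued reads are \emph{not}
#' counted: the published per-control arithmetic (species rows summing to the
#' printed value) shows the quantity is species-rank-only.
#'
#' @inheritParams matchSpecies
#' @return A number in [0, 100].
#' @export
percentCorrect <- function(x, ref, control_id) {
  stopifnot(is(x, "AbundanceTable"), is(ref, "MockReference"))
  if (!control_id %in% sampleIDs(x))
    stop("unknown control id: '", control_id, "'", call. = FALSE)
  sum(.observedPercent(x, ref)[, control_id])
}

#' Score one mock control end to end
#'
#' Runs [matchSpecies()], [confusion()], [performance()] and
#' [percentCorrect()] for a single control column.
#'
#' @inheritParams matchSpecies
#' @return A list with \code{control_id}, \code{counts}
#'   ([ConfusionCounts-class]), \code{scores} ([PerformanceScores-class]),
#'   \code{percent_correct}, \code{genus_rescues} and \code{spurious}.
#' @export
evaluateMockControl <- function(x, ref, control_id, floor = 0) {
  m <- matchSpecies(x, ref, control_id, floor = floor)
  counts <- confusion(m$detected, m$spurious, ref)
  structure(list(control_id = control_id,
                 counts = counts,
                 scores = performance(counts),
                 percent_correct = percentCorrect(x, ref, control_id),
                 genus_rescues = m$genus_rescues,
                 spurious = m$spurious),
            class = "mock_control_report")
}

#' @export
print.mock_control_report <- function(x, ...) {
  cat(sprintf(
    "Mock control %s: TP=%d FP=%d FN=%d | P=%.2f S=%.2f F=%.2f | %%correct=%.2f\n",
    x$control_id, x$counts@tp, x$counts@fp, x$counts@fn,
    x$scores@precision, x$scores@sensitivity, x$scores@f_score,
    x$percent_correct))
  if (length(x$genus_rescues))
    cat("  genus rescues:", paste(x$genus_rescues, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn evaluateMockControl Score every column of a control table.
#' @return For \code{evaluateMocks}, a list of per-control reports.
#' @export
evaluateMocks <- function(x, ref, floor = 0) {
  lapply(sampleIDs(x), function(id)
    evaluateMockControl(x, ref, id, floor = floor))
}

#' Aggregate mock-control reports
#'
#' Median and range of the F-score over controls (full-precision scores;
#' zeros from total misses included), plus a per-control score table.
#'
#' @param reports List of reports from [evaluateMockControl()] /
#'   [evaluateMocks()], or a list of [PerformanceScores-class].
#' @return A list with \code{n}, \code{f_median}, \code{f_range} (length-2
#'   numeric) and \code{per_control} (\code{data.frame}).
#' @export
aggregateControls <- function(reports) {
  if (length(reports) == 0L) stop("at least one report required", call. = FALSE)
  getScores <- function(r) if (is(r, "PerformanceScores")) r else r$scores
  f <- vapply(reports, function(r) getScores(r)@f_score, numeric(1))
  per <- data.frame(
    control_id = vapply(seq_along(reports), function(i) {
      r <- reports[[i]]
      if (is.list(r) && !is.null(r$control_id)) r$control_id
      else sprintf("control_%d", i)
    }, character(1)),
    precision = vapply(reports, function(r) getScores(r)@precision, numeric(1)),
    sensitivity = vapply(reports, function(r) getScores(r)@sensitivity,
                         numeric(1)),
    f_score = f, stringsAsFactors = FALSE)
  list(n = length(f), f_median = stats::median(f), f_range = range(f),
       per_control = per)
}
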