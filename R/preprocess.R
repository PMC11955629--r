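#' Plate-wise contaminant filtering against negative controls
#'
#' Classifies taxa as reagent/environmental contaminants using the plate's
#' own negative controls and removes them. Two per-taxon scores are computed,
#' each on a p-value-like [0, 1] scale where small means contaminant-like:
#'
#' \itemize{
#' \item \strong{prevalence score}: one-sided Fisher exact p-value on the
#'   2x2 presence/absence table (taxon present/absent x negative/real
#'   sample), alternative = presence enriched in negatives;
#' \item \strong{frequency score} (only when \code{dna_concentration} is
#'   available for the plate's real samples): one-sided Spearman rank
#'   correlation test of the taxon's within-sample relative frequency against
#'   inverse DNA concentration — contaminants make up more of low-input
#'   libraries.
#' }
#'
#' When both scores exist they are combined by Fisher's method; otherwise the
#' combined score is the prevalence score. A taxon is flagged as a
#' contaminant when its combined score falls below \code{threshold}, and
#' flagged taxa are removed (row deletion; remaining values untouched).
#' Decontamination is refused — not silently skipped — when the plate has no
#' negative controls.
#'
#' @param x An [AbundanceTable-class] in counts mode, containing the plate's
#'   samples (other plates' samples are ignored).
#' @param meta Sample metadata \code{data.frame}
#'   (see [readSampleMetadata()]).
#' @param plate Plate identifier to decontaminate.
#' @param threshold Combined-score threshold below which a taxon is flagged
#'   (default 0.1).
#' @param presence_floor Minimum count for a taxon to be considered present
#'   in a sample (default 0, i.e. presence = count > 0).
#' @return A list with \code{table} (the plate's samples with contaminant
#'   rows removed) and \code{scores} (per-taxon \code{data.frame} with
#'   \code{taxon}, \code{prevalence_score}, \code{frequency_score},
#'   \code{combined_score}, \code{is_contaminant}).
#' @export
decontaminate <- function(x, meta, plate, threshold = 0.1,
                          presence_floor = 0) {
  stopifnot(is(x, "AbundanceTable"))
  if (abundanceMode(x) != "counts")
    stop("decontaminate requires a counts-mode table", call. = FALSE)
  meta <- validateSampleMetadata(meta)
  plate_meta <- meta[meta$plate == plate & meta$sample_id %in% sampleIDs(x), ,
                     drop = FALSE]
  if (nrow(plate_meta) == 0L)
    stop("no samples found for plate '", plate, "'", call. = FALSE)
  neg_ids <- plate_meta$sample_id[plate_meta$control_role == "negative"]
  real_ids <- plate_meta$sample_id[plate_meta$control_role != "negative"]
  if (length(neg_ids) == 0L)
    stop("plate '", plate, "' has no negative controls; ",
         "decontamination refused", call. = FALSE)
  if (length(real_ids) == 0L)
    stop("plate '", plate, "' has no non-negative samples", call. = FALSE)
  m <- abundances(x)[, plate_meta$sample_id, drop = FALSE]
  present <- m > presence_floor

  prev_p <- vapply(seq_len(nrow(m)), function(i) {
    a <- sum(present[i, neg_ids])                 # negatives with taxon
    b <- length(neg_ids) - a
    c_ <- sum(present[i, real_ids])               # real samples with taxon
    d <- length(real_ids) - c_
    stats::fisher.test(cbind(c(a, b), c(c_, d)),
                       alternative = "greater")$p.value
  }, numeric(1))

  freq_p <- rep(NA_real_, nrow(m))
  if ("dna_concentration" %in% colnames(plate_meta)) {
    conc <- stats::setNames(plate_meta$dna_concentration,
                            plate_meta$sample_id)[real_ids]
    usable <- real_ids[!is.na(conc)]
    if (length(usable) >= 4L) {
      totals <- colSums(m[, usable, drop = FALSE])
      relfreq <- sweep(m[, usable, drop = FALSE], 2, totals, "/")
      inv_conc <- 1 / conc[usable]
      for (i in seq_len(nrow(m))) {
        f <- relfreq[i, ]
        if (sum(f > 0) >= 3L && stats::sd(f) > 0) {
          freq_p[i] <- suppressWarnings(
            stats::cor.test(f, inv_conc, method = "spearman",
                            alternative = "greater")$p.value)
        }
      }
    }
  }

  combined <- prev_p
  both <- !is.na(freq_p)
  if (any(both)) {
    p1 <- pmax(prev_p[both], 1e-300)
    p2 <- pmax(freq_p[both], 1e-300)
    combined[both] <- stats::pchisq(-2 * (log(p1) + log(p2)), df = 4,
                                    lower.tail = FALSE)
  }
  is_contam <- combined < threshold

  scores <- data.frame(taxon = rownames(m),
                       prevalence_score = prev_p,
                       frequency_score = freq_p,
                       combined_score = combined,
                       is_contaminant = is_contam,
                       stringsAsFactors = FALSE)
  keep <- m[!is_contam, , drop = FALSE]
  out <- AbundanceTable(keep, rownames(keep), colnames(keep),
                        mode = "counts")
  list(table = out, scores = scores)
}

#' Median library-size normalisation
#'
#' Rescales every sample column so its total equals the median of the
#' original library sizes. Within-sample proportions are preserved exactly;
#' values may become fractional but the table remains in (scaled) counts
#' mode.
#'
#' @param x An [AbundanceTable-class] in counts mode with positive sample
#'   totals.
#' @return An [AbundanceTable-class] in counts mode, all totals equal to the
#'   median original total.
#' @examples
#' at <- AbundanceTable(matrix(c(10, 0, 600, 400), 2,
#'                             dimnames = list(NULL, c("a", "b"))),
#'                      c("g__X;s__x", "g__Y;s__y"), mode = "counts")
#' colSums(abundances(normalizeMedianLibrary(at)))
#' @export
normalizeMedianLibrary <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  if (abundanceMode(x) != "counts")
    stop("normalizeMedianLibrary requires a counts-mode table", call. = FALSE)
  m <- abundances(x)
  totals <- colSums(m)
  zero <- which(totals <= 0)
  if (length(zero))
    stop("sample '", colnames(m)[zero[1]], "' has zero total abundance",
         call. = FALSE)
  med <- stats::median(totals)
  out <- sweep(m, 2, med / totals, "*")
  AbundanceTable(out, rownames(m), colnames(m), mode = "counts")
}
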