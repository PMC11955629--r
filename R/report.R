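#' Round half-up and format to fixed decimals
#'
#' Report-boundary rounding: exact halves round away from zero (so 0.875
#' renders as "0.88" and 0.125 as "0.13"), unlike base \code{round()}'s
#' round-half-even. Full precision is kept everywhere upstream; this is only
#' for rendering.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Character vector, or (with \code{character = FALSE}) numeric.
#' @param character Return formatted strings (default) or rounded numbers.
#' @examples
#' formatHalfUp(c(0.875, 0.125, 1.0661))
#' @export
formatHalfUp <- function(x, digits = 2, character = TRUE) {
  scaled <- abs(x) * 10^digits
  rounded <- sign(x) * floor(scaled + 0.5 + 1e-9) / 10^digits
  if (!character) return(rounded)
  formatC(rounded, digits = digits, format = "f")
}

#' Render per-control performance reports as a published-style table
#'
#' Rows are the confusion counts followed by the three scores (2 decimals,
#' half-up); columns are the controls.
#'
#' @param reports List of reports from [evaluateMocks()], or a named list of
#'   [ConfusionCounts-class].
#' @return A \code{data.frame} with a \code{measure} column plus one column
#'   per control.
#' @export
renderPerformanceTable <- function(reports) {
  if (length(reports) == 0L)
    return(data.frame(measure = character(0)))
  getCounts <- function(r) if (is(r, "ConfusionCounts")) r else r$counts
  ids <- if (!is.null(names(reports)) && all(nzchar(names(reports))))
    names(reports)
  else vapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    if (is.list(r) && !is.null(r$control_id)) r$control_id
    else sprintf("control_%d", i)
  }, character(1))
  cols <- lapply(reports, function(r) {
    cc <- getCounts(r)
    sc <- performance(cc)
    c(as.character(c(cc@tp, cc@fp, cc@fn)),
      formatHalfUp(c(sc@precision, sc@sensitivity, sc@f_score)))
  })
  out <- data.frame(measure = c("True positives", "False positives",
                                "False negatives", "Precision",
                                "Sensitivity", "F-score"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[ids[i]]] <- cols[[i]]
  out
}

#' Format an O/E record as "median (min-max)"
#'
#' @param median_ratio,min_ratio,max_ratio Numbers.
#' @return Character, e.g. \code{"1.07 (0.00–1.13)"}.
#' @export
formatOERecord <- function(median_ratio, min_ratio, max_ratio) {
  sprintf("%s (%s–%s)", formatHalfUp(median_ratio),
          formatHalfUp(min_ratio), formatHalfUp(max_ratio))
}

#' Render an observed-vs-expected abundance table
#'
#' Published-style layout: one row per reference species with its theoretical
#' percentage, the observed percentage in every control (2 decimals,
#' half-up), and the O/E ratio as "median (range)"; then an "Other" row
#' (100 minus the correctly-classified percentage) and a "% Correctly
#' classified" row.
#'
#' @param oe Result of [oeRatios()].
#' @param percent_correct Named numeric vector of [percentCorrect()] values
#'   (names = control ids, matching the columns of \code{oe}'s observed
#'   matrix).
#' @return A \code{data.frame}.
#' @export
renderOETable <- function(oe, percent_correct) {
  obs <- attr(oe, "observed_percent")
  ids <- colnames(obs)
  out <- data.frame(species = oe$species_label,
                    theoretical_percent = formatHalfUp(oe$theoretical_percent,
                                                       1),
                    stringsAsFactors = FALSE)
  for (id in ids) out[[id]] <- formatHalfUp(obs[, id])
  out[["oe_ratio_median_range"]] <-
    formatOERecord(oe$median_ratio, oe$min_ratio, oe$max_ratio)
  other <- data.frame(species = "Other", theoretical_percent = "0",
                      stringsAsFactors = FALSE)
  correct <- data.frame(species = "% Correctly classified",
                        theoretical_percent = "100",
                        stringsAsFactors = FALSE)
  for (id in ids) {
    other[[id]] <- formatHalfUp(100 - percent_correct[[id]])
    correct[[id]] <- formatHalfUp(percent_correct[[id]])
  }
  other[["oe_ratio_median_range"]] <- "-"
  correct[["oe_ratio_median_range"]] <- "-"
  rbind(out, other, correct)
}

#' Render reproducibility results
#'
#' One row per metric: Wilcoxon results for alpha-diversity measures
#' (statistic, Hodges-Lehmann 95% CI, p) and dICC results for beta-diversity
#' metrics (estimate, qualitative label).
#'
#' @param wilcoxon Named list of [pairedWilcoxon()] results (names = alpha
#'   measures).
#' @param dicc_results Named list of [dicc()] results (names = beta metrics).
#' @return A \code{data.frame}.
#' @export
renderReproTable <- function(wilcoxon = list(), dicc_results = list()) {
  rows <- list()
  for (nm in names(wilcoxon)) {
    w <- wilcoxon[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      measure = nm, kind = "paired_wilcoxon", n_pairs = w$n_pairs,
      estimate = formatHalfUp(w$estimate, 3),
      ci = sprintf("(%s, %s)", formatHalfUp(w$ci_low), formatHalfUp(w$ci_high)),
      p_value = formatHalfUp(w$p_value, 3), label = "",
      stringsAsFactors = FALSE)
  }
  for (nm in names(dicc_results)) {
    d <- dicc_results[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      measure = nm, kind = "dicc", n_pairs = d$n_pairs,
      estimate = formatHalfUp(d$dicc, 3), ci = "", p_value = "",
      label = interpretDicc(d), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(measure = character(0)))
  do.call(rbind, rows)
}

#' Write a rendered report
#'
#' @param x A rendered \code{data.frame} (from one of the \code{render*}
#'   functions) or, for JSON, any list of results.
#' @param path Output file path.
#' @param format \code{"tsv"} (default), \code{"json"} or \code{"markdown"}.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(x, path, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stopifnot(is.data.frame(x))
    header <- paste0("| ", paste(colnames(x), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(x)), collapse = "|"), "|")
    body <- apply(x, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path, useBytes = TRUE)
  }
  invisible(path)
}
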