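#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.MODES <- c("counts", "relative", "percent")
.REL_TOL <- 1e-6     # column-closure tolerance accepted from files
.PCT_TOL <- 0.05     # percent tables are usually rounded to 2 dp

#' Taxa-by-sample abundance table
#'
#' The central container of the package: a \linkS4class{SummarizedExperiment}
#' whose single assay \code{"abundance"} holds a non-negative taxa x samples
#' matrix and whose \code{rowData} carries the parsed lineage (one column per
#' rank plus \code{resolved_rank}, \code{species_label} and the canonical
#' lineage string, which is also the row name). Taxon identity is the full
#' canonical lineage string, so genus-only and species-level records of the
#' same genus are distinct rows.
#'
#' Three value modes are supported: \code{"counts"} (read counts; fractional
#' values are permitted after median library-size normalisation),
#' \code{"relative"} (per-sample proportions, columns closed to 1) and
#' \code{"percent"} (per-sample percentages, columns closed to 100; the form
#' in which mock-community tables are conventionally printed).
#'
#' @slot abundance_mode One of \code{"counts"}, \code{"relative"},
#'   \code{"percent"}.
#'
#' @seealso [readAbundanceTable()], [toRelative()], [collapseAtRank()]
#' @export
setClass("AbundanceTable",
         contains = "SummarizedExperiment",
         representation(abundance_mode = "character"))

setValidity("AbundanceTable", function(object) {
  if (length(object@abundance_mode) != 1L ||
      !object@abundance_mode %in% .MODES)
    return(sprintf("abundance_mode must be one of: %s",
                   paste(.MODES, collapse = ", ")))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  m <- SummarizedExperiment::assay(object, "abundance")
  if (anyNA(m)) return("abundance values must not be NA")
  if (any(m < 0)) return("abundance values must be non-negative")
  if (anyDuplicated(colnames(m))) return("sample ids must be unique")
  if (anyDuplicated(rownames(m)))
    return("taxa must be unique by canonical lineage string")
  if (!all(c("resolved_rank", "species_label") %in%
           colnames(SummarizedExperiment::rowData(object))))
    return("rowData must carry parsed lineage columns")
  if (object@abundance_mode == "relative" && ncol(m) > 0) {
    cs <- colSums(m)
    if (any(abs(cs - 1) > .REL_TOL))
      return("mode 'relative' requires every sample column to sum to 1")
  }
  if (object@abundance_mode == "percent" && ncol(m) > 0) {
    cs <- colSums(m)
    if (any(abs(cs - 100) > .PCT_TOL))
      return("mode 'percent' requires every sample column to sum to 100")
  }
  TRUE
})

#' Construct an AbundanceTable
#'
#' @param values Numeric taxa x samples matrix (non-negative).
#' @param lineages Character vector of lineage strings, one per row of
#'   \code{values} (any dialect accepted by [parseLineage()]).
#' @param sample_ids Character vector of unique sample ids; defaults to the
#'   column names of \code{values}.
#' @param mode One of \code{"counts"}, \code{"relative"}, \code{"percent"}.
#' @return An [AbundanceTable-class].
#' @examples
#' at <- AbundanceTable(matrix(c(50, 50, 30, 70), nrow = 2,
#'                             dimnames = list(NULL, c("s1", "s2"))),
#'                      lineages = c("g__Bacillus;s__subtilis",
#'                                   "g__Listeria;s__monocytogenes"),
#'                      mode = "counts")
#' abundanceMode(at)
#' @export
AbundanceTable <- function(values, lineages, sample_ids = colnames(values),
                           mode = c("counts", "relative", "percent")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(lineages) != nrow(values))
    stop("one lineage string per row of 'values' is required", call. = FALSE)
  if (is.null(sample_ids))
    stop("sample ids are required (name the columns of 'values')",
         call. = FALSE)
  rd <- .lineageFrame(lineages)
  if (anyDuplicated(rd$canonical))
    stop("duplicate lineage: '",
         rd$canonical[duplicated(rd$canonical)][1], "'", call. = FALSE)
  rownames(values) <- rd$canonical
  colnames(values) <- sample_ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), rowData = rd)
  new("AbundanceTable", se, abundance_mode = mode)
}

#' @describeIn AbundanceTable Value mode of the table.
#' @param x An [AbundanceTable-class].
#' @export
abundanceMode <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  x@abundance_mode
}

#' @describeIn AbundanceTable Abundance matrix (taxa x samples).
#' @export
abundances <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  SummarizedExperiment::assay(x, "abundance")
}

#' @describeIn AbundanceTable Canonical lineage strings (row identity).
#' @export
lineageStrings <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  rownames(x)
}

#' @describeIn AbundanceTable Sample ids.
#' @export
sampleIDs <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  colnames(x)
}

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable with ", nrow(object), " taxa and ",
      ncol(object), " samples (mode: ", object@abundance_mode, ")\n",
      sep = "")
  rr <- SummarizedExperiment::rowData(object)$resolved_rank
  tab <- table(factor(ifelse(is.na(rr), "unassigned", rr),
                      levels = c(.RANKS, "unassigned")))
  tab <- tab[tab > 0]
  cat("resolved ranks: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})

.isWholeNumber <- function(x, tol = 1e-9) all(abs(x - round(x)) < tol)

#' Read a taxa-by-sample abundance table from TSV
#'
#' Expects a UTF-8 tab-delimited file whose first column holds lineage
#' strings and whose remaining columns (named by sample id in the header) are
#' numeric. The value mode is auto-detected unless \code{mode_hint} is given:
#' all-integer tables are counts; non-integer tables whose columns close to 1
#' are relative, to 100 percent.
#'
#' @param path Path to the TSV file.
#' @param mode_hint Optional mode overriding auto-detection.
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, mode_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", sep = "\t",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L)
    stop("abundance table needs a lineage column plus >=1 sample column: ",
         path, call. = FALSE)
  lineages <- df[[1]]
  sample_ids <- colnames(df)[-1]
  values <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                   bad[1], sample_ids[j], path), call. = FALSE)
    neg <- which(v < 0)
    if (length(neg))
      stop(sprintf("negative abundance %g at row %d, column '%s' in %s",
                   v[neg[1]], neg[1], sample_ids[j], path), call. = FALSE)
    values[, j] <- v
  }
  colnames(values) <- sample_ids
  mode <- if (!is.null(mode_hint)) {
    match.arg(mode_hint, .MODES)
  } else if (.isWholeNumber(values)) {
    "counts"
  } else {
    cs <- colSums(values)
    if (all(abs(cs - 1) <= .REL_TOL)) "relative"
    else if (all(abs(cs - 100) <= .PCT_TOL)) "percent"
    else stop("cannot auto-detect value mode (columns close to neither 1 ",
              "nor 100); pass mode_hint", call. = FALSE)
  }
  AbundanceTable(values, lineages, sample_ids, mode = mode)
}

#' Write an abundance table to TSV
#'
#' Writes the same dialect [readAbundanceTable()] reads: a \code{lineage}
#' column of canonical lineage strings followed by one numeric column per
#' sample. Values are written with 17 significant digits so a
#' read-write-read round trip is bit-exact.
#'
#' @param x An [AbundanceTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
  stopifnot(is(x, "AbundanceTable"))
  m <- abundances(x)
  fmt <- function(v) {
    out <- formatC(v, digits = 17, format = "g")
    out[v == round(v) & abs(v) < 2^53] <- format(v[v == round(v) & abs(v) < 2^53],
                                                 scientific = FALSE, trim = TRUE)
    out
  }
  cols <- c(list(lineage = rownames(m)),
            stats::setNames(lapply(seq_len(ncol(m)), function(j) fmt(m[, j])),
                            colnames(m)))
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert counts (or percent) to relative abundances
#'
#' Divides every sample column by its total. Already-relative input is
#' refused rather than passed through, so an accidental double normalisation
#' cannot slip by silently.
#'
#' @param x An [AbundanceTable-class] in counts or percent mode.
#' @return An [AbundanceTable-class] in relative mode; column sums are 1
#'   within 1e-9.
#' @export
toRelative <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  if (abundanceMode(x) == "relative")
    stop("table is already in relative mode; refusing to re-normalise",
         call. = FALSE)
  m <- abundances(x)
  totals <- colSums(m)
  zero <- which(totals <= 0)
  if (length(zero))
    stop("sample '", colnames(m)[zero[1]], "' has zero total abundance",
         call. = FALSE)
  out <- sweep(m, 2, totals, "/")
  AbundanceTable(out, rownames(m), colnames(m), mode = "relative")
}

## Proportion-scale view of a relative/percent table (columns ~ sum to 1).
.asProportions <- function(x) {
  mode <- abundanceMode(x)
  m <- abundances(x)
  switch(mode,
         relative = m,
         percent = m / 100,
         stop("a relative (or percent) table is required; call toRelative() ",
              "first", call. = FALSE))
}

#' Collapse a table to one taxonomic rank
#'
#' Pools taxa by their label at \code{rank} (for species, the binomial
#' [speciesLabel()]; for shallower ranks, the rank's name field). Taxa not
#' resolved at \code{rank} are pooled into an \code{"unassigned"} bin, which
#' is dropped unless \code{include_unassigned} is \code{TRUE}.
#'
#' @param x An [AbundanceTable-class].
#' @param rank One of the seven canonical ranks.
#' @param include_unassigned Keep the pooled unassigned bin as a row.
#' @return A base matrix (labels x samples) with attribute \code{"mode"}.
#' @export
collapseAtRank <- function(x, rank = "species", include_unassigned = FALSE) {
  stopifnot(is(x, "AbundanceTable"))
  rank <- match.arg(rank, .RANKS)
  rd <- SummarizedExperiment::rowData(x)
  labels <- if (rank == "species") rd$species_label
            else ifelse(nzchar(rd[[rank]]), rd[[rank]], NA_character_)
  labels[is.na(labels)] <- "unassigned"
  m <- rowsum(abundances(x), group = labels)
  if (!include_unassigned) m <- m[rownames(m) != "unassigned", , drop = FALSE]
  attr(m, "mode") <- abundanceMode(x)
  m
}

#' Read a sample metadata table from TSV
#'
#' Requires columns \code{sample_id}, \code{run}, \code{plate} and
#' \code{control_role} (one of none, mock_extraction, mock_sequencing,
#' negative); optional columns \code{replicate_pair_id},
#' \code{replicate_scope} (within_run / between_run), \code{sample_type}
#' (stool / swab) and \code{dna_concentration} (positive). A non-missing
#' \code{replicate_pair_id} must be shared by exactly two samples, and
#' negative controls may not be members of a pair.
#'
#' @param path Path to the TSV file.
#' @return A validated \code{data.frame}.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  validateSampleMetadata(df)
}

#' @describeIn readSampleMetadata Validate an in-memory metadata data.frame.
#' @param meta A \code{data.frame} of sample metadata.
#' @export
validateSampleMetadata <- function(meta) {
  required <- c("sample_id", "run", "plate", "control_role")
  missing <- setdiff(required, colnames(meta))
  if (length(missing))
    stop("metadata lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  roles <- c("none", "mock_extraction", "mock_sequencing", "negative")
  bad <- setdiff(unique(meta$control_role), roles)
  if (length(bad))
    stop("unknown control_role value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("replicate_pair_id" %in% colnames(meta)) {
    pid <- meta$replicate_pair_id
    pid[!is.na(pid) & pid == ""] <- NA
    meta$replicate_pair_id <- pid
    counts <- table(pid[!is.na(pid)])
    if (any(counts != 2L))
      stop("replicate_pair_id must be shared by exactly two samples; ",
           "offending pair(s): ",
           paste(names(counts)[counts != 2L], collapse = ", "), call. = FALSE)
    paired_neg <- !is.na(pid) & meta$control_role == "negative"
    if (any(paired_neg))
      stop("negative controls cannot be members of a replicate pair",
           call. = FALSE)
  }
  if ("dna_concentration" %in% colnames(meta)) {
    dc <- meta$dna_concentration
    if (any(!is.na(dc) & dc <= 0))
      stop("dna_concentration must be positive where present", call. = FALSE)
  }
  meta
}
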