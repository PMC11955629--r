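#' Mock community reference composition
#'
#' The expected species of a defined mock community together with their
#' theoretical (supplier-stated) percentage abundances, plus an alias map for
#' classifier-era synonymy (e.g. \emph{Lactobacillus fermentum} for
#' \emph{Limosilactobacillus fermentum}).
#'
#' @slot entries \code{data.frame} with columns \code{species_label} and
#'   \code{theoretical_percent}.
#' @slot aliases Named character vector mapping alternative labels to
#'   canonical \code{species_label}s.
#'
#' @seealso [zymoReference()], [readMockReference()]
#' @export
setClass("MockReference",
         representation(entries = "data.frame", aliases = "character"))

setValidity("MockReference", function(object) {
  e <- object@entries
  if (!all(c("species_label", "theoretical_percent") %in% colnames(e)))
    return("entries needs columns species_label, theoretical_percent")
  if (anyDuplicated(e$species_label))
    return("species labels must be unique")
  if (any(e$theoretical_percent <= 0))
    return("theoretical percents must be positive")
  if (abs(sum(e$theoretical_percent) - 100) > 0.5)
    return("theoretical percents must sum to 100 (within 0.5)")
  if (length(object@aliases)) {
    if (is.null(names(object@aliases)) || any(!nzchar(names(object@aliases))))
      return("aliases must be a named character vector (alias -> label)")
    if (!all(object@aliases %in% e$species_label))
      return("every alias must resolve to a reference species label")
    if (any(names(object@aliases) %in% e$species_label))
      return("an alias may not shadow a reference species label")
  }
  TRUE
})

#' Construct a MockReference
#'
#' @param species_label Character vector of expected species labels.
#' @param theoretical_percent Positive percentages, summing to 100 within 0.5.
#' @param aliases Optional named character vector (alias -> species_label).
#' @return A [MockReference-class].
#' @export
MockReference <- function(species_label, theoretical_percent,
                          aliases = character(0)) {
  new("MockReference",
      entries = data.frame(species_label = as.character(species_label),
                           theoretical_percent = as.numeric(theoretical_percent),
                           stringsAsFactors = FALSE),
      aliases = aliases)
}

#' @describeIn MockReference Expected species labels.
#' @param ref A [MockReference-class].
#' @export
referenceSpecies <- function(ref) {
  stopifnot(is(ref, "MockReference"))
  ref@entries$species_label
}

#' @describeIn MockReference Theoretical percentages, named by species label.
#' @export
theoreticalPercent <- function(ref) {
  stopifnot(is(ref, "MockReference"))
  stats::setNames(ref@entries$theoretical_percent, ref@entries$species_label)
}

setMethod("show", "MockReference", function(object) {
  cat("MockReference with", nrow(object@entries), "expected species\n")
  print(object@entries, row.names = FALSE)
  if (length(object@aliases))
    cat("aliases:", paste(names(object@aliases), object@aliases,
                          sep = " -> ", collapse = "; "), "\n")
})

#' Resolve observed species labels against a mock reference
#'
#' Maps labels to canonical reference species labels via the alias table;
#' labels matching neither a reference species nor an alias give
#' \code{NA_character_}.
#'
#' @param ref A [MockReference-class].
#' @param labels Character vector of observed species labels.
#' @return Character vector of resolved labels (NA where unresolved).
#' @export
resolveAlias <- function(ref, labels) {
  stopifnot(is(ref, "MockReference"))
  out <- ifelse(labels %in% ref@entries$species_label, labels, NA_character_)
  hit <- match(labels, names(ref@aliases))
  out[!is.na(hit)] <- unname(ref@aliases[hit[!is.na(hit)]])
  out
}

#' Read a mock reference from TSV or JSON
#'
#' TSV form: columns \code{species} (or \code{species_label}) and
#' \code{theoretical_percent}. JSON form: an object with \code{entries} (array
#' of \code{{species, theoretical_percent}}) and optional \code{aliases}
#' (object alias -> species). A separate two-column alias TSV
#' (\code{alias}, \code{species}) may accompany the TSV form.
#'
#' @param path Reference file path (.tsv or .json).
#' @param aliases_path Optional alias TSV path (TSV form only).
#' @return A [MockReference-class].
#' @export
readMockReference <- function(path, aliases_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    aliases <- character(0)
    if (!is.null(obj$aliases))
      aliases <- unlist(obj$aliases)
    entries <- obj$entries
    lab <- if ("species" %in% names(entries)) entries$species
           else entries$species_label
    return(MockReference(lab, entries$theoretical_percent, aliases))
  }
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  lab_col <- intersect(c("species", "species_label"), colnames(df))[1]
  if (is.na(lab_col) || !"theoretical_percent" %in% colnames(df))
    stop("reference TSV needs columns species (or species_label) and ",
         "theoretical_percent", call. = FALSE)
  aliases <- character(0)
  if (!is.null(aliases_path)) {
    ad <- utils::read.delim(aliases_path, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    aliases <- stats::setNames(ad$species, ad$alias)
  }
  MockReference(df[[lab_col]], df$theoretical_percent, aliases)
}

#' The 8-species ZymoBIOMICS microbial community standard
#'
#' Theoretical species composition of the ZymoBIOMICS Microbial Community
#' Standard (8 bacterial species; the supplier also includes two yeasts,
#' which 16S profiling does not observe, so bacterial percentages are the
#' supplier's 16S-facing values summing to 100). Ships with aliases mapping
#' \emph{Escherichia coli} to the classifier's \emph{Escherichia/Shigella
#' coli} label and \emph{Lactobacillus fermentum} to
#' \emph{Limosilactobacillus fermentum}.
#'
#' @return A [MockReference-class].
#' @examples
#' zymoReference()
#' @export
zymoReference <- function() {
  readMockReference(
    system.file("extdata", "zymo8.tsv", package = "mockbench",
                mustWork = TRUE),
    system.file("extdata", "zymo8_aliases.tsv", package = "mockbench",
                mustWork = TRUE))
}
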