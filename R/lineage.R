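#' @import methods
NULL

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIXES <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s")

#' Taxonomic lineage
#'
#' A seven-rank (kingdom to species) taxonomic lineage. Ranks may be empty;
#' the deepest non-empty rank is the resolved rank. A record whose species
#' field is populated while the genus field is empty is flagged as
#' rank-skipped rather than rejected, since classifiers occasionally emit
#' such lineages.
#'
#' @slot ranks Named character vector of length 7 (kingdom..species); empty
#'   string for unpopulated ranks.
#' @slot rank_skipped Logical; \code{TRUE} when a deeper rank is populated
#'   above an empty shallower one (e.g. species without genus).
#'
#' @seealso [parseLineage()], [formatLineage()]
#' @export
setClass("Lineage",
         representation(ranks = "character", rank_skipped = "logical"))

setValidity("Lineage", function(object) {
  if (length(object@ranks) != 7L || !identical(names(object@ranks), .RANKS))
    return("ranks must be a named character vector with the 7 canonical ranks")
  if (any(is.na(object@ranks)))
    return("ranks must not contain NA (use empty string)")
  if (nzchar(object@ranks[["species"]]) && !nzchar(object@ranks[["genus"]]) &&
      !isTRUE(object@rank_skipped))
    return("species without genus requires the rank_skipped flag")
  TRUE
})

.newLineage <- function(ranks) {
  skipped <- FALSE
  filled <- nzchar(ranks)
  if (any(filled)) {
    deepest <- max(which(filled))
    if (deepest > 1L && any(!filled[seq_len(deepest - 1L)])) skipped <- TRUE
  }
  new("Lineage", ranks = ranks, rank_skipped = skipped)
}

#' Parse a lineage string
#'
#' Parses a Greengenes-style prefixed lineage string such as
#' \code{"k__Bacteria;p__Firmicutes;...;g__Bacillus;s__subtilis"}. Missing
#' ranks may be given as bare prefixes (\code{"s__"}) or omitted entirely;
#' both normalise to the empty rank. Whitespace around tokens is trimmed and
#' prefix case is normalised. An empty string yields a fully unassigned
#' lineage.
#'
#' @param raw Single character string.
#' @return A [Lineage-class] object.
#' @examples
#' lin <- parseLineage("g__Bacillus;s__")
#' resolvedRank(lin)
#' @export
parseLineage <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  ranks <- structure(character(7L), names = .RANKS)
  raw <- trimws(raw)
  if (!nzchar(raw)) return(.newLineage(ranks))
  tokens <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  seen <- character(0)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([A-Za-z])__(.*)$", tok))[[1]]
    if (length(m) == 0L)
      stop("unparseable lineage token: '", tok, "'", call. = FALSE)
    prefix <- tolower(m[2])
    rank <- names(.RANK_PREFIXES)[match(prefix, .RANK_PREFIXES)]
    if (is.na(rank))
      stop("unknown rank prefix in lineage token: '", tok, "'", call. = FALSE)
    if (rank %in% seen)
      stop("duplicate rank '", rank, "' in lineage: '", raw, "'", call. = FALSE)
    seen <- c(seen, rank)
    ranks[[rank]] <- trimws(m[3])
  }
  .newLineage(ranks)
}

#' Format a lineage as its canonical string
#'
#' The canonical form always carries all seven prefixes
#' (\code{"k__...;p__...;c__...;o__...;f__...;g__...;s__..."}) with empty
#' ranks as bare prefixes, so that \code{parseLineage(formatLineage(x))}
#' recovers \code{x} exactly.
#'
#' @param lineage A [Lineage-class] object.
#' @return Single character string.
#' @export
formatLineage <- function(lineage) {
  stopifnot(is(lineage, "Lineage"))
  paste(paste0(.RANK_PREFIXES, "__", lineage@ranks), collapse = ";")
}

#' @describeIn parseLineage Deepest populated rank of a lineage
#'   (\code{NA_character_} when fully unassigned).
#' @param lineage A [Lineage-class] object.
#' @export
resolvedRank <- function(lineage) {
  stopifnot(is(lineage, "Lineage"))
  filled <- nzchar(lineage@ranks)
  if (!any(filled)) return(NA_character_)
  .RANKS[max(which(filled))]
}

#' Species label of a lineage
#'
#' Binomial-style label for a species-rank lineage: when the species field is
#' a bare epithet the genus is prepended (\code{"g__Bacillus;s__subtilis"}
#' gives \code{"Bacillus subtilis"}); a species field already containing a
#' space is used verbatim.
#'
#' @param lineage A [Lineage-class] object.
#' @return Single character string, or \code{NA_character_} when the lineage
#'   has no species rank.
#' @export
speciesLabel <- function(lineage) {
  stopifnot(is(lineage, "Lineage"))
  sp <- lineage@ranks[["species"]]
  if (!nzchar(sp)) return(NA_character_)
  if (grepl(" ", sp, fixed = TRUE)) return(sp)
  g <- lineage@ranks[["genus"]]
  if (nzchar(g)) paste(g, sp) else sp
}

setMethod("show", "Lineage", function(object) {
  rr <- resolvedRank(object)
  cat("Lineage: ", formatLineage(object), "\n",
      "resolved rank: ", ifelse(is.na(rr), "<unassigned>", rr),
      if (object@rank_skipped) " (rank-skipped)" else "", "\n", sep = "")
})

## Vectorised lineage parsing into per-rank columns used for rowData.
.lineageFrame <- function(strings) {
  lins <- lapply(unname(strings), parseLineage)
  mat <- do.call(rbind, lapply(lins, function(l) l@ranks))
  df <- S4Vectors::DataFrame(mat)
  colnames(df) <- .RANKS
  df$resolved_rank <- vapply(lins, resolvedRank, character(1))
  df$species_label <- vapply(lins, speciesLabel, character(1))
  df$canonical <- vapply(lins, formatLineage, character(1))
  df
}
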