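#' Parameterisation of the synthetic-data generator
#'
#' Captures every knob of the seeded generator: compositional noise around
#' the mock reference, per-species dropout (with optional genus rescue),
#' spurious low-abundance taxa, library sizes, the Gaussian variance
#' -components model behind replicate pairs, and the contaminant plan for
#' synthetic plates. Identical spec + seed gives bit-identical output.
#'
#' @slot seed Integer RNG seed.
#' @slot reference A [MockReference-class] (defaults to [zymoReference()]).
#' @slot noise_concentration Positive Dirichlet-style concentration around
#'   the reference composition; implemented as a log-normal perturbation with
#'   sd \code{1/sqrt(noise_concentration)} followed by closure, so the
#'   parameter maps monotonically to compositional spread (\code{Inf} =
#'   noiseless).
#' @slot dropout_probs Named numeric vector of per-species probabilities of
#'   species-level non-detection (species absent from the vector have
#'   probability 0).
#' @slot genus_rescue Named logical vector: when a named species drops out,
#'   is its mass retained at genus rank (\code{TRUE}) or lost and
#'   reallocated proportionally (\code{FALSE})?
#' @slot spurious_rate Expected number of false-positive taxa per control
#'   (Poisson).
#' @slot spurious_abundance_range Percent abundance range (lo, hi) of each
#'   spurious taxon.
#' @slot library_size_range Reads per library (lo, hi) for real samples and
#'   mock controls.
#' @slot pair_sigma_b,pair_sigma_w Between-subject and within-pair standard
#'   deviations of the log-abundance pair model.
#' @slot pair_n,pair_taxa Number of replicate pairs and taxa in the pair
#'   model.
#' @slot contaminant_plan Species labels planted as contaminants in negative
#'   controls of synthetic plates.
#' @slot contaminant_fold Enrichment of contaminants in negatives relative to
#'   the real samples that carry them.
#' @slot plate_samples,plate_negatives Real samples and negative controls per
#'   synthetic plate.
#' @export
setClass("SyntheticSpec",
         representation(seed = "integer",
                        reference = "MockReference",
                        noise_concentration = "numeric",
                        dropout_probs = "numeric",
                        genus_rescue = "logical",
                        spurious_rate = "numeric",
                        spurious_abundance_range = "numeric",
                        library_size_range = "numeric",
                        pair_sigma_b = "numeric",
                        pair_sigma_w = "numeric",
                        pair_n = "integer",
                        pair_taxa = "integer",
                        contaminant_plan = "character",
                        contaminant_fold = "numeric",
                        plate_samples = "integer",
                        plate_negatives = "integer"))

setValidity("SyntheticSpec", function(object) {
  rng <- function(r) length(r) == 2L && !anyNA(r) && r[1] <= r[2]
  if (object@noise_concentration <= 0)
    return("noise_concentration must be positive")
  if (any(object@dropout_probs < 0 | object@dropout_probs > 1))
    return("dropout probabilities must lie in [0, 1]")
  if (!rng(object@spurious_abundance_range) ||
      object@spurious_abundance_range[1] < 0)
    return("spurious_abundance_range must be 0 <= lo <= hi")
  if (!rng(object@library_size_range) || object@library_size_range[1] < 1)
    return("library_size_range must be 1 <= lo <= hi")
  if (object@spurious_rate < 0) return("spurious_rate must be >= 0")
  if (object@pair_sigma_b < 0 || object@pair_sigma_w < 0)
    return("pair model sigmas must be >= 0")
  if (object@pair_n < 1L || object@pair_taxa < 2L)
    return("pair model needs >= 1 pair and >= 2 taxa")
  if (object@contaminant_fold <= 1)
    return("contaminant_fold must exceed 1")
  if (object@plate_samples < 1L || object@plate_negatives < 1L)
    return("plates need >= 1 real sample and >= 1 negative control")
  TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults emulate a realistic species-level benchmarking campaign: the
#' 8-species
#' ZymoBIOMICS reference; compositional noise concentration 100 (log-sd 0.1,
#' about the spread the printed mock-control columns show around the
#' theoretical values); dropout 0.15 for the two hard-to-lyse gram-positive
#' species (\emph{Bacillus subtilis}, rescued at genus rank as observed, and
#' \emph{Listeria monocytogenes}, lost outright); around 3 spurious taxa per
#' control at 0.01-0.5% each; libraries of 50k-200k reads; 17 replicate
#' pairs of 50 taxa with between/within log-sd 1 / 0.25; and 3 planted
#' reagent contaminants at 10x negative-control enrichment on plates of 12
#' real samples and 4 negatives.
#'
#' @param seed Integer RNG seed.
#' @param reference A [MockReference-class].
#' @param noise_concentration,spurious_rate,spurious_abundance_range
#'   Mock-control error-mode parameters (see class slots).
#' @param dropout_probs,genus_rescue Named per-species dropout parameters.
#' @param library_size_range Library-size draw range.
#' @param pair_sigma_b,pair_sigma_w,pair_n,pair_taxa Pair-model parameters.
#' @param contaminant_plan,contaminant_fold Plate contaminant parameters.
#' @param plate_samples,plate_negatives Plate layout.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(seed = 1L,
                          reference = zymoReference(),
                          noise_concentration = 100,
                          dropout_probs = c("Bacillus subtilis" = 0.15,
                                            "Listeria monocytogenes" = 0.15),
                          genus_rescue = c("Bacillus subtilis" = TRUE,
                                           "Listeria monocytogenes" = FALSE),
                          spurious_rate = 3,
                          spurious_abundance_range = c(0.01, 0.5),
                          library_size_range = c(50000, 200000),
                          pair_sigma_b = 1,
                          pair_sigma_w = 0.25,
                          pair_n = 17L,
                          pair_taxa = 50L,
                          contaminant_plan = c("Cutibacterium acnes",
                                               "Ralstonia pickettii",
                                               "Bradyrhizobium japonicum"),
                          contaminant_fold = 10,
                          plate_samples = 12L,
                          plate_negatives = 4L) {
  new("SyntheticSpec", seed = as.integer(seed), reference = reference,
      noise_concentration = noise_concentration,
      dropout_probs = dropout_probs, genus_rescue = genus_rescue,
      spurious_rate = spurious_rate,
      spurious_abundance_range = as.numeric(spurious_abundance_range),
      library_size_range = as.numeric(library_size_range),
      pair_sigma_b = pair_sigma_b, pair_sigma_w = pair_sigma_w,
      pair_n = as.integer(pair_n), pair_taxa = as.integer(pair_taxa),
      contaminant_plan = contaminant_plan,
      contaminant_fold = contaminant_fold,
      plate_samples = as.integer(plate_samples),
      plate_negatives = as.integer(plate_negatives))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec (seed ", object@seed, "): ",
      length(referenceSpecies(object@reference)), "-species reference, ",
      "noise concentration ", object@noise_concentration,
      ", spurious rate ", object@spurious_rate,
      ", ", object@pair_n, " pairs, ",
      length(object@contaminant_plan), " planted contaminants\n", sep = "")
})

## Deterministic child seed from the spec seed and a stream tag.
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.decoyCatalogue <- function() {
  readLines(system.file("extdata", "decoy_taxa.txt", package = "mockbench",
                        mustWork = TRUE))
}

.communityCatalogue <- function() {
  readLines(system.file("extdata", "community_taxa.txt",
                        package = "mockbench", mustWork = TRUE))
}

## "Genus epithet" label -> short lineage string (last token = epithet).
.speciesLineage <- function(label) {
  epithet <- sub("^.* ", "", label)
  genus <- sub(" [^ ]*$", "", label)
  sprintf("g__%s;s__%s", genus, epithet)
}

.genusLineage <- function(label) {
  sprintf("g__%s;s__", sub(" [^ ]*$", "", label))
}

#' Simulate one mock-control profile with controlled error modes
#'
#' Draws a composition around the reference's theoretical percentages
#' (log-normal noise + closure), applies per-species dropout — moving the
#' dropped species' mass to its genus-rank taxon when genus rescue is
#' flagged, otherwise reallocating it proportionally — and adds
#' Poisson-many spurious taxa from a fixed decoy catalogue at low
#' abundances. The returned truth record lists the planted TP/FP/FN so the
#' evaluator can be scored against it.
#'
#' @param spec A [SyntheticSpec-class].
#' @param control_id Sample id for the simulated control (also seeds its RNG
#'   stream, so each control is reproducible in isolation).
#' @return A list with \code{table} (single-column relative-mode
#'   [AbundanceTable-class]) and \code{truth} (list with \code{detected},
#'   \code{dropped}, \code{genus_rescues}, \code{spurious}).
#' @export
simulateMockControl <- function(spec, control_id = "mock_1") {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(.deriveSeed(spec@seed, control_id))
  theo <- theoreticalPercent(spec@reference)
  species <- names(theo)
  sigma <- if (is.finite(spec@noise_concentration))
    1 / sqrt(spec@noise_concentration) else 0
  w <- theo * exp(stats::rnorm(length(theo), 0, sigma))

  p_drop <- stats::setNames(rep(0, length(species)), species)
  p_drop[intersect(names(spec@dropout_probs), species)] <-
    spec@dropout_probs[intersect(names(spec@dropout_probs), species)]
  dropped <- species[stats::runif(length(species)) < p_drop]
  rescue <- stats::setNames(rep(FALSE, length(species)), species)
  rescue[intersect(names(spec@genus_rescue), species)] <-
    spec@genus_rescue[intersect(names(spec@genus_rescue), species)]
  rescued <- dropped[rescue[dropped]]

  k <- stats::rpois(1, spec@spurious_rate)
  decoys <- setdiff(.decoyCatalogue(), species)
  k <- min(k, length(decoys))
  spurious <- if (k > 0) sample(decoys, k) else character(0)
  sp_pct <- if (k > 0)
    stats::runif(k, spec@spurious_abundance_range[1],
                 spec@spurious_abundance_range[2]) else numeric(0)
  total_sp <- sum(sp_pct)
  if (total_sp > 50) {           # defensive cap; defaults never approach it
    sp_pct <- sp_pct * 50 / total_sp
    total_sp <- 50
  }

  kept <- setdiff(species, dropped)
  weights <- c(stats::setNames(w[kept], vapply(kept, .speciesLineage, "")),
               stats::setNames(w[rescued], vapply(rescued, .genusLineage, "")))
  if (length(weights) == 0L || sum(weights) <= 0)
    stop("simulated control has no expected-species mass; ",
         "lower the dropout probabilities", call. = FALSE)
  pct <- c(weights / sum(weights) * (100 - total_sp),
           stats::setNames(sp_pct, vapply(spurious, .speciesLineage, "")))
  values <- matrix(pct / 100, ncol = 1,
                   dimnames = list(names(pct), control_id))
  list(table = AbundanceTable(values, names(pct), control_id,
                              mode = "relative"),
       truth = list(control_id = control_id,
                    detected = kept,
                    dropped = dropped,
                    genus_rescues = rescued,
                    spurious = spurious))
}

#' @describeIn simulateMockControl Simulate several controls and merge them
#'   into one table over the union of taxa (absent taxa filled with 0).
#' @param control_ids Character vector of control ids.
#' @return For \code{simulateMockControls}: list with \code{table}
#'   (multi-column [AbundanceTable-class]) and \code{truths} (list of truth
#'   records).
#' @export
simulateMockControls <- function(spec, control_ids) {
  sims <- lapply(control_ids, function(id) simulateMockControl(spec, id))
  taxa <- unique(unlist(lapply(sims, function(s) rownames(s$table))))
  values <- matrix(0, length(taxa), length(control_ids),
                   dimnames = list(taxa, control_ids))
  for (s in sims) values[rownames(s$table), sampleIDs(s$table)] <-
      abundances(s$table)
  list(table = AbundanceTable(values, taxa, control_ids, mode = "relative"),
       truths = lapply(sims, `[[`, "truth"))
}

#' Simulate technical-replicate pairs with known reproducibility
#'
#' Gaussian variance-components model on log abundances: a shared base
#' profile, per-subject effects with sd \code{pair_sigma_b}, and per-replicate
#' noise with sd \code{pair_sigma_w}, closed to compositions by softmax with
#' a 0.5% detection limit (rare taxa are genuinely absent, so
#' presence/absence metrics stay informative). The
#' ground truth \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)} is returned;
#' it is exactly what [dicc()] estimates when run on Euclidean distances of
#' the latent log profiles (also returned), and it bounds what
#' compositional distances can recover.
#'
#' @param spec A [SyntheticSpec-class].
#' @return A list with \code{table} (relative-mode [AbundanceTable-class],
#'   two columns per pair), \code{design} ([PairedDesign-class]),
#'   \code{truth_dicc}, and \code{latent} (taxa x samples matrix of the
#'   latent log profiles).
#' @export
simulatePairs <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(.deriveSeed(spec@seed, "pairs"))
  tt <- spec@pair_taxa
  n <- spec@pair_n
  mu <- stats::rnorm(tt, 0, 1)
  subj <- matrix(stats::rnorm(tt * n, 0, spec@pair_sigma_b), tt, n)
  noise <- matrix(stats::rnorm(tt * 2 * n, 0, spec@pair_sigma_w), tt, 2 * n)
  rep_idx <- rep(seq_len(n), each = 2)
  latent <- mu + subj[, rep_idx] + noise
  ids <- sprintf("P%02d_%s", rep_idx, rep(c("a", "b"), n))
  colnames(latent) <- ids
  lineages <- sprintf("g__SimGenus%03d;s__sp%03d", seq_len(tt), seq_len(tt))
  rownames(latent) <- lineages
  comp <- apply(latent, 2, function(v) {
    e <- exp(v - max(v))
    p <- e / sum(e)
    p[p < 0.005] <- 0       # detection limit: rare taxa go unobserved
    p / sum(p)
  })
  design <- pairedDesign(ids[seq(1, 2 * n, by = 2)],
                         ids[seq(2, 2 * n, by = 2)],
                         pair_id = sprintf("P%02d", seq_len(n)),
                         scope = "within_run")
  sb2 <- spec@pair_sigma_b^2
  sw2 <- spec@pair_sigma_w^2
  list(table = AbundanceTable(comp, lineages, ids, mode = "relative"),
       design = design,
       truth_dicc = if (sb2 + sw2 == 0) NA_real_ else sb2 / (sb2 + sw2),
       latent = latent)
}

#' Simulate a sequencing plate with negative controls and planted contaminants
#'
#' Emits a counts-mode table and matching metadata for one plate: real
#' samples (a 20-species community with per-sample log-normal variation),
#' negative controls dominated by the planted contaminants (plus low-level
#' cross-talk from community taxa), and one mock extraction plus one mock
#' sequencing control. Each planted contaminant is present in every negative
#' and in a fixed 25% of the real samples at \code{1/contaminant_fold} of
#' its negative-control share, so the prevalence signal is structural rather
#' than a property of one lucky seed. Community taxa are present in every
#' real sample.
#'
#' @param spec A [SyntheticSpec-class].
#' @param run,plate Identifiers stamped into sample ids and metadata.
#' @return A list with \code{table} (counts [AbundanceTable-class]),
#'   \code{meta} (metadata \code{data.frame}) and \code{truth} (list with
#'   \code{contaminants} = planted lineage strings, \code{carrier_samples}).
#' @export
simulatePlate <- function(spec, run = "R1", plate = "P1") {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(.deriveSeed(spec@seed, paste0("plate:", run, plate)))
  community <- .communityCatalogue()
  n_real <- spec@plate_samples
  n_neg <- spec@plate_negatives
  contam <- spec@contaminant_plan
  zymo <- referenceSpecies(spec@reference)

  comm_lin <- vapply(community, .speciesLineage, "")
  cont_lin <- vapply(contam, .speciesLineage, "")
  zymo_lin <- vapply(zymo, .speciesLineage, "")
  taxa <- c(comm_lin, cont_lin, zymo_lin)

  real_ids <- sprintf("%s%s_S%02d", run, plate, seq_len(n_real))
  neg_ids <- sprintf("%s%s_NEG%d", run, plate, seq_len(n_neg))
  mock_ids <- c(sprintf("%s%sZymoex", run, plate),
                sprintf("%s%sZymoseq", run, plate))
  all_ids <- c(real_ids, neg_ids, mock_ids)
  values <- matrix(0, length(taxa), length(all_ids),
                   dimnames = list(taxa, all_ids))

  base_prop <- 0.85^seq_along(community)
  base_prop <- base_prop / sum(base_prop)       # min ~0.006 of community mass
  neg_share <- if (length(contam)) 0.6 / length(contam) else 0
  real_share <- neg_share / spec@contaminant_fold
  carriers <- lapply(contam, function(cc)
    sample(real_ids, ceiling(0.25 * n_real)))
  names(carriers) <- contam

  for (s in real_ids) {
    comm <- base_prop * exp(stats::rnorm(length(base_prop), 0, 0.5))
    comm <- comm / sum(comm)
    c_prop <- vapply(contam, function(cc) {
      if (s %in% carriers[[cc]]) real_share else 0
    }, numeric(1))
    props <- c(comm * (1 - sum(c_prop)), c_prop)
    lib <- round(stats::runif(1, spec@library_size_range[1],
                              spec@library_size_range[2]))
    values[c(comm_lin, cont_lin), s] <-
      stats::rmultinom(1, lib, prob = props)[, 1]
  }
  for (s in neg_ids) {
    cross_idx <- sample(seq_along(community), 5)
    cross <- numeric(length(community))
    cross[cross_idx] <- stats::runif(5, 0.5, 1.5)
    if (length(contam)) {
      props <- c(cross / sum(cross) * 0.4, rep(neg_share, length(contam)))
    } else {
      props <- cross / sum(cross)
    }
    lib <- round(stats::runif(1, 500, 3000))
    values[c(comm_lin, cont_lin), s] <- stats::rmultinom(1, lib, props)[, 1]
  }
  theo <- theoreticalPercent(spec@reference)
  for (s in mock_ids) {
    w <- theo * exp(stats::rnorm(length(theo), 0, 0.05))
    lib <- round(stats::runif(1, spec@library_size_range[1],
                              spec@library_size_range[2]))
    values[zymo_lin, s] <- stats::rmultinom(1, lib, w / sum(w))[, 1]
  }

  meta <- data.frame(
    sample_id = all_ids,
    run = run,
    plate = plate,
    control_role = c(rep("none", n_real), rep("negative", n_neg),
                     "mock_extraction", "mock_sequencing"),
    sample_type = c(rep(c("stool", "swab"), length.out = n_real),
                    rep(NA_character_, n_neg + 2L)),
    stringsAsFactors = FALSE)

  tab <- AbundanceTable(values, taxa, all_ids, mode = "counts")
  list(table = tab,
       meta = meta,
       truth = list(contaminants = rownames(tab)[match(cont_lin, taxa)],
                    carrier_samples = carriers))
}
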