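#' Simulation configuration for synthetic enrichment experiments
#'
#' Holds every tunable of the synthetic-data generator. Defaults reproduce the
#' study design the package targets: three faecal-filtrate pools ("A", "B",
#' "C") enriched on 26, 53 and 37 bacterial strains respectively, one
#' unenriched baseline per pool, one blank amplification control, a shared
#' per-pool background virome, and a triple-round enrichment amplifying each
#' planted phage 10-fold per round in its cognate-host sample.
#'
#' @slot nPools number of faecal-filtrate pools.
#' @slot strainsPerPool integer vector, enriched strain cultures per pool.
#' @slot nBackgroundPhages background phage genomes shared within each pool.
#' @slot nHostFragments non-viral bacterial-fragment genomes per pool; these
#'   model host-DNA contamination and carry near-zero pVOG densities.
#' @slot nPlantedPairs number of truly enriched phage-host pairs planted
#'   across the experiment.
#' @slot genomeLengthRange min/max phage genome length (bp).
#' @slot hostLengthRange min/max host-fragment length (bp).
#' @slot circularFraction fraction of phage genomes that are circular; the
#'   linearized sequence then carries an exact terminal direct repeat.
#' @slot terminalRepeatLen terminal direct repeat length for circular genomes.
#' @slot enrichmentFactorPerRound fold-amplification per enrichment round.
#' @slot nRounds number of enrichment rounds (study design: 3).
#' @slot backgroundMu,backgroundSigma log-normal parameters of the per-pool
#'   background abundance draw.
#' @slot sampleNoiseSigma log-scale SD of the multiplicative per-sample noise
#'   applied to background abundances.
#' @slot hostFractionShape Beta shape parameters of the per-sample host-DNA
#'   fraction for ordinary (non-cognate) samples.
#' @slot cognateHostFractionShape Beta shape parameters for cognate samples,
#'   where phage lysis depletes host DNA.
#' @slot blankHostFraction fixed host-DNA fraction of the blank control.
#' @slot blankDilution multiplier applied to the blank's phage background
#'   (the blank receives 100-fold diluted background by default).
#' @slot detectionFloor relative abundance below which a genome yields no
#'   contig in a sample (emulates failed assembly of rare phages).
#' @slot fragmentationRate Poisson mean of extra assembly breakpoints per
#'   genome per sample.
#' @slot readsPerSample,readLength,readErrorRate read simulation parameters.
#' @slot mdaSsdnaBiasSigma log-scale SD of the stochastic MDA multiplier
#'   applied to circular genomes per sample; 0 disables the bias.
#' @slot pvogMeanViral,pvogMeanHost Poisson mean pVOG hits per 10 kb for true
#'   phage contigs and for host-fragment decoys.
#' @slot externalProbViral,externalProbHost probability of an external
#'   (VirSorter-style) viral flag by contig origin.
#' @slot dbHitProbViral,dbHitProbHost probability of a viral-database hit.
#' @slot seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#'
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig", representation(
  nPools = "integer",
  strainsPerPool = "integer",
  nBackgroundPhages = "integer",
  nHostFragments = "integer",
  nPlantedPairs = "integer",
  genomeLengthRange = "numeric",
  hostLengthRange = "numeric",
  circularFraction = "numeric",
  terminalRepeatLen = "integer",
  enrichmentFactorPerRound = "numeric",
  nRounds = "integer",
  backgroundMu = "numeric",
  backgroundSigma = "numeric",
  sampleNoiseSigma = "numeric",
  hostFractionShape = "numeric",
  cognateHostFractionShape = "numeric",
  blankHostFraction = "numeric",
  blankDilution = "numeric",
  detectionFloor = "numeric",
  fragmentationRate = "numeric",
  readsPerSample = "integer",
  readLength = "integer",
  readErrorRate = "numeric",
  mdaSsdnaBiasSigma = "numeric",
  pvogMeanViral = "numeric",
  pvogMeanHost = "numeric",
  externalProbViral = "numeric",
  externalProbHost = "numeric",
  dbHitProbViral = "numeric",
  dbHitProbHost = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  cnt <- c(nPools = object@nPools, nBackgroundPhages = object@nBackgroundPhages,
           nHostFragments = object@nHostFragments,
           nPlantedPairs = object@nPlantedPairs, nRounds = object@nRounds,
           readsPerSample = object@readsPerSample,
           readLength = object@readLength,
           terminalRepeatLen = object@terminalRepeatLen)
  if (any(cnt < 0)) msg <- c(msg, "all counts must be >= 0")
  if (length(object@strainsPerPool) != object@nPools)
    msg <- c(msg, "strainsPerPool must have one entry per pool")
  if (any(object@strainsPerPool < 0)) msg <- c(msg, "strainsPerPool must be >= 0")
  prp <- c(object@circularFraction, object@readErrorRate,
           object@blankHostFraction, object@detectionFloor)
  if (any(prp < 0 | prp > 1)) msg <- c(msg, "proportions must lie in [0, 1]")
  if (object@enrichmentFactorPerRound < 1)
    msg <- c(msg, "enrichmentFactorPerRound must be >= 1")
  for (rng in list(object@genomeLengthRange, object@hostLengthRange)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1)
      msg <- c(msg, "degenerate length range (need 1 <= min <= max)")
  }
  if (object@nPlantedPairs > sum(object@strainsPerPool))
    msg <- c(msg, "more planted pairs than enriched strain cultures")
  if (any(c(object@backgroundSigma, object@sampleNoiseSigma,
            object@mdaSsdnaBiasSigma, object@fragmentationRate) < 0))
    msg <- c(msg, "scale parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults state the emulated study design: 3 pools with 26/53/37 enriched
#' strains, 200 background phages and 20 host fragments per pool, 10 planted
#' phage-host pairs, log-normal(0, 0.3) background with log-normal(0, 0.3)
#' per-sample noise, enrichment factor 10 per round over 3 rounds, 50,000
#' reads per sample, and MDA circular-genome bias disabled.
#'
#' @param nPools,strainsPerPool,nBackgroundPhages,nHostFragments,nPlantedPairs
#'   experiment design; see [SimConfig-class].
#' @param genomeLengthRange,hostLengthRange,circularFraction,terminalRepeatLen
#'   genome composition.
#' @param enrichmentFactorPerRound,nRounds enrichment model.
#' @param backgroundMu,backgroundSigma,sampleNoiseSigma abundance model.
#' @param hostFractionShape,cognateHostFractionShape,blankHostFraction,blankDilution
#'   host-DNA contamination model.
#' @param detectionFloor,fragmentationRate assembly emulation.
#' @param readsPerSample,readLength,readErrorRate read simulation.
#' @param mdaSsdnaBiasSigma MDA bias on circular genomes (0 disables).
#' @param pvogMeanViral,pvogMeanHost,externalProbViral,externalProbHost,dbHitProbViral,dbHitProbHost
#'   evidence simulation.
#' @param seed integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nPools = 1L, strainsPerPool = 4L,
#'                  nBackgroundPhages = 10L, nPlantedPairs = 1L, seed = 1L)
#' cfg
#' @export
simConfig <- function(nPools = 3L,
                      strainsPerPool = c(26L, 53L, 37L),
                      nBackgroundPhages = 200L,
                      nHostFragments = 20L,
                      nPlantedPairs = 10L,
                      genomeLengthRange = c(15000, 50000),
                      hostLengthRange = c(2000, 40000),
                      circularFraction = 0.25,
                      terminalRepeatLen = 55L,
                      enrichmentFactorPerRound = 10,
                      nRounds = 3L,
                      backgroundMu = 0,
                      backgroundSigma = 0.3,
                      sampleNoiseSigma = 0.3,
                      hostFractionShape = c(2, 2),
                      cognateHostFractionShape = c(1, 9),
                      blankHostFraction = 0.97,
                      blankDilution = 0.01,
                      detectionFloor = 1e-5,
                      fragmentationRate = 0.5,
                      readsPerSample = 50000L,
                      readLength = 100L,
                      readErrorRate = 0.01,
                      mdaSsdnaBiasSigma = 0,
                      pvogMeanViral = 6,
                      pvogMeanHost = 0.5,
                      externalProbViral = 0.8,
                      externalProbHost = 0.02,
                      dbHitProbViral = 0.5,
                      dbHitProbHost = 0.01,
                      seed = 1L) {
  new("SimConfig",
      nPools = as.integer(nPools),
      strainsPerPool = as.integer(strainsPerPool),
      nBackgroundPhages = as.integer(nBackgroundPhages),
      nHostFragments = as.integer(nHostFragments),
      nPlantedPairs = as.integer(nPlantedPairs),
      genomeLengthRange = as.numeric(genomeLengthRange),
      hostLengthRange = as.numeric(hostLengthRange),
      circularFraction = as.numeric(circularFraction),
      terminalRepeatLen = as.integer(terminalRepeatLen),
      enrichmentFactorPerRound = as.numeric(enrichmentFactorPerRound),
      nRounds = as.integer(nRounds),
      backgroundMu = as.numeric(backgroundMu),
      backgroundSigma = as.numeric(backgroundSigma),
      sampleNoiseSigma = as.numeric(sampleNoiseSigma),
      hostFractionShape = as.numeric(hostFractionShape),
      cognateHostFractionShape = as.numeric(cognateHostFractionShape),
      blankHostFraction = as.numeric(blankHostFraction),
      blankDilution = as.numeric(blankDilution),
      detectionFloor = as.numeric(detectionFloor),
      fragmentationRate = as.numeric(fragmentationRate),
      readsPerSample = as.integer(readsPerSample),
      readLength = as.integer(readLength),
      readErrorRate = as.numeric(readErrorRate),
      mdaSsdnaBiasSigma = as.numeric(mdaSsdnaBiasSigma),
      pvogMeanViral = as.numeric(pvogMeanViral),
      pvogMeanHost = as.numeric(pvogMeanHost),
      externalProbViral = as.numeric(externalProbViral),
      externalProbHost = as.numeric(externalProbHost),
      dbHitProbViral = as.numeric(dbHitProbViral),
      dbHitProbHost = as.numeric(dbHitProbHost),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPools, "pool(s), strains per pool:",
      paste(object@strainsPerPool, collapse = "/"), "\n")
  cat("  genomes/pool:", object@nBackgroundPhages, "background phages +",
      object@nHostFragments, "host fragments;",
      object@nPlantedPairs, "planted pair(s) overall\n")
  cat("  enrichment:", object@enrichmentFactorPerRound, "x per round x",
      object@nRounds, "rounds; noise sigma", object@sampleNoiseSigma,
      "; background LN(", object@backgroundMu, ",",
      object@backgroundSigma, ")\n")
  cat("  reads/sample:", object@readsPerSample, "x", object@readLength,
      "bp, error", object@readErrorRate, "; seed", object@seed, "\n")
})

#' Ground truth of a synthetic enrichment experiment
#'
#' Records what the generator planted so recovery can be scored: the
#' phage-host pairs, which samples should show enrichment, per-genome
#' metadata (pool, length, circularity, origin type), and the mapping from
#' genomes to the contigs emitted from them.
#'
#' @slot plantedPairs data.frame with columns `genome_id`, `strain_id`,
#'   `pool_id`, `sample_id` (the cognate enriched sample).
#' @slot genomeInfo data.frame with columns `genome_id`, `pool_id`, `type`
#'   (one of `phage_background`, `phage_planted`, `host_fragment`), `length`,
#'   `circular`, `terminal_repeat_len`.
#' @slot genomeToContigs data.frame mapping `genome_id` to emitted
#'   `contig_id` with `sample_id`, `start`, `end` coordinates.
#' @slot expectedEnriched data.frame with columns `genome_id`, `sample_id`.
#' @export
setClass("GroundTruth", representation(
  plantedPairs = "data.frame",
  genomeInfo = "data.frame",
  genomeToContigs = "data.frame",
  expectedEnriched = "data.frame"
))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genomeInfo), "genomes,",
      nrow(object@plantedPairs), "planted phage-host pair(s),",
      nrow(object@genomeToContigs), "emitted contig(s)\n")
})

#' Accessor: planted phage-host pairs
#' @param x a [GroundTruth-class] object.
#' @return data.frame of planted pairs.
#' @export
plantedPairs <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@plantedPairs
}

#' Accessor: per-genome truth metadata
#' @param x a [GroundTruth-class] object.
#' @return data.frame of genome metadata.
#' @export
genomeInfo <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@genomeInfo
}

#' Accessor: genome-to-contig mapping
#' @param x a [GroundTruth-class] object.
#' @return data.frame mapping genomes to emitted contigs.
#' @export
genomeToContigs <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@genomeToContigs
}

#' Contig dereplication result
#'
#' Greedy longest-first clustering of pooled per-sample contigs at identity
#' and overlap thresholds, with the longest member of each cluster as its
#' representative (ties broken lexicographically by id).
#'
#' @slot members data.frame with columns `member_id`, `representative_id`,
#'   `identity`, `overlap`, `origin_sample`, `length`.
#' @slot representatives [Biostrings::DNAStringSet] of cluster
#'   representatives.
#' @seealso [dereplicate()]
#' @export
setClass("ContigClusters", representation(
  members = "data.frame",
  representatives = "DNAStringSet"
))

setValidity("ContigClusters", function(object) {
  m <- object@members
  if (nrow(m) == 0) return(TRUE)
  if (!all(m$representative_id %in% names(object@representatives)))
    return("every cluster representative must be present in the FASTA set")
  replen <- setNames(m$length[match(unique(m$representative_id), m$member_id)],
                     unique(m$representative_id))
  if (any(m$length > replen[m$representative_id]))
    return("a member is longer than its representative")
  TRUE
})

setMethod("show", "ContigClusters", function(object) {
  cat("ContigClusters:", nrow(object@members), "contigs in",
      length(object@representatives), "clusters\n")
})

#' Accessor: cluster representatives
#' @param x a [ContigClusters-class] object.
#' @return a `DNAStringSet` of representatives.
#' @export
representatives <- function(x) {
  stopifnot(is(x, "ContigClusters"))
  x@representatives
}

#' Accessor: cluster membership table
#' @param x a [ContigClusters-class] object.
#' @return data.frame of cluster members.
#' @export
clusterMembers <- function(x) {
  stopifnot(is(x, "ContigClusters"))
  x@members
}

#' Abundance container for enrichment viromes
#'
#' A [SummarizedExperiment::SummarizedExperiment] with `counts` and
#' `proportions` assays over representatives x samples, the sample sheet as
#' `colData` (columns `pool_id`, `strain_id`, `strain_taxon`, `sample_type`,
#' `unassigned`), and viral evidence as `rowData`. Proportions use the
#' whole-sample denominator: assigned plus unassigned reads, so each sample's
#' proportions plus its unassigned fraction sum to one.
#'
#' @seealso [viromeExperiment()], [relativeAbundance()], [viralFraction()]
#' @export
setClass("ViromeExperiment", contains = "SummarizedExperiment")

setValidity("ViromeExperiment", function(object) {
  msg <- character(0)
  if (!all(c("counts", "proportions") %in% assayNames(object)))
    msg <- c(msg, "assays 'counts' and 'proportions' are required")
  need <- c("pool_id", "sample_type", "unassigned")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!length(msg)) {
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be non-negative integers")
    tot <- colSums(cnt) + object$unassigned
    pos <- tot > 0
    ps <- colSums(assay(object, "proportions")) +
      ifelse(tot > 0, object$unassigned / tot, 0)
    if (any(abs(ps[pos] - 1) > 1e-9))
      msg <- c(msg, "proportions + unassigned fraction must sum to 1 per sample")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ViromeExperiment", function(object) {
  callNextMethod()
  vf <- if ("viral" %in% colnames(rowData(object)))
    sum(rowData(object)$viral) else NA
  cat("viral representatives:", vf, "| sample types:",
      paste(names(table(object$sample_type)), table(object$sample_type),
            sep = "=", collapse = " "), "\n")
})

#' Accessor: relative-abundance proportions
#' @param x a [ViromeExperiment-class].
#' @return matrix of per-sample relative abundances.
#' @export
proportions <- function(x) {
  stopifnot(is(x, "ViromeExperiment"))
  assay(x, "proportions")
}

#' Accessor: the sample sheet
#' @param x a [ViromeExperiment-class].
#' @return data.frame of sample metadata.
#' @export
sampleSheet <- function(x) {
  stopifnot(is(x, "ViromeExperiment"))
  as.data.frame(colData(x))
}

#' Accessor: viral classification flags
#' @param x a [ViromeExperiment-class].
#' @return named logical vector, or NULL when classification has not run.
#' @export
viralFlags <- function(x) {
  stopifnot(is(x, "ViromeExperiment"))
  if (!"viral" %in% colnames(rowData(x))) return(NULL)
  setNames(rowData(x)$viral, rownames(x))
}

#' Shortlist cascade report
#'
#' Result of the three-step shortlist cascade: candidates passed every step
#' (Z-score, abundance, viral evidence with minimum length); rejected
#' representatives record the first step they failed. Curation flags
#' (`multi_taxon_ambiguous`, `possible_host_fragment`) annotate candidates
#' without removing them.
#'
#' @slot candidates data.frame of passing representatives.
#' @slot rejected data.frame of failing representatives with
#'   `rejection_reason`.
#' @slot parameters list of the thresholds used.
#' @seealso [shortlist()], [flagCuration()], [linkHosts()]
#' @export
setClass("ShortlistReport", representation(
  candidates = "data.frame",
  rejected = "data.frame",
  parameters = "list"
))

setValidity("ShortlistReport", function(object) {
  if (nrow(object@rejected) &&
      any(!nzchar(object@rejected$rejection_reason)))
    return("every rejected entry must name a failed step")
  TRUE
})

setMethod("show", "ShortlistReport", function(object) {
  cat("ShortlistReport:", nrow(object@candidates), "candidate(s),",
      nrow(object@rejected), "rejected\n")
  p <- object@parameters
  cat(sprintf("  thresholds: Z >= %s, abundance >= %s, length >= %s bp\n",
              p$zMin, p$abundanceMin, p$lengthMin))
})

#' Accessor: shortlist candidates
#' @param x a [ShortlistReport-class].
#' @return data.frame of candidates.
#' @export
candidates <- function(x) {
  stopifnot(is(x, "ShortlistReport"))
  x@candidates
}

#' Accessor: rejected representatives
#' @param x a [ShortlistReport-class].
#' @return data.frame with rejection reasons.
#' @export
rejected <- function(x) {
  stopifnot(is(x, "ShortlistReport"))
  x@rejected
}

#' Principal-coordinates ordination result
#'
#' Classical scaling of a sample-by-sample distance matrix: axes ordered by
#' decreasing eigenvalue, coordinates centred, negative eigenvalues reported
#' rather than corrected.
#'
#' @slot sampleIds character vector of sample ids.
#' @slot coordinates samples x axes coordinate matrix.
#' @slot eigenvalues all eigenvalues (may include negatives).
#' @slot proportionExplained fraction of positive-eigenvalue inertia per
#'   retained axis.
#' @seealso [runPCoA()]
#' @export
setClass("PCoAOrdination", representation(
  sampleIds = "character",
  coordinates = "matrix",
  eigenvalues = "numeric",
  proportionExplained = "numeric"
))

setValidity("PCoAOrdination", function(object) {
  if (nrow(object@coordinates) &&
      nrow(object@coordinates) != length(object@sampleIds))
    return("one coordinate row per sample required")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be in decreasing order")
  TRUE
})

setMethod("show", "PCoAOrdination", function(object) {
  cat("PCoAOrdination:", length(object@sampleIds), "samples,",
      ncol(object@coordinates), "axes;",
      "first axes explain",
      paste(sprintf("%.1f%%", 100 * object@proportionExplained),
            collapse = ", "), "\n")
})

#' Accessor: ordination coordinates
#' @param x a [PCoAOrdination-class].
#' @return samples x axes matrix.
#' @export
ordCoordinates <- function(x) {
  stopifnot(is(x, "PCoAOrdination"))
  x@coordinates
}

#' Accessor: ordination eigenvalues
#' @param x a [PCoAOrdination-class].
#' @return numeric vector of eigenvalues.
#' @export
ordEigenvalues <- function(x) {
  stopifnot(is(x, "PCoAOrdination"))
  x@eigenvalues
}
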