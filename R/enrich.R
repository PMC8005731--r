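# Per-pool Z-score enrichment and the three-step shortlist cascade.

#' Per-pool Z-scores of relative abundance
#'
#' For representative r and sample s in pool P, `z = (a_rs - mean_P(a_r)) /
#' sd_P(a_r)`, where mean and SD run over all non-blank samples of P
#' (including s itself by default; `leaveOneOut = TRUE` excludes it). The SD
#' uses the sample (n-1) denominator. When the pool SD is zero the score is
#' `+Inf` if the abundance exceeds the pool mean, `-Inf` below it, and 0
#' when all values are equal. Blank controls never enter pool statistics.
#' A warning is issued for any pool whose size makes the threshold
#' unattainable (the maximum possible z is `(n-1)/sqrt(n)`).
#'
#' @param x a [ViromeExperiment-class], or a proportions matrix.
#' @param sheet sample sheet (taken from `colData` for a
#'   `ViromeExperiment`).
#' @param includeBaseline include the unenriched pool baseline in the pool
#'   statistics (default TRUE).
#' @param leaveOneOut exclude the focal sample from its own pool mean/SD.
#' @param zMin,abundanceMin thresholds used to fill the `passes_z` and
#'   `passes_abundance` flags.
#' @return data.frame of enrichment records: `representative_id`,
#'   `sample_id`, `pool_id`, `sample_type`, `strain_id`, `strain_taxon`,
#'   `relative_abundance`, `zscore`, `passes_z`, `passes_abundance`.
#' @examples
#' pr <- cbind(s1 = c(r = 0.01), s2 = c(r = 0.01),
#'             s3 = c(r = 0.01), s4 = c(r = 0.25))
#' sheet <- data.frame(sample_id = colnames(pr), pool_id = "A",
#'                     strain_id = colnames(pr),
#'                     strain_taxon = "Escherichia coli",
#'                     sample_type = "enriched")
#' poolZscores(pr, sheet)$zscore
#' @export
poolZscores <- function(x, sheet = NULL, includeBaseline = TRUE,
                        leaveOneOut = FALSE, zMin = 4.0,
                        abundanceMin = 0.01) {
  if (is(x, "ViromeExperiment")) {
    if (is.null(sheet)) sheet <- sampleSheet(x)
    if (!"sample_id" %in% names(sheet)) sheet$sample_id <- rownames(sheet)
    x <- assay(x, "proportions")
  }
  stopifnot(is.matrix(x), !is.null(sheet))
  m <- match(colnames(x), sheet$sample_id)
  if (anyNA(m)) stop("samples missing from the sheet: ",
                     paste(colnames(x)[is.na(m)], collapse = ", "))
  sheet <- sheet[m, , drop = FALSE]
  keep <- sheet$sample_type != "blank" &
    (includeBaseline | sheet$sample_type != "pool_baseline")
  pools <- unique(sheet$pool_id[keep & !is.na(sheet$pool_id)])
  out <- list()
  for (p in pools) {
    cols <- which(keep & sheet$pool_id == p)
    n <- length(cols)
    if (n < 2) stop("pool '", p, "' has fewer than 2 usable samples")
    if ((n - 1) / sqrt(n) < zMin)
      warning("pool '", p, "': a Z-score of ", zMin,
              " is unattainable with ", n,
              " samples (max ", round((n - 1) / sqrt(n), 2), ")")
    sub <- x[, cols, drop = FALSE]
    if (leaveOneOut) {
      S <- rowSums(sub); Q <- rowSums(sub^2)
      mu <- (S - sub) / (n - 1)
      va <- (Q - sub^2 - (n - 1) * mu^2) / (n - 2)
      sdv <- sqrt(pmax(va, 0))
    } else {
      mu0 <- rowMeans(sub)
      sd0 <- apply(sub, 1, sd)
      mu <- matrix(mu0, nrow(sub), n)
      sdv <- matrix(sd0, nrow(sub), n)
    }
    z <- (sub - mu) / sdv
    z[sdv == 0 & sub > mu] <- Inf
    z[sdv == 0 & sub < mu] <- -Inf
    z[sdv == 0 & sub == mu] <- 0
    for (j in seq_len(n)) {
      sj <- cols[j]
      out[[length(out) + 1L]] <- data.frame(
        representative_id = rownames(x),
        sample_id = sheet$sample_id[sj],
        pool_id = p,
        sample_type = sheet$sample_type[sj],
        strain_id = sheet$strain_id[sj],
        strain_taxon = sheet$strain_taxon[sj],
        relative_abundance = sub[, j],
        zscore = z[, j],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  rec <- do.call(rbind, out)
  rec$passes_z <- rec$zscore >= zMin
  rec$passes_abundance <- rec$relative_abundance >= abundanceMin
  rec
}

#' The three-step shortlist cascade
#'
#' A representative becomes a candidate when (1) some enriched sample shows
#' `z >= zMin`, (2) some enriched sample shows relative abundance of at
#' least `abundanceMin`, and (3) the representative carries viral evidence
#' (external viral call, pVOG density of at least 3 per 10 kb, or
#' circularity - the database criterion is off at this stage) and its
#' trimmed length is at least `lengthMin`. Pool baselines and blanks never
#' satisfy the existential clauses. Rejected representatives record the
#' first failed step (`zscore`, `abundance`, `viral_evidence`, `length`).
#'
#' @param records enrichment records from [poolZscores()].
#' @param evidence evidence data.frame covering exactly the same
#'   representatives (its `length` column should be the trimmed length).
#' @param zMin,abundanceMin,lengthMin cascade thresholds (defaults 4, 0.01,
#'   10000 - the standard cascade thresholds).
#' @param minPvogDensity pVOG density threshold (default 3 per 10 kb).
#' @return a [ShortlistReport-class].
#' @export
shortlist <- function(records, evidence, zMin = 4.0, abundanceMin = 0.01,
                      lengthMin = 10000L, minPvogDensity = 3.0) {
  rid <- unique(records$representative_id)
  eid <- unique(evidence$representative_id)
  if (!setequal(rid, eid))
    stop("record/evidence id sets differ; orphans: ",
         paste(c(setdiff(rid, eid), setdiff(eid, rid)), collapse = ", "))
  ev <- classifyViral(evidence, minPvogDensity = minPvogDensity,
                      useDbHit = FALSE)
  enr <- records[records$sample_type == "enriched", , drop = FALSE]
  cand <- list(); rej <- list()
  for (i in seq_along(eid)) {
    id <- eid[i]
    e <- ev[ev$representative_id == id, ][1, ]
    r <- enr[enr$representative_id == id, , drop = FALSE]
    zpass <- any(r$zscore >= zMin)
    apass <- any(r$relative_abundance >= abundanceMin)
    fail <- if (!zpass) "zscore"
    else if (!apass) "abundance"
    else if (!e$viral) "viral_evidence"
    else if (e$length < lengthMin) "length"
    else NA_character_
    row <- data.frame(
      representative_id = id,
      pool_id = if (nrow(r)) r$pool_id[which.max(r$zscore)] else
        records$pool_id[records$representative_id == id][1],
      max_zscore = if (nrow(r)) max(r$zscore) else -Inf,
      max_abundance = if (nrow(r)) max(r$relative_abundance) else 0,
      viral = e$viral,
      viral_reasons = e$reasons,
      length = e$length,
      stringsAsFactors = FALSE)
    if (is.na(fail)) {
      row$curation_flags <- ""
      cand[[length(cand) + 1L]] <- row
    } else {
      row$rejection_reason <- fail
      rej[[length(rej) + 1L]] <- row
    }
  }
  empty_c <- data.frame(representative_id = character(0),
                        pool_id = character(0), max_zscore = numeric(0),
                        max_abundance = numeric(0), viral = logical(0),
                        viral_reasons = character(0), length = integer(0),
                        curation_flags = character(0),
                        stringsAsFactors = FALSE)
  empty_r <- cbind(empty_c[, seq_len(7)],
                   data.frame(rejection_reason = character(0)))
  new("ShortlistReport",
      candidates = if (length(cand)) do.call(rbind, cand) else empty_c,
      rejected = if (length(rej)) do.call(rbind, rej) else empty_r,
      parameters = list(zMin = zMin, abundanceMin = abundanceMin,
                        lengthMin = lengthMin,
                        minPvogDensity = minPvogDensity))
}

#' Link shortlisted candidates to bacterial host strains
#'
#' One row per (candidate, strain): the strains of every enriched sample in
#' which the candidate shows both `z >= zMin` and relative abundance of at
#' least `abundanceMin`.
#'
#' @param report a [ShortlistReport-class].
#' @param records the enrichment records the report was built from.
#' @return data.frame with columns `representative_id`, `pool_id`,
#'   `sample_id`, `strain_id`, `strain_taxon`, `zscore`,
#'   `relative_abundance`.
#' @export
linkHosts <- function(report, records) {
  stopifnot(is(report, "ShortlistReport"))
  p <- report@parameters
  hits <- records[records$sample_type == "enriched" &
                    records$representative_id %in%
                      report@candidates$representative_id &
                    records$zscore >= p$zMin &
                    records$relative_abundance >= p$abundanceMin,
                  c("representative_id", "pool_id", "sample_id",
                    "strain_id", "strain_taxon", "zscore",
                    "relative_abundance"), drop = FALSE]
  rownames(hits) <- NULL
  hits[order(hits$representative_id, hits$strain_id), , drop = FALSE]
}

#' Annotate candidates with curation flags
#'
#' Non-destructive stand-ins for the manual curation step:
#' `multi_taxon_ambiguous` marks candidates whose `z >= zMin` enriched
#' samples span strains of different genera (genus = first token of the
#' strain taxon); `possible_host_fragment` marks candidates more than half
#' of whose k-mers occur in a supplied host genome. Flags annotate, never
#' remove.
#'
#' @param report a [ShortlistReport-class].
#' @param records the enrichment records the report was built from.
#' @param representativeSeqs optional named `DNAStringSet` of candidate
#'   sequences (needed for the host-fragment check).
#' @param hostGenomes optional named `DNAStringSet` of host genomes; when
#'   absent the fragment check is skipped with a message.
#' @param k k-mer size for the containment check.
#' @param containmentMin k-mer containment above which a candidate is
#'   flagged as a possible host fragment (default 0.5).
#' @return the report with `curation_flags` filled in.
#' @export
flagCuration <- function(report, records, representativeSeqs = NULL,
                         hostGenomes = NULL, k = 21L,
                         containmentMin = 0.5) {
  stopifnot(is(report, "ShortlistReport"))
  cand <- report@candidates
  if (!nrow(cand)) return(report)
  p <- report@parameters
  zhits <- records[records$sample_type == "enriched" &
                     records$zscore >= p$zMin, , drop = FALSE]
  checkHost <- !is.null(hostGenomes) && !is.null(representativeSeqs)
  if (is.null(hostGenomes))
    message("no host genomes supplied: host-fragment flag skipped")
  flags <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    id <- cand$representative_id[i]
    f <- character(0)
    taxa <- zhits$strain_taxon[zhits$representative_id == id]
    genera <- unique(vapply(strsplit(taxa[!is.na(taxa)], "[ _]"),
                            `[`, character(1), 1L))
    if (length(genera) > 1) f <- c(f, "multi_taxon_ambiguous")
    if (checkHost && id %in% names(representativeSeqs)) {
      fr <- .cpp_kmer_fraction_in(
        as.character(representativeSeqs[[id]]),
        as.character(hostGenomes), as.integer(k))
      if (any(fr > containmentMin)) f <- c(f, "possible_host_fragment")
    }
    flags[i] <- paste(f, collapse = ",")
  }
  cand$curation_flags <- flags
  report@candidates <- cand
  report
}

#' Score recovery of planted phage-host pairs
#'
#' Joins discovered host links against the generator's ground truth.
#' A discovered (genome, strain) pair is a true positive when it was
#' planted; sensitivity is the fraction of planted pairs recovered and the
#' false-discovery proportion is the fraction of discovered pairs that were
#' not planted.
#'
#' @param links host links from [linkHosts()].
#' @param truth a [GroundTruth-class].
#' @param repToGenome optional named character vector mapping representative
#'   ids to genome ids (defaults to identity, as in count mode; in read
#'   mode derive it from [genomeToContigs()]).
#' @return list with `sensitivity`, `fdp`, `n_true`, `n_false`,
#'   `n_planted`, and the annotated `pairs` data.frame.
#' @export
recoveryStats <- function(links, truth, repToGenome = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  planted <- truth@plantedPairs
  if (nrow(links)) {
    gid <- if (is.null(repToGenome)) links$representative_id
    else unname(repToGenome[links$representative_id])
    pairs <- unique(data.frame(genome_id = gid,
                               strain_id = links$strain_id,
                               stringsAsFactors = FALSE))
    pairs$true_positive <- paste(pairs$genome_id, pairs$strain_id) %in%
      paste(planted$genome_id, planted$strain_id)
  } else {
    pairs <- data.frame(genome_id = character(0), strain_id = character(0),
                        true_positive = logical(0))
  }
  ntrue <- sum(pairs$true_positive)
  nfalse <- sum(!pairs$true_positive)
  list(sensitivity = if (nrow(planted)) ntrue / nrow(planted) else NA_real_,
       fdp = if (nrow(pairs)) nfalse / nrow(pairs) else 0,
       n_true = ntrue, n_false = nfalse, n_planted = nrow(planted),
       pairs = pairs)
}
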