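# Synthetic enrichment-culture experiments with known phage-host truth.
#
# Every operation derives its own RNG stream from config@seed, so each stage
# is independently reproducible and a full simulateExperiment() run is
# byte-identical for identical (config, seed).

.GENERA <- c("Bacteroides", "Escherichia", "Faecalibacterium", "Prevotella",
             "Bifidobacterium", "Roseburia", "Akkermansia", "Klebsiella",
             "Anaerostipes", "Blautia", "Ruminococcus", "Parabacteroides",
             "Subdoligranulum", "Eubacterium", "Collinsella", "Dorea",
             "Alistipes", "Enterococcus", "Veillonella", "Coprococcus")

#' Build the sample sheet implied by a simulation configuration
#'
#' One enriched sample per strain per pool, one unenriched pool baseline per
#' pool, and a single blank amplification control. Strain taxa are drawn from
#' a fixed catalogue of common gut genera; the genus is the first token of
#' `strain_taxon`.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `sample_id`, `pool_id`, `strain_id`,
#'   `strain_taxon`, `sample_type`.
#' @examples
#' head(simulateSampleSheet(simConfig(seed = 1L)))
#' @export
simulateSampleSheet <- function(config) {
  validObject(config)
  set.seed(.stageSeed(config@seed, 0L))
  rows <- list()
  for (p in seq_len(config@nPools)) {
    pool <- LETTERS[p]
    ns <- config@strainsPerPool[p]
    if (ns > 0) {
      sid <- sprintf("%s_s%02d", pool, seq_len(ns))
      genus <- sample(.GENERA, ns, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, pool_id = pool, strain_id = sid,
        strain_taxon = sprintf("%s sp. %s", genus, sid),
        sample_type = "enriched", stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(pool, "_baseline"), pool_id = pool,
      strain_id = NA_character_, strain_taxon = NA_character_,
      sample_type = "pool_baseline", stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sample_id = "blank", pool_id = NA_character_, strain_id = NA_character_,
    strain_taxon = NA_character_, sample_type = "blank",
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Generate phage and host-fragment genomes with planted phage-host pairs
#'
#' Genomes are pool-scoped: each pool receives its own background phages,
#' planted phages and host fragments, with uniform-random nucleotide
#' composition and lengths uniform in the configured ranges. Circular phage
#' genomes are emitted linearized with an exact terminal direct repeat so
#' downstream circularity detection can recover them. Planted pairs are
#' assigned to randomly chosen enriched strain cultures.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `genomes` (a named `DNAStringSet` whose `mcols`
#'   carry `pool_id`, `type`, `circular`, `terminal_repeat_len`), `truth`
#'   (a [GroundTruth-class]) and `sampleSheet`.
#' @examples
#' g <- simulateGenomes(simConfig(nPools = 1L, strainsPerPool = 3L,
#'                                nBackgroundPhages = 4L, nHostFragments = 2L,
#'                                nPlantedPairs = 1L, seed = 7L))
#' g$genomes
#' @export
simulateGenomes <- function(config) {
  validObject(config)
  sheet <- simulateSampleSheet(config)
  set.seed(.stageSeed(config@seed, 1L))
  enr <- sheet[sheet$sample_type == "enriched", , drop = FALSE]
  pick <- if (config@nPlantedPairs > 0)
    enr[sample.int(nrow(enr), config@nPlantedPairs), , drop = FALSE]
  else enr[0, , drop = FALSE]

  seqs <- character(0)
  info <- list()
  for (p in seq_len(config@nPools)) {
    pool <- LETTERS[p]
    npl <- sum(pick$pool_id == pool)
    ids <- c(sprintf("%s_bg%03d", pool, seq_len(config@nBackgroundPhages)),
             if (npl > 0) sprintf("%s_pl%02d", pool, seq_len(npl)),
             if (config@nHostFragments > 0)
               sprintf("%s_hf%02d", pool, seq_len(config@nHostFragments)))
    type <- rep(c("phage_background", "phage_planted", "host_fragment"),
                c(config@nBackgroundPhages, npl, config@nHostFragments))
    nphage <- config@nBackgroundPhages + npl
    len <- integer(length(ids))
    len[type != "host_fragment"] <- as.integer(round(runif(
      nphage, config@genomeLengthRange[1], config@genomeLengthRange[2])))
    len[type == "host_fragment"] <- as.integer(round(runif(
      config@nHostFragments, config@hostLengthRange[1],
      config@hostLengthRange[2])))
    circ <- logical(length(ids))
    circ[type != "host_fragment"] <-
      runif(nphage) < config@circularFraction
    tr <- ifelse(circ, config@terminalRepeatLen, 0L)
    sq <- vapply(seq_along(ids), function(i) {
      if (circ[i]) {
        core <- .randomDNA(len[i] - tr[i])
        paste0(core, substr(core, 1L, tr[i]))
      } else .randomDNA(len[i])
    }, character(1))
    names(sq) <- ids
    seqs <- c(seqs, sq)
    info[[p]] <- data.frame(
      genome_id = ids, pool_id = pool, type = type, length = len,
      circular = circ, terminal_repeat_len = as.integer(tr),
      stringsAsFactors = FALSE)
  }
  gi <- do.call(rbind, info)

  pp <- data.frame(genome_id = character(0), strain_id = character(0),
                   pool_id = character(0), sample_id = character(0),
                   stringsAsFactors = FALSE)
  if (nrow(pick) > 0) {
    # planted genomes were created per pool in pick order within that pool
    pp <- do.call(rbind, lapply(seq_len(config@nPools), function(p) {
      pool <- LETTERS[p]
      rows <- pick[pick$pool_id == pool, , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      data.frame(genome_id = sprintf("%s_pl%02d", pool, seq_len(nrow(rows))),
                 strain_id = rows$strain_id, pool_id = pool,
                 sample_id = rows$sample_id, stringsAsFactors = FALSE)
    }))
    rownames(pp) <- NULL
  }

  genomes <- DNAStringSet(seqs)
  mcols(genomes) <- DataFrame(gi[, c("pool_id", "type", "circular",
                                     "terminal_repeat_len")])
  truth <- new("GroundTruth", plantedPairs = pp, genomeInfo = gi,
               genomeToContigs = data.frame(
                 genome_id = character(0), contig_id = character(0),
                 sample_id = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE),
               expectedEnriched = pp[, c("genome_id", "sample_id")])
  list(genomes = genomes, truth = truth, sampleSheet = sheet)
}

#' Simulate true relative abundances of genomes across all samples
#'
#' Background abundance is drawn once per pool from the log-normal model and
#' shared across the pool's samples with multiplicative per-sample log-normal
#' noise. Each planted phage is additionally amplified by
#' `enrichmentFactorPerRound^nRounds` in its cognate-host sample only.
#' Circular genomes may receive an independent per-sample MDA multiplier
#' `exp(N(0, mdaSsdnaBiasSigma))`. Host fragments form a separate
#' compartment whose per-sample share (the host-DNA fraction) is Beta-drawn;
#' cognate samples use the lysis-depleted Beta, the blank uses a fixed high
#' fraction and its phage compartment is diluted `blankDilution`-fold. Every
#' sample column is renormalized to proportions summing to one.
#'
#' @param config a [SimConfig-class].
#' @param truth a [GroundTruth-class] from [simulateGenomes()].
#' @param sheet the sample sheet; regenerated from `config` when omitted.
#' @return numeric matrix (genomes x samples) of true relative abundances.
#' @examples
#' g <- simulateGenomes(simConfig(nPools = 1L, strainsPerPool = 3L,
#'                                nBackgroundPhages = 5L, nPlantedPairs = 1L,
#'                                seed = 3L))
#' ab <- simulateAbundances(simConfig(nPools = 1L, strainsPerPool = 3L,
#'                                    nBackgroundPhages = 5L,
#'                                    nPlantedPairs = 1L, seed = 3L), g$truth)
#' colSums(ab)
#' @export
simulateAbundances <- function(config, truth,
                               sheet = simulateSampleSheet(config)) {
  validObject(config)
  set.seed(.stageSeed(config@seed, 2L))
  gi <- truth@genomeInfo
  enrich <- config@enrichmentFactorPerRound^config@nRounds
  cognate <- setNames(truth@plantedPairs$genome_id,
                      truth@plantedPairs$sample_id)
  ab <- matrix(0, nrow(gi), nrow(sheet),
               dimnames = list(gi$genome_id, sheet$sample_id))
  base <- setNames(numeric(nrow(gi)), gi$genome_id)
  for (p in seq_len(config@nPools)) {
    pool <- LETTERS[p]
    idx <- which(gi$pool_id == pool)
    base[idx] <- rlnorm(length(idx), config@backgroundMu,
                        config@backgroundSigma)
    phage <- idx[gi$type[idx] != "host_fragment"]
    host <- idx[gi$type[idx] == "host_fragment"]
    scols <- which(sheet$pool_id == pool & sheet$sample_type != "blank")
    for (s in scols) {
      sid <- sheet$sample_id[s]
      ph <- base[phage] * rlnorm(length(phage), 0, config@sampleNoiseSigma)
      cg <- cognate[sid]
      if (!is.na(cg) && sid %in% names(cognate))
        ph[gi$genome_id[phage] == cg] <-
          ph[gi$genome_id[phage] == cg] * enrich
      if (config@mdaSsdnaBiasSigma > 0) {
        circ <- gi$circular[phage]
        ph[circ] <- ph[circ] * rlnorm(sum(circ), 0, config@mdaSsdnaBiasSigma)
      }
      hf <- if (sid %in% names(cognate))
        rbeta(1, config@cognateHostFractionShape[1],
              config@cognateHostFractionShape[2])
      else rbeta(1, config@hostFractionShape[1], config@hostFractionShape[2])
      col <- numeric(nrow(gi))
      col[phage] <- (1 - hf) * ph / sum(ph)
      if (length(host)) {
        hh <- base[host] * rlnorm(length(host), 0, config@sampleNoiseSigma)
        col[host] <- hf * hh / sum(hh)
      } else {
        col[phage] <- col[phage] / (1 - hf)
      }
      ab[, s] <- col
    }
  }
  # blank: 100-fold diluted phage background from every pool, host fraction
  # fixed high (near-zero viral signal)
  bl <- which(sheet$sample_type == "blank")
  if (length(bl)) {
    phage <- which(gi$type != "host_fragment")
    host <- which(gi$type == "host_fragment")
    ph <- base[phage] * config@blankDilution *
      rlnorm(length(phage), 0, config@sampleNoiseSigma)
    col <- numeric(nrow(gi))
    hf <- config@blankHostFraction
    if (length(host)) {
      hh <- base[host] * rlnorm(length(host), 0, config@sampleNoiseSigma)
      col[phage] <- (1 - hf) * ph / sum(ph)
      col[host] <- hf * hh / sum(hh)
    } else {
      col[phage] <- ph / sum(ph)
    }
    ab[, bl] <- col
  }
  sweep(ab, 2, colSums(ab), "/")
}

#' Fragment genomes into per-sample contigs
#'
#' Each genome present in a sample above the detection floor is emitted as
#' `1 + Poisson(fragmentationRate)` contigs with uniform-random breakpoints;
#' fragments shorter than 1 kb are dropped, mirroring a per-sample assembly
#' length filter. Contig ids encode the sample of origin and the
#' genome-to-contig map in the ground truth is updated.
#'
#' @param genomes named `DNAStringSet` from [simulateGenomes()].
#' @param abundance matrix from [simulateAbundances()].
#' @param truth the [GroundTruth-class] to update.
#' @param config a [SimConfig-class].
#' @return list with `contigs` (a `DNAStringSet` with `origin_sample` in
#'   `mcols`) and the updated `truth`.
#' @export
fragmentContigs <- function(genomes, abundance, truth, config) {
  validObject(config)
  set.seed(.stageSeed(config@seed, 3L))
  gl <- width(genomes)
  names(gl) <- names(genomes)
  seqs <- character(0)
  origin <- character(0)
  map <- list()
  for (s in colnames(abundance)) {
    counter <- 0L
    present <- rownames(abundance)[abundance[, s] >= config@detectionFloor]
    for (g in present) {
      L <- gl[[g]]
      nb <- rpois(1, config@fragmentationRate)
      bounds <- if (nb > 0 && L > nb + 1)
        c(0L, sort(sample.int(L - 1L, nb)), L)
      else c(0L, L)
      for (i in seq_len(length(bounds) - 1L)) {
        st <- bounds[i] + 1L
        en <- bounds[i + 1L]
        if (en - st + 1L < 1000L) next
        counter <- counter + 1L
        cid <- sprintf("%s_c%04d", s, counter)
        seqs[cid] <- substr(as.character(genomes[[g]]), st, en)
        origin <- c(origin, s)
        map[[length(map) + 1L]] <- data.frame(
          genome_id = g, contig_id = cid, sample_id = s,
          start = st, end = en, stringsAsFactors = FALSE)
      }
    }
  }
  contigs <- DNAStringSet(seqs)
  mcols(contigs) <- DataFrame(origin_sample = origin)
  truth@genomeToContigs <- if (length(map)) do.call(rbind, map) else
    truth@genomeToContigs
  list(contigs = contigs, truth = truth)
}

#' Simulate shotgun reads from the true abundances
#'
#' Source genomes are picked proportional to abundance times length; start
#' positions are uniform, wrapping across the junction for circular genomes;
#' substitution errors occur independently at `readErrorRate` per base.
#'
#' @param genomes named `DNAStringSet`.
#' @param abundance matrix from [simulateAbundances()].
#' @param config a [SimConfig-class].
#' @param samples samples to simulate (default: all abundance columns).
#' @return named list of `DNAStringSet`s (one per sample) whose `mcols`
#'   carry the true `source_genome` of every read.
#' @export
simulateReads <- function(genomes, abundance, config,
                          samples = colnames(abundance)) {
  validObject(config)
  rl <- config@readLength
  circ <- mcols(genomes)$circular
  tr <- mcols(genomes)$terminal_repeat_len
  if (is.null(circ)) circ <- rep(FALSE, length(genomes))
  if (is.null(tr)) tr <- rep(0L, length(genomes))
  eff <- ifelse(circ, width(genomes) - tr, width(genomes))
  if (rl > min(eff))
    stop("readLength exceeds the shortest genome (", min(eff), " bp)")
  set.seed(.stageSeed(config@seed, 4L))
  gseq <- as.character(genomes)
  # circular templates doubled over the trimmed core so reads wrap
  template <- ifelse(circ,
                     vapply(seq_along(gseq), function(i) {
                       core <- substr(gseq[i], 1L, eff[i])
                       paste0(core, substr(core, 1L, rl))
                     }, character(1)),
                     gseq)
  out <- list()
  for (s in samples) {
    w <- abundance[names(genomes), s] * width(genomes)
    n <- config@readsPerSample
    src <- sample.int(length(genomes), n, replace = TRUE, prob = w)
    reads <- character(n)
    for (gi in unique(src)) {
      ri <- which(src == gi)
      maxstart <- if (circ[gi]) eff[gi] else eff[gi] - rl + 1L
      starts <- sample.int(maxstart, length(ri), replace = TRUE)
      reads[ri] <- substring(template[gi], starts, starts + rl - 1L)
    }
    if (config@readErrorRate > 0) {
      nerr <- rbinom(n, rl, config@readErrorRate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(rl, nerr[i])
        ch <- strsplit(reads[i], "")[[1]]
        for (p in pos)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        reads[i] <- paste(ch, collapse = "")
      }
    }
    rs <- DNAStringSet(reads)
    names(rs) <- sprintf("%s_r%06d", s, seq_len(n))
    mcols(rs) <- DataFrame(source_genome = names(genomes)[src])
    out[[s]] <- rs
  }
  out
}

#' Draw per-sample read counts directly from the true abundances
#'
#' Count-space stand-in for read simulation plus assignment: each sample's
#' counts are one multinomial draw of `readsPerSample` reads over the true
#' genome proportions. Statistically equivalent to error-free read mapping
#' at the same depth.
#'
#' @param abundance matrix from [simulateAbundances()].
#' @param config a [SimConfig-class].
#' @return integer matrix of read counts (genomes x samples).
#' @export
simulateCounts <- function(abundance, config) {
  validObject(config)
  set.seed(.stageSeed(config@seed, 6L))
  cnt <- vapply(seq_len(ncol(abundance)), function(j)
    rmultinom(1, config@readsPerSample, abundance[, j])[, 1],
    integer(nrow(abundance)))
  dimnames(cnt) <- dimnames(abundance)
  cnt
}

#' Simulate the viral-evidence table
#'
#' For every representative-eligible sequence: a Poisson pVOG hit count
#' (mean `pvogMeanViral` per 10 kb for phage-derived sequences,
#' `pvogMeanHost` for host-fragment decoys), an external viral flag and a
#' database-hit flag drawn with origin-dependent probabilities. Circularity
#' is inherited from the source genome for full-length sequences.
#'
#' @param x named `DNAStringSet` of contigs (or genomes in count mode).
#' @param truth the [GroundTruth-class] (identifies each item's origin).
#' @param config a [SimConfig-class].
#' @param forceFlags set every external and database flag to 1 (degenerate
#'   world in which classification is trivially positive).
#' @return data.frame with columns `representative_id`, `pvog_hits`,
#'   `external_viral_flag`, `db_hit_flag`, `length`, `circular`,
#'   `terminal_repeat_len`.
#' @export
simulateEvidence <- function(x, truth, config, forceFlags = FALSE) {
  validObject(config)
  set.seed(.stageSeed(config@seed, 5L))
  gi <- truth@genomeInfo
  ids <- names(x)
  len <- width(x)
  if (all(ids %in% gi$genome_id)) {         # genome-level (count mode)
    m <- gi[match(ids, gi$genome_id), ]
    circ <- m$circular
    trl <- m$terminal_repeat_len
    type <- m$type
  } else {                                   # contig-level
    g2c <- truth@genomeToContigs
    gid <- g2c$genome_id[match(ids, g2c$contig_id)]
    m <- gi[match(gid, gi$genome_id), ]
    full <- g2c$start[match(ids, g2c$contig_id)] == 1L &
      g2c$end[match(ids, g2c$contig_id)] == m$length
    circ <- m$circular & full
    trl <- ifelse(circ, m$terminal_repeat_len, 0L)
    type <- m$type
  }
  isviral <- type != "host_fragment"
  mu <- ifelse(isviral, config@pvogMeanViral, config@pvogMeanHost)
  pvog <- rpois(length(ids), mu * len / 1e4)
  ext <- rbinom(length(ids), 1, ifelse(isviral, config@externalProbViral,
                                       config@externalProbHost))
  db <- rbinom(length(ids), 1, ifelse(isviral, config@dbHitProbViral,
                                      config@dbHitProbHost))
  if (forceFlags) { ext[] <- 1L; db[] <- 1L }
  data.frame(representative_id = ids, pvog_hits = pvog,
             external_viral_flag = ext, db_hit_flag = db,
             length = len, circular = circ,
             terminal_repeat_len = as.integer(trl),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete enrichment experiment
#'
#' Runs the generator end to end. In `"counts"` mode (the default, suitable
#' for statistical benchmarking) per-sample read counts are drawn
#' multinomially from the true abundances and evidence is emitted per
#' genome. In `"reads"` mode per-sample contigs and error-bearing reads are
#' emitted, with evidence per contig.
#'
#' @param config a [SimConfig-class].
#' @param mode `"counts"` or `"reads"`.
#' @return list with elements `config`, `sampleSheet`, `genomes`, `truth`,
#'   `abundance`, `evidence`, plus `counts` (counts mode) or `contigs` and
#'   `reads` (reads mode).
#' @examples
#' cfg <- simConfig(nPools = 1L, strainsPerPool = 4L,
#'                  nBackgroundPhages = 8L, nHostFragments = 2L,
#'                  nPlantedPairs = 1L, readsPerSample = 500L, seed = 2L)
#' sim <- simulateExperiment(cfg)
#' colSums(sim$counts)
#' @export
simulateExperiment <- function(config, mode = c("counts", "reads")) {
  mode <- match.arg(mode)
  g <- simulateGenomes(config)
  ab <- simulateAbundances(config, g$truth, g$sampleSheet)
  out <- list(config = config, sampleSheet = g$sampleSheet,
              genomes = g$genomes, truth = g$truth, abundance = ab)
  if (mode == "counts") {
    out$counts <- simulateCounts(ab, config)
    out$evidence <- simulateEvidence(g$genomes, g$truth, config)
  } else {
    fc <- fragmentContigs(g$genomes, ab, g$truth, config)
    out$contigs <- fc$contigs
    out$truth <- fc$truth
    out$evidence <- simulateEvidence(fc$contigs, fc$truth, config)
    out$reads <- simulateReads(g$genomes, ab, config)
  }
  out
}

#' Write a simulated experiment to disk
#'
#' Emits the generator's external formats: per-sample contig FASTA and/or
#' read FASTQ (fixed Sanger Phred+33 qualities), the sample sheet, the
#' evidence table, the true abundance (and count) matrices, and the ground
#' truth tables.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(d, f) {
    path <- file.path(dir, f)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wtsv(sim$sampleSheet, "samplesheet.tsv")
  wtsv(sim$evidence, "evidence.tsv")
  ab <- data.frame(genome_id = rownames(sim$abundance), sim$abundance,
                   check.names = FALSE)
  wtsv(ab, "true_abundance.tsv")
  if (!is.null(sim$counts)) {
    wtsv(data.frame(genome_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE), "counts.tsv")
  }
  truth <- sim$truth
  wtsv(truth@plantedPairs, "truth_planted_pairs.tsv")
  wtsv(truth@genomeInfo, "truth_genome_info.tsv")
  wtsv(truth@genomeToContigs, "truth_genome_to_contigs.tsv")
  if (!is.null(sim$contigs)) {
    cdir <- file.path(dir, "contigs")
    dir.create(cdir, showWarnings = FALSE)
    origin <- mcols(sim$contigs)$origin_sample
    for (s in unique(origin)) {
      path <- file.path(cdir, paste0(s, ".fasta"))
      writeXStringSet(sim$contigs[origin == s], path)
      files <- c(files, path)
    }
  }
  if (!is.null(sim$reads)) {
    rdir <- file.path(dir, "reads")
    dir.create(rdir, showWarnings = FALSE)
    for (s in names(sim$reads)) {
      path <- file.path(rdir, paste0(s, ".fastq"))
      rs <- sim$reads[[s]]
      qual <- BStringSet(rep(paste(rep("I", sim$config@readLength),
                                   collapse = ""), length(rs)))
      writeXStringSet(rs, path, format = "fastq", qualities = qual)
      files <- c(files, path)
    }
  }
  invisible(files)
}
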