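test_that("config validation rejects degenerate worlds", {
  expect_error(simConfig(genomeLengthRange = c(20000, 15000)), "degenerate")
  expect_error(simConfig(enrichmentFactorPerRound = 0.5), "must be >= 1")
  expect_error(simConfig(circularFraction = 1.2), "proportions")
  expect_error(simConfig(nPools = 2L, strainsPerPool = 5L), "per pool")
})

test_that("genome generation honours counts, circularity and planting", {
  cfg <- simConfig(nPools = 1L, strainsPerPool = 6L, nBackgroundPhages = 5L,
                   nHostFragments = 2L, nPlantedPairs = 0L,
                   circularFraction = 1, genomeLengthRange = c(3000, 5000),
                   hostLengthRange = c(2000, 3000), seed = 4L)
  g <- simulateGenomes(cfg)
  info <- genomeInfo(g$truth)
  expect_equal(sum(info$type == "phage_background"), 5L)
  expect_equal(nrow(plantedPairs(g$truth)), 0L)
  # every circular genome carries an exact 55 bp terminal repeat
  for (id in info$genome_id[info$circular]) {
    s <- as.character(g$genomes[[id]])
    expect_identical(substr(s, 1, 55), substr(s, nchar(s) - 54, nchar(s)))
  }
  expect_true(all(!info$circular[info$type == "host_fragment"]))
  expect_true(all(info$length >= 2000 & info$length <= 5000))

  # planted pairs always name a strain of the right pool
  cfg2 <- tinyConfig()
  g2 <- simulateGenomes(cfg2)
  pp <- plantedPairs(g2$truth)
  sheet <- g2$sampleSheet
  expect_equal(nrow(pp), 2L)
  expect_true(all(sheet$pool_id[match(pp$strain_id, sheet$strain_id)] ==
                    pp$pool_id))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- simConfig(nPools = 1L, strainsPerPool = 4L, nBackgroundPhages = 6L,
                   nHostFragments = 2L, nPlantedPairs = 1L,
                   genomeLengthRange = c(3000, 6000),
                   hostLengthRange = c(2000, 3000),
                   readsPerSample = 300L, readLength = 80L, seed = 99L)
  s1 <- simulateExperiment(cfg, mode = "reads")
  s2 <- simulateExperiment(cfg, mode = "reads")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulation(s1, d1)
  writeSimulation(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
})

test_that("abundance columns are proportions and planting dominates pools", {
  cfg <- tinyConfig()
  g <- simulateGenomes(cfg)
  ab <- simulateAbundances(cfg, g$truth, g$sampleSheet)
  expect_true(all(abs(colSums(ab) - 1) < 1e-9))
  expect_true(all(ab >= 0))
  # cognate sample is the argmax of every planted genome across its pool
  pp <- plantedPairs(g$truth)
  sheet <- g$sampleSheet
  for (i in seq_len(nrow(pp))) {
    pool_samp <- sheet$sample_id[!is.na(sheet$pool_id) &
                                   sheet$pool_id == pp$pool_id[i]]
    expect_identical(pool_samp[which.max(ab[pp$genome_id[i], pool_samp])],
                     pp$sample_id[i])
  }
})

test_that("triple-round enrichment multiplies cognate odds a thousandfold", {
  # with per-sample noise and host compartment disabled, the proportion
  # odds-ratio between cognate and any other sample equals factor^rounds
  cfg <- simConfig(nPools = 1L, strainsPerPool = 5L, nBackgroundPhages = 20L,
                   nHostFragments = 0L, nPlantedPairs = 1L,
                   sampleNoiseSigma = 0, enrichmentFactorPerRound = 10,
                   nRounds = 3L, genomeLengthRange = c(3000, 5000),
                   seed = 21L)
  g <- simulateGenomes(cfg)
  ab <- simulateAbundances(cfg, g$truth, g$sampleSheet)
  pp <- plantedPairs(g$truth)
  other <- setdiff(g$sampleSheet$sample_id[
    g$sampleSheet$sample_type == "enriched"], pp$sample_id)[1]
  odds <- function(p) p / (1 - p)
  ratio <- odds(ab[pp$genome_id, pp$sample_id]) /
    odds(ab[pp$genome_id, other])
  expect_equal(ratio, 1000, tolerance = 1e-9)
})

test_that("disabling the MDA bias makes circularity abundance-neutral", {
  base <- list(nPools = 1L, strainsPerPool = 6L, nBackgroundPhages = 15L,
               nHostFragments = 3L, nPlantedPairs = 1L,
               genomeLengthRange = c(3000, 5000), seed = 31L)
  ab_lin <- do.call(simConfig, c(base, circularFraction = 0))
  ab_cir <- do.call(simConfig, c(base, circularFraction = 1))
  g1 <- simulateGenomes(ab_lin); g2 <- simulateGenomes(ab_cir)
  a1 <- simulateAbundances(ab_lin, g1$truth, g1$sampleSheet)
  a2 <- simulateAbundances(ab_cir, g2$truth, g2$sampleSheet)
  expect_equal(unname(a1), unname(a2), tolerance = 1e-12)
  # with the bias on, circular genomes pick up extra abundance noise
  cfgm <- do.call(simConfig, c(base, circularFraction = 1,
                               mdaSsdnaBiasSigma = 1.5))
  gm <- simulateGenomes(cfgm)
  am <- simulateAbundances(cfgm, gm$truth, gm$sampleSheet)
  expect_gt(max(abs(am - a2)), 0.001)
})

test_that("exactly the planted genomes stand out by max/median pool ratio", {
  cfg <- simConfig(nPools = 1L, strainsPerPool = 20L,
                   nBackgroundPhages = 200L, nHostFragments = 20L,
                   nPlantedPairs = 3L, seed = 7L)
  g <- simulateGenomes(cfg)
  ab <- simulateAbundances(cfg, g$truth, g$sampleSheet)
  sheet <- g$sampleSheet
  pool_samp <- sheet$sample_id[!is.na(sheet$pool_id)]
  ratio <- apply(ab[, pool_samp], 1, function(v) max(v) / median(v))
  expect_identical(sort(names(ratio)[ratio > 100]),
                   sort(plantedPairs(g$truth)$genome_id))
})

test_that("contig emission respects floor, fragmentation and truth bookkeeping", {
  cfg <- simConfig(nPools = 1L, strainsPerPool = 3L, nBackgroundPhages = 8L,
                   nHostFragments = 2L, nPlantedPairs = 1L,
                   fragmentationRate = 0, genomeLengthRange = c(3000, 6000),
                   hostLengthRange = c(2000, 3000), seed = 13L)
  g <- simulateGenomes(cfg)
  ab <- simulateAbundances(cfg, g$truth, g$sampleSheet)
  fc <- fragmentContigs(g$genomes, ab, g$truth, cfg)
  g2c <- genomeToContigs(fc$truth)
  # rate 0: every contig is a full genome
  expect_true(all(g2c$start == 1))
  expect_equal(g2c$end,
               genomeInfo(g$truth)$length[match(g2c$genome_id,
                                                genomeInfo(g$truth)$genome_id)])
  # truth completeness: every emitted contig in exactly one truth row
  expect_identical(sort(names(fc$contigs)), sort(g2c$contig_id))
  expect_false(anyDuplicated(g2c$contig_id) > 0)

  # a genome below the detection floor yields no contig in that sample
  ab2 <- ab
  gid <- rownames(ab2)[1]
  sid <- colnames(ab2)[1]
  ab2[gid, sid] <- cfg@detectionFloor / 10
  fc2 <- fragmentContigs(g$genomes, ab2, g$truth, cfg)
  g2c2 <- genomeToContigs(fc2$truth)
  expect_false(any(g2c2$genome_id == gid & g2c2$sample_id == sid))

  # fragmentation: contig count matches an RNG replay of the Poisson draws
  cfg3 <- simConfig(nPools = 1L, strainsPerPool = 3L, nBackgroundPhages = 8L,
                    nHostFragments = 2L, nPlantedPairs = 1L,
                    fragmentationRate = 2, detectionFloor = 0,
                    genomeLengthRange = c(30000, 40000),
                    hostLengthRange = c(20000, 30000), seed = 13L)
  g3 <- simulateGenomes(cfg3)
  ab3 <- simulateAbundances(cfg3, g3$truth, g3$sampleSheet)
  fc3 <- fragmentContigs(g3$genomes, ab3, g3$truth, cfg3)
  set.seed(phageome:::.stageSeed(cfg3@seed, 3L))
  lens <- genomeInfo(g3$truth)$length
  names(lens) <- genomeInfo(g3$truth)$genome_id
  expected <- 0L
  for (s in colnames(ab3)) {
    for (gid in rownames(ab3)[ab3[, s] >= cfg3@detectionFloor]) {
      nb <- rpois(1, cfg3@fragmentationRate)
      bounds <- if (nb > 0 && lens[gid] > nb + 1)
        c(0L, sort(sample.int(lens[gid] - 1L, nb)), lens[gid])
      else c(0L, lens[gid])
      expected <- expected + sum(diff(bounds) >= 1000L)
    }
  }
  expect_equal(length(fc3$contigs), expected)
})

test_that("read simulation is exact at zero error and tracks abundance", {
  genomes <- Biostrings::DNAStringSet(c(gA = rndSeq(4000),
                                        gB = circularSeq(4000)))
  S4Vectors::mcols(genomes) <- S4Vectors::DataFrame(
    circular = c(FALSE, TRUE), terminal_repeat_len = c(0L, 55L))
  ab <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(names(genomes), "s1"))
  cfg <- simConfig(readsPerSample = 50000L, readLength = 100L,
                   readErrorRate = 0, seed = 3L)
  reads <- simulateReads(genomes, ab, cfg, samples = "s1")[["s1"]]
  src <- S4Vectors::mcols(reads)$source_genome
  # every error-free read is a substring of its genome (circular wrap ok)
  templates <- c(gA = as.character(genomes[["gA"]]),
                 gB = paste0(substr(as.character(genomes[["gB"]]), 1, 3945),
                             substr(as.character(genomes[["gB"]]), 1, 150)))
  idx <- sample.int(length(reads), 200)
  for (i in idx)
    expect_true(grepl(as.character(reads[[i]]), templates[[src[i]]],
                      fixed = TRUE))
  # source counts within 3 SD of Binomial(n, 0.9 * w / (0.9 w + 0.1 w'))
  w <- ab[, 1] * Biostrings::width(genomes)
  p <- w[1] / sum(w)
  n <- length(reads)
  expect_lt(abs(sum(src == "gA") - n * p), 3 * sqrt(n * p * (1 - p)))
  expect_error(simulateReads(genomes, ab,
                             simConfig(readLength = 5000L, seed = 1L),
                             samples = "s1"),
               "shortest genome")
})

test_that("evidence simulation separates phages from host-fragment decoys", {
  cfg <- simConfig(nPools = 1L, strainsPerPool = 5L,
                   nBackgroundPhages = 400L, nHostFragments = 150L,
                   nPlantedPairs = 0L,
                   genomeLengthRange = c(10000, 10000),
                   hostLengthRange = c(10000, 10000), seed = 17L)
  g <- simulateGenomes(cfg)
  ev <- simulateEvidence(g$genomes, g$truth, cfg)
  info <- genomeInfo(g$truth)
  host <- ev[info$type == "host_fragment", ]
  phage <- ev[info$type != "host_fragment", ]
  dens_host <- pvogDensity(host$pvog_hits, host$length)
  dens_phage <- pvogDensity(phage$pvog_hits, phage$length)
  # decoys: Poisson(0.5) on 10 kb, median far below the 3/10 kb threshold
  expect_lt(median(dens_host), 3)
  # true phages at mean 6/10 kb clear the threshold with P = 1-ppois(2, 6)
  expect_gt(mean(dens_phage >= 3), 0.88)
  # forced flags short-circuit classification for every contig
  evf <- classifyViral(simulateEvidence(g$genomes, g$truth, cfg,
                                        forceFlags = TRUE))
  expect_true(all(evf$viral))
})
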