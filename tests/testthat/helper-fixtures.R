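# Shared fixture builders; everything is generated in code under fixed seeds.

rndSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# many random sequences at once (column-wise paste of a base matrix)
rndSeqs <- function(count, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), count * len, replace = TRUE),
              nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

mutateSeq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

circularSeq <- function(totalLen, tr = 55L) {
  core <- rndSeq(totalLen - tr)
  paste0(core, substr(core, 1L, tr))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# small but z-capable experiment: one pool of 20 strains
tinyConfig <- function(...) {
  simConfig(nPools = 1L, strainsPerPool = 20L, nBackgroundPhages = 30L,
            nHostFragments = 5L, nPlantedPairs = 2L,
            genomeLengthRange = c(12000, 20000),
            hostLengthRange = c(2000, 12000),
            readsPerSample = 2000L, seed = 11L, ...)
}

# sample sheet for hand-built proportion matrices: one pool, last column
# optionally a baseline
toySheet <- function(samples, pool = "A", baseline = NULL,
                     taxa = "Escherichia coli") {
  sheet <- data.frame(sample_id = samples, pool_id = pool,
                      strain_id = samples,
                      strain_taxon = rep_len(taxa, length(samples)),
                      sample_type = "enriched", stringsAsFactors = FALSE)
  if (!is.null(baseline)) {
    sheet <- rbind(sheet, data.frame(
      sample_id = baseline, pool_id = pool, strain_id = NA_character_,
      strain_taxon = NA_character_, sample_type = "pool_baseline"))
  }
  sheet
}

# eight-representative cascade toy: exactly three pass, each reject fails
# a known step
toyCascade <- function() {
  ids <- c("pass_ext", "pass_dens", "pass_circ", "fail_z", "fail_ab",
           "fail_vir", "fail_len", "fail_base")
  samples <- c(sprintf("e%02d", 1:20), "base")
  pr <- matrix(1e-4, length(ids), 21, dimnames = list(ids, samples))
  spike <- function(m, id, s, v) { m[id, s] <- v; m }
  pr <- spike(pr, "pass_ext", "e01", 0.30)
  pr <- spike(pr, "pass_dens", "e02", 0.05)
  pr <- spike(pr, "pass_circ", "e03", 0.20)
  pr["fail_z", ] <- 0.02                       # constant: z = 0 everywhere
  pr <- spike(pr, "fail_ab", "e05", 0.005)     # z passes, abundance < 1%
  pr["fail_ab", setdiff(samples, "e05")] <- 1e-6
  pr <- spike(pr, "fail_vir", "e06", 0.15)
  pr <- spike(pr, "fail_len", "e07", 0.12)
  pr <- spike(pr, "fail_base", "base", 0.25)   # enriched only in baseline
  ev <- data.frame(
    representative_id = ids,
    pvog_hits = c(0L, 8L, 0L, 5L, 5L, 0L, 0L, 5L),
    external_viral_flag = c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L),
    db_hit_flag = c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),  # db alone: not enough
    length = c(20000L, 16000L, 12000L, 15000L, 15000L, 15000L, 9999L,
               15000L),
    circular = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  sheet <- toySheet(sprintf("e%02d", 1:20), baseline = "base")
  list(pr = pr, ev = ev, sheet = sheet)
}
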