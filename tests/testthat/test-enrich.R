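# Hand-computable Z-score fixtures ----------------------------------------

test_that("pool z-scores reproduce direct arithmetic", {
  # constant abundance: zero deviation everywhere
  prc <- matrix(0.02, 1, 4, dimnames = list("r", paste0("s", 1:4)))
  rec <- suppressWarnings(poolZscores(prc, toySheet(paste0("s", 1:4))))
  expect_equal(rec$zscore, rep(0, 4))

  # (0.01, 0.01, 0.01, 0.25): focal z = 0.18 / 0.12 = 1.5 with n-1 SD
  pr <- matrix(c(0.01, 0.01, 0.01, 0.25), 1, 4,
               dimnames = list("r", paste0("s", 1:4)))
  rec <- suppressWarnings(poolZscores(pr, toySheet(paste0("s", 1:4))))
  expect_equal(rec$zscore[rec$sample_id == "s4"], 1.5, tolerance = 1e-12)
  # z = 4 is unattainable in a pool this small: the tool must warn
  expect_warning(poolZscores(pr, toySheet(paste0("s", 1:4))),
                 "unattainable")

  # single presence at 0.30 in a 20-sample pool: z from first principles
  v <- c(0.30, rep(0, 19))
  pr20 <- matrix(v, 1, 20, dimnames = list("r", sprintf("e%02d", 1:20)))
  sheet20 <- toySheet(sprintf("e%02d", 1:20))
  rec <- poolZscores(pr20, sheet20)
  zexp <- (0.30 - mean(v)) / sd(v)
  expect_equal(max(rec$zscore), zexp, tolerance = 1e-12)
  expect_gt(zexp, 4)
  expect_true(rec$passes_z[which.max(rec$zscore)])
})

test_that("zero-variance pools hit the documented sentinels", {
  pr <- matrix(c(0.1, 0.1, 0.1, 0.4), 1, 4,
               dimnames = list("r", paste0("s", 1:4)))
  rec <- suppressWarnings(poolZscores(pr, toySheet(paste0("s", 1:4)),
                                      leaveOneOut = TRUE))
  # leaving out the outlier makes the rest constant: +Inf sentinel passes
  expect_equal(rec$zscore[rec$sample_id == "s4"], Inf)
  expect_true(rec$passes_z[rec$sample_id == "s4"])
  expect_true(all(rec$zscore[rec$sample_id != "s4"] < 0))
  expect_error(poolZscores(pr[, 1, drop = FALSE], toySheet("s1")),
               "fewer than 2")
})

test_that("z-scores match the naive two-pass oracle on random matrices", {
  set.seed(71)
  for (i in 1:10) {
    nr <- sample(5:60, 1)
    ns <- sample(6:25, 1)
    mat <- matrix(runif(nr * ns), nr, ns,
                  dimnames = list(sprintf("r%03d", seq_len(nr)),
                                  sprintf("s%03d", seq_len(ns))))
    pools <- sample(c("A", "B"), ns, replace = TRUE)
    pools[1:4] <- c("A", "A", "B", "B")   # both pools always usable
    sheet <- data.frame(sample_id = colnames(mat), pool_id = pools,
                        strain_id = colnames(mat), strain_taxon = "G x",
                        sample_type = "enriched")
    rec <- suppressWarnings(poolZscores(mat, sheet))
    zo <- naiveZ(mat, sheet)
    zgot <- zo
    zgot[cbind(rec$representative_id, rec$sample_id)] <- rec$zscore
    expect_lt(max(abs(zgot - zo), na.rm = TRUE), 1e-12)
  }
})

test_that("baselines enter pool statistics but never the existentials", {
  # spike lives in the baseline only: z-passes are ineligible
  pr <- matrix(c(rep(1e-4, 20), 0.30), 1, 21,
               dimnames = list("r", c(sprintf("e%02d", 1:20), "base")))
  sheet <- toySheet(sprintf("e%02d", 1:20), baseline = "base")
  rec <- poolZscores(pr, sheet)
  expect_gt(rec$zscore[rec$sample_id == "base"], 4)
  ev <- data.frame(representative_id = "r", pvog_hits = 6L,
                   external_viral_flag = 1L, db_hit_flag = 0L,
                   length = 15000L, circular = FALSE)
  rep <- shortlist(rec, ev)
  expect_equal(nrow(candidates(rep)), 0L)
  expect_identical(rejected(rep)$rejection_reason, "zscore")
  # excluding the baseline from pool statistics is available as an option
  rec2 <- poolZscores(pr, sheet, includeBaseline = FALSE)
  expect_false("base" %in% rec2$sample_id)
})

# The cascade on a constructed toy (built in helper-fixtures.R) ------------

test_that("the three-step cascade passes and rejects by design", {
  toy <- toyCascade()
  for (loo in c(FALSE, TRUE)) {
    rec <- poolZscores(toy$pr, toy$sheet, leaveOneOut = loo)
    rep <- shortlist(rec, toy$ev)
    expect_setequal(candidates(rep)$representative_id,
                    c("pass_ext", "pass_dens", "pass_circ"))
    rej <- rejected(rep)
    want <- c(fail_z = "zscore", fail_ab = "abundance",
              fail_vir = "viral_evidence", fail_len = "length",
              fail_base = "zscore")
    expect_identical(
      setNames(rej$rejection_reason, rej$representative_id)[names(want)],
      want)
  }
  # reasons recorded for the passing candidates re-verify
  rec <- poolZscores(toy$pr, toy$sheet)
  rep <- shortlist(rec, toy$ev)
  cand <- candidates(rep)
  expect_identical(cand$viral_reasons[cand$representative_id == "pass_circ"],
                   "circular")
  expect_identical(cand$viral_reasons[cand$representative_id == "pass_dens"],
                   "pvog_density")
  # mismatched id sets are a hard error naming the orphans
  expect_error(shortlist(rec, toy$ev[-1, ]), "pass_ext")
})

test_that("cascade is monotone in its thresholds", {
  toy <- toyCascade()
  rec <- poolZscores(toy$pr, toy$sheet)
  strict <- candidates(shortlist(rec, toy$ev))$representative_id
  for (args in list(list(zMin = 3), list(abundanceMin = 0.004),
                    list(lengthMin = 9000L))) {
    rec2 <- poolZscores(toy$pr, toy$sheet,
                        zMin = if (is.null(args$zMin)) 4 else args$zMin,
                        abundanceMin = if (is.null(args$abundanceMin)) 0.01
                        else args$abundanceMin)
    loose <- candidates(do.call(shortlist, c(list(rec2, toy$ev), args)))
    expect_true(all(strict %in% loose$representative_id))
  }
})

test_that("host links and curation flags follow the qualifying samples", {
  # two co-enriched strains need a larger pool: with two equal spikes the
  # attainable z tops out near sqrt(n/2)
  samples <- sprintf("e%02d", 1:40)
  pr <- matrix(1e-5, 2, 40, dimnames = list(c("one", "two"), samples))
  pr["one", "e01"] <- 0.30
  pr["two", c("e02", "e03")] <- 0.25
  sheet <- toySheet(samples,
                    taxa = c("Escherichia coli K12",
                             "Bacteroides fragilis X1",
                             "Bacteroides fragilis X2",
                             rep("Blautia sp. Y", 37)))
  rec <- poolZscores(pr, sheet)
  ev <- data.frame(representative_id = c("one", "two"),
                   pvog_hits = c(8L, 8L), external_viral_flag = c(1L, 1L),
                   db_hit_flag = c(0L, 0L), length = c(15000L, 15000L),
                   circular = c(FALSE, FALSE))
  rep <- shortlist(rec, ev)
  links <- linkHosts(rep, rec)
  expect_equal(nrow(links[links$representative_id == "one", ]), 1L)
  expect_identical(links$strain_id[links$representative_id == "one"], "e01")
  # two qualifying same-genus strains: two rows, no ambiguity flag
  expect_equal(nrow(links[links$representative_id == "two", ]), 2L)
  rep <- suppressMessages(flagCuration(rep, rec))
  flags <- setNames(candidates(rep)$curation_flags,
                    candidates(rep)$representative_id)
  expect_identical(unname(flags["two"]), "")

  # different genera across qualifying samples: ambiguous
  pr2 <- pr
  pr2["two", "e01"] <- 0.25
  pr2["two", "e02"] <- 0.25
  pr2["two", "e03"] <- 1e-5
  rec2 <- poolZscores(pr2, sheet)
  rep2 <- suppressMessages(flagCuration(shortlist(rec2, ev), rec2))
  flags2 <- setNames(candidates(rep2)$curation_flags,
                     candidates(rep2)$representative_id)
  expect_identical(unname(flags2["two"]), "multi_taxon_ambiguous")
})

test_that("verbatim host-genome slices are flagged as possible fragments", {
  set.seed(81)
  host <- rndSeq(30000)
  repseq <- Biostrings::DNAStringSet(c(frag = substr(host, 5000, 17000),
                                       phage = rndSeq(12000)))
  samples <- sprintf("e%02d", 1:20)
  pr <- matrix(1e-5, 2, 20, dimnames = list(names(repseq), samples))
  pr["frag", "e01"] <- 0.3
  pr["phage", "e02"] <- 0.3
  sheet <- toySheet(samples)
  rec <- poolZscores(pr, sheet)
  ev <- data.frame(representative_id = names(repseq),
                   pvog_hits = c(6L, 6L), external_viral_flag = c(1L, 1L),
                   db_hit_flag = c(0L, 0L),
                   length = Biostrings::width(repseq),
                   circular = c(FALSE, FALSE))
  rep <- shortlist(rec, ev)
  rep <- flagCuration(rep, rec, representativeSeqs = repseq,
                      hostGenomes = Biostrings::DNAStringSet(c(h = host)))
  flags <- setNames(candidates(rep)$curation_flags,
                    candidates(rep)$representative_id)
  expect_identical(unname(flags["frag"]), "possible_host_fragment")
  expect_identical(unname(flags["phage"]), "")
  # absent host genomes: skipped with a notice, never an error
  expect_message(flagCuration(rep, rec), "skipped")
})

test_that("recovery scoring joins links against the planted truth", {
  truth <- new("GroundTruth",
               plantedPairs = data.frame(
                 genome_id = c("g1", "g2"), strain_id = c("s1", "s2"),
                 pool_id = "A", sample_id = c("s1", "s2")),
               genomeInfo = data.frame(), genomeToContigs = data.frame(),
               expectedEnriched = data.frame())
  links <- data.frame(representative_id = c("c1", "c1", "c3"),
                      pool_id = "A", sample_id = c("s1", "s1", "s9"),
                      strain_id = c("s1", "s1", "s9"),
                      strain_taxon = "G x", zscore = 5,
                      relative_abundance = 0.2)
  st <- recoveryStats(links, truth,
                      repToGenome = c(c1 = "g1", c3 = "g9"))
  expect_equal(st$sensitivity, 0.5)
  expect_equal(st$fdp, 0.5)
  expect_equal(st$n_true, 1L)
  expect_equal(st$n_false, 1L)
})
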