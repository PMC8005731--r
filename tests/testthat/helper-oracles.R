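# Independent oracles kept deliberately naive.

# exact identity/overlap from full dynamic-programming local alignment,
# best of both strands; overlap measured on the shorter sequence
alignIdentityOverlap <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  score1 <- function(x, y) {
    Biostrings::pairwiseAlignment(x, y, type = "local",
                                  substitutionMatrix = sm,
                                  gapOpening = 5, gapExtension = 2)
  }
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln_f <- score1(a, b)
  aln_r <- score1(revcomp(a), b)
  aln <- if (Biostrings::score(aln_f) >= Biostrings::score(aln_r)) aln_f
  else aln_r
  pat <- Biostrings::pattern(aln)
  span <- Biostrings::end(pat) - Biostrings::start(pat) + 1
  ident <- Biostrings::pid(aln, type = "PID1") / 100
  c(identity = ident, overlap = span / nchar(a))
}

# greedy longest-first clustering with alignment-based thresholds; the same
# algorithm as the k-mer path but with exact measures
greedyOracleCluster <- function(seqs, minIdentity = 0.90, minOverlap = 0.90) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  assign <- character(length(seqs))
  names(assign) <- names(seqs)
  for (id in names(seqs)) {
    joined <- NA_character_
    for (r in reps) {
      m <- alignIdentityOverlap(seqs[[id]], seqs[[r]])
      if (m["identity"] >= minIdentity && m["overlap"] >= minOverlap) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, id)
      assign[id] <- id
    } else {
      assign[id] <- joined
    }
  }
  assign
}

# partition of member ids by representative, order-free comparable
partitionOf <- function(assign) {
  unname(lapply(split(names(assign), assign), sort))
}

# naive two-pass per-pool z-scores: explicit loops, mean() and sd()
naiveZ <- function(mat, sheet, includeBaseline = TRUE) {
  keep <- sheet$sample_type != "blank" &
    (includeBaseline | sheet$sample_type != "pool_baseline")
  z <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (p in unique(sheet$pool_id[keep & !is.na(sheet$pool_id)])) {
    cols <- which(keep & sheet$pool_id == p)
    for (r in seq_len(nrow(mat))) {
      v <- mat[r, cols]
      m <- mean(v)
      s <- sd(v)
      for (j in cols) {
        z[r, j] <- if (s == 0) {
          if (mat[r, j] > m) Inf else if (mat[r, j] < m) -Inf else 0
        } else (mat[r, j] - m) / s
      }
    }
  }
  z
}

# mean silhouette width over the first ordination axes
meanSilhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
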