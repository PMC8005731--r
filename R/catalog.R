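# Contig catalogue: pooling, circularity detection, dereplication.

#' Detect a terminal direct repeat (assembly-style circularity)
#'
#' Searches for the longest exact prefix that equals a suffix, from
#' `min(floor(length/2), 2000)` bp downward. A sequence is called circular
#' when the repeat reaches `minRepeat`; the trimmed length (with the repeat
#' removed once) is what downstream length thresholds use. A homopolymer
#' trivially matches at the capped search length; this degenerate behaviour
#' is by definition of the detector.
#'
#' @param x a character vector or `DNAStringSet` of sequences.
#' @param minRepeat minimum exact repeat length to call circularity
#'   (default 20 bp).
#' @return data.frame with columns `circular`, `repeat_length`,
#'   `trimmed_length` (one row per sequence).
#' @examples
#' core <- paste(rep("ACGT", 500), collapse = "")
#' circ <- paste0(core, substr(core, 1, 55))
#' detectTerminalRepeat(circ)
#' @export
detectTerminalRepeat <- function(x, minRepeat = 20L) {
  if (is(x, "DNAStringSet") || is(x, "DNAString")) x <- as.character(x)
  stopifnot(is.character(x))
  if (any(!nzchar(x))) stop("sequences must be non-empty")
  if (minRepeat < 1) stop("minRepeat must be >= 1")
  rep_len <- vapply(unname(x), .cpp_terminal_repeat,
                    integer(1), min_repeat = as.integer(minRepeat))
  circ <- rep_len >= minRepeat
  data.frame(circular = circ, repeat_length = as.integer(rep_len),
             trimmed_length = nchar(x) - as.integer(rep_len),
             row.names = if (!is.null(names(x))) names(x) else NULL)
}

#' Estimate pairwise identity and overlap from shared k-mers
#'
#' Canonical (strand-collapsed) k-mers of the shorter sequence are located
#' in the longer one; runs of shared k-mers (gaps up to `bridgeGap` bases
#' bridged) define the shared region. `overlap` is the fraction of the
#' shorter sequence covered by that region; `identity` is the per-base
#' identity within it, inverted from the k-mer survival rate as
#' `containment^(1/k)`. Symmetric in input order.
#'
#' @param a,b sequences (character or `DNAString`).
#' @param k k-mer size (8..31; the estimator breaks down below 8).
#' @param bridgeGap maximum gap (bp) bridged between shared-k-mer runs.
#' @return named numeric vector `c(identity, overlap)`.
#' @examples
#' a <- paste(sample(c("A","C","G","T"), 3000, TRUE), collapse = "")
#' pairwiseContainment(substr(a, 101, 1600), a)
#' @export
pairwiseContainment <- function(a, b, k = 21L, bridgeGap = 250L) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (k < 8) stop("k < 8 rejected: containment estimator breaks down")
  if (k > 31) stop("k must be <= 31")
  if (k > min(nchar(a), nchar(b)))
    stop("k exceeds the shorter sequence length")
  .cpp_containment(a, b, as.integer(k), as.integer(bridgeGap))
}

#' Remove contigs at or below a minimum length
#'
#' Strictly-greater-than filter on the untrimmed length (a 1000 bp contig is
#' excluded at `minLen = 1000`).
#'
#' @param contigs a `DNAStringSet`.
#' @param minLen length threshold in bp (default 1000).
#' @return the filtered `DNAStringSet`.
#' @export
filterMinLength <- function(contigs, minLen = 1000L) {
  stopifnot(is(contigs, "DNAStringSet"))
  contigs[width(contigs) > minLen]
}

#' Dereplicate pooled contigs into a representative database
#'
#' Greedy longest-first clustering: contigs are sorted by decreasing length
#' (ties lexicographically by id) and each joins the first existing cluster
#' whose representative reaches both the identity and overlap thresholds
#' (estimated from canonical k-mer containment, so reverse-complement
#' duplicates collapse); otherwise it founds a new cluster. Representatives
#' are therefore always the longest members.
#'
#' @param contigs a named `DNAStringSet` (ids must be unique); an
#'   `origin_sample` column in `mcols` is propagated.
#' @param minIdentity,minOverlap clustering thresholds (default 0.90/0.90).
#' @param k k-mer size for the containment estimate.
#' @param bridgeGap see [pairwiseContainment()].
#' @return a [ContigClusters-class].
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 5000, TRUE), collapse = "")
#' cs <- Biostrings::DNAStringSet(c(big = s, small = substr(s, 1000, 3500)))
#' dereplicate(cs)
#' @export
dereplicate <- function(contigs, minIdentity = 0.90, minOverlap = 0.90,
                        k = 21L, bridgeGap = 250L) {
  stopifnot(is(contigs, "DNAStringSet"))
  if (k < 8) stop("k < 8 rejected: containment estimator breaks down")
  if (length(contigs) == 0) {
    return(new("ContigClusters",
               members = data.frame(member_id = character(0),
                                    representative_id = character(0),
                                    identity = numeric(0),
                                    overlap = numeric(0),
                                    origin_sample = character(0),
                                    length = integer(0),
                                    stringsAsFactors = FALSE),
               representatives = DNAStringSet()))
  }
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must carry unique names")
  ord <- order(-width(contigs), names(contigs))
  sorted <- contigs[ord]
  res <- .cpp_greedy_cluster(as.character(sorted), as.integer(k),
                             minIdentity, minOverlap, as.integer(bridgeGap))
  origin <- mcols(contigs)$origin_sample
  if (is.null(origin)) origin <- rep(NA_character_, length(contigs))
  members <- data.frame(
    member_id = names(sorted),
    representative_id = names(sorted)[res$representative],
    identity = res$identity,
    overlap = res$overlap,
    origin_sample = origin[ord],
    length = width(sorted),
    stringsAsFactors = FALSE)
  reps <- sorted[unique(res$representative)]
  new("ContigClusters", members = members, representatives = reps)
}

#' Read per-sample contig FASTA files from a directory
#'
#' Each `*.fasta`/`*.fa` file is one sample; the file stem is used as the
#' sample id, injected into `mcols(x)$origin_sample`, and contig ids are
#' prefixed with it when not already unique.
#'
#' @param dir directory of per-sample multi-FASTA files.
#' @return a `DNAStringSet` with `origin_sample` metadata.
#' @export
readContigDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files found in ", dir)
  sets <- lapply(files, function(f) {
    x <- readDNAStringSet(f)
    sid <- sub("\\.(fasta|fa)$", "", basename(f))
    names(x) <- sub(" .*", "", names(x))
    mcols(x) <- DataFrame(origin_sample = rep(sid, length(x)))
    x
  })
  out <- do.call(c, sets)
  if (anyDuplicated(names(out)))
    names(out) <- paste0(mcols(out)$origin_sample, "|", names(out))
  out
}
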