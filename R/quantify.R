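# Read assignment and relative-abundance quantification.

#' Assign reads to representatives by shared canonical k-mers
#'
#' Each read is assigned to the representative sharing the largest number of
#' its distinct canonical k-mers, provided that share reaches `minKmerFrac`
#' of the read's k-mers; ties break toward the longer representative, then
#' lexicographically by id. Reads matching nothing are counted unassigned.
#'
#' @param reads a `DNAStringSet`, or a named list of them (one per sample).
#' @param representatives a named `DNAStringSet` (the dereplicated
#'   database).
#' @param k k-mer size (default 21).
#' @param minKmerFrac minimum shared fraction of the read's k-mers
#'   (default 0.5; balances ~1% sequencing error against chance hits).
#' @return list with `counts` (integer matrix, representatives x samples)
#'   and `unassigned` (integer vector per sample).
#' @export
assignReads <- function(reads, representatives, k = 21L, minKmerFrac = 0.5) {
  if (is(reads, "DNAStringSet")) reads <- list(sample = reads)
  stopifnot(is.list(reads), is(representatives, "DNAStringSet"))
  if (length(representatives) == 0) {
    warning("empty representative database: all reads unassigned")
    cnt <- matrix(0L, 0, length(reads),
                  dimnames = list(NULL, names(reads)))
    return(list(counts = cnt,
                unassigned = vapply(reads, length, integer(1))))
  }
  ord <- order(-width(representatives), names(representatives))
  reps <- representatives[ord]
  cnt <- matrix(0L, length(reps), length(reads),
                dimnames = list(names(reps), names(reads)))
  unassigned <- setNames(integer(length(reads)), names(reads))
  for (s in names(reads)) {
    rs <- reads[[s]]
    if (any(width(rs) < k))
      stop("sample ", s, ": reads shorter than k = ", k)
    a <- .cpp_assign_reads(as.character(rs), as.character(reps),
                           as.integer(k), minKmerFrac)
    tab <- tabulate(a[a > 0], nbins = length(reps))
    cnt[, s] <- tab
    unassigned[s] <- sum(a == 0)
  }
  # restore the caller's representative order
  cnt <- cnt[names(representatives), , drop = FALSE]
  list(counts = cnt, unassigned = unassigned)
}

#' Convert read counts to relative-abundance proportions
#'
#' The default denominator is the whole sample - assigned plus unassigned
#' reads - so representative proportions plus the unassigned fraction sum to
#' one; `denominator = "assigned"` restricts it to assigned reads.
#'
#' @param counts integer matrix (representatives x samples).
#' @param unassigned integer vector of unassigned reads per sample
#'   (default 0).
#' @param denominator `"total"` (default) or `"assigned"`.
#' @return numeric matrix of proportions; all-zero samples give an all-zero
#'   column with a warning.
#' @examples
#' relativeAbundance(cbind(s1 = c(a = 50, b = 30)), unassigned = c(s1 = 20))
#' @export
relativeAbundance <- function(counts, unassigned = 0,
                              denominator = c("total", "assigned")) {
  denominator <- match.arg(denominator)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(unassigned) == 1) unassigned <- rep(unassigned, ncol(counts))
  tot <- colSums(counts) + if (denominator == "total") unassigned else 0
  if (any(tot == 0)) {
    warning("sample(s) with zero reads: ",
            paste(colnames(counts)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  sweep(counts, 2, tot, "/")
}

#' Assemble a ViromeExperiment container
#'
#' Bundles counts, proportions, the sample sheet and (optionally
#' classified) evidence into a [ViromeExperiment-class].
#'
#' @param counts integer matrix (representatives x samples).
#' @param sheet sample sheet data.frame with `sample_id`, `pool_id`,
#'   `strain_id`, `strain_taxon`, `sample_type` covering every count column.
#' @param evidence optional evidence data.frame (joined by
#'   `representative_id` into `rowData`).
#' @param unassigned integer vector of unassigned reads per sample.
#' @return a [ViromeExperiment-class].
#' @export
viromeExperiment <- function(counts, sheet, evidence = NULL, unassigned = 0) {
  if (length(unassigned) == 1)
    unassigned <- setNames(rep(unassigned, ncol(counts)), colnames(counts))
  m <- match(colnames(counts), sheet$sample_id)
  if (anyNA(m)) stop("samples missing from the sheet: ",
                     paste(colnames(counts)[is.na(m)], collapse = ", "))
  cd <- DataFrame(sheet[m, setdiff(names(sheet), "sample_id"), drop = FALSE],
                  unassigned = as.integer(unassigned[colnames(counts)]),
                  row.names = colnames(counts))
  props <- relativeAbundance(counts, unassigned[colnames(counts)])
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(evidence)) {
    em <- match(rownames(counts), evidence$representative_id)
    if (anyNA(em)) stop("representatives missing from evidence: ",
                        paste(rownames(counts)[is.na(em)], collapse = ", "))
    rd <- DataFrame(evidence[em, setdiff(names(evidence),
                                         "representative_id"),
                             drop = FALSE],
                    row.names = rownames(counts))
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts, proportions = props),
    colData = cd, rowData = rd)
  new("ViromeExperiment", se)
}

#' Per-sample fraction of reads on viral representatives
#'
#' @param x a [ViromeExperiment-class] (with a `viral` rowData column), or a
#'   proportions matrix.
#' @param viral logical vector of viral flags (required for a matrix).
#' @return named numeric vector of per-sample viral fractions.
#' @export
viralFraction <- function(x, viral = NULL) {
  if (is(x, "ViromeExperiment")) {
    if (is.null(viral)) viral <- rowData(x)$viral
    x <- assay(x, "proportions")
  }
  if (is.null(viral)) stop("viral flags are required")
  stopifnot(length(viral) == nrow(x))
  colSums(x[viral, , drop = FALSE])
}

#' Read a precomputed counts TSV
#'
#' Long format with columns `representative_id`, `sample_id`, `count` - the
#' substitution path for any external aligner producing primary-assignment
#' counts.
#'
#' @param path TSV file path.
#' @return integer matrix (representatives x samples).
#' @export
readCountsTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("representative_id", "sample_id", "count")
  if (!all(need %in% names(d)))
    stop("counts table lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  reps <- sort(unique(d$representative_id))
  samp <- sort(unique(d$sample_id))
  m <- matrix(0L, length(reps), length(samp), dimnames = list(reps, samp))
  m[cbind(match(d$representative_id, reps), match(d$sample_id, samp))] <-
    as.integer(d$count)
  m
}
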