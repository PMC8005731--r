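# Viral-origin classification from an evidence table.

#' pVOG density per 10 kb of contig length
#'
#' @param pvogHits non-negative hit count(s).
#' @param length contig length(s) in bp (must be >= 1).
#' @return numeric vector of hits per 10 kb: `pvogHits * 10000 / length`.
#' @examples
#' pvogDensity(6, 20000)   # 3 per 10 kb
#' pvogDensity(3, 10000)   # exactly at the classification threshold
#' @export
pvogDensity <- function(pvogHits, length) {
  if (any(length < 1)) stop("length must be >= 1")
  if (any(pvogHits < 0)) stop("pvogHits must be >= 0")
  pvogHits * 1e4 / length
}

#' Classify representatives as viral from the union of evidence criteria
#'
#' A representative is called viral when any enabled criterion holds:
#' a match to viral reference databases, an external (VirSorter-style) viral
#' call, a pVOG density of at least `minPvogDensity` per 10 kb, or
#' circularity. The discovery-stage rule uses all four; the shortlist
#' cascade's variant disables the database criterion (`useDbHit = FALSE`).
#' The 10 kb minimum-length rule is *not* applied here; it belongs to the
#' shortlist cascade. Adding evidence can only ever add reasons, never flip
#' a call to non-viral.
#'
#' @param evidence data.frame with columns `representative_id`, `pvog_hits`,
#'   `external_viral_flag`, `db_hit_flag`, `length`, `circular`.
#' @param minPvogDensity density threshold (default 3 per 10 kb).
#' @param useDbHit,useExternal,usePvog,useCircular per-criterion switches.
#' @return the input data.frame with added columns `viral` (logical) and
#'   `reasons` (comma-separated satisfied criteria; empty when none).
#' @examples
#' ev <- data.frame(representative_id = c("a", "b"),
#'                  pvog_hits = c(0L, 2L),
#'                  external_viral_flag = c(0L, 1L),
#'                  db_hit_flag = c(0L, 0L),
#'                  length = c(5000L, 10000L),
#'                  circular = c(TRUE, FALSE))
#' classifyViral(ev)[, c("viral", "reasons")]
#' @export
classifyViral <- function(evidence, minPvogDensity = 3.0,
                          useDbHit = TRUE, useExternal = TRUE,
                          usePvog = TRUE, useCircular = TRUE) {
  need <- c("representative_id", "pvog_hits", "external_viral_flag",
            "db_hit_flag", "length", "circular")
  if (!all(need %in% names(evidence)))
    stop("evidence table lacks columns: ",
         paste(setdiff(need, names(evidence)), collapse = ", "))
  dens <- pvogDensity(evidence$pvog_hits, evidence$length)
  crit <- cbind(
    db_hit = useDbHit & evidence$db_hit_flag > 0,
    external_flag = useExternal & evidence$external_viral_flag > 0,
    pvog_density = usePvog & dens >= minPvogDensity,
    circular = useCircular & as.logical(evidence$circular))
  evidence$pvog_density <- dens
  evidence$viral <- rowSums(crit) > 0
  evidence$reasons <- apply(crit, 1, function(r)
    paste(colnames(crit)[r], collapse = ","))
  evidence
}

#' Read an evidence TSV
#'
#' Expected columns: `representative_id`, `pvog_hits`,
#' `external_viral_flag` (0/1), `db_hit_flag` (0/1), and optionally
#' `length`, `circular`, `terminal_repeat_len`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readEvidenceTable <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("representative_id", "pvog_hits", "external_viral_flag",
            "db_hit_flag")
  if (!all(need %in% names(ev)))
    stop("evidence table lacks columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  if ("circular" %in% names(ev))
    ev$circular <- as.logical(ev$circular) |
      (is.character(ev$circular) & ev$circular %in% c("1", "TRUE", "true"))
  ev
}

#' Parse HMMER --tblout output into per-contig pVOG hit counts
#'
#' Format-only adapter for a profile search against a viral-orthologue
#' collection: hits with a full-sequence score of at least `minScore` are
#' kept, and by default distinct query families per target are counted
#' (set `distinctFamilies = FALSE` to count every hit).
#'
#' @param path HMMER tabular (`--tblout`) file.
#' @param minScore minimum full-sequence bit score.
#' @param distinctFamilies count distinct query profiles per target.
#' @return data.frame with columns `representative_id`, `pvog_hits`.
#' @export
readHmmerTblout <- function(path, minScore = 0, distinctFamilies = TRUE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(representative_id = character(0),
                      pvog_hits = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "[[:space:]]+")
  target <- vapply(fields, `[`, character(1), 1L)
  query <- vapply(fields, `[`, character(1), 3L)
  score <- as.numeric(vapply(fields, `[`, character(1), 6L))
  keep <- !is.na(score) & score >= minScore
  target <- target[keep]; query <- query[keep]
  if (distinctFamilies) {
    dup <- duplicated(paste(target, query))
    target <- target[!dup]
  }
  tab <- table(target)
  data.frame(representative_id = names(tab),
             pvog_hits = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
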