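# Sample-level summaries and ordination.

#' Spearman-correlation distance between samples
#'
#' Spearman's rank correlation between per-sample abundance vectors (ties
#' mid-ranked), mapped to a distance by `d = (1 - rho) / 2`, so identical
#' rankings give 0 and perfectly reversed rankings give 1. Restricted to
#' viral representatives by default. A constant (zero-variance) sample
#' vector has undefined correlation; its distances are set to 0.5 with a
#' warning.
#'
#' @param x a [ViromeExperiment-class] or a proportions matrix
#'   (representatives x samples).
#' @param viralOnly restrict to viral-flagged representatives.
#' @param viral logical flags (taken from `rowData` when `x` is a
#'   `ViromeExperiment`).
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
spearmanDistance <- function(x, viralOnly = TRUE, viral = NULL) {
  if (is(x, "ViromeExperiment")) {
    if (is.null(viral)) viral <- rowData(x)$viral
    x <- assay(x, "proportions")
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("at least 2 samples required")
  if (viralOnly) {
    if (is.null(viral)) stop("viral flags required when viralOnly = TRUE")
    x <- x[as.logical(viral), , drop = FALSE]
  }
  suppressWarnings(rho <- cor(x, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant sample vector(s): undefined correlations set to ",
            "d = 0.5")
    rho[is.na(rho)] <- 0
  }
  d <- (1 - rho) / 2
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-D^2/2`, eigendecomposes, and keeps up to `nAxes` axes
#' with positive eigenvalues. Negative eigenvalues (non-Euclidean input)
#' are reported, not corrected.
#'
#' @param d square symmetric distance matrix with zero diagonal.
#' @param nAxes number of axes to retain (default 2).
#' @return a [PCoAOrdination-class].
#' @examples
#' d <- as.matrix(dist(cbind(c(0, 3, 0), c(0, 0, 4))))
#' ordCoordinates(runPCoA(d))
#' @export
runPCoA <- function(d, nAxes = 2L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  n <- nrow(d)
  ids <- if (!is.null(rownames(d))) rownames(d) else as.character(seq_len(n))
  k <- min(nAxes, n - 1)
  sc <- suppressWarnings(cmdscale(as.dist(d), k = k, eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  pts <- sc$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  keep <- seq_len(min(ncol(pts), sum(eig > 1e-12), nAxes))
  if (length(keep) == 0) {
    pts <- matrix(0, n, min(nAxes, 1),
                  dimnames = list(ids, "Axis1"))
    pe <- rep(0, ncol(pts))
  } else {
    pts <- pts[, keep, drop = FALSE]
    colnames(pts) <- paste0("Axis", keep)
    rownames(pts) <- ids
    pe <- eig[keep] / sum(eig[eig > 0])
  }
  new("PCoAOrdination", sampleIds = ids, coordinates = pts,
      eigenvalues = eig, proportionExplained = pe)
}

#' Per-sample composition table and run summary
#'
#' Per sample: the viral read fraction, the single most abundant
#' representative with its proportion, and how many representatives exceed
#' 1% relative abundance. The run summary totals representatives, viral
#' representatives, shortlist candidates and host links.
#'
#' @param x a [ViromeExperiment-class] with classified evidence in
#'   `rowData`.
#' @param report optional [ShortlistReport-class].
#' @param links optional host links from [linkHosts()].
#' @return list with `perSample` and `summary` data.frames.
#' @export
compositionSummary <- function(x, report = NULL, links = NULL) {
  stopifnot(is(x, "ViromeExperiment"))
  pr <- assay(x, "proportions")
  viral <- rowData(x)$viral
  vf <- if (!is.null(viral)) viralFraction(x) else rep(NA_real_, ncol(pr))
  top_i <- apply(pr, 2, which.max)
  perSample <- data.frame(
    sample_id = colnames(pr),
    pool_id = x$pool_id,
    sample_type = x$sample_type,
    viral_fraction = unname(vf),
    top_representative = rownames(pr)[top_i],
    top_proportion = pr[cbind(top_i, seq_len(ncol(pr)))],
    n_above_1pct = colSums(pr >= 0.01),
    stringsAsFactors = FALSE, row.names = NULL)
  summary <- data.frame(
    metric = c("samples", "representatives", "viral_representatives",
               "shortlist_candidates", "host_links"),
    value = c(ncol(pr), nrow(pr),
              if (!is.null(viral)) sum(viral) else NA_integer_,
              if (!is.null(report)) nrow(candidates(report)) else
                NA_integer_,
              if (!is.null(links)) nrow(links) else NA_integer_),
    stringsAsFactors = FALSE)
  list(perSample = perSample, summary = summary)
}

#' Scatter plot of the first two ordination axes
#'
#' @param ord a [PCoAOrdination-class].
#' @param sheet sample sheet supplying `pool_id` per sample.
#' @return a ggplot object.
#' @export
plotOrdination <- function(ord, sheet) {
  stopifnot(is(ord, "PCoAOrdination"))
  co <- ordCoordinates(ord)
  if (ncol(co) < 2) stop("need at least two retained axes to plot")
  df <- data.frame(sample_id = ord@sampleIds, x = co[, 1], y = co[, 2],
                   pool = sheet$pool_id[match(ord@sampleIds,
                                              sheet$sample_id)])
  pe <- 100 * ord@proportionExplained
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$pool)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2]),
                  colour = "Pool") +
    ggplot2::theme_minimal()
}

#' Stacked per-sample composition bars
#'
#' Samples ordered by decreasing viral fraction; the `nTop` most abundant
#' representatives are coloured individually, everything else is pooled.
#'
#' @param x a [ViromeExperiment-class].
#' @param nTop representatives to colour individually (default 12).
#' @return a ggplot object.
#' @export
plotComposition <- function(x, nTop = 12L) {
  stopifnot(is(x, "ViromeExperiment"))
  pr <- assay(x, "proportions")
  viral <- rowData(x)$viral
  ord <- order(-if (!is.null(viral)) viralFraction(x) else colSums(pr))
  top <- names(sort(rowSums(pr), decreasing = TRUE))[seq_len(min(nTop,
                                                                 nrow(pr)))]
  grp <- ifelse(rownames(pr) %in% top, rownames(pr), "other")
  agg <- rowsum(pr, grp)
  df <- data.frame(
    sample = factor(rep(colnames(pr)[ord], each = nrow(agg)),
                    levels = colnames(pr)[ord]),
    representative = rep(rownames(agg), ncol(agg)),
    proportion = as.vector(agg[, ord]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$proportion,
                                   fill = .data$representative)) +
    ggplot2::geom_col(width = 1, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Relative abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
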