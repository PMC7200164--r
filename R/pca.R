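# PCA of binned contact ratios across samples/alleles. Each sample's reads
# are counted in fixed-width bins over a region of interest, converted to
# within-region ratios (rows sum to 1), and the sample-by-bin matrix is
# decomposed with column centering but no variance scaling: ratio bins share
# a scale, and scaling would inflate the noise of near-empty bins. Component
# loadings (eigenvector entries times the square root of the eigenvalue) are
# mapped back to bin coordinates as a genome track; a changepoint in a
# loading track localizes where the contact pattern pivots between sample
# groups, e.g. at an insulator insertion site.

#' Build a samples-by-bins matrix of contact ratios
#'
#' Reads of each profile are counted per bin (fragment-to-bin assignment by
#' midpoint), bins whose midpoint lies in a profile's viewpoint exclusion
#' zone are dropped, bins empty across all samples are dropped with a
#' warning, and each row is divided by its total so rows sum to 1 within the
#' region of interest. Replicates should be combined beforehand with
#' \code{\link{combine_replicates}}.
#'
#' @param profiles List of \code{fragment_counts}, one per sample/allele,
#'   sharing a fragment map.
#' @param grid A \code{bin_grid} over the region of interest.
#' @param region Region of interest; defaults to the grid's region. Bins
#'   whose midpoint falls outside it are dropped and ratios are
#'   (re-)normalized over the remaining bins, as done for sub-region
#'   analyses.
#' @return A \code{bin_matrix}: list with \code{X} (samples x bins),
#'   \code{samples}, \code{bins} (coordinates of retained bins),
#'   \code{grid}, \code{normalized = TRUE}.
#' @export
build_bin_matrix <- function(profiles, grid, region = grid$region) {
  stopifnot(length(profiles) >= 1L, inherits(grid, "bin_grid"))
  map <- profiles[[1]]$map
  assign <- assign_fragments_to_bins(map, grid)
  mid <- fragment_midpoints(map)
  binmid <- (grid$bins$start + grid$bins$end) / 2
  keep_bin <- point_in_gi(binmid, region)
  for (fc in profiles) {
    excl <- exclusion_zone(fc$viewpoint, fc$map$locus)
    keep_bin <- keep_bin & !point_in_gi(binmid, excl)
  }
  nb <- nrow(grid$bins)
  percell <- vapply(profiles, function(fc) {
    if (!same_backbone(profiles[[1]], fc))
      stop("all profiles must share the same fragment map and viewpoint")
    # exclusion-zone fragments never contribute, even to retained bins
    ok <- informative_fragments(fc)
    b <- assign[ok]
    use <- !is.na(b)
    out <- numeric(nb)
    if (any(use)) {
      ag <- rowsum(fc$counts[ok][use], b[use])
      out[as.integer(rownames(ag))] <- ag[, 1]
    }
    out
  }, numeric(nb))
  # vapply drops the bin dimension when nb == 1
  counts <- if (nb == 1L) matrix(percell, ncol = 1L) else t(percell)
  counts <- counts[, keep_bin, drop = FALSE]
  bins <- grid$bins[keep_bin, , drop = FALSE]
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning(sum(empty), " bin(s) empty across all samples dropped")
    counts <- counts[, !empty, drop = FALSE]
    bins <- bins[!empty, , drop = FALSE]
  }
  samples <- vapply(profiles, `[[`, "", "sample")
  totals <- rowSums(counts)
  if (any(totals <= 0))
    stop("sample(s) with zero reads in region: ",
         paste(samples[totals <= 0], collapse = ", "))
  X <- counts / totals
  rownames(X) <- samples
  structure(list(X = X, samples = samples, bins = bins, grid = grid,
                 region = region, normalized = TRUE),
            class = "bin_matrix")
}

#' PCA of a bin matrix
#'
#' Columns are centered but not variance-scaled; eigenvalues use the n - 1
#' covariance divisor. Eigenvector signs are fixed so the largest-magnitude
#' entry of each component is positive (the sign of an eigenvector is
#' mathematically indeterminate; a deterministic convention makes tracks and
#' scores reproducible).
#'
#' @param M A \code{bin_matrix} (or any samples-by-bins numeric matrix in
#'   \code{M$X}) with at least 2 samples and 2 bins.
#' @return A \code{pca_result}: \code{eigenvalues}, \code{eigenvectors}
#'   (bins x components), \code{scores} (samples x components),
#'   \code{center} (per-bin means), \code{bins}, \code{samples}.
#' @export
run_pca <- function(M) {
  stopifnot(inherits(M, "bin_matrix"))
  X <- M$X
  if (nrow(X) < 2L) stop("PCA requires at least 2 samples")
  if (ncol(X) < 2L) stop("PCA requires at least 2 bins")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  V <- p$rotation
  S <- p$x
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) {
      V[, k] <- -V[, k]
      S[, k] <- -S[, k]
    }
  }
  colnames(V) <- colnames(S) <- paste0("PC", seq_len(ncol(V)))
  structure(list(eigenvalues = ev, eigenvectors = V, scores = S,
                 center = p$center, bins = M$bins, samples = M$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("pca_result: %d samples x %d bins; variance explained: %s\n",
              length(x$samples), nrow(x$eigenvectors),
              paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(pct))),
                            pct[seq_len(min(3, length(pct)))]),
                    collapse = ", ")))
  invisible(x)
}

#' Per-bin component loadings of a principal component
#'
#' The loading of bin j on component k is the eigenvector entry times the
#' square root of the eigenvalue. On data standardized to unit column
#' variance this equals the Pearson correlation between the bin's values and
#' the component scores, so a loading track shows how much each bin's
#' contact ratio is reflected by the component.
#'
#' @param res A \code{pca_result}.
#' @param k Component number (1-based).
#' @return A \code{loading_track}: \code{component}, \code{loadings},
#'   \code{bins}.
#' @export
component_loadings <- function(res, k = 1) {
  stopifnot(inherits(res, "pca_result"))
  if (k < 1 || k > length(res$eigenvalues))
    stop("component k out of range (1..", length(res$eigenvalues), ")")
  structure(list(component = k,
                 loadings = res$eigenvectors[, k] * sqrt(res$eigenvalues[k]),
                 bins = res$bins),
            class = "loading_track")
}

#' Changepoint of a loading track
#'
#' Scans every boundary between consecutive bins and returns the split that
#' maximizes the absolute difference between the mean loading left and right
#' of it (ties broken toward the leftmost split). For a loading track with a
#' step-like sign change, this localizes the genomic position where the
#' contact pattern pivots — e.g. the insertion site of an insulator.
#'
#' @param track A \code{loading_track} with at least 3 bins.
#' @return List with \code{boundary} (genomic coordinate between the two
#'   bins), \code{split_index} (number of bins left of the boundary) and
#'   \code{statistic} (the mean difference achieved).
#' @export
loading_changepoint <- function(track) {
  stopifnot(inherits(track, "loading_track"))
  l <- track$loadings
  n <- length(l)
  if (n < 3L) stop("changepoint needs at least 3 bins")
  if (max(l) - min(l) == 0) stop("no changepoint: constant track")
  cs <- cumsum(l)
  tot <- cs[n]
  s <- seq_len(n - 1L)
  d <- abs(cs[s] / s - (tot - cs[s]) / (n - s))
  best <- which.max(d)  # ties -> leftmost
  list(boundary = track$bins$end[best], split_index = best,
       statistic = d[best])
}

#' Write a loading track as BedGraph
#'
#' @param track A \code{loading_track}.
#' @param path Output path.
#' @param header Optional "#" comment lines.
#' @export
write_loading_bedgraph <- function(track, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(chrom = track$bins$chrom,
                   start = format(track$bins$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(track$bins$end, scientific = FALSE,
                                trim = TRUE),
                   value = format(track$loadings, digits = 15,
                                  scientific = FALSE, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
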