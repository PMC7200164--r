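# Folding directionality: does a viewpoint contact predominantly its left or
# its right flank? Computed as the normalized difference of raw read counts
# in two windows of equal genomic span abutting the viewpoint fragment,
# (R - L) / (R + L), so the statistic lies in [-1, 1], is invariant to
# sequencing depth, and flips sign exactly under a mirror reflection of the
# locus. Diverging directionality of the two viewpoints flanking a site is a
# hallmark of a contact-domain boundary.

#' Folding directionality of a viewpoint
#'
#' Counts raw reads in the windows \code{[vp_start - d, vp_start)} (left) and
#' \code{[vp_end, vp_end + d)} (right), drops fragments inside the viewpoint
#' exclusion zone from both windows, and returns
#' \code{(R - L) / (R + L)}. Positive values mean rightward folding (toward
#' higher coordinates). Windows extending past the locus edge are clipped
#' with a warning, as happens for megabase windows near a locus end.
#'
#' @param fc A \code{fragment_counts}.
#' @param d Window span in bp (the published panels use 1 Mb, 500 kb and
#'   100 kb).
#' @return A \code{directionality_index} list: \code{viewpoint},
#'   \code{distance}, \code{value}, \code{left_reads}, \code{right_reads},
#'   \code{clipped}.
#' @export
folding_directionality <- function(fc, d) {
  stopifnot(inherits(fc, "fragment_counts"))
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("window distance d must be positive")
  vp <- fc$viewpoint
  locus <- fc$map$locus
  lw_start <- vp$position$start - d
  rw_end <- vp$position$end + d
  clipped <- FALSE
  if (lw_start < locus$start || rw_end > locus$end) {
    clipped <- TRUE
    warning("directionality window clipped at locus edge for ", vp$name,
            " at d = ", format(d, scientific = FALSE))
    lw_start <- max(lw_start, locus$start)
    rw_end <- min(rw_end, locus$end)
  }
  mid <- fragment_midpoints(fc$map)
  keep <- informative_fragments(fc)
  left <- genomic_interval(locus$chrom, lw_start, vp$position$start)
  right <- genomic_interval(locus$chrom, vp$position$end, rw_end)
  L <- sum(fc$counts[keep][point_in_gi(mid[keep], left)])
  R <- sum(fc$counts[keep][point_in_gi(mid[keep], right)])
  if (L + R <= 0) stop("no reads in windows")
  structure(list(viewpoint = vp, distance = d, value = (R - L) / (R + L),
                 left_reads = L, right_reads = R, clipped = clipped),
            class = "directionality_index")
}

#' @export
print.directionality_index <- function(x, ...) {
  cat(sprintf("directionality %s @ %s bp: %+.3f (L=%s, R=%s)%s\n",
              x$viewpoint$name, format(x$distance, scientific = FALSE),
              x$value,
              format(x$left_reads, scientific = FALSE),
              format(x$right_reads, scientific = FALSE),
              if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Tabulate folding directionality over profiles and distances
#'
#' One row per (profile, distance), ordered by sample then by ascending
#' distance. A cell whose windows contain no reads is reported as \code{NA}
#' with a warning rather than aborting the table.
#'
#' @param profiles List of \code{fragment_counts}.
#' @param distances Numeric vector of window spans in bp.
#' @return data.frame with columns sample, viewpoint, distance, left_reads,
#'   right_reads, value.
#' @export
directionality_table <- function(profiles,
                                 distances = c(100000, 500000, 1000000)) {
  stopifnot(length(profiles) >= 1L, length(distances) >= 1L)
  distances <- sort(distances)
  rows <- lapply(profiles, function(fc) {
    cells <- lapply(distances, function(d) {
      di <- tryCatch(suppressWarnings(folding_directionality(fc, d)),
                     error = function(e) {
                       warning("sample '", fc$sample, "' at d = ",
                               format(d, scientific = FALSE), ": ",
                               conditionMessage(e))
                       NULL
                     })
      if (is.null(di))
        data.frame(sample = fc$sample, viewpoint = fc$viewpoint$name,
                   distance = d, left_reads = NA_real_,
                   right_reads = NA_real_, value = NA_real_)
      else
        data.frame(sample = fc$sample, viewpoint = fc$viewpoint$name,
                   distance = d, left_reads = di$left_reads,
                   right_reads = di$right_reads, value = di$value)
    })
    do.call(rbind, cells)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
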