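# Per-fragment 4C signal: raw counts -> RPM -> running-mean smoothing for
# track display, and viewpoint-excluded contact-frequency ratios computed on
# the raw counts. Interval ratios are the quantity the downstream
# directionality, PCA and scaling modules consume; RPM + smoothing exist only
# for visualization, because smoothing would leak reads across interval
# boundaries.

#' Define a 4C viewpoint
#'
#' The viewpoint is the restriction fragment whose contacts the experiment
#' profiles. Reads very close to it are dominated by self-ligation and
#' undigested template, so an exclusion zone of the viewpoint fragment plus
#' \code{exclusion_flank} bp on each side is removed from every ratio
#' computation.
#'
#' @param map A \code{fragment_map}.
#' @param fragment_index 1-based index of the viewpoint fragment in the map.
#' @param name Viewpoint label, e.g. \code{"VP-MYC2"}.
#' @param exclusion_flank Flank excluded on each side of the viewpoint
#'   fragment, in bp (default 10 kb).
#' @return A \code{viewpoint} object.
#' @export
viewpoint <- function(map, fragment_index, name = "VP",
                      exclusion_flank = 10000) {
  stopifnot(inherits(map, "fragment_map"))
  fragment_index <- as.integer(fragment_index)
  if (fragment_index < 1L || fragment_index > nrow(map$fragments))
    stop("fragment_index out of range")
  if (exclusion_flank < 0) stop("exclusion_flank must be >= 0")
  fr <- map$fragments[fragment_index, ]
  structure(list(name = name, fragment_index = fragment_index,
                 position = genomic_interval(fr$chrom, fr$start, fr$end),
                 exclusion_flank = exclusion_flank),
            class = "viewpoint")
}

# viewpoint fragment extended by the flank on both sides, clipped to locus
exclusion_zone <- function(vp, locus) {
  genomic_interval(vp$position$chrom,
                   max(locus$start, vp$position$start - vp$exclusion_flank),
                   min(locus$end, vp$position$end + vp$exclusion_flank))
}

#' Per-fragment 4C read counts for one viewpoint and sample
#'
#' @param map A \code{fragment_map}.
#' @param vp A \code{\link{viewpoint}}.
#' @param counts Non-negative integer vector, one entry per fragment.
#' @param sample Sample / allele label.
#' @return A \code{fragment_counts} object.
#' @export
fragment_counts <- function(map, vp, counts, sample = "sample") {
  stopifnot(inherits(map, "fragment_map"), inherits(vp, "viewpoint"))
  if (length(counts) != nrow(map$fragments))
    stop("length(counts) must equal the number of fragments (",
         nrow(map$fragments), ")")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  structure(list(map = map, viewpoint = vp,
                 counts = as.numeric(counts), sample = sample),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("fragment_counts: sample '%s', viewpoint %s, %d fragments, %s reads\n",
              x$sample, x$viewpoint$name, length(x$counts),
              format(sum(x$counts), scientific = FALSE)))
  invisible(x)
}

same_backbone <- function(a, b) {
  identical(a$map$fragments[c("start", "end")],
            b$map$fragments[c("start", "end")]) &&
    a$viewpoint$fragment_index == b$viewpoint$fragment_index
}

#' Combine replicate 4C libraries of the same viewpoint
#'
#' Replicates from the same viewpoint are pooled by element-wise summation of
#' raw fragment counts before any ratio is computed, so downstream contact
#' frequencies are read-weighted over replicates.
#'
#' @param replicates List of \code{fragment_counts} sharing the same fragment
#'   map and viewpoint.
#' @return A single \code{fragment_counts}; sample labels are joined with
#'   \code{"+"}.
#' @export
combine_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  base <- replicates[[1]]
  for (r in replicates[-1]) {
    if (!same_backbone(base, r))
      stop("replicates must share the same fragment map and viewpoint")
  }
  counts <- Reduce(`+`, lapply(replicates, `[[`, "counts"))
  fragment_counts(base$map, base$viewpoint, counts,
                  sample = paste(vapply(replicates, `[[`, "", "sample"),
                                 collapse = "+"))
}

#' Normalize fragment counts to reads per million
#'
#' @param fc A \code{fragment_counts} with at least one read.
#' @return Numeric vector: \code{counts * 1e6 / sum(counts)}.
#' @export
normalize_rpm <- function(fc) {
  stopifnot(inherits(fc, "fragment_counts"))
  total <- sum(fc$counts)
  if (total <= 0) stop("empty profile")
  fc$counts * 1e6 / total
}

#' Smooth a per-fragment signal with a centered running mean
#'
#' The published track processing smooths RPM values over a window of seven
#' fragments. Near the ends of the locus the window is truncated to the
#' available fragments rather than zero-padded, because padding would
#' fabricate signal decay at the locus edges.
#'
#' @param values Numeric per-fragment vector.
#' @param w Odd window size in fragments (default 7); \code{w = 1} is the
#'   identity.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, w = 7) {
  if (w %% 2 == 0) stop("window size must be odd")
  if (w < 1) stop("window size must be >= 1")
  if (w == 1 || length(values) <= 1L) return(values)
  as.numeric(zoo::rollapply(values, width = w, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Build a normalized, smoothed fragment profile
#'
#' Convenience wrapper bundling the raw counts with their RPM normalization
#' and running-mean smoothing, as written to visualization tracks.
#'
#' @param fc A \code{fragment_counts}.
#' @param w Odd smoothing window in fragments (default 7).
#' @return A \code{fragment_profile} list: \code{base}, \code{rpm},
#'   \code{smoothed}, \code{window_w}.
#' @export
fragment_profile <- function(fc, w = 7) {
  rpm <- normalize_rpm(fc)
  structure(list(base = fc, rpm = rpm,
                 smoothed = smooth_profile(rpm, w), window_w = w),
            class = "fragment_profile")
}

# fragment indices whose midpoint lies outside the viewpoint exclusion zone
informative_fragments <- function(fc) {
  excl <- exclusion_zone(fc$viewpoint, fc$map$locus)
  mid <- fragment_midpoints(fc$map)
  which(!point_in_gi(mid, excl))
}

#' Viewpoint-excluded contact frequency of an interval
#'
#' The contact frequency of a region is the fraction of informative reads
#' mapping there: reads in the interval divided by all reads in the locus,
#' in both cases after removing fragments whose midpoint falls in the
#' viewpoint exclusion zone (viewpoint fragment plus
#' \code{exclusion_flank} bp on each side). Computed on raw counts, never on
#' smoothed values. Ratios of disjoint intervals are additive and an
#' interval equal to the whole locus has ratio 1.
#'
#' @param fc A \code{fragment_counts}.
#' @param interval A \code{\link{genomic_interval}} inside the locus.
#' @return A \code{contact_frequency} list: \code{interval}, \code{ratio},
#'   \code{numerator_reads}, \code{denominator_reads}, \code{excluded}.
#' @export
contact_frequency <- function(fc, interval) {
  stopifnot(inherits(fc, "fragment_counts"),
            inherits(interval, "genomic_interval"))
  locus <- fc$map$locus
  if (!gi_contains(locus, interval))
    stop("interval must lie within the locus")
  excl <- exclusion_zone(fc$viewpoint, locus)
  keep <- informative_fragments(fc)
  mid <- fragment_midpoints(fc$map)
  denom <- sum(fc$counts[keep])
  if (denom <= 0) stop("no informative reads")
  inside <- keep[point_in_gi(mid[keep], interval)]
  num <- sum(fc$counts[inside])
  structure(list(interval = interval, ratio = num / denom,
                 numerator_reads = num, denominator_reads = denom,
                 excluded = excl),
            class = "contact_frequency")
}

#' @export
print.contact_frequency <- function(x, ...) {
  cat(sprintf("contact_frequency %s:%s-%s = %.4f (%s / %s reads)\n",
              x$interval$chrom,
              format(x$interval$start, scientific = FALSE),
              format(x$interval$end, scientific = FALSE),
              x$ratio,
              format(x$numerator_reads, scientific = FALSE),
              format(x$denominator_reads, scientific = FALSE)))
  invisible(x)
}
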