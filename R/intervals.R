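#' Genomic interval
#'
#' A minimal 0-based, half-open genomic interval. All coordinates in the
#' package use this convention internally; BED and BedGraph files are read
#' and written in their native 0-based half-open form, so no shifting occurs
#' at the file boundary.
#'
#' @param chrom Chromosome / sequence name.
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); must satisfy \code{0 <= start < end}.
#' @return An object of class \code{genomic_interval}.
#' @examples
#' genomic_interval("chr8", 127000000, 130000000)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s> (%s bp)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(x$end - x$start, scientific = FALSE)))
  invisible(x)
}

gi_length <- function(x) x$end - x$start

#' Parse a "chrom:start-end" region string
#'
#' Coordinates in the string are 0-based half-open, matching the rest of the
#' package.
#'
#' @param region A string like \code{"chr8:0-3000000"}.
#' @return A \code{\link{genomic_interval}}.
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", region)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

# containment of one interval in another (same chrom required)
gi_contains <- function(outer, inner) {
  outer$chrom == inner$chrom &&
    inner$start >= outer$start && inner$end <= outer$end
}

# is a point (e.g. a fragment midpoint) inside the half-open interval?
point_in_gi <- function(pos, x) pos >= x$start & pos < x$end

# intersect two intervals on the same chrom; NULL when empty
gi_intersect <- function(a, b) {
  if (a$chrom != b$chrom) return(NULL)
  s <- max(a$start, b$start); e <- min(a$end, b$end)
  if (s >= e) NULL else genomic_interval(a$chrom, s, e)
}
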