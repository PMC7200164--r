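# Plain-text track and table IO. BedGraph is a 4-column TSV (chrom, start,
# end, value; 0-based half-open); the writers here additionally support "#"
# comment headers so pipeline outputs can carry their seed and config hash,
# and the readers skip such lines.

#' Write a per-fragment signal as BedGraph
#'
#' One line per fragment, 0-based half-open coordinates. Optional header
#' lines are written as "#" comments before the data.
#'
#' @param values Finite numeric vector, one value per fragment.
#' @param map A \code{fragment_map}.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written without
#'   the leading \code{"# "}).
#' @export
write_bedgraph <- function(values, map, path, header = NULL) {
  stopifnot(inherits(map, "fragment_map"))
  if (length(values) != nrow(map$fragments))
    stop("one value per fragment required")
  if (any(!is.finite(values))) stop("values must be finite (no NaN/Inf)")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(chrom = map$fragments$chrom,
                   start = format(map$fragments$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(map$fragments$end, scientific = FALSE,
                                trim = TRUE),
                   value = format(values, digits = 15, scientific = FALSE,
                                  trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BedGraph track
#'
#' Skips "#" comment and "track" lines. Errors on an empty (data-less) file.
#'
#' @param path BedGraph path.
#' @return data.frame with columns chrom, start, end, value (0-based
#'   half-open).
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#|^track|^browser", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    stop("no data lines in BedGraph file: ", path)
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  df
}

#' Write fragment counts as a 4-column TSV
#'
#' Columns: chrom, fragment start, fragment end, count (0-based half-open).
#'
#' @param fc A \code{fragment_counts}.
#' @param path Output path.
#' @param header Optional "#" comment lines.
#' @export
write_counts_tsv <- function(fc, path, header = NULL) {
  stopifnot(inherits(fc, "fragment_counts"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(chrom = fc$map$fragments$chrom,
                   start = format(fc$map$fragments$start,
                                  scientific = FALSE, trim = TRUE),
                   end = format(fc$map$fragments$end,
                                scientific = FALSE, trim = TRUE),
                   count = format(fc$counts, scientific = FALSE, trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read fragment counts from a 4-column TSV, validated against a map
#'
#' The file's fragment coordinates must match the map's exactly (same order,
#' same boundaries); mismatches indicate counts produced against a different
#' digestion and are an error.
#'
#' @param path TSV path (chrom, start, end, count).
#' @param map The \code{fragment_map} the counts were produced against.
#' @param vp A \code{\link{viewpoint}} on that map.
#' @param sample Sample label for the returned object.
#' @return A \code{fragment_counts}.
#' @export
read_counts_tsv <- function(path, map, vp, sample = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "count"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  fr <- map$fragments
  if (nrow(df) != nrow(fr) ||
      any(df$chrom != fr$chrom) ||
      any(df$start != fr$start) || any(df$end != fr$end))
    stop("counts table does not match the fragment map: ", path)
  fragment_counts(map, vp, df$count, sample = sample)
}

#' Read named intervals from a BED file
#'
#' @param path BED path (0-based half-open, as BED natively is).
#' @return Named list of \code{\link{genomic_interval}}s; unnamed records get
#'   \code{region<i>} labels.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("region", seq_along(gr))
  nm[is.na(nm) | !nzchar(nm)] <- paste0("region", which(is.na(nm) | !nzchar(nm)))
  out <- lapply(seq_along(gr), function(i)
    genomic_interval(as.character(GenomicRanges::seqnames(gr)[i]),
                     BiocGenerics::start(gr)[i] - 1L,
                     BiocGenerics::end(gr)[i]))
  names(out) <- nm
  out
}
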