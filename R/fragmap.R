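# Restriction-fragment maps and bin grids: the coordinate backbone that all
# read counting in the package is performed against. A 4C library is built by
# digesting chromatin with a frequent first cutter (here NlaIII, CATG),
# ligating, then trimming circles with a second cutter (DpnII, GATC); mapped
# reads land on the first-cutter fragments, so analysis starts from an in
# silico digestion of the locus sequence.

#' Find all occurrences of a DNA motif in a sequence
#'
#' Case-insensitive exact matching over the alphabet A/C/G/T/N; an N in the
#' sequence never matches a motif base (masked sequence is treated
#' conservatively). Overlapping occurrences are all reported.
#'
#' @param seq A DNA sequence as a single string.
#' @param motif A non-empty DNA motif string (e.g. \code{"CATG"}).
#' @return Ascending integer vector of 0-based start offsets.
#' @examples
#' find_motif_occurrences("CATGCATG", "CATG")  # 0 4
#' @export
find_motif_occurrences <- function(seq, motif) {
  if (!nzchar(motif)) stop("empty motif")
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(motif) > nchar(seq)) return(integer(0))
  subject <- Biostrings::DNAString(seq)
  # fixed = TRUE: IUPAC ambiguity codes are literal, so N in the subject
  # cannot match a motif base
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif), subject,
                                   fixed = TRUE)
  sort(BiocGenerics::start(hits)) - 1L
}

#' In silico two-enzyme digestion of a locus
#'
#' Cuts the locus at every occurrence of the first cutter, placing each
#' fragment boundary at the motif start offset (the analysis is invariant to
#' a constant shift of at most the motif length, so a single documented
#' convention is used rather than the enzyme's biochemical cut position).
#' Each fragment is flagged for whether its sequence contains at least one
#' second-cutter site; fragments without one ("blind" fragments) cannot be
#' trimmed in the 4C protocol, and the flag lets either filtering policy be
#' applied downstream (default everywhere in this package: keep all).
#'
#' @param seq Locus sequence; its length must equal the locus interval length.
#' @param locus A \code{\link{genomic_interval}} giving genomic coordinates.
#' @param first_cutter,second_cutter Recognition motifs, e.g. \code{"CATG"}
#'   and \code{"GATC"}.
#' @return A \code{fragment_map}: list with \code{locus}, \code{first_cutter},
#'   \code{second_cutter} and a \code{fragments} data.frame (chrom, start,
#'   end, index, has_second_site) tiling the locus without gaps or overlaps.
#' @export
digest <- function(seq, locus, first_cutter = "CATG", second_cutter = "GATC") {
  stopifnot(inherits(locus, "genomic_interval"))
  if (nchar(seq) != gi_length(locus))
    stop("sequence length (", nchar(seq), ") does not match locus length (",
         gi_length(locus), ")")
  offs <- find_motif_occurrences(seq, first_cutter)
  # a cut at offset 0 would create an empty fragment: it is a no-op
  cuts <- offs[offs > 0L]
  bounds <- c(0, cuts, nchar(seq))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  has2 <- vapply(seq_along(starts), function(i) {
    fragseq <- substr(seq, starts[i] + 1L, ends[i])
    length(find_motif_occurrences(fragseq, second_cutter)) > 0L
  }, logical(1))
  fragments <- data.frame(
    chrom = locus$chrom,
    start = locus$start + starts,
    end = locus$start + ends,
    index = seq_along(starts),
    has_second_site = has2
  )
  structure(list(locus = locus, first_cutter = first_cutter,
                 second_cutter = second_cutter, fragments = fragments),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("fragment_map: %d fragments (%s/%s) over %s:%s-%s\n",
              nrow(x$fragments), x$first_cutter, x$second_cutter,
              x$locus$chrom, format(x$locus$start, scientific = FALSE),
              format(x$locus$end, scientific = FALSE)))
  invisible(x)
}

fragment_midpoints <- function(map) {
  (map$fragments$start + map$fragments$end) / 2
}

#' Tile a region with fixed-width bins
#'
#' Left-anchored tiling; a trailing partial bin is retained (flagged in the
#' output) so the bin grid always covers the full region and loading tracks
#' keep full locus coverage.
#'
#' @param region A \code{\link{genomic_interval}}.
#' @param bin_size Bin width in bp (the published analyses use 30 kb and
#'   10 kb).
#' @return A \code{bin_grid}: list with \code{region}, \code{bin_size} and a
#'   \code{bins} data.frame (chrom, start, end, index, partial).
#' @export
make_bins <- function(region, bin_size) {
  stopifnot(inherits(region, "genomic_interval"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1)
    stop("bin_size must be a positive integer")
  starts <- seq(region$start, region$end - 1, by = bin_size)
  ends <- pmin(starts + bin_size, region$end)
  bins <- data.frame(chrom = region$chrom, start = starts, end = ends,
                     index = seq_along(starts),
                     partial = (ends - starts) < bin_size)
  structure(list(region = region, bin_size = bin_size, bins = bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d bins of %s bp over %s:%s-%s\n",
              nrow(x$bins), format(x$bin_size, scientific = FALSE),
              x$region$chrom, format(x$region$start, scientific = FALSE),
              format(x$region$end, scientific = FALSE)))
  invisible(x)
}

#' Assign restriction fragments to bins by midpoint
#'
#' Each fragment belongs to the bin containing its midpoint, so a fragment
#' straddling a bin boundary is counted exactly once. Fragments whose
#' midpoint lies outside the grid region are unassigned (\code{NA}).
#'
#' @param map A \code{fragment_map}.
#' @param grid A \code{bin_grid}; its region must lie within the map's locus.
#' @return Integer vector, one entry per fragment: bin index or \code{NA}.
#' @export
assign_fragments_to_bins <- function(map, grid) {
  stopifnot(inherits(map, "fragment_map"), inherits(grid, "bin_grid"))
  if (!gi_contains(map$locus, grid$region))
    stop("bin grid region must lie within the fragment map locus")
  mid <- fragment_midpoints(map)
  inside <- point_in_gi(mid, grid$region)
  idx <- rep(NA_integer_, length(mid))
  idx[inside] <- floor((mid[inside] - grid$region$start) / grid$bin_size) + 1L
  idx
}

#' Read a locus sequence from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @param region Either \code{NULL} (use the first record whole, locus named
#'   after the record starting at 0) or a \code{"chrom:start-end"} string
#'   (0-based half-open) selecting a sub-sequence of the named record.
#' @return List with \code{seq} (character) and \code{locus}
#'   (\code{\link{genomic_interval}}).
#' @export
read_locus_fasta <- function(path, region = NULL) {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  names(recs) <- sub("\\s.*$", "", names(recs))
  if (is.null(region)) {
    locus <- genomic_interval(names(recs)[1], 0, Biostrings::width(recs)[1])
    return(list(seq = as.character(recs[[1]]), locus = locus))
  }
  gi <- parse_region(region)
  if (!gi$chrom %in% names(recs))
    stop("record '", gi$chrom, "' not found in ", path)
  rec <- recs[[gi$chrom]]
  if (gi$end > length(rec)) stop("region extends past end of record")
  list(seq = as.character(Biostrings::subseq(rec, gi$start + 1L, gi$end)),
       locus = gi)
}

#' Export a fragment map to BED
#'
#' One BED line per fragment; \code{name} is the fragment index and
#' \code{score} is 1 when the fragment contains a second-cutter site, else 0.
#'
#' @param map A \code{fragment_map}.
#' @param path Output BED path.
#' @export
write_fragment_bed <- function(map, path) {
  fr <- map$fragments
  gr <- GenomicRanges::GRanges(
    fr$chrom, IRanges::IRanges(fr$start + 1L, fr$end),
    name = as.character(fr$index),
    score = as.integer(fr$has_second_site))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Import a fragment map from BED
#'
#' Inverse of \code{\link{write_fragment_bed}}. Cutter motifs are not stored
#' in BED, so they must be resupplied (defaults match the 4C protocol's
#' NlaIII/DpnII pair).
#'
#' @param path BED path written by \code{\link{write_fragment_bed}}.
#' @param first_cutter,second_cutter Motifs recorded on the returned map.
#' @return A \code{fragment_map}.
#' @export
read_fragment_bed <- function(path, first_cutter = "CATG",
                              second_cutter = "GATC") {
  gr <- rtracklayer::import(path, format = "bed")
  o <- order(BiocGenerics::start(gr))
  gr <- gr[o]
  fragments <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    index = as.integer(gr$name),
    has_second_site = as.logical(gr$score))
  locus <- genomic_interval(fragments$chrom[1], min(fragments$start),
                            max(fragments$end))
  structure(list(locus = locus, first_cutter = first_cutter,
                 second_cutter = second_cutter, fragments = fragments),
            class = "fragment_map")
}

#' Export a bin grid to BED
#' @param grid A \code{bin_grid}.
#' @param path Output BED path.
#' @export
write_bin_bed <- function(grid, path) {
  b <- grid$bins
  gr <- GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(b$start + 1L, b$end),
    name = as.character(b$index), score = as.integer(b$partial))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
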