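# Independent brute-force oracles and small fixture builders, kept free of
# the package's own code paths wherever they serve as a cross-check.

# sliding-window motif scan; N never matches; case-insensitive
brute_motif_scan <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  k <- nchar(motif)
  if (k > nchar(seq)) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - k + 1L)) {
    win <- substr(seq, i, i + k - 1L)
    if (win == motif && !grepl("N", win)) hits <- c(hits, i - 1L)
  }
  hits
}

random_dna <- function(n, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (p_n > 0) {
    mask <- stats::runif(n) < p_n
    s[mask] <- "N"
  }
  paste(s, collapse = "")
}

# windowed mean with truncation at the edges, computed index by index
brute_windowed_mean <- function(x, w) {
  h <- (w - 1) / 2
  vapply(seq_along(x), function(i) {
    lo <- max(1L, i - h); hi <- min(length(x), i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# uniform toy map: n fragments of width bp each, starting at 0
toy_map <- function(n = 20, width = 100, chrom = "chrT") {
  starts <- (seq_len(n) - 1L) * width
  structure(list(
    locus = genomic_interval(chrom, 0, n * width),
    first_cutter = "CATG", second_cutter = "GATC",
    fragments = data.frame(chrom = chrom, start = starts,
                           end = starts + width, index = seq_len(n),
                           has_second_site = TRUE)),
    class = "fragment_map")
}

toy_counts <- function(counts, vp_index = 10, flank = 0, width = 100,
                       sample = "s", n = length(counts)) {
  map <- toy_map(n, width)
  vp <- viewpoint(map, vp_index, exclusion_flank = flank)
  fragment_counts(map, vp, counts, sample = sample)
}

# small fast model for simulation-based tests
small_model <- function(...) {
  locus_model(locus_length = 3e5, n_fragments = 300, viewpoint_pos = 9e4,
              barrier_pos = 9.3e4,
              enhancer_region = genomic_interval("synthLocus", 9.3e4, 1.34e5),
              ...)
}
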