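# Synthetic 4C locus generator. The model emulates an engineered, locally
# haploid ~3 Mb locus with one viewpoint: contact probability decays with
# genomic distance as a power law, a barrier at a fixed position attenuates
# all cross-barrier contact by a permeability factor beta in (0, 1] set by
# each allele's CTCF-site composition (beta = 1: no insulation), and an
# enhancer region beyond the barrier responds super-linearly (weight
# beta^delta, delta >= 1), so releasing insulation escalates gene-enhancer
# contact preferentially over neutral regions. Reads are a multinomial draw
# over the expected contact vector; expression follows a power law of
# enhancer contact frequency with lognormal noise. Every parameter is
# recorded as ground truth so each pipeline statistic can be tested against
# a known answer.

#' Generative model of a synthetic insulated locus
#'
#' Defaults describe a 3 Mb locus of 3000 uniform 1 kb fragments with the
#' viewpoint (the profiled gene promoter) at 900 kb, a barrier 30 kb to its
#' right, and an enhancer region spanning 930-1340 kb — i.e. the barrier
#' separates a 900 kb left region from the enhancer-bearing right side, and
#' the enhancer occupies the +30 kb to +440 kb band beyond the barrier.
#'
#' @param locus_length Locus length in bp.
#' @param n_fragments Number of uniform-length fragments.
#' @param viewpoint_pos Viewpoint position in bp (0-based, within locus).
#' @param barrier_pos Barrier position in bp; must differ from
#'   \code{viewpoint_pos}.
#' @param decay_alpha Distance-decay exponent alpha > 0 (contact
#'   probability proportional to distance^-alpha).
#' @param enhancer_region \code{\link{genomic_interval}} of the enhancer on
#'   the far side of the barrier (default 930-1340 kb).
#' @param enhancer_affinity_delta delta >= 1; enhancer cross-barrier weight
#'   is beta^delta, making delta the enhancer-vs-neutral contact-scaling
#'   exponent by construction.
#' @param expression_scale Expression prefactor c > 0.
#' @param expression_exponent gamma > 0 in E = c * f_enh^gamma.
#' @param noise_sigma Lognormal noise sd (natural-log scale) on expression.
#' @param chrom Sequence name used on all coordinates.
#' @return A \code{locus_model}.
#' @export
locus_model <- function(locus_length = 3e6,
                        n_fragments = 3000,
                        viewpoint_pos = 9e5,
                        barrier_pos = 9.3e5,
                        decay_alpha = 1.0,
                        enhancer_region = NULL,
                        enhancer_affinity_delta = 1.15,
                        expression_scale = 100,
                        expression_exponent = 4.0,
                        noise_sigma = 0.05,
                        chrom = "synthLocus") {
  stopifnot(locus_length > 0, n_fragments >= 3,
            viewpoint_pos >= 0, viewpoint_pos < locus_length,
            barrier_pos >= 0, barrier_pos < locus_length)
  if (decay_alpha <= 0) stop("decay_alpha must be > 0")
  if (enhancer_affinity_delta < 1) stop("enhancer_affinity_delta must be >= 1")
  if (barrier_pos == viewpoint_pos)
    stop("barrier_pos must differ from viewpoint_pos")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (expression_scale <= 0 || expression_exponent <= 0)
    stop("expression_scale and expression_exponent must be > 0")
  if (is.null(enhancer_region))
    enhancer_region <- genomic_interval(chrom, 9.3e5, 1.34e6)
  m <- structure(list(locus_length = locus_length, n_fragments = n_fragments,
                      viewpoint_pos = viewpoint_pos, barrier_pos = barrier_pos,
                      decay_alpha = decay_alpha,
                      enhancer_region = enhancer_region,
                      enhancer_affinity_delta = enhancer_affinity_delta,
                      expression_scale = expression_scale,
                      expression_exponent = expression_exponent,
                      noise_sigma = noise_sigma, chrom = chrom),
                 class = "locus_model")
  m
}

#' Fragment map implied by a locus model
#'
#' Uniform fragment lengths by design: tests of counting, binning and
#' ratios should not be confounded by fragment-size variation. All
#' fragments carry a second-cutter site flag of TRUE (blind-fragment
#' filtering is exercised on digested sequence maps, not here).
#'
#' @param m A \code{locus_model}.
#' @return A \code{fragment_map}.
#' @export
model_fragment_map <- function(m) {
  stopifnot(inherits(m, "locus_model"))
  bounds <- round(seq(0, m$locus_length, length.out = m$n_fragments + 1))
  fragments <- data.frame(chrom = m$chrom,
                          start = bounds[-length(bounds)],
                          end = bounds[-1],
                          index = seq_len(m$n_fragments),
                          has_second_site = TRUE)
  structure(list(locus = genomic_interval(m$chrom, 0, m$locus_length),
                 first_cutter = "CATG", second_cutter = "GATC",
                 fragments = fragments),
            class = "fragment_map")
}

#' Viewpoint implied by a locus model
#'
#' @param m A \code{locus_model}.
#' @param exclusion_flank Exclusion flank in bp (default 10 kb).
#' @return A \code{\link{viewpoint}} on \code{\link{model_fragment_map}}.
#' @export
model_viewpoint <- function(m, exclusion_flank = 10000) {
  map <- model_fragment_map(m)
  mid <- fragment_midpoints(map)
  idx <- which(m$viewpoint_pos >= map$fragments$start &
               m$viewpoint_pos < map$fragments$end)[1]
  viewpoint(map, idx, name = "VP-synth", exclusion_flank = exclusion_flank)
}

#' Configuration of one allele: its barrier permeability
#'
#' beta is the fraction of cross-barrier contact retained: 1 for alleles
#' without a functional insulator, decreasing as more CTCF sites are bound.
#'
#' @param name Allele label.
#' @param beta Permeability in (0, 1].
#' @return An \code{allele_config}.
#' @export
allele_config <- function(name, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1] for allele ", name)
  structure(list(name = name, beta = beta), class = "allele_config")
}

#' Default nine-allele panel emulating a CTCF-site titration series
#'
#' Permeabilities follow the qualitative ordering of blocking strength with
#' CTCF-site number and orientation: the intact divergent array and its full
#' inversion block most strongly; deleting the whole array (or all sites)
#' restores full permeability; partial deletions are intermediate. The
#' numeric values are generator constants chosen once to satisfy that
#' ordering — they are not estimates of any real allele.
#'
#' @return Named list of \code{\link{allele_config}}s.
#' @export
default_allele_panel <- function() {
  betas <- c("Hap" = 1.0, "del(L1-R3)" = 1.0, "del(L1-R2)" = 0.8,
             "del(L2-R2)" = 0.6, "delL" = 0.45, "delR" = 0.4,
             "invR" = 0.35, "STITCH" = 0.15, "inv(L1-R3)" = 0.15)
  out <- lapply(names(betas), function(nm) allele_config(nm, betas[[nm]]))
  names(out) <- names(betas)
  out
}

#' Expected per-fragment contact probabilities of an allele
#'
#' p_i is proportional to d_i^-alpha times a barrier weight: 1 on the
#' viewpoint side, beta^delta for cross-barrier fragments inside the
#' enhancer region, beta for other cross-barrier fragments; the viewpoint
#' fragment itself gets probability 0 and the vector is normalized to sum 1.
#'
#' @param m A \code{locus_model}.
#' @param a An \code{allele_config}.
#' @return Numeric probability vector, one entry per fragment.
#' @export
expected_contact_vector <- function(m, a) {
  stopifnot(inherits(m, "locus_model"), inherits(a, "allele_config"))
  map <- model_fragment_map(m)
  vp <- model_viewpoint(m)
  mid <- fragment_midpoints(map)
  vp_mid <- (vp$position$start + vp$position$end) / 2
  d <- abs(mid - vp_mid)
  w <- rep(1, length(mid))
  cross <- if (m$barrier_pos > m$viewpoint_pos) mid > m$barrier_pos
           else mid < m$barrier_pos
  in_enh <- point_in_gi(mid, m$enhancer_region)
  w[cross] <- a$beta
  w[cross & in_enh] <- a$beta^m$enhancer_affinity_delta
  p <- d^(-m$decay_alpha) * w
  p[vp$fragment_index] <- 0
  tot <- sum(p)
  if (tot <= 0) stop("all-zero contact weights")
  p / tot
}

#' Expected (noise-free) contact frequency of an interval under the model
#'
#' The viewpoint-excluded interval ratio computed directly on the expected
#' contact vector, i.e. the infinite-depth limit of
#' \code{\link{contact_frequency}} on simulated counts.
#'
#' @param m A \code{locus_model}.
#' @param a An \code{allele_config}.
#' @param interval A \code{\link{genomic_interval}} within the locus.
#' @param exclusion_flank Exclusion flank in bp (default 10 kb).
#' @return Expected ratio in [0, 1].
#' @export
expected_contact_frequency <- function(m, a, interval,
                                       exclusion_flank = 10000) {
  p <- expected_contact_vector(m, a)
  map <- model_fragment_map(m)
  vp <- model_viewpoint(m, exclusion_flank)
  mid <- fragment_midpoints(map)
  excl <- exclusion_zone(vp, map$locus)
  keep <- !point_in_gi(mid, excl)
  denom <- sum(p[keep])
  if (denom <= 0) stop("no informative probability mass")
  sum(p[keep & point_in_gi(mid, interval)]) / denom
}

#' Simulate a 4C library as a multinomial draw
#'
#' @param m A \code{locus_model}.
#' @param a An \code{allele_config}.
#' @param depth Total read count N >= 1.
#' @param seed Integer seed; the draw is reproducible per seed.
#' @param exclusion_flank Exclusion flank stored on the viewpoint.
#' @return A \code{fragment_counts} with \code{sum(counts) == depth}.
#' @export
simulate_counts <- function(m, a, depth, seed, exclusion_flank = 10000) {
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("invalid depth: need N >= 1")
  p <- expected_contact_vector(m, a)
  set.seed(as.integer(seed))
  counts <- as.numeric(stats::rmultinom(1, size = depth, prob = p))
  fragment_counts(model_fragment_map(m), model_viewpoint(m, exclusion_flank),
                  counts, sample = a$name)
}

#' Simulate an expression value from enhancer contact frequency
#'
#' E = c * f^gamma * exp(eps), eps ~ Normal(0, sigma^2); with sigma = 0 the
#' value is exactly the power law.
#'
#' @param f_enh Enhancer contact frequency, > 0.
#' @param m A \code{locus_model} (supplies c, gamma, sigma).
#' @param seed Integer seed.
#' @return Positive expression value.
#' @export
simulate_expression <- function(f_enh, m, seed) {
  stopifnot(inherits(m, "locus_model"))
  if (!is.numeric(f_enh) || f_enh <= 0)
    stop("f_enh must be > 0")
  set.seed(as.integer(seed))
  eps <- if (m$noise_sigma > 0) stats::rnorm(1, 0, m$noise_sigma) else 0
  m$expression_scale * f_enh^m$expression_exponent * exp(eps)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483587)
}

#' Generate a full allelic panel: counts, expression and ground truth
#'
#' For each allele, draws a 4C library at the given depth and an expression
#' value from the allele's expected (noise-free) enhancer contact frequency.
#' Sub-seeds are derived deterministically from \code{seed}, so the whole
#' panel is byte-reproducible. When \code{out_dir} is given, writes one
#' counts TSV per allele, the fragment map BED, an expression TSV and a flat
#' key=value truth file recording every generative parameter.
#'
#' @param m A \code{locus_model}.
#' @param alleles List of \code{\link{allele_config}}s with unique names
#'   (default \code{\link{default_allele_panel}()}).
#' @param depth Reads per allele (default 1e6).
#' @param seed Integer master seed.
#' @param out_dir Optional output directory.
#' @return An \code{allele_panel}: \code{model}, \code{alleles},
#'   \code{counts} (list of \code{fragment_counts}), \code{expression}
#'   (data.frame sample/beta/f_enhancer/expression), \code{truth} (named
#'   list).
#' @export
make_allele_panel <- function(m = locus_model(),
                              alleles = default_allele_panel(),
                              depth = 1e6, seed = 1, out_dir = NULL) {
  nms <- vapply(alleles, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate allele names")
  counts <- vector("list", length(alleles))
  names(counts) <- nms
  f_enh <- expr <- numeric(length(alleles))
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    counts[[i]] <- simulate_counts(m, a, depth, derive_seed(seed, i))
    f_enh[i] <- expected_contact_frequency(m, a, m$enhancer_region)
    expr[i] <- simulate_expression(f_enh[i], m, derive_seed(seed, 1000 + i))
  }
  expression <- data.frame(sample = nms,
                           beta = vapply(alleles, `[[`, 0, "beta"),
                           f_enhancer = f_enh, expression = expr)
  truth <- c(list(seed = seed, depth = depth),
             m[c("locus_length", "n_fragments", "viewpoint_pos",
                 "barrier_pos", "decay_alpha", "enhancer_affinity_delta",
                 "expression_scale", "expression_exponent", "noise_sigma")],
             list(enhancer_start = m$enhancer_region$start,
                  enhancer_end = m$enhancer_region$end),
             stats::setNames(as.list(expression$beta),
                             paste0("beta.", nms)))
  panel <- structure(list(model = m, alleles = alleles, counts = counts,
                          expression = expression, truth = truth),
                     class = "allele_panel")
  if (!is.null(out_dir)) write_panel(panel, out_dir)
  panel
}

#' Write an allele panel to a directory
#'
#' @param panel An \code{allele_panel}.
#' @param out_dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_panel <- function(panel, out_dir) {
  stopifnot(inherits(panel, "allele_panel"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fragment_bed(panel$counts[[1]]$map,
                     file.path(out_dir, "fragments.bed"))
  for (nm in names(panel$counts)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    write_counts_tsv(panel$counts[[nm]],
                     file.path(out_dir, paste0("counts_", safe, ".tsv")))
  }
  utils::write.table(panel$expression,
                     file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tl <- vapply(names(panel$truth), function(k)
    paste0(k, "=", format(panel$truth[[k]], scientific = FALSE, digits = 15)),
    character(1))
  writeLines(tl, file.path(out_dir, "truth.txt"))
  invisible(out_dir)
}
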