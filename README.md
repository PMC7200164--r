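# fourCquant

Quantification of 4C-seq contact profiles and CTCF insulation around a
single viewpoint.

4C-seq (circular chromosome conformation capture sequencing) measures how
often one chosen restriction fragment — the *viewpoint*, typically a gene
promoter — touches every other fragment of its locus. When a CTCF-based
insulator is placed between a gene and its enhancer, the contact profile
redistributes and expression drops. `fourCquant` implements the
quantitative toolkit for analyzing such experiments on an allelic series:

- **Fragment maps** — in silico two-enzyme digestion (e.g. NlaIII/DpnII) of
  a locus FASTA into the restriction-fragment backbone that reads are
  counted on, with blind-fragment flags and BED import/export.
- **Contact profiles** — replicate pooling, reads-per-million
  normalization, 7-fragment running-mean smoothing for BedGraph tracks, and
  viewpoint-excluded contact frequencies: the fraction of reads in an
  interval among all reads in the locus, after removing the viewpoint
  fragment ± 10 kb,

  f(I) = reads(I ∖ excl) / reads(locus ∖ excl).

- **Folding directionality** — (R − L)/(R + L) on raw read counts in
  windows of a given span (100 kb, 500 kb, 1 Mb) flanking the viewpoint;
  +1 means all contacts lie rightward.
- **Contact-profile PCA** — contact ratios in fixed bins (30 kb default)
  across samples, column-centered unscaled PCA, per-bin component loadings
  ℓ_jk = v_jk √λ_k rendered as genome tracks, and a changepoint scan that
  localizes where the contact pattern pivots between sample groups.
- **Power-law scaling** — OLS on log10–log10 axes for expression vs
  enhancer contact frequency (E = c·f^γ) and for contact–contact scaling
  between two regions, with Spearman rank correlation.
- **Synthetic locus generator** — a distance-decay + permeable-barrier
  model of an engineered haploid ~3 Mb locus: contact probability ∝ d^−α,
  cross-barrier contacts attenuated by a per-allele permeability β ∈ (0, 1],
  enhancer contacts attenuated as β^δ (δ ≥ 1, so insulation hits the
  gene–enhancer contact preferentially), multinomial read sampling, and
  expression linked to enhancer contact by a power law with lognormal
  noise. Ground truth is recorded so every statistic above can be tested
  against a known answer.

## Worked example

Simulate the default nine-allele insulator titration panel and run every
stage:

```r
library(fourCquant)

m <- locus_model()                               # 3 Mb locus, VP at 900 kb, barrier at 930 kb
panel <- make_allele_panel(m, depth = 1e6, seed = 1)

fc <- panel$counts[["STITCH"]]                   # strongly insulated allele
contact_frequency(fc, m$enhancer_region)
#> contact_frequency synthLocus:930000-1340000 = 0.0502 (25450 / 506766 reads)

folding_directionality(fc, 5e5)
#> directionality VP-synth @ 500000 bp: -0.483 (L=325488, R=113339)

grid <- make_bins(genomic_interval(m$chrom, 0, m$locus_length), 30000)
res <- run_pca(build_bin_matrix(unname(panel$counts), grid))
res
#> pca_result: 9 samples x 100 bins; variance explained: PC1 99.9%, PC2 0.0%, PC3 0.0%
loading_changepoint(component_loadings(res, 1))$boundary
#> [1] 930000

f_enh <- sapply(panel$counts, function(fc)
  contact_frequency(fc, m$enhancer_region)$ratio)
fit_power_law(panel$expression$expression, f_enh)
#> scaling_fit: exponent 4.004, intercept(log10) 2.008, Spearman rho 0.967, n = 9
```

Reading the numbers: the insulated allele keeps only 5% of informative
contacts in the enhancer region (the open allele keeps ~28%), and its
folding directionality at 500 kb is pulled to −0.48 because the barrier
sits immediately to the viewpoint's right. PC1 of the binned contact
ratios absorbs ~99.9% of the variance, separates blocking from
non-blocking alleles, and its loading changepoint lands exactly on the
barrier position (930 kb). The fitted expression exponent 4.004 recovers
the generator's γ = 4 and the Spearman correlation is 0.97 across the
nine alleles.

`run_pipeline(out_dir, seed = 1)` executes all of the above and writes
BedGraph tracks, TSV tables, and a checksummed manifest; re-running with
the same seed reproduces every file byte for byte.

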