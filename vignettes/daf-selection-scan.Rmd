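---
title: "Detecting purifying selection from DAF spectra of annotated SNP classes"
author: "dafscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting purifying selection from DAF spectra of annotated SNP classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Genome-wide association signals frequently land far from any protein-coding
gene, so prioritising variants for follow-up purely by gene proximity throws
information away. A complementary signal is *negative (purifying) selection*:
if an annotation class — constrained elements, a histone-methylation mark,
predicted microRNA targets — is intolerant of new mutations, deleterious
derived alleles in it are held at low population frequency. Its
derived-allele-frequency (DAF) spectrum is then shifted toward zero relative
to neutrally evolving sequence, and SNPs in it are better candidates for
functional follow-up.

`dafscan` implements that scan as a reusable pipeline:

1. **Filtering** (`filter_snps`): drop SNPs that map to multiple genomic
   positions, map to the Y chromosome, are absent from dbSNP, are not
   biallelic single-base substitutions, and (by default) were not
   resequenced. The resequencing restriction trades sample size against the
   ascertainment bias that otherwise inflates allele frequencies in
   well-studied genic regions. Drops are attributed to the *first* failing
   rule in that fixed order so the filter log is deterministic; the order of
   exclusions does not change the kept set, only the attribution.
2. **Polarization** (`polarize_snps`): the ancestral allele is the
   chimpanzee base at the orthologous position when it matches either human
   allele; otherwise the macaque base is consulted; otherwise the SNP is
   discarded. A missing outgroup base is treated exactly like a mismatching
   one — the rule is match/non-match. The derived allele frequency is then
   `1 - frequency(ancestral)` in each population. Sites monomorphic within a
   single population (DAF 0 or 1) are retained in that population's
   spectrum; they carry real information about the absence of segregating
   derived alleles, and excluding them is left to the caller.
3. **Class construction** (`build_class_catalog`): promoter, splice-control
   and coding classes are derived from gene models; constrained elements,
   regulatory attributes, ancestral repeats and similar sets are supplied as
   BED intervals; constrained-element subsets (minus coding, minus genes, at
   least 1 kb / 100 kb from the nearest gene) are derived automatically.
4. **The scan** (`run_scan`): each class's DAF spectrum is compared with a
   background spectrum by a one-sided Mann–Whitney rank test, and the ranked
   p-values pass through Benjamini–Hochberg step-up FDR control.
5. **The hitchhiking control** (`matched_null_test`): a permutation null of
   random regions matched in size and gene distance, to exclude linked
   selection as the explanation for a class's low spectrum.

## Coordinate and window conventions

All internal coordinates are 0-based half-open (`[start, end)`), BED's native
convention; GFF3/GTF input is converted once on read
(`start_0 = start_1 - 1`, `end_0 = end_1`). A SNP occupies the 1-bp interval
`[pos, pos + 1)` and belongs to a class iff that interval intersects the
class; a SNP at `pos = end` of an interval is therefore outside it.

The bp windows are read as inclusive of both stated endpoints *and* of the
anchor base where one exists (a TSS is a base; an exon/intron boundary is
not), stated explicitly because prose window definitions are ambiguous:

* **Promoter**: 1000 bases upstream of the transcription start site, the TSS
  base itself, and 200 bases downstream — 1201 bp per transcript,
  strand-aware, clipped at the chromosome start.
* **Splice acceptor** (intron→exon in transcript orientation): 50 intronic +
  2 exonic bases (52 bp), covering the polypyrimidine tract.
* **Splice donor** (exon→intron): 3 exonic + 6 intronic bases (9 bp).

Windows are clipped to their carrying intron/exon when those are shorter,
and per-gene regions are the union over *all* transcripts — no canonical
transcript is chosen. Class sizes are merged interval lengths (the unmerged
sum is reported alongside, since supplied sets may overlap internally).

Distances to genes are edge-to-edge gaps to the transcript-union gene span:
whole-interval queries use the plain half-open gap; SNP queries are measured
from the base position itself. "Minus" subsets subtract base-wise (elements
may be truncated or split); "minimum distance" subsets keep or drop whole
elements atomically — distance is a property of an element, coverage of a
base.

## The rank test and its p-values

The Mann–Whitney U statistic is computed from midranks, so ties (inevitable
when DAFs live on a `1/2n` grid) are handled throughout. The one-sided
alternative "class stochastically smaller than background" is the default:
the scan looks specifically for an excess of *low* derived frequencies, and
a two-sided test is available by flag.

Three p-value routes, chosen by `method = "auto"`:

* tie-free data with `min(n)` at most `exact_threshold` (default 50) and a
  background below 10,000: the exact null distribution of U
  (`stats::pwilcox`);
* tied data with combined `n` at most 25: exact enumeration of all
  class/background splits of the pooled midranks;
* otherwise: normal approximation with tie-corrected variance and continuity
  correction (the same formula as `stats::wilcox.test`).

Exact enumeration against genome-scale backgrounds is refused and falls back
to the approximation with a logged note — with `min(n)` in the hundreds the
approximation error is far below any decision threshold (the test suite
bounds the exact-vs-approximate gap at 0.01 for `n = (10, 200)`).

Reported p-values are floored at `1e-8`; full precision is kept internally
and used for ranking, so classes below the floor still order correctly.

Two FDR-related quantities appear in the output and are deliberately kept
apart: the step-up **critical values** `i * alpha / m` against which ranked
p-values are compared, and the **BH-adjusted p-values**
`min over j >= i of (m * p_j / j)`. The declared number of tests `m` is a
parameter, not inferred from the input: a study may declare more tests than
it could compute (the classical situation is a genome-background scan that
skips small classes whose exact test is infeasible against millions of
background SNPs, yet still corrects for the declared family).

Overlap removal before each comparison follows the background: against the
genome-wide background, overlapping SNPs are removed from the *background
only* (the genome contains every class, and the class sample is never
changed); against ancestral repeats, overlap is removed from *both* sides,
leaving disjoint samples.

## The matched-region permutation null

A low DAF spectrum can also arise from hitchhiking or background selection —
linkage to selected sites nearby, rather than selection on the class itself.
The control replaces each attribute region with a random region of
*identical length* at *identical edge distance* from a uniformly drawn gene
(side up/downstream randomized; the distance is matched to the drawn gene,
not re-measured against all genes, since exact matching against a global
nearest-gene distance is generally infeasible). For sources overlapping a
gene (distance 0) the source's offset relative to its own nearest gene's
start is transplanted to the drawn gene. Overlapping sampled regions within
one iteration are merged before SNP mining so no SNP enters the pool twice.
Each iteration pools the SNPs in the sampled regions and produces one
Mann–Whitney p-value against the chosen background; after `n_iter` (default
100) iterations the real p-value's rank among the generated ones is the
result. A class whose real p-value beats all 100 generated p-values — and
whose FDR-adjusted real p-value still does — cannot be explained by its
positioning relative to genes alone. An iteration that pools zero SNPs is
re-drawn once and then recorded as `p = 1` with a warning, biasing the
control conservatively.

## The synthetic-data generator

The generator exists so every downstream stage is testable without any
external download; it defines the study conditions and is not a tuning
dial. Population frequencies are drawn from the classical diffusion
stationary form of the site frequency spectrum,

$$f(q \mid \gamma) \propto \frac{1 - e^{-\gamma(1-q)}}{q(1-q)\,(1 - e^{-\gamma})},$$

with `gamma = 0` reducing to the neutral `1/q`. Negative `gamma` (scaled
selection coefficient `2Ns` of a deleterious derived allele) tilts mass
toward low frequencies — precisely the signature the scan detects. Sampling
is inverse-CDF on a 4096-point grid over `(1/(2·2n), 1 - 1/(2·2n))` (finer
than one sample-frequency step), followed by a binomial draw of `2n`
chromosomes, so monomorphic sample outcomes occur naturally.

Default study conditions: three 10-Mb chromosomes, 100 non-overlapping
genes (2–20 kb), a constrained-element-like class of 200 elements at
`gamma = -15` carrying 600 SNPs, a neutral ancestral-repeat class, 6000
neutral background SNPs, three populations of `2n = 48` chromosomes sharing
one population frequency per SNP with independent binomial sampling, a 2%
chimpanzee call failure rate and an 80% macaque rescue rate. `gamma = -15`
is a strong but realistic intensity for conserved functional sequence;
`2n = 48` matches a small resequencing panel; the outgroup rates give the
roughly 2% polarization discard one sees with two primate outgroups. The
test and acceptance suites scale these conditions down (1–2 chromosomes of
2–5 Mb, 8–40 genes, 250–550 class SNPs, single population) so that hundreds
of replicates run in minutes; the quantities checked — type-I rate, power,
calibration — are rates over replicates, not functions of genome size.

What the generator deliberately does **not** emulate: linkage
disequilibrium (every SNP draws an independent frequency), demographic
history (no bottlenecks or growth, no covariance between populations beyond
the shared `q`), mutation-rate heterogeneity, and real ascertainment bias
(flags are set clean by default). Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under an idealised
frequency model — not that real data meet these assumptions. In particular
the matched-null control is *validated* here under independence, whereas its
scientific purpose on real data is precisely to catch the linkage effects
the generator omits.

All randomness in a bundle flows from the single seed in its configuration
(one seeded R RNG consumed sequentially), so a bundle is a pure function of
its configuration; the permutation test takes its own seed the same way.

## Numerical and degenerate-input choices

* Frequencies are validated into `[0, 1]` on read; duplicate SNP ids are an
  error, not a silent de-duplication.
* Chromosome names are taken verbatim; no `chr`-prefix normalization is
  applied anywhere, so a naming mismatch surfaces as empty intersections
  rather than silently renamed data.
* A class that becomes empty after overlap removal is a degenerate
  comparison: skipped with a warning in the scan, an error when tested
  directly.
* Two samples with all values identical give `p = 1` with a warning rather
  than a 0/0 variance.
* Zero-length classes report an undefined density (`NA`), not an error.
* DAF histograms use fixed 0.05-wide bins, right-open except the last.
* Written tables serialise doubles at 17 significant digits so a
  write/read round trip preserves rank ties exactly (byte-identical reruns
  are a tested contract).

## Interfaces

The package's functions are the interface, wired end-to-end by
`run_pipeline(run_config(...))`, which writes the density table, ranked scan
tables, per-class DAF medians and histograms, class-intersection counts,
the matched-null summaries, and a provenance record; `generate_bundle()` +
`write_bundle()` produce complete on-disk input sets (GFF3, BED, TSV, JSON)
for the file-based route.

## Known limitations

* No composite-likelihood or SFS-model-fitting selection statistics
  (Tajima's D, Fay–Wu's H, DFE inference) — the scan is rank-based by
  design.
* No probabilistic ancestral-state reconstruction and no correction for
  ancestral misidentification; polarization is the deterministic two-outgroup
  rule.
* No liftover, no reference-FASTA validation of alleles.
* Multi-assembly mapping bookkeeping is consumed as the `multi_mapped` input
  flag, not reconstructed.
* The matched-null control matches size and gene distance only; it is not
  recombination-map-aware and does not model B-values.
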