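# dafscan

Detects **negative (purifying) selection** acting on annotation-defined
classes of SNPs — promoters, splice control regions, coding sequence,
cross-species constrained elements, experimentally mapped regulatory
attributes such as histone-methylation regions — by comparing each class's
**derived allele frequency (DAF) spectrum** with genome-wide and
ancestral-repeat backgrounds. Classes under purifying selection carry an
excess of low-frequency derived alleles; their SNPs are strong candidates
for follow-up after genome-wide association or whole-genome sequencing
studies, *whether or not a protein-coding gene is nearby*.

The package is aimed at population geneticists and GWAS analysts who want a
principled, reproducible way to rank annotation classes (and hence the SNPs
in them) by evidence of functional constraint.

## The method

For each SNP the **ancestral allele** is the chimpanzee base at the
orthologous position when it matches either human allele, else the macaque
base, else the SNP is discarded; the **derived allele** is the other human
allele, and its frequency in a population sample of `2n` chromosomes is the
DAF. For an annotation class `C` with background `B` (the genome-wide SNP
set, or SNPs in ancestral repeats — transposable-element relics that are a
standard neutral reference), the scan tests

- H0: DAF spectra of `C` and `B` are exchangeable
- H1: `C` is stochastically **smaller** (excess of rare derived alleles)

with a Mann–Whitney U rank test (midranks for ties; exact null distribution
for small tie-free samples, full enumeration for small tied samples, normal
approximation with tie-corrected variance otherwise). Overlapping SNPs are
removed from the background only (genome comparisons) or from both sides
(ancestral-repeat comparisons). Ranked p-values pass through
Benjamini–Hochberg step-up FDR control at level α: rank-`i` critical value
`i·α/m` and adjusted p-value `min_{j≥i} (m·p_j / j)`, with the number of
declared tests `m` an explicit parameter.

A **matched-region permutation null** controls for hitchhiking and
background selection: each attribute region is replaced by a random region
of identical length at identical distance from a randomly drawn gene, the
SNPs in the sampled regions are pooled, and the real Mann–Whitney p-value is
ranked among 100 such "generated" p-values.

A synthetic-data generator (`generate_bundle`) draws population frequencies
from the diffusion-form site frequency spectrum
`f(q|γ) ∝ (1 − e^{−γ(1−q)}) / (q(1−q)(1 − e^{−γ}))` (`γ = 2Ns`; `γ = 0`
gives the neutral `1/q`), so the whole pipeline is testable end to end
without any external download.

## Worked example

```r
library(dafscan)

cfg <- simulation_config(seed = 7)      # 3 x 10 Mb, 100 genes,
bundle <- generate_bundle(cfg)          # constrained-like class at gamma = -15

filt <- filter_snps(bundle$snps)
pol  <- polarize_snps(filt$kept, bundle$outgroup)
pol$counts
#>     chimp   macaque discarded
#>      7950       132        18

catalog    <- build_class_catalog(bundle$genes, bundle$region_sets)
membership <- assign_snps_to_classes(pol$polarized, catalog)
run_scan(pol$polarized, membership, "AFR", background = "genome")
#> <scan_result> AFR vs genome background (8 classes)
#>                                   class n_class       U  p_value median_class
#> 1                  constrained_elements     663 1359192 1.00e-08       0.0208
#> 2     constrained_elements_minus_coding     642 1319472 1.00e-08       0.0208
#> 3      constrained_elements_minus_genes     626 1279604 1.00e-08       0.0208
#> 4   constrained_elements_1kb_from_genes     621 1271146 1.00e-08       0.0208
#> 5 constrained_elements_100kb_from_genes     274  600958 1.00e-08       0.0208
#> 6                           splice_site       1    1352 1.24e-01       0.0208
#> 7                                coding     206  808104 4.62e-01       0.1042
#> 8                              promoter      30  141740 9.50e-01       0.1667
#>   rank critical_value adjusted_p significant
#> 1    1        0.00625   1.60e-08        TRUE
#> 2    2        0.01250   1.60e-08        TRUE
#> 3    3        0.01875   1.60e-08        TRUE
#> 4    4        0.02500   1.60e-08        TRUE
#> 5    5        0.03125   1.60e-08        TRUE
#> 6    6        0.03750   1.66e-01       FALSE
#> 7    7        0.04375   5.28e-01       FALSE
#> 8    8        0.05000   9.50e-01       FALSE
```

Reading the output: of 8100 simulated SNPs, 7950 were polarized by the
chimpanzee call, 132 rescued by macaque and 18 discarded. The class
simulated under strong purifying selection (`γ = −15`) and all four of its
derived subsets rank at the top with p-values at the 1e-8 reporting floor
and survive FDR control (their DAF median 0.021 versus 0.104 for neutral
coding sequence), while the neutral gene-structure classes do not — exactly
the separation the scan is built to detect. The hitchhiking control
confirms the signal is not positional:

```r
matched_null_test(bundle$region_sets$constrained_elements, pol$polarized,
                  bundle$genes, cfg$chrom_lengths, n_iter = 20, seed = 3)
#> <matched_null_result> AFR vs genome: real p = 4.82e-82 (adjusted 2.12e-80);
#>   0 of 20 generated p <= real
```

`run_pipeline(run_config(...))` wires all stages together and writes the
density table, ranked scan tables, DAF histograms, intersection counts and
a provenance record to disk.

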