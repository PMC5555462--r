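# rcscan

Genome scans for quantitative traits in recombinant congenic strain (RCS)
panels of inbred mice.

## The problem

Plasma IgE concentration — elevated in allergy and a risk factor for asthma
— differs strongly between the A/J and C57BL/6J mouse strains. The AcB/BcA
panel of recombinant congenic strains turns that difference into a mapping
resource: each fully inbred RCS carries ~12.5% of one parent's genome
(the *minor donor*) in fixed chromosomal blocks on the other parent's
background, so a marker-by-marker comparison of strains carrying the A/J
versus the C57BL/6J allele localizes the loci controlling the trait.

`rcscan` implements that analysis end to end, plus a breeding-scheme
simulator so every stage can be exercised and calibrated without external
data:

- **Panel simulation** — explicit pedigrees (F1, two backcrosses to the
  recurrent parent, sib-mating to fixation) under Haldane's
  no-interference meiosis model, $c = (1 - e^{-2d})/2$; chromosome
  substitution (consomic) strains; QTL-driven log-normal phenotypes
  $\log_2 \mathrm{IgE} = \mu_c + \sum_q \beta_q x_q + u_{strain} + e$.
- **Strain statistics** — log2 means ± SEM, pooled t-tests, many-to-one
  Dunnett comparisons of each RCS against its major parental strain
  (equicorrelated multivariate t), Bonferroni-corrected three-group
  contrasts for consomic designs.
- **Genome scan** — per-marker OLS regression of strain-mean log2
  phenotype on parental-origin genotype (0 = C57BL/6J, 1 = A/J allele;
  equivalent to the pooled two-sample t-test), permutation-derived
  genome-wide thresholds (empirical $(1-\alpha)$ quantile of the maximum
  $-\log_{10} p$ over label permutations), and region delimitation as
  maximal runs of contiguous significant markers.
- **I/O and reporting** — TSV readers/writers for genotype, phenotype and
  marker-map tables, YAML run configs, Manhattan plots, region reports,
  and a one-call `run_pipeline()` (CLI wrapper in `inst/scripts/rcscan.R`).

## Worked example

Simulate a study-sized panel (10 AcB + 21 BcA strains, 1215 markers),
plant a 1.5 log2-unit QTL on chromosome 4 near 84 Mbp, and scan:

```r
library(rcscan)

map    <- default_marker_map()                      # 1215 markers, chr 1-19 + X
panel  <- breed_rcs_panel(breeding_config(seed = 1), map)
qtl    <- qtl_spec(effects = data.frame(marker_id = "m4_039", effect = 1.5))
phenos <- simulate_phenotypes(panel, qtl, n_per_strain = 10, seed = 2)

y    <- strain_means(phenos, "baseline")            # 31 RCS strain means
scan <- scan_genome(y, panel, map)
thr  <- permutation_threshold(y, panel, map, n_perm = 10000, seed = 3,
                              condition = "baseline")
thr
#> threshold_set: baseline alpha=0.05 n_perm=10000  -log10(p)=3.322  p=0.000476

regions <- call_regions(scan, thr)
regions[regions$chr == "4", ]
#>    condition chr start_mbp   end_mbp n_markers peak_marker       peak_p
#> 10  baseline   4  31.51938  44.56188         7      m4_015 7.407506e-05
#> 11  baseline   4  61.95188 101.07938        19      m4_046 1.649437e-05
#> 12  baseline   4 111.94812 114.12188         2      m4_052 3.069766e-04
#> 13  baseline   4 129.33812 138.03312         5      m4_060 2.519190e-05
```

The threshold line: across 10,000 permutations of the strain labels, the
95th percentile of the genome-wide maximum $-\log_{10} p$ was 3.322, i.e.
markers need $p \le 4.8 \times 10^{-4}$ for genome-wide significance at
$\alpha = 0.05$. The planted marker (`m4_039`, 83.7 Mbp) falls inside the
62–101 Mbp chromosome-4 region whose peak p is $1.6 \times 10^{-5}$. This
run also calls regions elsewhere: a lone QTL this large separates the two
family backgrounds (AcB strains carry the A/J allele almost everywhere),
which lifts association genome-wide — see the methods vignette
(`vignettes/rcs-genome-scans.Rmd`) for why, and for when a per-family
analysis is preferable.

`manhattan_plot(scan, thr)` draws the scan;
`informative_strains(phenos, "baseline")` flags strains differing from
their major parent (Dunnett-adjusted).

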