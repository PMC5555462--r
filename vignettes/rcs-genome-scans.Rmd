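---
title: "Genome scans in recombinant congenic strain panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome scans in recombinant congenic strain panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcscan)
```

## The mapping problem

Recombinant congenic strains (RCS) are fully inbred mouse strains bred from
two parental strains so that each carries a small fraction (~12.5%) of one
parent's genome — the *minor donor* — in fixed chromosomal blocks on the
other parent's background. The AcB/BcA panel derives from A/J and C57BL/6J:
AcB strains carry C57BL/6J segments on an A/J background, BcA strains the
reverse. Because every strain is inbred, a panel phenotyped once is a
permanent mapping resource: a quantitative trait that differs between the
parents can be localized by asking, marker by marker, whether strains
carrying the A/J allele differ from strains carrying the C57BL/6J allele.

`rcscan` implements this strain-panel genome scan for a positive,
log-normally distributed trait such as plasma IgE concentration, together
with a breeding-scheme simulator that generates AcB/BcA-style panels so the
whole pipeline can be exercised and calibrated without any external data.

## The breeding simulator

Each simulated strain is bred through an explicit pedigree:

1. F1 between the parents (one haplotype from each);
2. two backcrosses to the recurrent (major-donor) parent, giving an N3
   individual with expected minor-donor fraction $(1/2)^{k+1} = 12.5\%$ for
   $k = 2$ backcrosses;
3. brother–sister mating until every marker is homozygous in the breeding
   pair.

Meiosis uses the no-interference model: crossover counts per chromosome are
Poisson in the chromosome's genetic length (Morgans) and crossover positions
are uniform on the cM scale, so adjacent markers at distance $d$ Morgans
recombine with Haldane's map-function probability
$c = (1 - e^{-2d})/2$. The published construction of the real AcB/BcA
pedigrees is not reproduced here (exact inbreeding generations and residual
heterozygosity per strain live in the panel's construction report); the
simulator is pinned to the one quantitative constraint the panel design
states — the 12.5/87.5 composition — which the F1 → two-backcross →
sib-mating scheme yields in expectation. Sib-mating is capped at 20
generations (by then residual heterozygosity is rare); any residual
heterozygous segment is then fixed by a fair coin per segment, which
preserves the expected donor fraction and guarantees termination.

The default marker map is synthetic: 1215 markers — the density of the
established SNP/microsatellite panel used for AcB/BcA scans — spread over
the 19 autosomes and X proportionally to mm10 chromosome length, with a
uniform 0.5 cM/Mbp genetic map (only physical positions are published for
such marker lists; 0.5 cM/Mbp gives a ~13-Morgan genome, close to the
standard mouse map length). Real maps can be supplied as a `marker_map`.
The X chromosome is simulated and scanned like an autosome: study animals
are male and strains inbred, so parental-origin coding is well defined
either way.

## The phenotype model

Animal-level phenotypes are generated on the log2 scale:

$$\log_2 \mathrm{IgE}_{ija} = \mu_c + \sum_q \beta_q \, x_{iq} + u_i + e_{ija}$$

with condition baseline $\mu_c$, additive QTL effects $\beta_q$ (log2 units
added when strain $i$ carries the A/J allele $x_{iq} = 1$), a strain random
effect $u_i \sim N(0, \sigma^2_s)$ shared across conditions, and an animal
residual $e \sim N(0, \sigma^2_e)$. Reported IgE is $2^{\log_2 \mathrm{IgE}}$,
hence log-normal and strictly positive. Defaults are $\sigma^2_s = 0.25$,
$\sigma^2_e = 0.5$ (log2-units²), group sizes of 5–20 animals per strain and
condition, and condition baselines of 7, 9 and 11 log2(ng/ml) for baseline,
OVA-PBS and OVA-OVA — IgE of roughly 128, 512 and 2048 ng/ml, the order of
magnitude and allergen-driven rise seen in mouse plasma. The three
conditions are the allergen-exposure design: unsensitized baseline,
ovalbumin-sensitized/PBS-challenged, and ovalbumin-sensitized/
ovalbumin-challenged.

What the generator does *not* emulate: sex differences, litter and cage
effects, dominance or epistasis, assay floor/ceiling effects beyond the
lognormal residual, and the real panel's linkage-disequilibrium structure
beyond what the breeding scheme induces. Passing calibration tests on
simulated panels therefore demonstrates internal statistical validity of
the scan machinery — not that any particular real dataset meets the model's
assumptions.

## Strain-level statistics

All inference is on $\log_2$ values. `summarize_strains()` gives the
mean ± SEM per strain and condition. `parental_contrast()` compares two
strains with a two-sided t-test (pooled variance by default, Welch by flag;
the pooled form matches the one-way-ANOVA framework used for the
multi-strain comparisons). `dunnett_many_to_one()` compares each RCS to its
major parental strain — AcB versus A/J, BcA versus C57BL/6J — with t
statistics on the pooled ANOVA error and familywise adjustment under the
equicorrelated multivariate-t distribution; probabilities come from
Genz–Bretz quasi-Monte-Carlo integration (absolute tolerance ~1e-4, so the
documented agreement with the $k=1$ t-test is |Δp| < 1e-3). Correlation
uses the exact pairwise sample sizes by default; the balanced-design
constant 1/2 is available because commercial implementations differ and
the choice is not recoverable from a published analysis.
`bonferroni_three_group()` handles the three-strain consomic comparison
(e.g. A/J, C57BL/6J, CSS4): all pairwise contrasts on the pooled error,
p × 3 capped at 1. Strains whose adjusted p falls at or below 0.05 are
*informative*: they carry segregating alleles for the trait.

## The genome scan

The scan regresses per-strain mean log2 phenotype on genotype coded
0 = C57BL/6J allele, 1 = A/J allele, one marker at a time; for binary
genotype the slope t-test is algebraically the pooled two-sample t-test
comparing carrier groups (a property test holds this to 1e-12 relative).
Strain means — not animals — are the unit of analysis: strains are the
exchangeable units, and permuting animal-level data within a strain
structure would violate exchangeability. (An animal-level response can
still be supplied as `y` explicitly.) Parental and consomic strains are
excluded from the response by default: their genotypes are constant, or
single-chromosome, so a single-marker effect would be confounded with the
whole-genome background. Heterozygous and missing calls are dropped per
marker, and markers with fewer than 3 strains in either genotype class are
skipped — below that the slope test has fewer than 2 residual degrees of
freedom of contrast and is degenerate.

Genome-wide significance uses the standard family-wise permutation
construction: strain labels of the response are shuffled `n_perm` times
(default 10,000), the full scan re-run each time, and the genome-wide
maximum of $-\log_{10} p$ recorded; the threshold is the empirical
$(1-\alpha)$ quantile of those maxima. The quantile convention is the
ceiling order statistic ($k = \lceil q \cdot n \rceil$), so 10,000
permutations at $\alpha = 0.05$ use the 9,500th sorted maximum; the exact
convention behind any published threshold is rarely stated, and the choice
shifts the threshold by at most one order statistic. Thresholds are carried
on both reporting scales with `threshold_p = 10^(-threshold_neg_log10)`
held exact.

A *region* is a maximal run of consecutive non-skipped markers on one
chromosome, all at or below the threshold; bounds are the outermost
markers' Mbp positions (closed interval, single-marker regions allowed),
the peak is the smallest p with ties broken by lowest position, and by
default a single non-significant marker splits a region (`gap` is
configurable). Regions never span chromosomes.

### Family structure and single large QTL

One property of the combined AcB + BcA design deserves emphasis. A single
large-effect QTL does not only raise the phenotype of carrier strains — it
also separates the two family means, because AcB strains carry the A/J
allele at ~87.5% of loci and BcA strains at ~12.5%. Any family-level
phenotype difference is correlated with genotype at *every* marker, so a
strong lone QTL lifts association genome-wide, not just at its locus. The
scan's peak still localizes to the planted chromosome in the large majority
of simulated replicates (a property the test suite checks), but
surrounding regions can reach significance through this background. Real
complex traits spread their genetic variance over many loci of mixed sign,
which attenuates the family-mean gap; interpreting a combined-family scan
of a trait with a very large single-locus effect calls for caution, or for
per-family analysis.

## Numerical and design notes

- Permutation scans are vectorized: all permuted responses are fit at all
  markers via three matrix products, and since the residual degrees of
  freedom are constant for complete genotype data, p-values are evaluated
  only at each permutation's maximum |t|.
- p-values are floored at the smallest positive double so
  $-\log_{10} p$ stays finite; a zero pooled variance in the group
  comparisons is flagged degenerate rather than tested.
- Identical seeds give bit-identical panels, phenotypes, thresholds and
  output files; every stochastic entry point takes a seed.
- Calibration and power checks in the test suite run at deliberately
  desk-sized problem dimensions: 200 simulated strains for composition
  recovery, 200 null panels × 1000 permutations for family-wise error,
  100 replicates for planted-QTL recovery at the study's panel size
  (31 strains, 10 animals/strain). These sizes give Monte-Carlo standard
  errors small enough for 3-SE and binomial-CI checks while keeping the
  suite fast.

## Worked example

A small end-to-end run (tiny map and permutation count, for illustration):

```{r example, eval = FALSE}
map <- default_marker_map(300)
panel <- breed_rcs_panel(breeding_config(seed = 1), map)
qtl <- qtl_spec(effects = data.frame(marker_id = "m4_010", effect = 1.5))
phenos <- simulate_phenotypes(panel, qtl, n_per_strain = 10, seed = 2)

y <- strain_means(phenos, "baseline")
scan <- scan_genome(y, panel, map)
thr <- permutation_threshold(y, panel, map, n_perm = 1000, seed = 3,
                             condition = "baseline")
call_regions(scan, thr)
```

## Limitations

The simulator matches the AcB/BcA design in expectation, not any specific
strain's realized genome; detection-rate estimates transfer to real panels
only insofar as the variance components and marker density are realistic.
The scan is single-marker: no interval mapping, kinship correction,
multi-QTL selection or epistasis. Regions are delimited by marker
positions, so their physical bounds are only as fine as the map density.
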