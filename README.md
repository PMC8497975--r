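# darscale

Diversity-area relationship (DAR) scaling analysis for multi-site microbiome
cohorts.

## The problem

How much of a population's microbial diversity does one individual host, and
how does diversity accumulate as more individuals — or more body sites of one
individual — are sampled? The classical species-area relationship
`S = cA^z` answers such questions for richness; the DAR generalizes it to
Hill-number diversity of any order `q`,

    qD = (Σ p_i^q)^(1/(1-q)),    1D = exp(−Σ p_i ln p_i),

so richness (`q = 0`), Shannon diversity (`q = 1`) and Simpson diversity
(`q = 2`) are analysed with one set of tools. Two accrual models are fitted
to each diversity-accrual curve by log-linear least squares:

* PL:   `D = c A^z`          (`ln D = ln c + z ln A`)
* PLEC: `D = c A^z exp(dA)`  (`ln D = ln c + z ln A + dA`)

and four parameters are reported per diversity order: the scaling rate `z`,
the pairwise diversity overlap `g = 2 − 2^z`, the maximal accrual diversity
`Dmax = c(−z/d)^z e^(−z)` (a proxy for the population's potential
diversity, reached at `Amax = −z/d`), and `RIP = 100·c/Dmax`, the percent
ratio of individual to population diversity.

The package is aimed at microbiome researchers with taxon-abundance tables
(TSV or BIOM) plus subject/site metadata — for example multi-body-site 16S
cohorts binned at phylum to genus. It implements the two study designs used
for digestive-tract cohorts (inter-individual accumulation within a site;
intra-tract accumulation across sites in anatomical order), randomization
tests for pairwise site differences in `z` and `Dmax`, taxonomic collapsing
to any of the five ranks, and a calibratable synthetic-cohort generator for
validation.

## Worked example

Calibrate the synthetic generator's occupancy law to a target richness
scaling of `z = 0.30`, simulate one site sampled in 60 subjects, and run the
inter-individual design:

```r
library(darscale)

ab <- calibrateOccupancy(0.30, nRange = 1:60, poolSize = 300)
spec <- cohortSpec(nSubjects = 60, sites = "Stool", poolSize = 300,
                   occupancyBeta = ab, lognormalSigma = 2, readDepth = 10000)
cohort <- generateCohort(spec, seed = 11)
profiles <- interIndividualProfiles(cohort, "Stool", nResamples = 30, seed = 12)
profiles
```

```
DARProfileSet [inter-individual] Stool, level = genus, 30 resamples
 q  mean_z     se_z mean_c    mean_d mean_g mean_Dmax mean_RIP      R   p_value
 0 0.31105 0.002938 80.970 -0.012135 0.7593   255.339    31.71 0.9411 1.130e-26
 1 0.15303 0.020212  9.036 -0.010661 0.8865    16.499    55.22 0.6592 6.617e-04
 2 0.06410 0.032270  3.969 -0.011878 0.9523     5.166    75.39 0.5548 4.199e-04
 3 0.03757 0.025008  3.069 -0.009549 0.9721     3.679    82.45 0.4738 3.275e-03
 N_success n_resamples
        30          30
        16          30
        10          30
        11          30
```

Reading the `q = 0` row: richness accumulates across individuals with
scaling rate `mean_z = 0.311` (recovering the calibrated 0.30), implying a
pairwise overlap `g = 0.76` between two individuals' genus sets; the fitted
potential richness of the population is `Dmax ≈ 255` genera, of which an
average individual hosts `RIP ≈ 32%`. The scaling rate falls and the overlap
rises with the diversity order: individuals differ mainly in *which* taxa
they carry, much less in how abundance is distributed. `N_success` counts
the resampled accumulation orders in which both model fits succeeded (and
the PLEC cutoff `d` was negative, so `Dmax` exists).

Other entry points: `intraIndividualProfiles()` (accumulation across body
sites in anatomical order, `dtSiteOrder()`), `runAllLevels()` +
`writeProfileTable()` (both designs at several taxonomic ranks, tidy TSV
out), `randomizationTest()` / `pairwiseMatrix()` (permutation tests and the
coded site-by-site significance matrix), `readAbundanceTable()` /
`collapseToLevel()` (TSV/BIOM input, rank collapsing), and
`plotProfiles()` / `plotAccrualFit()` for the standard profile bars and
log-log fit figures. The methods vignette
(`vignettes/diversity-scaling.Rmd`) documents the models, the resampling and
permutation designs, and the generator's assumptions.

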