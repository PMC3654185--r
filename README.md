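# famlink

Family-based linkage and association analysis of a quantitative
endophenotype and a late-onset disease, in the style of classical
gene-mapping studies of nuclear families: a region shows linkage to a
trait, dense SNPs are typed under the peak, and the question becomes
*which variants explain the linkage signal, and do they also associate
with disease?*

The package implements the full chain, each stage re-implemented from
first principles rather than wrapped:

- **Multipoint IBD** for nuclear families by a hidden Markov model over
  inheritance vectors (two meiosis bits per sib, Haldane map function,
  founder-frequency emission when parents are ungenotyped; Mendelian-
  inconsistent markers dropped per family).  Verified against exhaustive
  inheritance-vector path enumeration.
- **Variance-components linkage** (univariate and bivariate): per-family
  multivariate normal with covariance
  `s2_q * Pi(c) + s2_g * 2Phi + s2_e * I`, GLS-profiled fixed effects,
  LOD curves, `1/2 chi2_0 + 1/2 chi2_1` pointwise p-values, and the
  bivariate locus correlation `rho_q` with LRTs against 0 and -1.
- **Age-adjusted disease score**: affection status minus the
  Kaplan-Meier cumulative incidence at the relevant age, so a binary
  late-onset disease can enter the quantitative-trait machinery.
- **Family association**: linear mixed model (sibship random effect,
  LRT p-values) for the trait; GEE logistic regression with
  exchangeable working correlation (model-based or robust SEs, OR per
  allele copy) for disease; two-population admixture MLE as a
  covariate; forward step-wise conditional selection; region scans with
  the MAF >= 0.05 plotting rule.
- **Linked-variance partition**: how much of the *linked-locus*
  variance does an associated SNP explain?  Fits a bivariate model to
  the trait and its genotype-adjusted residual (fixed effects only
  subtracted), tests `s2_q(resid) = s2_q(trait)` by a chi2_1 LRT, and
  reports percent of total and of linked variance, LOD_una vs LOD_adj,
  with an optional rank-based normalizing transform for stability.
- **LD and haplotypes**: EM haplotype frequencies, pairwise D/D'/r2 with
  profile-likelihood D' confidence intervals, confidence-interval
  haplotype blocks (95%-of-informative-pairs rule), greedy tag-SNP
  selection at r2 > 0.8, zero-recombinant family-aware haplotype
  dosages, haplotype association and an ordered-diplotype trend test.
- **Synthetic cohorts**: gene-dropping simulator that reproduces the
  study design the methods assume — 264 nuclear families (~970
  members), a 4-SNP tag cluster at 131 cM whose QTL drives about half
  the trait variance, an age-dependent disease from a Gompertz-hazard
  liability sharing the locus, and replication strata.  Exact founder
  origins are recorded so tests can compare against true IBD.

## Worked example

```r
library(famlink)

co   <- simulate_cohort(default_paper_config(seed = 1))
co
#> cohort: 3774 individuals in 1062 families, 72 markers
#> traits: 3774 phenotyped individuals
surf <- ibd_surface(co, families = nuclear_families(co)[1:264])
lc   <- lod_curve(co, "trait", surf,
                  ids = co$traits$id[co$traits$stratum == "linkage"])
lc
#> lod_curve (trait): peak LOD 3.066 at 131.2 cM over 184 positions

set.seed(1)
pr <- linked_variance_reduction(co, "trait", "T2", surf, lc$peak_cM)
pr
#> partition [T2] @ 131.2 cM: %total=56.0 %linked=74.3 LOD_una=3.48
#>   LOD_adj=0.30 p_red=9.69e-08
```

Read: the trait maps to 131 cM (peak LOD 3.1 in this simulated
cohort); adjusting the trait for the causal cluster SNP `T2` removes
most of the locus-specific variance (about three quarters of the
linked-locus variance, 56% of the total), collapsing the adjusted LOD
to 0.3 — the signature of a variant that accounts for a linkage signal.

The whole surface (scans, linkage curves, LD/blocks/tags, partition
table, stratified odds ratios, haplotype report) runs as one pipeline:

```r
run_pipeline(run_config(sim = default_paper_config()), "out/", seed = 1)
```

or from the command line:

```sh
Rscript inst/cli/famlink.R all --out out --seed 1
Rscript inst/cli/famlink.R simulate --out data --seed 1   # .ped/.map/.csv
```

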