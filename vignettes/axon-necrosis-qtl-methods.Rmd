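---
title: "Mapping and triaging modifiers of optic-nerve axon necrosis in an RI panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and triaging modifiers of optic-nerve axon necrosis in an RI panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riqtl)
```

# The problem

In a biparental recombinant inbred (RI) family such as the BXD mouse panel,
every strain is an inbred mosaic of the two parental genomes (coded `B` and
`D`). A quantitative phenotype measured across the family — here, the number
of necrotic retinal-ganglion-cell axons per optic-nerve cross-section in aged
mice — can be mapped to quantitative trait loci (QTL), and the genes under a
mapped locus can be triaged with expression, variant and network evidence.
`riqtl` implements that full workflow: strain aggregation and heritability,
outlier winsorization, two genome-scan methods with resampling-based
thresholds, cis-eQTL classification of expression microtraits, a
seven-criterion candidate cascade, GO over-representation of correlate
networks, and cross-trait correlate comparison. A synthetic panel generator
with planted ground truth makes every stage testable offline.

# Phenotype model

## Field counts and strain summaries

Counting is done on a minimum of 12 evenly spaced fields (7.49 um x 7.49 um)
per nerve cross-section. `nerve_counts()` converts field counts to a density
(counts per um^2 of sampled area) and extrapolates to the whole nerve area;
per-nerve counts are rounded half-up to integers. `strain_summary()` reduces
animal records to per-strain mean, SEM and replicate count — the shape in
which RI phenotypes are published and mapped.

## Heritability

`heritability()` fits the one-way random-effects ANOVA across strains.
With $MS_B$ and $MS_W$ the between/within mean squares and
$n_0 = (N - \sum n_i^2/N)/(k-1)$ the unbalanced-design replicate coefficient,

$$\hat V_e = MS_W, \qquad \hat V_a = \max\!\left(0, \frac{MS_B - MS_W}{n_0}\right),$$

and two heritabilities are reported: the conventional animal-level
$h^2 = V_a/(V_a+V_e)$ and the RI strain-mean version
$h^2_{RI\bar x} = V_a/(V_a + V_e/\bar n)$ with $\bar n$ the harmonic-mean
replicate count. The strain-mean version credits replication: it always
dominates the conventional value when $\bar n > 1$, and the two coincide at
$\bar n = 1$. A summary-level path reconstructs within-strain variances from
published SEMs as $s_i^2 = n_i \cdot \mathrm{SEM}_i^2$ and gives identical
answers to the replicate-level path.

## Winsorization

Extreme strains are not censored but winsorized before mapping, with a
rank-preserving unit-step rule: the $k$ flagged high strains, in ascending
raw order, become $\max(\text{retained}) + 1, +2, \dots, +k$; flagged low
strains, descending, become $\min(\text{retained}) - 1, -2, \dots$ This rule
was chosen because it reproduces exactly the four published replacement pairs
for the aged axon-necrosis panel (5,825/5,552/4,121 to 3,736/3,735/3,734
against a retained maximum of 3,733, and the low value to 616 against a
retained minimum of 617). Note the published record is internally ambiguous
about two raw values (the low strain is quoted both as 276 and as 376, the
top strain both as 4,122 and 5,825); the package uses the values quoted in
the winsorization procedure itself and does not attempt to reconcile the
others. `detect_outliers()` supplies an automatic Tukey-fence default
(`k_iqr = 1.5`) for pipelines where outliers are not hand-curated.

# Genome scans

## Dosage and the RI recombination model

Genotypes are coded as allele dosage 0 (`B`) / 2 (`D`), so a regression
slope is directly the additive effect per allele substitution.
Heterozygous and unknown calls are treated as missing — RI strains are
nominally homozygous. Between typed markers the expected dosage is the
conditional probability of the `D` state under a two-state Markov chain
whose step probability is the RI map-expanded recombination fraction

$$R(d) = \frac{4r}{1+6r}, \qquad r = \tfrac12\left(1 - e^{-2d/100}\right),$$

the sib-mating expansion of the Haldane single-meiosis fraction at distance
$d$ cM. The same $R(d)$ drives the genotype simulator, which generates each
strain directly as a Markov mosaic rather than simulating breeding
generations — the marginal structure is what mapping consumes, at a tiny
fraction of the cost.

## Haley-Knott regression

`hk_scan()` regresses strain means (unweighted) on expected dosage at every
typed marker and on a 1 cM pseudomarker grid, reporting
$LRS = n \ln(RSS_0/RSS_1)$ and $LOD = LRS/(2\ln 10)$. The LRS is invariant
under affine transforms of the trait and, for complete dosage columns,
reduces to $-n\ln(1-r^2)$, which lets permutations and bootstraps run as
single matrix products.

## Permutation thresholds and bootstrap localization

`permutation_thresholds()` permutes strain means, records each permutation's
genome-wide maximum LRS, and returns the empirical 95th percentile as the
genome-wide $p = 0.05$ significant threshold and the 37th percentile as the
suggestive threshold (genome-wide $p = 0.63$, one expected false positive
per scan — the GeneNetwork convention). `bootstrap_peak()` resamples strains
with replacement and tallies the argmax position (ties to the lowest
coordinate). `support_interval()` reports the 1.5-LOD drop interval around
the peak, extended one position outward on each side; 1.5 LOD was adopted
because the source analysis states its interval without stating a rule.

## Kinship-corrected mixed model

`lmm_scan()` fits, at each marker,

$$y = \mu + x\beta + u + \varepsilon, \quad u \sim N(0, \sigma_g^2 K),
\quad \varepsilon \sim N(0, \sigma_e^2 I),$$

with $K = ZZ^\top/p$ over the column-centred dosages of the $p$ markers
passing MAF > 0.05, recomputed per chromosome with LOCO (leave one
chromosome out) so a locus cannot absorb its own signal through the kinship
term. After one eigendecomposition of $K$ per chromosome, the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$ is profiled by bounded scalar search on
$\log_{10}\lambda \in [-5, 5]$. Maximum likelihood (not REML) is used so
that the reported $LRS = 2(\ell_1 - \ell_0)$ is a valid likelihood-ratio
statistic, with $\lambda$ re-optimized under both null and alternative; a
Wald mode (null $\lambda$, slope chi-square) is available as an option since
the upstream tooling's exact statistic is not documented. With $K = I$ the
model collapses exactly onto Haley-Knott, which the tests exploit as an
oracle, alongside a dense-grid multivariate-normal likelihood check.

# Expression and triage

## eQTL classification

Each probe's strain values are mapped as a microtrait (`eqtl_peak()`,
Haley-Knott by default for speed). A transcript is cis-modulated when its
peak lies on the gene's own chromosome within a window of the gene position
and reaches a minimum LRS. The phrase "within a 10 Mb window of its
position" is ambiguous between a 10 Mb total window and a 10 Mb half-width;
the package defaults to the conservative half-width of 5 Mb
(`cis_window_Mb = 5`, boundary inclusive) and exposes the wider reading as
configuration. The minimum LRS defaults in the pipeline to the suggestive
permutation threshold computed from the phenotype: under strain
exchangeability the permutation null of the genome-wide maximum depends on
the genotypes and strain count, not on which trait is permuted, so one
threshold serves all probes of a panel.

## Detection and probe hygiene

A probe is "detected" when its strain-mean log2 expression is at or above
6.8 (inclusive; a max-across-strains summary is available). Probes whose
target sequence overlaps a SNP between the parental genomes are excluded
from all triage criteria, since allele-dependent hybridization masquerades
as expression variation.

## The seven-criterion cascade

`triage()` scores every positional candidate: (1) inside the QTL interval
(closed boundaries); (2) cis-modulated in retina and/or eye; (3) among the
top-N trait correlates (sign-blind $|r|$ ranking, ties by probe id);
(4) detected; (5) has at least one SNP-free probe; (6) harbors a
nonsynonymous SNP, indel or transcript variant; (7) operates in a network
plausibly related to the phenotype. Criteria 2-5 are satisfied if satisfied
in either tissue, and any SNP-free probe of a gene can satisfy a
probe-level criterion. Tier 1 requires all seven, tier 2 exactly one
failure, and a relaxed mode waives the cis requirement. Criterion 7 — a
qualitative judgment in the source analysis — is operationalized as: at
least one significant terminal GO cellular-component term of the gene's
correlate network matches a configurable keyword pattern (default
`mitochondri|axon|cytoskelet`); it can be disabled or supplied externally.

## GO over-representation

`go_ora()` computes the upper-tail hypergeometric probability
$P(X \ge \text{observed})$ per term, the expected count
$|set| \cdot |term| / |background|$, the observed/expected ratio, and
Benjamini-Hochberg FDR across tested terms. The background is the
detection-passing genes on the platform, not the genome: correlate sets are
drawn from expressed genes, so an expressed background is the only fair
null. `terminal_significant()` keeps terms with FDR < 0.05 that have no
significant descendant — "terminal branches" of the significant subtree,
which may be interior nodes of the full DAG. The significance convention
(FDR rather than raw p, at 0.05) is the package's choice where the source
states none.

# The synthetic panel

`sim_config()` defaults define the emulated study: 75 strains genotyped on a
19-chromosome map at 2 cM spacing (2 Mb/cM), phenotyped with 1-10
replicates per strain at a baseline of ~2,000 necrotic axons per nerve, one
QTL on chromosome 12 at 110 Mb with additive effect +380 counts per D
allele, between-strain residual SD 600 (`var_strain = 3e5`), within-strain
SD ~894 (`var_within = 8e5`), an age trend of +34 counts per month above 13
months, and four injected outlier strains (three high, one low, at ~2.2
panel SDs before the random inflation factor). These components were chosen
once so that the published constraints emerge as consequences: the QTL
explains about 20% of strain-mean variance
($a^2 / (a^2 + V_s + V_e \overline{1/n}) \approx 0.21$), the plug-in
conventional heritability without the injected outliers is
$(a^2 + V_s)/(a^2 + V_s + V_e) \approx 0.36$, and the expected Haley-Knott
LRS at the locus is in the mid-teens. Two caveats the tests make visible:
the injected outliers inflate the raw-data ANOVA heritability above the
plug-in value (the estimator cannot distinguish an outlier strain from
genetic variance), and at this effect size the locus is marginally powered,
so individual panels scatter widely around the expected LRS — faithful to a
study whose locus reached genome-wide significance but not by a wide
margin.

Expression data are generated for two tissues (retina, eye) over a shared
catalog of 5,000 genes, 156 of them inside the 109-112.5 Mb interval.
Planted structure: 20 cis genes (effect 0.5 log2 units per allele at the
marker nearest the gene), a 50-gene module correlated with the trait at 0.7,
and a causal gene that sits exactly at the QTL, is cis-modulated, carries a
nonsynonymous SNP and an indel, keeps one SNP-free probe alongside a
SNP-contaminated duplicate, and is annotated to a "mitochondrion-like" GO
leaf together with the module. An IOP-like second trait is generated with
correlation -0.296 to the primary trait. What the generator does *not*
emulate: linkage disequilibrium between non-syntenic regions, genuine
45k-probe array density (the platform is scaled to 5,000 genes, so literal
top-1000/top-2000 correlate lists cover a much larger platform fraction
than on a real array and overlap counts are correspondingly larger),
epistasis, X-chromosome dosage, genotyping error, and realistic GO topology.
Passing tests therefore demonstrate the correctness of the machinery and
calibration of its statistics under the stated model, not robustness to
those real-data complications.

Counts are truncated (not re-drawn) at zero, which slightly biases the
lowest strains upward; this is documented rather than corrected because it
preserves the mean structure used by mapping.

# Numerical choices and problem sizes

- LRS clamps $1-r^2$ at machine epsilon; zero-variance dosage columns score 0.
- Eigenvalues of $K$ are clamped at zero; asymmetry beyond 1e-8 and
  negative eigenvalues beyond tolerance raise errors rather than warnings.
- $\lambda$ search tolerance 1e-8 on $\log_{10}\lambda$; argmax ties break
  to the lowest genomic coordinate everywhere.
- Permutations permute strain means, not animals — the scans map means.
- The test suite validates permutation calibration on 200 null panels of 75
  strains (5 chromosomes, 200 permutations each), parameter recovery on 50
  panels with a one-SD additive effect, and triage truth recovery on 20
  fixtures with a 1,200-gene platform; these sizes keep the full suite in a
  few minutes while leaving binomial acceptance bands meaningful.

# Limitations

The cis window, detection summary, correlate-ranking direction, criterion-7
keyword rule, and the GO significance convention are all explicit decisions
where the source workflow is qualitative or unstated; each is configurable.
The additive-effect estimate at a scan peak carries winner's-curse bias,
visible in the recovery tests as a median slightly above truth. The
mixed-model LRS and the Haley-Knott LRS are on the same scale but not
identical statistics; both are reported, as in the original analysis.
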