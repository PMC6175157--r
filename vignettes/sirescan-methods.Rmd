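---
title: "Models and methods behind sirescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sirescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirescan)
```

`sirescan` analyses sire-fertility evaluations such as sire conception
rate (SCR): per-bull conception-rate deviations in percentage points,
published repeatedly over time with a reliability per record. This
vignette documents the statistical models, the synthetic-data design,
the numerical choices, and what the tests do and do not establish.

## 1. The additive scan

### Model

The additive stage fits the reliability-weighted repeatability animal
model

$$y = X\beta + Zu + W\,pe + e,$$

with $u \sim N(0, H\sigma_u^2)$, $pe \sim N(0, I\sigma_{pe}^2)$ and
$e \sim N(0, R^{-1}\sigma_e^2)$, where $R = \mathrm{diag}(r_i)$ holds
the record reliabilities. A reliability is a precision weight (a
function of the number of breedings behind the evaluation): record $i$
has residual variance $\sigma_e^2 / r_i$, so an evaluation backed by
many breedings is trusted more. Fixed effects default to an intercept
only, because SCR-style evaluations are already adjusted for management
and cow factors upstream; arbitrary covariate columns are accepted.

### Relationship matrices

* `build_A()` uses the tabular method; `inbreeding()` uses the
  Meuwissen–Luo recursion (no dense $A$ needed); `build_A_inverse()`
  applies Henderson's rules with inbreeding-adjusted Mendelian-sampling
  variances. The suite verifies
  $A^{-1}_{\text{rules}} A_{\text{tabular}} = I$ to $10^{-8}$ on random
  inbred pedigrees up to 1000 animals.
* `build_G()` is VanRaden method 1,
  $G = Z Z' / (2\sum_j p_j(1-p_j))$, with $Z$ the column-centered code
  matrix and $p_j$ observed B-allele frequencies by default. Because
  observed-frequency centering makes the column means exactly zero, the
  raw $G$ is structurally singular; the returned matrix is blended,
  $wG + (1-w)A_{22}$ with $w = 0.95$ by default, which guarantees a
  positive-definite matrix. No "tuning" (rescaling of $G$ to the
  $A_{22}$ means) is applied: the combined inverse is used exactly as
  $H^{-1} = A^{-1} + [0\;0;\;0\;G^{-1}-A_{22}^{-1}]$.
* Missing genotype codes are mean-imputed (centered value 0), the
  unbiased choice under missingness at random.

### Variance components and solving

`estimate_variance_components()` runs AI-REML on the record-level
covariance $V = \sigma_u^2 ZHZ' + \sigma_{pe}^2 ZZ' +
\sigma_e^2\,\mathrm{diag}(1/r)$, with step-halving whenever the
average-information step would leave the parameter space or decrease
the restricted likelihood, and boundary clamping at $10^{-10}$.
Convergence is declared at a log-likelihood change below $10^{-8}$ or a
parameter change below $10^{-6}$. The implementation is dense in the
number of records and is intentionally capped at 4000 records: at the
scale this package targets (desk-scale replication studies) this is
faster and more transparent than a sparse-MME REML, and fixed
components can be supplied for anything larger. The permanent-
environment variance is only identifiable when some animals have
repeated records; the function warns otherwise.

`solve_mme()` builds Henderson's mixed-model equations with
$\lambda_u = \sigma_e^2/\sigma_u^2$, $\lambda_{pe} =
\sigma_e^2/\sigma_{pe}^2$ and sparse $H^{-1}$, solves by sparse
Cholesky with one step of iterative refinement, and fails loudly if the
relative residual exceeds $10^{-8}$ (it is typically $10^{-14}$).
Rank-deficient fixed-effect matrices are pruned column-wise with a
warning.

### Back-solution and windows

SNP effects come from the GEBVs of the genotyped animals via
$\hat s = DM'[MDM']^{-1}\hat u$. With the default identity weights the
middle factor is taken to be the same blended $G$ used in $H^{-1}$
(scale $2\sum p(1-p)$), so the product is invertible by construction.
When all animals are genotyped and $w = 1$ with an invertible $G$, the
identity $M\hat s = \hat u$ holds to machine precision (tested to
$10^{-8}$ through a full MME solve).

Window results report $100\,\mathrm{Var}(\Sigma_j M_j\hat s_j)/
\sigma_u^2$ per window, where the variance is the empirical variance of
the window genetic values across genotyped animals and $\sigma_u^2$ is
the (REML or supplied) additive variance. Windows are *sliding*: one
window starts at every SNP and extends over all adjacent SNPs within
1.5 Mb. We chose sliding rather than fixed bins as the default because
published candidate regions are rarely aligned to fixed 1.5-Mb
boundaries; fixed non-overlapping bins are available via
`mode = "bins"`, and `collapse_windows()` greedily reduces overlapping
windows to per-region maxima for reporting.

## 2. The non-additive scan

Only the most reliable record per animal enters this stage
(`select_best_record()`; ties break toward the latest record for
determinism). Step 1 fits $y = X\beta + u + e$,
$u \sim N(0, G_2\sigma_u^2)$, by REML profiled on the eigendecomposition
of $G_2$ — a one-dimensional optimization in
$\delta = \sigma_e^2/\sigma_u^2$ — giving
$V_0 = G_2\hat\sigma_u^2 + I\hat\sigma_e^2$ factorized once; per-SNP
work is then a handful of matrix-vector products. An explicit direct
inverse of $V_0$ is kept as an internal consistency check
(`v0_inverse(..., method = "direct")`).

Step 2 recodes each SNP's codes (0,1,2) as (0,1,1), (0,0,1) or (0,1,0)
for dominance, recessive and overdominance tests, plus the additive
coding (0,1,2) reported alongside, and computes the score statistic

$$z = \frac{x'V_0^{-1}(y - X\hat\beta)}{\sqrt{x'Px}},\qquad
P = V_0^{-1} - V_0^{-1}X(X'V_0^{-1}X)^{-1}X'V_0^{-1}.$$

**Design decision — the denominator.** The textbook presentation of
this statistic writes $\sqrt{x'V_0^{-1}x}$. The two forms have the same
numerator (the GLS residual is $V_0^{-1}$-orthogonal to $X$), but only
the projected denominator makes $z$ exactly unit-variance under the
null: with the unprojected form, a coding with a large mean component
(e.g. the additive or dominance coding of a common allele) is
materially deflated — on 20 000 simulated null tests the genomic-
control $\lambda$ drops to about 0.5. Since the statistic is meant to
be asymptotically standard normal and the calibration suite demands a
type-I error of 0.045–0.055 at $\alpha = 0.05$, we use $x'Px$, which
for an intercept-only $X$ is simply the $V_0^{-1}$-weighted centering
of the coding. Effect estimates are reported as
$\hat\beta_{SNP} = x'Py/(x'Px)$ with the null-variance plug-in standard
error $1/\sqrt{x'Px}$ (score-test convention).

A recoded SNP that is constant (e.g. recessive coding with no BB
animals) is skipped with a recorded reason, never NaN. Missing codes
are mean-imputed after recoding so the tested $n$ is constant across
SNPs.

Genomic control uses the median definition
$\lambda = \mathrm{median}(z^2)/0.4549364$, deflating only when
$\lambda > 1$; the cited implementations of this correction do not
publish their exact algorithm, so the median form — robust to a small
fraction of true signals — is used and recorded in the run metadata.
Bonferroni adjustment is per coding family over the non-skipped tests,
with strict flagging (`adjusted P < alpha`, default 0.01).

## 3. Gene-set enrichment

SNPs are assigned to genes when within the gene or at most 15 kb up- or
downstream, boundaries inclusive; a SNP may hit several genes.
Internally gene intervals are 1-based inclusive (matching the marker
map); BED files are converted at the I/O boundary (`read_bed()` /
`write_bed()`). Significant SNPs are the $\lceil 0.01\,m\rceil$ largest
$|\hat s_j|$ (ties: $|$effect$|$ descending, then SNP ID ascending —
the rule is stated because a plain top-1% rule does not define ties).
$N$ counts genes hit by at least one *analyzed* SNP — not the whole
annotation — and $S$ counts genes hit by a significant SNP.

Each term is tested with the exact upper-tail hypergeometric
probability, computed as the upper sum in log space
(`lchoose`-based log-sum-exp), verified against full enumeration for
all universes $N \le 12$ and against the closed form on published
inputs. Raw P-values carry the significance flag (the historical
convention for this analysis reports unadjusted hypergeometric P);
a Benjamini–Hochberg column is emitted alongside for users who want it.
A single gene universe $N$ is used per run and recorded in the run
metadata, even when the GMT mixes collections of different provenance.

## 4. The synthetic-data generator

`run_simulation()` emulates the structure of a national bull-fertility
evaluation at desk scale. Defaults (all overridable in `sim_config()`):

| parameter | default | why |
|---|---|---|
| pedigree | 150 founders, 5 generations, 4 offspring/mating | ~1.6K related bulls, mirroring a five-generation AI pedigree |
| markers | 3000 SNPs, 29 autosomes, 10 Mb each | 29 bovine autosomes; density gives ~15 SNPs per 1.5-Mb window |
| founder MAF | Uniform(0.05, 0.5) | post-QC spectrum of a commercial array |
| $\sigma_u^2,\sigma_{pe}^2,\sigma_e^2$ | 4, 3, 13 (SCR points²) | repeatability ≈ 0.35, $h^2$ ≈ 0.2, realistic for SCR-type traits |
| additive QTL | 2 QTL, jointly 30% of $\sigma_u^2$ | large enough to be mapped at desk scale |
| recessive QTL | 1 QTL, −6 SCR points at B freq 0.12 | mirrors published recessive loci (−4 to −8 points at B frequencies 0.05–0.14) |
| records/animal | 1–8, reliabilities Uniform(0.3, 0.99) | ~4 evaluations per bull on average; the reliability distribution is not published, so a wide uniform is used |
| missing rate | 1% | comfortably above the 90% call-rate filter |

Genotypes are gene-dropped: founders from Hardy–Weinberg, offspring by
Mendelian segregation independently per marker. **No linkage is
simulated** — the window scan operates on map positions, which uniform
placement supports, and no test relies on LD decay. Recessive QTL act
on the phenotype scale only (a −6-point shift for BB animals, outside
$u$), so the additive scan sees them weakly and the recessive coding
strongly — the signature of a purely non-additive locus. Additive QTL
effects are sized from $a^2\,2p(1-p)$ under Hardy–Weinberg to hit the
configured variance fraction; the polygenic remainder is sampled down
the pedigree with inbreeding-adjusted Mendelian-sampling variances.

What a green test therefore establishes: correct linear algebra,
correct model fitting, calibrated tests and realistic power at the
published effect sizes, *given* unlinked markers, a closed homogeneous
population, and missingness at random. What it does not establish:
behavior under real bovine LD, selection, genotyping-batch artifacts,
or imputation error — all explicitly out of scope.

One structural consequence worth knowing: the polygenic background is
only visible to the genomic models through relatedness. In a simulation
with unrelated founders ($n$ generations = 0) the pedigree-sampled $u$
is independent of the marker panel, the null-model REML correctly
drives $\hat\sigma_u^2 \to 0$, and the background lands in the
residual. The power studies in the acceptance suite therefore use a
multi-generation pedigree, matching both the emulated data and the
model premise.

## 5. Numerical choices and degenerate inputs

* Seeds: every generator function derives its stream from
  `sim_config(seed)` (with small fixed offsets per stage), so a config
  fully determines all artifacts, byte for byte.
* QC order and attribution: sex-chromosome → monomorphic → MAF <
  threshold → call rate < threshold; a SNP counts toward the first
  filter that catches it; thresholds are strict (exact 0.01 MAF and
  exact 0.90 call rate are retained). QC is idempotent.
* `hypergeometric_test()` computes the upper tail directly (not
  1 − lower), so P-values near 0 keep full relative precision.
* `fit_null()` optimizes over $\log\delta \in [-12, 12]$, covering
  heritabilities from ~0.000006 to ~0.99999; boundary optima surface as
  near-zero components rather than errors.
* Degenerate inputs: empty post-QC panels, cyclic pedigrees, unknown
  genotyped IDs, inconsistent enrichment counts and reliabilities
  outside (0, 1] all raise errors naming the offender; parents absent
  from the pedigree file are auto-added as founders with a warning.

## 6. Known limitations

* Dense-in-records REML (≤ 4000 records) and dense $A$ (≤ 5000
  animals): deliberate desk-scale bounds, not algorithmic limits.
* Single-trait, intercept-default models; no genotype-by-environment,
  no iterative SNP reweighting (one back-solution pass), no
  unknown-parent groups or metafounders.
* Genomic control is median-based and may differ numerically from
  other published corrections of the same name.
* The generator does not model LD, selection or imputation error; gene
  sets are consumed as given (no ontology propagation).
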