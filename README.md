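# sirescan

Genome scans and gene-set enrichment for sire-fertility traits.

## What this package is for

Service-sire fertility in dairy cattle is evaluated phenotypically through
sire conception rate (SCR): a bull's expected deviation in conception rate
(percentage points) from the mean of evaluated bulls, published with a
per-evaluation reliability. Dissecting the genetics behind SCR-style
evaluations requires three coupled analyses, and `sirescan` implements all
of them as a reusable, tested pipeline for quantitative geneticists:

1. **Additive scan (ssGBLUP).** A reliability-weighted repeatability
   animal model

   `y = Xβ + Zu + Wpe + e`,  with `u ~ N(0, H σᵤ²)`, `pe ~ N(0, I σₚₑ²)`,
   `e ~ N(0, R⁻¹ σₑ²)`, `R = diag(reliability)`,

   where `H⁻¹ = A⁻¹ + [0 0; 0 G⁻¹ − A₂₂⁻¹]` combines the pedigree
   relationship matrix `A` (tabular method; Henderson-rules sparse
   inverse with inbreeding via Meuwissen–Luo) and a VanRaden-method-1
   genomic matrix `G` blended with `A₂₂`. SNP effects are back-solved
   from the GEBVs as `ŝ = DM'[MDM']⁻¹û`, and candidate regions are
   ranked by the percentage of additive variance explained by 1.5-Mb
   sliding windows, `100 · Var(Σⱼ Mⱼ ŝⱼ) / σᵤ²`.

2. **Non-additive scan.** A two-step mixed model: the null
   `y = Xβ + u + e` with `u ~ N(0, G₂ σᵤ²)` is fitted once (REML on the
   eigendecomposition of `G₂`), then every SNP is score-tested under the
   dominance (0,1,1), recessive (0,0,1) and overdominance (0,1,0)
   recodings of the genotype codes (0,1,2), with
   `z = x'V₀⁻¹(y − Xβ̂) / √(x'Px)`, genomic control
   (`λ = median(z²)/0.455`, deflation only) and per-coding Bonferroni
   flagging (adjusted P < 0.01).

3. **Gene-set enrichment.** SNPs are assigned to genes within ±15 kb,
   genes flagged by the top 1% of |ŝ| are called significant, and every
   GMT term is tested with the exact upper-tail hypergeometric
   probability `P(X ≥ g)` given `(N, S, k)`.

Because national SCR evaluations and AI-company genotypes are
proprietary, the package ships a first-class synthetic-data module
(`sim_config()`, `run_simulation()`) that emulates their structure —
a multi-generation pedigree of ~1.5K bulls, 29 autosomes, repeated
records with reliabilities, an additive polygenic background plus a few
additive QTL, and rare recessive QTL with large negative effects —
so every stage is testable end to end with known truth.

## Worked example

```r
library(sirescan)

cfg <- run_config(seed = 11,
                  sim = sim_config(n_founders = 100, n_generations = 3,
                                   offspring_per_mating = 3, n_snps = 800,
                                   n_chromosomes = 5, chrom_length_bp = 8e6,
                                   seed = 11),
                  sigma_u2 = 4, sigma_pe2 = 3, sigma_e2 = 13,
                  n_genes = 250, n_sets = 25)
res <- run_pipeline(cfg, out_dir = "example_run")
#> [simulate] generating synthetic dataset (seed 11)
#> [qc] retained 800 of 800 SNPs (removed: sex_chromosome=0, monomorphic=0, low_maf=0, low_call_rate=0)
#> [scan-additive] 550 animals, 800 SNPs
#> [scan-nonadditive] codings: dominance, recessive, overdominance
#> [geneset] N = 166 analyzed genes, S = 4 significant

# top non-overlapping additive windows (% of additive variance)
w <- collapse_windows(res$scan_additive$windows)
head(w[order(-w$pct_additive_variance), ], 3)
#>  chrom start_bp  end_bp n_snps pct_additive_variance
#>      5  5828393 7318396     39              1.821639
#>      1  4106468 5551868     40              1.240105
#>      2  1074889 2556750     40              1.236559

# strongest recessive-coding hits
rec <- res$scan_nonadditive$recessive
rec[order(rec$p_gc)[1:3], c("snp", "maf", "beta", "se", "z", "p_gc", "p_bonf")]
#>       snp       maf      beta        se         z         p_gc     p_bonf
#>  snp00796 0.1208791 -6.032954 1.3834320 -4.360860 2.263799e-05 0.01777083
#>  snp00105 0.3566176 -2.372628 0.6298599 -3.766914 2.521675e-04 0.19795151
#>  snp00481 0.1829044  3.444884 1.1596235  2.970692 3.896584e-03 1.00000000

res$simulate$truth$qtl
#>       snp      type    effect    freq_b
#>  snp00541  additive -1.139221 0.3627273
#>  snp00667  additive  1.213930 0.2845455
#>  snp00796 recessive -6.000000 0.1209091
```

The planted recessive locus (`snp00796`, effect −6 SCR points at B-allele
frequency 0.12) is the top recessive-coding hit, with an effect estimate
of −6.03 ± 1.38 SCR points; at this deliberately small desk scale its
Bonferroni-adjusted P (0.018) sits just above the 0.01 flagging
threshold — the acceptance suite runs the same design at n = 1500, where
it is flagged in the large majority of replicates. Published genotype
counts and enrichment inputs reproduce exactly, e.g.

```r
maf_from_counts(1211, 240, 10)            # 0.0889... -> printed 0.09
hypergeometric_test(8, 502, 19792, 137)   # 0.0236... -> printed 0.024
```

## Command line

```sh
sirescan run-all --config config.json --out run_dir --seed 11
sirescan show-config            # all defaults (MAF 0.01, call rate 0.90,
                                # 1.5 Mb windows, 15 kb flank, top 1%, ...)
```

(Or `Rscript exec/sirescan ...` from a source tree.)

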