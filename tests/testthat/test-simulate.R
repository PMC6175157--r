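# Synthetic-data generator: determinism, Mendelian structure, variance
# calibration, annotation validity.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_founders = 20, n_generations = 3, offspring_per_mating = 2,
             n_snps = 200, n_chromosomes = 4, chrom_length_bp = 4e6,
             seed = seed, ...)
}

test_that("pedigree generator honours counts and degenerate cases", {
  trio <- simulate_pedigree(sim_config(n_founders = 2, n_generations = 1,
                                       offspring_per_mating = 1))
  expect_equal(length(trio$id), 3)
  expect_equal(sum(is.na(trio$sire) & is.na(trio$dam)), 2)

  founders <- simulate_pedigree(sim_config(n_founders = 10,
                                           n_generations = 0))
  expect_equal(length(founders$id), 10)
  expect_true(all(is.na(founders$sire)))

  ped <- simulate_pedigree(small_cfg())
  # parents precede offspring
  expect_true(all(ped$sire < seq_along(ped$id), na.rm = TRUE))
  expect_true(all(ped$dam < seq_along(ped$id), na.rm = TRUE))
})

test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 99)
  s1 <- run_simulation(cfg, n_genes = 30, n_sets = 8)
  s2 <- run_simulation(cfg, n_genes = 30, n_sets = 8)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$panel$codes, s2$panel$codes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$sets, s2$sets)
  # and the on-disk artifacts are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("founder genotypes respect configured allele frequencies", {
  cfg <- sim_config(n_founders = 1000, n_generations = 0, n_snps = 60,
                    n_chromosomes = 2, founder_maf_range = c(0.3, 0.3),
                    missing_rate = 0, n_recessive_qtl = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  # mean genotype ~ 2p = 0.6 within 3 binomial SEs per SNP
  se3 <- 3 * sqrt(0.3 * 0.7 / (2 * 1000))
  fr <- allele_frequencies(panel)$freq_b
  expect_true(all(abs(fr - 0.3) < se3 + 1e-9))
  expect_lt(abs(mean(panel$codes) - 0.6), 3 * sqrt(0.6 * 0.7 / 60000))
})

test_that("gene dropping is Mendelian", {
  cfg <- small_cfg(missing_rate = 0)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  g <- panel$truth_codes
  s <- ped$sire; d <- ped$dam
  kids <- which(!is.na(s) & !is.na(d))
  # parent genotypes 2 x 2 -> offspring always 2; 0 x 0 -> 0
  both2 <- g[s[kids], ] == 2 & g[d[kids], ] == 2
  expect_true(all(g[kids, ][both2] == 2))
  both0 <- g[s[kids], ] == 0 & g[d[kids], ] == 0
  expect_true(all(g[kids, ][both0] == 0))

  # offspring-on-midparent regression slope ~ 1 (equivalently 0.5 on a
  # single parent), large n
  cfg2 <- sim_config(n_founders = 400, n_generations = 1,
                     offspring_per_mating = 2, n_snps = 150,
                     n_chromosomes = 3, missing_rate = 0, seed = 5)
  ped2 <- simulate_pedigree(cfg2)
  panel2 <- simulate_genotypes(ped2, cfg2)
  g2 <- panel2$truth_codes
  kids2 <- which(!is.na(ped2$sire))
  off <- as.numeric(g2[kids2, ])
  mid <- as.numeric((g2[ped2$sire[kids2], ] + g2[ped2$dam[kids2], ]) / 2)
  slope <- coef(lm(off ~ mid))[2]
  expect_lt(abs(slope - 1), 0.05)

  # pedigree must be topologically ordered
  bad <- ped
  bad$sire[1] <- 5L
  expect_error(simulate_genotypes(bad, cfg), "topologically")
})

test_that("phenotype decomposition matches the configured variances", {
  # all variances zero, no QTL -> every record equals the fixed part (0)
  cfg0 <- small_cfg(sigma_u2 = 0, sigma_pe2 = 0, sigma_e2 = 0,
                    n_additive_qtl = 0, n_recessive_qtl = 0)
  ped <- simulate_pedigree(cfg0)
  panel <- simulate_genotypes(ped, cfg0)
  py <- simulate_phenotypes(ped, panel, cfg0)
  expect_true(all(py$phenotypes$value == 0))

  # one recessive QTL, effect -6, everything else silent -> BB animals
  # exactly 6 points below the others
  cfg1 <- sim_config(n_founders = 600, n_generations = 0, n_snps = 100,
                     n_chromosomes = 2, sigma_u2 = 0, sigma_pe2 = 0,
                     sigma_e2 = 0, n_additive_qtl = 0, n_recessive_qtl = 1,
                     recessive_effect = -6, reliability_range = c(1, 1),
                     missing_rate = 0, seed = 8)
  ped <- simulate_pedigree(cfg1)
  panel <- simulate_genotypes(ped, cfg1)
  py <- simulate_phenotypes(ped, panel, cfg1)
  qsnp <- py$truth$qtl$snp[py$truth$qtl$type == "recessive"]
  bb <- panel$truth_codes[, qsnp] == 2
  expect_gt(sum(bb), 0)
  vals <- py$truth$u + py$truth$recessive_shift
  expect_true(all(py$phenotypes$value[bb[match(py$phenotypes$animal,
                                               ped$id)]] == -6))
  expect_true(all(py$phenotypes$value[!bb[match(py$phenotypes$animal,
                                                ped$id)]] == 0))

  # variance calibration: var(u) within 10% of sigma_u2 over >= 2000
  # animals (average over repeated seeds)
  ratios <- sapply(1:3, function(sd) {
    cfg <- sim_config(n_founders = 500, n_generations = 2,
                      offspring_per_mating = 4, n_snps = 100,
                      n_chromosomes = 2, sigma_u2 = 4,
                      additive_qtl_var_fraction = 0.3, seed = sd)
    ped <- simulate_pedigree(cfg)
    panel <- simulate_genotypes(ped, cfg)
    py <- simulate_phenotypes(ped, panel, cfg)
    var(py$truth$u) / cfg$sigma_u2
  })
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("single-record heritability emerges as configured", {
  cfg <- sim_config(n_founders = 2000, n_generations = 0, n_snps = 50,
                    n_chromosomes = 2, sigma_u2 = 4, sigma_pe2 = 0,
                    sigma_e2 = 12, n_additive_qtl = 0, n_recessive_qtl = 0,
                    records_per_animal_range = c(1, 1),
                    reliability_range = c(1, 1), seed = 11)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  py <- simulate_phenotypes(ped, panel, cfg)
  h2 <- var(py$truth$u) / var(py$phenotypes$value)
  expect_lt(abs(h2 - 0.25), 3 * 0.25 / sqrt(2000) * 3)
})

test_that("reliabilities scale the residual variance", {
  cfg <- sim_config(n_founders = 3000, n_generations = 0, n_snps = 10,
                    n_chromosomes = 1, sigma_u2 = 0, sigma_pe2 = 0,
                    sigma_e2 = 10, n_additive_qtl = 0, n_recessive_qtl = 0,
                    records_per_animal_range = c(1, 1),
                    reliability_range = c(0.25, 0.25), seed = 12)
  ped <- simulate_pedigree(cfg)
  panel <- simulate_genotypes(ped, cfg)
  py <- simulate_phenotypes(ped, panel, cfg)
  # Var(e) = sigma_e2 / rel = 40
  expect_lt(abs(var(py$phenotypes$value) / 40 - 1), 0.1)
})

test_that("annotation and gene sets are valid and deterministic", {
  cfg <- small_cfg()
  panel <- simulate_genotypes(simulate_pedigree(cfg), cfg)
  ann1 <- simulate_annotation(panel, 40, 12, seed = 2)
  ann2 <- simulate_annotation(panel, 40, 12, seed = 2)
  expect_identical(ann1, ann2)
  a <- ann1$annotation
  expect_equal(nrow(a), 40)
  expect_true(all(a$start < a$end))
  # non-overlapping within chromosome
  for (ch in unique(a$chrom)) {
    w <- a[a$chrom == ch, ]
    w <- w[order(w$start), ]
    if (nrow(w) > 1) expect_true(all(w$start[-1] > w$end[-nrow(w)]))
  }
  # sets are subsets of emitted gene IDs, sizes within [4, 250]
  expect_true(all(unlist(ann1$sets) %in% a$gene))
  expect_true(all(lengths(ann1$sets) >= 4 & lengths(ann1$sets) <= 250))
  # single gene -> single-line BED
  one <- simulate_annotation(panel, 1, 0, seed = 3)
  expect_equal(nrow(one$annotation), 1)
  # too many genes for the chromosome length -> error
  expect_error(simulate_annotation(panel, 1e5, 0, seed = 4), "too large")
})
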