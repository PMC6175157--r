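# Mixed-model machinery: REML, MME vs dense GLS oracle, SNP back-solution
# and the window variance scan.

make_dataset <- function(n_anim = 120, seed = 1, sigma_u2 = 4,
                         sigma_pe2 = 3, sigma_e2 = 13,
                         records = c(1, 4), rel = c(0.4, 1)) {
  set.seed(seed)
  ped <- random_pedigree(n_anim, seed = seed)
  A <- build_A(ped)
  L <- t(chol(A + diag(1e-8, n_anim)))
  u <- as.numeric(L %*% rnorm(n_anim)) * sqrt(sigma_u2)
  pe <- rnorm(n_anim, 0, sqrt(sigma_pe2))
  nrec <- sample(records[1]:records[2], n_anim, replace = TRUE)
  idx <- rep(seq_len(n_anim), nrec)
  reliability <- runif(length(idx), rel[1], rel[2])
  y <- 1.5 + u[idx] + pe[idx] +
    rnorm(length(idx), 0, sqrt(sigma_e2 / reliability))
  phen <- data.frame(animal = ped$id[idx],
                     record_id = unlist(lapply(nrec, seq_len)),
                     value = y, reliability = reliability)
  list(ped = ped, A = A, phen = phen)
}

test_that("solve_mme matches the dense GLS oracle", {
  for (seed in c(2, 3)) {
    ds <- make_dataset(100, seed = seed)
    a_inv <- build_A_inverse(ds$ped)
    spec <- model_spec(sigma_u2 = 4, sigma_pe2 = 3, sigma_e2 = 13)
    sol <- solve_mme(ds$phen, a_inv, spec)
    H <- ds$A
    dimnames(H) <- list(ds$ped$id, ds$ped$id)
    orc <- gls_oracle(ds$phen, H, 4, 3, 13)
    expect_all_close(sol$beta, orc$beta, 1e-8)
    expect_all_close(sol$u, orc$u[names(sol$u)], 1e-8)
    expect_all_close(sol$pe, orc$pe[names(sol$pe)], 1e-8)
  }
})

test_that("single-record shrinkage agrees with the 3x3 dense system", {
  # one animal, one record, rel = 1, intercept only is unidentifiable
  # (mean absorbs everything), so use 2 unrelated animals and check the
  # shrinkage structure against a direct dense solve of the MME
  phen <- data.frame(animal = c("a", "b"), record_id = 1,
                     value = c(3, -1), reliability = 1)
  ped <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA))
  a_inv <- build_A_inverse(ped)
  spec <- model_spec(sigma_u2 = 2, sigma_pe2 = 1, sigma_e2 = 4)
  sol <- solve_mme(phen, a_inv, spec)
  X <- matrix(1, 2, 1); Z <- diag(2); W <- diag(2); R <- diag(2)
  C <- rbind(cbind(t(X) %*% X, t(X) %*% Z, t(X) %*% W),
             cbind(t(Z) %*% X, t(Z) %*% Z + diag(2) * 2, t(Z) %*% W),
             cbind(t(W) %*% X, t(W) %*% Z, t(W) %*% W + diag(2) * 4))
  rhs <- rbind(t(X) %*% phen$value, t(Z) %*% phen$value,
               t(W) %*% phen$value)
  dsol <- solve(C, rhs)
  expect_all_close(c(sol$beta, sol$u, sol$pe), as.numeric(dsol), 1e-10)
  # shrinkage: u = (y - beta) * sigma_u2 / (sigma_u2 + sigma_pe2 + sigma_e2)
  expect_all_close(sol$u, (phen$value - sol$beta) * 2 / 7, 1e-10)
})

test_that("u shrinks to zero as sigma_u2 -> 0", {
  ds <- make_dataset(60, seed = 4)
  a_inv <- build_A_inverse(ds$ped)
  sol <- solve_mme(ds$phen, a_inv,
                   model_spec(sigma_u2 = 1e-8, sigma_pe2 = 3,
                              sigma_e2 = 13))
  expect_lt(max(abs(sol$u)), 1e-6)
})

test_that("solutions are invariant to record permutation", {
  ds <- make_dataset(80, seed = 5)
  a_inv <- build_A_inverse(ds$ped)
  spec <- model_spec(sigma_u2 = 4, sigma_pe2 = 3, sigma_e2 = 13)
  sol1 <- solve_mme(ds$phen, a_inv, spec)
  perm <- sample(nrow(ds$phen))
  sol2 <- solve_mme(ds$phen[perm, ], a_inv, spec)
  expect_all_close(sol1$u, sol2$u[names(sol1$u)], 1e-8)
  expect_all_close(sol1$beta, sol2$beta, 1e-8)
})

test_that("rank-deficient fixed effects are dropped with a warning", {
  ds <- make_dataset(40, seed = 6)
  ds$phen$cov1 <- 1  # aliased with the intercept
  a_inv <- build_A_inverse(ds$ped)
  expect_warning(
    sol <- solve_mme(ds$phen, a_inv,
                     model_spec(fixed = "cov1", sigma_u2 = 4,
                                sigma_pe2 = 3, sigma_e2 = 13)),
    "dependent")
  expect_length(sol$beta, 1)
})

test_that("REML matches the balanced one-way ANOVA closed form", {
  # identity relationships, balanced records, rel = 1: animal and pe are
  # jointly the 'between' component, residual the 'within'. REML on
  # balanced data equals the ANOVA estimators.
  set.seed(7)
  n <- 60; r <- 4
  between <- 6; within <- 10
  a <- rnorm(n, 0, sqrt(between))
  y <- rep(a, each = r) + rnorm(n * r, 0, sqrt(within))
  phen <- data.frame(animal = rep(paste0("x", 1:n), each = r),
                     record_id = rep(1:r, n), value = y, reliability = 1)
  ped <- pedigree(paste0("x", 1:n), rep(NA, n), rep(NA, n))
  a_inv <- build_A_inverse(ped)
  vc <- estimate_variance_components(phen, a_inv)
  msw <- anova(lm(y ~ factor(rep(1:n, each = r))))$`Mean Sq`
  anova_between <- (msw[1] - msw[2]) / r
  expect_equal(vc$sigma_e2, msw[2], tolerance = 1e-4)
  expect_equal(vc$sigma_u2 + vc$sigma_pe2, anova_between, tolerance = 1e-3)
})

test_that("REML is unbiased at desk scale", {
  # scaled-down replicate study (n = 120 animals instead of 1500, 12
  # replicates instead of 100, to stay inside the test-time budget); the
  # full-size check lives in the acceptance suite
  est <- sapply(1:12, function(seed) {
    ds <- make_dataset(120, seed = 100 + seed)
    a_inv <- build_A_inverse(ds$ped)
    vc <- suppressWarnings(estimate_variance_components(ds$phen, a_inv))
    c(vc$sigma_u2, vc$sigma_pe2, vc$sigma_e2)
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - 4) / 4, 0.35)
  expect_lt(abs(m[2] - 3) / 3, 0.35)
  expect_lt(abs(m[3] - 13) / 13, 0.15)
})

test_that("back-solved effects reproduce the dense formula and GEBVs", {
  # all animals genotyped, H from G alone (blend 1). G must be centered
  # with external (population) frequencies: observed-frequency centering
  # zeroes the column means and makes raw G structurally singular.
  set.seed(8)
  n <- 100; m <- 250
  p_ext <- runif(m, 0.2, 0.5)
  codes <- sapply(p_ext, function(pj) rbinom(n, 2L, pj))
  rownames(codes) <- paste0("id", seq_len(n))
  panel <- genotype_panel(codes,
                          data.frame(snp = sprintf("s%04d", 1:m),
                                     chrom = "1", pos = seq_len(m) * 1000))
  g <- build_G(panel, freqs = p_ext, blend_weight = 1)
  expect_gt(min(eigen(g$G, only.values = TRUE)$values), 0)
  sol <- list(u = setNames(rnorm(n), panel$animals))
  eff <- backsolve_snp_effects(sol, panel, g)
  # dense oracle: s = D M'[M D M']^-1 u with M = Z/sqrt(scale)
  Z <- center_markers(panel, g$freqs)
  s_orc <- (t(Z) / g$scale) %*% solve(tcrossprod(Z) / g$scale, sol$u)
  expect_all_close(eff$effect, as.numeric(s_orc), 1e-8)
  # GBLUP = SNP-BLUP: M s = u exactly
  expect_all_close(as.numeric(Z %*% eff$effect), unname(sol$u), 1e-8)
  # u = 0 -> s = 0
  eff0 <- backsolve_snp_effects(list(u = setNames(rep(0, n),
                                                  panel$animals)),
                                panel, g)
  expect_true(all(eff0$effect == 0))
})

test_that("window scan percentages behave as defined", {
  panel <- random_panel(150, 60, seed = 9, n_chrom = 3)
  g <- build_G(panel, blend_weight = 1)
  eff <- data.frame(snp = panel$snps, chrom = panel$map$chrom,
                    pos = panel$map$pos, effect = 0)
  attr(eff, "freqs") <- g$freqs
  class(eff) <- c("marker_effects", "data.frame")
  # zero effects -> all windows 0%
  w0 <- window_scan(eff, panel, sigma_u2 = 4)
  expect_true(all(w0$pct_additive_variance == 0))
  expect_true(all(w0$end_bp - w0$start_bp <= 1.5e6))
  expect_true(all(w0$n_snps >= 1))

  # single-SNP self-normalization: sigma_u2 = Var(M s) -> 100%
  one <- genotype_panel(matrix(c(0, 1, 2, 0, 1, 2), 6, 1,
                               dimnames = list(paste0("a", 1:6), "s1")),
                        data.frame(snp = "s1", chrom = "1", pos = 100))
  eff1 <- data.frame(snp = "s1", chrom = "1", pos = 100, effect = 1)
  attr(eff1, "freqs") <- 0.5
  class(eff1) <- c("marker_effects", "data.frame")
  v <- var(c(0, 1, 2, 0, 1, 2) - 1)
  w1 <- window_scan(eff1, one, sigma_u2 = v)
  expect_equal(w1$pct_additive_variance, 100)

  # invariance to chromosome processing order
  eff$effect <- rnorm(60)
  w_a <- window_scan(eff, panel, sigma_u2 = 4)
  perm <- sample(60)
  shuffled <- genotype_panel(panel$codes[, perm], panel$map[perm, ])
  # the panel constructor re-sorts by position, so results must agree
  w_b <- window_scan(eff, shuffled, sigma_u2 = 4)
  key <- function(w) w[order(w$chrom, w$start_bp), ]
  expect_equal(key(w_a)$pct_additive_variance,
               key(w_b)$pct_additive_variance, tolerance = 1e-12)

  expect_error(window_scan(eff, panel, sigma_u2 = 0), "positive")
})

test_that("collapse_windows keeps non-overlapping per-region maxima", {
  w <- data.frame(chrom = "1",
                  start_bp = c(100, 200, 5000, 5100),
                  end_bp = c(1100, 1200, 6000, 6100),
                  n_snps = 2,
                  pct_additive_variance = c(1, 3, 2, 0.5))
  out <- collapse_windows(w)
  expect_equal(out$start_bp, c(200, 5000))
  expect_equal(out$pct_additive_variance, c(3, 2))
})
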