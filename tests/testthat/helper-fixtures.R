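# Shared fixtures and independent oracles used across the suite.

# random pedigree: founders plus animals with parents drawn among earlier
# animals (possibly unknown), so arbitrary inbreeding loops arise
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L,
                            p_unknown = 0.1) {
  set.seed(seed)
  id <- paste0("A", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq.int(n_founders + 1L, n)) {
    pool <- id[seq_len(i - 1L)]
    pick <- sample(pool, 2L, replace = FALSE)
    if (runif(1) > p_unknown) sire[i] <- pick[1L]
    if (runif(1) > p_unknown) dam[i] <- pick[2L]
  }
  pedigree(id, sire, dam)
}

# HWE panel of unrelated animals (used where no pedigree is needed)
random_panel <- function(n, m, seed = 1L, maf_range = c(0.1, 0.5),
                         n_chrom = 2L, chrom_len = 5e6) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  codes <- sapply(p, function(pj) rbinom(n, 2L, pj))
  rownames(codes) <- paste0("id", seq_len(n))
  chrom <- sort(rep(seq_len(n_chrom), length.out = m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(chrom_len, length(ix)))), use.names = FALSE)
  map <- data.frame(snp = sprintf("s%04d", seq_len(m)),
                    chrom = as.character(chrom), pos = pos)
  genotype_panel(codes, map)
}

# dense GLS oracle for the weighted repeatability model: direct
# variance-matrix algebra, independent of the MME route
gls_oracle <- function(phen, H, sigma_u2, sigma_pe2, sigma_e2,
                       X = matrix(1, nrow(phen), 1)) {
  ids <- rownames(H)
  ia <- match(phen$animal, ids)
  Zh <- H[ia, ia]
  S <- outer(ia, ia, "==") * 1
  V <- sigma_u2 * Zh + sigma_pe2 * S +
    sigma_e2 * diag(1 / phen$reliability, nrow(phen))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% phen$value)
  r <- phen$value - X %*% beta
  u <- sigma_u2 * H[, ids[ia]] %*% Vi %*% r   # cov(u, y) V^-1 r
  pe_anim <- sort(unique(ia))
  pe <- sigma_u2 * 0  # placeholder
  Wcov <- sigma_pe2 * t(outer(ia, pe_anim, "==") * 1)
  pe <- Wcov %*% Vi %*% r
  list(beta = as.numeric(beta),
       u = setNames(as.numeric(u), ids),
       pe = setNames(as.numeric(pe), ids[pe_anim]))
}

# brute-force hypergeometric upper tail by full enumeration of draws
hyper_enum_oracle <- function(g, S, N, k) {
  sig <- seq_len(S)
  draws <- utils::combn(N, k)
  mean(colSums(matrix(draws %in% sig, nrow = k)) >= g)
}

expect_all_close <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)), tol)
}
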