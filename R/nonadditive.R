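# Two-step mixed-model genome scan for non-additive (dominance,
# recessive, overdominance) effects: null model with a genomic covariance
# V0, per-SNP score tests on recoded genotypes, genomic control and
# Bonferroni thresholding.

#' Keep the most reliable record per animal
#'
#' @param phen phenotype data.frame (`animal`, `record_id`, `value`,
#'   `reliability`, ...).
#' @return One row per animal: the record with maximal reliability, ties
#'   broken by the latest `record_id`.
#' @export
select_best_record <- function(phen) {
  stopifnot(all(c("animal", "reliability") %in% names(phen)))
  rid <- if ("record_id" %in% names(phen)) phen$record_id else
    stats::ave(seq_len(nrow(phen)), phen$animal, FUN = seq_along)
  ord <- order(phen$animal, -phen$reliability, -xtfrm(rid))
  p <- phen[ord, , drop = FALSE]
  p <- p[!duplicated(p$animal), , drop = FALSE]
  p <- p[order(match(p$animal, unique(phen$animal))), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Fit the null genomic mixed model (step 1)
#'
#' `y = X beta + u + e` with `u ~ N(0, G2 sigma_u2)` and
#' `e ~ N(0, I sigma_e2)`, one record per animal. REML over
#' `(sigma_u2, sigma_e2)` is profiled on the eigendecomposition of `G2`
#' (a one-dimensional optimization in the variance ratio), then `beta` is
#' the GLS estimate under `V0 = G2 sigma_u2 + I sigma_e2`.
#'
#' @param y numeric phenotype vector (one value per animal).
#' @param X fixed-effect design matrix (default intercept only).
#' @param g2 `genomic_matrix` (or plain matrix) over the same animals.
#' @return Object of class `"null_model"`: `beta`, `sigma_u2`, `sigma_e2`,
#'   `residual` (`y - X beta`), eigen pieces for fast `V0^-1` products.
#' @export
fit_null <- function(y, X = NULL, g2) {
  G <- if (inherits(g2, "genomic_matrix")) g2$G else as.matrix(g2)
  n <- length(y)
  stopifnot(all(dim(G) == n))
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- .prune_X(as.matrix(X))
  p <- ncol(X)
  ed <- eigen((G + t(G)) / 2, symmetric = TRUE)
  U <- ed$vectors
  D <- pmax(ed$values, 0)
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)

  # profile REML log-likelihood in delta = sigma_e2 / sigma_u2
  neg_restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (D + delta)            # V_delta^-1 = U diag(w) U'
    XtWX <- crossprod(Xr, Xr * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xr, yr * w)))
    r <- yr - Xr %*% beta
    quad <- sum(r^2 * w)
    sigma_u2 <- quad / (n - p)
    0.5 * ((n - p) * log(sigma_u2) + sum(log(D + delta)) +
             2 * sum(log(diag(ch))) + (n - p))
  }
  opt <- stats::optimize(neg_restricted_ll, interval = c(-12, 12), tol = 1e-9)
  if (!is.finite(opt$objective) || opt$objective >= 1e10) {
    stop("null-model REML failed to converge")
  }
  delta <- exp(opt$minimum)
  w <- 1 / (D + delta)
  XtWX <- crossprod(Xr, Xr * w)
  beta <- solve(XtWX, crossprod(Xr, yr * w))
  r_rot <- yr - Xr %*% beta
  sigma_u2 <- sum(r_rot^2 * w) / (n - p)
  sigma_e2 <- delta * sigma_u2
  residual <- as.numeric(y - X %*% beta)
  structure(list(
    beta = stats::setNames(as.numeric(beta), colnames(X)),
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
    X = X, y = y, residual = residual,
    U = U, D = D,
    v0_diag_inv = 1 / (sigma_u2 * D + sigma_e2),
    logl = -opt$objective
  ), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> n = ", length(x$y),
      ", sigma_u2 = ", signif(x$sigma_u2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4), "\n", sep = "")
  invisible(x)
}

#' V0 inverse (or its product with a matrix)
#'
#' `V0 = G2 sigma_u2 + I sigma_e2`. The eigen path reuses the stored
#' decomposition; the direct path inverts `V0` explicitly (an internal
#' consistency check, and a fallback for modified `V0`).
#'
#' @param null a `null_model`.
#' @param B optional matrix/vector to multiply; when `NULL` the full
#'   inverse is returned.
#' @param method `"eigen"` (default) or `"direct"`.
#' @return `V0^-1` or `V0^-1 B`.
#' @export
v0_inverse <- function(null, B = NULL, method = c("eigen", "direct")) {
  method <- match.arg(method)
  if (method == "eigen") {
    if (is.null(B)) {
      return(null$U %*% (null$v0_diag_inv * t(null$U)))
    }
    return(null$U %*% (null$v0_diag_inv * crossprod(null$U, B)))
  }
  V0 <- null$U %*% (null$sigma_u2 * null$D * t(null$U)) +
    diag(null$sigma_e2, length(null$y))
  Vi <- chol2inv(chol(V0))
  if (is.null(B)) Vi else Vi %*% B
}

#' Recode genotypes for non-additive tests
#'
#' Dominance: codes (0,1,2) map to (0,1,1); recessive: (0,0,1);
#' overdominance: (0,1,0); additive: unchanged (0,1,2). Missing codes are
#' imputed to the mean of the recoded non-missing values.
#'
#' @param codes numeric vector of 0/1/2/NA genotype codes.
#' @param mode one of `"dominance"`, `"recessive"`, `"overdominance"`,
#'   `"additive"`.
#' @return Numeric indicator vector, no missing values.
#' @export
recode_genotype <- function(codes,
                            mode = c("dominance", "recessive",
                                     "overdominance", "additive")) {
  mode <- match.arg(mode)
  bad <- codes[!is.na(codes) & !(codes %in% c(0, 1, 2))]
  if (length(bad)) stop("invalid genotype code: ", bad[[1L]])
  x <- switch(mode,
              dominance = as.numeric(codes >= 1),
              recessive = as.numeric(codes == 2),
              overdominance = as.numeric(codes == 1),
              additive = as.numeric(codes))
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

#' Score test of a single (recoded) SNP against the null model
#'
#' `z = x' V0^-1 (y - X beta_hat) / sqrt(x' P x)`, asymptotically
#' standard normal under the null, where
#' `P = V0^-1 - V0^-1 X (X' V0^-1 X)^-1 X' V0^-1` is the null projection.
#' Because `X' V0^-1 (y - X beta_hat) = 0`, the numerator equals
#' `x' P y`, so this is the classical score statistic; the projection in
#' the denominator (equivalent to GLS-centering the coding on the fixed
#' effects) is what makes the statistic exactly unit-variance under the
#' null. The effect estimate is `beta_SNP = x' P y / (x' P x)` with
#' plug-in standard error `1 / sqrt(x' P x)` (null-variance convention).
#'
#' @param null a `null_model` from [fit_null()].
#' @param x_snp recoded genotype vector (see [recode_genotype()]).
#' @return list with `beta`, `se`, `z`, `p`, `skipped` (reason or `NA`).
#' @export
score_test <- function(null, x_snp) {
  if (stats::sd(x_snp) == 0) {
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                skipped = "constant genotype coding"))
  }
  xt <- .project_out_fixed(null, x_snp)
  den <- sum(x_snp * as.numeric(v0_inverse(null, xt)))
  if (den <= 0 || !is.finite(den)) {
    warning("non-positive quadratic form for SNP; skipping")
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                skipped = "non-positive x'V0^-1 x"))
  }
  num <- sum(x_snp * v0_inverse(null, null$residual))
  z <- num / sqrt(den)
  list(beta = num / den, se = 1 / sqrt(den), z = z,
       p = 2 * stats::pnorm(-abs(z)), skipped = NA_character_)
}

# residualize codings on the fixed effects under the V0^-1 inner product,
# so that x' V0^-1 x_res = x' P x
.project_out_fixed <- function(null, Xs) {
  X <- null$X
  ViX <- v0_inverse(null, X)
  XtViX <- crossprod(X, ViX)
  Xs - X %*% solve(XtViX, crossprod(ViX, Xs))
}

# vectorized score tests for a matrix of codings (animals x SNPs)
.score_scan <- function(null, Xs) {
  keep <- .col_sds(Xs) > 0
  z <- beta <- se <- rep(NA_real_, ncol(Xs))
  if (any(keep)) {
    Vr <- as.numeric(v0_inverse(null, null$residual))
    Xk <- Xs[, keep, drop = FALSE]
    ViX <- v0_inverse(null, .project_out_fixed(null, Xk))
    num <- as.numeric(crossprod(Xk, Vr))
    den <- colSums(Xk * ViX)
    ok <- den > 0 & is.finite(den)
    zk <- ifelse(ok, num / sqrt(den), NA_real_)
    z[keep] <- zk
    beta[keep] <- ifelse(ok, num / den, NA_real_)
    se[keep] <- ifelse(ok, 1 / sqrt(den), NA_real_)
  }
  data.frame(beta = beta, se = se, z = z,
             p_raw = 2 * stats::pnorm(-abs(z)),
             skipped = ifelse(keep, NA_character_, "constant genotype coding"),
             stringsAsFactors = FALSE)
}

# base-R column standard deviations (avoids a matrixStats dependency)
.col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1L))
}

#' Genomic-control correction
#'
#' `lambda = median(z^2) / 0.4549364` (the median of a 1-df chi-square).
#' When `lambda > 1`, squared statistics are deflated by `lambda` and
#' P-values recomputed; when `lambda <= 1` statistics are unchanged.
#'
#' @param tests data.frame with columns `z` and `p_raw` (e.g. from the
#'   scan functions).
#' @return `tests` with columns `z_gc`, `p_gc` added and attribute
#'   `lambda`.
#' @export
genomic_control <- function(tests) {
  z <- tests$z
  if (sum(is.finite(z)) < 100L) {
    warning("fewer than 100 tests; genomic-control lambda is unstable")
  }
  lambda <- stats::median(z^2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  if (is.finite(lambda) && lambda > 1) {
    tests$z_gc <- z / sqrt(lambda)
  } else {
    tests$z_gc <- z
  }
  tests$p_gc <- 2 * stats::pnorm(-abs(tests$z_gc))
  attr(tests, "lambda") <- lambda
  tests
}

#' Bonferroni adjustment and flagging
#'
#' Adjusted P = `min(1, p * n_tests)` within the coding family (the
#' number of non-skipped tests); flagged when adjusted P is strictly
#' below `alpha`.
#'
#' @param tests data.frame with a `p_gc` (or `p_raw`) column.
#' @param alpha significance level (default 0.01).
#' @param p_col column to adjust (default `p_gc` if present).
#' @return `tests` with `p_bonf` and `flagged` columns.
#' @export
bonferroni <- function(tests, alpha = 0.01,
                       p_col = if ("p_gc" %in% names(tests)) "p_gc"
                               else "p_raw") {
  p <- tests[[p_col]]
  n_tests <- sum(is.finite(p))
  tests$p_bonf <- pmin(1, p * n_tests)
  tests$flagged <- !is.na(tests$p_bonf) & tests$p_bonf < alpha
  tests
}

#' Genome scan for non-additive effects (step 2)
#'
#' Runs [fit_null()] once, then score-tests every SNP under the requested
#' recodings plus the additive coding (reported as `p_add`), applies
#' genomic control per coding family and Bonferroni flagging.
#'
#' @param panel a QC-filtered [genotype_panel].
#' @param phen phenotype table (reduced to the best record per animal via
#'   [select_best_record()]).
#' @param codings subset of `c("dominance", "recessive", "overdominance")`.
#' @param fixed covariate names for the null-model fixed part.
#' @param blend_weight blending weight for `G2` (with the identity, or
#'   `a22` when given).
#' @param a22 optional pedigree block over the tested animals.
#' @param gc apply genomic control (default TRUE).
#' @param alpha Bonferroni flagging level (default 0.01).
#' @return list of per-coding data.frames (`snp`, `chrom`, `pos`, `maf`,
#'   `n_aa`, `n_ab`, `n_bb`, `beta`, `se`, `z`, `p_raw`, `z_gc`, `p_gc`,
#'   `p_add`, `p_bonf`, `flagged`, `skipped`) with `lambda` attributes,
#'   plus elements `null` and `lambdas`.
#' @export
scan_nonadditive <- function(panel, phen,
                             codings = c("dominance", "recessive",
                                         "overdominance"),
                             fixed = character(0),
                             blend_weight = 0.95, a22 = NULL,
                             gc = TRUE, alpha = 0.01) {
  stopifnot(is.genotype_panel(panel))
  codings <- match.arg(codings, several.ok = TRUE)
  best <- select_best_record(phen)
  ix <- match(panel$animals, best$animal)
  if (anyNA(ix)) {
    stop("phenotype records missing for ", sum(is.na(ix)),
         " genotyped animal(s)")
  }
  best <- best[ix, , drop = FALSE]
  y <- best$value
  X <- .design_X(best, fixed)
  if (is.null(a22)) a22 <- diag(length(y))
  g2 <- build_G(panel, blend_weight = blend_weight, a22 = a22)
  null <- fit_null(y, X, g2)

  codes <- panel$codes
  counts <- data.frame(
    n_aa = colSums(codes == 0, na.rm = TRUE),
    n_ab = colSums(codes == 1, na.rm = TRUE),
    n_bb = colSums(codes == 2, na.rm = TRUE))
  fr <- allele_frequencies(panel)
  base <- data.frame(snp = panel$snps, chrom = panel$map$chrom,
                     pos = panel$map$pos, maf = fr$maf, counts,
                     stringsAsFactors = FALSE)

  recode_matrix <- function(mode) {
    apply(codes, 2L, recode_genotype, mode = mode)
  }
  add_tests <- .score_scan(null, recode_matrix("additive"))
  out <- list()
  lambdas <- c()
  for (cd in codings) {
    tests <- .score_scan(null, recode_matrix(cd))
    tests <- cbind(base, tests)
    if (gc) {
      tests <- genomic_control(tests)
    } else {
      tests$z_gc <- tests$z
      tests$p_gc <- tests$p_raw
      attr(tests, "lambda") <- NA_real_
    }
    tests$p_add <- add_tests$p_raw
    tests <- bonferroni(tests, alpha = alpha)
    lambdas[cd] <- attr(tests, "lambda")
    out[[cd]] <- tests
  }
  out$null <- null
  out$lambdas <- lambdas
  out
}
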