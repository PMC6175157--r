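# Reliability-weighted repeatability animal model solved with H^-1
# (ssGBLUP), AI-REML variance components, SNP-effect back-solution from
# GEBVs, and the 1.5-Mb window variance scan.

#' Model specification for the repeatability animal model
#'
#' @param fixed character vector of covariate column names in the
#'   phenotype table entering the fixed part (an intercept is always
#'   included; SCR-style traits are usually pre-adjusted, so the default
#'   is intercept-only).
#' @param sigma_u2,sigma_pe2,sigma_e2 variance components; leave `NULL` to
#'   estimate them by REML.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(fixed = character(0), sigma_u2 = NULL,
                       sigma_pe2 = NULL, sigma_e2 = NULL) {
  vc <- c(sigma_u2, sigma_pe2, sigma_e2)
  if (length(vc) && any(vc <= 0)) stop("supplied variances must be > 0")
  structure(list(fixed = fixed, sigma_u2 = sigma_u2,
                 sigma_pe2 = sigma_pe2, sigma_e2 = sigma_e2),
            class = "model_spec")
}

# fixed-effect design matrix for a phenotype table
.design_X <- function(phen, fixed) {
  if (length(fixed) == 0L) {
    return(matrix(1, nrow(phen), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  missing_cols <- setdiff(fixed, names(phen))
  if (length(missing_cols)) {
    stop("fixed-effect columns absent from phenotypes: ",
         paste(missing_cols, collapse = ", "))
  }
  stats::model.matrix(stats::reformulate(fixed), data = phen)
}

# drop linearly dependent columns of X (rank-deficient fixed effects)
.prune_X <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    warning("dropping linearly dependent fixed-effect column(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  X
}

# Generic dense AI-REML for V = sum_i theta_i * K_i. Kernels are dense
# record-level covariance matrices; the last kernel is typically the
# weighted residual diag(1/rel). Returns theta, logL and the trajectory.
.ai_reml <- function(y, X, kernels, theta0 = NULL,
                     tol_logl = 1e-8, tol_par = 1e-6, max_iter = 100L) {
  n <- length(y)
  p <- ncol(X)
  k <- length(kernels)
  if (is.null(theta0)) theta0 <- rep(stats::var(y) / k, k)
  theta <- pmax(theta0, 1e-6)

  objective <- function(theta) {
    V <- Reduce(`+`, Map(`*`, kernels, theta))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    XtVinv <- crossprod(X, Vinv)
    XtVinvX <- XtVinv %*% X
    chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    P <- Vinv - t(XtVinv) %*% chol2inv(chx) %*% XtVinv
    Py <- P %*% y
    logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                      sum(y * Py))
    list(logl = as.numeric(logl), P = P, Py = as.numeric(Py))
  }

  st <- objective(theta)
  if (is.null(st)) stop("REML: initial variance matrix not positive definite")
  trajectory <- data.frame(iter = 0L, logl = st$logl,
                           t(stats::setNames(theta, paste0("theta", 1:k))))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    KPy <- lapply(kernels, function(K) K %*% st$Py)
    score <- numeric(k)
    for (i in seq_len(k)) {
      score[i] <- -0.5 * (sum(st$P * kernels[[i]]) -
                            sum(st$Py * KPy[[i]]))
    }
    AI <- matrix(0, k, k)
    PKPy <- lapply(KPy, function(v) st$P %*% v)
    for (i in seq_len(k)) {
      for (j in i:k) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
      }
    }
    step <- tryCatch(solve(AI + diag(1e-10, k), score),
                     error = function(e) score / diag(AI + 1e-10))
    # step-halving: keep parameters positive and the likelihood increasing
    # (EM-flavoured fallback when the AI step overshoots)
    accepted <- FALSE
    for (half in 0:12) {
      cand <- theta + step / 2^half
      cand <- pmax(cand, 1e-10)
      st_new <- objective(cand)
      if (!is.null(st_new) && st_new$logl >= st$logl - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }  # no uphill move left
    dpar <- max(abs(cand - theta))
    dll <- st_new$logl - st$logl
    theta <- cand
    st <- st_new
    trajectory <- rbind(trajectory,
                        data.frame(iter = it, logl = st$logl,
                                   t(stats::setNames(theta,
                                                     paste0("theta", 1:k)))))
    if (dll < tol_logl || dpar < tol_par) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("AI-REML did not converge after ", max_iter,
         " iterations; trajectory:\n",
         paste(utils::capture.output(print(utils::tail(trajectory, 5))),
               collapse = "\n"))
  }
  boundary <- theta <= 1e-9
  if (any(boundary)) {
    warning("variance component(s) at boundary clamped near zero: ",
            paste(which(boundary), collapse = ", "))
  }
  list(theta = theta, logl = st$logl, trajectory = trajectory,
       n = n, p = p)
}

# record-level covariance kernels of the weighted repeatability model
.repeatability_kernels <- function(phen, h_inv) {
  ids <- rownames(h_inv)
  ia <- match(phen$animal, ids)
  if (anyNA(ia)) {
    stop("phenotyped animals absent from the relationship matrix: ",
         paste(unique(phen$animal[is.na(ia)])[1:min(5, sum(is.na(ia)))],
               collapse = ", "))
  }
  H <- solve(as(h_inv, "CsparseMatrix"))
  H <- as.matrix((H + Matrix::t(H)) / 2)
  K_u <- H[ia, ia, drop = FALSE]
  K_pe <- outer(ia, ia, "==") * 1
  K_e <- diag(1 / phen$reliability, nrow(phen))
  list(u = K_u, pe = K_pe, e = K_e, animal_index = ia, ids = ids)
}

#' REML variance components of the weighted repeatability model
#'
#' AI-REML (with step-halving fallback) on the record-level covariance
#' `V = sigma_u2 ZHZ' + sigma_pe2 ZZ' + sigma_e2 diag(1/rel)`. Dense in
#' the number of records, so intended for desk-scale data (<= ~4000
#' records).
#'
#' @param phen phenotype data.frame (`animal`, `value`, `reliability`,
#'   covariates).
#' @param h_inv relationship inverse over all pedigree animals (sparse,
#'   ID dimnames), e.g. from [build_H_inverse()] or [build_A_inverse()].
#' @param spec a [model_spec()].
#' @return list with `sigma_u2`, `sigma_pe2`, `sigma_e2`, `logl`,
#'   `trajectory`.
#' @export
estimate_variance_components <- function(phen, h_inv, spec = model_spec()) {
  if (nrow(phen) > 4000L) {
    stop("dense REML is limited to 4000 records; supply fixed variance ",
         "components in model_spec() for larger data")
  }
  if (max(table(phen$animal)) < 2L) {
    warning("no animal has repeated records; sigma_pe2 is not identifiable ",
            "and will drift to the boundary")
  }
  kern <- .repeatability_kernels(phen, h_inv)
  X <- .prune_X(.design_X(phen, spec$fixed))
  fit <- .ai_reml(phen$value, X, list(kern$u, kern$pe, kern$e))
  list(sigma_u2 = fit$theta[1], sigma_pe2 = fit$theta[2],
       sigma_e2 = fit$theta[3], logl = fit$logl,
       trajectory = fit$trajectory)
}

#' Solve the mixed-model equations of the weighted repeatability model
#'
#' Henderson's MME with residual weights equal to the record
#' reliabilities (`Var(e_i) = sigma_e2 / rel_i`):
#' \deqn{[X'RX, X'RZ, X'RW; Z'RX, Z'RZ + H^{-1}\lambda_u, Z'RW;
#'        W'RX, W'RZ, W'RW + I\lambda_{pe}]}
#' with `lambda_u = sigma_e2/sigma_u2`, `lambda_pe = sigma_e2/sigma_pe2`
#' and `R = diag(rel)`. Solved by sparse Cholesky factorization; the
#' relative residual of the normal equations is checked against 1e-10.
#'
#' @inheritParams estimate_variance_components
#' @param spec a [model_spec()]; variance components are estimated first
#'   if not supplied.
#' @return Object of class `"mme_solution"`: `beta` (named), `u` (GEBV,
#'   one per pedigree animal), `pe` (per phenotyped animal),
#'   `components`, `relative_residual`.
#' @export
solve_mme <- function(phen, h_inv, spec = model_spec()) {
  stopifnot(all(c("animal", "value", "reliability") %in% names(phen)))
  if (is.null(spec$sigma_u2) || is.null(spec$sigma_pe2) ||
      is.null(spec$sigma_e2)) {
    vc <- estimate_variance_components(phen, h_inv, spec)
    spec$sigma_u2 <- vc$sigma_u2
    spec$sigma_pe2 <- vc$sigma_pe2
    spec$sigma_e2 <- vc$sigma_e2
  }
  ids <- rownames(h_inv)
  n_anim <- length(ids)
  ia <- match(phen$animal, ids)
  if (anyNA(ia)) stop("phenotyped animals absent from H^-1")
  phen_ids <- ids[sort(unique(ia))]
  ipe <- match(phen$animal, phen_ids)
  nrec <- nrow(phen)

  X <- .prune_X(.design_X(phen, spec$fixed))
  p <- ncol(X)
  Z <- Matrix::sparseMatrix(i = seq_len(nrec), j = ia, x = 1,
                            dims = c(nrec, n_anim))
  W <- Matrix::sparseMatrix(i = seq_len(nrec), j = ipe, x = 1,
                            dims = c(nrec, length(phen_ids)))
  R <- Matrix::Diagonal(x = phen$reliability)
  lambda_u <- spec$sigma_e2 / spec$sigma_u2
  lambda_pe <- spec$sigma_e2 / spec$sigma_pe2
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  RX <- R %*% Xs; RZ <- R %*% Z; RW <- R %*% W
  C <- rbind(
    cbind(Matrix::t(Xs) %*% RX, Matrix::t(Xs) %*% RZ, Matrix::t(Xs) %*% RW),
    cbind(Matrix::t(Z) %*% RX,
          Matrix::t(Z) %*% RZ + as(h_inv, "CsparseMatrix") * lambda_u,
          Matrix::t(Z) %*% RW),
    cbind(Matrix::t(W) %*% RX, Matrix::t(W) %*% RZ,
          Matrix::t(W) %*% RW +
            Matrix::Diagonal(length(phen_ids)) * lambda_pe))
  rhs <- rbind(Matrix::t(Xs) %*% (R %*% phen$value),
               Matrix::t(Z) %*% (R %*% phen$value),
               Matrix::t(W) %*% (R %*% phen$value))
  C <- Matrix::forceSymmetric((C + Matrix::t(C)) / 2)
  sol <- Matrix::solve(C, rhs)
  rel_res <- as.numeric(sqrt(sum((C %*% sol - rhs)^2)) /
                          max(sqrt(sum(rhs^2)), .Machine$double.eps))
  if (rel_res > 1e-10) {
    sol <- sol + Matrix::solve(C, rhs - C %*% sol)  # one refinement step
    rel_res <- as.numeric(sqrt(sum((C %*% sol - rhs)^2)) /
                            max(sqrt(sum(rhs^2)), .Machine$double.eps))
  }
  if (rel_res > 1e-8) {
    stop("mixed-model equations not solved to tolerance (relative residual ",
         signif(rel_res, 3), ")")
  }
  sol <- as.numeric(sol)
  structure(list(
    beta = stats::setNames(sol[seq_len(p)], colnames(X)),
    u = stats::setNames(sol[p + seq_len(n_anim)], ids),
    pe = stats::setNames(sol[p + n_anim + seq_along(phen_ids)], phen_ids),
    components = list(sigma_u2 = spec$sigma_u2, sigma_pe2 = spec$sigma_pe2,
                      sigma_e2 = spec$sigma_e2),
    relative_residual = rel_res
  ), class = "mme_solution")
}

#' @export
print.mme_solution <- function(x, ...) {
  cat("<mme_solution> ", length(x$u), " breeding values; beta = ",
      paste(signif(x$beta, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Back-solve SNP effects from genomic breeding values
#'
#' Computes `s_hat = D M' [M D M']^{-1} u_hat` with `M` the centered,
#' scaled marker matrix. With the default identity weights, `M D M'` is
#' taken as the same (blended) genomic relationship matrix used to build
#' `H^-1`, so the product is guaranteed invertible:
#' `s_hat = D Z' G^{-1} u_g / (2 sum p (1 - p))`.
#'
#' @param sol an `mme_solution` (or any object with named element `u`).
#' @param panel the QC-filtered [genotype_panel] of the genotyped animals.
#' @param g the `genomic_matrix` used for `H^-1` (from [build_G()]).
#' @param d_weights optional per-SNP diagonal weights (default identity).
#'   When supplied, `M D M'` is recomputed from the weighted markers.
#' @return Object of class `"marker_effects"`: data.frame `snp`, `chrom`,
#'   `pos`, `effect` with attributes `freqs` and `d_weights`.
#' @export
backsolve_snp_effects <- function(sol, panel, g, d_weights = NULL) {
  stopifnot(is.genotype_panel(panel), inherits(g, "genomic_matrix"))
  u <- sol$u[panel$animals]
  if (anyNA(u)) stop("GEBVs missing for some genotyped animals")
  Z <- center_markers(panel, g$freqs)
  m <- ncol(Z)
  if (is.null(d_weights)) d_weights <- rep(1, m)
  stopifnot(length(d_weights) == m)
  if (all(d_weights == 1)) {
    K <- g$G
  } else {
    K <- tcrossprod(sweep(Z, 2L, d_weights, "*"), Z) / g$scale
  }
  ch <- tryCatch(chol(K), error = function(e) {
    stop("M D M' is singular; blend G with A22 (blend_weight < 1)")
  })
  Kinv_u <- backsolve(ch, forwardsolve(t(ch), u))
  s <- d_weights * as.numeric(crossprod(Z, Kinv_u)) / g$scale
  out <- data.frame(snp = panel$snps, chrom = panel$map$chrom,
                    pos = panel$map$pos, effect = s,
                    stringsAsFactors = FALSE)
  attr(out, "freqs") <- g$freqs
  attr(out, "d_weights") <- d_weights
  class(out) <- c("marker_effects", "data.frame")
  out
}

#' Window scan of additive genetic variance
#'
#' Splits each chromosome into windows of adjacent SNPs spanning at most
#' `window_bp` and reports, per window, the empirical variance across
#' genotyped animals of the window genetic value `sum_j M_j s_hat_j` as a
#' percentage of the additive genetic variance `sigma_u2`.
#'
#' @param effects a `marker_effects` object from
#'   [backsolve_snp_effects()].
#' @param panel the matching [genotype_panel].
#' @param sigma_u2 additive genetic variance (denominator), > 0.
#' @param window_bp window span in bp (default 1.5 Mb).
#' @param mode `"sliding"` (default): one window starting at every SNP,
#'   containing all adjacent SNPs within `window_bp`; `"bins"`: fixed
#'   non-overlapping bins of `window_bp`.
#' @return data.frame `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `pct_additive_variance`.
#' @export
window_scan <- function(effects, panel, sigma_u2, window_bp = 1.5e6,
                        mode = c("sliding", "bins")) {
  mode <- match.arg(mode)
  stopifnot(is.genotype_panel(panel))
  if (!is.numeric(sigma_u2) || sigma_u2 <= 0) {
    stop("sigma_u2 must be a positive number")
  }
  ix <- match(panel$snps, effects$snp)
  if (anyNA(ix)) stop("effects missing for some panel SNPs")
  s <- effects$effect[ix]
  freqs <- attr(effects, "freqs")
  Z <- center_markers(panel, freqs)
  Tm <- sweep(Z, 2L, s, "*")  # per-SNP genetic values, animals x SNPs
  res <- list()
  for (ch in unique(panel$map$chrom)) {
    on_ch <- which(panel$map$chrom == ch)
    pos <- panel$map$pos[on_ch]
    Tc <- Tm[, on_ch, drop = FALSE]
    # cumulative genetic values along the chromosome for O(1) window sums
    CS <- if (ncol(Tc) == 1L) Tc else t(apply(Tc, 1L, cumsum))
    windows <- if (mode == "sliding") {
      start_ix <- seq_along(pos)
      end_ix <- findInterval(pos + window_bp, pos)
      unique(data.frame(a = start_ix, b = end_ix))
    } else {
      bin <- (pos - 1) %/% window_bp
      agg <- split(seq_along(pos), bin)
      data.frame(a = vapply(agg, min, 1L), b = vapply(agg, max, 1L))
    }
    w_val <- matrix(0, nrow(Tc), nrow(windows))
    for (r in seq_len(nrow(windows))) {
      a <- windows$a[r]; b <- windows$b[r]
      w_val[, r] <- CS[, b] - (if (a > 1L) CS[, a - 1L] else 0)
    }
    v <- apply(w_val, 2L, stats::var)
    res[[as.character(ch)]] <- data.frame(
      chrom = ch,
      start_bp = pos[windows$a],
      end_bp = pos[windows$b],
      n_snps = windows$b - windows$a + 1L,
      pct_additive_variance = 100 * v / sigma_u2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Collapse overlapping windows to per-region maxima
#'
#' Greedy, per chromosome: repeatedly keeps the window with the largest
#' variance percentage and discards windows overlapping it.
#'
#' @param windows output of [window_scan()].
#' @return Subset of `windows`, non-overlapping, sorted by chromosome and
#'   start.
#' @export
collapse_windows <- function(windows) {
  keep <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(-w$pct_additive_variance, w$start_bp), , drop = FALSE]
    taken <- w[0, ]
    for (r in seq_len(nrow(w))) {
      ov <- taken$start_bp <= w$end_bp[r] & taken$end_bp >= w$start_bp[r]
      if (!any(ov)) taken <- rbind(taken, w[r, ])
    }
    keep[[as.character(ch)]] <- taken
  }
  out <- do.call(rbind, keep)
  out <- out[order(.chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
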