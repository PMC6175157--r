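# Pedigree relationship structures: tabular A, inbreeding (Meuwissen-Luo),
# sparse A-inverse (Henderson's rules with inbreeding), and the genotyped
# block A22.

#' Construct a pedigree object
#'
#' A pedigree is a set of animal/sire/dam triples. Animals are re-ordered
#' topologically so that parents always precede their offspring; unknown
#' parents are encoded as `NA`.
#'
#' @param animal character or integer vector of animal IDs (unique).
#' @param sire,dam parent IDs; `NA`, `""` or `"0"` mean unknown. A parent ID
#'   that does not appear in `animal` is added as a founder with a warning.
#' @return An object of class `"pedigree"`: a list with `id` (external IDs in
#'   topological order), `sire` and `dam` (integer indices into `id`, `NA`
#'   when unknown).
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (anyDuplicated(animal)) {
    stop("duplicated animal IDs: ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  }
  unk <- function(x) is.na(x) | x == "" | x == "0"
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(parents)) {
    warning(length(parents), " parent ID(s) absent from the animal column; ",
            "added as founders: ",
            paste(utils::head(parents, 5L), collapse = ", "),
            if (length(parents) > 5L) ", ..." else "")
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  ord <- .topo_order(si, di, animal)
  rk <- integer(n); rk[ord] <- seq_len(n)
  structure(list(
    id = animal[ord],
    sire = rk[si][ord],
    dam = rk[di][ord]
  ), class = "pedigree")
}

# Kahn topological sort over the parent->offspring DAG; reports a cycle
# member on failure.
.topo_order <- function(si, di, ids) {
  n <- length(ids)
  npar <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(stats::na.omit(c(si[i], di[i])))) {
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(npar == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      npar[k] <- npar[k] - 1L
      if (npar[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- setdiff(seq_len(n), ord)[1L]
    stop("pedigree contains a parentage cycle involving animal '",
         ids[bad], "'")
  }
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", length(x$id), " animals (",
      sum(is.na(x$sire) & is.na(x$dam)), " founders)\n", sep = "")
  invisible(x)
}

#' @export
length.pedigree <- function(x) length(x$id)

#' @rdname pedigree
#' @param x object to test.
#' @export
is.pedigree <- function(x) inherits(x, "pedigree")

#' Read a pedigree from CSV
#'
#' Expects columns `animal,sire,dam`; `0` or empty fields denote unknown
#' parents. Rows may be in any order; the result is topologically sorted.
#'
#' @param path path to a CSV file.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(dt))) {
    stop("pedigree file must have columns animal,sire,dam; got: ",
         paste(names(dt), collapse = ","))
  }
  pedigree(dt$animal, dt$sire, dt$dam)
}

#' Write a pedigree to CSV
#'
#' @param ped a [pedigree].
#' @param path output path; unknown parents are written as `0`.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(is.pedigree(ped))
  code <- function(ix) ifelse(is.na(ix), "0", ped$id[ix])
  dt <- data.table::data.table(animal = ped$id,
                               sire = code(ped$sire),
                               dam = code(ped$dam))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Pedigree relationship matrix A (tabular method)
#'
#' Builds the additive (numerator) relationship matrix by the tabular
#' recursion: `a(i,i) = 1 + 0.5 a(s,d)` and
#' `a(i,j) = 0.5 (a(j,s) + a(j,d))` for `j` preceding `i`, with unknown
#' parents contributing zero.
#'
#' @param ped a [pedigree].
#' @return A dense symmetric matrix with dimnames set to the animal IDs.
#' @export
build_A <- function(ped) {
  stopifnot(is.pedigree(ped))
  n <- length(ped$id)
  if (n > 5000L) {
    stop("dense A is limited to 5000 animals; use inbreeding()/",
         "build_A_inverse()/subset_A22() for larger pedigrees")
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  s <- ped$sire; d <- ped$dam
  for (i in seq_len(n)) {
    asd <- 0
    if (!is.na(s[i]) && !is.na(d[i])) asd <- A[s[i], d[i]]
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- numeric(i - 1L)
      if (!is.na(s[i])) aij <- aij + A[j, s[i]]
      if (!is.na(d[i])) aij <- aij + A[j, d[i]]
      aij <- 0.5 * aij
      A[i, j] <- aij
      A[j, i] <- aij
    }
  }
  A
}

#' Inbreeding coefficients
#'
#' Computes `F_i = a(sire_i, dam_i) / 2` for every animal with the
#' Meuwissen-Luo recursion, without materializing the full A matrix.
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of inbreeding coefficients (founders 0).
#' @export
inbreeding <- function(ped) {
  stopifnot(is.pedigree(ped))
  n <- length(ped$id)
  s <- ped$sire; d <- ped$dam
  F <- numeric(n)
  # Meuwissen & Luo: a(i,i) = sum over ancestors j (including i) of
  # L_j^2 * d_j, where L propagates halves down the pedigree from L_i = 1
  # and d_j is the Mendelian-sampling variance; then F_i = a(i,i) - 1.
  for (i in seq_len(n)) {
    if (is.na(s[i]) || is.na(d[i])) { F[i] <- 0; next }
    L <- numeric(i)
    L[s[i]] <- L[s[i]] + 0.5
    L[d[i]] <- L[d[i]] + 0.5
    aii <- .mendelian_var(F, s, d, i)  # L_i = 1 contribution
    for (j in rev(seq_len(i - 1L))) {
      if (L[j] == 0) next
      sj <- s[j]; dj <- d[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * L[j]
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * L[j]
      aii <- aii + L[j]^2 * .mendelian_var(F, s, d, j)
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$id
  F
}

# Mendelian-sampling variance coefficient d_j used in the Meuwissen-Luo
# accumulation and in Henderson's A-inverse rules.
.mendelian_var <- function(F, s, d, j) {
  ks <- !is.na(s[j]); kd <- !is.na(d[j])
  if (ks && kd) {
    0.5 - 0.25 * (F[s[j]] + F[d[j]])
  } else if (ks) {
    0.75 - 0.25 * F[s[j]]
  } else if (kd) {
    0.75 - 0.25 * F[d[j]]
  } else {
    1
  }
}

#' Sparse inverse of A by Henderson's rules
#'
#' Uses the known sparse structure of the inverse of the numerator
#' relationship matrix: each animal contributes
#' `alpha * {(i,i): 1, (i,parent): -1/2, (parent,parent'): 1/4}` with
#' `alpha = 1 / d_i`, where `d_i` is the Mendelian-sampling variance
#' adjusted for parental inbreeding.
#'
#' @param ped a [pedigree].
#' @param F optional precomputed inbreeding coefficients (from
#'   [inbreeding()]); computed if missing.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with animal-ID
#'   dimnames.
#' @export
build_A_inverse <- function(ped, F = NULL) {
  stopifnot(is.pedigree(ped))
  n <- length(ped$id)
  if (is.null(F)) F <- inbreeding(ped)
  s <- ped$sire; d <- ped$dam
  # triplet accumulation
  cap <- 9L * n
  ii <- integer(cap); jj <- integer(cap); xx <- numeric(cap)
  k <- 0L
  push <- function(a, b, v) {
    k <<- k + 1L
    ii[k] <<- a; jj[k] <<- b; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    alpha <- 1 / .mendelian_var(F, s, d, i)
    push(i, i, alpha)
    par <- c(s[i], d[i])
    par <- par[!is.na(par)]
    for (p in par) {
      push(i, p, -0.5 * alpha)
      push(p, i, -0.5 * alpha)
    }
    if (length(par)) {
      for (p in par) for (q in par) push(p, q, 0.25 * alpha)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii[seq_len(k)], j = jj[seq_len(k)],
                               x = xx[seq_len(k)], dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree relationships among genotyped animals (A22)
#'
#' Extracts the block of A corresponding to the genotyped animals, in the
#' order given (typically the genotype panel's animal order).
#'
#' @param ped a [pedigree].
#' @param genotyped_ids character vector of genotyped animal IDs, all
#'   present in the pedigree.
#' @return Dense symmetric matrix with `genotyped_ids` dimnames.
#' @export
subset_A22 <- function(ped, genotyped_ids) {
  stopifnot(is.pedigree(ped))
  genotyped_ids <- as.character(genotyped_ids)
  missing_ids <- setdiff(genotyped_ids, ped$id)
  if (length(missing_ids)) {
    stop("genotyped IDs absent from pedigree: ",
         paste(utils::head(missing_ids, 10L), collapse = ", "),
         if (length(missing_ids) > 10L) ", ..." else "")
  }
  A <- build_A(ped)
  A[genotyped_ids, genotyped_ids, drop = FALSE]
}

#' Write a matrix in coordinate (i, j, value) text format
#'
#' Upper triangle only for symmetric matrices; intended for inspection of
#' relationship matrices.
#'
#' @param m matrix (base or Matrix).
#' @param path output TSV path.
#' @export
write_coo <- function(m, path) {
  m <- as(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  keep <- m@i <= m@j
  dt <- data.table::data.table(i = m@i[keep] + 1L, j = m@j[keep] + 1L,
                               value = m@x[keep])
  data.table::setorder(dt, i, j)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
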