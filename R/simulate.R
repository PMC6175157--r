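# Synthetic-data generator: pedigrees, gene-dropped genotypes, QTL
# architectures and repeated, reliability-weighted phenotype records with
# known truth. Emulates the structure of a national sire-fertility
# evaluation (SCR-like trait, ~1.5K genotyped bulls, 29 autosomes) at desk
# scale.

#' Simulation configuration
#'
#' Collects and validates all generator parameters. Defaults describe a
#' desk-scale version of a sire-fertility dataset: a five-generation
#' pedigree of ~1.6K bulls, 29 autosomes, a polygenic background with a
#' few additive QTL, and one rare recessive QTL with a large negative
#' effect (SCR points) at a low B-allele frequency.
#'
#' @param n_founders founder animals in generation 0.
#' @param n_generations generations bred after the founders.
#' @param offspring_per_mating offspring per mating pair.
#' @param n_snps markers placed uniformly over the chromosomes.
#' @param n_chromosomes autosome count (default 29, the bovine karyotype).
#' @param chrom_length_bp length of each chromosome in bp.
#' @param founder_maf_range range the founder B-allele frequencies are
#'   drawn from, in (0, 0.5].
#' @param n_additive_qtl number of additive QTL (drawn among the SNPs).
#' @param additive_qtl_var_fraction fraction of `sigma_u2` jointly
#'   explained by the additive QTL; the rest is pedigree polygenic.
#' @param n_recessive_qtl number of recessive QTL.
#' @param recessive_effect phenotypic shift (SCR points, negative) applied
#'   to BB animals at each recessive QTL, outside the additive value.
#' @param recessive_b_freq target B-allele frequency of recessive QTL.
#' @param sigma_u2,sigma_pe2,sigma_e2 additive-genetic, permanent-
#'   environment and residual variances, in (SCR points)^2.
#' @param records_per_animal_range inclusive range of evaluation records
#'   per animal.
#' @param reliability_range range of per-record reliabilities in (0, 1].
#' @param missing_rate fraction of genotype calls set missing.
#' @param seed integer seed; fully determines all generated data.
#' @return Object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_founders = 150L,
                       n_generations = 5L,
                       offspring_per_mating = 4L,
                       n_snps = 3000L,
                       n_chromosomes = 29L,
                       chrom_length_bp = 1e7,
                       founder_maf_range = c(0.05, 0.5),
                       n_additive_qtl = 2L,
                       additive_qtl_var_fraction = 0.3,
                       n_recessive_qtl = 1L,
                       recessive_effect = -6,
                       recessive_b_freq = 0.12,
                       sigma_u2 = 4,
                       sigma_pe2 = 3,
                       sigma_e2 = 13,
                       records_per_animal_range = c(1L, 8L),
                       reliability_range = c(0.3, 0.99),
                       missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              founder_maf_range = as.numeric(founder_maf_range),
              n_additive_qtl = as.integer(n_additive_qtl),
              additive_qtl_var_fraction = as.numeric(additive_qtl_var_fraction),
              n_recessive_qtl = as.integer(n_recessive_qtl),
              recessive_effect = as.numeric(recessive_effect),
              recessive_b_freq = as.numeric(recessive_b_freq),
              sigma_u2 = as.numeric(sigma_u2),
              sigma_pe2 = as.numeric(sigma_pe2),
              sigma_e2 = as.numeric(sigma_e2),
              records_per_animal_range = as.integer(records_per_animal_range),
              reliability_range = as.numeric(reliability_range),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  fail <- function(...) stop("invalid simulation configuration: ", ...)
  if (cfg$n_founders < 2L) fail("n_founders must be >= 2")
  if (cfg$n_generations < 0L) fail("n_generations must be >= 0")
  if (cfg$offspring_per_mating < 1L) fail("offspring_per_mating must be >= 1")
  if (cfg$n_snps < 1L) fail("n_snps must be >= 1")
  if (cfg$n_chromosomes < 1L) fail("n_chromosomes must be >= 1")
  if (cfg$chrom_length_bp <= 0) fail("chrom_length_bp must be > 0")
  r <- cfg$founder_maf_range
  if (length(r) != 2L || r[1] > r[2] || r[1] <= 0 || r[2] > 0.5) {
    fail("founder_maf_range must be an increasing pair in (0, 0.5]")
  }
  if (any(c(cfg$sigma_u2, cfg$sigma_pe2, cfg$sigma_e2) < 0)) {
    fail("variances must be >= 0")
  }
  if (cfg$additive_qtl_var_fraction < 0 || cfg$additive_qtl_var_fraction > 1) {
    fail("additive_qtl_var_fraction must lie in [0, 1]")
  }
  if (cfg$recessive_b_freq <= 0 || cfg$recessive_b_freq >= 1) {
    fail("recessive_b_freq must lie in (0, 1)")
  }
  rr <- cfg$records_per_animal_range
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] < 1L) {
    fail("records_per_animal_range must be an increasing pair of counts >= 1")
  }
  rel <- cfg$reliability_range
  if (length(rel) != 2L || rel[1] > rel[2] || rel[1] <= 0 || rel[2] > 1) {
    fail("reliability_range must be an increasing pair in (0, 1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    fail("missing_rate must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Simulate a multi-generation pedigree
#'
#' Generation 0 holds the founders. Each later generation draws
#' `floor(n_founders / 2)` mating pairs (two distinct parents per pair)
#' from all previously born animals and produces `offspring_per_mating`
#' offspring per pair, so parents always precede offspring.
#'
#' @param config a [sim_config()].
#' @return A [pedigree] with an extra element `generation` (integer per
#'   animal).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  id <- paste0("F", seq_len(config$n_founders))
  sire <- rep(NA_character_, config$n_founders)
  dam <- rep(NA_character_, config$n_founders)
  gen <- rep(0L, config$n_founders)
  n_matings <- config$n_founders %/% 2L
  for (g in seq_len(config$n_generations)) {
    pool <- id
    kid_sire <- character(0); kid_dam <- character(0)
    for (m in seq_len(n_matings)) {
      pair <- sample(pool, 2L)
      kid_sire <- c(kid_sire, rep(pair[1L], config$offspring_per_mating))
      kid_dam <- c(kid_dam, rep(pair[2L], config$offspring_per_mating))
    }
    kid_id <- paste0("G", g, "_", seq_along(kid_sire))
    id <- c(id, kid_id)
    sire <- c(sire, kid_sire)
    dam <- c(dam, kid_dam)
    gen <- c(gen, rep(g, length(kid_id)))
  }
  ped <- pedigree(id, sire, dam)
  # pedigree() preserves this birth order (it is already topological)
  ped$generation <- gen[match(ped$id, id)]
  ped
}

#' Simulate genotypes by gene dropping
#'
#' Founders are drawn from Hardy-Weinberg proportions at per-marker
#' B-allele frequencies sampled uniformly within `founder_maf_range`.
#' Offspring receive one allele from each parent by Mendelian segregation,
#' independently per marker (no linkage map). Markers are placed uniformly
#' along equal-length chromosomes. Missing calls are injected at
#' `missing_rate`; the pre-missingness codes are kept in `$truth_codes`
#' for downstream truth construction.
#'
#' @param ped a [pedigree] (topologically ordered).
#' @param config a [sim_config()].
#' @return A [genotype_panel] with extra elements `truth_codes` (complete
#'   code matrix) and `founder_freq` (per-SNP founder B-allele frequency).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(is.pedigree(ped), inherits(config, "sim_config"))
  s <- ped$sire; d <- ped$dam
  if (any(!is.na(s) & s >= seq_along(s)) || any(!is.na(d) & d >= seq_along(d))) {
    stop("pedigree is not topologically ordered")
  }
  set.seed(config$seed + 1L)
  n <- length(ped$id); m <- config$n_snps
  # map: markers spread round-robin over chromosomes, uniform positions
  chrom <- rep(seq_len(config$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    sort(sample.int(config$chrom_length_bp, length(ix), replace = FALSE))
  }), use.names = FALSE)
  map <- data.frame(snp = sprintf("snp%05d", seq_len(m)),
                    chrom = as.character(chrom), pos = pos)
  p <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  if (config$n_recessive_qtl > 0L) {
    # pin candidate recessive loci at the target B-allele frequency so the
    # planted architecture matches the configured carrier frequency
    pin <- sample.int(m, min(config$n_recessive_qtl, m))
    p[pin] <- config$recessive_b_freq
  }
  G <- matrix(0L, n, m, dimnames = list(ped$id, map$snp))
  for (i in seq_len(n)) {
    a1 <- if (is.na(s[i])) stats::rbinom(m, 1L, p) else
      stats::rbinom(m, 1L, G[s[i], ] / 2)
    a2 <- if (is.na(d[i])) stats::rbinom(m, 1L, p) else
      stats::rbinom(m, 1L, G[d[i], ] / 2)
    G[i, ] <- a1 + a2
  }
  codes <- G
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(codes)) < config$missing_rate
    codes[miss] <- NA_integer_
  }
  panel <- genotype_panel(codes, map)
  panel$truth_codes <- G[, panel$snps, drop = FALSE]
  panel$founder_freq <- p[match(panel$snps, map$snp)]
  panel
}

#' Simulate repeated phenotype records with known truth
#'
#' The additive value `u` of each animal is a pedigree-sampled polygenic
#' component (variance `(1 - f) sigma_u2`, with Mendelian-sampling
#' variance reduced by parental inbreeding) plus centered additive-QTL
#' contributions (variance `f sigma_u2` jointly, `f` =
#' `additive_qtl_var_fraction`). Recessive QTL add `recessive_effect` to
#' BB animals on the phenotype scale only, outside `u`, so an additive
#' scan sees them weakly and a recessive scan strongly. Record `j` of
#' animal `i` is `u_i + pe_i + recessive shift + e_ij` with
#' `Var(e_ij) = sigma_e2 / reliability_ij`.
#'
#' @param ped a [pedigree].
#' @param geno a panel from [simulate_genotypes()] (its `truth_codes` are
#'   used for QTL carriers).
#' @param config a [sim_config()].
#' @return list with `phenotypes` (data.frame `animal`, `record_id`,
#'   `value`, `reliability`) and `truth` (list: `u`, `pe`, `qtl`
#'   data.frame, `recessive_shift` per animal).
#' @export
simulate_phenotypes <- function(ped, geno, config) {
  stopifnot(is.pedigree(ped), is.genotype_panel(geno),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- length(ped$id)
  M <- geno$truth_codes
  if (is.null(M)) M <- geno$codes
  stopifnot(identical(rownames(M), ped$id))
  fr <- colSums(M, na.rm = TRUE) / (2 * colSums(!is.na(M)))

  qtl <- data.frame(snp = character(0), type = character(0),
                    effect = numeric(0), freq_b = numeric(0),
                    stringsAsFactors = FALSE)
  # additive QTL: effects sized so they jointly explain the configured
  # fraction of sigma_u2 under HWE (var per QTL = a^2 * 2p(1-p))
  u_qtl <- numeric(n)
  f_add <- if (config$n_additive_qtl > 0L) config$additive_qtl_var_fraction else 0
  if (config$n_additive_qtl > 0L && f_add > 0 && config$sigma_u2 > 0) {
    eligible <- which(fr >= 0.1 & fr <= 0.9)
    if (length(eligible) < config$n_additive_qtl) {
      eligible <- order(abs(fr - 0.5))[seq_len(config$n_additive_qtl)]
    }
    add_ix <- eligible[sample.int(length(eligible), config$n_additive_qtl)]
    for (j in add_ix) {
      pj <- fr[j]
      a <- sqrt(f_add * config$sigma_u2 /
                  (config$n_additive_qtl * 2 * pj * (1 - pj)))
      a <- a * sample(c(-1, 1), 1L)
      u_qtl <- u_qtl + a * (M[, j] - 2 * pj)
      qtl <- rbind(qtl, data.frame(snp = colnames(M)[j], type = "additive",
                                   effect = a, freq_b = unname(pj)))
    }
  }
  # polygenic component sampled down the pedigree
  sig_poly <- (1 - f_add) * config$sigma_u2
  u_poly <- numeric(n)
  if (sig_poly > 0) {
    F <- inbreeding(ped)
    s <- ped$sire; d <- ped$dam
    for (i in seq_len(n)) {
      mu <- 0; vfrac <- 1
      if (!is.na(s[i]) || !is.na(d[i])) {
        mu <- 0.5 * sum(u_poly[c(s[i], d[i])], na.rm = TRUE)
        vfrac <- .mendelian_var(F, s, d, i)
      }
      u_poly[i] <- mu + stats::rnorm(1L, 0, sqrt(sig_poly * vfrac))
    }
  }
  u <- u_poly + u_qtl

  # recessive QTL: genotype-conditional phenotype shift for BB animals
  rec_shift <- numeric(n)
  if (config$n_recessive_qtl > 0L) {
    rec_ix <- order(abs(fr - config$recessive_b_freq))[
      seq_len(min(config$n_recessive_qtl, ncol(M)))]
    for (j in rec_ix) {
      rec_shift <- rec_shift + config$recessive_effect * (M[, j] == 2L)
      qtl <- rbind(qtl, data.frame(snp = colnames(M)[j], type = "recessive",
                                   effect = config$recessive_effect,
                                   freq_b = unname(fr[j])))
    }
  }

  pe <- stats::rnorm(n, 0, sqrt(config$sigma_pe2))
  rr <- config$records_per_animal_range
  nrec <- if (rr[1] == rr[2]) rep(rr[1], n) else
    sample(seq(rr[1], rr[2]), n, replace = TRUE)
  animal <- rep(ped$id, nrec)
  idx <- rep(seq_len(n), nrec)
  record_id <- unlist(lapply(nrec, seq_len), use.names = FALSE)
  rel <- config$reliability_range
  reliability <- if (rel[1] == rel[2]) rep(rel[1], length(idx)) else
    stats::runif(length(idx), rel[1], rel[2])
  e <- stats::rnorm(length(idx), 0, sqrt(config$sigma_e2 / reliability))
  value <- u[idx] + pe[idx] + rec_shift[idx] + e
  phen <- data.frame(animal = animal, record_id = record_id,
                     value = value, reliability = reliability,
                     stringsAsFactors = FALSE)
  truth <- list(u = stats::setNames(u, ped$id),
                pe = stats::setNames(pe, ped$id),
                qtl = qtl,
                recessive_shift = stats::setNames(rec_shift, ped$id))
  list(phenotypes = phen, truth = truth)
}

#' Simulate a gene annotation and gene-set collection
#'
#' Genes are non-overlapping intervals placed in equal slots along the
#' simulated chromosomes; gene sets are random subsets with sizes spanning
#' 4 to 250 genes (bounded by the number of genes).
#'
#' @param geno a [genotype_panel] (defines the chromosomes).
#' @param n_genes number of genes.
#' @param n_sets number of gene sets.
#' @param seed integer seed.
#' @param chrom_length_bp chromosome length in bp (default: max mapped
#'   position, rounded up).
#' @return list with `annotation` (data.frame `gene`, `chrom`, `start`,
#'   `end`; 1-based inclusive) and `sets` (named list of gene-ID vectors,
#'   class `"gmt_collection"` with a `description` attribute).
#' @export
simulate_annotation <- function(geno, n_genes, n_sets, seed = 1L,
                                chrom_length_bp = NULL) {
  stopifnot(is.genotype_panel(geno), n_genes >= 1L, n_sets >= 0L)
  set.seed(seed)
  chroms <- unique(geno$map$chrom)
  if (is.null(chrom_length_bp)) chrom_length_bp <- max(geno$map$pos) * 1.05
  per_chrom <- table(rep(chroms, length.out = n_genes))
  rows <- list()
  gid <- 0L
  for (ch in chroms) {
    k <- as.integer(per_chrom[ch])
    if (is.na(k) || k == 0L) next
    slot <- floor(chrom_length_bp / k)
    if (slot < 2000) {
      stop("n_genes too large for chromosome length: slot of ", slot,
           " bp per gene on chromosome ", ch)
    }
    for (ii in seq_len(k)) {
      gid <- gid + 1L
      len <- sample(1000:min(50000, slot - 1000), 1L)
      start <- (ii - 1L) * slot + sample.int(slot - len, 1L)
      rows[[gid]] <- data.frame(gene = sprintf("GENE%04d", gid),
                                chrom = ch, start = start,
                                end = start + len)
    }
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  sets <- list()
  if (n_sets > 0L) {
    max_size <- min(250L, nrow(ann))
    sizes <- sample(seq(min(4L, max_size), max_size), n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sort(sample(ann$gene, k)))
    names(sets) <- sprintf("SET%03d", seq_len(n_sets))
    attr(sets, "description") <- rep("synthetic gene set", n_sets)
    class(sets) <- "gmt_collection"
  }
  list(annotation = ann, sets = sets)
}

#' Write all simulated artifacts to a directory
#'
#' Emits pedigree CSV, genotype + map TSV, phenotype TSV, gene BED and
#' gene-set GMT, plus a JSON truth file.
#'
#' @param sim list as produced by [run_simulation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  write_genotypes(sim$panel, file.path(dir, "genotypes.tsv"),
                  file.path(dir, "map.tsv"))
  write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_bed(sim$annotation, file.path(dir, "genes.bed"))
  write_gmt(sim$sets, file.path(dir, "sets.gmt"))
  truth <- sim$truth
  jsonlite::write_json(
    list(u = as.list(truth$u), qtl = truth$qtl),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full generator
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()], [simulate_phenotypes()] and
#' [simulate_annotation()].
#'
#' @param config a [sim_config()].
#' @param n_genes,n_sets annotation size (defaults scale with the panel).
#' @return list with `pedigree`, `panel`, `phenotypes`, `truth`,
#'   `annotation`, `sets`, `config`.
#' @export
run_simulation <- function(config, n_genes = 200L, n_sets = 50L) {
  ped <- simulate_pedigree(config)
  panel <- simulate_genotypes(ped, config)
  py <- simulate_phenotypes(ped, panel, config)
  ann <- simulate_annotation(panel, n_genes, n_sets,
                             seed = config$seed + 3L,
                             chrom_length_bp = config$chrom_length_bp)
  list(pedigree = ped, panel = panel, phenotypes = py$phenotypes,
       truth = py$truth, annotation = ann$annotation, sets = ann$sets,
       config = config)
}
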