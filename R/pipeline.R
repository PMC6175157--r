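# Structured run configuration and the multi-stage pipeline driver:
# simulate -> qc -> scan-additive -> scan-nonadditive -> geneset.

#' Default run configuration
#'
#' All stage parameters with their conventional defaults: MAF threshold
#' 0.01, call-rate threshold 0.90, 1.5-Mb windows, 15-kb gene flank, top
#' 1% of SNP effects, Bonferroni alpha 0.01, enrichment alpha 0.05, G
#' blending 0.95.
#'
#' @param ... overrides for individual fields (unknown names rejected).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # QC
    maf_min = 0.01,
    callrate_min = 0.90,
    autosomes_only = TRUE,
    sex_chroms = c("X", "Y"),
    # relationship matrices
    blend_weight = 0.95,
    # additive scan
    fixed = character(0),
    sigma_u2 = NULL, sigma_pe2 = NULL, sigma_e2 = NULL,
    window_bp = 1.5e6,
    window_mode = "sliding",
    # non-additive scan
    codings = c("dominance", "recessive", "overdominance"),
    gc = TRUE,
    bonferroni_alpha = 0.01,
    # gene-set stage
    flank_bp = 15000,
    top_fraction = 0.01,
    enrichment_alpha = 0.05,
    # simulation stage
    sim = NULL,
    n_genes = 200L,
    n_sets = 50L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  .validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$maf_min) || cfg$maf_min < 0 || cfg$maf_min > 0.5) {
    stop("maf_min must lie in [0, 0.5]")
  }
  if (cfg$callrate_min < 0 || cfg$callrate_min > 1) {
    stop("callrate_min must lie in [0, 1]")
  }
  if (cfg$blend_weight <= 0 || cfg$blend_weight > 1) {
    stop("blend_weight must lie in (0, 1]")
  }
  if (cfg$window_bp <= 0) stop("window_bp must be > 0")
  if (cfg$flank_bp < 0) stop("flank_bp must be >= 0")
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  if (cfg$bonferroni_alpha <= 0 || cfg$bonferroni_alpha > 1 ||
      cfg$enrichment_alpha <= 0 || cfg$enrichment_alpha > 1) {
    stop("alpha levels must lie in (0, 1]")
  }
  invisible(cfg)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys match [run_config()] fields; the
#'   `sim` entry (if any) is passed to [sim_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, as.list(raw$sim))
  do.call(run_config, raw)
}

#' Run pipeline stages
#'
#' Executes the requested stages in dependency order against a working
#' directory; every stage writes its outputs plus a provenance JSON
#' (`<stage>_meta.json`) into `out_dir`.
#'
#' Stage inputs are read from `out_dir` (`pedigree.csv`,
#' `genotypes.tsv`, `map.tsv`, `phenotypes.tsv`, `genes.bed`,
#' `sets.gmt`), as written by the `simulate` stage or supplied by the
#' user.
#'
#' @param config a [run_config()].
#' @param out_dir working/output directory.
#' @param stages character vector among `"simulate"`, `"qc"`,
#'   `"scan-additive"`, `"scan-nonadditive"`, `"geneset"`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("simulate", "qc", "scan-additive",
                                    "scan-nonadditive", "geneset")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "qc", "scan-additive", "scan-nonadditive",
                  "geneset")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  need <- function(path, producer) {
    if (!file.exists(path)) {
      stop("missing input '", basename(path), "'; run the '", producer,
           "' stage first (or place the file in ", out_dir, ")")
    }
    path
  }
  cfg_json <- unclass(config)
  cfg_json$sim <- if (is.null(config$sim)) NULL else unclass(config$sim)

  if ("simulate" %in% stages) {
    sim_cfg <- config$sim
    if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = config$seed)
    message("[simulate] generating synthetic dataset (seed ",
            sim_cfg$seed, ")")
    sim <- run_simulation(sim_cfg, n_genes = config$n_genes,
                          n_sets = config$n_sets)
    write_simulation(sim, out_dir)
    .write_run_meta(out_dir, "simulate", cfg_json,
                    list(n_animals = length(sim$pedigree$id),
                         n_snps = length(sim$panel$snps)))
    results$simulate <- sim
  }

  panel <- NULL
  load_panel <- function() {
    if (is.null(panel)) {
      panel <<- read_genotypes(need(file.path(out_dir, "genotypes.tsv"),
                                    "simulate"),
                               need(file.path(out_dir, "map.tsv"),
                                    "simulate"))
    }
    panel
  }

  if ("qc" %in% stages) {
    qc <- qc_filter(load_panel(), maf_min = config$maf_min,
                    callrate_min = config$callrate_min,
                    autosomes_only = config$autosomes_only,
                    sex_chroms = config$sex_chroms)
    message("[qc] retained ", qc$report$retained, " of ",
            qc$report$n_input, " SNPs (removed: ",
            paste(names(qc$report$removed), qc$report$removed,
                  sep = "=", collapse = ", "), ")")
    write_genotypes(qc$panel, file.path(out_dir, "genotypes_qc.tsv"),
                    file.path(out_dir, "map_qc.tsv"))
    write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
    .write_run_meta(out_dir, "qc", cfg_json)
    results$qc <- qc
    panel <- qc$panel
  }

  qc_panel <- function() {
    gp <- file.path(out_dir, "genotypes_qc.tsv")
    if (file.exists(gp)) {
      read_genotypes(gp, file.path(out_dir, "map_qc.tsv"))
    } else {
      stop("missing input 'genotypes_qc.tsv'; run the 'qc' stage first")
    }
  }

  if ("scan-additive" %in% stages) {
    ped <- read_pedigree(need(file.path(out_dir, "pedigree.csv"),
                              "simulate"))
    phen <- read_phenotypes(need(file.path(out_dir, "phenotypes.tsv"),
                                 "simulate"))
    pq <- qc_panel()
    message("[scan-additive] ", length(ped$id), " animals, ",
            length(pq$snps), " SNPs")
    a_inv <- build_A_inverse(ped)
    a22 <- subset_A22(ped, pq$animals)
    g <- build_G(pq, blend_weight = config$blend_weight, a22 = a22)
    h_inv <- build_H_inverse(a_inv, g, a22, pq$animals)
    spec <- model_spec(fixed = config$fixed, sigma_u2 = config$sigma_u2,
                       sigma_pe2 = config$sigma_pe2,
                       sigma_e2 = config$sigma_e2)
    sol <- solve_mme(phen, h_inv, spec)
    effects <- backsolve_snp_effects(sol, pq, g)
    windows <- window_scan(effects, pq, sol$components$sigma_u2,
                           window_bp = config$window_bp,
                           mode = config$window_mode)
    write_effects(effects, file.path(out_dir, "snp_effects.tsv"))
    write_windows(windows, file.path(out_dir, "windows.tsv"))
    .write_run_meta(out_dir, "scan-additive", cfg_json,
                    list(components = sol$components))
    results$scan_additive <- list(solution = sol, effects = effects,
                                  windows = windows, g = g)
  }

  if ("scan-nonadditive" %in% stages) {
    phen <- read_phenotypes(need(file.path(out_dir, "phenotypes.tsv"),
                                 "simulate"))
    pq <- qc_panel()
    message("[scan-nonadditive] codings: ",
            paste(config$codings, collapse = ", "))
    scan <- scan_nonadditive(pq, phen, codings = config$codings,
                             fixed = config$fixed,
                             blend_weight = config$blend_weight,
                             gc = config$gc,
                             alpha = config$bonferroni_alpha)
    for (cd in config$codings) {
      data.table::fwrite(scan[[cd]],
                         file.path(out_dir, paste0("scan_", cd, ".tsv")),
                         sep = "\t")
    }
    .write_run_meta(out_dir, "scan-nonadditive", cfg_json,
                    list(lambdas = as.list(scan$lambdas)))
    results$scan_nonadditive <- scan
  }

  if ("geneset" %in% stages) {
    pq <- qc_panel()
    effects <- read_effects(need(file.path(out_dir, "snp_effects.tsv"),
                                 "scan-additive"))
    ann <- read_bed(need(file.path(out_dir, "genes.bed"), "simulate"))
    sets <- read_gmt(need(file.path(out_dir, "sets.gmt"), "simulate"))
    mapping <- assign_snps_to_genes(pq$map, ann,
                                    flank_bp = config$flank_bp)
    flags <- flag_significant_genes(effects, mapping,
                                    top_fraction = config$top_fraction)
    message("[geneset] N = ", flags$N, " analyzed genes, S = ", flags$S,
            " significant")
    enr <- run_enrichment(flags$significant_genes, flags$universe, sets,
                          alpha = config$enrichment_alpha)
    data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t")
    .write_run_meta(out_dir, "geneset", cfg_json,
                    list(N = flags$N, S = flags$S))
    results$geneset <- list(mapping = mapping, flags = flags,
                            enrichment = enr)
  }

  invisible(results)
}
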