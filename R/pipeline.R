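#' Configuration of a full pipeline run
#'
#' @param sim a [sim_config()] to simulate the study on the fly, or `NULL`
#'   to read files.
#' @param ped_path,map_path,pheno_path,manifest_path input files (used when
#'   `sim` is `NULL`).
#' @param traits trait columns to analyse.
#' @param covariates covariate columns for the residualisation; the derived
#'   indicator `smoking_ever` (ever vs never smoker) is built from
#'   `smoking` automatically.
#' @param log_transform log-transform traits before residualising.
#' @param exclusion_required columns that must be non-missing for a member
#'   to enter the analysis (smoking counted as its own reason).
#' @param exclude_diabetes sensitivity switch: drop members with diabetes.
#' @param adjust_bmi sensitivity switch: add BMI to the covariates of every
#'   non-BMI trait.
#' @param drop_snp sensitivity switch: SNP id removed from the combination
#'   stage.
#' @param combine a [combine_config()].
#' @param correction_scope `"per_trait"` corrects each trait's p-values
#'   separately (default); `"joint"` pools traits before correction.
#' @param min_informative minimum informative families per SNP.
#' @param out_dir optional output directory; when set, result tables, the
#'   exclusion log and a machine-readable run manifest are written there.
#' @param seed optional master seed; when given it deterministically
#'   re-seeds both the simulator and the Monte Carlo ensemble.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       ped_path = NULL, map_path = NULL, pheno_path = NULL,
                       manifest_path = NULL,
                       traits = c("bmi", "wc", "whr", "pbf"),
                       covariates = c("age", "sex", "center", "smoking_ever",
                                      "alcohol", "steps_day", "energy_kcal",
                                      "ses", "diabetes"),
                       log_transform = TRUE,
                       exclusion_required = c("smoking", "alcohol",
                                              "steps_day", "energy_kcal",
                                              "ses", "diabetes"),
                       exclude_diabetes = FALSE,
                       adjust_bmi = FALSE,
                       drop_snp = NULL,
                       combine = combine_config(),
                       correction_scope = c("per_trait", "joint"),
                       min_informative = 10L,
                       out_dir = NULL,
                       seed = NULL) {
  correction_scope <- match.arg(correction_scope)
  if (is.null(sim)) {
    for (p in c(ped_path, map_path, pheno_path, manifest_path))
      if (is.null(p) || !file.exists(p))
        stop("input file missing: ", p %||% "(unset)")
  }
  if (!is.null(seed)) {
    if (!is.null(sim)) sim$seed <- derive_seed(seed, "simulate")
    combine$seed <- derive_seed(seed, "combine")
  }
  structure(list(sim = sim, ped_path = ped_path, map_path = map_path,
                 pheno_path = pheno_path, manifest_path = manifest_path,
                 traits = traits, covariates = covariates,
                 log_transform = log_transform,
                 exclusion_required = exclusion_required,
                 exclude_diabetes = exclude_diabetes,
                 adjust_bmi = adjust_bmi, drop_snp = drop_snp,
                 combine = combine, correction_scope = correction_scope,
                 min_informative = as.integer(min_informative),
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    st <- simulate_study(cfg$sim)
    list(ped = st$ped, geno = st$geno, pheno = st$pheno,
         manifest = st$manifest)
  } else {
    pm <- read_pedmap(cfg$ped_path, cfg$map_path)
    list(ped = pm$ped, geno = pm$geno,
         pheno = read_phenotypes(cfg$pheno_path),
         manifest = read_gene_manifest(cfg$manifest_path))
  }
}

#' Run the full joint-association pipeline
#'
#' simulate/read, exclude, residualise, single-SNP family-based tests,
#' gene-level and gene-family weighted truncated-product combination,
#' Storey q-values, and (optionally) result tables on disk. Fully
#' deterministic under a fixed configuration.
#'
#' @param cfg a [run_config()].
#' @return a list of class `famtpm_run`: `snp_results` (long, per trait),
#'   `snp_table` (wide, Table-2-like), `gene_table` (gene x trait p-values
#'   with a gene-family row; q < 0.05 entries flagged `*`), `per_trait`
#'   (per-trait details: residuals n, snp results, `gene_combine`),
#'   `exclusions`, `ld`, `manifest`, `paths` (when written), `cfg`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- load_inputs(cfg)
  ped <- inp$ped; geno <- inp$geno; manifest <- inp$manifest
  pheno <- inp$pheno
  pheno$smoking_ever <- ifelse(is.na(pheno$smoking), NA_integer_,
                               as.integer(pheno$smoking != "never"))

  excl <- apply_exclusions(pheno, required = cfg$exclusion_required)
  dat <- excl$pheno
  if (cfg$exclude_diabetes) {
    if (!"diabetes" %in% names(dat)) {
      warning("no diabetes column; exclude_diabetes skipped", call. = FALSE)
    } else {
      n_drop <- sum(dat$diabetes == 1, na.rm = TRUE)
      dat <- dat[!is.na(dat$diabetes) & dat$diabetes == 0, , drop = FALSE]
      excl$log <- rbind(excl$log,
                        data.frame(reason = "diabetes (sensitivity)",
                                   n_excluded = n_drop))
      excl$n_final <- nrow(dat)
      excl$pheno <- dat
    }
  }

  founders <- ped$iid[ped$pat == "0" & ped$mat == "0"]
  R <- if (cfg$combine$null_mode == "ld_mvn") {
    estimate_ld_correlation(geno[founders, manifest$snp, drop = FALSE])
  } else {
    structure(diag(nrow(manifest)),
              dimnames = list(manifest$snp, manifest$snp))
  }
  ensemble <- mc_null_ensemble(R, cfg$combine)

  per_trait <- list()
  snp_long <- list()
  gene_long <- list()
  for (tr in cfg$traits) {
    covs <- cfg$covariates
    if (cfg$exclude_diabetes)      # constant after exclusion
      covs <- setdiff(covs, "diabetes")
    if (cfg$adjust_bmi && tr != "bmi") covs <- union(covs, "bmi")
    resid <- adjust_covariates(dat, tr, covs, cfg$log_transform)
    snp_res <- fbat_scan(ped, geno, resid, snps = manifest$snp,
                         min_informative = cfg$min_informative)
    gc <- if (!is.null(cfg$drop_snp)) {
      leave_one_snp_out(snp_res, manifest, ensemble, cfg$combine,
                        cfg$drop_snp)
    } else {
      combine_genes(snp_res, manifest, ensemble, cfg$combine)
    }
    snp_res$trait <- tr
    gdf <- gc$genes
    gdf$trait <- tr
    per_trait[[tr]] <- list(n = attr(resid, "n"), snp_results = snp_res,
                            combine = gc)
    snp_long[[tr]] <- snp_res
    gene_long[[tr]] <- gdf
  }
  snp_long <- do.call(rbind, snp_long)
  gene_long <- do.call(rbind, gene_long)
  rownames(snp_long) <- rownames(gene_long) <- NULL

  by <- if (cfg$correction_scope == "per_trait") "trait" else NULL
  snp_long <- add_qvalues(snp_long, "p", by = by)
  gene_long <- add_qvalues(gene_long, "p", by = by)

  gene_table <- build_gene_table(gene_long, per_trait, cfg$traits)
  snp_table <- build_snp_table(snp_long, manifest, cfg$traits)

  run <- structure(list(snp_results = snp_long, snp_table = snp_table,
                        gene_table = gene_table, per_trait = per_trait,
                        exclusions = excl, ld = R, manifest = manifest,
                        ensemble = ensemble, cfg = cfg),
                   class = "famtpm_run")
  if (!is.null(cfg$out_dir)) run$paths <- write_run(run, cfg$out_dir)
  run
}

build_snp_table <- function(snp_long, manifest, traits) {
  out <- manifest[, c("snp", "gene")]
  for (tr in traits) {
    sl <- snp_long[snp_long$trait == tr, ]
    out[[paste0("p_", tr)]] <- sl$p[match(out$snp, sl$snp)]
    out[[paste0("q_", tr)]] <- sl$p_q[match(out$snp, sl$snp)]
  }
  out
}

build_gene_table <- function(gene_long, per_trait, traits) {
  genes <- unique(gene_long$gene)
  out <- data.frame(gene = c(genes, "gene_family"),
                    stringsAsFactors = FALSE)
  for (tr in traits) {
    gl <- gene_long[gene_long$trait == tr, ]
    fam <- per_trait[[tr]]$combine$family
    p <- c(gl$p[match(genes, gl$gene)], fam$p %||% NA_real_)
    sig <- c(gl$p_sig[match(genes, gl$gene)], FALSE)
    out[[tr]] <- ifelse(is.na(p), NA_character_,
                        paste0(formatC(p, format = "f", digits = 4),
                               ifelse(sig, "*", "")))
  }
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(snp = file.path(out_dir, "snp_results.tsv"),
                gene = file.path(out_dir, "gene_results.tsv"),
                excl = file.path(out_dir, "exclusions.txt"),
                manifest = file.path(out_dir, "run_manifest.json"))
  utils::write.table(run$snp_table, paths$snp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(run$gene_table, paths$gene, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  con <- file(paths$excl, "w")
  sink(con); print(run$exclusions); sink()
  close(con)
  cfg <- run$cfg
  manifest <- list(
    package_version = as.character(utils::packageVersion("famtpm")),
    seed = cfg$seed,
    sim_seed = if (!is.null(cfg$sim)) cfg$sim$seed else NULL,
    tau = cfg$combine$tau, B = cfg$combine$B,
    weight_mode = cfg$combine$weight_mode,
    null_mode = cfg$combine$null_mode,
    ensemble_seed = cfg$combine$seed,
    traits = cfg$traits, covariates = cfg$covariates,
    exclusion_required = cfg$exclusion_required,
    exclude_diabetes = cfg$exclude_diabetes,
    adjust_bmi = cfg$adjust_bmi, drop_snp = cfg$drop_snp,
    n_final = run$exclusions$n_final,
    config = jsonlite::serializeJSON(cfg))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             paths$manifest)
  paths
}

#' Re-run a pipeline from its run manifest
#'
#' The run manifest written by [run_pipeline()] embeds the complete
#' serialized configuration; this reconstructs it and reproduces the run
#' (byte-identical tables under the same package version).
#'
#' @param manifest_path path to `run_manifest.json`.
#' @param out_dir optional new output directory (defaults to the one in the
#'   stored configuration).
#' @return a `famtpm_run`.
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::fromJSON(manifest_path)
  cfg <- jsonlite::unserializeJSON(m$config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(cfg)
}

#' Sensitivity analyses around a base run
#'
#' Re-runs the pipeline under four standard perturbations: members with
#' diabetes excluded; smoking removed from the covariates; BMI added as a
#' covariate for the non-BMI traits; and, per trait, the most significant
#' SNP removed from the combination stage (recomputed from the base run's
#' single-SNP results without re-testing). Variants that do not apply are
#' skipped with a warning.
#'
#' @param cfg a [run_config()] for the base analysis.
#' @param variants subset of
#'   `c("exclude_diabetes", "no_smoking", "adjust_bmi", "drop_top_snp")`.
#' @return a list of class `famtpm_sensitivity`: `base` (the base
#'   `famtpm_run`), `runs` (variant results), `comparison` (data.frame of
#'   gene-family p per trait and variant).
#' @export
sensitivity_suite <- function(cfg,
                              variants = c("exclude_diabetes", "no_smoking",
                                           "adjust_bmi", "drop_top_snp")) {
  base <- run_pipeline(cfg)
  runs <- list()

  fam_p <- function(run) vapply(cfg$traits, function(tr)
    run$per_trait[[tr]]$combine$family$p %||% NA_real_, numeric(1))

  if ("exclude_diabetes" %in% variants) {
    cfg2 <- cfg; cfg2$exclude_diabetes <- TRUE; cfg2$out_dir <- NULL
    runs$exclude_diabetes <- run_pipeline(cfg2)
  }
  if ("no_smoking" %in% variants) {
    cfg2 <- cfg; cfg2$out_dir <- NULL
    cfg2$covariates <- setdiff(cfg2$covariates, "smoking_ever")
    runs$no_smoking <- run_pipeline(cfg2)
  }
  if ("adjust_bmi" %in% variants) {
    if (!"bmi" %in% c(cfg$traits, names(base$exclusions$pheno))) {
      warning("no BMI available; adjust_bmi variant skipped", call. = FALSE)
    } else {
      cfg2 <- cfg; cfg2$adjust_bmi <- TRUE; cfg2$out_dir <- NULL
      runs$adjust_bmi <- run_pipeline(cfg2)
    }
  }
  drop_fam <- NULL
  if ("drop_top_snp" %in% variants) {
    # reuse the base single-SNP results; only the combination is redone
    drop_fam <- vapply(cfg$traits, function(tr) {
      sr <- base$per_trait[[tr]]$snp_results
      top <- sr$snp[which.min(sr$p)]
      gc <- leave_one_snp_out(sr, base$manifest, base$ensemble,
                              cfg$combine, top)
      gc$family$p %||% NA_real_
    }, numeric(1))
  }

  comparison <- rbind(
    data.frame(variant = "base", trait = cfg$traits, family_p = fam_p(base)),
    do.call(rbind, lapply(names(runs), function(v)
      data.frame(variant = v, trait = cfg$traits, family_p = fam_p(runs[[v]])))),
    if (!is.null(drop_fam))
      data.frame(variant = "drop_top_snp", trait = cfg$traits,
                 family_p = drop_fam))
  rownames(comparison) <- NULL
  structure(list(base = base, runs = runs, comparison = comparison),
            class = "famtpm_sensitivity")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map to [run_config()] arguments; `sim: true` requests the
#' default simulated study, `sim` as a mapping is passed to [sim_config()],
#' and `combine` as a mapping is passed to [combine_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    y$sim <- if (isTRUE(y$sim)) sim_config() else do.call(sim_config, y$sim)
  }
  if (!is.null(y$combine)) y$combine <- do.call(combine_config, y$combine)
  do.call(run_config, y)
}

#' @export
print.famtpm_run <- function(x, ...) {
  cat("famtpm run:", x$exclusions$n_final, "members,",
      nrow(x$manifest), "SNPs in", length(unique(x$manifest$gene)),
      "genes\n")
  cat("gene-level / gene-family p-values (q < 0.05 flagged *):\n")
  print(x$gene_table, row.names = FALSE)
  invisible(x)
}
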