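# Small configurable fixtures, all built in code at test time.

# synthetic manifest: named vector genes = c(geneA = n_snps, ...)
tiny_manifest <- function(genes = c(GA = 4L, GB = 3L), maf = 0.3) {
  rows <- lapply(seq_along(genes), function(i) {
    n <- genes[[i]]
    data.frame(snp = sprintf("%s_s%02d", names(genes)[i], seq_len(n)),
               gene = names(genes)[i], chrom = i,
               pos = 1000L * seq_len(n),
               maf = rep_len(maf, n),
               minor_allele = "A", major_allele = "G",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# nuclear-family-only study configuration with a single trait "y"
nuclear_cfg <- function(n_fam, n_off = 2L, manifest = tiny_manifest(),
                        adjacent_r = 0.6, beta = NULL, log_scale = TRUE,
                        family_effect_var = NULL, noise_var = NULL,
                        seed = 1L) {
  te <- matrix(0, nrow(manifest), 1L,
               dimnames = list(manifest$snp, "y"))
  if (!is.null(beta)) te[names(beta), "y"] <- beta
  sim_config(n_families = n_fam, target_n = NULL, units_per_family = 1L,
             offspring_range = c(n_off, n_off), manifest = manifest,
             adjacent_r = adjacent_r, trait_names = "y",
             trait_effects = te, log_scale = log_scale,
             family_effect_var = family_effect_var, noise_var = noise_var,
             n_missing_smoking = 0L, n_missing_covariate = 0L, seed = seed)
}

# one nuclear family as the objects the test statistic consumes
make_family <- function(gf, gm, xs, ts) {
  n <- length(xs)
  iids <- c("dad", "mom", sprintf("k%d", seq_len(n)))
  geno <- matrix(c(gf, gm, xs), ncol = 1,
                 dimnames = list(iids, "s1"))
  resid <- stats::setNames(c(0, 0, ts), iids)
  fam <- list(fid = "F1", father = "dad", mother = "mom",
              offspring = iids[-(1:2)])
  list(fam = fam, geno = geno, resid = resid)
}

# residuals of the single trait "y" adjusted for age and sex
resid_y <- function(study, covariates = c("age", "sex"), log_transform = TRUE) {
  adjust_covariates(study$pheno, "y", covariates, log_transform)
}
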