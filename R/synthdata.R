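#' Configuration for the synthetic family-study generator
#'
#' Bundles every knob of the simulator. The defaults emulate the design of a
#' multi-centre American Indian family study: 94 multiplex families totalling
#' 3,665 members, organised as three-generation chains of nuclear units
#' (about six offspring-bearing units per family), genotyped at 61 tagSNPs in
#' seven nicotinic-receptor genes with block linkage disequilibrium, and four
#' right-skewed, correlated obesity traits (BMI, waist circumference,
#' waist-to-hip ratio, percent body fat) with covariate effects and a shared
#' family random effect. A small number of members are given missing smoking
#' status (15) or a missing covariate (10) so the exclusion filter of the
#' analysis pipeline has work to do.
#'
#' @param n_families number of extended families.
#' @param target_n total number of individuals to generate; sibship sizes are
#'   nudged deterministically so the realised count is exact. `NULL` leaves
#'   the drawn sizes untouched.
#' @param units_per_family nuclear (offspring-bearing) units per extended
#'   family; one first-generation couple plus `units_per_family - 1` of their
#'   children who marry in a founder spouse.
#' @param offspring_range integer range (min, max) for third-generation
#'   sibship sizes.
#' @param manifest gene-to-SNP manifest (see [gene_manifest()]); rows are
#'   sorted by chromosome and position and define the SNP order everywhere.
#' @param snp_freqs minor-allele frequencies per SNP, in (0, 0.5]; defaults
#'   to the manifest `maf` column.
#' @param adjacent_r target founder-haplotype allelic correlation between
#'   adjacent SNPs within a gene block; a single number or a named vector
#'   (one entry per gene). Across blocks haplotypes are independent.
#' @param recomb_within recombination fraction between adjacent SNPs of the
#'   same gene; adjacent SNPs in different genes recombine freely (0.5).
#' @param recomb_fractions optional explicit vector of length `n_snps - 1`
#'   overriding the within/between default.
#' @param trait_names names of the simulated traits.
#' @param trait_mean trait scale: median trait value for a reference
#'   individual (kg/m^2, cm, ratio, percent).
#' @param trait_effects numeric matrix (`n_snps` x `n_traits`) of additive
#'   per-minor-allele effects on the log-trait scale. The default places a
#'   modest effect at three CHRNA5 SNPs on the two abdominal traits (`wc`,
#'   `whr`) and none elsewhere, so central obesity carries a joint signal
#'   while general obesity is null.
#' @param covariate_effects numeric matrix (covariate term x trait) of
#'   log-scale effects; see Details.
#' @param family_effect_var per-trait variance of the family random effect
#'   (log scale when `log_scale = TRUE`).
#' @param noise_var per-trait residual variance (same scale).
#' @param trait_cor correlation matrix of the residual noise across traits.
#' @param log_scale when `TRUE` (default) the linear predictor acts on the
#'   log scale and traits are exponentiated, giving right-skewed traits whose
#'   log transform restores linearity; when `FALSE` traits are generated
#'   additively on the raw scale.
#' @param geno_missing_rate per-genotype missingness rate (default 0:
#'   complete genotypes, matching the complete-parent design of the
#'   family-based test).
#' @param n_missing_smoking,n_missing_covariate members given a missing
#'   smoking status / a missing covariate (alcohol), to exercise the
#'   exclusion filter.
#' @param seed master integer seed; per-stage sub-seeds are derived from it
#'   with [derive_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @details The covariate design contains, per individual: centred age in
#'   decades, male indicator, study-centre indicators, ever-smoker indicator,
#'   current-alcohol indicator, centred log steps/day, centred log energy
#'   intake, centred 3-level socioeconomic score, and diabetes indicator.
#'   Covariates are generated independently of genotype, so genotype--trait
#'   association arises only through `trait_effects`.
#' @export
sim_config <- function(n_families = 94L,
                       target_n = 3665L,
                       units_per_family = 6L,
                       offspring_range = c(3L, 7L),
                       manifest = gene_manifest(),
                       snp_freqs = NULL,
                       adjacent_r = 0.6,
                       recomb_within = 0.01,
                       recomb_fractions = NULL,
                       trait_names = c("bmi", "wc", "whr", "pbf"),
                       trait_mean = c(bmi = 31.5, wc = 103, whr = 0.90,
                                      pbf = 36),
                       trait_effects = NULL,
                       covariate_effects = NULL,
                       family_effect_var = NULL,
                       noise_var = NULL,
                       trait_cor = NULL,
                       log_scale = TRUE,
                       geno_missing_rate = 0,
                       n_missing_smoking = 15L,
                       n_missing_covariate = 10L,
                       seed = 1L) {
  manifest <- manifest[order(manifest$chrom, manifest$pos), , drop = FALSE]
  L <- nrow(manifest)
  snp_freqs <- snp_freqs %||% manifest$maf
  if (is.null(snp_freqs))
    stop("snp_freqs not given and manifest has no 'maf' column")
  if (length(snp_freqs) != L)
    stop("snp_freqs must have one entry per manifest SNP")
  if (any(snp_freqs <= 0 | snp_freqs > 0.5))
    stop("minor-allele frequencies must lie in (0, 0.5]")

  genes <- unique(manifest$gene)
  if (length(adjacent_r) == 1L)
    adjacent_r <- stats::setNames(rep(adjacent_r, length(genes)), genes)
  if (!all(genes %in% names(adjacent_r)))
    stop("adjacent_r must cover every gene in the manifest")
  if (any(abs(adjacent_r) > 1)) stop("adjacent_r must lie in [-1, 1]")

  if (is.null(recomb_fractions)) {
    same_gene <- manifest$gene[-L] == manifest$gene[-1] &
      manifest$chrom[-L] == manifest$chrom[-1]
    recomb_fractions <- ifelse(same_gene, recomb_within, 0.5)
  }
  if (length(recomb_fractions) != L - 1L ||
      any(recomb_fractions < 0 | recomb_fractions > 0.5))
    stop("recomb_fractions must have length n_snps - 1 with values in [0, 0.5]")

  nt <- length(trait_names)
  tm <- trait_mean[trait_names]
  tm[is.na(tm)] <- if (isTRUE(log_scale)) 1 else 0
  trait_mean <- stats::setNames(as.numeric(tm), trait_names)
  if (is.null(trait_effects)) {
    trait_effects <- matrix(0, L, nt,
                            dimnames = list(manifest$snp, trait_names))
    causal <- intersect(c("rs16969968", "rs2036527", "rs8034191"),
                        manifest$snp)
    # log-scale per-allele effects calibrated per SNP (they differ in MAF
    # and LD context) so each causal SNP has roughly 30% power at
    # alpha = 0.05 under the default 94-family design; the WHR effects are
    # scaled by its smaller residual log-sd so both abdominal traits carry
    # the same standardised signal (see methods vignette)
    beta_wc <- c(rs16969968 = 0.0078, rs2036527 = 0.0057,
                 rs8034191 = 0.0108)[causal]
    if ("wc" %in% trait_names) trait_effects[causal, "wc"] <- beta_wc
    if ("whr" %in% trait_names) trait_effects[causal, "whr"] <- beta_wc / 2
  }
  trait_effects <- as.matrix(trait_effects)
  if (nrow(trait_effects) != L || ncol(trait_effects) != nt)
    stop("trait_effects must be a ", L, " x ", nt, " matrix")

  if (is.null(covariate_effects)) covariate_effects <- default_covariate_effects(trait_names)

  # total log-sd per trait split 30% family / 70% residual by default
  total_sd <- c(bmi = 0.24, wc = 0.17, whr = 0.085, pbf = 0.27)[trait_names]
  total_sd[is.na(total_sd)] <- 0.2
  family_effect_var <- family_effect_var %||% (0.3 * total_sd^2)
  noise_var <- noise_var %||% (0.7 * total_sd^2)
  family_effect_var <- rep_len(family_effect_var, nt)
  noise_var <- rep_len(noise_var, nt)
  if (any(family_effect_var < 0) || any(noise_var < 0))
    stop("variances must be non-negative")

  if (is.null(trait_cor)) trait_cor <- default_trait_cor(trait_names)
  trait_cor <- as.matrix(trait_cor)
  stopifnot(nrow(trait_cor) == nt, ncol(trait_cor) == nt)

  cfg <- list(n_families = as.integer(n_families),
              target_n = if (is.null(target_n)) NULL else as.integer(target_n),
              units_per_family = as.integer(units_per_family),
              offspring_range = as.integer(offspring_range),
              manifest = manifest,
              snp_freqs = as.numeric(snp_freqs),
              adjacent_r = adjacent_r,
              recomb_fractions = as.numeric(recomb_fractions),
              trait_names = trait_names,
              trait_mean = trait_mean,
              trait_effects = trait_effects,
              covariate_effects = covariate_effects,
              family_effect_var = stats::setNames(family_effect_var, trait_names),
              noise_var = stats::setNames(noise_var, trait_names),
              trait_cor = trait_cor,
              log_scale = isTRUE(log_scale),
              geno_missing_rate = geno_missing_rate,
              n_missing_smoking = as.integer(n_missing_smoking),
              n_missing_covariate = as.integer(n_missing_covariate),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

default_covariate_effects <- function(trait_names) {
  terms <- c("age10", "male", "centerOK", "centerDK", "smoker_ever",
             "alcohol_current", "log_steps_c", "log_energy_c", "ses_c",
             "diabetes")
  eff <- cbind(
    bmi = c(0.010, -0.02, 0.010, -0.010, -0.005, 0.000, -0.020, 0.020, -0.010, 0.040),
    wc  = c(0.030,  0.04, 0.010,  0.005,  0.010, 0.000, -0.020, 0.020, -0.010, 0.060),
    whr = c(0.015,  0.04, 0.005,  0.005,  0.010, 0.005, -0.010, 0.005, -0.005, 0.020),
    pbf = c(0.020, -0.25, 0.010, -0.005, -0.010, 0.000, -0.020, 0.010, -0.010, 0.030))
  rownames(eff) <- terms
  out <- matrix(0, length(terms), length(trait_names),
                dimnames = list(terms, trait_names))
  known <- intersect(trait_names, colnames(eff))
  out[, known] <- eff[, known]
  out
}

default_trait_cor <- function(trait_names) {
  base <- matrix(c(1.00, 0.85, 0.45, 0.80,
                   0.85, 1.00, 0.70, 0.70,
                   0.45, 0.70, 1.00, 0.35,
                   0.80, 0.70, 0.35, 1.00), 4, 4,
                 dimnames = list(c("bmi", "wc", "whr", "pbf"),
                                 c("bmi", "wc", "whr", "pbf")))
  nt <- length(trait_names)
  out <- diag(nt)
  dimnames(out) <- list(trait_names, trait_names)
  known <- intersect(trait_names, colnames(base))
  out[known, known] <- base[known, known]
  out
}

#' Map a latent Gaussian correlation to an allelic correlation
#'
#' Founder haplotypes are generated by thresholding a latent multivariate
#' normal vector: SNP `j` carries the minor allele when its latent coordinate
#' exceeds the upper-`f_j` quantile. `allelic_r_from_latent()` computes, by
#' numerical integration of the bivariate-normal orthant probability, the
#' correlation between the two resulting 0/1 alleles for a given latent
#' correlation; `latent_rho_for_target()` inverts the map. Because thresholded
#' binary variables cannot reach arbitrary correlations when frequencies
#' differ, an unattainable target raises an error naming the offending block.
#'
#' @param rho latent (tetrachoric-scale) correlation in (-1, 1).
#' @param f1,f2 minor-allele frequencies of the two SNPs.
#' @param r target allelic correlation.
#' @param block label used in error messages.
#' @return a correlation value.
#' @export
allelic_r_from_latent <- function(rho, f1, f2) {
  a1 <- stats::qnorm(1 - f1)
  a2 <- stats::qnorm(1 - f2)
  if (abs(rho) < 1e-12) {
    p11 <- f1 * f2
  } else if (rho >= 1 - 1e-12) {
    p11 <- min(f1, f2)
  } else if (rho <= -1 + 1e-12) {
    p11 <- max(0, f1 + f2 - 1)
  } else {
    p11 <- stats::integrate(function(x)
      stats::dnorm(x) * stats::pnorm((rho * x - a2) / sqrt(1 - rho^2)),
      lower = a1, upper = Inf, rel.tol = 1e-10)$value
  }
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

#' @rdname allelic_r_from_latent
#' @export
latent_rho_for_target <- function(r, f1, f2, block = "?") {
  if (abs(r) < 1e-12) return(0)
  lim <- 1 - 1e-9
  r_hi <- allelic_r_from_latent(lim, f1, f2)
  r_lo <- allelic_r_from_latent(-lim, f1, f2)
  if (r > r_hi + 1e-8 || r < r_lo - 1e-8)
    stop(sprintf(paste0("LD block '%s': target allelic correlation %.3f is ",
                        "not attainable for frequencies (%.3f, %.3f); ",
                        "attainable range is [%.3f, %.3f]"),
                 block, r, f1, f2, r_lo, r_hi), call. = FALSE)
  stats::uniroot(function(rho) allelic_r_from_latent(rho, f1, f2) - r,
                 interval = c(-lim, lim), tol = 1e-9)$root
}

#' Simulate founder haplotypes with block linkage disequilibrium
#'
#' Draws `n_haplotypes` binary haplotypes over the configured SNPs by
#' thresholding a latent multivariate-normal vector. Within a gene block the
#' latent correlation of adjacent SNPs is solved numerically so the allelic
#' correlation hits the configured target, and non-adjacent pairs follow the
#' implied first-order (path-product) structure; across blocks haplotypes are
#' independent.
#'
#' @param cfg a [sim_config()].
#' @param n_haplotypes number of haplotypes (rows) to draw; 0 gives an empty
#'   pool.
#' @return an object of class `haplotype_pool`: list with `haplotypes`
#'   (0/1 matrix, haplotype x SNP), `freq_target`, `freq_realized`,
#'   `adjacent_r_target`, `adjacent_r_realized`.
#' @export
simulate_founder_haplotypes <- function(cfg, n_haplotypes) {
  stopifnot(inherits(cfg, "sim_config"), n_haplotypes >= 0)
  man <- cfg$manifest
  L <- nrow(man)
  f <- cfg$snp_freqs

  # latent correlation: path products of the solved adjacent correlations
  # within each block; blocks are independent
  R <- diag(L)
  for (g in unique(man$gene)) {
    idx <- which(man$gene == g)
    if (length(idx) < 2L) next
    rho_adj <- vapply(seq_len(length(idx) - 1L), function(k)
      latent_rho_for_target(cfg$adjacent_r[[g]], f[idx[k]], f[idx[k + 1L]],
                            block = g), numeric(1))
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b) R[idx[a], idx[b]] <- R[idx[b], idx[a]] <- prod(rho_adj[a:(b - 1L)])
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("assembled latent correlation matrix is not positive semidefinite; ",
         "check block LD targets", call. = FALSE)

  thr <- stats::qnorm(1 - f)
  if (n_haplotypes == 0L) {
    H <- matrix(0L, 0L, L, dimnames = list(NULL, man$snp))
    realized <- rep(NA_real_, L)
    adj_real <- rep(NA_real_, L - 1L)
  } else {
    U <- chol(R + diag(1e-10, L))
    Z <- matrix(stats::rnorm(n_haplotypes * L), n_haplotypes, L) %*% U
    H <- (Z > matrix(thr, n_haplotypes, L, byrow = TRUE)) + 0L
    dimnames(H) <- list(NULL, man$snp)
    realized <- colMeans(H)
    adj_real <- if (n_haplotypes > 2L && L > 1L)
      vapply(seq_len(L - 1L), function(j)
        suppressWarnings(stats::cor(H[, j], H[, j + 1L])), numeric(1))
    else rep(NA_real_, max(0L, L - 1L))
  }
  structure(list(haplotypes = H,
                 freq_target = stats::setNames(f, man$snp),
                 freq_realized = stats::setNames(realized, man$snp),
                 adjacent_r_target = cfg$adjacent_r,
                 adjacent_r_realized = adj_real),
            class = "haplotype_pool")
}

resample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulate multiplex pedigrees as three-generation chains
#'
#' Each extended family consists of a first-generation founder couple, their
#' children (of whom `units_per_family - 1` marry in a founder spouse), and
#' the resulting grandchildren. When `target_n` is set, third-generation
#' sibship sizes are nudged deterministically so the total member count is
#' exact.
#'
#' @param cfg a [sim_config()].
#' @return a data.frame with columns `fid`, `iid`, `pat`, `mat` (`"0"` marks
#'   a founder), `sex` (1 = male, 2 = female) and `gen` (1--3).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nF <- cfg$n_families
  units <- cfg$units_per_family
  rng <- cfg$offspring_range
  n_marry <- max(0L, units - 1L)

  # draw sibship sizes first so they can be adjusted to target_n
  gen2_n <- pmax(n_marry + 1L,
                 vapply(seq_len(nF), function(i)
                   resample1(seq(rng[1], rng[2])), integer(1)))
  gen3_n <- if (n_marry > 0L)
    matrix(vapply(seq_len(nF * n_marry), function(i)
      resample1(seq(rng[1], rng[2])), integer(1)), nF, n_marry)
  else matrix(integer(0), nF, 0L)

  total <- sum(2L + gen2_n + n_marry + rowSums(gen3_n))
  if (!is.null(cfg$target_n) && n_marry > 0L) {
    delta <- cfg$target_n - total
    k <- length(gen3_n)
    i <- 0L
    while (delta != 0L) {
      i <- i %% k + 1L
      step <- sign(delta)
      newv <- gen3_n[i] + step
      if (newv >= 1L && newv <= rng[2] + 6L) {
        gen3_n[i] <- newv
        delta <- delta - step
      } else if (all(gen3_n <= 1L) && delta < 0L) {
        stop("target_n too small for the requested family structure")
      }
    }
  }

  rows <- vector("list", nF)
  for (fidx in seq_len(nF)) {
    fid <- sprintf("F%03d", fidx)
    c1 <- gen2_n[fidx]
    g3 <- if (n_marry > 0L) gen3_n[fidx, ] else integer(0)
    nmem <- 2L + c1 + n_marry + sum(g3)
    iid <- sprintf("%s_%03d", fid, seq_len(nmem))
    pat <- rep("0", nmem); mat <- rep("0", nmem)
    sex <- integer(nmem); gen <- integer(nmem)
    sex[1:2] <- c(1L, 2L); gen[1:2] <- 1L
    kid <- 2L + seq_len(c1)                      # gen-2 children
    pat[kid] <- iid[1L]; mat[kid] <- iid[2L]
    sex[kid] <- ifelse(stats::runif(c1) < 0.5, 1L, 2L); gen[kid] <- 2L
    sp <- 2L + c1 + seq_len(n_marry)             # married-in founder spouses
    sex[sp] <- ifelse(sex[kid[seq_len(n_marry)]] == 1L, 2L, 1L)
    gen[sp] <- 2L
    nxt <- 2L + c1 + n_marry
    for (u in seq_len(n_marry)) {
      k <- g3[u]
      idx <- nxt + seq_len(k); nxt <- nxt + k
      if (sex[kid[u]] == 1L) {
        pat[idx] <- iid[kid[u]]; mat[idx] <- iid[sp[u]]
      } else {
        pat[idx] <- iid[sp[u]]; mat[idx] <- iid[kid[u]]
      }
      sex[idx] <- ifelse(stats::runif(k) < 0.5, 1L, 2L); gen[idx] <- 3L
    }
    rows[[fidx]] <- list(fid = rep(fid, nmem), iid = iid, pat = pat,
                         mat = mat, sex = sex, gen = gen)
  }
  data.frame(fid = unlist(lapply(rows, `[[`, "fid")),
             iid = unlist(lapply(rows, `[[`, "iid")),
             pat = unlist(lapply(rows, `[[`, "pat")),
             mat = unlist(lapply(rows, `[[`, "mat")),
             sex = unlist(lapply(rows, `[[`, "sex")),
             gen = unlist(lapply(rows, `[[`, "gen")),
             stringsAsFactors = FALSE)
}

ped_depths <- function(ped) {
  depth <- ifelse(ped$pat == "0" & ped$mat == "0", 0L, NA_integer_)
  names(depth) <- ped$iid
  one_parent <- xor(ped$pat == "0", ped$mat == "0")
  if (any(one_parent))
    stop("individual(s) with exactly one known parent: ",
         paste(utils::head(ped$iid[one_parent], 5L), collapse = ", "),
         "; the simulator handles complete nuclear families only",
         call. = FALSE)
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    dp <- depth[ped$pat[todo]]
    dm <- depth[ped$mat[todo]]
    ready <- !is.na(dp) & !is.na(dm)
    if (!any(ready))
      stop("pedigree contains a cycle or a reference to a missing parent",
           call. = FALSE)
    depth[todo[ready]] <- pmax(dp[ready], dm[ready]) + 1L
  }
  depth
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders receive two haplotypes from the pool (assigned in order when the
#' pool holds exactly two per founder, otherwise resampled with replacement);
#' every meiosis transmits a recombinant of the parent's two haplotypes with
#' per-interval crossover probability equal to the configured recombination
#' fraction. Output is the additive minor-allele count (0/1/2).
#'
#' @param ped pedigree data.frame (`fid`, `iid`, `pat`, `mat`).
#' @param pool a `haplotype_pool` from [simulate_founder_haplotypes()].
#' @param cfg a [sim_config()] supplying `recomb_fractions` and
#'   `geno_missing_rate`.
#' @param keep_haplotypes when `TRUE` the two haplotype matrices are attached
#'   as attribute `"haplotypes"`.
#' @return integer genotype matrix (individual x SNP, rownames = `iid`).
#' @export
gene_drop <- function(ped, pool, cfg, keep_haplotypes = FALSE) {
  stopifnot(inherits(pool, "haplotype_pool"))
  HP <- pool$haplotypes
  L <- ncol(HP)
  n <- nrow(ped)
  theta <- cfg$recomb_fractions
  stopifnot(length(theta) == L - 1L)

  depth <- ped_depths(ped)
  founders <- which(depth[ped$iid] == 0L)
  if (length(founders) && nrow(HP) == 0L)
    stop("haplotype pool is empty but the pedigree has founders")

  H1 <- matrix(0L, n, L)
  H2 <- matrix(0L, n, L)
  rownames(H1) <- rownames(H2) <- ped$iid

  if (nrow(HP) == 2L * length(founders)) {
    idx <- matrix(seq_len(nrow(HP)), ncol = 2L, byrow = TRUE)
  } else {
    idx <- matrix(sample.int(nrow(HP), 2L * length(founders), replace = TRUE),
                  ncol = 2L)
  }
  H1[founders, ] <- HP[idx[, 1L], , drop = FALSE]
  H2[founders, ] <- HP[idx[, 2L], , drop = FALSE]

  meiose <- function(A1, A2) {
    m <- nrow(A1)
    c0 <- stats::rbinom(m, 1L, 0.5)
    if (L > 1L) {
      X <- (matrix(stats::runif(m * (L - 1L)), m, L - 1L) <
              matrix(theta, m, L - 1L, byrow = TRUE)) + 0
      phase <- (c0 + cbind(0, row_cumsum(X))) %% 2
    } else {
      phase <- matrix(c0, m, 1L)
    }
    A1 * (1 - phase) + A2 * phase
  }

  for (d in sort(unique(depth[depth > 0L]))) {
    kids <- which(depth[ped$iid] == d)
    fi <- match(ped$pat[kids], ped$iid)
    mi <- match(ped$mat[kids], ped$iid)
    H1[kids, ] <- meiose(H1[fi, , drop = FALSE], H2[fi, , drop = FALSE])
    H2[kids, ] <- meiose(H1[mi, , drop = FALSE], H2[mi, , drop = FALSE])
  }

  G <- H1 + H2
  storage.mode(G) <- "integer"
  dimnames(G) <- list(ped$iid, colnames(HP))
  if (cfg$geno_missing_rate > 0) {
    drop <- stats::runif(length(G)) < cfg$geno_missing_rate
    G[drop] <- NA_integer_
  }
  if (keep_haplotypes) attr(G, "haplotypes") <- list(H1 = H1, H2 = H2)
  G
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate covariates and quantitative traits on a genotyped pedigree
#'
#' Each trait is built as covariate term + additive genetic term + shared
#' family random effect + correlated residual noise; with `log_scale` the
#' linear predictor is exponentiated so the observed traits are right-skewed
#' and a log transform restores linearity. Covariates (age by generation,
#' sex, study centre, smoking, alcohol, activity, energy intake,
#' socioeconomic score, diabetes) are drawn independently of genotype.
#'
#' @param geno genotype matrix from [gene_drop()].
#' @param ped pedigree data.frame (needs the `gen` column produced by
#'   [simulate_pedigree()]; if absent, generation is inferred from depth).
#' @param cfg a [sim_config()].
#' @return a phenotype/covariate data.frame, one row per pedigree member.
#' @export
simulate_phenotypes <- function(geno, ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(ped$iid %in% rownames(geno)))
    stop("genotype matrix does not cover every pedigree member")
  if (nrow(cfg$trait_effects) != ncol(geno))
    stop("trait_effects has ", nrow(cfg$trait_effects),
         " rows but the genotype matrix has ", ncol(geno), " SNPs")
  n <- nrow(ped)
  nt <- length(cfg$trait_names)

  gen <- ped$gen %||% (ped_depths(ped)[ped$iid] + 1L)
  age_mean <- c(62, 40, 20)[pmin(gen, 3L)]
  age <- round(rtrunc_norm(n, age_mean, c(8, 8, 4)[pmin(gen, 3L)], 14, 93), 1)
  male <- as.integer(ped$sex == 1L)

  centers <- c("AZ", "OK", "DK")
  fidx <- as.integer(factor(ped$fid, levels = unique(ped$fid)))
  center <- centers[(fidx - 1L) %% 3L + 1L]

  smoking <- sample(c("current", "former", "never"), n, replace = TRUE,
                    prob = c(0.36, 0.22, 0.42))
  pack_years <- ifelse(smoking == "never", 0,
                       round(stats::rgamma(n, shape = 2, scale = 8), 1))
  alcohol <- sample(c("current", "former", "never"), n, replace = TRUE,
                    prob = c(0.50, 0.20, 0.30))
  steps_day <- round(exp(stats::rnorm(n, log(5200), 0.55)))
  energy_kcal <- round(exp(stats::rnorm(n, log(2000), 0.35)))
  ses <- sample(1:3, n, replace = TRUE, prob = c(0.30, 0.45, 0.25))
  diabetes <- stats::rbinom(n, 1L, 0.23)

  X <- cbind(age10 = (age - 40) / 10,
             male = male,
             centerOK = as.integer(center == "OK"),
             centerDK = as.integer(center == "DK"),
             smoker_ever = as.integer(smoking != "never"),
             alcohol_current = as.integer(alcohol == "current"),
             log_steps_c = log(steps_day) - log(5200),
             log_energy_c = log(energy_kcal) - log(2000),
             ses_c = ses - 2L,
             diabetes = diabetes)
  eff <- cfg$covariate_effects[colnames(X), , drop = FALSE]
  cov_term <- X %*% eff

  G <- geno[ped$iid, , drop = FALSE]
  G[is.na(G)] <- 0L
  gen_term <- G %*% cfg$trait_effects

  a <- stats::rnorm(max(fidx))
  fam_term <- outer(a[fidx], sqrt(cfg$family_effect_var))

  Z <- matrix(stats::rnorm(n * nt), n, nt) %*% chol(cfg$trait_cor + diag(1e-10, nt))
  noise <- sweep(Z, 2L, sqrt(cfg$noise_var), `*`)

  eta <- cov_term + gen_term + fam_term + noise
  traits <- if (cfg$log_scale) {
    sweep(exp(eta), 2L, cfg$trait_mean[cfg$trait_names], `*`)
  } else {
    sweep(eta, 2L, cfg$trait_mean[cfg$trait_names], `+`)
  }
  colnames(traits) <- cfg$trait_names

  pheno <- data.frame(fid = ped$fid, iid = ped$iid, sex = ped$sex, age = age,
                      center = center, smoking = smoking,
                      pack_years = pack_years, alcohol = alcohol,
                      steps_day = steps_day, energy_kcal = energy_kcal,
                      ses = ses, diabetes = diabetes,
                      stringsAsFactors = FALSE)

  # raw anthropometry consistent with the derived traits: BMI and WHR stay
  # recomputable from the stored fields
  if (all(c("bmi", "wc", "whr", "pbf") %in% cfg$trait_names)) {
    height_m <- round(stats::rnorm(n, 1.64 + 0.12 * male, 0.07), 3)
    weight_kg <- round(traits[, "bmi"] * height_m^2, 1)
    wc_cm <- round(traits[, "wc"], 1)
    hip_cm <- round(traits[, "wc"] / traits[, "whr"], 1)
    pheno$height_m <- height_m
    pheno$weight_kg <- weight_kg
    pheno$wc <- wc_cm
    pheno$hip_cm <- hip_cm
    pheno$bmi <- weight_kg / height_m^2
    pheno$whr <- wc_cm / hip_cm
    pheno$pbf <- round(traits[, "pbf"], 1)
  } else {
    for (tr in cfg$trait_names) pheno[[tr]] <- traits[, tr]
  }

  if (cfg$n_missing_smoking > 0L) {
    miss_s <- sample.int(n, min(cfg$n_missing_smoking, n))
    pheno$smoking[miss_s] <- NA_character_
    pheno$pack_years[miss_s] <- NA_real_
  } else miss_s <- integer(0)
  if (cfg$n_missing_covariate > 0L) {
    pool <- setdiff(seq_len(n), miss_s)
    miss_c <- sample(pool, min(cfg$n_missing_covariate, length(pool)))
    pheno$alcohol[miss_c] <- NA_character_
  }
  pheno
}

#' Simulate a complete synthetic family study
#'
#' Runs pedigree construction, founder-haplotype simulation, gene drop and
#' phenotype generation, each on its own deterministic sub-stream of the
#' master seed, and returns the pieces the analysis pipeline consumes.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `famtpm_study`: list with `ped`, `geno`,
#'   `pheno`, `manifest` and the generating `cfg`.
#' @examples
#' cfg <- sim_config(n_families = 4, target_n = NULL, units_per_family = 2,
#'                   seed = 7)
#' st <- simulate_study(cfg)
#' dim(st$geno)
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "pedigree"))
  ped <- simulate_pedigree(cfg)
  n_founders <- sum(ped$pat == "0" & ped$mat == "0")
  set.seed(derive_seed(cfg$seed, "haplotypes"))
  pool <- simulate_founder_haplotypes(cfg, 2L * n_founders)
  set.seed(derive_seed(cfg$seed, "genedrop"))
  geno <- gene_drop(ped, pool, cfg)
  set.seed(derive_seed(cfg$seed, "phenotypes"))
  pheno <- simulate_phenotypes(geno, ped, cfg)
  structure(list(ped = ped, geno = geno, pheno = pheno,
                 manifest = cfg$manifest, cfg = cfg),
            class = "famtpm_study")
}

#' Write a simulated study to PLINK-style text files
#'
#' @param study a `famtpm_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths (`ped`, `map`, `pheno`,
#'   `manifest`).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "famtpm_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ped = file.path(dir, "study.ped"),
                map = file.path(dir, "study.map"),
                pheno = file.path(dir, "phenotypes.tsv"),
                manifest = file.path(dir, "gene_manifest.tsv"))
  write_pedmap(study$ped, study$geno, study$manifest, paths$ped, paths$map)
  write_phenotypes(study$pheno, paths$pheno)
  utils::write.table(study$manifest, paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a simulator configuration from a YAML file
#'
#' Scalar fields of [sim_config()] can be set from a YAML key-value file;
#' `manifest` may be given as a path to a manifest TSV.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$manifest) && is.character(y$manifest))
    y$manifest <- read_gene_manifest(y$manifest)
  do.call(sim_config, y)
}
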