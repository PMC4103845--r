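#' Configuration for the p-value combination stage
#'
#' @param tau truncation threshold in (0, 1]: only p-values at or below
#'   `tau` enter the product. 0.05 is the canonical choice for the truncated
#'   product method.
#' @param weight_mode `"uniform"` (default) gives the unweighted truncated
#'   product, which is exactly calibrated against the Monte Carlo null.
#'   `"abs_effect"` weights each SNP by the absolute effect-size proxy
#'   `|b| = |U/V|` of the single-SNP test (normalised to mean 1 within the
#'   combining set, and frozen at the observed values when evaluating null
#'   draws). Because `|U/V|` is itself monotone in the evidence against the
#'   null, freezing data-estimated weights couples the observed statistic to
#'   the ensemble and inflates the type-I error noticeably (see the methods
#'   vignette); use it only for descriptive sensitivity analyses.
#' @param B Monte Carlo draws for the null ensemble (default 50,000).
#' @param seed integer seed for the ensemble.
#' @param null_mode `"ld_mvn"` draws null test statistics from a
#'   multivariate normal with the observed genotype-correlation (LD) matrix;
#'   `"independent"` uses the identity.
#' @return a list of class `combine_config`.
#' @export
combine_config <- function(tau = 0.05,
                           weight_mode = c("uniform", "abs_effect"),
                           B = 50000L, seed = 1L,
                           null_mode = c("ld_mvn", "independent")) {
  weight_mode <- match.arg(weight_mode)
  null_mode <- match.arg(null_mode)
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  if (B < 1) stop("B must be at least 1")
  structure(list(tau = tau, weight_mode = weight_mode, B = as.integer(B),
                 seed = as.integer(seed), null_mode = null_mode),
            class = "combine_config")
}

#' (Weighted) truncated product statistic
#'
#' `W = prod_i p_i ^ (w_i * I(p_i <= tau))`: the product of the p-values at
#' or below the truncation threshold, each raised to its weight. The empty
#' product is 1. Computation is in the log domain, so 61 p-values of 1e-300
#' pose no underflow problem when `log = TRUE` is used downstream.
#'
#' @param p p-values in (0, 1]; non-positive values are clamped to
#'   `p_floor` with a warning.
#' @param w non-negative weights, recycled; used as given (the gene-level
#'   tests normalise their weights to mean 1 before calling).
#' @param tau truncation threshold.
#' @param log return `log(W)` instead of `W`.
#' @param p_floor clamp value for non-positive p-values.
#' @return the statistic `W` (or its log).
#' @examples
#' tpm_statistic(c(0.0360, 0.2220, 0.0001, 0.4033, 0.3010, 0.0370, 0.0560))
#' @export
tpm_statistic <- function(p, w = NULL, tau = 0.05, log = FALSE,
                          p_floor = 1e-300) {
  if (any(p <= 0, na.rm = TRUE)) {
    warning("p-value(s) <= 0 clamped to ", format(p_floor), call. = FALSE)
    p[p <= 0] <- p_floor
  }
  assert_in_01(p, "p")
  w <- rep_len(w %||% 1, length(p))
  if (any(w < 0)) stop("weights must be non-negative")
  keep <- p <= tau
  lw <- sum(w[keep] * base::log(p[keep]))
  if (log) lw else exp(lw)
}

#' Closed-form null distribution of the unweighted truncated product
#'
#' Analytic tail probability `P(W_null <= W)` for the truncated product of
#' `L` independent uniform p-values (unit weights): the sum over `k`, the
#' number of p-values falling below `tau`, of the binomial weight times the
#' conditional tail of a product of `k` truncated uniforms. Evaluated in the
#' log domain. Serves as the independent oracle against which the Monte
#' Carlo null is verified.
#'
#' @param W observed statistic in (0, 1]; alternatively pass `log_w`.
#' @param L number of combined p-values.
#' @param tau truncation threshold.
#' @param log_w optional `log(W)` (takes precedence over `W`).
#' @return the combination p-value.
#' @export
tpm_pvalue_closedform <- function(W = NULL, L, tau = 0.05, log_w = NULL) {
  lw <- log_w %||% {
    if (is.null(W)) stop("give W or log_w")
    if (W <= 0 || W > 1) stop("W must lie in (0, 1]")
    base::log(W)
  }
  if (lw > 0) stop("W must lie in (0, 1]")
  if (lw == 0) return(1)   # the W = 1 atom (all p above tau) is included
  ltau <- base::log(tau)
  terms <- vapply(seq_len(L), function(k) {
    # (L - k) * log(1 - tau) with the 0 * -Inf case (tau = 1, k = L) fixed
    base <- lchoose(L, k) +
      if (k == L) 0 else (L - k) * log1p(-tau)
    if (lw <= k * ltau) {
      y <- k * ltau - lw            # >= 0
      s <- 0:(k - 1L)
      inner <- s * base::log(y) - lgamma(s + 1)
      inner[s == 0L] <- 0
      base + lw + logsumexp(inner)
    } else {
      base + k * ltau
    }
  }, numeric(1))
  min(1, exp(logsumexp(terms)))
}

#' Estimate the linkage-disequilibrium correlation matrix
#'
#' Pairwise correlation of additive genotype codes over founders
#' (pairwise-complete for missingness). Monomorphic SNPs get an identity
#' row/column with a warning. If the assembled matrix is not positive
#' semidefinite it is repaired by eigenvalue clipping (negative eigenvalues
#' set to zero, rescaled to unit diagonal) and flagged.
#'
#' @param geno genotype matrix restricted to founders (individual x SNP);
#'   at least 30 rows.
#' @param snps columns to use (default all).
#' @return correlation matrix of class `ld_matrix` with attribute
#'   `repaired` (logical).
#' @export
estimate_ld_correlation <- function(geno, snps = colnames(geno)) {
  G <- geno[, snps, drop = FALSE]
  if (nrow(G) < 30)
    stop("need at least 30 founders to estimate LD (got ", nrow(G), ")")
  R <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))
  mono <- which(colSums(is.na(R)) >= ncol(R) - 1L |
                  apply(G, 2L, function(x) stats::var(x, na.rm = TRUE) == 0 ||
                          all(is.na(x))))
  if (length(mono)) {
    warning("monomorphic SNP(s), correlation set to identity: ",
            paste(colnames(G)[mono], collapse = ", "), call. = FALSE)
    R[mono, ] <- 0; R[, mono] <- 0
  }
  R[is.na(R)] <- 0
  diag(R) <- 1
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    d <- pmax(ev$values, 0)
    R <- ev$vectors %*% (d * t(ev$vectors))
    R <- stats::cov2cor(R)
    repaired <- TRUE
  }
  dimnames(R) <- list(snps, snps)
  structure(R, class = c("ld_matrix", "matrix"), repaired = repaired)
}

#' Monte Carlo null ensemble of p-values
#'
#' Each of the `B` draws simulates a vector of null test statistics
#' `Z ~ MVN(0, R)` (identity under `null_mode = "independent"`) and converts
#' them to two-sided p-values `2 * (1 - Phi(|Z|))`. The same ensemble
#' calibrates both the gene-level and the gene-family stage, which keeps
#' between-gene LD intact without nested simulation.
#'
#' @param R correlation matrix ([estimate_ld_correlation()]); under the
#'   independent mode only its dimension and column names are used.
#' @param cfg a [combine_config()].
#' @return an object of class `null_ensemble`: list with `p` (`B` x `L`
#'   matrix of null p-values), `seed`, `null_mode`.
#' @export
mc_null_ensemble <- function(R, cfg) {
  stopifnot(inherits(cfg, "combine_config"))
  L <- ncol(R)
  snps <- colnames(R)
  set.seed(derive_seed(cfg$seed, "null-ensemble"))
  if (cfg$null_mode == "independent") {
    Z <- matrix(stats::rnorm(cfg$B * L), cfg$B, L)
  } else {
    # Cholesky when possible; eigen square root for exactly singular PSD
    # matrices (e.g. perfectly correlated SNPs)
    A <- tryCatch(chol(R), error = function(e) {
      ev <- eigen(R, symmetric = TRUE)
      if (min(ev$values) < -1e-8)
        stop("LD matrix is not positive semidefinite even after repair",
             call. = FALSE)
      t(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors)))
    })
    Z <- matrix(stats::rnorm(cfg$B * L), cfg$B, L) %*% A
  }
  P <- 2 * stats::pnorm(-abs(Z))
  P[P < 1e-300] <- 1e-300
  colnames(P) <- snps
  structure(list(p = P, seed = cfg$seed, null_mode = cfg$null_mode,
                 B = cfg$B),
            class = "null_ensemble")
}

# Shared internals of the gene-level stage: observed and null log-statistics
# for every gene with at least one usable SNP, weights frozen at observed
# values.
.gene_stage <- function(snp_results, manifest, ensemble, cfg) {
  usable <- snp_results[!is.na(snp_results$p), , drop = FALSE]
  man <- manifest[manifest$snp %in% usable$snp &
                    manifest$snp %in% colnames(ensemble$p), , drop = FALSE]
  genes <- unique(man$gene)
  if (!length(genes)) stop("no gene has a usable SNP in both the results ",
                           "table and the ensemble")
  p_obs <- stats::setNames(usable$p, usable$snp)[man$snp]
  if (any(p_obs <= 0)) {
    warning("observed p-value(s) <= 0 clamped to 1/(B+1)", call. = FALSE)
    p_obs[p_obs <= 0] <- 1 / (ensemble$B + 1)
  }
  raw_w <- if (cfg$weight_mode == "abs_effect") {
    b <- stats::setNames(usable$b, usable$snp)[man$snp]
    abs(b)
  } else rep(1, nrow(man))
  w <- numeric(nrow(man))
  for (g in genes) {
    i <- man$gene == g
    wg <- raw_w[i]
    if (!any(is.finite(wg)) || sum(wg, na.rm = TRUE) == 0) {
      warning("gene ", g, ": effect-size weights unavailable, ",
              "falling back to uniform", call. = FALSE)
      wg <- rep(1, sum(i))
    }
    wg[!is.finite(wg)] <- 0
    w[i] <- wg / mean(wg)            # mean-1 within the combining set
  }

  Pm <- ensemble$p[, man$snp, drop = FALSE]
  M <- base::log(Pm) * (Pm <= cfg$tau)
  Wt <- matrix(vapply(genes, function(g) w * (man$gene == g),
                      numeric(nrow(man))),
               nrow = nrow(man))     # L x G weight matrix, zero off-gene
  lw_null <- M %*% Wt                # B x G null log-statistics
  lw_obs <- vapply(genes, function(g) {
    i <- man$gene == g
    sum(w[i] * base::log(p_obs[i]) * (p_obs[i] <= cfg$tau))
  }, numeric(1))
  list(genes = genes, man = man, weights = stats::setNames(w, man$snp),
       lw_obs = lw_obs, lw_null = lw_null)
}

#' Gene-level and gene-family truncated-product tests
#'
#' `combine_genes()` runs the gene-level weighted truncated product test for
#' every gene in the manifest against the shared Monte Carlo null ensemble:
#' the observed statistic uses the observed p-values and (frozen) weights,
#' each null draw applies the same weights to its simulated p-values, and
#' the Monte Carlo p-value is the add-one estimator
#' `(1 + #\{W_b <= W_obs\}) / (B + 1)`, never exactly zero. The gene-family
#' stage then combines the gene-level p-values (uniform weights): each null
#' draw's gene statistics are converted to rank-based null gene p-values
#' within the same ensemble, so between-gene LD carries through without a
#' nested simulation.
#'
#' @param snp_results single-SNP results ([fbat_scan()]): columns `snp`,
#'   `p`, `b`. SNPs with missing p are left out.
#' @param manifest gene-to-SNP manifest.
#' @param ensemble null ensemble from [mc_null_ensemble()].
#' @param cfg a [combine_config()].
#' @param family also run the gene-family stage (needs >= 2 genes).
#' @return an object of class `gene_combine`: `genes` (data.frame with
#'   `gene`, `n_snps`, `W`, `log_w`, `p`), `family` (list with `W`, `p`,
#'   `n_genes`, or `NULL`), `weights`, `tau`, `B`, `ensemble_seed`,
#'   `ensemble_mode`.
#' @export
combine_genes <- function(snp_results, manifest, ensemble, cfg,
                          family = TRUE) {
  stopifnot(inherits(ensemble, "null_ensemble"),
            inherits(cfg, "combine_config"))
  st <- .gene_stage(snp_results, manifest, ensemble, cfg)
  B <- nrow(st$lw_null)
  cnt <- colSums(st$lw_null <= rep(st$lw_obs, each = B))
  p_gene <- (1 + cnt) / (B + 1)
  genes_df <- data.frame(gene = st$genes,
                         n_snps = as.integer(table(st$man$gene)[st$genes]),
                         W = exp(st$lw_obs), log_w = st$lw_obs,
                         p = p_gene, stringsAsFactors = FALSE)
  zero_w <- genes_df$log_w == 0
  genes_df$note <- ifelse(zero_w, "no SNP below tau", "")
  if (any(zero_w) && isTRUE(getOption("famtpm.verbose", FALSE)))
    message("gene(s) with no SNP below tau, W = 1: ",
            paste(genes_df$gene[zero_w], collapse = ", "))

  fam <- NULL
  if (family && length(st$genes) >= 2L) {
    fam <- .family_stage(st$lw_null, p_gene, cfg)
  }
  structure(list(genes = genes_df, family = fam,
                 weights = st$weights, tau = cfg$tau, B = B,
                 ensemble_seed = ensemble$seed,
                 ensemble_mode = ensemble$null_mode),
            class = "gene_combine")
}

.family_stage <- function(lw_null, p_gene_obs, cfg) {
  B <- nrow(lw_null)
  # rank-based null gene p-values within the single shared ensemble
  Pstar <- apply(lw_null, 2L, rank, ties.method = "max") / B
  S_null <- rowSums(base::log(Pstar) * (Pstar <= cfg$tau))
  S_obs <- sum(base::log(p_gene_obs) * (p_gene_obs <= cfg$tau))
  p_fam <- (1 + sum(S_null <= S_obs)) / (B + 1)
  list(W = exp(S_obs), log_w = S_obs, p = p_fam, n_genes = ncol(lw_null))
}

#' @rdname combine_genes
#' @param gene label of a single gene to test.
#' @return `gene_based_test()` returns the single gene's one-row data.frame
#'   with the weights used attached as attribute `"weights"`.
#' @export
gene_based_test <- function(snp_results, gene, manifest, ensemble, cfg) {
  man <- manifest[manifest$gene == gene, , drop = FALSE]
  if (!nrow(man)) stop("gene '", gene, "' not in manifest")
  gc <- combine_genes(snp_results, man, ensemble, cfg, family = FALSE)
  out <- gc$genes
  attr(out, "weights") <- gc$weights
  out
}

#' @rdname combine_genes
#' @param gene_results a `gene_combine` object (gene stage) whose ensemble
#'   must be the one passed here; a differing seed or null mode is an error.
#' @return `gene_family_test()` returns the family-stage list (`W`, `p`,
#'   `n_genes`).
#' @export
gene_family_test <- function(gene_results, ensemble, manifest, cfg) {
  stopifnot(inherits(gene_results, "gene_combine"),
            inherits(ensemble, "null_ensemble"))
  if (gene_results$ensemble_seed != ensemble$seed ||
      gene_results$ensemble_mode != ensemble$null_mode)
    stop("gene-level and gene-family stages must share one null ensemble ",
         "(seed/mode differ)")
  if (nrow(gene_results$genes) < 2L)
    stop("gene-family stage needs at least 2 genes")
  st <- .gene_stage_from_weights(gene_results, manifest, ensemble, cfg)
  .family_stage(st$lw_null, gene_results$genes$p, cfg)
}

# rebuild the null gene log-statistics from frozen weights
.gene_stage_from_weights <- function(gene_results, manifest, ensemble, cfg) {
  w <- gene_results$weights
  man <- manifest[manifest$snp %in% names(w), , drop = FALSE]
  genes <- gene_results$genes$gene
  Pm <- ensemble$p[, man$snp, drop = FALSE]
  M <- base::log(Pm) * (Pm <= cfg$tau)
  Wt <- matrix(vapply(genes, function(g) w[man$snp] * (man$gene == g),
                      numeric(nrow(man))),
               nrow = nrow(man))
  list(lw_null = M %*% Wt)
}

#' Sensitivity reanalysis with one SNP removed
#'
#' Recomputes the gene-level and gene-family results on the SNP set without
#' `snp_to_drop` (ensemble columns subset accordingly). A gene reduced to
#' zero SNPs is omitted with a warning.
#'
#' @inheritParams combine_genes
#' @param snp_to_drop SNP id to remove.
#' @return a `gene_combine` object on the reduced SNP set.
#' @export
leave_one_snp_out <- function(snp_results, manifest, ensemble, cfg,
                              snp_to_drop) {
  if (!snp_to_drop %in% manifest$snp)
    stop("SNP '", snp_to_drop, "' not in manifest")
  man2 <- manifest[manifest$snp != snp_to_drop, , drop = FALSE]
  gone <- setdiff(unique(manifest$gene), unique(man2$gene))
  if (length(gone))
    warning("gene(s) left with no SNP and omitted: ",
            paste(gone, collapse = ", "), call. = FALSE)
  combine_genes(snp_results, man2, ensemble, cfg)
}
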