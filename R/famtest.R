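#' Covariate-adjust and log-transform a quantitative trait
#'
#' Ordinary least-squares residuals of (optionally log-transformed) trait on
#' the covariate design, categoricals expanded to indicators. The residuals
#' are the trait scores fed to the family-based test; they are centred (the
#' fitted mean is the subtracted offset) and sum to zero over the regression
#' sample.
#'
#' @param pheno phenotype data.frame with an `iid` column.
#' @param trait name of the trait column; must be strictly positive when
#'   `log_transform` is set.
#' @param covariates character vector of covariate column names (possibly
#'   empty). Character/factor columns are expanded to indicator contrasts.
#' @param log_transform log-transform the trait first (default `TRUE`).
#' @return a named numeric vector of residuals (names = `iid`) of class
#'   `trait_residuals`, with attributes `trait`, `covariates`, `n` and
#'   `offset_mean`.
#' @export
adjust_covariates <- function(pheno, trait, covariates = character(0),
                              log_transform = TRUE) {
  stopifnot(trait %in% names(pheno))
  miss <- setdiff(covariates, names(pheno))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  y <- pheno[[trait]]
  keep <- !is.na(y)
  if (length(covariates))
    keep <- keep & stats::complete.cases(pheno[covariates])
  dat <- pheno[keep, , drop = FALSE]
  y <- dat[[trait]]
  if (log_transform) {
    if (any(y <= 0))
      stop("trait '", trait, "' must be strictly positive for log transform")
    y <- log(y)
  }
  if (length(covariates)) {
    for (cl in covariates)
      if (is.character(dat[[cl]])) dat[[cl]] <- factor(dat[[cl]])
    f <- stats::reformulate(covariates)
    mm <- stats::model.matrix(f, data = dat)
    fit <- stats::lm.fit(mm, y)
    if (any(is.na(fit$coefficients))) {
      bad <- names(fit$coefficients)[is.na(fit$coefficients)]
      stop("covariate design is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    res <- fit$residuals
  } else {
    res <- y - mean(y)
  }
  structure(stats::setNames(as.numeric(res), dat$iid),
            class = "trait_residuals",
            trait = trait, covariates = covariates,
            n = length(res), offset_mean = mean(y))
}

#' Mendelian offspring-genotype distribution given both parents
#'
#' Exact transmission probabilities for the additive minor-allele count of an
#' offspring, conditional on both parental genotypes. Each parent transmits
#' a minor allele with probability (own count)/2.
#'
#' @param father,mother parental genotypes in `{0, 1, 2}` (non-missing).
#' @return numeric vector of length 3: P(offspring = 0, 1, 2).
#' @examples
#' offspring_genotype_distribution(1, 1)  # 0.25 0.50 0.25
#' @export
offspring_genotype_distribution <- function(father, mother) {
  if (is.na(father) || is.na(mother))
    stop("parental genotypes must be non-missing")
  stopifnot(father %in% 0:2, mother %in% 0:2)
  pf <- father / 2
  pm <- mother / 2
  c(`0` = (1 - pf) * (1 - pm),
    `1` = pf * (1 - pm) + (1 - pf) * pm,
    `2` = pf * pm)
}

#' Score contribution of one nuclear family at one SNP
#'
#' The family-based score conditions on parental genotypes: each phenotyped,
#' genotyped offspring `j` contributes `T_j * (X_j - E[X_j | parents])` to
#' the score `U` and `T_j^2 * Var(X_j | parents)` to its variance `V`, with
#' transmissions to different offspring independent given the parents. A
#' family with a missing parental genotype is flagged non-computable and
#' skipped; a family whose parents cannot segregate (conditional variance 0)
#' is uninformative and contributes (0, 0).
#'
#' @param family a nuclear unit from [nuclear_families()].
#' @param geno genotype matrix (minor-allele counts).
#' @param resid trait residuals from [adjust_covariates()].
#' @param snp SNP id (column of `geno`).
#' @return a list: `U`, `V`, `n_offspring_used`, `informative`, `computable`.
#' @export
family_contribution <- function(family, geno, resid, snp) {
  gf <- geno[family$father, snp]
  gm <- geno[family$mother, snp]
  if (is.na(gf) || is.na(gm))
    return(list(U = 0, V = 0, n_offspring_used = 0L,
                informative = FALSE, computable = FALSE))
  off <- family$offspring
  off <- off[off %in% rownames(geno) & off %in% names(resid)]
  x <- geno[off, snp]
  t <- resid[off]
  use <- !is.na(x) & !is.na(t)
  x <- x[use]; t <- t[use]
  e <- (gf + gm) / 2
  v <- gf / 2 * (1 - gf / 2) + gm / 2 * (1 - gm / 2)
  U <- sum(t * (x - e))
  V <- sum(t^2 * v)
  list(U = U, V = V, n_offspring_used = length(x),
       informative = V > 0, computable = TRUE)
}

#' Family-based association test for one SNP
#'
#' Sums the family score contributions, forms `Z = U / sqrt(V)` and the
#' two-sided normal p-value. Families contributing no conditional variance
#' are not counted as informative; with fewer than `min_informative`
#' informative families (or `V = 0`) the p-value is reported missing with a
#' reason.
#'
#' @param families list of nuclear units ([nuclear_families()]).
#' @param geno genotype matrix.
#' @param resid trait residuals ([adjust_covariates()]).
#' @param snp SNP id.
#' @param min_informative minimum number of informative families (default
#'   10, the usual practice for this class of tests).
#' @return a one-row data.frame: `snp`, `U`, `V`, `Z`, `p`, `b` (= `U/V`,
#'   an effect-size proxy), `n_informative`, `status`.
#' @export
fbat_test <- function(families, geno, resid, snp, min_informative = 10L) {
  U <- V <- 0
  n_inf <- 0L
  for (fam in families) {
    fc <- family_contribution(fam, geno, resid, snp)
    U <- U + fc$U
    V <- V + fc$V
    if (fc$informative) n_inf <- n_inf + 1L
  }
  finish_snp_result(snp, U, V, n_inf, min_informative)
}

finish_snp_result <- function(snp, U, V, n_inf, min_informative) {
  if (V <= 0) {
    return(data.frame(snp = snp, U = U, V = V, Z = NA_real_, p = NA_real_,
                      b = NA_real_, n_informative = as.integer(n_inf),
                      status = "uninformative", stringsAsFactors = FALSE))
  }
  Z <- U / sqrt(V)
  p <- 2 * stats::pnorm(-abs(Z))
  status <- if (n_inf < min_informative) "too_few_informative" else "ok"
  data.frame(snp = snp, U = U, V = V, Z = Z,
             p = if (status == "ok") p else NA_real_,
             b = U / V, n_informative = as.integer(n_inf), status = status,
             stringsAsFactors = FALSE)
}

#' Family-based association scan over many SNPs
#'
#' Vectorised equivalent of calling [fbat_test()] per SNP: one pass over all
#' offspring with both parents genotyped builds the score, variance and
#' informative-family count for every SNP at once. Extended pedigrees are
#' decomposed into nuclear units treated as independent contributions.
#'
#' @param ped pedigree data.frame.
#' @param geno genotype matrix (minor-allele counts, rownames = iid).
#' @param resid trait residuals ([adjust_covariates()]).
#' @param snps SNP ids to test (default: all genotype columns).
#' @param min_informative minimum informative families per SNP.
#' @return a data.frame with one row per SNP (same columns as
#'   [fbat_test()]).
#' @export
fbat_scan <- function(ped, geno, resid, snps = colnames(geno),
                      min_informative = 10L) {
  kids <- which(ped$pat != "0" & ped$mat != "0")
  fi <- match(ped$pat[kids], rownames(geno))
  mi <- match(ped$mat[kids], rownames(geno))
  ki <- match(ped$iid[kids], rownames(geno))
  t_all <- resid[ped$iid[kids]]
  use <- !is.na(fi) & !is.na(mi) & !is.na(ki) & !is.na(t_all)
  kids <- kids[use]; fi <- fi[use]; mi <- mi[use]; ki <- ki[use]
  tvec <- as.numeric(t_all[use])

  G <- geno[, snps, drop = FALSE]
  if (length(kids) == 0L) {
    out <- do.call(rbind, lapply(snps, function(s)
      finish_snp_result(s, 0, 0, 0L, min_informative)))
    return(out)
  }
  Gf <- G[fi, , drop = FALSE]
  Gm <- G[mi, , drop = FALSE]
  Gk <- G[ki, , drop = FALSE]
  ok <- !(is.na(Gf) | is.na(Gm) | is.na(Gk))   # entry-wise complete trios
  Gf[!ok] <- 0L; Gm[!ok] <- 0L; Gk[!ok] <- 0L

  E <- (Gf + Gm) / 2
  Vx <- Gf / 2 * (1 - Gf / 2) + Gm / 2 * (1 - Gm / 2)
  Umat <- tvec * (Gk - E) * ok
  Vmat <- tvec^2 * Vx * ok

  famkey <- paste(ped$fid[kids], ped$pat[kids], ped$mat[kids], sep = "\r")
  Vfam <- rowsum(Vmat, famkey)
  n_inf <- colSums(Vfam > 0)

  U <- colSums(Umat)
  V <- colSums(Vmat)
  out <- do.call(rbind, lapply(seq_along(snps), function(j)
    finish_snp_result(snps[j], U[j], V[j], n_inf[j], min_informative)))
  rownames(out) <- NULL
  out
}
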