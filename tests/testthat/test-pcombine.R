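test_that("the truncated product statistic multiplies exactly the sub-tau p-values", {
  # the bundled gene-level example, waist-circumference column
  g <- example_gene_pvalues()
  p_wc <- g$wc[g$gene != "gene_family"]
  expect_equal(tpm_statistic(p_wc, tau = 0.05),
               0.0360 * 0.0001 * 0.0370, tolerance = 1e-12)

  expect_equal(tpm_statistic(c(0.2, 0.9, 0.06), tau = 0.05), 1)  # empty product
  expect_equal(tpm_statistic(c(0.01, 0.04), w = c(2, 1), tau = 0.05),
               0.01^2 * 0.04, tolerance = 1e-15)

  expect_warning(w0 <- tpm_statistic(c(0, 0.5), tau = 0.05, log = TRUE),
                 "clamped")
  expect_true(is.finite(w0))

  # log-domain: 61 p-values of 1e-300 do not underflow
  lw <- tpm_statistic(rep(1e-300, 61), tau = 0.05, log = TRUE)
  expect_equal(lw, 61 * log(1e-300), tolerance = 1e-9)
})

test_that("W is monotone in its inputs", {
  set.seed(50)
  for (i in 1:20) {
    p <- runif(8)
    w <- runif(8, 0.5, 2)
    W <- tpm_statistic(p, w, tau = 0.05)
    # decreasing a sub-tau p cannot increase W
    j <- which(p <= 0.05)
    if (length(j)) {
      p2 <- p; p2[j[1]] <- p2[j[1]] / 2
      expect_lte(tpm_statistic(p2, w, tau = 0.05), W)
    }
    # appending a p above tau leaves W unchanged
    expect_equal(tpm_statistic(c(p, 0.5), c(w, 3), tau = 0.05), W)
  }
})

test_that("the closed form matches its boundary cases and the MC oracle", {
  expect_equal(tpm_pvalue_closedform(0.37, L = 1, tau = 1), 0.37)
  expect_equal(tpm_pvalue_closedform(1, L = 7, tau = 0.05), 1)
  expect_error(tpm_pvalue_closedform(1.5, L = 3), "0, 1")

  set.seed(51)
  for (case in list(list(L = 3, lw = log(1e-3)),
                    list(L = 7, lw = log(1.332e-7)),
                    list(L = 10, lw = log(0.01)))) {
    pc <- tpm_pvalue_closedform(L = case$L, tau = 0.05, log_w = case$lw)
    pm <- oracle_mc_tpm_pvalue(case$lw, case$L, 0.05, B = 200000L)
    se <- sqrt(pc * (1 - pc) / 200000)
    expect_lt(abs(pc - pm), 3 * se + 1e-12)
  }
})

test_that("LD estimation flags monomorphic SNPs, repairs PSD, finds blocks", {
  set.seed(52)
  G <- matrix(rbinom(500 * 4, 2, 0.3), 500, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  G[, 4] <- G[, 3]                       # duplicated column
  R <- estimate_ld_correlation(G)
  expect_equal(R["s3", "s4"], 1)
  expect_lt(max(abs(R[1:2, 3:4])), 0.1)  # independent SNPs

  G2 <- G; G2[, 2] <- 1L                 # monomorphic
  expect_warning(R2 <- estimate_ld_correlation(G2), "monomorphic")
  expect_equal(unname(R2[2, -2]), rep(0, 3))
  expect_equal(R2[2, 2], 1)

  expect_error(estimate_ld_correlation(G[1:10, ]), "at least 30")

  # simulator round-trip: a strong block is recovered within 0.1
  cfg <- nuclear_cfg(300, manifest = tiny_manifest(c(GA = 3L), maf = 0.3),
                     adjacent_r = 0.8, seed = 53)
  st <- simulate_study(cfg)
  fnd <- st$ped$iid[st$ped$pat == "0"]
  R3 <- estimate_ld_correlation(st$geno[fnd, ])
  expect_equal(unname(R3[1, 2]), 0.8, tolerance = 0.1)

  # pairwise-complete estimates can need PSD repair; repair leaves unit diag
  set.seed(54)
  G4 <- matrix(rbinom(200 * 6, 2, 0.4), 200, 6,
               dimnames = list(NULL, paste0("t", 1:6)))
  G4[sample(length(G4), 600)] <- NA
  R4 <- estimate_ld_correlation(G4)
  expect_equal(unname(diag(R4)), rep(1, 6))
  expect_gte(min(eigen(unclass(R4), symmetric = TRUE)$values), -1e-8)
})

test_that("the Monte Carlo null ensemble is uniform, correlated and reproducible", {
  cfg <- combine_config(B = 50000, seed = 60, null_mode = "independent")
  R <- diag(3); dimnames(R) <- list(paste0("s", 1:3), paste0("s", 1:3))
  en <- mc_null_ensemble(R, cfg)
  for (j in 1:3)
    expect_gt(ks.test(en$p[, j], "punif")$p.value, 0.01)

  en2 <- mc_null_ensemble(R, cfg)
  expect_identical(en$p, en2$p)

  # perfectly correlated statistics give identical p-values within a draw
  cfg_ld <- combine_config(B = 100, seed = 61, null_mode = "ld_mvn")
  R1 <- matrix(1, 3, 3); dimnames(R1) <- dimnames(R)
  en3 <- mc_null_ensemble(R1, cfg_ld)
  expect_equal(en3$p[, 1], en3$p[, 2], tolerance = 1e-6)
  expect_equal(en3$p[, 1], en3$p[, 3], tolerance = 1e-6)
})

fake_snp_results <- function(p, b = NULL, snps = names(p)) {
  data.frame(snp = snps, p = as.numeric(p),
             b = b %||% rep(1, length(p)),
             stringsAsFactors = FALSE)
}

test_that("gene-based MC p-values agree with the closed form and its floor", {
  man <- data.frame(snp = paste0("s", 1:7), gene = "G1")
  R <- diag(7); dimnames(R) <- list(man$snp, man$snp)
  cfg <- combine_config(tau = 0.05, weight_mode = "uniform", B = 50000,
                        seed = 62, null_mode = "independent")
  en <- mc_null_ensemble(R, cfg)

  for (pset in list(c(0.036, 0.222, 1e-4, 0.4033, 0.301, 0.037, 0.056),
                    rep(0.5, 7),
                    c(0.04, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7))) {
    sr <- fake_snp_results(stats::setNames(pset, man$snp))
    g <- gene_based_test(sr, "G1", man, en, cfg)
    pc <- tpm_pvalue_closedform(L = 7, tau = 0.05,
                                log_w = tpm_statistic(pset, tau = 0.05,
                                                      log = TRUE))
    se <- sqrt(pc * (1 - pc) / cfg$B)
    expect_lt(abs(g$p - pc), 3 * se + 2 / cfg$B)
    expect_gte(g$p, 1 / (cfg$B + 1))
  }

  # an observed statistic below every null draw hits the add-one floor
  sr <- fake_snp_results(stats::setNames(rep(1e-12, 7), man$snp))
  g <- gene_based_test(sr, "G1", man, en, cfg)
  expect_equal(g$p, 1 / (cfg$B + 1))

  # a single-SNP gene with tau = 1 reduces to the SNP p-value
  man1 <- data.frame(snp = "s1", gene = "G1")
  cfg1 <- combine_config(tau = 1, weight_mode = "uniform", B = 50000,
                         seed = 63, null_mode = "independent")
  R1 <- matrix(1, 1, 1, dimnames = list("s1", "s1"))
  en1 <- mc_null_ensemble(R1, cfg1)
  g1 <- gene_based_test(fake_snp_results(c(s1 = 0.2)), "G1", man1, en1, cfg1)
  expect_lt(abs(g1$p - 0.2), 0.01)
})

test_that("the gene-family stage behaves at its boundaries and matches stage-2 oracle", {
  man <- data.frame(snp = paste0("s", 1:6),
                    gene = rep(c("G1", "G2", "G3"), each = 2))
  R <- diag(6); dimnames(R) <- list(man$snp, man$snp)
  cfg <- combine_config(tau = 0.05, weight_mode = "uniform", B = 20000,
                        seed = 64, null_mode = "independent")
  en <- mc_null_ensemble(R, cfg)

  # all observed p-values at 1: every stage returns 1
  sr <- fake_snp_results(stats::setNames(rep(1, 6), man$snp))
  gc <- combine_genes(sr, man, en, cfg)
  expect_true(all(gc$genes$p == 1))
  expect_equal(gc$family$p, 1)

  # one extreme gene drives the family result while the null genes are kept
  # out of the observed product by truncation; the family p follows the
  # closed form (which also prices in multi-gene null excursions)
  sr2 <- fake_snp_results(stats::setNames(c(1e-6, 1e-5, 0.9, 0.8, 0.7, 0.6),
                                          man$snp))
  gc2 <- combine_genes(sr2, man, en, cfg)
  expect_lt(gc2$family$p, 0.01)
  pc2 <- tpm_pvalue_closedform(L = 3, tau = 0.05, log_w = gc2$family$log_w)
  expect_lt(abs(gc2$family$p - pc2),
            3 * sqrt(pc2 * (1 - pc2) / cfg$B) + 3 / cfg$B)

  # stage-2 statistic of independent genes matches the closed form at a
  # moderate signal (away from the Monte Carlo resolution floor)
  sr3 <- fake_snp_results(stats::setNames(c(0.004, 0.3, 0.03, 0.6, 0.5, 0.9),
                                          man$snp))
  gc3 <- combine_genes(sr3, man, en, cfg)
  s_obs <- tpm_statistic(gc3$genes$p, tau = 0.05, log = TRUE)
  pc <- tpm_pvalue_closedform(L = 3, tau = 0.05, log_w = s_obs)
  se <- sqrt(pc * (1 - pc) / cfg$B)
  expect_lt(abs(gc3$family$p - pc), 3 * se + 2 / cfg$B)

  # mismatched ensembles between stages are refused
  cfg_other <- combine_config(tau = 0.05, B = 20000, seed = 65,
                              null_mode = "independent")
  en_other <- mc_null_ensemble(R, cfg_other)
  expect_error(gene_family_test(gc2, en_other, man, cfg), "share one")
})

test_that("effect-size weights are normalised, frozen, and fall back cleanly", {
  man <- data.frame(snp = paste0("s", 1:4), gene = "G1")
  R <- diag(4); dimnames(R) <- list(man$snp, man$snp)
  cfg <- combine_config(tau = 0.05, weight_mode = "abs_effect", B = 2000,
                        seed = 66, null_mode = "independent")
  en <- mc_null_ensemble(R, cfg)
  sr <- fake_snp_results(stats::setNames(c(0.01, 0.2, 0.03, 0.5), man$snp),
                         b = c(-2, 1, 0.5, 0.1))
  g <- gene_based_test(sr, "G1", man, en, cfg)
  w <- attr(g, "weights")
  expect_equal(mean(w), 1)                      # mean-1 normalisation
  expect_equal(unname(w / w[1]), abs(c(-2, 1, 0.5, 0.1)) / 2)

  sr0 <- fake_snp_results(stats::setNames(c(0.01, 0.2, 0.03, 0.5), man$snp),
                          b = rep(0, 4))
  expect_warning(g0 <- gene_based_test(sr0, "G1", man, en, cfg),
                 "falling back to uniform")
  expect_equal(unname(attr(g0, "weights")), rep(1, 4))
})

test_that("leave-one-SNP-out removes exactly the dropped SNP's influence", {
  man <- data.frame(snp = paste0("s", 1:5),
                    gene = c("G1", "G1", "G1", "G2", "G2"))
  R <- diag(5); dimnames(R) <- list(man$snp, man$snp)
  cfg <- combine_config(tau = 0.05, weight_mode = "uniform", B = 5000,
                        seed = 67, null_mode = "independent")
  en <- mc_null_ensemble(R, cfg)
  sr <- fake_snp_results(stats::setNames(c(0.01, 0.5, 0.6, 0.02, 0.7),
                                         man$snp))
  full <- combine_genes(sr, man, en, cfg)

  # dropping a SNP above tau leaves the gene statistic unchanged
  l1 <- leave_one_snp_out(sr, man, en, cfg, "s2")
  expect_equal(l1$genes$W[l1$genes$gene == "G1"],
               full$genes$W[full$genes$gene == "G1"])

  # dropping the only sub-tau SNP pushes the gene statistic to 1
  l2 <- leave_one_snp_out(sr, man, en, cfg, "s4")
  expect_equal(l2$genes$W[l2$genes$gene == "G2"], 1)

  # dropping a gene's only SNP omits the gene with a warning
  man1 <- data.frame(snp = paste0("s", 1:3),
                     gene = c("G1", "G1", "G2"))
  sr1 <- fake_snp_results(stats::setNames(c(0.01, 0.5, 0.3), man1$snp))
  expect_warning(l3 <- leave_one_snp_out(sr1, man1, en, cfg, "s3"),
                 "omitted")
  expect_identical(l3$genes$gene, "G1")

  expect_error(leave_one_snp_out(sr, man, en, cfg, "nope"), "not in manifest")
})
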