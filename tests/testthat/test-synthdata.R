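test_that("founder haplotype frequencies and block LD hit their targets", {
  man <- tiny_manifest(c(GA = 6L), maf = 0.3)
  cfg0 <- nuclear_cfg(10, manifest = man, adjacent_r = 0)
  set.seed(11)
  pool0 <- simulate_founder_haplotypes(cfg0, 20000L)
  expect_true(all(abs(pool0$freq_realized - 0.3) < 0.01))
  # independent blocks: adjacent correlation near 0
  expect_true(all(abs(pool0$adjacent_r_realized) < 0.03))

  cfg8 <- nuclear_cfg(10, manifest = man, adjacent_r = 0.8)
  set.seed(12)
  pool8 <- simulate_founder_haplotypes(cfg8, 20000L)
  expect_true(all(abs(pool8$adjacent_r_realized - 0.8) < 0.05))
})

test_that("empty pools work and infeasible LD targets fail naming the block", {
  cfg <- nuclear_cfg(5)
  pool <- simulate_founder_haplotypes(cfg, 0L)
  expect_equal(nrow(pool$haplotypes), 0L)

  man <- tiny_manifest(c(GBAD = 2L))
  man$maf <- c(0.08, 0.45)          # very unequal frequencies bound r
  expect_error(nuclear_cfg(5, manifest = man, adjacent_r = 0.9,
                           seed = 1) |> simulate_founder_haplotypes(100L),
               "GBAD")
})

test_that("the latent-threshold map matches realized allelic correlation", {
  # numerical-integration map rho -> r agrees with a large thresholded sample
  rho <- latent_rho_for_target(0.65, 0.2, 0.3)
  set.seed(5)
  z1 <- rnorm(200000)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(200000)
  a <- (z1 > qnorm(0.8)) + 0
  b <- (z2 > qnorm(0.7)) + 0
  expect_equal(cor(a, b), 0.65, tolerance = 0.02)
  expect_equal(allelic_r_from_latent(rho, 0.2, 0.3), 0.65, tolerance = 1e-6)
})

test_that("gene drop without recombination transmits whole parental haplotypes", {
  man <- tiny_manifest(c(GA = 5L), maf = 0.4)
  cfg <- sim_config(n_families = 30, target_n = NULL, units_per_family = 1,
                    offspring_range = c(2, 2), manifest = man,
                    adjacent_r = 0.5, recomb_fractions = rep(0, 4),
                    trait_names = "y",
                    trait_effects = matrix(0, 5, 1),
                    n_missing_smoking = 0, n_missing_covariate = 0, seed = 2)
  set.seed(21)
  ped <- simulate_pedigree(cfg)
  pool <- simulate_founder_haplotypes(cfg, 2L * sum(ped$pat == "0"))
  geno <- gene_drop(ped, pool, cfg, keep_haplotypes = TRUE)
  hap <- attr(geno, "haplotypes")
  kids <- which(ped$pat != "0")
  for (k in kids) {
    fi <- match(ped$pat[k], ped$iid)
    expect_true(identical(hap$H1[k, ], hap$H1[fi, ]) ||
                  identical(hap$H1[k, ], hap$H2[fi, ]))
  }
  # Mendelian containment at every SNP
  Gf <- geno[match(ped$pat[kids], ped$iid), ]
  Gm <- geno[match(ped$mat[kids], ped$iid), ]
  Gk <- geno[kids, ]
  expect_true(all(Gk >= (Gf == 2) + (Gm == 2)))
  expect_true(all(Gk <= (Gf >= 1) + (Gm >= 1)))
})

test_that("an individual with exactly one known parent is rejected", {
  ped <- data.frame(fid = "F1", iid = c("a", "b", "c"),
                    pat = c("0", "0", "a"), mat = c("0", "0", "0"),
                    sex = c(1L, 2L, 1L))
  cfg <- nuclear_cfg(1)
  pool <- simulate_founder_haplotypes(cfg, 4L)
  expect_error(gene_drop(ped, pool, cfg), "exactly one known parent")
})

test_that("free recombination makes transmitted alleles independent", {
  man <- tiny_manifest(c(GA = 2L), maf = 0.5)
  cfg <- sim_config(n_families = 1, target_n = NULL, units_per_family = 1,
                    offspring_range = c(2, 2), manifest = man,
                    adjacent_r = 0, recomb_fractions = 0.5,
                    trait_names = "y", trait_effects = matrix(0, 2, 1),
                    n_missing_smoking = 0, n_missing_covariate = 0, seed = 3)
  n_off <- 10000L
  ped <- data.frame(fid = "F1",
                    iid = c("dad", "mom", sprintf("k%05d", seq_len(n_off))),
                    pat = c("0", "0", rep("dad", n_off)),
                    mat = c("0", "0", rep("mom", n_off)),
                    sex = 1L)
  # both parents doubly heterozygous with known phase
  pool <- structure(list(haplotypes = matrix(c(1L, 0L,
                                               0L, 1L,
                                               1L, 0L,
                                               0L, 1L), 4, 2, byrow = TRUE,
                                             dimnames = list(NULL, man$snp))),
                    class = "haplotype_pool")
  set.seed(31)
  geno <- gene_drop(ped, pool, cfg)
  kids <- geno[-(1:2), ]
  expect_lt(abs(cor(kids[, 1], kids[, 2])), 3 / sqrt(n_off))
})

test_that("phenotype generation obeys its variance model", {
  man <- tiny_manifest(c(GA = 1L), maf = 0.3)

  # pure noise, additive scale: trait variance = noise_var
  cfg <- nuclear_cfg(500, n_off = 4, manifest = man, log_scale = FALSE,
                     family_effect_var = 0, noise_var = 1, seed = 4)
  st <- simulate_study(cfg)
  expect_gt(nrow(st$pheno), 2999)
  expect_equal(var(st$pheno$y), 1, tolerance = 0.05)

  # single causal SNP recovered by OLS on founders
  cfg2 <- nuclear_cfg(500, n_off = 2, manifest = man, log_scale = FALSE,
                      beta = c(GA_s01 = 0.5), family_effect_var = 0,
                      noise_var = 1, seed = 5)
  st2 <- simulate_study(cfg2)
  fnd <- st2$ped$iid[st2$ped$pat == "0"]
  fit <- summary(lm(st2$pheno$y[match(fnd, st2$pheno$iid)] ~
                      st2$geno[fnd, "GA_s01"]))
  expect_lt(abs(fit$coefficients[2, 1] - 0.5),
            3 * fit$coefficients[2, 2])

  # family effect: intraclass correlation among sibs ~ var_f/(var_f+var_e)
  cfg3 <- nuclear_cfg(800, n_off = 2, manifest = man, log_scale = FALSE,
                      family_effect_var = 1, noise_var = 1, seed = 6)
  st3 <- simulate_study(cfg3)
  kids <- st3$ped$iid[st3$ped$pat != "0"]
  ym <- matrix(st3$pheno$y[match(kids, st3$pheno$iid)], ncol = 2,
               byrow = TRUE)
  expect_equal(cor(ym[, 1], ym[, 2]), 0.5, tolerance = 0.08)
})

test_that("trait effect vector of the wrong length fails", {
  cfg <- nuclear_cfg(5, seed = 7)
  st <- simulate_study(cfg)
  cfg$trait_effects <- cfg$trait_effects[-1, , drop = FALSE]
  expect_error(simulate_phenotypes(st$geno, st$ped, cfg), "trait_effects")
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- nuclear_cfg(20, seed = 42)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$pheno, b$pheno)
  cfg2 <- nuclear_cfg(20, seed = 43)
  c <- simulate_study(cfg2)
  expect_false(identical(a$geno, c$geno))
})

test_that("the default design hits its member count after targeted nudging", {
  cfg <- sim_config(n_families = 10, target_n = 400, seed = 8)
  ped <- local({set.seed(1); simulate_pedigree(cfg)})
  expect_identical(nrow(ped), 400L)
  expect_setequal(unique(ped$gen), 1:3)
})

test_that("null single-SNP p-values are uniform across replicate studies", {
  man61 <- gene_manifest()
  te <- matrix(0, nrow(man61), 1, dimnames = list(man61$snp, "y"))
  ps <- unlist(lapply(1:20, function(r) {
    cfg <- sim_config(n_families = 120, target_n = NULL,
                      units_per_family = 1, offspring_range = c(2, 2),
                      manifest = man61, trait_names = "y",
                      trait_effects = te, n_missing_smoking = 0,
                      n_missing_covariate = 0, seed = 500 + r)
    st <- simulate_study(cfg)
    sr <- fbat_scan(st$ped, st$geno, resid_y(st), min_informative = 10)
    sr$p
  }))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 1100)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
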