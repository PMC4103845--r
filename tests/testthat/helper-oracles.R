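# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: transmission distributions come from
# enumerating parental allele pairs, truncated-product tail probabilities
# from brute-force uniform simulation, and BH adjustment from p.adjust().

# exact offspring genotype distribution by enumerating the 2 x 2 equally
# likely parental allele transmissions
oracle_offspring_dist <- function(gf, gm) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  af <- alleles(gf); am <- alleles(gm)
  d <- numeric(3)
  for (a in af) for (b in am) d[a + b + 1L] <- d[a + b + 1L] + 0.25
  d
}

# family score/variance by enumeration: E and Var of each offspring genotype
# from the exact distribution, then U = sum t (x - E), V = sum t^2 Var
oracle_family_contribution <- function(gf, gm, xs, ts) {
  d <- oracle_offspring_dist(gf, gm)
  ex <- sum((0:2) * d)
  vx <- sum(((0:2) - ex)^2 * d)
  list(U = sum(ts * (xs - ex)), V = sum(ts^2 * vx))
}

# expectation of U over every offspring genotype configuration of a family
# with k offspring (exhaustive, weighted by the exact Mendelian probability)
oracle_expected_U <- function(gf, gm, ts) {
  k <- length(ts)
  d <- oracle_offspring_dist(gf, gm)
  ex <- sum((0:2) * d)
  configs <- as.matrix(expand.grid(rep(list(0:2), k)))
  pr <- apply(configs, 1L, function(x) prod(d[x + 1L]))
  u <- apply(configs, 1L, function(x) sum(ts * (x - ex)))
  sum(pr * u)
}

# brute-force Monte Carlo tail probability of the unweighted truncated
# product of L independent uniforms
oracle_mc_tpm_pvalue <- function(log_w, L, tau, B = 200000L) {
  P <- matrix(stats::runif(B * L), B, L)
  S <- rowSums(log(P) * (P <= tau))
  mean(S <= log_w)
}

oracle_bh <- function(p) stats::p.adjust(p, method = "BH")
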