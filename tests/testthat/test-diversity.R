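test_that("pi matches brute-force mean pairwise differences", {
  ## 4 haplotypes over 100 sites -> 2 diploids; compare with O(n^2) count
  ## on allele copies at each variant site
  g <- random_geno(6, 30, miss = 0, seed = 2)
  brute <- 0
  for (s in seq_len(n_snps(g))) {
    copies <- unlist(lapply(g$geno[, s], function(x) {
      if (x == 0) c(0, 0) else if (x == 1) c(0, 1) else c(1, 1)
    }))
    n <- length(copies)
    diff_sum <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      diff_sum <- diff_sum + (copies[i] != copies[j])
    brute <- brute + diff_sum / choose(n, 2)
  }
  out <- nucleotide_diversity(g)
  expect_equal(out$pi, unname(brute) / total_sites(g), tolerance = 1e-12)
  ## monomorphic unit
  mono <- make_geno(matrix(0L, 5, 4))
  expect_equal(nucleotide_diversity(mono)$pi, 0)
})

test_that("Watterson's theta follows the closed form", {
  ## 5 segregating sites in 5 diploids (10 copies), 100 total sites
  codes <- matrix(0L, 5, 5)
  codes[1, ] <- 1L   # each SNP a singleton: S = 5
  g <- make_geno(codes, loci = paste0("L", 1:5), sites = 20)
  th <- wattersons_theta(g)
  a1 <- sum(1 / (1:9))
  expect_equal(th$theta_w, 5 / (a1 * 100), tolerance = 1e-12)
  expect_equal(th$S, 5L)
  ## no segregating sites
  expect_equal(wattersons_theta(make_geno(matrix(2L, 4, 3)))$theta_w, 0)
})

test_that("theta and pi are invariant to ordering and allele relabeling", {
  g <- random_geno(12, 60, miss = 0.1, seed = 13)
  perm <- sample(12)
  g_perm <- g; g_perm$geno <- g$geno[perm, , drop = FALSE]
  expect_equal(wattersons_theta(g)$theta_w, wattersons_theta(g_perm)$theta_w)
  expect_equal(nucleotide_diversity(g)$pi, nucleotide_diversity(g_perm)$pi)
  g_flip <- g; g_flip$geno <- 2L - g$geno  # swap ref/alt at every SNP
  expect_equal(wattersons_theta(g)$theta_w, wattersons_theta(g_flip)$theta_w)
  expect_equal(nucleotide_diversity(g)$pi, nucleotide_diversity(g_flip)$pi)
})

test_that("heterozygosity and F_IS match a brute-force per-site computation", {
  g <- random_geno(10, 50, miss = 0.15, seed = 5)
  out <- heterozygosity_fis(g)
  ## brute force
  ho <- he <- fis <- c()
  for (s in seq_len(50)) {
    v <- g$geno[, s]; v <- v[!is.na(v)]
    n <- 2 * length(v)
    if (n < 2) next
    p <- sum(v) / n
    if (p == 0 || p == 1) next
    h_obs <- mean(v == 1)
    h_exp <- 2 * p * (1 - p) * n / (n - 1)
    ho <- c(ho, h_obs); he <- c(he, h_exp)
    fis <- c(fis, 1 - h_obs / h_exp)
  }
  expect_equal(out$h_obs, mean(ho), tolerance = 1e-12)
  expect_equal(out$h_exp, mean(he), tolerance = 1e-12)
  expect_equal(out$f_is, mean(fis), tolerance = 1e-12)
  ## all heterozygotes at p = 0.5 show excess heterozygosity
  allhet <- make_geno(matrix(1L, 8, 10))
  expect_lt(heterozygosity_fis(allhet)$f_is, 0)
})

test_that("windowed Tajima's D matches an independent formula evaluation", {
  g <- random_geno(10, 80, miss = 0, seed = 17)
  ## put everything on one chromosome within one window
  g$snps$chrom <- "chr1"; g$snps$pos <- seq_len(80) * 10L
  win <- tajimas_d_windows(g, window_bp = 100000)
  expect_equal(nrow(win), 1L)
  ## independent: canonical constants at n = 20 copies
  n <- 20
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  alt <- colSums(g$geno)
  seg <- alt > 0 & alt < n
  S <- sum(seg)
  pi_sum <- sum(2 * alt[seg] * (n - alt[seg]) / (n * (n - 1)))
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(win$D, D, tolerance = 1e-10)
  ## windows with S < 2 are flagged
  g2 <- make_geno(matrix(c(1L, rep(0L, 5)), 6, 1))
  w2 <- tajimas_d_windows(g2)
  expect_false(w2$defined)
})

test_that("windows tile chromosomes from position 1, half-open", {
  codes <- matrix(sample(0:2, 8 * 4, TRUE), 8, 4)
  g <- make_geno(codes, loci = paste0("L", 1:4),
                 pos = c(50, 99999, 100000, 100001))
  w <- tajimas_d_windows(g, window_bp = 100000)
  expect_equal(w$start, c(1, 100001))
  expect_equal(w$end, c(100001, 200001))
  alt <- colSums(codes)
  seg <- alt > 0 & alt < 16
  ## position 100000 falls in [1, 100001), 100001 starts the next window
  expect_equal(w$S, c(sum(seg[1:3]), sum(seg[4])))
})

test_that("D t-tests behave at the identity and under a shift", {
  wa <- data.frame(D = rnorm(50), defined = TRUE)
  res <- d_tests(wa, wa)
  expect_equal(res$two_sample$t, 0)
  expect_equal(res$two_sample$p, 1)
  set.seed(30)
  wb <- data.frame(D = rnorm(200) - 0.5, defined = TRUE)
  wa2 <- data.frame(D = rnorm(200), defined = TRUE)
  res2 <- d_tests(wa2, wb)
  expect_lt(res2$two_sample$p, 0.001)
  expect_lt(res2$one_sample$p[2], 0.001)
})

test_that("one-sample D test p-values are uniform under the null", {
  set.seed(99)
  ps <- vapply(1:500, function(i) {
    w <- data.frame(D = rnorm(25), defined = TRUE)
    d_tests(w)$one_sample$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the urbanization model equals the normal-equations solution", {
  set.seed(12)
  dat <- data.frame(site_id = sprintf("s%02d", 1:40),
                    pi = runif(40, 0, 0.002),
                    dist_km = runif(40, 1, 60),
                    n_individuals = sample(2:5, 40, TRUE))
  fit <- eq1_model(dat, "pi", "dist_km")
  X <- cbind(1, dat$dist_km, dat$n_individuals)
  beta <- solve(t(X) %*% X, t(X) %*% dat$pi)
  expect_equal(unname(coef(fit$model)), drop(beta), tolerance = 1e-8)
  ## chi2 = squared t of the coefficient
  tv <- summary(fit$model)$coefficients["dist_km", "t value"]
  expect_equal(fit$anova$chisq[fit$anova$term == "dist_km"], tv^2,
               tolerance = 1e-10)
  ## single-individual sites are excluded
  dat2 <- rbind(dat, data.frame(site_id = "x1", pi = 1, dist_km = 5,
                                n_individuals = 1))
  expect_equal(eq1_model(dat2, "pi", "dist_km")$n_sites, 40L)
  expect_error(eq1_model(dat[1:2, ], "pi", "dist_km"), "fewer than 3")
})

test_that("null urbanization models give uniform p-values over seeds", {
  set.seed(71)
  ps <- vapply(1:300, function(i) {
    dat <- data.frame(pi = rnorm(30), dist_km = runif(30, 0, 60),
                      n_individuals = sample(2:5, 30, TRUE))
    eq1_model(dat, "pi", "dist_km")$anova$p[1]
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
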