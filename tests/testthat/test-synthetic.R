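test_that("identical seeds give byte-identical VCFs", {
  scn <- simulation_scenario("null_panmixia", n_individuals = 10,
                             n_loci = 100, mu = 1e-6,
                             epochs = data.frame(start_gen = 0, ne = 3000))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_coalescent(scn, seed = 42, out_dir = d1)
  simulate_coalescent(scn, seed = 42, out_dir = d2)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})

test_that("segregating sites match the Watterson expectation", {
  N <- 2000; mu <- 2e-6; L <- 74; n_loci <- 2000
  scn <- simulation_scenario("null_panmixia", n_individuals = 10,
                             n_loci = n_loci, mu = mu,
                             epochs = data.frame(start_gen = 0, ne = N))
  sim <- simulate_coalescent(scn, seed = 12)
  a1 <- sum(1 / (1:19))
  expected <- n_loci * 4 * N * mu * L * a1
  ## Poisson-ish spread over independent loci: 4 sigma band via observed SE
  expect_lt(abs(n_snps(sim$geno) - expected) / expected, 0.05)
})

test_that("pairwise coalescence time is 2Ne for a sample of two", {
  scn <- simulation_scenario("null_panmixia", n_individuals = 1,
                             n_loci = 4000, mu = 1e-9,
                             epochs = data.frame(start_gen = 0, ne = 5000))
  set.seed(9)
  sim <- gbspopgen:::sim_loci_cpp(4000, c(0L, 0L), 0,
                                  matrix(5000, 1, 1), 0, 1e-9, 74)
  se <- sd(sim$tmrca) / sqrt(4000)
  expect_lt(abs(mean(sim$tmrca) - 2 * 5000), 3.5 * se)
})

test_that("the island-model presets produce the expected F_ST ordering", {
  fst_of <- function(model, M, seed) {
    scn <- simulation_scenario(model, M = M, n_individuals = 20,
                               n_loci = 2500, mu = 5e-7,
                               epochs = data.frame(start_gen = 0, ne = 5000))
    sim <- simulate_two_habitat(scn, seed = seed)
    af <- allele_frequencies(sim$geno, sim$habitat)
    u <- af[af$group == "urban", ]; r <- af[af$group == "rural", ]
    hudson_fst_pair(u$freq_alt, u$n_copies, r$freq_alt, r$n_copies)$fst
  }
  f_frag <- fst_of("fragmentation", 1, 3)
  f_fac <- fst_of("facilitation", 24, 3)
  f_null <- fst_of("null_panmixia", 0, 3)
  expect_gt(f_frag, f_fac)
  expect_lt(abs(f_frag - 0.5), 0.05)
  expect_lt(abs(f_fac - 0.04), 0.025)
  expect_lt(abs(f_null), 0.02)
})

test_that("the landscape respects counts, radii and ramet spacing", {
  md <- simulate_landscape(n_urban_sites = 63, n_rural_sites = 61, seed = 2)
  site_hab <- tapply(md$habitat_by_distance, md$site_id, function(x) x[1])
  expect_equal(sum(site_hab == "urban"), 63)
  expect_equal(sum(site_hab == "rural"), 61)
  urb <- md[md$habitat_by_distance == "urban", ]
  expect_true(all(urb$dist_km <= 30))
  expect_true(all(tapply(md$sample_id, md$site_id, length) %in% 1:5))
  ## within-site spacing > 3 m
  for (s in unique(md$site_id)) {
    rows <- md[md$site_id == s, ]
    if (nrow(rows) > 1) {
      d <- as.matrix(geo_dist(rows$lat, rows$lon)) * 1000
      expect_gt(min(d[upper.tri(d)]), 3)
    }
  }
})

test_that("missingness masking hits its rate and the no-op is exact", {
  g <- random_geno(20, 300, miss = 0, seed = 8)
  out0 <- add_missingness_and_sibs(g, miss_rate = 0, n_sib_pairs = 0,
                                   seed = 1)
  expect_identical(out0$geno, g$geno)
  out <- add_missingness_and_sibs(g, miss_rate = 0.3, n_sib_pairs = 0,
                                  seed = 2)
  expect_equal(mean(is.na(out$geno)), 0.3, tolerance = 0.02)
})

test_that("planted sib pedigrees carry the top relatedness", {
  hits <- 0
  for (sd in 1:5) {
    scn <- simulation_scenario("null_panmixia", n_individuals = 20,
                               n_loci = 2000, mu = 2e-6,
                               epochs = data.frame(start_gen = 0, ne = 5000))
    sim <- simulate_coalescent(scn, seed = 500 + sd)
    out <- add_missingness_and_sibs(sim$geno, miss_rate = 0,
                                    n_sib_pairs = 1, seed = sd)
    rep <- attr(out, "sib_report")
    A <- relatedness_matrix(out)
    ped <- c(rep$sib1, rep$sib2, rep$parent1, rep$parent2)
    ## the sib pair is strongly related (sample-frequency GRMs shrink
    ## below the pedigree 0.5 at small n) ...
    expect_gt(A[rep$sib1, rep$sib2], 0.2)
    ## ... and the most related pair overall lies inside the pedigree
    ## (full sibs and parent-offspring both have expectation 0.5)
    top <- which(A == max(A, na.rm = TRUE), arr.ind = TRUE)[1, ]
    if (all(rownames(out$geno)[top] %in% ped)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("constant-Ne folded spectra pass a 1/i goodness-of-fit", {
  ok <- 0
  for (sd in 1:6) {
    ## keep the per-locus mutation rate low so most loci carry at most one
    ## SNP: the chi-square assumes independent sites
    scn <- simulation_scenario("null_panmixia", n_individuals = 10,
                               n_loci = 3000, mu = 1e-7,
                               epochs = data.frame(start_gen = 0, ne = 4000))
    sim <- simulate_coalescent(scn, seed = 600 + sd)
    sfs <- build_folded_sfs(sim$geno, n_chrom = 20)
    xi <- 1 / (1:19)
    pfold <- gbspopgen:::fold_spectrum(xi)
    pfold <- pfold / sum(pfold)
    ## chi-square GOF on expected proportions (loci are weakly dependent
    ## through shared genealogies; one SNP per genealogy on average here)
    stat <- sum((sfs$counts - sfs$S * pfold)^2 / (sfs$S * pfold))
    p <- pchisq(stat, df = length(pfold) - 1, lower.tail = FALSE)
    if (p > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("decline and constant scenarios differ in windowed Tajima's D", {
  scn_d <- simulation_scenario("decline", n_individuals = 15, n_loci = 1500,
                               mu = 1e-6)
  scn_c <- simulation_scenario("null_panmixia", n_individuals = 15,
                               n_loci = 1500, mu = 1e-6,
                               epochs = data.frame(start_gen = 0,
                                                   ne = 25000))
  d_d <- tajimas_d_windows(simulate_coalescent(scn_d, seed = 9)$geno)
  d_c <- tajimas_d_windows(simulate_coalescent(scn_c, seed = 9)$geno)
  tt <- t.test(d_d$D[d_d$defined], d_c$D[d_c$defined])
  expect_lt(tt$p.value, 0.01)
})
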