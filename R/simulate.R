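#' Simulation scenario
#'
#' Describes a coalescent simulation: a piecewise-constant effective
#' population size history (single population) or a symmetric two-deme
#' island model. The two-deme migration parameter `M` is scaled so the
#' equilibrium island-model expectation of Hudson's F_ST between the demes
#' is exactly `1/(1+M)` (per-lineage migration probability `M/(8N)` per
#' generation, from the pairwise-coalescence-time argument for two demes).
#'
#' Presets: `null_panmixia` (one constant-size population, arbitrary
#' urban/rural labels), `fragmentation` (two demes, low migration, M = 1),
#' `facilitation` (two demes, high migration, M = 24), `decline`
#' (single population, 100-fold drop from the ancestral size at 500
#' generations before sampling).
#'
#' @param model one of `"null_panmixia"`, `"fragmentation"`,
#'   `"facilitation"`, `"decline"`, or `"custom"`
#' @param epochs data.frame `start_gen` (ascending, first row 0) and `ne`
#'   (diploid size; most recent epoch first)
#' @param M scaled migration (two-deme models)
#' @param n_individuals diploid sample size (split evenly across demes when
#'   two demes are simulated)
#' @param n_loci,locus_len number and length (nt) of GBS loci
#' @param mu mutation rate per site per generation
#' @param loci_per_chrom loci laid out per pseudo-chromosome
#' @param locus_spacing_bp spacing of locus starts along a chromosome
#' @return list of class `"sim_scenario"`
#' @export
simulation_scenario <- function(model = c("null_panmixia", "fragmentation",
                                          "facilitation", "decline", "custom"),
                                epochs = NULL, M = NULL, n_individuals = 40,
                                n_loci = 2000, locus_len = 74, mu = 1.8e-8,
                                loci_per_chrom = 100, locus_spacing_bp = 5000) {
  model <- match.arg(model)
  if (is.null(epochs)) {
    epochs <- switch(model,
      decline = data.frame(start_gen = c(0, 500), ne = c(250, 25000)),
      data.frame(start_gen = 0, ne = 10000))
  }
  stopifnot(epochs$start_gen[1] == 0, !is.unsorted(epochs$start_gen),
            all(epochs$ne > 0), locus_len >= 1)
  if (is.null(M))
    M <- switch(model, fragmentation = 1, facilitation = 24, 0)
  stopifnot(M >= 0)
  n_demes <- if (model %in% c("fragmentation", "facilitation")) 2L else 1L
  structure(list(model = model, epochs = epochs, M = M,
                 n_demes = n_demes, n_individuals = n_individuals,
                 n_loci = n_loci, locus_len = locus_len, mu = mu,
                 loci_per_chrom = loci_per_chrom,
                 locus_spacing_bp = locus_spacing_bp),
            class = "sim_scenario")
}

## haplotype matrix -> diploid geno_matrix with locus/position annotation
haps_to_geno <- function(sim, scn, ind_ids) {
  n_ind <- length(ind_ids)
  S <- ncol(sim$hap)
  geno <- sim$hap[seq(1, 2 * n_ind, 2), , drop = FALSE] +
    sim$hap[seq(2, 2 * n_ind, 2), , drop = FALSE]
  rownames(geno) <- ind_ids
  loci_all <- paste0("L", formatC(seq_len(scn$n_loci), width = 6, flag = "0"))
  chrom_of <- paste0("chr", (seq_len(scn$n_loci) - 1) %/% scn$loci_per_chrom + 1)
  start_of <- ((seq_len(scn$n_loci) - 1) %% scn$loci_per_chrom) *
    scn$locus_spacing_bp + 1L
  li <- sim$locus
  snps <- data.frame(
    snp_id = if (S) paste0(loci_all[li], "_", sim$pos) else character(0),
    locus = loci_all[li], chrom = chrom_of[li],
    pos = start_of[li] + sim$pos - 1L,
    ref = rep("A", S), alt = rep("T", S), stringsAsFactors = FALSE)
  sites <- stats::setNames(rep(scn$locus_len, scn$n_loci), loci_all)
  genotype_matrix(geno, snps, sites)
}

#' Simulate a GBS genotype dataset under the coalescent
#'
#' One genealogy per locus under the scenario's piecewise-constant size
#' history (and two-deme structure for the fragmentation/facilitation
#' models); Poisson mutations with infinite-sites placement inside each
#' locus (finite-sites truncation when a locus saturates, counted in the
#' truth record). Haplotypes are paired into diploid individuals. Fully
#' reproducible from `seed`.
#'
#' @param scn a [simulation_scenario()]
#' @param seed integer seed
#' @param out_dir optional directory: writes `genotypes.vcf`,
#'   `metadata.tsv` and `truth.json`
#' @param deme_of_individuals optional 0/1 vector overriding the default
#'   half-and-half deme assignment (two-deme models); its length overrides
#'   `scn$n_individuals`
#' @return list: `geno` (a `geno_matrix`), `habitat` (per-individual label),
#'   `truth` (scenario parameters and genealogy summaries)
#' @export
simulate_coalescent <- function(scn, seed = 1, out_dir = NULL,
                                deme_of_individuals = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  set.seed(seed)
  if (!is.null(deme_of_individuals)) {
    deme_of_ind <- as.integer(deme_of_individuals)
    n_ind <- length(deme_of_ind)
    stopifnot(all(deme_of_ind %in% 0:1))
    if (scn$n_demes == 1L) deme_of_ind <- rep(0L, n_ind)
  } else {
    n_ind <- scn$n_individuals
    if (scn$n_demes == 2L) {
      n1 <- n_ind %/% 2L
      deme_of_ind <- rep(c(0L, 1L), c(n1, n_ind - n1))
    } else deme_of_ind <- rep(0L, n_ind)
  }
  deme_of_hap <- rep(deme_of_ind, each = 2L)
  ne_mat <- matrix(rep(scn$epochs$ne, scn$n_demes), ncol = scn$n_demes)
  mig <- if (scn$n_demes == 2L && scn$M > 0)
    scn$M / (8 * scn$epochs$ne[1]) else 0
  sim <- sim_loci_cpp(scn$n_loci, deme_of_hap, scn$epochs$start_gen,
                      ne_mat, mig, scn$mu, scn$locus_len)
  ind_ids <- sprintf("ind%04d", seq_len(n_ind))
  g <- haps_to_geno(sim, scn, ind_ids)
  habitat <- if (scn$n_demes == 2L) {
    ifelse(deme_of_ind == 0L, "urban", "rural")
  } else {
    ## panmictic: arbitrary half-and-half labels
    rep(c("urban", "rural"), c(ceiling(n_ind / 2), floor(n_ind / 2)))
  }
  habitat <- stats::setNames(habitat, ind_ids)
  truth <- list(model = scn$model, seed = seed,
                epochs = scn$epochs, M = scn$M,
                expected_fst = if (scn$n_demes == 2L) 1 / (1 + scn$M) else 0,
                n_individuals = n_ind, n_loci = scn$n_loci,
                locus_len = scn$locus_len, mu = scn$mu,
                S = n_snps(g), mean_tmrca = mean(sim$tmrca),
                mean_total_branch_length = mean(sim$tlen),
                n_mut_truncated = sim$n_mut_truncated)
  out <- list(geno = g, habitat = habitat, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(g, file.path(out_dir, "genotypes.vcf"))
    md <- data.frame(sample_id = ind_ids,
                     site_id = paste0("site_", ind_ids),
                     lat = NA_real_, lon = NA_real_, habitat = habitat)
    write_metadata(md, file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Simulate a labeled two-habitat dataset
#'
#' Thin preset wrapper around [simulate_coalescent()]: `fragmentation`
#' (M = 1) and `facilitation` (M = 24) run the two-deme island model with
#' the demes labeled urban/rural; `null_panmixia` runs one panmictic
#' population with arbitrary labels.
#'
#' @inheritParams simulate_coalescent
#' @export
simulate_two_habitat <- function(scn, seed = 1, out_dir = NULL) {
  stopifnot(scn$model %in% c("fragmentation", "facilitation", "null_panmixia"))
  simulate_coalescent(scn, seed = seed, out_dir = out_dir)
}

## km offsets (east, north) from the center -> lat/lon on the 6371.0088 sphere
offset_to_latlon <- function(dx_km, dy_km, center) {
  km_per_deg <- 6371.0088 * pi / 180
  lat <- center[1] + dy_km / km_per_deg
  lon <- center[2] + dx_km / (km_per_deg * cos(center[1] * pi / 180))
  cbind(lat = lat, lon = lon)
}

#' Simulate an urbanization-gradient sampling layout
#'
#' Urban sampling sites are drawn one per 2.5 km x 2.5 km grid cell within
#' 30 km of the city center, rural sites one per 10 km x 10 km cell beyond
#' it (out to 80 km); optional transect sites span the gradient. Each site
#' holds 1-5 individuals jittered at least 3 m apart (clonal ramets closer
#' than that could be the same genet).
#'
#' @param n_urban_sites,n_rural_sites site counts (defaults 63 / 61)
#' @param transect also place sites along a radial transect
#' @param n_transect number of transect sites when `transect = TRUE`
#' @param seed integer seed
#' @param center `c(lat, lon)` of the city center
#' @return metadata data.frame with `sample_id`, `site_id`, `lat`, `lon`
#'   plus the columns added by [classify_habitat()]
#' @export
simulate_landscape <- function(n_urban_sites = 63, n_rural_sites = 61,
                               transect = FALSE, n_transect = 10, seed = 1,
                               center = c(43.6563, -79.3809)) {
  stopifnot(n_urban_sites >= 1, n_rural_sites >= 1)
  set.seed(seed)
  draw_sites <- function(n, cell_km, r_min, r_max, prefix) {
    cc <- seq(-r_max, r_max, by = cell_km)
    grid <- expand.grid(dx = cc, dy = cc)
    r <- sqrt(grid$dx^2 + grid$dy^2)
    grid <- grid[r >= r_min & r <= r_max - cell_km, , drop = FALSE]
    if (nrow(grid) < n) stop("grid too small for requested site count")
    pick <- grid[sample(nrow(grid), n), ]
    out <- NULL
    for (i in seq_len(n)) {
      repeat {
        dx <- pick$dx[i] + stats::runif(1, -cell_km / 2, cell_km / 2)
        dy <- pick$dy[i] + stats::runif(1, -cell_km / 2, cell_km / 2)
        ll <- offset_to_latlon(dx, dy, center)
        d <- distance_to_center(ll[1], ll[2], center)
        inside <- if (r_min == 0) d <= r_max - 0.1 else
          d > r_min + 0.1 && d <= r_max
        if (inside) break
      }
      out <- rbind(out, data.frame(site_id = sprintf("%s%03d", prefix, i),
                                   lat = ll[1], lon = ll[2]))
    }
    out
  }
  sites <- rbind(
    draw_sites(n_urban_sites, 2.5, 0, 30, "U"),
    draw_sites(n_rural_sites, 10, 30, 80, "R"))
  if (transect) {
    ang <- stats::runif(1, 0, 2 * pi)
    rr <- seq(2, 78, length.out = n_transect)
    ll <- offset_to_latlon(rr * cos(ang), rr * sin(ang), center)
    sites <- rbind(sites, data.frame(
      site_id = sprintf("T%03d", seq_len(n_transect)),
      lat = ll[, 1], lon = ll[, 2]))
  }
  ## 1-5 individuals per site, >= 3 m apart within the site
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    k <- sample(1:5, 1)
    pts <- matrix(0, 0, 2)
    while (nrow(pts) < k) {
      cand <- c(stats::runif(1, -0.05, 0.05), stats::runif(1, -0.05, 0.05))
      if (nrow(pts) == 0 ||
          min(sqrt(colSums((t(pts) - cand)^2))) > 0.003)
        pts <- rbind(pts, cand)
    }
    ll <- offset_to_latlon(pts[, 1], pts[, 2],
                           c(sites$lat[i], sites$lon[i]))
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_s%02d", sites$site_id[i], seq_len(k)),
      site_id = sites$site_id[i], lat = ll[, 1], lon = ll[, 2],
      stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  classify_habitat(md, center = center)
}

#' Mask genotypes and plant full-sib pairs
#'
#' Masks each genotype call independently at `miss_rate`, then replaces
#' `2 * n_sib_pairs` randomly chosen individuals with full-sib pairs bred by
#' Mendelian sampling from random parent pairs drawn from the remaining
#' individuals. The planted pedigree is attached as `attr(, "sib_report")`.
#'
#' @param g a `geno_matrix`
#' @param miss_rate missingness probability in `[0, 1]`
#' @param n_sib_pairs number of full-sib pairs to plant
#' @param seed integer seed
#' @return modified `geno_matrix`
#' @export
add_missingness_and_sibs <- function(g, miss_rate = 0, n_sib_pairs = 0,
                                     seed = 1) {
  stopifnot(miss_rate >= 0, miss_rate <= 1)
  set.seed(seed)
  geno <- g$geno
  ids <- rownames(geno)
  sib_report <- NULL
  if (n_sib_pairs > 0) {
    stopifnot(nrow(geno) >= 4 * n_sib_pairs)
    shuffled <- sample(ids)
    parents <- matrix(shuffled[seq_len(2 * n_sib_pairs)], ncol = 2)
    targets <- matrix(shuffled[2 * n_sib_pairs + seq_len(2 * n_sib_pairs)],
                      ncol = 2)
    mendel <- function(gp1, gp2) {
      a1 <- ifelse(is.na(gp1), NA_integer_,
                   stats::rbinom(length(gp1), 1, gp1 / 2))
      a2 <- ifelse(is.na(gp2), NA_integer_,
                   stats::rbinom(length(gp2), 1, gp2 / 2))
      as.integer(a1 + a2)
    }
    for (k in seq_len(n_sib_pairs)) {
      gp1 <- geno[parents[k, 1], ]; gp2 <- geno[parents[k, 2], ]
      geno[targets[k, 1], ] <- mendel(gp1, gp2)
      geno[targets[k, 2], ] <- mendel(gp1, gp2)
    }
    sib_report <- data.frame(pair = seq_len(n_sib_pairs),
                             sib1 = targets[, 1], sib2 = targets[, 2],
                             parent1 = parents[, 1], parent2 = parents[, 2])
  }
  if (miss_rate > 0) {
    mask <- matrix(stats::runif(length(geno)) < miss_rate, nrow(geno))
    geno[mask] <- NA_integer_
  }
  out <- g
  out$geno <- geno
  attr(out, "sib_report") <- sib_report
  out
}
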