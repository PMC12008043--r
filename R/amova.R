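## sum of squared pairwise distances within an index set, divided by set size
ss_of <- function(D2, idx) {
  if (length(idx) < 2) return(0)
  sum(D2[idx, idx]) / (2 * length(idx))
}

## variance-component decomposition for a two-level (sites only) or
## three-level (groups/sites/individuals) hierarchy
amova_decompose <- function(D2, sites, groups = NULL) {
  N <- length(sites)
  ss_tot <- ss_of(D2, seq_len(N))
  site_idx <- split(seq_len(N), sites)
  S <- length(site_idx)
  ss_wp <- sum(vapply(site_idx, function(i) ss_of(D2, i), 0))
  n_s <- lengths(site_idx)
  if (is.null(groups)) {
    df_ap <- S - 1; df_wp <- N - S
    ss_ap <- ss_tot - ss_wp
    ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
    ms_wp <- if (df_wp > 0) ss_wp / df_wp else NA_real_
    n1 <- (N - sum(n_s^2) / N) / df_ap
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n1
    return(list(components = c(among_sites = sig_b, within_sites = sig_c),
                df = c(df_ap, df_wp), SS = c(ss_ap, ss_wp),
                phi = c(phi_st = sig_b / (sig_b + sig_c))))
  }
  grp_of_site <- tapply(as.character(groups), sites, function(x) x[1])
  group_idx <- split(seq_len(N), groups)
  G <- length(group_idx)
  ss_wg <- sum(vapply(group_idx, function(i) ss_of(D2, i), 0))
  ss_ag <- ss_tot - ss_wg
  ss_ap <- ss_wg - ss_wp
  df_ag <- G - 1; df_ap <- S - G; df_wp <- N - S
  ms_ag <- if (df_ag > 0) ss_ag / df_ag else NA_real_
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
  ms_wp <- if (df_wp > 0) ss_wp / df_wp else NA_real_
  N_g <- lengths(group_idx)
  sum_ns2_by_g <- tapply(n_s, grp_of_site[names(site_idx)], function(x) sum(x^2))
  ## align with group sizes
  sum_ns2_by_g <- sum_ns2_by_g[names(group_idx)]
  n1 <- (N - sum(sum_ns2_by_g / N_g)) / df_ap
  n2 <- (sum(sum_ns2_by_g / N_g) - sum(n_s^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sig_c <- ms_wp
  sig_b <- (ms_ap - sig_c) / n1
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(components = c(among_groups = sig_a, among_sites_within_groups = sig_b,
                      within_sites = sig_c),
       df = c(df_ag, df_ap, df_wp), SS = c(ss_ag, ss_ap, ss_wp),
       phi = c(phi_ct = sig_a / tot,
               phi_sc = sig_b / (sig_b + sig_c),
               phi_st = (sig_a + sig_b) / tot))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions the variance of squared Euclidean distances between individual
#' allele-count vectors (missing genotypes mean-imputed per SNP) across a
#' group/site/individual hierarchy, with permutation tests per component:
#' whole sites are permuted among groups for the among-group component,
#' individuals among sites within groups for the among-site component, and
#' individuals among all sites for the Phi_ST (within-site) test. P-values
#' use the add-one rule \eqn{(1 + \#\{perm \ge obs\})/(1 + n_{perm})}.
#'
#' @param g a `geno_matrix` (or a precomputed `dist` via `dist_obj`)
#' @param sites per-individual sampling-site assignment
#' @param groups optional per-individual group (habitat) assignment; must be
#'   constant within sites. `NULL` fits the one-level sites/individuals
#'   decomposition.
#' @param n_perm permutations per component
#' @param seed RNG seed for reproducible permutations
#' @param dist_obj optional `dist` to use instead of `geno_dist(g)`
#' @return object of class `"amova_result"` with a `table` data.frame
#'   (component, df, SS, sigma2, percent, phi, p)
#' @export
amova <- function(g, sites, groups = NULL, n_perm = 999, seed = NULL,
                  dist_obj = NULL) {
  sites <- as.character(sites)
  if (!is.null(groups)) {
    groups <- as.character(groups)
    chk <- tapply(groups, sites, function(x) length(unique(x)))
    if (any(chk > 1)) stop("groups must be constant within sites")
    if (length(unique(groups)) < 2) {
      warning("single group: among-group component undefined; ",
              "fitting one-level AMOVA")
      groups <- NULL
    } else {
      gs <- tapply(sites, groups, function(x) length(unique(x)))
      if (any(gs < 2))
        warning("group(s) with a single site: among-site component weakly defined")
    }
  }
  D <- if (is.null(dist_obj)) geno_dist(g) else dist_obj
  D2 <- as.matrix(D)^2
  obs <- amova_decompose(D2, sites, groups)
  if (!is.null(seed)) set.seed(seed)
  N <- length(sites)
  k <- length(obs$components)
  p <- rep(NA_real_, k)
  tot <- sum(obs$components)
  degenerate <- !is.finite(tot) || tot <= 0
  if (!degenerate && n_perm > 0) {
    if (is.null(groups)) {
      hits <- 0
      for (b in seq_len(n_perm)) {
        perm <- amova_decompose(D2, sample(sites), NULL)
        hits <- hits + (perm$phi["phi_st"] >= obs$phi["phi_st"])
      }
      p <- c((1 + hits) / (1 + n_perm), NA_real_)
    } else {
      site_names <- unique(sites)
      grp_of_site <- tapply(groups, sites, function(x) x[1])[site_names]
      hits <- c(0, 0, 0)
      for (b in seq_len(n_perm)) {
        ## (a) whole sites among groups
        g_perm <- stats::setNames(sample(grp_of_site), site_names)
        pa <- amova_decompose(D2, sites, unname(g_perm[sites]))
        hits[1] <- hits[1] + (pa$phi["phi_ct"] >= obs$phi["phi_ct"])
        ## (b) individuals among sites within groups
        s_perm <- sites
        for (gr in unique(groups)) {
          idx <- which(groups == gr)
          s_perm[idx] <- sites[sample(idx)]
        }
        pb <- amova_decompose(D2, s_perm, groups)
        hits[2] <- hits[2] + (pb$phi["phi_sc"] >= obs$phi["phi_sc"])
        ## (c) individuals among all sites (Phi_ST)
        ord <- sample(N)
        pc <- amova_decompose(D2, sites[ord] , groups[ord])
        hits[3] <- hits[3] + (pc$phi["phi_st"] >= obs$phi["phi_st"])
      }
      p <- (1 + hits) / (1 + n_perm)
    }
  }
  tab <- data.frame(
    component = names(obs$components),
    df = obs$df, SS = obs$SS, sigma2 = unname(obs$components),
    percent = if (degenerate) rep(NA_real_, k) else
      100 * unname(obs$components) / tot,
    phi = c(unname(obs$phi), rep(NA_real_, k - length(obs$phi)))[seq_len(k)],
    p = p[seq_len(k)], stringsAsFactors = FALSE)
  structure(list(table = tab, degenerate = degenerate, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (Euclidean distances of allele counts)\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$sigma2 <- signif(tab$sigma2, 4)
  tab$percent <- round(tab$percent, 2); tab$phi <- round(tab$phi, 4)
  print(tab, row.names = FALSE)
  if (x$degenerate) cat("  (zero total variance: percentages undefined)\n")
  invisible(x)
}
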