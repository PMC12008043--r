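#' Hudson's F_ST for one pair of populations
#'
#' Ratio-of-averages estimator: per SNP the numerator is
#' \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and the
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}; the estimate is the sum of
#' numerators over the sum of denominators across SNPs. `n` is the number of
#' sampled allele copies by default; `convention = "individuals"` uses the
#' individual count instead (the convention under which single-individual
#' sites force division by zero and must be excluded).
#'
#' @param p1,p2 alternate-allele frequencies per SNP
#' @param n1,n2 allele-copy counts per SNP (or individual counts under the
#'   `"individuals"` convention)
#' @param convention `"copies"` or `"individuals"`
#' @return list: `fst`, `n_snps` used, `num`, `den`
#' @export
hudson_fst_pair <- function(p1, n1, p2, n2,
                            convention = c("copies", "individuals")) {
  convention <- match.arg(convention)
  if (convention == "individuals") { n1 <- n1 / 2; n2 <- n2 / 2 }
  ok <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sn <- sum(num[ok]); sd <- sum(den[ok])
  list(fst = if (sd > 0) sn / sd else NA_real_,
       n_snps = sum(ok), num = sn, den = sd)
}

#' Pairwise Hudson F_ST between sampling sites
#'
#' Computes the site-by-site matrix of Hudson/ratio-of-averages F_ST.
#' Sites with fewer than `min_individuals` genotyped individuals are
#' excluded (mirroring the exclusion of single-individual sites, for which
#' the individual-count convention is undefined).
#'
#' @param g a `geno_matrix`
#' @param sites per-individual sampling-site assignment
#' @param min_individuals minimum genotyped individuals per site (default 2)
#' @param convention see [hudson_fst_pair()]
#' @return object of class `"fst_matrix"`: list with `fst` (symmetric
#'   matrix, diagonal `NA`), `n_snps` (pairwise SNP counts), `sites`
#' @export
hudson_fst_matrix <- function(g, sites, min_individuals = 2,
                              convention = c("copies", "individuals")) {
  convention <- match.arg(convention)
  sites <- as.character(sites)
  stopifnot(length(sites) == n_individuals(g))
  tab <- table(sites)
  keep_sites <- names(tab)[tab >= min_individuals]
  k <- length(keep_sites)
  if (k < 2) stop("fewer than 2 sites with >= ", min_individuals,
                  " individuals")
  counts <- lapply(keep_sites, function(s) alt_counts(g, which(sites == s)))
  P <- vapply(counts, function(x) ifelse(x$n > 0, x$alt / x$n, NA_real_),
              numeric(n_snps(g)))
  N <- vapply(counts, function(x) x$n, numeric(n_snps(g)))
  fst <- matrix(NA_real_, k, k, dimnames = list(keep_sites, keep_sites))
  nsnp <- fst
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    h <- hudson_fst_pair(P[, i], N[, i], P[, j], N[, j],
                         convention = convention)
    fst[i, j] <- fst[j, i] <- h$fst
    nsnp[i, j] <- nsnp[j, i] <- h$n_snps
  }
  structure(list(fst = fst, n_snps = nsnp, sites = keep_sites),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  v <- x$fst[upper.tri(x$fst)]
  cat(sprintf("fst_matrix: %d sites, %d pairs; mean F_ST = %.4f (range %.4f..%.4f)\n",
              length(x$sites), sum(!is.na(v)), mean(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Mean pairwise F_ST within and between habitat groups
#'
#' @param fm an `fst_matrix`
#' @param site_habitat named character vector mapping site id to habitat
#'   label (e.g. urban/rural)
#' @return data.frame `pair_type`, `mean_fst`, `n_pairs`
#' @export
fst_group_means <- function(fm, site_habitat) {
  hab <- site_habitat[fm$sites]
  if (anyNA(hab)) stop("habitat label missing for some sites")
  k <- length(fm$sites)
  rows <- list()
  pt <- outer(hab, hab, function(a, b)
    ifelse(a == b, paste0(a, "-", a),
           paste(pmin(a, b), pmax(a, b), sep = "-")))
  ut <- upper.tri(fm$fst)
  for (tp in sort(unique(pt[ut]))) {
    sel <- ut & pt == tp & !is.na(fm$fst)
    rows[[tp]] <- data.frame(pair_type = tp,
                             mean_fst = mean(fm$fst[sel]),
                             n_pairs = sum(sel))
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
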