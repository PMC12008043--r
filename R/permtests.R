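#' PERMANOVA on a genetic distance matrix
#'
#' Tests whether mean pairwise distances differ between groups, via the
#' pseudo-F of the Gower-centered distance partition with a permutation
#' p-value \eqn{(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})}
#' (vegan's `adonis2` engine).
#'
#' @param dist_obj a `dist` of individuals (e.g. [geno_dist()])
#' @param labels group label per individual (>= 2 groups required)
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return data.frame: `pseudo_F`, `df`, `df_resid`, `R2`, `p`
#' @export
permanova <- function(dist_obj, labels, n_perm = 999, seed = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("permanova needs at least 2 groups")
  stopifnot(length(labels) == attr(dist_obj, "Size"))
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(label = labels)
  fit <- vegan::adonis2(dist_obj ~ label, data = df, permutations = n_perm)
  data.frame(pseudo_F = fit$F[1], df = fit$Df[1], df_resid = fit$Df[2],
             R2 = fit$R2[1], p = fit$`Pr(>F)`[1])
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates, measures each
#' individual's distance to its own group's spatial median, and tests the
#' group effect on those distances by a permutation F-test (vegan's
#' `betadisper` + `permutest`). A warning is emitted when the negative
#' eigenvalue mass exceeds 10% of the total (non-Euclidean distances).
#'
#' @inheritParams permanova
#' @param center `"median"` (spatial median, default) or `"centroid"`
#' @return data.frame: `F`, `df`, `df_resid`, `p`
#' @export
permdisp <- function(dist_obj, labels, n_perm = 999, seed = NULL,
                     center = c("median", "centroid")) {
  center <- match.arg(center)
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stop("permdisp needs >= 2 individuals per group")
  if (!is.null(seed)) set.seed(seed)
  bd <- vegan::betadisper(dist_obj, labels, type = center)
  eig <- bd$eig
  neg <- sum(abs(eig[eig < 0]))
  if (neg > 0.1 * sum(abs(eig)))
    warning("negative eigenvalue mass > 10% of total: distance is markedly non-Euclidean")
  pt <- vegan::permutest(bd, permutations = n_perm)
  tab <- pt$tab
  data.frame(F = tab$F[1], df = tab$Df[1], df_resid = tab$Df[2],
             p = tab$`Pr(>F)`[1])
}
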