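#' PCA of genotypes
#'
#' Mean-imputes missing genotypes per SNP, centers (optionally scales) and
#' decomposes the individual-by-SNP matrix.
#'
#' @param g a `geno_matrix`
#' @param n_components number of components to return (default all)
#' @param scale divide each SNP by its standard deviation
#' @return list: `scores` (individuals x components), `var_frac` explained
#'   variance fractions, `sdev`
#' @export
pca_genotypes <- function(g, n_components = NULL, scale = FALSE) {
  stopifnot(n_individuals(g) >= 2)
  m <- impute_geno(g)
  sds <- apply(m, 2, stats::sd)
  if (scale) m <- m[, sds > 0, drop = FALSE]
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  vf <- p$sdev^2 / sum(p$sdev^2)
  k <- if (is.null(n_components)) length(p$sdev) else
    min(n_components, length(p$sdev))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       var_frac = vf[seq_len(k)], sdev = p$sdev[seq_len(k)])
}

#' Mantel correlogram of genetic against geographic distance
#'
#' Distance classes follow Sturges' rule on the geographic distances; per
#' class, the Mantel statistic between the genetic distances and the
#' class-membership indicator is tested by permutation, with progressive
#' Holm correction (vegan's `mantel.correlog`). Classes beyond the one
#' containing the median geographic distance are flagged (`tested = FALSE`),
#' the usual reduced-power convention.
#'
#' @param gen_dist,geo_dist conformable `dist` objects (individuals or sites)
#' @param n_classes number of distance classes (default: Sturges)
#' @param n_perm permutations
#' @param seed RNG seed
#' @return data.frame: `class_lo`, `class_hi`, `n_pairs`, `mantel_r`, `p`,
#'   `p_corrected`, `tested`
#' @export
mantel_correlogram <- function(gen_dist, geo_dist, n_classes = NULL,
                               n_perm = 999, seed = NULL) {
  stopifnot(attr(gen_dist, "Size") == attr(geo_dist, "Size"))
  if (!is.null(seed)) set.seed(seed)
  mc <- vegan::mantel.correlog(gen_dist, D.geo = geo_dist,
                               n.class = if (is.null(n_classes)) 0 else n_classes,
                               nperm = n_perm, cutoff = TRUE, mult = "holm",
                               progressive = TRUE)
  res <- as.data.frame(mc$mantel.res)
  brk <- mc$break.pts
  out <- data.frame(
    class_lo = brk[-length(brk)], class_hi = brk[-1],
    n_pairs = res$n.dist,
    mantel_r = res$Mantel.cor,
    p = res[["Pr(Mantel)"]],
    p_corrected = res[["Pr(corrected)"]])
  out$tested <- !is.na(out$mantel_r) & !is.na(out$p)
  out
}

## Moran eigenvector maps from a set of locations: truncate distances at the
## largest minimum-spanning-tree edge (distances beyond become 4x the
## threshold), double-center the squared truncated distances, and keep the
## eigenvectors with positive eigenvalues.
build_mems <- function(geo_d, tol = 1e-8) {
  D <- as.matrix(geo_d)
  n <- nrow(D)
  tr <- vegan::spantree(geo_d)
  thresh <- max(tr$dist)
  Dt <- ifelse(D > thresh, 4 * thresh, D)
  diag(Dt) <- 0
  A <- -0.5 * Dt^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  G <- ctr %*% A %*% ctr
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  list(vectors = e$vectors[, pos, drop = FALSE],
       values = e$values[pos], threshold = thresh)
}

## redundancy R^2 of (centered) multivariate Y on orthonormalized predictors
rda_r2 <- function(Y, X) {
  if (is.null(X) || ncol(X) == 0) return(0)
  Q <- qr.Q(qr(X))
  sum((crossprod(Q, Y))^2) / sum(Y^2)
}

#' Moran-eigenvector-map analysis of spatial genetic structure
#'
#' Builds MEMs from the sampling locations (minimum-spanning-tree truncated
#' distances, positive-eigenvalue eigenvectors of the doubly centered
#' matrix) and forward-selects them against the genotype PC scores with
#' permutation tests. Selection uses the double stopping rule: a global test
#' gate (no selection when the all-MEM model is not significant), then
#' stepwise addition until the added MEM is non-significant at `alpha` or
#' the cumulative Ezekiel-adjusted R-squared exceeds the global model's.
#'
#' @param g a `geno_matrix`
#' @param lat,lon sampling coordinates, one per individual
#' @param alpha selection threshold
#' @param n_perm permutations per test
#' @param seed RNG seed
#' @param n_axes number of genotype PCs used as the response (default:
#'   enough to explain 80% of variance)
#' @return list of class `"mem_result"`: `n_candidates`, `selected`
#'   (indices), `adj_r2`, `p_values` (per selected MEM), `global_r2`,
#'   `global_adj_r2`, `global_p`, `threshold`
#' @export
mem_analysis <- function(g, lat, lon, alpha = 0.05, n_perm = 999,
                         seed = NULL, n_axes = NULL) {
  stopifnot(length(lat) == n_individuals(g))
  if (length(unique(paste(lat, lon))) < 5)
    stop("mem_analysis needs >= 5 distinct sampling locations")
  if (!is.null(seed)) set.seed(seed)
  mem <- build_mems(geo_dist(lat, lon))
  X <- mem$vectors
  n <- nrow(X)
  empty <- structure(list(n_candidates = ncol(X), selected = integer(0),
                          adj_r2 = 0, p_values = numeric(0),
                          global_r2 = 0, global_adj_r2 = 0, global_p = NA_real_,
                          threshold = mem$threshold),
                     class = "mem_result")
  if (ncol(X) == 0) return(empty)
  pca <- pca_genotypes(g)
  if (is.null(n_axes)) {
    n_axes <- max(1L, which(cumsum(pca$var_frac) >= 0.8)[1])
  }
  n_axes <- min(n_axes, ncol(pca$scores))
  Y <- scale(pca$scores[, seq_len(n_axes), drop = FALSE],
             center = TRUE, scale = FALSE)
  adj <- function(r2, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)
  ## global gate
  m_all <- ncol(X)
  r2_glob <- rda_r2(Y, X)
  glob_perm <- replicate(n_perm, rda_r2(Y[sample(n), , drop = FALSE], X))
  p_glob <- (1 + sum(glob_perm >= r2_glob)) / (1 + n_perm)
  empty$global_r2 <- r2_glob
  empty$global_adj_r2 <- adj(r2_glob, m_all)
  empty$global_p <- p_glob
  if (p_glob >= alpha) return(empty)
  sel <- integer(0); pvals <- numeric(0)
  r2_cur <- 0
  repeat {
    remaining <- setdiff(seq_len(ncol(X)), sel)
    if (!length(remaining)) break
    gains <- vapply(remaining, function(j)
      rda_r2(Y, X[, c(sel, j), drop = FALSE]), 0)
    j_best <- remaining[which.max(gains)]
    r2_new <- max(gains)
    m_new <- length(sel) + 1L
    pf <- function(r2o, r2n) (r2n - r2o) / ((1 - r2n) / (n - m_new - 1))
    f_obs <- pf(r2_cur, r2_new)
    f_perm <- replicate(n_perm, {
      Yp <- Y[sample(n), , drop = FALSE]
      r2o <- rda_r2(Yp, X[, sel, drop = FALSE])
      gains_p <- vapply(remaining, function(j)
        rda_r2(Yp, X[, c(sel, j), drop = FALSE]), 0)
      pf(r2o, max(gains_p))
    })
    p_add <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
    if (p_add >= alpha) break
    if (adj(r2_new, m_new) > adj(r2_glob, m_all) && length(sel) > 0) break
    sel <- c(sel, j_best); pvals <- c(pvals, p_add); r2_cur <- r2_new
  }
  structure(list(n_candidates = ncol(X), selected = sel,
                 adj_r2 = if (length(sel)) adj(r2_cur, length(sel)) else 0,
                 p_values = pvals, global_r2 = r2_glob,
                 global_adj_r2 = adj(r2_glob, m_all), global_p = p_glob,
                 threshold = mem$threshold),
            class = "mem_result")
}

#' @export
print.mem_result <- function(x, ...) {
  cat(sprintf("MEM analysis: %d candidate MEMs, %d selected (global p = %s)\n",
              x$n_candidates, length(x$selected),
              format.pval(x$global_p)))
  if (length(x$selected))
    cat(sprintf("  selected: %s; adjusted R^2 = %.3f\n",
                paste(x$selected, collapse = ", "), x$adj_r2))
  else cat("  no spatial structure detected (single-population verdict)\n")
  invisible(x)
}
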