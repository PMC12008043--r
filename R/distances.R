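#' Euclidean genetic distances between individuals
#'
#' Individuals are represented by their alternate-allele-count vectors
#' (0/1/2); missing entries are mean-imputed per SNP (the PCA-standard
#' convention, which preserves sample size at the cost of shrinking missing
#' individuals toward the centroid). Distances are Euclidean, the metric
#' used for allele-frequency AMOVA/PERMANOVA/PERMDISP.
#'
#' @param g a `geno_matrix`
#' @return a `dist` object
#' @export
geno_dist <- function(g) {
  stats::dist(impute_geno(g))
}

## mean-impute per SNP; columns with no calls at all are set to 0
impute_geno <- function(g) {
  m <- g$geno
  storage.mode(m) <- "double"
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2]]
  m
}

#' Pairwise great-circle distances between sampling locations
#'
#' @param lat,lon coordinate vectors
#' @param ids optional labels
#' @return a `dist` object, in km
#' @export
geo_dist <- function(lat, lon, ids = NULL) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- distance_to_center(lat, lon, center = c(lat[i], lon[i]))
  }
  m <- (m + t(m)) / 2
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  stats::as.dist(m)
}
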