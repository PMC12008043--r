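#' SNP filtering configuration
#'
#' @param mmaf minimum minor-allele frequency, as a fraction of non-missing
#'   allele copies in `[0, 0.5]`. The permissive GBS convention `2/(2n)` (a
#'   variant present in at least two of `n` individuals) and the strict `0.05`
#'   are the two presets used throughout; see [filter_presets()].
#' @param R minimum fraction of individuals with a valid call, in `(0, 1]`.
#' @param single_snp_per_locus keep only the first SNP (smallest position,
#'   ties broken by ref/alt lexicographic order) of each locus, to avoid
#'   non-independence of linked SNPs on one GBS fragment.
#' @param relatedness_bounds numeric `(low, high)` identity interval within
#'   which one member of a pair is pruned (at least half-sibling range).
#' @return a list of class `"filter_config"`
#' @export
filter_config <- function(mmaf = 0, R = 0.5, single_snp_per_locus = TRUE,
                          relatedness_bounds = c(0.25, 0.75)) {
  stopifnot(mmaf >= 0, mmaf <= 0.5, R > 0, R <= 1,
            length(relatedness_bounds) == 2,
            relatedness_bounds[1] < relatedness_bounds[2],
            relatedness_bounds[1] >= 0, relatedness_bounds[2] <= 1)
  structure(list(mmaf = mmaf, R = R,
                 single_snp_per_locus = single_snp_per_locus,
                 relatedness_bounds = relatedness_bounds),
            class = "filter_config")
}

#' The two filtering presets used by the pipeline
#'
#' Dataset #1 (permissive; diversity and demographic analyses): minor alleles
#' present in at least two individuals (`mmaf = 2/(2 n)`) and calls for at
#' least half of individuals (`R = 0.5`). Dataset #2 (strict; structure and
#' F_IS analyses): `mmaf = 0.05`, `R = 0.75`.
#'
#' @param n_individuals sample size used to form the permissive `2/(2 n)`
#'   threshold
#' @return named list of two `filter_config`s, `permissive` and `strict`
#' @export
filter_presets <- function(n_individuals) {
  list(permissive = filter_config(mmaf = 2 / (2 * n_individuals), R = 0.5),
       strict = filter_config(mmaf = 0.05, R = 0.75))
}

#' Filter SNPs by minor-allele frequency, completeness and locus
#'
#' Keeps SNPs whose minor-allele frequency (computed over non-missing allele
#' copies) is at least `cfg$mmaf` and whose call fraction is at least
#' `cfg$R`; optionally thins to one SNP per locus (smallest position, ties by
#' ref then alt allele). A per-SNP report of removals is attached as
#' `attr(, "filter_report")`.
#'
#' @param g a `geno_matrix`
#' @param cfg a [filter_config()]
#' @return the filtered `geno_matrix`; empty result triggers a warning, not
#'   an error.
#' @export
filter_snps <- function(g, cfg) {
  stopifnot(inherits(g, "geno_matrix"), n_snps(g) > 0)
  ac <- alt_counts(g)
  maf <- maf_of(ac$alt, ac$n)
  call_frac <- (ac$n / 2) / n_individuals(g)
  reason <- rep(NA_character_, n_snps(g))
  fail_maf <- is.na(maf) | maf < cfg$mmaf
  fail_call <- call_frac < cfg$R
  reason[fail_call] <- "call_fraction"
  reason[fail_maf] <- ifelse(is.na(reason[fail_maf]), "maf",
                             paste0(reason[fail_maf], "+maf"))
  keep <- !(fail_maf | fail_call)
  if (cfg$single_snp_per_locus && any(keep)) {
    tab <- g$snps[keep, , drop = FALSE]
    idx <- which(keep)
    o <- order(tab$locus, tab$pos, tab$ref, tab$alt)
    first <- !duplicated(tab$locus[o])
    chosen <- idx[o][first]
    dropped <- setdiff(idx, chosen)
    reason[dropped] <- "not_first_snp_in_locus"
    keep[dropped] <- FALSE
  }
  report <- data.frame(snp_id = g$snps$snp_id,
                       reason_removed = ifelse(keep, "", reason),
                       stringsAsFactors = FALSE)
  if (!any(keep)) warning("all SNPs removed by filtering")
  out <- subset_geno(g, snps = which(keep))
  attr(out, "filter_report") <- report
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Pairwise relatedness estimates
#'
#' `method = "grm"` (default) is the method-of-moments genomic-relationship
#' estimate from allele frequencies,
#' \eqn{A_{ij} = m^{-1} \sum_s (g_{is}-2p_s)(g_{js}-2p_s)/(2p_s(1-p_s))},
#' averaged over SNPs called in both individuals and polymorphic overall:
#' ~1 for duplicates/identical twins, ~0.5 for parent-offspring or full sibs,
#' ~0.25 for half sibs, ~0 for unrelated pairs. `method = "ibs"` is the plain
#' identity-by-state fraction of shared alleles.
#'
#' @param g a `geno_matrix`
#' @param method `"grm"` or `"ibs"`
#' @return symmetric matrix of pairwise estimates (diagonal `NA`)
#' @export
relatedness_matrix <- function(g, method = c("grm", "ibs")) {
  method <- match.arg(method)
  geno <- g$geno
  n <- nrow(geno)
  stopifnot(n >= 2)
  if (method == "grm") {
    ac <- alt_counts(g)
    p <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
    poly <- !is.na(p) & p > 0 & p < 1
    x <- geno[, poly, drop = FALSE]
    p <- p[poly]
    z <- sweep(x, 2, 2 * p)          # g - 2p, NA where missing
    w <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
    w0 <- w; w0[is.na(w0)] <- 0
    obs <- (!is.na(w)) * 1
    num <- tcrossprod(w0)
    den <- tcrossprod(obs)
    A <- ifelse(den > 0, num / den, NA_real_)
  } else {
    x <- geno
    A <- matrix(NA_real_, n, n)
    ok <- !is.na(x)
    x0 <- x; x0[!ok] <- 0
    ## shared alleles for a pair at one SNP = 2 - |g_i - g_j|... except
    ## (1,1) which shares 2; |g_i-g_j| handles all codes correctly for the
    ## standard IBS definition 1 - |g_i - g_j|/2.
    ## compute via sum over SNPs: |g_i - g_j| = g_i^2 + g_j^2 - 2 g_i g_j only
    ## for 0/2 codes; do it directly with a loop over genotype values.
    d <- matrix(0, n, n); cnt <- matrix(0, n, n)
    for (a in 0:2) for (b in 0:2) {
      ia <- (x0 == a & ok) * 1; ib <- (x0 == b & ok) * 1
      d <- d + abs(a - b) * tcrossprod(ia, ib)
      cnt <- cnt + tcrossprod(ia, ib)
    }
    A <- ifelse(cnt > 0, 1 - d / (2 * cnt), NA_real_)
  }
  diag(A) <- NA_real_
  dimnames(A) <- list(rownames(geno), rownames(geno))
  A
}

#' Prune one member of each related pair
#'
#' For every pair whose relatedness estimate falls inside `bounds`
#' (inclusive), removes the member with more missing calls (ties broken by
#' removing the lexicographically larger id). Pairs already broken by an
#' earlier removal are skipped. The removal report is attached as
#' `attr(, "prune_report")`.
#'
#' @param g a `geno_matrix`
#' @param bounds numeric `(low, high)` identity interval
#' @param method relatedness estimator, see [relatedness_matrix()]
#' @return pruned `geno_matrix`
#' @export
relatedness_prune <- function(g, bounds = c(0.25, 0.75),
                              method = c("grm", "ibs")) {
  A <- relatedness_matrix(g, method = match.arg(method))
  ids <- rownames(g$geno)
  n_miss <- rowSums(is.na(g$geno))
  pairs <- which(upper.tri(A) & A >= bounds[1] & A <= bounds[2], arr.ind = TRUE)
  removed <- character(0)
  rep_rows <- list()
  if (nrow(pairs)) {
    ## most related pairs first, deterministically
    pairs <- pairs[order(-A[pairs], ids[pairs[, 1]], ids[pairs[, 2]]), ,
                   drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (ids[i] %in% removed || ids[j] %in% removed) next
      drop_id <- if (n_miss[i] != n_miss[j]) {
        ids[c(i, j)][which.max(n_miss[c(i, j)])]
      } else max(ids[i], ids[j])
      keep_id <- setdiff(ids[c(i, j)], drop_id)
      removed <- c(removed, drop_id)
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(removed = drop_id, kept = keep_id,
                   relatedness = A[i, j], stringsAsFactors = FALSE)
    }
  }
  out <- subset_geno(g, individuals = setdiff(ids, removed))
  attr(out, "prune_report") <-
    if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(removed = character(0), kept = character(0),
                 relatedness = numeric(0))
  out
}

#' Per-group per-SNP allele frequencies
#'
#' @param g a `geno_matrix`
#' @param grouping vector (length = individuals) assigning each individual to
#'   exactly one group, e.g. the sampling site or the habitat label
#' @return data.frame with `group`, `snp_id`, `freq_alt` (NA when no copies
#'   were called — flagged by `defined = FALSE`) and `n_copies`
#' @export
allele_frequencies <- function(g, grouping) {
  stopifnot(length(grouping) == n_individuals(g), !anyNA(grouping))
  grouping <- as.character(grouping)
  out <- lapply(unique(grouping), function(gr) {
    ac <- alt_counts(g, rows = which(grouping == gr))
    data.frame(group = gr, snp_id = g$snps$snp_id,
               freq_alt = ifelse(ac$n > 0, ac$alt / ac$n, NA_real_),
               n_copies = ac$n, defined = ac$n > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
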