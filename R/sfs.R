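fold_spectrum <- function(xi) {
  ## xi: unfolded expected/observed counts for i = 1..n-1
  n <- length(xi) + 1L
  half <- n %/% 2L
  out <- numeric(half)
  for (i in seq_len(half)) {
    out[i] <- if (i == n - i) xi[i] else xi[i] + xi[n - i]
  }
  out
}

#' Build a folded site-frequency spectrum with hypergeometric projection
#'
#' Per SNP, the alternate-allele count among non-missing allele copies is
#' projected down to `n_chrom` copies. The default spreads each SNP's
#' full hypergeometric mass across the spectrum (deterministic expected
#' projection; counts are then fractional); `sample_projection = TRUE` draws
#' one hypergeometric sample per SNP instead. SNPs with fewer than `n_chrom`
#' called copies are dropped and counted, as is mass projected to
#' monomorphic classes (0 or `n_chrom` copies). Folding merges classes `i`
#' and `n_chrom - i` (ancestral states are unknown in GBS data).
#'
#' @param g a `geno_matrix`
#' @param group optional row index / logical / ids selecting the group
#' @param n_chrom projection size in allele copies; must be even; default
#'   0.8 x the maximum called copies, rounded down to even
#' @param sample_projection draw projections instead of using expectations
#' @param seed RNG seed (used only when sampling)
#' @return object of class `"folded_sfs"`: `counts` (classes
#'   `1..n_chrom/2`), `n_chrom`, `S` (= sum of counts), `L` total nucleotide
#'   sites, `n_dropped` (SNPs under the projection size), `mono_mass`
#' @export
build_folded_sfs <- function(g, group = NULL, n_chrom = NULL,
                             sample_projection = FALSE, seed = NULL) {
  rows <- if (is.null(group)) seq_len(n_individuals(g)) else group
  cs <- unit_snp_counts(g, rows)
  if (is.null(n_chrom)) {
    n_chrom <- floor(0.8 * max(cs$n))
    n_chrom <- n_chrom - n_chrom %% 2L
  }
  if (n_chrom %% 2L != 0L) stop("projection size n_chrom must be even")
  if (n_chrom < 2L) stop("projection size too small")
  usable <- cs$n >= n_chrom
  n_dropped <- sum(!usable)
  xi <- numeric(n_chrom - 1L)
  mono <- 0
  if (!is.null(seed)) set.seed(seed)
  for (s in which(usable)) {
    a <- cs$alt[s]; m <- cs$n[s]
    if (sample_projection) {
      k <- stats::rhyper(1, a, m - a, n_chrom)
      if (k == 0 || k == n_chrom) mono <- mono + 1 else xi[k] <- xi[k] + 1
    } else {
      k <- 0:n_chrom
      pr <- stats::dhyper(k, a, m - a, n_chrom)
      mono <- mono + pr[1] + pr[n_chrom + 1]
      xi <- xi + pr[2:n_chrom]
    }
  }
  structure(list(counts = fold_spectrum(xi), n_chrom = n_chrom,
                 S = sum(fold_spectrum(xi)), L = total_sites(g),
                 n_dropped = n_dropped, mono_mass = mono),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded_sfs: projection %d copies, S = %.1f over L = %s sites (%d SNPs dropped)\n",
              x$n_chrom, x$S, format(x$L), x$n_dropped))
  print(round(x$counts, 2))
  invisible(x)
}

#' Write / read a folded SFS as a whitespace-delimited text file
#'
#' First line is a header `n_chrom L`, second line the class counts.
#'
#' @param sfs a `folded_sfs`
#' @param path file path
#' @export
write_sfs <- function(sfs, path) {
  writeLines(c(paste(sfs$n_chrom, format(sfs$L, scientific = FALSE)),
               paste(format(sfs$counts, digits = 10), collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  ln <- readLines(path)
  hd <- as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]])
  counts <- as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]])
  structure(list(counts = counts, n_chrom = as.integer(hd[1]),
                 S = sum(counts), L = hd[2], n_dropped = 0L, mono_mass = 0),
            class = "folded_sfs")
}

#' Expected folded SFS under a piecewise-constant Ne history
#'
#' `method = "exact"` integrates the lineage-count death process per
#' constant-size epoch (uniformization; exact up to numerical tolerance) and
#' converts expected coalescent interval lengths to expected branch lengths
#' subtending each class. `method = "mc"` averages branch lengths over
#' `n_mc` simulated genealogies (Monte Carlo standard errors attached as
#' `attr(, "se")`). For a single constant epoch the exact mode reduces to
#' the classical \eqn{E[\xi_i] = \theta L / i}.
#'
#' @param epochs data.frame `start_gen` (ascending from 0) and `ne`
#' @param n_chrom sample size in allele copies (even for folding)
#' @param mu mutation rate per site per generation
#' @param L number of nucleotide sites
#' @param method `"exact"` or `"mc"`
#' @param n_mc Monte Carlo genealogies (mc mode)
#' @param seed RNG seed (mc mode)
#' @param fold return the folded spectrum (default) or unfolded
#' @return numeric vector of expected counts
#' @export
expected_sfs <- function(epochs, n_chrom, mu, L, method = c("exact", "mc"),
                         n_mc = 5000, seed = NULL, fold = TRUE) {
  method <- match.arg(method)
  stopifnot(all(epochs$ne > 0), epochs$start_gen[1] == 0,
            !is.unsorted(epochs$start_gen))
  if (method == "exact") {
    xi <- expected_sfs_exact_cpp(as.integer(n_chrom), epochs$start_gen,
                                 epochs$ne, mu, L)
    return(if (fold) fold_spectrum(xi) else xi)
  }
  stopifnot(n_mc >= 1000)
  if (!is.null(seed)) set.seed(seed)
  bl <- sfs_branch_cpp(n_mc, as.integer(n_chrom), epochs$start_gen,
                       epochs$ne)
  xi <- mu * L * colMeans(bl)
  se <- mu * L * apply(bl, 2, stats::sd) / sqrt(n_mc)
  if (fold) {
    out <- fold_spectrum(xi)
    attr(out, "se") <- sqrt(fold_spectrum(se^2))
  } else {
    out <- xi
    attr(out, "se") <- se
  }
  out
}
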