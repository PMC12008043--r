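#' Genotype matrix container
#'
#' Bundles a diploid biallelic genotype matrix (counts of the alternate
#' allele, `NA` = missing call) with its per-SNP annotation and the number of
#' genotyped nucleotide sites (variant plus invariant) per locus. The latter
#' is the denominator used by per-site diversity statistics, mirroring how
#' reduced-representation (GBS) pipelines report an average number of sites
#' per assembled locus.
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`. Row names are individual ids, column names SNP ids.
#' @param snps data.frame with one row per SNP: `snp_id`, `locus`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param sites_per_locus named numeric vector: genotyped nucleotide sites
#'   per locus; names must cover every locus in `snps`. A single unnamed
#'   value is recycled to all loci.
#' @return An object of class `"geno_matrix"`.
#' @export
genotype_matrix <- function(geno, snps, sites_per_locus) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(snps), ncol(geno) == nrow(snps))
  req <- c("snp_id", "locus", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols))
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp ids")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  if (anyDuplicated(rownames(geno))) stop("duplicate individual ids")
  colnames(geno) <- snps$snp_id
  loci <- unique(as.character(snps$locus))
  if (length(sites_per_locus) == 1L && is.null(names(sites_per_locus)))
    sites_per_locus <- stats::setNames(rep(as.numeric(sites_per_locus), length(loci)), loci)
  if (!all(loci %in% names(sites_per_locus)))
    stop("sites_per_locus must name every locus")
  if (any(sites_per_locus < 1)) stop("sites_per_locus must be >= 1")
  ## loci without a retained SNP stay in sites_per_locus: their invariant
  ## sites still count toward per-site diversity denominators
  snps$locus <- as.character(snps$locus)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  o <- order(snps$chrom, snps$pos)
  snps <- snps[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  rownames(snps) <- NULL
  structure(
    list(geno = geno, snps = snps, sites_per_locus = sites_per_locus),
    class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs in %d loci\n",
              nrow(x$geno), ncol(x$geno), length(x$sites_per_locus)))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%; total nucleotide sites: %s\n",
              100 * miss, format(sum(x$sites_per_locus))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of individuals / SNPs
#' @param g a `geno_matrix`
#' @return integer count
#' @export
n_individuals <- function(g) nrow(g$geno)

#' @rdname n_individuals
#' @export
n_snps <- function(g) ncol(g$geno)

#' Total genotyped nucleotide sites (variant + invariant)
#' @param g a `geno_matrix`
#' @return numeric, the sum of per-locus site counts
#' @export
total_sites <- function(g) sum(g$sites_per_locus)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`
#' @param individuals character or integer index of individuals to keep
#' @param snps character or integer index of SNPs to keep
#' @param drop_empty_loci drop loci that no longer carry any SNP from
#'   `sites_per_locus` (the default keeps them; diversity denominators then
#'   still count their invariant sites, which is correct when the SNPs were
#'   removed by filtering rather than by subsetting loci)
#' @return a `geno_matrix`
#' @export
subset_geno <- function(g, individuals = NULL, snps = NULL,
                        drop_empty_loci = FALSE) {
  geno <- g$geno
  tab <- g$snps
  if (!is.null(individuals)) geno <- geno[individuals, , drop = FALSE]
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, tab$snp_id)
    geno <- geno[, snps, drop = FALSE]
    tab <- tab[snps, , drop = FALSE]
    rownames(tab) <- NULL
  }
  spl <- g$sites_per_locus
  if (drop_empty_loci) spl <- spl[names(spl) %in% tab$locus]
  structure(list(geno = geno, snps = tab, sites_per_locus = spl),
            class = "geno_matrix")
}

## alternate-allele count and called-copy count per SNP (optionally a subset
## of individuals); the workhorse behind most statistics.
alt_counts <- function(g, rows = NULL) {
  m <- if (is.null(rows)) g$geno else g$geno[rows, , drop = FALSE]
  alt <- colSums(m, na.rm = TRUE)
  n <- 2L * colSums(!is.na(m))
  list(alt = alt, n = n)
}

## minor-allele frequency per SNP over non-missing allele copies
maf_of <- function(alt, n) {
  p <- ifelse(n > 0, alt / n, NA_real_)
  pmin(p, 1 - p)
}
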