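## Deterministic builders used across tests. No file I/O unless stated.

## small genotype matrix straight from a matrix of codes
make_geno <- function(codes, loci = NULL, pos = NULL, sites = 74,
                      chrom = "chr1") {
  codes <- as.matrix(codes)
  n_snp <- ncol(codes)
  if (is.null(loci)) loci <- paste0("L", seq_len(n_snp))
  if (is.null(pos)) pos <- seq_len(n_snp) * 100L
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("i%03d", seq_len(nrow(codes)))
  snps <- data.frame(snp_id = paste0(loci, "_", pos), locus = loci,
                     chrom = chrom, pos = as.integer(pos),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  spl <- stats::setNames(rep(sites, length(unique(loci))), unique(loci))
  genotype_matrix(codes, snps, spl)
}

## The 20-SNP / 24-individual filtering fixture. Genotypes are filled
## deterministically per SNP from (alt copies, missing individuals): the
## last `miss` individuals are NA, alt copies fill from individual 1 as
## homozygotes then one heterozygote. The same table drives the packaged
## VCF under inst/extdata.
toy_fixture_table <- function() {
  data.frame(
    snp = 1:20,
    locus = c("L1","L1","L2","L2","L3","L3","L4","L4","L5","L5","L5",
              "L6","L6","L6","L7","L7","L7","L8","L8","L8"),
    pos = c(5,40, 10,20, 7,30, 3,9, 12,13,60, 8,22,35, 2,18,19, 4,25,44),
    alt = c(10,12, 1,3, 2,20, 10,8, 6,5,2, 0,4,16, 47,44,12, 3,10,1),
    miss = c(0,0, 0,0, 0,0, 14,8, 4,0,2, 0,20,0, 0,0,0, 12,0,0))
}

toy_fixture_geno <- function() {
  tab <- toy_fixture_table()
  n_ind <- 24L
  codes <- matrix(0L, n_ind, nrow(tab))
  for (s in seq_len(nrow(tab))) {
    a <- tab$alt[s]; miss <- tab$miss[s]
    called <- n_ind - miss
    g <- integer(n_ind)
    if (miss > 0) g[(called + 1):n_ind] <- NA_integer_
    n_hom <- a %/% 2L; n_het <- a %% 2L
    stopifnot(n_hom + n_het <= called)
    if (n_hom > 0) g[seq_len(n_hom)] <- 2L
    if (n_het > 0) g[n_hom + 1L] <- 1L
    codes[, s] <- g
  }
  rownames(codes) <- sprintf("tox%02d", seq_len(n_ind))
  make_geno(codes, loci = tab$locus, pos = tab$pos)
}

## hand-enumerated retained sets (indices into the fixture table, derived
## once by per-SNP arithmetic on the table above)
toy_expected_permissive <- c(1, 4, 5, 8, 9, 14, 16, 18)
toy_expected_strict <- c(1, 4, 6, 9, 14, 16, 19)

toy_snp_ids <- function(idx) {
  tab <- toy_fixture_table()
  paste0(tab$locus[idx], "_", tab$pos[idx])
}

## small random geno matrix with missingness
random_geno <- function(n_ind, n_snp, miss = 0.1, seed = 1) {
  set.seed(seed)
  p <- stats::runif(n_snp, 0.05, 0.95)
  codes <- vapply(p, function(pp) stats::rbinom(n_ind, 2, pp),
                  integer(n_ind))
  codes[matrix(stats::runif(n_ind * n_snp) < miss, n_ind)] <- NA_integer_
  make_geno(codes)
}
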