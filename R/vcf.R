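#' Read a VCF of biallelic SNPs into a genotype matrix
#'
#' Reads diploid `GT` calls from a VCF 4.x file. Multiallelic records are
#' skipped (their count is reported in the returned object's
#' `attr(, "skipped_multiallelic")` and via a message). The locus id of each
#' SNP is taken from the VCF `ID` column when present, otherwise derived as
#' `chrom:floor(pos/locus_span)` so that SNPs on the same short GBS fragment
#' share a locus.
#'
#' @param path path to a VCF (plain text or gzipped)
#' @param metadata a data.frame with at least `sample_id`, or a path to a
#'   tab-separated file with a header (`sample_id`, `site_id`, `lat`, `lon`,
#'   optional `urban_score`). Every VCF sample must appear in it.
#' @param sites_per_locus genotyped nucleotide sites per locus: a single
#'   number applied to all loci (GBS pipelines report an average, e.g. ~74
#'   for 74 nt fragments) or a named vector per locus.
#' @param locus_span span (bp) used to derive locus ids when the VCF `ID`
#'   column is missing.
#' @return a [genotype_matrix()] with attribute `skipped_multiallelic`.
#' @export
read_vcf <- function(path, metadata, sites_per_locus = 74, locus_span = 1000) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  n_multi <- sum(multi)
  if (n_multi > 0)
    message(n_multi, " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  absent <- setdiff(samples, metadata$sample_id)
  if (length(absent))
    stop("sample(s) in VCF absent from metadata: ", paste(absent, collapse = ", "))
  ## diploid GT -> alternate-allele count
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- t(apply(gt, 2, code))
  if (nrow(fix) == 1L) geno <- matrix(as.integer(geno), ncol = 1L,
                                      dimnames = list(samples, NULL))
  rownames(geno) <- samples
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  locus <- ifelse(is.na(id) | id == "." | id == "",
                  paste0(fix[, "CHROM"], ":", pos %/% locus_span),
                  ## IDs of form locus_pos (or any string) name the locus:
                  ## strip a trailing _<pos> if present
                  sub("_[0-9]+$", "", id))
  has_ids <- !(is.na(id) | id == "." | id == "") & !anyDuplicated(id)
  snps <- data.frame(
    snp_id = if (all(has_ids)) id else paste0(fix[, "CHROM"], "_", pos),
    locus = locus, chrom = fix[, "CHROM"], pos = pos,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  g <- genotype_matrix(geno, snps, sites_per_locus)
  attr(g, "skipped_multiallelic") <- n_multi
  g
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' The inverse of [read_vcf()]: genotype codes 0/1/2/NA become `0/0`, `0/1`,
#' `1/1`, `./.`. The locus id is written to the `ID` column as
#' `<locus>_<pos>`. Output is deterministic (no timestamps).
#'
#' @param g a `geno_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path) {
  geno <- g$geno
  tab <- g$snps
  gt_str <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt_str[which(geno == 0L)] <- "0/0"
  gt_str[which(geno == 1L)] <- "0/1"
  gt_str[which(geno == 2L)] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gbspopgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- paste(tab$chrom, tab$pos, paste0(tab$locus, "_", tab$pos),
                tab$ref, tab$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Tab-separated with a header; columns `sample_id`, `site_id`, `lat`, `lon`
#' and optionally `urban_score` plus any columns added by
#' [classify_habitat()].
#'
#' @param path file path
#' @return data.frame
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "site_id", "lat", "lon")
  missing_cols <- setdiff(req, names(md))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$site_id <- as.character(md$site_id)
  md
}

#' @rdname read_metadata
#' @param md metadata data.frame
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
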