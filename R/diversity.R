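## ---- per-SNP building blocks ------------------------------------------

## per-SNP heterozygosity-style summaries within a set of rows:
## alt copies, called copies, called individuals, het individuals
unit_snp_counts <- function(g, rows) {
  m <- g$geno[rows, , drop = FALSE]
  called <- colSums(!is.na(m))
  list(alt = colSums(m, na.rm = TRUE),
       n = 2L * called,
       called = called,
       het = colSums(m == 1L, na.rm = TRUE))
}

## per-site pi contribution: 1 - sum_a C(n_a,2)/C(n,2) = 2 a (n-a) / (n (n-1))
pi_per_site <- function(alt, n) {
  ifelse(n >= 2, 2 * alt * (n - alt) / (n * (n - 1)), 0)
}

harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

tajima_constants <- function(n) {
  ## canonical constants at allele-copy count n
  stopifnot(n >= 2)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

resolve_groups <- function(g, grouping) {
  if (is.null(grouping)) grouping <- rep("all", n_individuals(g))
  stopifnot(length(grouping) == n_individuals(g))
  as.character(grouping)
}

## ---- unit-level statistics --------------------------------------------

#' Nucleotide diversity per unit
#'
#' Nei-Li nucleotide diversity: per variant site
#' \eqn{\pi_s = 2 a (n-a) / (n(n-1))} over the unit's non-missing allele
#' copies, summed and divided by the total number of genotyped nucleotide
#' sites (variant plus invariant, from the per-locus site counts) so the
#' result is per-site. `denominator = "variant"` divides by the number of
#' variant sites instead.
#'
#' @param g a `geno_matrix`
#' @param grouping per-individual unit assignment (default: one unit)
#' @param denominator `"all_sites"` (default) or `"variant"`
#' @return data.frame `unit`, `pi`, `n_individuals`
#' @export
nucleotide_diversity <- function(g, grouping = NULL,
                                 denominator = c("all_sites", "variant")) {
  denominator <- match.arg(denominator)
  grouping <- resolve_groups(g, grouping)
  L <- total_sites(g)
  if (L <= 0) stop("zero total nucleotide sites")
  out <- lapply(unique(grouping), function(u) {
    rows <- which(grouping == u)
    cs <- unit_snp_counts(g, rows)
    ps <- pi_per_site(cs$alt, cs$n)
    den <- if (denominator == "all_sites") L else max(1L, sum(ps > 0))
    data.frame(unit = u, pi = sum(ps) / den, n_individuals = length(rows))
  })
  do.call(rbind, out)
}

#' Watterson's theta per unit
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}, where
#' `S` counts sites segregating within the unit and `L` is the total number
#' of genotyped nucleotide sites. With unequal missingness the copy number
#' `n` is the unit's median allele-copy count across SNPs (rounded).
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame `unit`, `theta_w`, `S`, `n_copies`
#' @export
wattersons_theta <- function(g, grouping = NULL) {
  grouping <- resolve_groups(g, grouping)
  L <- total_sites(g)
  out <- lapply(unique(grouping), function(u) {
    cs <- unit_snp_counts(g, which(grouping == u))
    usable <- cs$n >= 2
    if (!any(usable)) stop("unit ", u, ": fewer than 2 allele copies")
    S <- sum(usable & cs$alt > 0 & cs$alt < cs$n)
    n_med <- max(2L, as.integer(round(stats::median(cs$n[usable]))))
    data.frame(unit = u, theta_w = S / (harmonic(n_med - 1) * L),
               S = S, n_copies = n_med)
  })
  do.call(rbind, out)
}

#' Observed/expected heterozygosity and F_IS per unit
#'
#' Per variant site: `h_obs` is the fraction of heterozygous calls, `h_exp`
#' the small-sample-corrected expectation \eqn{2p(1-p)\,n/(n-1)} (n allele
#' copies) and \eqn{F_{IS} = 1 - h_{obs}/h_{exp}}. Unit values average over
#' sites polymorphic within the unit; monomorphic-in-unit sites are excluded
#' from the F_IS average (set `include_monomorphic = TRUE` to count them as
#' zero instead).
#'
#' @inheritParams nucleotide_diversity
#' @param include_monomorphic include monomorphic-in-unit sites as F_IS = 0
#' @return data.frame `unit`, `h_obs`, `h_exp`, `f_is`, `n_individuals`
#' @export
heterozygosity_fis <- function(g, grouping = NULL,
                               include_monomorphic = FALSE) {
  grouping <- resolve_groups(g, grouping)
  out <- lapply(unique(grouping), function(u) {
    rows <- which(grouping == u)
    cs <- unit_snp_counts(g, rows)
    ok <- cs$n >= 2
    p <- ifelse(ok, cs$alt / cs$n, NA_real_)
    h_obs <- ifelse(cs$called > 0, cs$het / cs$called, NA_real_)
    h_exp <- 2 * p * (1 - p) * cs$n / (cs$n - 1)
    fis <- ifelse(!is.na(h_exp) & h_exp > 0, 1 - h_obs / h_exp, 0)
    poly <- ok & cs$alt > 0 & cs$alt < cs$n
    sel <- if (include_monomorphic) ok else poly
    data.frame(unit = u,
               h_obs = mean(h_obs[sel], na.rm = TRUE),
               h_exp = mean(h_exp[sel], na.rm = TRUE),
               f_is = if (any(sel)) mean(fis[sel], na.rm = TRUE) else NA_real_,
               n_individuals = length(rows))
  })
  do.call(rbind, out)
}

#' Combined per-unit diversity table
#'
#' @inheritParams nucleotide_diversity
#' @return data.frame with `unit`, `pi`, `theta_w`, `h_obs`, `h_exp`,
#'   `f_is`, `n_individuals`
#' @export
diversity_table <- function(g, grouping = NULL,
                            denominator = c("all_sites", "variant")) {
  pi_t <- nucleotide_diversity(g, grouping, denominator = denominator)
  th <- wattersons_theta(g, grouping)
  he <- heterozygosity_fis(g, grouping)
  out <- merge(merge(pi_t, th[, c("unit", "theta_w", "S")], by = "unit"),
               he[, c("unit", "h_obs", "h_exp", "f_is")], by = "unit")
  out[order(out$unit),
      c("unit", "pi", "theta_w", "S", "h_obs", "h_exp", "f_is",
        "n_individuals")]
}

## ---- windowed Tajima's D ----------------------------------------------

#' Tajima's D in genomic windows
#'
#' Windows of `window_bp` tile each chromosome from position 1 (half-open,
#' last partial window retained). Per window,
#' \eqn{D = (\pi_{sum} - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}} with the
#' canonical constants evaluated at the window's median allele-copy count.
#' Windows with fewer than 2 segregating sites are flagged (`defined =
#' FALSE`, `D = NA`).
#'
#' @inheritParams nucleotide_diversity
#' @param window_bp window size in base pairs
#' @return data.frame `unit`, `chrom`, `start`, `end`, `S`, `D`, `defined`
#' @export
tajimas_d_windows <- function(g, grouping = NULL, window_bp = 100000) {
  grouping <- resolve_groups(g, grouping)
  win_id <- paste(g$snps$chrom, (g$snps$pos - 1L) %/% window_bp, sep = "@")
  out <- list()
  for (u in unique(grouping)) {
    cs <- unit_snp_counts(g, which(grouping == u))
    for (w in unique(win_id)) {
      idx <- which(win_id == w)
      alt <- cs$alt[idx]; n <- cs$n[idx]
      seg <- n >= 2 & alt > 0 & alt < n
      S <- sum(seg)
      parts <- strsplit(w, "@", fixed = TRUE)[[1]]
      wstart <- as.integer(parts[2]) * window_bp + 1L
      row <- data.frame(unit = u, chrom = parts[1], start = wstart,
                        end = wstart + window_bp, S = S, D = NA_real_,
                        defined = FALSE, stringsAsFactors = FALSE)
      if (S >= 2) {
        n_med <- max(2L, as.integer(round(stats::median(n[seg]))))
        if (n_med >= 3) {
          k <- tajima_constants(n_med)
          pi_sum <- sum(pi_per_site(alt[seg], n[seg]))
          denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
          if (denom > 0) {
            row$D <- (pi_sum - S / k$a1) / denom
            row$defined <- TRUE
          }
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  out[order(out$unit, out$chrom, out$start), ]
}

#' t-tests on windowed Tajima's D
#'
#' One-sample two-sided t-test of mean D against zero per window table, and
#' a Welch two-sample t-test between the two tables when both are given.
#' Undefined windows are excluded.
#'
#' @param windows_a,windows_b tables from [tajimas_d_windows()]
#' @return list with `one_sample` (data.frame) and optionally `two_sample`
#' @export
d_tests <- function(windows_a, windows_b = NULL) {
  one <- function(tab, label) {
    d <- tab$D[tab$defined]
    if (length(d) < 2) stop("fewer than 2 defined windows in ", label)
    if (stats::sd(d) == 0)
      return(data.frame(group = label, mean_D = mean(d), t = NA_real_,
                        df = NA_real_, p = NA_real_, degenerate = TRUE))
    tt <- stats::t.test(d, mu = 0)
    data.frame(group = label, mean_D = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
  }
  res <- list(one_sample = rbind(
    one(windows_a, "a"),
    if (!is.null(windows_b)) one(windows_b, "b")))
  if (!is.null(windows_b)) {
    da <- windows_a$D[windows_a$defined]
    db <- windows_b$D[windows_b$defined]
    if (identical(da, db)) {
      res$two_sample <- data.frame(t = 0, df = NA_real_, p = 1,
                                   mean_diff = 0)
    } else {
      tt <- stats::t.test(da, db)
      res$two_sample <- data.frame(t = unname(tt$statistic),
                                   df = unname(tt$parameter), p = tt$p.value,
                                   mean_diff = mean(da) - mean(db))
    }
  }
  res
}

## ---- urbanization regression ------------------------------------------

#' Linear model of site diversity against an urbanization metric
#'
#' Fits `response ~ predictor + n_individuals` by least squares (the maximum
#' likelihood fit for a Gaussian linear model) on sampling sites with at
#' least two genotyped individuals, and reports a type-II Wald chi-square
#' and p-value per fixed effect (for single-df continuous terms without
#' interactions this equals the partial Wald test of the coefficient),
#' plus the model R-squared.
#'
#' @param data data.frame with one row per sampling site
#' @param response,predictor column names, e.g. `"pi"` and `"dist_km"`
#' @param n_col column holding the number of genotyped individuals per site
#' @param min_individuals sites below this count are excluded (default 2)
#' @return list of class `"eq1_fit"`: `model` (the `lm`), `anova`
#'   (data.frame term, chisq, df, p), `r2`, `n_sites`
#' @export
eq1_model <- function(data, response, predictor, n_col = "n_individuals",
                      min_individuals = 2) {
  stopifnot(all(c(response, predictor, n_col) %in% names(data)))
  use <- data[data[[n_col]] >= min_individuals, , drop = FALSE]
  use <- use[stats::complete.cases(use[, c(response, predictor, n_col)]), ,
             drop = FALSE]
  if (nrow(use) < 3) stop("fewer than 3 usable sampling sites")
  form <- stats::reformulate(c(predictor, n_col), response = response)
  fit <- stats::lm(form, data = use)
  cf <- summary(fit)$coefficients
  terms <- setdiff(rownames(cf), "(Intercept)")
  chisq <- (cf[terms, "Estimate"] / cf[terms, "Std. Error"])^2
  res <- list(
    model = fit,
    anova = data.frame(term = terms, chisq = unname(chisq), df = 1L,
                       p = stats::pchisq(unname(chisq), 1, lower.tail = FALSE)),
    r2 = summary(fit)$r.squared,
    n_sites = nrow(use),
    response = response, predictor = predictor)
  class(res) <- "eq1_fit"
  res
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat(sprintf("Urbanization model: %s ~ %s + individuals (%d sites)\n",
              x$response, x$predictor, x$n_sites))
  cat(sprintf("  R^2 = %.3f\n", x$r2))
  for (i in seq_len(nrow(x$anova)))
    cat(sprintf("  %-16s Wald chi^2 = %.3f, p = %.4g\n",
                x$anova$term[i], x$anova$chisq[i], x$anova$p[i]))
  invisible(x)
}
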