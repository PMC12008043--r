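#' Demographic-inference configuration
#'
#' @param mu mutation rate per site per generation (default 1.8e-8, a
#'   published herbaceous-perennial rate)
#' @param gen_time years per generation (default 2)
#' @param n_epochs number of piecewise-constant epochs on the time grid
#' @param t_min,t_max epoch-grid range in generations; `NULL` scales them to
#'   the data (`0.005 x` and `4 x` the Watterson-based size estimate)
#' @param max_free largest number of free size parameters considered during
#'   complexity selection
#' @param train_frac fraction of segregating sites used for training (the
#'   rest scores model complexity)
#' @param mask_low number of low-frequency folded-SFS classes excluded from
#'   the likelihood; set to 1 when the genotype data were filtered with a
#'   minimum minor-allele-count threshold that censors singletons
#' @param sel_margin held-out composite-log-likelihood units an additional
#'   free size must gain to be accepted; a conservative penalty because
#'   SNPs on one GBS locus share a genealogy, which correlates the split
#'   halves and otherwise favours overfitting
#' @param n_bootstrap SNP-resampling bootstrap replicates
#' @param seed RNG seed
#' @return list of class `"demography_config"`
#' @export
demography_config <- function(mu = 1.8e-8, gen_time = 2, n_epochs = 14,
                              t_min = NULL, t_max = NULL, max_free = 5,
                              train_frac = 0.67, mask_low = 0L,
                              sel_margin = 5, n_bootstrap = 200, seed = 1) {
  stopifnot(mu > 0, gen_time > 0, n_bootstrap >= 1, n_epochs >= 2,
            train_frac > 0, train_frac < 1, sel_margin >= 0, mask_low >= 0)
  structure(list(mu = mu, gen_time = gen_time, n_epochs = n_epochs,
                 t_min = t_min, t_max = t_max, max_free = max_free,
                 train_frac = train_frac, mask_low = as.integer(mask_low),
                 sel_margin = sel_margin,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "demography_config")
}

## log-spaced epoch start times (generations); first epoch starts at 0
epoch_grid <- function(n_epochs, t_min, t_max) {
  c(0, exp(seq(log(t_min), log(t_max), length.out = n_epochs - 1)))
}

## map change-point epoch indices (block starts, excluding 1) onto the grid:
## epochs between consecutive change points share one free size
block_map <- function(n_epochs, cuts) {
  blocks <- rep(1L, n_epochs)
  for (cp in sort(cuts)) blocks[seq(cp, n_epochs)] <- blocks[cp] + 1L
  blocks
}

## Poisson composite negative log-likelihood of folded counts x given
## per-epoch log-Ne parameters
sfs_nll <- function(log_ne_blocks, blocks, starts, n_chrom, mu, L, x, frac,
                    mask_low = 0L) {
  ne <- exp(log_ne_blocks)[blocks]
  mexp <- frac * fold_spectrum(
    expected_sfs_exact_cpp(as.integer(n_chrom), starts, ne, mu, L))
  mexp <- pmax(mexp, 1e-12)
  keep <- seq_along(x) > mask_low
  sum(mexp[keep] - x[keep] * log(mexp[keep]))
}

fit_sfs_model <- function(x, frac, blocks, starts, n_chrom, mu, L, start_par,
                          factr = 1e8, mask_low = 0L) {
  opt <- stats::optim(start_par, sfs_nll, method = "L-BFGS-B",
                      lower = log(1), upper = log(1e10),
                      blocks = blocks, starts = starts, n_chrom = n_chrom,
                      mu = mu, L = L, x = x, frac = frac, mask_low = mask_low,
                      control = list(maxit = 150, factr = factr))
  list(par = opt$par, nll = opt$value, converged = opt$convergence == 0)
}

#' Reconstruct the effective-population-size trajectory from a folded SFS
#'
#' A stairway-style composite-likelihood estimator: folded SFS entries are
#' treated as independent Poisson counts whose means come from the exact
#' expected spectrum under a piecewise-constant Ne history on a log-spaced
#' epoch grid. The number of free size parameters (contiguous epoch blocks)
#' is chosen on a held-out fraction of segregating sites; uncertainty comes
#' from refitting SNP-resampling bootstrap replicates, summarised as the
#' median and 2.5/97.5 percentile trajectories. Generations are converted
#' to years via `cfg$gen_time`.
#'
#' @param sfs a [build_folded_sfs()] result (needs `S >= 100`)
#' @param cfg a [demography_config()]
#' @return object of class `"ne_trajectory"`: `epochs_years` (epoch start
#'   times, years before sampling), `ne_median`, `ne_lo`, `ne_hi`,
#'   `ne_point` (full-data fit), `m_chosen`, `n_nonconverged`, `boot`
#'   (replicate-by-epoch matrix), `cfg`
#' @export
infer_ne_trajectory <- function(sfs, cfg = demography_config()) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (sfs$S < 100) stop("need at least 100 segregating sites")
  x <- sfs$counts
  n <- sfs$n_chrom
  L <- sfs$L
  set.seed(cfg$seed)
  ## initial size scale from Watterson's estimator
  a1 <- harmonic(n - 1)
  N0 <- max(10, sfs$S / (a1 * L * 4 * cfg$mu))
  t_min <- if (is.null(cfg$t_min)) max(4, 0.005 * N0) else cfg$t_min
  t_max <- if (is.null(cfg$t_max)) 4 * N0 else cfg$t_max
  starts <- epoch_grid(cfg$n_epochs, t_min, t_max)
  K <- cfg$n_epochs
  ## ---- complexity selection on a train/test split of segregating sites:
  ## change points are inserted greedily on the epoch grid (best insertion
  ## by training likelihood); an extra free size is accepted only when it
  ## improves the held-out composite log-likelihood by more than
  ## `sel_margin` units, a conservative penalty against the genealogical
  ## correlation between split halves.
  xr <- round(x)
  xtr <- stats::rbinom(length(xr), xr, cfg$train_frac)
  xte <- xr - xtr
  margin <- cfg$sel_margin
  ml <- cfg$mask_low
  cuts <- integer(0)
  fit <- fit_sfs_model(xtr, cfg$train_frac, rep(1L, K), starts, n, cfg$mu, L,
                       log(N0), mask_low = ml)
  te_best <- sfs_nll(fit$par, rep(1L, K), starts, n, cfg$mu, L, xte,
                     1 - cfg$train_frac, mask_low = ml)
  while (length(cuts) + 1L < cfg$max_free) {
    cand <- setdiff(2:K, cuts)
    cand_fits <- vector("list", length(cand))
    cand_nll <- rep(Inf, length(cand))
    for (ci in seq_along(cand)) {
      blocks_c <- block_map(K, c(cuts, cand[ci]))
      sp <- fit$par[block_map(K, cuts)][vapply(seq_len(max(blocks_c)),
        function(b) which(blocks_c == b)[1], 0L)]
      f <- fit_sfs_model(xtr, cfg$train_frac, blocks_c, starts, n, cfg$mu,
                         L, sp, factr = 1e9, mask_low = ml)
      cand_fits[[ci]] <- f
      cand_nll[ci] <- f$nll
    }
    ## among numerical near-ties prefer the earliest cut, which puts the
    ## most coalescent signal behind the poorly constrained ancient block
    near <- which(cand_nll <= min(cand_nll) + 0.05)
    ci_best <- near[which.min(cand[near])]
    fit_new <- cand_fits[[ci_best]]
    cut_new <- cand[ci_best]
    blocks_n <- block_map(K, c(cuts, cut_new))
    te_new <- sfs_nll(fit_new$par, blocks_n, starts, n, cfg$mu, L, xte,
                      1 - cfg$train_frac, mask_low = ml)
    if (te_new < te_best - margin) {
      cuts <- sort(c(cuts, cut_new))
      fit <- fit_new
      te_best <- te_new
    } else break
  }
  m <- length(cuts) + 1L
  ## re-place the change points on the full data (the split fixed only how
  ## many free sizes are supportable), then refit
  if (m > 1L) {
    cuts <- integer(0)
    full <- fit_sfs_model(x, 1, rep(1L, K), starts, n, cfg$mu, L,
                          fit$par[1], mask_low = ml)
    while (length(cuts) + 1L < m) {
      cand <- setdiff(2:K, cuts)
      fits <- lapply(cand, function(cp) {
        blocks_c <- block_map(K, sort(c(cuts, cp)))
        sp <- full$par[block_map(K, cuts)][vapply(seq_len(max(blocks_c)),
          function(bl) which(blocks_c == bl)[1], 0L)]
        fit_sfs_model(x, 1, blocks_c, starts, n, cfg$mu, L, sp,
                      mask_low = ml)
      })
      nlls <- vapply(fits, function(f) f$nll, 0)
      near <- which(nlls <= min(nlls) + 0.05)
      ci <- near[which.min(cand[near])]
      cuts <- sort(c(cuts, cand[ci]))
      full <- fits[[ci]]
    }
  } else {
    full <- fit_sfs_model(x, 1, rep(1L, K), starts, n, cfg$mu, L,
                          fit$par, mask_low = ml)
  }
  blocks <- block_map(K, cuts)
  ## ---- SNP bootstrap; each replicate re-places the change points (with
  ## the chosen number of free sizes) so placement uncertainty propagates
  ## into the trajectory percentiles
  S_int <- max(1L, round(sfs$S))
  prob <- x / sum(x)
  boot <- matrix(NA_real_, cfg$n_bootstrap, cfg$n_epochs)
  n_bad <- 0L
  for (b in seq_len(cfg$n_bootstrap)) {
    xb <- as.numeric(stats::rmultinom(1, S_int, prob))
    ## re-place each change point within +/-2 grid positions of the
    ## full-data solution, so placement uncertainty reaches the percentiles
    ## without re-running the whole insertion scan
    cuts_b <- integer(0)
    fb <- fit_sfs_model(xb, 1, rep(1L, K), starts, n, cfg$mu, L,
                        full$par[1], factr = 1e9, mask_low = ml)
    for (cp0 in cuts) {
      cand <- setdiff(max(2, cp0 - 2):min(K, cp0 + 2), cuts_b)
      fits <- lapply(cand, function(cp) {
        blocks_c <- block_map(K, sort(c(cuts_b, cp)))
        sp <- fb$par[block_map(K, cuts_b)][vapply(seq_len(max(blocks_c)),
          function(bl) which(blocks_c == bl)[1], 0L)]
        fit_sfs_model(xb, 1, blocks_c, starts, n, cfg$mu, L, sp,
                      factr = 1e9, mask_low = ml)
      })
      nlls <- vapply(fits, function(f) f$nll, 0)
      near <- which(nlls <= min(nlls) + 0.05)
      ci <- near[which.min(cand[near])]
      cuts_b <- sort(c(cuts_b, cand[ci]))
      fb <- fits[[ci]]
    }
    if (!fb$converged) { n_bad <- n_bad + 1L; next }
    boot[b, ] <- exp(fb$par)[block_map(K, cuts_b)]
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(
    epochs_years = starts * cfg$gen_time,
    ne_median = qs[2, ], ne_lo = qs[1, ], ne_hi = qs[3, ],
    ne_point = exp(full$par)[blocks],
    m_chosen = m, n_nonconverged = n_bad, boot = boot, cfg = cfg),
    class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("ne_trajectory: %d epochs, %d free sizes, %d bootstrap replicates (%d non-converged)\n",
              length(x$epochs_years), x$m_chosen, nrow(x$boot),
              x$n_nonconverged))
  df <- as.data.frame(x)
  print(utils::head(df, 8), row.names = FALSE)
  if (nrow(df) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.ne_trajectory <- function(x, ...) {
  data.frame(t_years = x$epochs_years, ne_median = x$ne_median,
             ne_lo = x$ne_lo, ne_hi = x$ne_hi)
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  df <- as.data.frame(x)
  t <- pmax(df$t_years, 1)
  graphics::plot(t, df$ne_median, log = "xy", type = "s",
                 xlab = "years before sampling", ylab = "Ne",
                 ylim = range(c(df$ne_lo, df$ne_hi)), ...)
  graphics::lines(t, df$ne_lo, type = "s", lty = 2)
  graphics::lines(t, df$ne_hi, type = "s", lty = 2)
  invisible(x)
}

#' Evaluate a trajectory's median Ne at arbitrary years (step function)
#'
#' @param traj an `ne_trajectory` or a data.frame with `t_years` and
#'   `ne_median` (step starts)
#' @param years years before sampling
#' @param what which column to read (`"ne_median"`, `"ne_lo"`, `"ne_hi"`)
#' @return numeric vector: the most recent step value at or before each year
#' @export
ne_at <- function(traj, years, what = "ne_median") {
  df <- as.data.frame(traj)
  stats::approx(df$t_years, df[[what]], xout = years, method = "constant",
                f = 0, rule = 2)$y
}

#' Sensitivity sweep over mutation rate and generation time
#'
#' Re-runs [infer_ne_trajectory()] for every combination of `mu_grid` and
#' `gen_time_grid` and summarises the timing of the most pronounced change:
#' the year (backward in time) of the largest step in median ln(Ne).
#'
#' @param sfs a `folded_sfs`
#' @param mu_grid,gen_time_grid nonempty numeric grids
#' @param cfg base [demography_config()] (its `mu`/`gen_time` are overridden)
#' @return list: `trajectories` (named list of `ne_trajectory`), `summary`
#'   data.frame (`mu`, `gen_time`, `onset_years`, `ne_recent`, `ne_ancient`)
#' @export
sensitivity_sweep <- function(sfs, mu_grid, gen_time_grid,
                              cfg = demography_config()) {
  stopifnot(length(mu_grid) >= 1, length(gen_time_grid) >= 1)
  out <- list(); rows <- list()
  for (mu in mu_grid) for (gt in gen_time_grid) {
    cfg_i <- cfg; cfg_i$mu <- mu; cfg_i$gen_time <- gt
    tr <- infer_ne_trajectory(sfs, cfg_i)
    key <- sprintf("mu%.2e_gt%g", mu, gt)
    out[[key]] <- tr
    dln <- diff(log(tr$ne_median))
    onset <- if (length(dln)) tr$epochs_years[which.max(abs(dln)) + 1] else NA
    rows[[key]] <- data.frame(mu = mu, gen_time = gt, onset_years = onset,
                              ne_recent = tr$ne_median[1],
                              ne_ancient = tr$ne_median[length(tr$ne_median)])
  }
  summary <- do.call(rbind, rows); rownames(summary) <- NULL
  list(trajectories = out, summary = summary)
}
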