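#' The systematic year-subsampling grid for breakpoint analysis
#'
#' Every year 1-100, every 19th year between 100 and 2,000, and every 130th
#' year between 2,000 and 15,000; after deduplication of the joint years the
#' grid holds exactly 300 years.
#'
#' @return integer vector of years
#' @export
subsample_grid <- function() {
  sort(unique(c(1:100, seq(100, 2000, by = 19), seq(2000, 15000, by = 130))))
}

#' Subsample ln(Ne) at the systematic year grid
#'
#' Reads the stepwise median-Ne trajectory at the [subsample_grid()] years
#' (most recent step value at or before each year) and returns the
#' `(t, ln Ne)` series the piecewise regression is fitted to. A trajectory
#' whose coverage ends before 15,000 years yields a truncated grid with a
#' warning; `ne_trajectory` objects extend their most ancient size
#' indefinitely (stairway-style) and therefore always cover the full grid.
#'
#' @param traj an `ne_trajectory` or a data.frame with `t_years`,
#'   `ne_median` (and optionally declared coverage via
#'   `attr(, "coverage_years")`)
#' @return data.frame of class `"subsampled_series"`: `t` (years), `y`
#'   (ln median Ne)
#' @export
subsample_years <- function(traj) {
  grid <- subsample_grid()
  ## step-function semantics: the most ancient step extends indefinitely,
  ## so coverage is unlimited unless the table declares otherwise
  coverage <- if (inherits(traj, "ne_trajectory")) Inf else {
    cv <- attr(traj, "coverage_years")
    if (is.null(cv)) Inf else cv
  }
  if (coverage < max(grid)) {
    warning("trajectory covers only [1, ", coverage,
            "]: subsampling grid truncated")
    grid <- grid[grid <= coverage]
  }
  ne <- ne_at(traj, grid)
  if (any(!is.finite(ne)) || any(ne <= 0))
    stop("non-positive or missing Ne on the subsampling grid")
  out <- data.frame(t = grid, y = log(ne))
  class(out) <- c("subsampled_series", "data.frame")
  out
}

## one pass of the iterative-linearization estimator
## (regress y on {1, t, (t-psi)+, -1[t>psi]}; update psi by gamma/beta)
muggeo_fit <- function(t, y, psi, tol, max_iter) {
  n <- length(t)
  t_inner <- sort(t)[c(2, n - 1)]
  it <- 0L
  converged <- FALSE
  merged <- FALSE
  slope_scale <- max(stats::sd(y) / stats::sd(t), 1e-12)
  repeat {
    it <- it + 1L
    k <- length(psi)
    if (k == 0L) break
    U <- pmax(outer(t, psi, "-"), 0)
    V <- -(outer(t, psi, ">") * 1)
    X <- cbind(1, t, U, V)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    beta <- cf[2 + seq_len(k)]
    gamma <- cf[2 + k + seq_len(k)]
    gap_scale <- max(stats::sd(y), 1e-12)
    ## rank-deficient, or both the slope change and the working gap are
    ## negligible: the breakpoint carries no signal and is dropped
    bad <- is.na(beta) | is.na(gamma) |
      (abs(beta) < 1e-8 * slope_scale & abs(gamma) < 1e-8 * gap_scale)
    if (any(bad)) {
      psi <- psi[!bad]
      merged <- TRUE
      if (it >= max_iter) break
      next
    }
    ## damped update: a near-zero slope change with a sizable gap would
    ## otherwise throw the breakpoint across the whole range
    step <- gamma / beta
    cap <- (t_inner[2] - t_inner[1]) / 4
    step <- sign(step) * pmin(abs(step), cap)
    psi_new <- psi + step
    psi_new <- pmin(pmax(psi_new, t_inner[1]), t_inner[2])
    psi_new <- sort(psi_new)
    ## merge breakpoints that fall into the same inter-observation gap
    ## (no data point between them: jointly unidentifiable)
    if (length(psi_new) > 1) {
      keep <- rep(TRUE, length(psi_new))
      for (j in seq_len(length(psi_new) - 1)) {
        between <- sum(t > psi_new[j] & t <= psi_new[j + 1])
        if (between < 1) { keep[j + 1] <- FALSE; merged <- TRUE }
      }
      psi_new <- psi_new[keep]
    }
    if (length(psi_new) == length(psi) &&
        max(abs(psi_new - psi)) < tol) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
    if (it >= max_iter) break
  }
  list(psi = psi, iterations = it, converged = converged || length(psi) == 0,
       merged = merged)
}

## staged initial breakpoints: fit within each subsampling period first
staged_init <- function(t, y, k, tol, max_iter) {
  ranges <- list(c(min(t), 100), c(100, 2000), c(2000, max(t)))
  n_r <- vapply(ranges, function(r) sum(t >= r[1] & t <= r[2]), 0L)
  alloc <- pmin(floor(k * n_r / sum(n_r)), pmax(n_r %/% 3L - 1L, 0L))
  while (sum(alloc) < k) {
    i <- which.max(n_r - 3 * alloc)
    alloc[i] <- alloc[i] + 1L
  }
  psi <- numeric(0)
  for (i in seq_along(ranges)) {
    if (alloc[i] == 0L) next
    sel <- t >= ranges[[i]][1] & t <= ranges[[i]][2]
    tt <- t[sel]; yy <- y[sel]
    init_i <- stats::quantile(tt, probs = seq_len(alloc[i]) / (alloc[i] + 1),
                              names = FALSE)
    if (length(tt) >= 2 * alloc[i] + 4) {
      m <- muggeo_fit(tt, yy, init_i, tol, max_iter)
      psi <- c(psi, if (length(m$psi)) m$psi else init_i)
    } else {
      psi <- c(psi, init_i)
    }
  }
  psi <- sort(psi)
  ## top up / trim to exactly k
  if (length(psi) > k) psi <- psi[round(seq(1, length(psi), length.out = k))]
  while (length(psi) < k) {
    gaps <- diff(c(min(t), psi, max(t)))
    j <- which.max(gaps)
    at <- c(min(t), psi, max(t))
    psi <- sort(c(psi, (at[j] + at[j + 1]) / 2))
  }
  psi
}

#' Piecewise (segmented) linear regression of ln(Ne) on time
#'
#' Fits a continuous piecewise-linear model with `k_breakpoints` estimated
#' change points by iterative linearization: at each iteration `y` is
#' regressed on the working design \eqn{\{1, t, (t-\psi_k)_+,
#' -1[t>\psi_k]\}} and each breakpoint is updated by
#' \eqn{\psi_k \leftarrow \psi_k + \gamma_k/\beta_k} until the largest
#' update falls below `tol`. Initial breakpoints come from staged fits
#' within the three subsampling periods (`init = "staged"`), from quantiles
#' (`"quantile"`), or from a user-supplied vector. Breakpoints whose
#' difference-in-slope collapses, or that approach within fewer than two
#' observations of a neighbour, are dropped/merged with a warning. Segment
#' slopes carry 95% confidence intervals from the final linear fit;
#' breakpoint standard errors use the delta method on \eqn{\gamma/\beta};
#' growth rates per segment follow from [slopes_to_rates()], which is
#' applied automatically.
#'
#' @param series a [subsample_years()] result or any data.frame with
#'   columns `t` and `y` (points are sorted internally)
#' @param k_breakpoints number of breakpoints (must satisfy
#'   `k < (nrow - 2)/2`)
#' @param init `"staged"`, `"quantile"`, or a numeric vector of starting
#'   breakpoints
#' @param tol convergence tolerance on the largest breakpoint update (years)
#' @param max_iter iteration cap; the best iterate is returned with
#'   `converged = FALSE` when reached
#' @param seed optional RNG seed (reserved for randomized restarts)
#' @return object of class `"piecewise_fit"`; see Details for fields
#' @export
fit_piecewise <- function(series, k_breakpoints = 8, init = "staged",
                          tol = 1e-6, max_iter = 100, seed = NULL) {
  df <- as.data.frame(series)
  stopifnot(all(c("t", "y") %in% names(df)))
  df <- df[order(df$t), ]
  df <- df[!duplicated(df$t), ]
  t <- df$t; y <- df$y
  n <- length(t)
  if (k_breakpoints >= (n - 2) / 2)
    stop("too many breakpoints for ", n, " points")
  if (!is.null(seed)) set.seed(seed)
  psi0 <- if (is.numeric(init)) sort(init) else if (init == "staged")
    staged_init(t, y, k_breakpoints, tol, max_iter) else
      stats::quantile(t, probs = seq_len(k_breakpoints) /
                        (k_breakpoints + 1), names = FALSE)
  m <- muggeo_fit(t, y, psi0, tol, max_iter)
  psi <- m$psi
  if (m$merged)
    warning("breakpoint(s) merged or dropped during fitting (",
            length(psi), " of ", k_breakpoints, " retained)")
  k <- length(psi)
  ## final fits: reduced design for slopes, full design for psi SEs
  lm0 <- stats::lm(y ~ t)
  rss0 <- sum(stats::residuals(lm0)^2)
  if (k == 0L) {
    cf <- stats::coef(summary(lm0))
    dfree <- n - 2
    segs <- data.frame(start = min(t), end = max(t),
                       b = cf["t", 1],
                       b_lo = cf["t", 1] - stats::qt(0.975, dfree) * cf["t", 2],
                       b_hi = cf["t", 1] + stats::qt(0.975, dfree) * cf["t", 2])
    obj <- structure(list(
      psi = numeric(0), psi_se = numeric(0), segments = segs,
      coefficients = stats::coef(lm0), fitted = stats::fitted(lm0),
      residuals = stats::residuals(lm0), rss = rss0, rss0 = rss0,
      iterations = m$iterations, converged = m$converged,
      k_requested = k_breakpoints, series = df), class = "piecewise_fit")
    return(slopes_to_rates(obj))
  }
  U <- pmax(outer(t, psi, "-"), 0)
  fit <- stats::lm(y ~ t + U)
  Vc <- stats::vcov(fit)
  cf <- stats::coef(fit)
  dfree <- fit$df.residual
  ## segment slopes: cumulative sums of (t, U) coefficients
  b <- se_b <- numeric(k + 1)
  for (s in seq_len(k + 1)) {
    a <- c(0, 1, as.numeric(seq_len(k) <= s - 1))
    b[s] <- sum(a * cf)
    se_b[s] <- sqrt(drop(a %*% Vc %*% a))
  }
  q <- stats::qt(0.975, dfree)
  segs <- data.frame(start = c(min(t), psi), end = c(psi, max(t)),
                     b = b, b_lo = b - q * se_b, b_hi = b + q * se_b)
  ## psi SEs from one evaluation of the full working design
  Vm <- -(outer(t, psi, ">") * 1)
  fitV <- stats::lm(y ~ t + U + Vm)
  psi_se <- rep(NA_real_, k)
  cfV <- stats::coef(fitV)
  if (!anyNA(cfV)) {
    VV <- stats::vcov(fitV)
    for (j in seq_len(k)) {
      ib <- 2 + j; ig <- 2 + k + j
      beta_j <- cfV[ib]; gamma_j <- cfV[ig]
      psi_se[j] <- sqrt(VV[ig, ig] / beta_j^2 +
                        gamma_j^2 * VV[ib, ib] / beta_j^4 -
                        2 * gamma_j * VV[ig, ib] / beta_j^3)
    }
  }
  obj <- structure(list(
    psi = psi, psi_se = psi_se, segments = segs,
    coefficients = cf, fitted = stats::fitted(fit),
    residuals = stats::residuals(fit),
    rss = sum(stats::residuals(fit)^2), rss0 = rss0,
    iterations = m$iterations, converged = m$converged,
    k_requested = k_breakpoints, series = df), class = "piecewise_fit")
  slopes_to_rates(obj)
}

#' Convert segment slopes to growth rates
#'
#' Under backward-in-time exponential growth/decay, a segment slope `b` of
#' ln(Ne) against years-before-sampling corresponds to a forward-in-time
#' per-year rate \eqn{r = -(e^b - 1)} (the sign is reverted because the
#' regression runs backward in time). The transform is decreasing, so the
#' confidence limits swap: `r` CI = \eqn{[-(e^{b_{hi}}-1), -(e^{b_{lo}}-1)]}.
#'
#' @param model a `piecewise_fit`
#' @return the model with `r`, `r_lo`, `r_hi` columns in `$segments`
#' @export
slopes_to_rates <- function(model) {
  stopifnot(inherits(model, "piecewise_fit"))
  s <- model$segments
  s$r <- -(exp(s$b) - 1)
  s$r_lo <- -(exp(s$b_hi) - 1)
  s$r_hi <- -(exp(s$b_lo) - 1)
  model$segments <- s
  model
}

#' @export
print.piecewise_fit <- function(x, ...) {
  k <- length(x$psi)
  cat(sprintf("piecewise_fit: %d breakpoint(s) [%d requested], %d segments, %s\n",
              k, x$k_requested, nrow(x$segments),
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else sprintf("NOT converged after %d iterations", x$iterations)))
  if (k)
    cat("  breakpoints (years):",
        paste(sprintf("%.1f", x$psi), collapse = ", "), "\n")
  cat(sprintf("  RSS = %.6g (0-breakpoint RSS = %.6g)\n", x$rss, x$rss0))
  invisible(x)
}

#' @export
summary.piecewise_fit <- function(object, ...) {
  print(object)
  s <- object$segments
  cat("\nPeriods (years before sampling):\n")
  out <- data.frame(start = round(s$start, 1), end = round(s$end, 1),
                    b = signif(s$b, 4),
                    b_CI = sprintf("[%.4g, %.4g]", s$b_lo, s$b_hi),
                    r = signif(s$r, 4),
                    r_CI = sprintf("[%.4g, %.4g]", s$r_lo, s$r_hi))
  print(out, row.names = FALSE)
  invisible(object)
}

#' @export
coef.piecewise_fit <- function(object, ...) {
  list(psi = object$psi, slopes = object$segments$b,
       rates = object$segments$r)
}

#' @export
residuals.piecewise_fit <- function(object, ...) object$residuals

#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$t else
    if (is.data.frame(newdata)) newdata$t else newdata
  cf <- object$coefficients
  k <- length(object$psi)
  y <- cf[1] + cf[2] * t
  if (k)
    for (j in seq_len(k))
      y <- y + cf[2 + j] * pmax(t - object$psi[j], 0)
  unname(y)
}

#' @export
plot.piecewise_fit <- function(x, ...) {
  graphics::plot(x$series$t, x$series$y, pch = 16, cex = 0.5,
                 xlab = "years before sampling", ylab = "ln(Ne)", ...)
  tt <- seq(min(x$series$t), max(x$series$t), length.out = 500)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  if (length(x$psi)) graphics::abline(v = x$psi, lty = 3)
  invisible(x)
}
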