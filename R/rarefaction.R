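# Sample-size-based rarefaction and extrapolation of species richness.
#
# Interpolation uses the analytic hypergeometric expectation of richness in a
# subsample; extrapolation uses the Chao lower-bound estimate of undetected
# richness (Chao1 for abundance data, Chao2 for incidence data) with the
# standard exponential approach to the asymptote. Confidence intervals come
# from a bootstrap over an estimated community that reserves probability mass
# for undetected species.

# E[S(m)]: S_obs - sum_i C(n - x_i, m) / C(n, m), on the log scale.
# `n` is the reference total: sum(x) for abundances, the number of sampling
# units for incidence frequencies.
rarefy_expected <- function(x, m, n = sum(x)) {
  x <- x[x > 0]
  if (m > n) stop("interpolation size exceeds reference sample size")
  lc_nm <- lchoose(n, m)
  miss <- vapply(x, function(xi) {
    if (n - xi < m) return(0)
    exp(lchoose(n - xi, m) - lc_nm)
  }, numeric(1L))
  length(x) - sum(miss)
}

# Chao estimate of undetected richness from singleton/doubleton counts
# (uniques/duplicates in incidence mode), bias-corrected form when f2 = 0.
chao_f0 <- function(f1, f2, n) {
  if (f2 > 0) ((n - 1) / n) * f1^2 / (2 * f2)
  else ((n - 1) / n) * f1 * (f1 - 1) / 2
}

#' Sample-size-based rarefaction and extrapolation of richness
#'
#' Expected species richness at a grid of sample sizes, interpolated below the
#' reference sample size by the analytic hypergeometric expectation and
#' extrapolated above it via the Chao estimate of undetected richness, with
#' bootstrap confidence intervals. Abundance mode treats \code{x} as a count
#' vector over taxa (the reference size is the number of individuals);
#' incidence mode treats \code{x} as a taxa-by-sampling-unit presence matrix
#' (the reference size is the number of sampling units).
#'
#' @param x count vector (abundance mode) or incidence matrix with taxa as
#'   rows (incidence mode); a count matrix is reduced to presence/absence.
#' @param mode \code{"abundance"} or \code{"incidence"}.
#' @param grid integer sample sizes; default an even grid from 1 to
#'   \code{extrap_factor} times the reference size.
#' @param extrap_factor cap on extrapolation, as a multiple of the reference
#'   size (default 2).
#' @param n_boot bootstrap replicates for the confidence band (default 200).
#' @param conf confidence level (default 0.95).
#' @param seed optional seed for the bootstrap; same seed, same band.
#' @return object of class \code{rarefaction_curve}: data.frame with columns
#'   \code{size}, \code{estimate}, \code{lower}, \code{upper}, \code{segment}
#'   (\code{"interp"}/\code{"extrap"}); attributes \code{n} (reference size),
#'   \code{S_obs}, \code{f1}, \code{f2}, \code{S_asymptote}.
#' @export
rarefy_extrapolate <- function(x, mode = c("abundance", "incidence"),
                               grid = NULL, extrap_factor = 2,
                               n_boot = 200, conf = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "abundance") {
    if (is.matrix(x) || is.data.frame(x))
      stop("abundance mode expects a count vector, not a matrix")
    x <- x[x > 0]
    if (length(x) == 0L) stop("total count must be >= 1")
    n <- sum(x)
    freq <- x
  } else {
    if (!is.matrix(x) && !is.data.frame(x))
      stop("incidence mode expects a taxa-by-unit matrix")
    x <- as.matrix(x) > 0
    n <- ncol(x)               # number of sampling units
    freq <- rowSums(x)         # incidence frequencies Q_i
    freq <- freq[freq > 0]
    if (length(freq) == 0L) stop("no occurrences in incidence matrix")
  }
  S_obs <- length(freq)
  f1 <- sum(freq == 1)
  f2 <- sum(freq == 2)
  f0 <- chao_f0(f1, f2, n)

  cap <- max(n, round(extrap_factor * n))
  if (is.null(grid))
    grid <- unique(c(round(seq(1, cap, length.out = 40)), n))
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1) || any(grid > cap))
    stop("grid sizes must lie in [1, ", cap, "]")

  est_one <- function(fr, nn, m) {
    Sb <- sum(fr > 0)
    if (m <= nn) return(rarefy_expected(fr, m, nn))
    f1b <- sum(fr == 1); f2b <- sum(fr == 2)
    f0b <- chao_f0(f1b, f2b, nn)
    if (f1b == 0 || f0b == 0) return(Sb)
    Sb + f0b * (1 - (1 - f1b / (nn * f0b + f1b))^(m - nn))
  }
  est <- vapply(grid, function(m) est_one(freq, n, m), numeric(1L))

  # bootstrap community: observed taxa with their sample fractions scaled by
  # estimated coverage, plus ceiling(f0) undetected taxa sharing the rest.
  Chat <- if (n > 1)
    1 - (f1 / n) * ifelse((n - 1) * f1 + 2 * f2 > 0,
                          (n - 1) * f1 / ((n - 1) * f1 + 2 * f2), 0)
  else 0
  p_seen <- (freq / n) * Chat
  k0 <- max(0L, ceiling(f0))
  p_unseen <- if (k0 > 0) rep((1 - Chat) / k0, k0) else numeric(0)
  p_all <- c(p_seen, p_unseen)
  p_all <- pmin(pmax(p_all, 0), 1)

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      if (mode == "abundance") {
        fr <- as.vector(rmultinom(1L, n, prob = p_all / sum(p_all)))
      } else {
        fr <- rbinom(length(p_all), n, p_all)
      }
      fr <- fr[fr > 0]
      if (length(fr) == 0L) return(rep(0, length(grid)))
      vapply(grid, function(m) est_one(fr, n, m), numeric(1L))
    }, numeric(length(grid)))
  })
  se <- apply(boots, 1L, sd)
  z <- qnorm(1 - (1 - conf) / 2)
  lower <- pmax(0, est - z * se)
  upper <- est + z * se

  out <- data.frame(size = grid, estimate = est, lower = lower, upper = upper,
                    segment = ifelse(grid <= n, "interp", "extrap"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("rarefaction_curve", "data.frame"),
            n = n, S_obs = S_obs, f1 = f1, f2 = f2,
            S_asymptote = S_obs + f0, mode = mode)
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf(
    "Rarefaction/extrapolation curve (%s mode)\n  reference size n = %d, S_obs = %d, f1 = %d, f2 = %d\n  Chao asymptote = %.2f; grid of %d sizes (%d extrapolated)\n",
    attr(x, "mode"), attr(x, "n"), attr(x, "S_obs"), attr(x, "f1"),
    attr(x, "f2"), attr(x, "S_asymptote"), nrow(x),
    sum(x$segment == "extrap")))
  invisible(x)
}

#' Plot a rarefaction/extrapolation curve
#'
#' Solid line over the interpolated range, dotted beyond the reference sample
#' size, shaded confidence band, and a point at the reference sample.
#'
#' @param x a \code{rarefaction_curve}.
#' @param col line colour.
#' @param add add to an existing plot.
#' @param ... passed to \code{plot}.
#' @export
plot.rarefaction_curve <- function(x, col = "steelblue", add = FALSE, ...) {
  if (!add)
    plot(x$size, x$estimate, type = "n", xlab = "Sample size",
         ylab = "Expected richness",
         ylim = range(c(x$lower, x$upper)), ...)
  polygon(c(x$size, rev(x$size)), c(x$lower, rev(x$upper)),
          col = adjustcolor(col, alpha.f = 0.2), border = NA)
  ii <- x$segment == "interp"
  lines(x$size[ii], x$estimate[ii], col = col, lwd = 2)
  lines(x$size[!ii | c(FALSE, diff(ii) < 0)], x$estimate[!ii | c(FALSE, diff(ii) < 0)],
        col = col, lwd = 2, lty = 3)
  points(attr(x, "n"), attr(x, "S_obs"), pch = 19, col = col)
  invisible(x)
}
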