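# Rhythmicity and circular-phase statistics for short, equally spaced
# time series sampled over whole periods (e.g. six points at 4-h intervals).

check_timepoints <- function(values, timepoints, period) {
  n <- length(values)
  stop_if(n < 4, "need at least 4 timepoints")
  stop_if(length(timepoints) != n, "values/timepoints length mismatch")
  dt <- diff(timepoints)
  stop_if(any(abs(dt - dt[1]) > 1e-8), "timepoints must be equally spaced")
  span <- n * dt[1]
  k <- span / period
  stop_if(abs(k - round(k)) > 1e-8,
          "series length times spacing must be a whole number of periods")
  as.integer(round(k))
}

#' Fourier component at a chosen period
#'
#' Computes the complex Fourier coefficient of the harmonic matching the
#' period of interest (default 24 h). The amplitude is the fitted cosine
#' amplitude (F24 for a 24-h period); the phase is the ZT hour at which the
#' fitted cosine x(t) = amplitude * cos(2 pi (t - phase) / period) peaks.
#'
#' @param values numeric series, one value per timepoint
#' @param timepoints equally spaced hours covering whole periods
#' @param period period of interest in hours (default 24)
#' @return list(amplitude, phase); phase is NA for a flat series
#' @export
fourier_component <- function(values, timepoints = DEFAULT_TIMEPOINTS,
                              period = 24) {
  check_timepoints(values, timepoints, period)
  n <- length(values)
  x <- values - mean(values)
  w <- 2 * pi * timepoints / period
  a <- (2 / n) * sum(x * cos(w))
  b <- (2 / n) * sum(x * sin(w))
  amp <- sqrt(a^2 + b^2)
  scale <- max(abs(x), 1)
  phase <- if (amp < 1e-12 * scale) NA_real_ else
    wrap24(atan2(b, a) * period / (2 * pi))
  list(amplitude = amp, phase = phase)
}

#' Exact Fisher test for one specific period
#'
#' Tests whether the periodogram ordinate at the pre-chosen period is larger
#' than expected under i.i.d. Gaussian noise. The statistic is
#' g = I(period) / sum of ordinates over all positive frequencies up to and
#' including the Nyquist. For even series length the Nyquist ordinate has one
#' degree of freedom and interior ordinates two, giving the exact tail
#' p(g) = (1 - g)^(m - 1) * (1 + 2c)^(-1/2) with c = g / (1 - g) and
#' m = N/2 - 1 interior ordinates; for odd length the classical
#' p(g) = (1 - g)^(m - 1) applies. A zero-variance series returns p = 1 by
#' convention.
#'
#' @inheritParams fourier_component
#' @return list(g, p_value)
#' @export
fisher_specific_period <- function(values, timepoints = DEFAULT_TIMEPOINTS,
                                   period = 24) {
  k <- check_timepoints(values, timepoints, period)
  n <- length(values)
  x <- values - mean(values)
  if (sum(x^2) < 1e-300) return(list(g = NA_real_, p_value = 1))
  even <- n %% 2 == 0
  kmax <- if (even) n %/% 2 else (n - 1) %/% 2
  stop_if(k < 1 || k > kmax, "period not resolvable at this sampling")
  stop_if(even && k == kmax,
          "period of interest falls on the Nyquist frequency")
  idx <- seq_len(n) - 1
  ords <- vapply(seq_len(kmax), function(j)
    sum(x * cos(2 * pi * j * idx / n))^2 +
      sum(x * sin(2 * pi * j * idx / n))^2, numeric(1))
  g <- ords[k] / sum(ords)
  m <- if (even) kmax - 1 else kmax    # interior ordinate count
  if (g >= 1) return(list(g = 1, p_value = 0))
  cc <- g / (1 - g)
  p <- if (even) (1 - g)^(m - 1) * (1 + 2 * cc)^(-1 / 2) else (1 - g)^(m - 1)
  list(g = g, p_value = min(max(p, 0), 1))
}

#' @rdname fisher_specific_period
#' @export
fisher_specific_period_pvalue <- function(values,
                                          timepoints = DEFAULT_TIMEPOINTS,
                                          period = 24) {
  fisher_specific_period(values, timepoints, period)$p_value
}

#' Full rhythm analysis of one series
#'
#' @inheritParams fourier_component
#' @return list(f24_amplitude, phase, g_statistic, p_value)
#' @export
rhythm_stats <- function(values, timepoints = DEFAULT_TIMEPOINTS,
                         period = 24) {
  fc <- fourier_component(values, timepoints, period)
  ft <- fisher_specific_period(values, timepoints, period)
  list(f24_amplitude = fc$amplitude, phase = fc$phase,
       g_statistic = ft$g, p_value = ft$p_value)
}

#' Rhythm analysis of a sites-by-timepoints matrix
#'
#' @param mat numeric matrix, rows are series
#' @param timepoints hours (columns)
#' @param period period of interest in hours
#' @param adjust add a Benjamini-Hochberg adjusted q column
#' @return data.table with amplitude, phase, g, p (and optionally q) per row
#' @export
rhythm_stats_matrix <- function(mat, timepoints = DEFAULT_TIMEPOINTS,
                                period = 24, adjust = FALSE) {
  res <- rbindlist(lapply(seq_len(nrow(mat)), function(i) {
    r <- rhythm_stats(as.numeric(mat[i, ]), timepoints, period)
    data.table(amplitude = r$f24_amplitude, phase = r$phase,
               g = r$g_statistic, p = r$p_value)
  }))
  if (adjust) res[, q := p.adjust(p, "BH")]
  res[]
}

hours_to_angle <- function(h) h * 2 * pi / 24

#' Circular mean of phases in hours
#'
#' @param phases hours (wrapped mod 24)
#' @return list(mean = hours in \[0, 24), resultant = mean resultant length);
#'   mean is NA when the resultant length is (numerically) zero
#' @export
circular_mean <- function(phases) {
  stop_if(length(phases) < 1, "need at least one phase")
  a <- hours_to_angle(phases)
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  m <- if (R < 1e-12) NA_real_ else wrap24(atan2(S, C) * 24 / (2 * pi))
  list(mean = m, resultant = R)
}

#' Rao test for homogeneity of circular dispersions
#'
#' Tests equality of polar dispersions across groups of phases: the per-group
#' mean resultant lengths (whose complements measure dispersion) are compared
#' by a chi-square homogeneity statistic with delta-method variances.
#' Invariant to rotating all phases by a constant. A permutation version is
#' available for small groups.
#'
#' @param groups list of >= 2 numeric vectors of phases in hours
#' @param method "chisq" (asymptotic) or "permutation"
#' @param n_perm permutations for the permutation method
#' @return list(statistic, p_value, resultants)
#' @export
rao_dispersion_homogeneity <- function(groups, method = c("chisq",
                                                          "permutation"),
                                       n_perm = 2000) {
  method <- match.arg(method)
  stop_if(length(groups) < 2, "need at least two groups")
  stop_if(any(vapply(groups, length, 1L) < 3),
          "each group needs at least 3 phases")
  stat_fun <- function(gr) {
    k <- length(gr)
    Rbar <- s2 <- nn <- numeric(k)
    for (i in seq_len(k)) {
      a <- hours_to_angle(gr[[i]])
      th <- atan2(mean(sin(a)), mean(cos(a)))
      z <- cos(a - th)
      Rbar[i] <- mean(z)
      s2[i] <- max(var(z), 1e-12)
      nn[i] <- length(a)
    }
    w <- nn / s2
    Rw <- sum(w * Rbar) / sum(w)
    list(stat = sum(w * (Rbar - Rw)^2), R = Rbar)
  }
  obs <- stat_fun(groups)
  k <- length(groups)
  if (method == "chisq") {
    p <- pchisq(obs$stat, df = k - 1, lower.tail = FALSE)
  } else {
    pool <- unlist(groups)
    sizes <- vapply(groups, length, 1L)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pool)
      gr <- split(perm, rep(seq_len(k), sizes))
      if (stat_fun(gr)$stat >= obs$stat) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  list(statistic = obs$stat, p_value = p, resultants = obs$R)
}
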