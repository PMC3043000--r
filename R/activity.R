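# Motif-activity inference: conservation-weighted site-count matrices and
# per-timepoint least-squares regression of mean-centered expression on
# motif site counts (E_gt = sum_m N_gm A_mt + I_t + noise), plus the
# site-to-expression integration analyses (cycling fraction by binding rank,
# phase dispersion by motif class).

#' Conservation-weighted motif site-count matrix
#'
#' For each promoter window and motif, sums the likelihood ratio of the PSWM
#' versus background over every position (both strands), each position
#' weighted by C^exponent where C is the product of the per-base conservation
#' scores over the motif footprint.
#'
#' @param windows named character vector of promoter sequences (one per gene)
#' @param pswms named list of PSWMs
#' @param conservation optional named list of per-base conservation vectors
#'   matching the windows (default: none, weight 1)
#' @param exponent conservation exponent (default 0.05)
#' @return genes x motifs matrix N_gm with non-negative entries
#' @export
build_site_count_matrix <- function(windows, pswms, conservation = NULL,
                                    exponent = 0.05) {
  stop_if(length(windows) == 0, "no promoter windows supplied")
  if (inherits(pswms, "PSWM")) pswms <- list(motif = pswms)
  N <- matrix(0, length(windows), length(pswms),
              dimnames = list(names(windows), names(pswms)))
  for (g in seq_along(windows)) {
    seq <- windows[[g]]
    codes <- seq_to_codes(seq)
    codes_rc <- seq_to_codes(revcomp(seq))
    cons <- if (is.null(conservation)) NULL else conservation[[g]]
    for (m in seq_along(pswms)) {
      pswm <- pswms[[m]]
      L <- ncol(pswm$probabilities)
      if (length(codes) < L) next
      lr <- 2^pswm_scores(codes, pswm) + 2^rev(pswm_scores(codes_rc, pswm))
      if (!is.null(cons)) {
        stop_if(length(cons) != nchar(seq),
                "conservation vector does not match window length")
        cw <- vapply(seq_along(lr), function(i)
          prod(cons[i:(i + L - 1)]), numeric(1))
        lr <- lr * cw^exponent
      }
      N[g, m] <- sum(lr)
    }
  }
  N
}

#' Infer motif activities by per-timepoint least squares
#'
#' Fits E_gt = sum_m N_gm A_mt + I_t independently at each timepoint by
#' ordinary least squares with an intercept. Expression rows are mean-centered
#' before fitting. Standard errors come from the per-timepoint residual
#' variance.
#'
#' @param expression genes x timepoints matrix
#' @param site_counts genes x motifs matrix N_gm
#' @param timepoints hours (defaults to ZT2..ZT22)
#' @return ActivityProfile: list(activities = motifs x timepoints,
#'   intercepts, se = motifs x timepoints, se_intercepts, timepoints,
#'   residuals)
#' @export
infer_activities <- function(expression, site_counts,
                             timepoints = DEFAULT_TIMEPOINTS) {
  E <- as.matrix(expression)
  N <- as.matrix(site_counts)
  stop_if(nrow(E) != nrow(N), "expression/site-count gene mismatch")
  stop_if(nrow(N) < ncol(N) + 1, "need more genes than motifs")
  E <- E - rowMeans(E)
  X <- cbind(`(Intercept)` = 1, N)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("site-count matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Tn <- ncol(E)
  fit <- lm.fit(X, E)
  coefs <- fit$coefficients
  res <- E - X %*% coefs
  df <- nrow(E) - ncol(X)
  sigma2 <- colSums(res^2) / df
  V <- chol2inv(qr.R(qx))
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qx$pivot, qx$pivot] <- V
  se <- sqrt(outer(diag(XtXinv), sigma2))
  structure(list(
    activities = coefs[-1, , drop = FALSE],
    intercepts = coefs[1, ],
    se = se[-1, , drop = FALSE],
    se_intercepts = se[1, ],
    timepoints = timepoints,
    residuals = res), class = "ActivityProfile")
}

#' Cyclic-activity test per motif
#'
#' Applies the exact Fisher specific-period test to each motif's inferred
#' activity profile.
#'
#' @param profile ActivityProfile
#' @param period period of interest in hours
#' @return data.table(motif, amplitude, phase, p)
#' @export
cyclic_activity_test <- function(profile, period = 24) {
  A <- profile$activities
  rbindlist(lapply(seq_len(nrow(A)), function(m) {
    r <- rhythm_stats(as.numeric(A[m, ]), profile$timepoints, period)
    data.table(motif = rownames(A)[m] %||% paste0("m", m),
               amplitude = r$f24_amplitude, phase = r$phase, p = r$p_value)
  }))
}

#' Fraction of cycling targets among top-ranked sites
#'
#' Sites are ranked by binding strength; for each rank cutoff the fraction of
#' assigned targets with a rhythmic expression profile (p below threshold) is
#' reported. Sites without an assigned target are excluded from both
#' numerator and denominator.
#'
#' @param strength per-site binding strength (peak signal)
#' @param target_p per-site target rhythmicity p-value (NA = unassigned)
#' @param cutoffs rank cutoffs (default c(10, 20, 50, ..., all))
#' @param p_threshold rhythmicity threshold (default 0.05)
#' @return data.table(cutoff, n_assigned, fraction)
#' @export
cycling_fraction_by_rank <- function(strength, target_p, cutoffs = NULL,
                                     p_threshold = 0.05) {
  stop_if(length(strength) != length(target_p),
          "strength/target_p length mismatch")
  n <- length(strength)
  if (is.null(cutoffs))
    cutoffs <- sort(unique(pmin(c(10, 20, 50, 100, 200, 500, 1000, n), n)))
  ord <- order(-strength)
  p_sorted <- target_p[ord]
  rbindlist(lapply(cutoffs, function(x) {
    top <- p_sorted[seq_len(x)]
    assigned <- !is.na(top)
    data.table(cutoff = x, n_assigned = sum(assigned),
               fraction = if (any(assigned))
                 mean(top[assigned] < p_threshold) else NA_real_)
  }))
}

#' Phase dispersion of target expression by motif class
#'
#' Per-class circular mean and resultant length of expression phases, with a
#' Rao equality-of-dispersions test across classes.
#'
#' @param phases numeric phases in hours
#' @param classes factor/character motif class per phase
#' @param min_n minimum group size (smaller groups are dropped)
#' @return list(summary = data.table(class, n, mean_phase, resultant),
#'   rao_p)
#' @export
phase_dispersion_by_class <- function(phases, classes, min_n = 3) {
  ok <- !is.na(phases) & !is.na(classes)
  phases <- phases[ok]; classes <- as.character(classes)[ok]
  groups <- split(phases, classes)
  groups <- groups[vapply(groups, length, 1L) >= min_n]
  stop_if(length(groups) < 2, "need at least two groups of size >= min_n")
  summ <- rbindlist(lapply(names(groups), function(cl) {
    cm <- circular_mean(groups[[cl]])
    data.table(class = cl, n = length(groups[[cl]]),
               mean_phase = cm$mean, resultant = cm$resultant)
  }))
  rao <- rao_dispersion_homogeneity(groups)
  list(summary = summ, rao_p = rao$p_value)
}
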