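# Site discovery: Poisson sliding-window region detection versus input,
# strand-kernel estimation, model-based deconvolution of strand profiles into
# point sources, local-maxima site calling, and spurious-site rejection.

#' Detect tag-enriched regions versus input
#'
#' Sliding-window Poisson test of ChIP tag counts against the depth-scaled
#' local input rate (floored at the genome-wide input rate). Windows passing
#' the Benjamini-Hochberg adjusted significance level and the fold cutoff are
#' merged when they overlap. Detection runs on the all-timepoints-merged
#' track.
#'
#' @param chip TagTrack of ChIP tags (collapsed over timepoints internally)
#' @param input TagTrack of input/control tags
#' @param window sliding window width in bp
#' @param step window step in bp
#' @param min_fold minimum fold enrichment over the scaled input rate; the
#'   Poisson/BH test is the primary criterion and the fold floor only guards
#'   against near-flat enrichment, since window counts include background
#'   tags that dilute the fold of genuine point sources
#' @param alpha BH-adjusted significance level
#' @return CandidateRegion data.table (chrom, start, end, chip_count,
#'   input_count, fold_enrichment); coordinates 0-based half-open
#' @export
detect_regions <- function(chip, input, window = 300, step = window %/% 2,
                           min_fold = 1.2, alpha = 0.01) {
  stop_if(nrow(chip$tags) == 0 || is.null(input),
          "both chip and input tracks are required")
  chip_c <- collapse_timepoints(chip)
  input_c <- collapse_timepoints(input)
  chip_total <- sum(chip_c$tags$count)
  input_total <- sum(input_c$tags$count)
  genome <- sum(chip$chrom_sizes)
  uniform_input <- input_total == 0
  if (uniform_input)
    message("input track has zero coverage; using uniform genome-wide rate")
  scale <- if (uniform_input) 1 else chip_total / input_total
  base_rate <- if (uniform_input) chip_total / genome else
    input_total / genome
  win_counts <- function(track, ch, starts, width) {
    tg <- track$tags[chrom == ch][order(pos)]
    if (nrow(tg) == 0) return(numeric(length(starts)))
    cum <- c(0, cumsum(tg$count))
    hi <- findInterval(starts + width - 1, tg$pos)
    lo <- findInterval(starts - 1, tg$pos)
    cum[hi + 1] - cum[lo + 1]
  }
  all_win <- rbindlist(lapply(names(chip$chrom_sizes), function(ch) {
    size <- chip$chrom_sizes[[ch]]
    starts <- seq(0L, max(0L, size - window), by = step)
    data.table(chrom = ch, start = starts,
               chip_n = win_counts(chip_c, ch, starts, window),
               input_n = if (uniform_input) rep(0, length(starts)) else
                 win_counts(input_c, ch, starts, window))
  }))
  all_win[, lambda := scale * pmax(input_n, base_rate * window)]
  all_win[, p := ppois(chip_n - 1, lambda, lower.tail = FALSE)]
  all_win[, padj := p.adjust(p, "BH")]
  hits <- all_win[padj <= alpha & chip_n / lambda >= min_fold & chip_n > 0]
  if (nrow(hits) == 0)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), chip_count = numeric(),
                      input_count = numeric(), fold_enrichment = numeric()))
  setorder(hits, chrom, start)
  hits[, end := start + window]
  hits[, newgrp := {
    e <- cummax(end)
    c(TRUE, start[-1] > head(e, -1))
  }, by = chrom]
  hits[, grp := cumsum(newgrp)]
  regions <- hits[, .(start = min(start), end = max(end)), by = .(chrom, grp)]
  regions[, grp := NULL]
  reg_sum <- function(track, col) vapply(seq_len(nrow(regions)), function(i) {
    sub <- track$tags[chrom == regions$chrom[i] & pos >= regions$start[i] &
                        pos < regions$end[i]]
    sum(sub[[col]])
  }, numeric(1))
  regions[, chip_count := reg_sum(chip_c, "weight")]
  regions[, input_count := reg_sum(input_c, "weight")]
  chip_tags <- reg_sum(chip_c, "count")
  input_tags <- reg_sum(input_c, "count")
  expected <- scale * pmax(input_tags, base_rate * (regions$end -
                                                      regions$start))
  regions[, fold_enrichment := chip_tags / pmax(expected, 1e-12)]
  regions[]
}

#' Estimate the strand offset kernel from strong regions
#'
#' The mean strand offset is found by maximizing the pooled cross-correlation
#' between plus- and minus-strand tag profiles over the top regions; the
#' kernel density is then estimated from the pooled per-tag offsets relative
#' to each region's center and symmetrized between strands (the minus-strand
#' kernel is the positional mirror of the plus-strand kernel).
#'
#' @param chip TagTrack (collapsed internally)
#' @param regions CandidateRegion table
#' @param top_k number of strongest regions to pool
#' @param min_strand_tags minimum tags required on each strand of a region
#' @param max_offset largest offset considered, bp
#' @return StrandKernel: list(offsets, density, mean_offset)
#' @export
estimate_kernel <- function(chip, regions, top_k = 50, min_strand_tags = 10,
                            max_offset = 400) {
  chip_c <- collapse_timepoints(chip)
  regions <- as.data.table(regions)[order(-chip_count)]
  pull <- function(i, st) {
    r <- regions[i]
    chip_c$tags[chrom == r$chrom & strand == st &
                  pos >= r$start - max_offset & pos < r$end + max_offset]
  }
  usable <- list()
  for (i in seq_len(nrow(regions))) {
    p <- pull(i, "+"); m <- pull(i, "-")
    if (sum(p$count) >= min_strand_tags && sum(m$count) >= min_strand_tags)
      usable[[length(usable) + 1]] <- list(plus = p, minus = m)
    if (length(usable) >= top_k) break
  }
  stop_if(length(usable) == 0,
          "no region with enough tags on both strands")
  lags <- 0:max_offset
  cc <- numeric(length(lags))
  for (u in usable) {
    origin <- min(u$plus$pos, u$minus$pos)
    span <- max(u$plus$pos, u$minus$pos) - origin + 1 + max_offset
    pv <- numeric(span); mv <- numeric(span)
    pv[u$plus$pos - origin + 1] <- u$plus$count
    mv[u$minus$pos - origin + 1] <- u$minus$count
    for (li in seq_along(lags)) {
      l <- lags[li]
      idx <- seq_len(span - l)
      cc[li] <- cc[li] + sum(pv[idx] * mv[idx + l])
    }
  }
  shift <- lags[which.max(cc)]          # approx 2 x mean offset
  offs <- numeric(0); wts <- numeric(0)
  for (u in usable) {
    ctr <- (sum(u$plus$pos * u$plus$count) / sum(u$plus$count) +
              sum(u$minus$pos * u$minus$count) / sum(u$minus$count)) / 2
    offs <- c(offs, ctr - u$plus$pos, u$minus$pos - ctr)
    wts <- c(wts, u$plus$count, u$minus$count)
  }
  keep <- abs(offs) <= max_offset
  offs <- offs[keep]; wts <- wts[keep]
  samp <- sample(offs, min(20000, 10 * length(offs)), replace = TRUE,
                 prob = wts)
  dens <- density(samp, from = 0, to = max_offset, n = max_offset + 1)
  grid <- round(dens$x)
  d <- pmax(dens$y, 0)
  nz <- which(d > max(d) * 1e-4)
  grid <- grid[min(nz):max(nz)]
  d <- d[min(nz):max(nz)]
  structure(list(offsets = as.integer(grid), density = d / sum(d),
                 mean_offset = sum(grid * d / sum(d)),
                 cc_shift = shift), class = "StrandKernel")
}

#' The generative truncated-normal kernel (for simulations and defaults)
#' @param mu,sd kernel mean and sd in bp
#' @param max_offset support bound in bp
#' @return StrandKernel
#' @export
normal_kernel <- function(mu = 100, sd = 25, max_offset = NULL) {
  if (is.null(max_offset)) max_offset <- ceiling(mu + 5 * sd)
  grid <- 0:max_offset
  d <- dnorm(grid, mu, sd)
  structure(list(offsets = as.integer(grid), density = d / sum(d),
                 mean_offset = sum(grid * d) / sum(d), cc_shift = 2 * mu),
            class = "StrandKernel")
}

#' Deconvolve a region's strand profiles into point sources
#'
#' Fits non-negative source intensities w_j on a grid so that the expected
#' strand profiles sum_j w_j K_strand(x - s_j) plus a flat background best
#' explain the observed tags under a Poisson likelihood, by multiplicative
#' Richardson-Lucy-style updates with an optional L1 sparsity penalty.
#' Plus-strand tags are expected at source - offset and minus-strand tags at
#' source + offset, each strand carrying half the kernel mass. With zero
#' penalty the fitted expected total equals the observed tag total.
#'
#' @param region one CandidateRegion row (chrom, start, end)
#' @param chip TagTrack (collapsed internally)
#' @param kernel StrandKernel
#' @param grid_step source grid spacing, bp
#' @param penalty L1 sparsity penalty per unit intensity
#' @param max_iter maximum iterations
#' @param tol relative log-likelihood convergence tolerance
#' @return DeconvolvedProfile: list(positions, intensity, background_level,
#'   loglik, converged, observed_total, fitted_total)
#' @export
deconvolve_region <- function(region, chip, kernel, grid_step = 10,
                              penalty = 0, max_iter = 500, tol = 1e-8) {
  chip_c <- collapse_timepoints(chip)
  pad <- max(kernel$offsets)
  r <- as.list(region)
  tg <- chip_c$tags[chrom == r$chrom & pos >= r$start - pad &
                      pos < r$end + pad]
  stop_if(nrow(tg) == 0, "region contains no tags")
  grid <- seq(r$start, r$end - 1, by = grid_step)
  kmin <- min(kernel$offsets)
  klen <- length(kernel$offsets)
  kdens <- function(d) {
    i <- d - kmin + 1L
    out <- numeric(length(d))
    ok <- i >= 1L & i <= klen
    out[ok] <- kernel$density[i[ok]]
    out
  }
  # A[i, j]: probability that a tag from source j lands at observed slot i
  x <- tg$pos
  sgn <- ifelse(tg$strand == "+", 1, -1)
  A <- outer(seq_along(x), seq_along(grid),
             function(i, j) 0.5 * kdens(sgn[i] * (grid[j] - x[i])))
  W2 <- 2 * (r$end - r$start + 2 * pad)   # background slots, both strands
  A <- cbind(A, 1 / W2)
  n <- tg$count
  nsrc <- length(grid)
  theta <- rep(sum(n) / (nsrc + 1), nsrc + 1)
  pen <- c(rep(penalty, nsrc), 0)
  ll_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lam <- as.vector(A %*% theta)
    lam <- pmax(lam, 1e-300)
    ll <- sum(n * log(lam)) - sum(theta) - sum(pen * theta)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(prev) && abs(ll - prev) <= tol * (abs(prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    prev <- ll
    ratio <- n / lam
    theta <- theta * as.vector(crossprod(A, ratio)) / (1 + pen)
  }
  if (!converged)
    warning("deconvolution did not converge within max_iter", call. = FALSE)
  structure(list(
    positions = grid, intensity = theta[seq_len(nsrc)],
    background_level = theta[nsrc + 1] / (W2 / 2),
    loglik = ll_trace, converged = converged,
    observed_total = sum(n), fitted_total = sum(theta)),
    class = "DeconvolvedProfile")
}

#' Call binding-site positions from a deconvolved profile
#'
#' Local maxima of the source intensity above `min_intensity` (and above
#' `min_rel_intensity` times the profile maximum, which suppresses the small
#' deconvolution side lobes that appear when the estimated kernel deviates
#' from the true fragment model); maxima closer than `min_separation` are
#' merged keeping the stronger one (ties keep the leftmost).
#'
#' @param profile DeconvolvedProfile
#' @param min_separation minimum distance between calls, bp
#' @param min_intensity minimum source intensity (tags)
#' @param min_rel_intensity minimum intensity as a fraction of the profile
#'   maximum
#' @return integer positions of called sites (possibly empty)
#' @export
call_sites <- function(profile, min_separation = 100, min_intensity = 0,
                       min_rel_intensity = 0.2) {
  w <- profile$intensity
  pos <- profile$positions
  if (length(w) == 0) return(integer(0))
  floor_w <- max(min_intensity, min_rel_intensity * max(w))
  left <- c(-Inf, w[-length(w)])
  right <- c(w[-1], -Inf)
  cand <- which(w > left & w >= right & w > floor_w)
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(-w[cand], pos[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pos[i] - pos[kept]) >= min_separation) || !length(kept))
      kept <- c(kept, i)
  }
  sort(as.integer(pos[kept]))
}

#' Reject spurious site calls
#'
#' Removes sites failing any of: minimum tag count in the quantification
#' window, minimum fold enrichment over the depth-scaled input, or strand
#' balance (each strand must carry at least `min_strand_frac` of the site's
#' tags). Every rejection is recorded with a reason.
#'
#' @param sites data.table with columns chrom, position
#' @param chip,input TagTracks (collapsed internally)
#' @param criteria list(halfwidth, min_tags, min_fold, min_strand_frac)
#' @return filtered sites; attribute "rejections" holds the dropped rows with
#'   reasons
#' @export
reject_spurious <- function(sites, chip, input,
                            criteria = list(halfwidth = 250, min_tags = 10,
                                            min_fold = 1.2,
                                            min_strand_frac = 0.2)) {
  sites <- as.data.table(sites)
  if (nrow(sites) == 0) {
    attr(sites, "rejections") <- data.table()
    return(sites)
  }
  cr <- modifyList(list(halfwidth = 250, min_tags = 10, min_fold = 1.2,
                        min_strand_frac = 0.2), criteria)
  chip_c <- collapse_timepoints(chip)
  input_c <- if (!is.null(input)) collapse_timepoints(input) else NULL
  chip_total <- sum(chip_c$tags$count)
  input_total <- if (is.null(input_c)) 0 else sum(input_c$tags$count)
  genome <- sum(chip$chrom_sizes)
  scale <- if (input_total > 0) chip_total / input_total else 1
  base_in <- if (input_total > 0) input_total / genome else chip_total / genome
  reasons <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p0 <- sites$position[i]
    sub <- chip_c$tags[chrom == ch & pos >= p0 - cr$halfwidth &
                         pos <= p0 + cr$halfwidth]
    tot <- sum(sub$count)
    if (tot < cr$min_tags) { reasons[i] <- "min_tags"; next }
    frac_plus <- sum(sub[strand == "+"]$count) / tot
    if (min(frac_plus, 1 - frac_plus) < cr$min_strand_frac) {
      reasons[i] <- "strand_balance"; next
    }
    in_n <- if (is.null(input_c)) 0 else
      sum(input_c$tags[chrom == ch & pos >= p0 - cr$halfwidth &
                         pos <= p0 + cr$halfwidth]$count)
    lambda <- scale * pmax(in_n, base_in * (2 * cr$halfwidth + 1))
    if (tot / lambda < cr$min_fold) reasons[i] <- "low_fold"
  }
  keep <- reasons == ""
  out <- sites[keep]
  rej <- sites[!keep][, reason := reasons[!keep]]
  attr(out, "rejections") <- rej
  out
}

#' Discover binding sites end to end
#'
#' Convenience wrapper: detect regions, estimate the strand kernel, deconvolve
#' each region, call local maxima, and reject spurious calls.
#'
#' @param chip,input TagTracks
#' @param kernel optional StrandKernel; estimated from the data when NULL
#' @param detect_args,deconvolve_args,call_args,criteria parameter lists
#'   passed to the respective stages
#' @return BindingSite data.table (chrom, position, intensity, region_start,
#'   region_end); attributes "regions", "kernel", "rejections"
#' @export
discover_sites <- function(chip, input, kernel = NULL,
                           detect_args = list(), deconvolve_args = list(),
                           call_args = list(), criteria = list()) {
  chip_c <- collapse_timepoints(chip)
  regions <- do.call(detect_regions, c(list(chip = chip_c, input = input),
                                       detect_args))
  if (nrow(regions) == 0) {
    out <- data.table(chrom = character(), position = integer(),
                      intensity = numeric())
    attr(out, "regions") <- regions
    return(out)
  }
  if (is.null(kernel))
    kernel <- estimate_kernel(chip_c, regions)
  calls <- rbindlist(lapply(seq_len(nrow(regions)), function(i) {
    prof <- do.call(deconvolve_region,
                    c(list(region = regions[i], chip = chip_c,
                           kernel = kernel), deconvolve_args))
    ps <- do.call(call_sites, c(list(profile = prof), call_args))
    if (length(ps) == 0) return(NULL)
    data.table(chrom = regions$chrom[i], position = ps,
               intensity = prof$intensity[match(ps, prof$positions)],
               region_start = regions$start[i], region_end = regions$end[i])
  }))
  if (is.null(calls) || nrow(calls) == 0)
    calls <- data.table(chrom = character(), position = integer(),
                        intensity = numeric())
  sites <- reject_spurious(calls, chip_c, input, criteria)
  attr(sites, "regions") <- regions
  attr(sites, "kernel") <- kernel
  sites
}
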