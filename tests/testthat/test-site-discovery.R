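chip_input_tracks <- function(fx) {
  dd <- deduplicate(fx$tags)
  sizes <- c(chrS = fx$truth$genome_length)
  list(chip = normalize_and_merge(dd[library != "input"], sizes),
       input = normalize_and_merge(dd[library == "input"], sizes))
}

test_that("detect_regions finds nothing when chip matches input", {
  set.seed(31)
  L <- 100000
  mk <- function(lib, tp) data.table::data.table(
    chrom = "chrS", pos = sample.int(L, 5000, TRUE) - 1L,
    strand = sample(c("+", "-"), 5000, TRUE), library = lib,
    timepoint = tp)
  chip <- normalize_and_merge(deduplicate(mk("libA", 2)),
                              c(chrS = L))
  input <- normalize_and_merge(deduplicate(mk("input", NA)),
                               c(chrS = L))
  expect_equal(nrow(detect_regions(chip, input)), 0)
})

test_that("a strong planted site yields exactly one region containing it", {
  set.seed(32)
  fx <- single_site_tags(strength = 500, background_fraction = 0.05,
                         seed = 32)
  tr <- chip_input_tracks(fx)
  regions <- detect_regions(tr$chip, tr$input)
  expect_equal(nrow(regions), 1)
  ctr <- fx$truth$sites$center[1]
  expect_true(regions$start[1] <= ctr && regions$end[1] > ctr)
  expect_gt(regions$fold_enrichment[1], 2)
})

test_that("overlapping enriched windows are merged into one region", {
  # two point sources 200 bp apart: their significant windows overlap
  set.seed(33)
  L <- 50000
  specs <- rbind(site_spec("NONE", 25000, strength = 400,
                           rel_amplitude = 0),
                 site_spec("NONE", 25200, strength = 400,
                           rel_amplitude = 0))
  g <- generate_genome(L, 0.5, seed = 33)
  pl <- plant_sites(g, specs, background_rate = 800 * 0.1 / L,
                    timepoints = 0, libraries = "libA", seed = 33)
  tags <- simulate_chip_tags(pl$truth, depth = 900, seed = 33)
  dd <- deduplicate(tags)
  chip <- normalize_and_merge(dd[library != "input"], c(chrS = L))
  input <- normalize_and_merge(dd[library == "input"], c(chrS = L))
  regions <- detect_regions(chip, input)
  expect_equal(nrow(regions), 1)
})

test_that("estimate_kernel recovers the generative mean offset", {
  set.seed(34)
  fx <- single_site_tags(strength = 5000, kernel_mu = 100, kernel_sd = 10,
                         seed = 34)
  tr <- chip_input_tracks(fx)
  regions <- detect_regions(tr$chip, tr$input)
  k <- estimate_kernel(tr$chip, regions)
  expect_gte(k$mean_offset, 90)
  expect_lte(k$mean_offset, 110)
  expect_equal(sum(k$density), 1, tolerance = 1e-9)
})

test_that("identical strand profiles at zero shift give offset ~ 0", {
  pos <- rep(c(1000L, 1010L, 1020L), each = 20)
  tags <- data.table::data.table(
    chrom = "chrS", pos = c(pos, pos),
    strand = rep(c("+", "-"), each = length(pos)),
    library = "libA", timepoint = 0)
  chip <- normalize_and_merge(tags, c(chrS = 5000))
  regions <- data.table::data.table(chrom = "chrS", start = 900L,
                                    end = 1100L, chip_count = 1)
  k <- estimate_kernel(chip, regions, min_strand_tags = 3)
  expect_equal(k$cc_shift, 0)
})

test_that("kernel estimation fails without two populated strands", {
  tags <- data.table::data.table(chrom = "chrS", pos = rep(1000L, 50),
                                 strand = "+", library = "libA",
                                 timepoint = 0)
  chip <- normalize_and_merge(tags, c(chrS = 5000))
  regions <- data.table::data.table(chrom = "chrS", start = 900L,
                                    end = 1100L, chip_count = 1)
  expect_error(estimate_kernel(chip, regions), "both strands")
})

test_that("deconvolution concentrates a single noiseless source", {
  # noiseless: observed counts equal the exact expected strand profiles
  kern <- normal_kernel(100, 25)
  ctr <- 10000L
  tg <- data.table::data.table(
    chrom = "chrS",
    pos = c(ctr - kern$offsets, ctr + kern$offsets),
    strand = rep(c("+", "-"), each = length(kern$offsets)),
    count = rep(1000 * 0.5 * kern$density, 2),
    timepoint = 0)
  tg[, weight := count]
  chip <- structure(list(tags = tg, timepoints = 0, libraries = "libA",
                         chrom_sizes = c(chrS = 20000)),
                    class = "TagTrack")
  region <- data.table::data.table(chrom = "chrS", start = 9700L,
                                   end = 10300L)
  prof <- deconvolve_region(region, chip, kern, grid_step = 10,
                            max_iter = 5000)
  top <- which.max(prof$intensity)
  expect_equal(prof$positions[top], ctr)
  expect_gte(prof$intensity[top] / sum(prof$intensity), 0.95)

  # with sampled tags (no dedup, so multiplicities stay Poisson) the peak
  # still localizes near the truth
  set.seed(35)
  fx <- single_site_tags(strength = 1000, background_fraction = 0,
                         seed = 35)
  chip2 <- normalize_and_merge(fx$tags[library != "input"],
                               c(chrS = fx$truth$genome_length))
  prof2 <- suppressWarnings(
    deconvolve_region(region, chip2, kern, grid_step = 10,
                      max_iter = 5000))
  top2 <- prof2$positions[which.max(prof2$intensity)]
  expect_lte(abs(top2 - fx$truth$sites$center[1]), 25)
})

test_that("penalty-free deconvolution conserves total signal within 1%", {
  set.seed(36)
  fx <- single_site_tags(strength = 400, background_fraction = 0.2,
                         seed = 36)
  tr <- chip_input_tracks(fx)
  region <- data.table::data.table(chrom = "chrS", start = 9700L,
                                   end = 10300L)
  prof <- suppressWarnings(
    deconvolve_region(region, tr$chip, normal_kernel(100, 25), penalty = 0))
  expect_lt(abs(prof$fitted_total - prof$observed_total) /
              prof$observed_total, 0.01)
  expect_true(all(prof$intensity >= 0))
  expect_true(all(diff(prof$loglik) > -1e-6))   # monotone ascent
})

test_that("two sources 300 bp apart resolve into two maxima", {
  set.seed(37)
  L <- 30000
  specs <- rbind(site_spec("NONE", 15000, strength = 1000,
                           rel_amplitude = 0),
                 site_spec("NONE", 15300, strength = 1000,
                           rel_amplitude = 0))
  g <- generate_genome(L, 0.5, seed = 37)
  pl <- plant_sites(g, specs, background_rate = 0, timepoints = 0,
                    libraries = "libA", seed = 37)
  tags <- simulate_chip_tags(pl$truth, depth = 2000, seed = 37)
  chip <- normalize_and_merge(deduplicate(tags[library != "input"]),
                              c(chrS = L))
  region <- data.table::data.table(chrom = "chrS", start = 14800L,
                                   end = 15600L)
  prof <- suppressWarnings(
    deconvolve_region(region, chip, normal_kernel(100, 25)))
  calls <- call_sites(prof, min_separation = 100)
  expect_equal(length(calls), 2)
  expect_lte(abs(calls[1] - 15000), 30)
  expect_lte(abs(calls[2] - 15300), 30)
})

test_that("deconvolution refuses an empty region", {
  tags <- data.table::data.table(chrom = "chrS", pos = 100L, strand = "+",
                                 library = "libA", timepoint = 0)
  chip <- normalize_and_merge(tags, c(chrS = 50000))
  region <- data.table::data.table(chrom = "chrS", start = 20000L,
                                   end = 20500L)
  expect_error(deconvolve_region(region, chip, normal_kernel()),
               "no tags")
})

test_that("penalized fit agrees with exhaustive source search on tiny
           regions", {
  set.seed(38)
  kern <- normal_kernel(50, 15)
  L <- 5000
  # one- and two-source truths on a coarse grid
  for (true_pos in list(2500L, c(2400L, 2700L))) {
    specs <- data.table::rbindlist(lapply(true_pos, function(p)
      site_spec("NONE", p, strength = 800, rel_amplitude = 0)))
    g <- generate_genome(L, 0.5, seed = 38)
    pl <- plant_sites(g, specs, kernel_mu = 50, kernel_sd = 15,
                      background_rate = 0, timepoints = 0,
                      libraries = "libA", seed = 38)
    tags <- simulate_chip_tags(pl$truth, depth = 800 * length(true_pos),
                               seed = 39)
    chip <- normalize_and_merge(deduplicate(tags[library != "input"]),
                                c(chrS = L))
    region <- data.table::data.table(chrom = "chrS", start = 2300L,
                                     end = 2800L)
    grid_step <- 25
    prof <- suppressWarnings(
      deconvolve_region(region, chip, kern, grid_step = grid_step))

    # brute force: Poisson log-likelihood over all 1- and 2-source
    # placements on the same grid, intensity split by golden-section-free
    # profile likelihood on a small simplex grid
    tg <- collapse_timepoints(chip)$tags
    pad <- max(kern$offsets)
    tg <- tg[pos >= 2300 - pad & pos < 2800 + pad]
    grid <- seq(2300, 2799, by = grid_step)
    kd <- function(d) {
      i <- d - min(kern$offsets) + 1L
      out <- numeric(length(d))
      ok <- i >= 1L & i <= length(kern$offsets)
      out[ok] <- kern$density[i[ok]]
      out
    }
    site_ll <- function(srcs, wts) {
      lam <- rep(1e-9, nrow(tg))
      for (j in seq_along(srcs)) {
        d <- ifelse(tg$strand == "+", srcs[j] - tg$pos, tg$pos - srcs[j])
        lam <- lam + 0.5 * wts[j] * kd(d)
      }
      sum(tg$count * log(lam)) - sum(wts)
    }
    total <- sum(tg$count)
    if (length(true_pos) == 1) {
      lls <- vapply(grid, function(s) site_ll(s, total), numeric(1))
      best_bf <- grid[which.max(lls)]
      best_rl <- prof$positions[which.max(prof$intensity)]
      expect_equal(best_rl, best_bf)
    } else {
      combs <- t(combn(grid, 2))
      fracs <- seq(0.2, 0.8, by = 0.1)
      best <- c(-Inf, NA, NA)
      for (r in seq_len(nrow(combs))) for (f in fracs) {
        ll <- site_ll(combs[r, ], total * c(f, 1 - f))
        if (ll > best[1]) best <- c(ll, combs[r, ])
      }
      top2 <- prof$positions[order(-prof$intensity)[1:2]]
      expect_setequal(sort(top2), sort(best[2:3]))
    }
  }
})

test_that("call_sites applies the stated maxima and tie rules", {
  mk <- function(w) structure(list(positions = seq(0, by = 10,
                                                   length.out = length(w)),
                                   intensity = w),
                              class = "DeconvolvedProfile")
  # monotone profile: one call
  expect_length(call_sites(mk(1:10), min_rel_intensity = 0), 1)
  expect_length(call_sites(mk(10:1), min_rel_intensity = 0), 1)
  # two equal maxima 50 bp apart with min_separation 100: leftmost kept
  w <- c(0, 5, 0, 0, 0, 5, 0)
  calls <- call_sites(mk(w), min_separation = 100, min_rel_intensity = 0)
  expect_equal(calls, 10)
  # both kept when separation allows
  calls2 <- call_sites(mk(w), min_separation = 30, min_rel_intensity = 0)
  expect_equal(calls2, c(10, 50))
  # everything below min_intensity: empty
  expect_length(call_sites(mk(w), min_intensity = 10), 0)
  expect_length(call_sites(mk(numeric(0))), 0)
})

test_that("calls are invariant under uniform translation", {
  set.seed(40)
  fx <- single_site_tags(strength = 600, seed = 40)
  dd <- deduplicate(fx$tags)
  shift <- 1234L
  dd2 <- data.table::copy(dd)[, pos := pos + shift]
  L <- fx$truth$genome_length
  kern <- normal_kernel(100, 25)
  run <- function(tags, size) {
    chip <- normalize_and_merge(tags[library != "input"], c(chrS = size))
    region <- data.table::data.table(
      chrom = "chrS", start = min(tags[library != "input"]$pos),
      end = max(tags[library != "input"]$pos) + 1L)
    prof <- suppressWarnings(deconvolve_region(region, chip, kern))
    call_sites(prof)
  }
  c1 <- run(dd, L)
  c2 <- run(dd2, L + shift)
  expect_equal(c2, c1 + shift)
})

test_that("reject_spurious enforces strand balance and retains true sites", {
  set.seed(41)
  # all tags on one strand: rejected
  tags <- data.table::data.table(chrom = "chrS",
                                 pos = rep(1000L + 0:49, 2),
                                 strand = "+", library = "libA",
                                 timepoint = 0)
  chip <- normalize_and_merge(deduplicate(tags), c(chrS = 5000))
  sites <- data.table::data.table(chrom = "chrS", position = 1025L)
  out <- reject_spurious(sites, chip, NULL)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejections")$reason, "strand_balance")

  # empty input
  empty <- reject_spurious(sites[0], chip, NULL)
  expect_equal(nrow(empty), 0)

  # planted true sites at depth 1e4 are nearly all retained
  L <- 500000
  specs <- random_site_specs(20, L, class_probs = c(NONE = 1),
                             min_gap = 20000, seed = 41)
  g <- generate_genome(L, 0.5, seed = 41)
  pl <- plant_sites(g, specs,
                    background_rate = 0.1 * sum(specs$strength) / (0.9 * L),
                    timepoints = 0, libraries = "libA", seed = 41)
  tags2 <- simulate_chip_tags(pl$truth, depth = 1e4, seed = 41)
  dd <- deduplicate(tags2)
  chip2 <- normalize_and_merge(dd[library != "input"], c(chrS = L))
  input2 <- normalize_and_merge(dd[library == "input"], c(chrS = L))
  true_sites <- data.table::data.table(chrom = "chrS",
                                       position = pl$truth$sites$center)
  kept <- reject_spurious(true_sites, chip2, input2)
  expect_gte(nrow(kept) / nrow(true_sites), 0.95)
})
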