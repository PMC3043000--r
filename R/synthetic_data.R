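# Synthetic-data generator: toy genomes, planted E-box sites, strand-specific
# circadian ChIP tags and matched expression matrices with known ground truth.

#' Evaluate an expression with a temporarily fixed RNG seed
#'
#' Restores the caller's RNG state afterwards, so fixed-seed generators do not
#' perturb the global random stream.
#' @param seed integer seed, or NULL to leave the RNG alone
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with the stated GC content, split evenly between the
#' two bases of each pair.
#'
#' @param length genome length in bp (> 0)
#' @param gc_fraction probability of G or C at each position, in \[0, 1\]
#' @param seed integer seed for reproducibility
#' @return a single character string over ACGT
#' @export
generate_genome <- function(length, gc_fraction = 0.42, seed = NULL) {
  stop_if(length(length) != 1 || !is.finite(length) || length <= 0,
          "`length` must be a single positive number")
  stop_if(gc_fraction < 0 || gc_fraction > 1,
          "`gc_fraction` must lie in [0, 1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                        collapse = ""))
}

#' Describe a planted binding site
#'
#' @param class one of "NONE", "E1", "E1E2"
#' @param position 0-based genome coordinate of the E1 start (for NONE, of the
#'   site point itself)
#' @param strength expected peak tag count at the site
#' @param phase ZT hour of peak binding, in \[0, 24)
#' @param rel_amplitude relative cosine amplitude in \[0, 1\]
#' @param spacer spacer length in bp between the E1 and E2 hexamers
#'   (E1E2 only)
#' @return one-row data.table (a SiteSpec)
#' @export
site_spec <- function(class = c("E1E2", "E1", "NONE"), position, strength = 500,
                      phase = 6, rel_amplitude = 0.8, spacer = NA_integer_) {
  class <- match.arg(class)
  stop_if(class == "E1E2" && (is.na(spacer) || spacer < 0),
          "E1E2 sites need a non-negative `spacer`")
  stop_if(class != "E1E2" && !is.na(spacer),
          "`spacer` is only meaningful for E1E2 sites")
  stop_if(rel_amplitude < 0 || rel_amplitude > 1,
          "`rel_amplitude` must lie in [0, 1]")
  data.table(class = class, spacer = as.integer(spacer),
             position = as.integer(position), strength = as.numeric(strength),
             phase = wrap24(phase), rel_amplitude = as.numeric(rel_amplitude))
}

E1_CONSENSUS <- "CACGTG"
E2_CONSENSUS <- "AACGTG"

site_footprint <- function(class, spacer) {
  ifelse(class == "E1E2", 12L + as.integer(spacer),
         ifelse(class == "E1", 6L, 0L))
}

#' Plant motif sites into a genome
#'
#' E1 sites write the canonical E-box CACGTG; E1E2 sites write
#' CACGTG + spacer background bases + AACGTG (the non-canonical box).
#' NONE sites leave the sequence untouched. The returned truth records exact
#' coordinates including the tag-source center (the motif footprint midpoint).
#'
#' @param genome character string genome
#' @param specs data.table of SiteSpecs (rbind of [site_spec()] rows)
#' @param kernel_mu,kernel_sd fragment 5'-offset kernel parameters in bp
#' @param background_rate background tags per bp per library-timepoint,
#'   expressed on the same scale as `strength`
#' @param timepoints ZT hours sampled
#' @param libraries ChIP library identifiers
#' @param seed seed used to draw spacer bases
#' @return list(genome = modified sequence, truth = SyntheticTruth)
#' @export
plant_sites <- function(genome, specs, kernel_mu = 100, kernel_sd = 25,
                        background_rate = 0, timepoints = DEFAULT_TIMEPOINTS,
                        libraries = c("libA", "libB"), seed = NULL) {
  stop_if(nrow(specs) == 0, "no site specs supplied")
  L <- nchar(genome)
  specs <- copy(as.data.table(specs))
  specs[, footprint := site_footprint(class, spacer)]
  specs[, center := as.integer(position + floor(footprint / 2))]
  stop_if(any(specs$position < 0 | specs$position + specs$footprint > L),
          "a site footprint exceeds the genome")
  occ <- specs[footprint > 0][order(position)]
  if (nrow(occ) > 1 &&
      any(occ$position[-1] < (occ$position + occ$footprint)[-nrow(occ)]))
    stop("planted site footprints overlap", call. = FALSE)
  chars <- strsplit(genome, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    for (i in seq_len(nrow(specs))) {
      s <- specs[i]
      if (s$class == "NONE") next
      word <- if (s$class == "E1") E1_CONSENSUS else
        paste0(E1_CONSENSUS,
               paste(sample(BASES, s$spacer, replace = TRUE), collapse = ""),
               E2_CONSENSUS)
      chars[(s$position + 1):(s$position + nchar(word))] <-
        strsplit(word, "", fixed = TRUE)[[1]]
    }
  })
  truth <- structure(list(
    sites = specs, genome_length = L, kernel_mu = kernel_mu,
    kernel_sd = kernel_sd, background_rate = background_rate,
    timepoints = sort(timepoints), libraries = libraries,
    chrom = "chrS"), class = "SyntheticTruth")
  list(genome = paste(chars, collapse = ""), truth = truth)
}

# Offsets from the site center to fragment 5' ends: Normal(mu, sd) truncated
# at zero, rounded to integer bp.
rtrunc_offset <- function(n, mu, sd) {
  if (sd <= 0) return(rep(round(mu), n))
  lo <- stats::pnorm(0, mu, sd)
  round(stats::qnorm(runif(n, lo, 1), mu, sd))
}

#' Simulate strand-specific circadian ChIP tags
#'
#' Each ChIP tag is drawn either from the uniform background or from a planted
#' site chosen with probability proportional to
#' strength * max(0, 1 + rel_amplitude * cos(2 pi (t - phase) / 24)).
#' Site tags take either strand with probability 1/2; plus-strand 5' ends fall
#' at center - offset and minus-strand ends at center + offset, with the
#' offset drawn from Normal(kernel_mu, kernel_sd) truncated at zero. The input
#' library contains background-only tags.
#'
#' @param truth SyntheticTruth from [plant_sites()]
#' @param depth tags per ChIP library per timepoint (the input library gets
#'   `depth` tags in total)
#' @param seed integer seed
#' @return data.table of tag records (chrom, pos, strand, library, timepoint);
#'   input records carry timepoint NA
#' @export
simulate_chip_tags <- function(truth, depth, seed = NULL) {
  stop_if(!inherits(truth, "SyntheticTruth"), "`truth` must be a SyntheticTruth")
  stop_if(nrow(truth$sites) == 0, "truth contains no sites")
  stop_if(depth <= 0, "`depth` must be positive")
  sites <- truth$sites
  L <- truth$genome_length
  bg_w <- truth$background_rate * L
  with_seed(seed, {
    recs <- vector("list", 0L)
    for (lib in truth$libraries) for (t in truth$timepoints) {
      mod <- pmax(0, 1 + sites$rel_amplitude *
                       cos(2 * pi * (t - sites$phase) / 24))
      w <- c(bg_w, sites$strength * mod)
      counts <- as.vector(rmultinom(1, depth, w))
      n_bg <- counts[1]
      pos <- integer(0); strand <- character(0)
      if (n_bg > 0) {
        pos <- sample.int(L, n_bg, replace = TRUE) - 1L
        strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      }
      for (i in seq_len(nrow(sites))) {
        n_i <- counts[i + 1]
        if (n_i == 0) next
        st <- sample(c("+", "-"), n_i, replace = TRUE)
        off <- rtrunc_offset(n_i, truth$kernel_mu, truth$kernel_sd)
        p <- ifelse(st == "+", sites$center[i] - off, sites$center[i] + off)
        pos <- c(pos, pmin(pmax(p, 0L), L - 1L))
        strand <- c(strand, st)
      }
      recs[[length(recs) + 1]] <- data.table(
        chrom = truth$chrom, pos = as.integer(pos), strand = strand,
        library = lib, timepoint = t)
    }
    n_in <- round(depth)
    recs[[length(recs) + 1]] <- data.table(
      chrom = truth$chrom,
      pos = sample.int(L, n_in, replace = TRUE) - 1L,
      strand = sample(c("+", "-"), n_in, replace = TRUE),
      library = "input", timepoint = NA_real_)
    rbindlist(recs)
  })
}

#' Draw a realistic set of site specifications
#'
#' Defaults emulate the study conditions of a liver circadian
#' transcription-factor time course: binding phases concentrated near ZT6,
#' strong relative amplitudes, peak strengths spanning one order of magnitude
#' (100-1000 tags), and tandem elements with 6-7 bp spacers.
#'
#' @param n number of sites
#' @param genome_length genome size in bp
#' @param class_probs probabilities for classes NONE, E1, E1E2
#' @param min_gap minimum distance between site positions in bp
#' @param seed integer seed
#' @return data.table of SiteSpecs
#' @export
random_site_specs <- function(n, genome_length,
                              class_probs = c(NONE = 0.2, E1 = 0.4, E1E2 = 0.4),
                              min_gap = 2000, seed = NULL) {
  stop_if(n * min_gap > genome_length * 0.8,
          "genome too small for `n` sites at `min_gap` spacing")
  with_seed(seed, {
    margin <- 1000
    slots <- seq(margin, genome_length - margin - 40, by = min_gap)
    stop_if(length(slots) < n, "not enough slots for the requested sites")
    pos <- sort(sample(slots, n)) +
      sample.int(min(min_gap %/% 2, 500), n, replace = TRUE)
    cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
    rbindlist(lapply(seq_len(n), function(i) {
      site_spec(class = cls[i], position = pos[i],
                strength = runif(1, 100, 1000),
                phase = wrap24(rnorm(1, mean = 6, sd = 1.5)),
                rel_amplitude = runif(1, 0.5, 1),
                spacer = if (cls[i] == "E1E2") sample(6:7, 1) else NA_integer_)
    }))
  })
}

#' Simulate a motif-activity expression data set
#'
#' Builds E = N A + I + noise: a non-negative site-count matrix N (genes x
#' motifs), motif activities A (motifs x timepoints), per-timepoint
#' intercepts I, and i.i.d. Gaussian noise.
#'
#' @param n_genes number of genes (> 0)
#' @param n_motifs number of motifs
#' @param timepoints ZT hours
#' @param activities optional motifs x timepoints activity matrix; by default
#'   cosine profiles with random phases and unit-scale amplitudes
#' @param noise_sd Gaussian noise standard deviation (>= 0)
#' @param seed integer seed
#' @return list(expression, site_counts, activities, intercepts, timepoints)
#' @export
simulate_expression <- function(n_genes, n_motifs = 5,
                                timepoints = DEFAULT_TIMEPOINTS,
                                activities = NULL, noise_sd = 0.1,
                                seed = NULL) {
  stop_if(n_genes <= 0, "`n_genes` must be positive")
  stop_if(noise_sd < 0, "`noise_sd` must be non-negative")
  with_seed(seed, {
    Tn <- length(timepoints)
    if (is.null(activities)) {
      ph <- runif(n_motifs, 0, 24); amp <- runif(n_motifs, 0.5, 1.5)
      activities <- t(sapply(seq_len(n_motifs), function(m)
        amp[m] * cos(2 * pi * (timepoints - ph[m]) / 24)))
    }
    stop_if(nrow(activities) != n_motifs || ncol(activities) != Tn,
            "`activities` must be n_motifs x length(timepoints)")
    N <- matrix(rpois(n_genes * n_motifs, lambda = 1.5) *
                  runif(n_genes * n_motifs, 0.5, 1.5),
                n_genes, n_motifs)
    intercepts <- rnorm(Tn, 0, 0.2)
    E <- N %*% activities + matrix(intercepts, n_genes, Tn, byrow = TRUE) +
      matrix(rnorm(n_genes * Tn, 0, noise_sd), n_genes, Tn)
    dimnames(E) <- list(paste0("g", seq_len(n_genes)),
                        paste0("ZT", timepoints))
    dimnames(N) <- list(rownames(E), paste0("m", seq_len(n_motifs)))
    dimnames(activities) <- list(colnames(N), colnames(E))
    list(expression = E, site_counts = N, activities = activities,
         intercepts = intercepts, timepoints = timepoints)
  })
}
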