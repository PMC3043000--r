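# Configuration-driven pipeline: tags -> regions -> deconvolution ->
# quantification -> rhythm -> motif -> annotation -> activities, with a run
# manifest and resumable intermediates.

#' Default pipeline configuration
#'
#' @param outdir output directory
#' @param seed integer seed recorded in the manifest and used by the
#'   simulation stage
#' @return nested configuration list
#' @export
default_config <- function(outdir = tempfile("circaseq_run_"), seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    paths = list(tags = NULL, genome = NULL, transcripts = NULL,
                 conservation = NULL, expression = NULL,
                 site_counts = NULL, regions = NULL),
    simulate = NULL,
    detect = list(window = 300, min_fold = 1.2, alpha = 0.01),
    deconvolve = list(grid_step = 10, penalty = 0, max_iter = 500,
                      tol = 1e-8),
    call = list(min_separation = 100, min_intensity = 5,
                min_rel_intensity = 0.2),
    reject = list(halfwidth = 250, min_tags = 10, min_fold = 1.2,
                  min_strand_frac = 0.2),
    quantify = list(halfwidth = 250),
    rhythm = list(period = 24, p_threshold = 0.05),
    motif = list(halfwidth = 50, max_iter = 30, tol = 1e-3),
    annotate = list(max_distance = 10000, coding_only = FALSE))
}

#' Default synthetic-demo simulation block
#'
#' The background fraction defaults to 0.8: in a real ChIP library the large
#' majority of tags are unenriched background (the strongest sites in a
#' liver time course hold on the order of 200 tags per 1e7 mapped), and the
#' per-library-timepoint rescaling only preserves binding rhythms when site
#' tags are a minority of each library.
#'
#' @param genome_length,n_sites,depth demo scale
#' @return list for `config$simulate`
#' @export
demo_simulation <- function(genome_length = 1e6, n_sites = 100,
                            depth = 1e5) {
  list(genome_length = genome_length, n_sites = n_sites, depth = depth,
       gc_fraction = 0.42, kernel_mu = 100, kernel_sd = 25,
       background_fraction = 0.8)
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (or path to a YAML file)
#' @return normalized configuration; stops with a descriptive error on
#'   schema violations
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stop_if(!is.list(config), "config must be a list or YAML path")
  config <- modifyList(default_config(), config)
  stop_if(is.null(config$outdir), "config: `outdir` is required")
  if (is.null(config$simulate)) {
    stop_if(is.null(config$paths$tags),
            "config: `paths$tags` is required unless `simulate` is set")
    stop_if(is.null(config$paths$genome),
            "config: `paths$genome` is required unless `simulate` is set")
    for (p in Filter(Negate(is.null), config$paths))
      stop_if(!file.exists(p), paste("config: missing input file:", p))
  }
  config
}

config_hash <- function(config) {
  b <- as.integer(serialize(config, NULL, version = 2))
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", h)
}

write_tsv_with_hash <- function(dt, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
}

#' Run the full pipeline
#'
#' Executes the stages in order: (optional) simulation of synthetic inputs,
#' tag processing, region detection, kernel estimation and deconvolution,
#' site calling and rejection, window quantification, rhythm statistics,
#' tandem-HMM motif classification, annotation, and (when expression inputs
#' are available) motif-activity inference. Writes the site table, regions,
#' model, activities and a run manifest into `config$outdir`.
#'
#' @param config configuration list or YAML path (see [default_config()])
#' @param resume reuse intermediates already present in `outdir`
#' @return invisible list(sites, regions, kernel, hmm, activities, manifest)
#' @export
run_pipeline <- function(config, resume = FALSE) {
  config <- validate_config(config)
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf("[circaseq %s] ", hash),
                                     sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)   # analysis stages with randomness are reproducible

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- modifyList(demo_simulation(), config$simulate)
    log_stage("simulate: genome %g bp, %d sites, depth %g",
              sim$genome_length, sim$n_sites, sim$depth)
    genome0 <- generate_genome(sim$genome_length, sim$gc_fraction,
                               seed = config$seed)
    specs <- random_site_specs(sim$n_sites, sim$genome_length,
                               seed = config$seed + 1)
    total_strength <- sum(specs$strength)
    bg_rate <- sim$background_fraction /
      (1 - sim$background_fraction) * total_strength / sim$genome_length
    planted <- plant_sites(genome0, specs, kernel_mu = sim$kernel_mu,
                           kernel_sd = sim$kernel_sd,
                           background_rate = bg_rate,
                           seed = config$seed + 2)
    tags <- simulate_chip_tags(planted$truth, depth = sim$depth,
                               seed = config$seed + 3)
    config$paths$tags <- file.path(out, "tags.bed")
    config$paths$genome <- file.path(out, "genome.fa")
    write_tags_bed(tags, config$paths$tags)
    write_genome_fasta(setNames(planted$genome, planted$truth$chrom),
                       config$paths$genome)
    write_truth(planted$truth, file.path(out, "truth"))
    truth <- planted$truth
  }

  log_stage("tags: reading %s", config$paths$tags)
  tags <- deduplicate(read_tags_bed(config$paths$tags))
  genome <- read_genome_fasta(config$paths$genome)
  chrom_sizes <- setNames(nchar(genome), names(genome))
  is_input <- tags$library == "input" | is.na(tags$timepoint)
  chip <- normalize_and_merge(tags[!is_input], chrom_sizes)
  input <- if (any(is_input))
    normalize_and_merge(tags[is_input], chrom_sizes) else NULL
  write_bedgraph_tracks(chip, file.path(out, "tracks"))

  log_stage("site discovery")
  sites_path <- file.path(out, "sites.tsv")
  raw_path <- file.path(out, "site_calls.tsv")
  if (resume && file.exists(raw_path)) {
    log_stage("resume: reusing %s", raw_path)
    sites <- fread(raw_path, skip = 1)
    regions <- NULL
    kernel <- NULL
  } else {
    sites <- discover_sites(
      chip, input,
      detect_args = config$detect,
      deconvolve_args = config$deconvolve,
      call_args = config$call,
      criteria = config$reject)
    regions <- attr(sites, "regions")
    kernel <- attr(sites, "kernel")
    write_tsv_with_hash(as.data.table(sites), raw_path, hash)
  }
  if (!is.null(regions) && nrow(regions) > 0)
    write_tsv_with_hash(regions, file.path(out, "regions.tsv"), hash)
  if (!is.null(kernel))
    jsonlite::write_json(unclass(kernel), file.path(out, "kernel.json"),
                         auto_unbox = TRUE, digits = NA)
  rej <- attr(sites, "rejections")
  if (!is.null(rej) && nrow(rej) > 0)
    log_stage("rejected %d spurious call(s)", nrow(rej))
  if (nrow(sites) == 0) {
    log_stage("no sites discovered; stopping after site stage")
    write_tsv_with_hash(as.data.table(sites), sites_path, hash)
    return(invisible(list(sites = sites, regions = regions,
                          kernel = kernel)))
  }

  log_stage("quantification and rhythm statistics (%d sites)", nrow(sites))
  sig <- quantify_sites(chip, sites, config$quantify$halfwidth)
  colnames(sig) <- paste0("signal_ZT", chip$timepoints)
  rhythm <- rhythm_stats_matrix(sig, chip$timepoints,
                                config$rhythm$period, adjust = TRUE)
  sites <- cbind(sites, as.data.table(sig), rhythm)
  sites[, peak_signal := apply(sig, 1, max)]

  log_stage("motif model")
  hw <- config$motif$halfwidth
  windows <- vapply(seq_len(nrow(sites)), function(i) {
    ch <- genome[[sites$chrom[i]]]
    lo <- max(0, sites$position[i] - hw)
    hi <- min(nchar(ch) - 1, sites$position[i] + hw)
    substr(ch, lo + 1, hi + 1)
  }, character(1))
  hmm <- NULL
  if (length(windows) >= 10) {
    hmm <- train_tandem_hmm(windows, weights = sites$peak_signal,
                            max_iter = config$motif$max_iter,
                            tol = config$motif$tol)
    calls <- classify_sites(hmm, windows)
    sites[, `:=`(motif_class = calls$class, motif_spacer = calls$spacer,
                 motif_score = calls$score, motif_offset = calls$offset)]
    write_hmm_json(hmm, file.path(out, "hmm.json"))
  } else {
    log_stage("too few sites (%d) to train the tandem HMM", length(windows))
  }

  if (!is.null(config$paths$transcripts)) {
    log_stage("annotation")
    tx <- read_transcripts_gtf(config$paths$transcripts)
    sites <- assign_targets(sites, tx, config$annotate$max_distance,
                            config$annotate$coding_only)
    if (!is.null(config$paths$conservation)) {
      cons <- read_conservation_bedgraph(config$paths$conservation)
      sites[, conservation := vapply(seq_len(.N), function(i)
        conservation_score(position[i], chrom[i], cons), numeric(1))]
    }
  }

  activities <- NULL
  if (!is.null(config$paths$expression) &&
      !is.null(config$paths$site_counts)) {
    log_stage("activity inference")
    E <- as.matrix(fread(config$paths$expression), rownames = 1)
    N <- as.matrix(fread(config$paths$site_counts), rownames = 1)
    tp <- as.numeric(sub("^.*ZT", "", colnames(E)))
    activities <- infer_activities(E, N, tp)
    act_dt <- data.table(motif = rownames(activities$activities),
                         as.data.table(activities$activities))
    write_tsv_with_hash(act_dt, file.path(out, "activities.tsv"), hash)
    cyc <- cyclic_activity_test(activities)
    write_tsv_with_hash(cyc, file.path(out, "activity_rhythm.tsv"), hash)
  }

  write_tsv_with_hash(sites, sites_path, hash)
  manifest <- list(
    package = "circaseq",
    version = as.character(utils::packageVersion("circaseq")),
    seed = config$seed, config_hash = hash, config = config,
    n_sites = nrow(sites),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("done: %d sites in %.1f s", nrow(sites),
            manifest$elapsed_seconds)
  invisible(list(sites = sites, regions = regions, kernel = kernel,
                 hmm = hmm, activities = activities, manifest = manifest,
                 truth = truth))
}
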