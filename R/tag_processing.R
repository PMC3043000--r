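# Tag processing: PCR de-duplication, per-library rescaling to tags per 1e7,
# merging across libraries, and window quantification.

#' Remove PCR duplicates
#'
#' Reads from the same sequencing unit (library at a given timepoint) that map
#' to the same genomic position on the same strand are collapsed to a single
#' tag. Tags at the same position on opposite strands are both kept.
#'
#' @param tags data.table of tag records (chrom, pos, strand, library,
#'   timepoint)
#' @return de-duplicated data.table, sorted for order-independence
#' @export
deduplicate <- function(tags) {
  tags <- as.data.table(tags)
  out <- unique(tags, by = c("library", "timepoint", "chrom", "pos", "strand"))
  setorder(out, library, timepoint, chrom, pos, strand, na.last = TRUE)
  out[]
}

#' Build a normalized, merged tag track
#'
#' Each tag is rescaled to tags per 1e7 within its sequencing unit (library x
#' timepoint), then units covering the same timepoint are summed per position
#' and strand. Sum of weights over the genome for one timepoint is therefore
#' 1e7 times the number of libraries covering it.
#'
#' @param tags de-duplicated tag records
#' @param chrom_sizes named vector of chromosome lengths (optional; inferred
#'   as max position + 1 when missing)
#' @return a TagTrack: list(tags = data.table(chrom, pos, strand, timepoint,
#'   weight, count), unit_totals, timepoints, libraries, chrom_sizes)
#' @export
normalize_and_merge <- function(tags, chrom_sizes = NULL) {
  tags <- as.data.table(tags)
  stop_if(nrow(tags) == 0, "no tags supplied")
  totals <- tags[, .(total = .N), by = .(library, timepoint)]
  stop_if(any(totals$total == 0), "empty library (missing data)")
  merged <- tags[totals, on = c("library", "timepoint")][
    , .(weight = sum(1e7 / total), count = .N),
    by = .(chrom, pos, strand, timepoint)]
  setorder(merged, timepoint, chrom, pos, strand, na.last = TRUE)
  if (is.null(chrom_sizes)) {
    cs <- tags[, .(size = max(pos) + 1L), by = chrom]
    chrom_sizes <- setNames(cs$size, cs$chrom)
  }
  structure(list(
    tags = merged[],
    unit_totals = totals,
    timepoints = sort(unique(tags$timepoint), na.last = TRUE),
    libraries = sort(unique(tags$library)),
    chrom_sizes = chrom_sizes), class = "TagTrack")
}

#' @export
print.TagTrack <- function(x, ...) {
  cat("TagTrack:", nrow(x$tags), "positions,",
      length(x$libraries), "libraries,",
      sum(!is.na(x$timepoints)), "timepoints\n")
  invisible(x)
}

#' Sum a TagTrack over timepoints (and optionally libraries)
#'
#' Used for region detection and deconvolution, which operate on the single
#' track in which all tags from all timepoints are merged.
#'
#' @param track a TagTrack
#' @param timepoints subset of timepoints to keep (default all non-input)
#' @return TagTrack with a single NA timepoint holding the summed weights
#' @export
collapse_timepoints <- function(track, timepoints = NULL) {
  tg <- track$tags
  if (!is.null(timepoints)) tg <- tg[timepoint %in% timepoints]
  merged <- tg[, .(weight = sum(weight), count = sum(count)),
               by = .(chrom, pos, strand)]
  merged[, timepoint := NA_real_]
  out <- track
  out$tags <- merged[]
  out$timepoints <- NA_real_
  out
}

#' Quantify signal in a window around a position
#'
#' Sums normalized weights on both strands over the closed interval
#' \[center - halfwidth, center + halfwidth\], clipped at chromosome bounds.
#'
#' @param track a TagTrack
#' @param chrom chromosome name
#' @param center 0-based window center
#' @param halfwidth window half-width in bp (default 250)
#' @return named numeric vector of per-timepoint summed weights
#' @export
quantify_window <- function(track, chrom, center, halfwidth = 250) {
  stop_if(halfwidth <= 0, "`halfwidth` must be positive")
  stop_if(!chrom %in% names(track$chrom_sizes), "unknown chromosome")
  lo <- max(0, center - halfwidth)
  hi <- min(track$chrom_sizes[[chrom]] - 1, center + halfwidth)
  tps <- track$timepoints
  ch <- chrom
  sub <- track$tags[chrom == ch & pos >= lo & pos <= hi]
  out <- setNames(numeric(length(tps)), paste0("ZT", tps))
  if (nrow(sub)) {
    agg <- sub[, .(w = sum(weight)), by = timepoint]
    idx <- match(agg$timepoint, tps)
    idx[is.na(agg$timepoint)] <- which(is.na(tps))[1]
    out[idx] <- agg$w
  }
  out
}

#' Quantify windows for many sites at once
#'
#' @param track a TagTrack
#' @param sites data.table with columns chrom, position
#' @param halfwidth window half-width in bp
#' @return matrix sites x timepoints of summed weights
#' @export
quantify_sites <- function(track, sites, halfwidth = 250) {
  t(vapply(seq_len(nrow(sites)),
           function(i) quantify_window(track, sites$chrom[i],
                                       sites$position[i], halfwidth),
           numeric(length(track$timepoints))))
}
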