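# Site annotation: nearest-TSS assignment, positional categories,
# conservation scoring, expressed-gene filtering, target assignment and
# control regions. Coordinates are 0-based; distances are signed in the
# transcript's orientation (negative = upstream of the TSS).

signed_tss_distance <- function(position, tss, strand) {
  ifelse(strand == "+", position - tss, tss - position)
}

#' Annotate a site with the transcript having the closest TSS
#'
#' Ties in |distance| are broken by the lexicographically smallest transcript
#' id, for determinism.
#'
#' @param position site coordinate (0-based)
#' @param chrom site chromosome
#' @param transcripts TranscriptRecord data.table (id, chrom, strand, tss,
#'   tes, ...)
#' @return list(transcript = one-row data.table, distance = signed bp)
#' @export
nearest_tss <- function(position, chrom, transcripts) {
  transcripts <- as.data.table(transcripts)
  keep <- which(transcripts$chrom == chrom)
  cand <- transcripts[keep]
  stop_if(nrow(cand) == 0, "no transcripts on the site's chromosome")
  d_abs <- abs(position - cand$tss)
  ord <- order(d_abs, cand$id)
  hit <- cand[ord[1]]
  list(transcript = hit,
       distance = signed_tss_distance(position, hit$tss, hit$strand))
}

#' Positional category of a site relative to its transcript
#'
#' promoter: within +/-2 kb of the TSS; upstream: -10 kb to -2 kb;
#' gene: +2 kb to the polyadenylation site; downstream: polyadenylation site
#' to +10 kb; other: anything else. Evaluated in transcript orientation.
#'
#' @param distance signed TSS distance in bp (transcript orientation)
#' @param transcript one-row transcript record (for the gene length)
#' @param promoter_halfwidth,flank_size category bounds in bp
#' @return one of "promoter", "upstream", "gene", "downstream", "other"
#' @export
categorize_site <- function(distance, transcript, promoter_halfwidth = 2000,
                            flank_size = 10000) {
  gene_len <- abs(transcript$tes - transcript$tss)
  if (abs(distance) <= promoter_halfwidth) return("promoter")
  if (distance < 0) {
    if (distance >= -flank_size) return("upstream")
    return("other")
  }
  if (distance <= gene_len) return("gene")
  if (distance <= gene_len + flank_size) return("downstream")
  "other"
}

#' Maximal conservation score around a site
#'
#' Maximum of the per-base conservation over the closed window
#' \[site - halfwidth, site + halfwidth\]; positions absent from the track
#' count as 0.
#'
#' @param position site coordinate
#' @param chrom chromosome
#' @param track ConservationTrack data.table (chrom, pos, score)
#' @param halfwidth window half-width in bp (default 50)
#' @return maximal score in \[0, 1\]
#' @export
conservation_score <- function(position, chrom, track, halfwidth = 50) {
  track <- as.data.table(track)
  stop_if(!chrom %in% track$chrom, "unknown chromosome in conservation track")
  ch <- chrom
  sub <- track[chrom == ch & pos >= position - halfwidth &
                 pos <= position + halfwidth]
  if (nrow(sub) == 0) 0 else max(max(sub$score), 0)
}

#' Filter transcripts to the expressed subset
#'
#' Keeps transcripts whose expression lies strictly above the given
#' percentile of the supplied expression distribution.
#'
#' @param transcripts data.table with an `expression` column
#' @param percentile percentile cutoff (default 50)
#' @return expressed subset; attribute "threshold" holds the cutoff value
#' @export
expressed_filter <- function(transcripts, percentile = 50) {
  transcripts <- as.data.table(transcripts)
  stop_if(!"expression" %in% names(transcripts) ||
            all(is.na(transcripts$expression)), "no expression data")
  thr <- quantile(transcripts$expression, percentile / 100, na.rm = TRUE,
                  names = FALSE)
  out <- transcripts[!is.na(expression) & expression > thr]
  attr(out, "threshold") <- thr
  out
}

#' Assign sites to target transcripts
#'
#' Each site is assigned the transcript with the nearest TSS, kept only when
#' |distance| does not exceed `max_distance`; optionally restricted to
#' protein-coding transcripts.
#'
#' @param sites data.table(chrom, position, ...)
#' @param transcripts TranscriptRecord data.table
#' @param max_distance assignment window in bp (default 10 kb)
#' @param coding_only restrict to biotype "coding"
#' @return sites with target_id, target_distance, target_category columns
#'   (NA where unassigned)
#' @export
assign_targets <- function(sites, transcripts, max_distance = 10000,
                           coding_only = FALSE) {
  sites <- copy(as.data.table(sites))
  transcripts <- as.data.table(transcripts)
  if (coding_only) transcripts <- transcripts[biotype == "coding"]
  n <- nrow(sites)
  ids <- rep(NA_character_, n); dist <- rep(NA_real_, n)
  cat <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cand <- transcripts[chrom == sites$chrom[i]]
    if (nrow(cand) == 0) next
    nt <- nearest_tss(sites$position[i], sites$chrom[i], cand)
    if (abs(nt$distance) > max_distance) next
    ids[i] <- nt$transcript$id
    dist[i] <- nt$distance
    cat[i] <- categorize_site(nt$distance, nt$transcript)
  }
  sites[, `:=`(target_id = ids, target_distance = dist,
               target_category = cat)]
  sites[]
}

#' Control region downstream of a site
#'
#' A window of the same width centered 500 bp downstream of the site in the
#' genome's + direction (sites are strandless points). Sites whose control
#' window would leave the chromosome are flagged.
#'
#' @param position site coordinate
#' @param halfwidth window half-width in bp
#' @param chrom_size chromosome length in bp
#' @param offset control-center offset in bp (default 500)
#' @return list(start, end, center, ok); 0-based half-open interval
#' @export
control_region <- function(position, halfwidth, chrom_size, offset = 500) {
  center <- position + offset
  start <- center - halfwidth
  end <- center + halfwidth + 1
  list(start = start, end = end, center = center,
       ok = start >= 0 && end <= chrom_size)
}
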