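# File interfaces. Coordinates are 0-based half-open on disk (BED/bedGraph)
# and 0-based points in memory; GTF's 1-based closed convention is converted
# at the boundary.

#' Write tag records as BED6
#'
#' One record per tag: chrom, start, start+1, name = "library:timepoint",
#' score 1, strand. Input-library tags (timepoint NA) use "library:NA".
#'
#' @param tags tag record data.table
#' @param path output file
#' @export
write_tags_bed <- function(tags, path) {
  bed <- data.table(chrom = tags$chrom, start = tags$pos,
                    end = tags$pos + 1L,
                    name = paste(tags$library, tags$timepoint, sep = ":"),
                    score = 1L, strand = tags$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
}

#' Read tag records from BED6
#'
#' @param path BED6 file written by [write_tags_bed()] (or any BED6 whose name
#'   field is "library:timepoint")
#' @return tag record data.table
#' @export
read_tags_bed <- function(path) {
  bed <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand"))
  parts <- tstrsplit(bed$name, ":", fixed = TRUE)
  data.table(chrom = bed$chrom, pos = as.integer(bed$start),
             strand = bed$strand, library = parts[[1]],
             timepoint = suppressWarnings(as.numeric(parts[[2]])))
}

#' Write a genome as FASTA
#' @param genome character string (or named character vector of chromosomes)
#' @param path output file
#' @param name sequence name used when `genome` is unnamed
#' @export
write_genome_fasta <- function(genome, path, name = "chrS") {
  if (is.null(names(genome))) names(genome) <- rep(name, length(genome))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write per-timepoint bedGraph coverage tracks
#'
#' Strands are merged; one file per timepoint, suitable for browser display.
#'
#' @param track a TagTrack
#' @param dir output directory
#' @param prefix file-name prefix
#' @return invisibly, the written paths
#' @export
write_bedgraph_tracks <- function(track, dir, prefix = "coverage") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in track$timepoints) {
    tg <- if (is.na(t)) track$tags[is.na(timepoint)] else
      track$tags[timepoint == t]
    agg <- tg[, .(value = sum(weight)), by = .(chrom, pos)][order(chrom, pos)]
    out <- data.table(chrom = agg$chrom, start = agg$pos,
                      end = agg$pos + 1L, value = round(agg$value, 4))
    p <- file.path(dir, sprintf("%s_ZT%s.bedGraph", prefix,
                                ifelse(is.na(t), "all", t)))
    fwrite(out, p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a bedGraph/wig-style conservation track
#'
#' @param path bedGraph file (chrom, start, end, score), scores in \[0, 1\]
#' @return ConservationTrack: data.table(chrom, pos, score) expanded per base
#' @export
read_conservation_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = gr$score)
  n <- dt$end - dt$start
  data.table(chrom = rep(dt$chrom, n),
             pos = as.integer(unlist(Map(seq.int, dt$start, dt$end - 1L))),
             score = rep(dt$score, n))
}

#' Read transcript annotation from GTF/GFF
#'
#' Extracts one record per transcript with its TSS/TES in 0-based
#' coordinates, oriented by strand.
#'
#' @param path GTF/GFF file with transcript features
#' @return TranscriptRecord data.table (id, chrom, strand, tss, tes, biotype)
#' @export
read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "transcript"]
  plus <- as.character(GenomicRanges::strand(gr)) != "-"
  data.table(
    id = if (!is.null(gr$transcript_id)) gr$transcript_id else
      paste0("tx", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = ifelse(plus, "+", "-"),
    tss = ifelse(plus, GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr) - 1L),
    tes = ifelse(plus, GenomicRanges::end(gr) - 1L,
                 GenomicRanges::start(gr) - 1L),
    biotype = if (!is.null(gr$transcript_biotype)) gr$transcript_biotype
              else "coding")
}

#' Write the synthetic ground truth
#'
#' Site table as TSV plus generator parameters as JSON.
#' @param truth SyntheticTruth
#' @param prefix output path prefix (writes prefix.tsv and prefix.json)
#' @export
write_truth <- function(truth, prefix) {
  fwrite(truth$sites, paste0(prefix, ".tsv"), sep = "\t")
  meta <- truth[setdiff(names(truth), "sites")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
}
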