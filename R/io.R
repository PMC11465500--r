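#' Read and write the standard text formats
#'
#' Thin, lossless wrappers around Biostrings / data.table for the formats
#' the workflow touches: FASTA, 4-line Phred+33 FASTQ, 3-column BED
#' (0-based half-open), and tab-separated beta tracks. FASTQ structure is
#' pre-validated so malformed files fail with the offending line number.
#'
#' @param path file path.
#' @param genome a `toy_genome` (FASTA writer).
#' @name io
NULL

#' @rdname io
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  structure(list(name = names(x)[1],
                 sequence = as.character(x[[1]]),
                 cgi_intervals = data.frame(start = integer(0), end = integer(0))),
            class = "toy_genome")
}

#' @rdname io
#' @param fastq `data.table` with `read_id`, `seq`, `qual`.
#' @export
write_fastq <- function(fastq, path) {
  lines <- character(4L * nrow(fastq))
  lines[seq(1, length(lines), 4)] <- paste0("@", fastq$read_id)
  lines[seq(2, length(lines), 4)] <- fastq$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- fastq$qual
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("read_fastq: truncated FASTQ record starting at line ",
         (n %/% 4L) * 4L + 1L, call. = FALSE)
  id_lines <- seq(1, n, 4)
  bad <- id_lines[!startsWith(lines[id_lines], "@")]
  if (length(bad))
    stop("read_fastq: expected '@' header at line ", bad[1], call. = FALSE)
  plus <- seq(3, n, 4)
  bad <- plus[!startsWith(lines[plus], "+")]
  if (length(bad))
    stop("read_fastq: expected '+' separator at line ", bad[1], call. = FALSE)
  data.table::data.table(
    read_id = sub("^@", "", sub(" .*", "", lines[id_lines])),
    seq = lines[seq(2, n, 4)],
    qual = lines[seq(4, n, 4)])
}

#' @rdname io
#' @param intervals data.frame with 0-based half-open `start`, `end`.
#' @param chrom chromosome name for BED output.
#' @export
write_bed <- function(intervals, path, chrom = "toy1") {
  dt <- data.table::data.table(chrom = chrom,
                               start = intervals$start, end = intervals$end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("read_bed: expected >= 3 columns", call. = FALSE)
  data.frame(chrom = dt[[1]], start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]))
}

#' @rdname io
#' @param track a beta-track `data.table` (see [beta_track()]).
#' @export
write_beta_track <- function(track, path) {
  data.table::fwrite(track, path, sep = "\t")
  invisible(path)
}

#' @rdname io
#' @export
read_beta_track <- function(path) {
  data.table::fread(path, sep = "\t")
}

#' @rdname io
#' @param truth truth-read table from [sequence_reads()].
#' @export
write_truth_reads <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname io
#' @param methylome a [build_methylome()] result.
#' @export
write_truth_methylome <- function(methylome, path) {
  dt <- data.table::data.table(pos0 = methylome$pos,
                               pos1 = methylome$pos + 1L,
                               beta = methylome$beta)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write every artefact of a simulated library to a directory
#'
#' Emits `reads.fastq`, `genome.fasta`, `cgi.bed`, `truth_methylome.tsv`
#' and `truth_reads.tsv`.
#'
#' @param lib a [simulate_library()] result.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_library <- function(lib, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(lib$fastq, file.path(outdir, "reads.fastq"))
  write_genome_fasta(lib$genome, file.path(outdir, "genome.fasta"))
  write_bed(lib$genome$cgi_intervals, file.path(outdir, "cgi.bed"),
            chrom = lib$genome$name)
  write_truth_methylome(lib$methylome, file.path(outdir, "truth_methylome.tsv"))
  write_truth_reads(lib$truth, file.path(outdir, "truth_reads.tsv"))
  invisible(outdir)
}
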