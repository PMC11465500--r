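#' Methylation contrast inside versus outside CpG islands
#'
#' Aggregates methylated / total call counts separately for positions inside
#' and outside the island intervals (membership by `position` in
#' `[start, end)`), and returns the two percentages and their difference
#' (outside minus inside). Vertebrate CGIs are hypomethylated, so the
#' difference is expected positive.
#'
#' @param calls `data.table` from [pileup_calls()].
#' @param cgi_intervals data.frame with sorted half-open `start`, `end`.
#' @return list with `mc_pct_inside`, `mc_pct_outside`, `difference`
#'   (NA when a side has no calls).
#' @export
cgi_contrast <- function(calls, cgi_intervals) {
  inside <- in_intervals(calls$position, cgi_intervals)
  pct <- function(sel) {
    nm <- sum(calls$n_methylated[sel])
    den <- nm + sum(calls$n_unmethylated[sel])
    if (den == 0) NA_real_ else 100 * nm / den
  }
  p_in <- pct(inside); p_out <- pct(!inside)
  list(mc_pct_inside = p_in, mc_pct_outside = p_out,
       difference = p_out - p_in)
}

#' Read-length frequency distributions
#'
#' `length_frequency` tabulates the relative frequency of each read length
#' (frequencies sum to 1). `compare_length_sets` aligns several samples'
#' frequency tables on a common length grid and reports mean and SD per
#' length.
#'
#' @param lengths integer vector of read or fragment lengths (or a
#'   `data.table` with a `seq` column, in which case `nchar(seq)` is used).
#' @return `data.table` with `length`, `count`, `frequency`.
#' @export
length_frequency <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- nchar(lengths$seq)
  if (length(lengths) == 0L) stop("length_frequency: empty input", call. = FALSE)
  tab <- table(lengths)
  data.table::data.table(length = as.integer(names(tab)),
                         count = as.integer(tab),
                         frequency = as.numeric(tab) / length(lengths))
}

#' @rdname length_frequency
#' @param sets named list of length vectors (or tables as above).
#' @export
compare_length_sets <- function(sets) {
  freqs <- lapply(sets, length_frequency)
  grid <- sort(unique(unlist(lapply(freqs, `[[`, "length"))))
  mat <- vapply(freqs, function(f) {
    v <- numeric(length(grid))
    v[match(f$length, grid)] <- f$frequency
    v
  }, numeric(length(grid)))
  data.table::data.table(length = grid,
                         mean = rowMeans(mat),
                         sd = apply(mat, 1L, stats::sd))
}

#' Library complexity by subsampling
#'
#' Reproduces the rarefaction analysis: starting at `start` reads and
#' doubling up to `max_n` (capped at the library size), subsample the
#' alignment table *without replacement* and count reads that survive
#' duplicate removal (unique (`position`, `end`, `strand_view`) keys). The
#' final table also carries the infinite-complexity diagonal
#' (`unique = subsample size`).
#'
#' @param alignments alignment `data.table` retaining duplicates.
#' @param start first subsample size.
#' @param max_n largest subsample size.
#' @return `data.table` of class `complexity_curve` with `subsample_size`,
#'   `unique_count`, `diagonal`.
#' @export
complexity_curve <- function(alignments, start = 350L, max_n = 1500000L) {
  total <- nrow(alignments)
  sizes <- start
  while (utils::tail(sizes, 1L) * 2L <= min(max_n, total))
    sizes <- c(sizes, utils::tail(sizes, 1L) * 2L)
  sizes <- sizes[sizes <= total]
  if (length(sizes) == 0L) sizes <- total
  key <- paste(alignments$position, alignments$end, alignments$strand_view)
  uniq <- vapply(sizes, function(n) {
    sub <- key[sample.int(total, n)]
    length(unique(sub))
  }, integer(1))
  out <- data.table::data.table(subsample_size = as.integer(sizes),
                                unique_count = uniq,
                                diagonal = as.integer(sizes))
  class(out) <- c("complexity_curve", class(out))
  out
}

#' Expected unique reads under uniform amplification
#'
#' Sampling `n` reads with replacement from `M` equally represented library
#' molecules yields `M * (1 - (1 - 1/M)^n)` unique molecules in expectation
#' -- the closed-form reference for [complexity_curve()].
#'
#' @param M number of unique library molecules.
#' @param n number of sequenced reads.
#' @return expected unique count.
#' @export
expected_unique <- function(M, n) {
  if (any(M < 1)) stop("expected_unique: M must be >= 1", call. = FALSE)
  if (any(n < 0)) stop("expected_unique: n must be >= 0", call. = FALSE)
  M * (1 - (1 - 1 / M)^n)
}

# wildcarded control match: template C positions accept C or T; elsewhere
# at most `max_other_mismatch` mismatches; lengths must be equal
match_control_template <- function(reads, template, max_other_mismatch = 1L) {
  tb <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(tb)
  cpos <- which(tb == "C")
  cand <- which(nchar(reads) == n)
  if (!length(cand)) return(list(idx = integer(0), cpos = cpos))
  m <- matrix(unlist(strsplit(reads[cand], "", fixed = TRUE)), nrow = n)
  mism <- m != tb
  if (length(cpos)) mism[cpos, ] <- mism[cpos, ] & m[cpos, , drop = FALSE] != "T"
  ok <- colSums(mism) <= max_other_mismatch
  list(idx = cand[ok], cpos = cpos,
       bases = if (any(ok)) m[, ok, drop = FALSE] else NULL)
}

#' Score the spiked methylation positive controls
#'
#' Reads are assigned to a control strand by a wildcarded sequence match:
#' every cytosine position of the 60-bp template accepts C or T (conversion
#' state unknown at match time) and at most one mismatch is tolerated
#' elsewhere; lengths must agree. For each matched read the 15 template-C
#' positions are scored as retained (read C, called methylated) or
#' deaminated/converted (read T).
#'
#' @param raw_reads `data.table` with `seq` (raw FASTQ reads) or character
#'   vector.
#' @param controls character vector of methylation control names.
#' @return list of class `control_report`: per control and strand, `n_reads`,
#'   `per_position` (`data.table`: position in template, retained,
#'   deaminated), `per_read_deaminated` (table of deaminated-C counts per
#'   read), plus `control_fraction` of all raw reads.
#' @export
score_positive_controls <- function(raw_reads,
                                    controls = c("control_full", "control_none")) {
  seqs <- if (is.data.frame(raw_reads)) raw_reads$seq else raw_reads
  out <- list()
  n_matched_total <- 0L
  for (ctl in controls) {
    top <- control_oligo_sequence(ctl)
    for (strand in c("top", "bottom")) {
      template <- if (strand == "top") top else revcomp_string(top)
      mt <- match_control_template(seqs, template)
      k <- length(mt$idx)
      n_matched_total <- n_matched_total + k
      per_pos <- data.table::data.table(
        template_pos = mt$cpos,
        retained = if (k) rowSums(mt$bases[mt$cpos, , drop = FALSE] == "C")
                   else integer(length(mt$cpos)),
        deaminated = if (k) rowSums(mt$bases[mt$cpos, , drop = FALSE] == "T")
                     else integer(length(mt$cpos)))
      per_read <- if (k) colSums(mt$bases[mt$cpos, , drop = FALSE] == "T")
                  else integer(0)
      out[[paste(ctl, strand, sep = ".")]] <- list(
        control = ctl, strand = strand, n_reads = k,
        per_position = per_pos,
        per_read_deaminated = per_read)
    }
  }
  structure(list(strands = out,
                 control_fraction = n_matched_total / length(seqs)),
            class = "control_report")
}

#' Score the exonuclease VII trimming controls
#'
#' Reads are assigned to a construct when they match a contiguous substring
#' of either construct strand (cytosines wildcarded to C/T, at most one
#' other mismatch); per construct the read-length frequency table is
#' returned. With incomplete exoVII trimming the top-strand modal lengths
#' fall at 60 - 10 + r per trimmed end, r in the residual support.
#'
#' @param raw_reads `data.table` with `seq`, or character vector.
#' @param constructs names of exoVII constructs to score.
#' @return named list of `data.table`s from [length_frequency()] (constructs
#'   with no matched reads are NULL).
#' @export
score_exovii_controls <- function(raw_reads, constructs = c("control_exovii")) {
  seqs <- if (is.data.frame(raw_reads)) raw_reads$seq else raw_reads
  out <- list()
  for (ctl in constructs) {
    mol <- control_oligo(ctl)
    top <- paste(chartr("U", "T", mol$top_bases), collapse = "")
    bot_read <- paste(rev(chartr("U", "T", mol$bot_bases)), collapse = "")
    hit <- substring_control_match(seqs, top) |
           substring_control_match(seqs, bot_read)
    out[[ctl]] <- if (any(hit)) length_frequency(nchar(seqs[hit])) else NULL
  }
  out
}

# does each read match some contiguous substring of `template` under the
# C-wildcard rule with <= 1 other mismatch?
substring_control_match <- function(reads, template, max_other_mismatch = 1L) {
  tb <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(tb)
  vapply(reads, function(s) {
    l <- nchar(s)
    if (l > n || l < 15L) return(FALSE)
    rb <- strsplit(s, "", fixed = TRUE)[[1]]
    for (off in 0:(n - l)) {
      t <- tb[(off + 1L):(off + l)]
      mism <- t != rb & !(t == "C" & rb == "T")
      if (sum(mism) <= max_other_mismatch) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' C-to-T damage rate by methylation level (beta bin)
#'
#' The damage/methylation confound of direct methylation sequencing:
#' methylated cytosines deaminate straight to thymine, so in a
#' *non-converted* library the C-to-T substitution rate at the 5' end of
#' reads grows with the methylation level of the region. For reads
#' overlapping segments of each beta bin (1..10), the per-5'-position
#' (1..20) substitution rate (reference-C read-as-T / reference-C covered)
#' is computed, split into CpG and non-CpG reference contexts. Conversion
#' chemistry would confound the same signal, so converted libraries are
#' refused.
#'
#' @param alignments alignment `data.table` (deduplicated, MAPQ >= 30 rows
#'   used) from a non-converted library.
#' @param reads `data.table` with `read_id`, `seq`.
#' @param genome a `toy_genome`.
#' @param segments_binned `data.table`/data.frame with `start`, `end`
#'   (0-based half-open) and `bin` (1..10).
#' @param library_conversion conversion model the library went through;
#'   anything other than `"none"` is an error.
#' @return `data.table` of class `damage_profile`: `bin`, `read_pos` (1..20
#'   from the 5' end), `context` ("CpG"/"nonCpG"), `covered`, `ct`, `rate`.
#' @export
ct_by_beta_bin <- function(alignments, reads, genome, segments_binned,
                           library_conversion = "none") {
  if (!identical(library_conversion, "none"))
    stop("ct_by_beta_bin: requires a non-converted library; conversion ",
         "chemistry confounds the C-to-T damage signal", call. = FALSE)
  aln <- alignments[mapq >= 30L & duplicate == FALSE]
  seqs <- reads$seq[match(aln$read_id, reads$read_id)]
  g <- genome_chars(genome)
  ctx <- context_tables(genome)
  segs <- data.table::as.data.table(segments_binned)[order(start)]
  # bin of the segment (if any) each read overlaps; first overlap wins
  read_bin <- rep(NA_integer_, nrow(aln))
  if (nrow(segs)) {
    i <- findInterval(aln$position, segs$start)
    ok <- i > 0L & aln$position < segs$end[pmax(i, 1L)]
    read_bin[ok] <- segs$bin[i[ok]]
    # also catch reads starting before a segment but overlapping it
    j <- findInterval(aln$end - 1L, segs$start)
    ok2 <- is.na(read_bin) & j > 0L & (aln$end - 1L) < segs$end[pmax(j, 1L)]
    read_bin[ok2] <- segs$bin[j[ok2]]
  }
  acc <- list()
  maxp <- 20L
  for (i in which(!is.na(read_bin))) {
    s <- aln$position[i]; e <- aln$end[i]
    len <- e - s
    rb <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    np <- min(maxp, len)
    jj <- seq_len(np)                       # 5' read positions
    if (aln$strand_view[i] == "OT") {
      p0 <- s + jj - 1L
      refC <- g[p0 + 1L] == "C"
      cx <- ctx$fwd[p0 + 1L]
      base <- rb[jj]
    } else {
      p0 <- e - jj                          # 5' end of an OB read is at `end`
      refC <- g[p0 + 1L] == "G"             # C on the reverse strand
      cx <- ctx$rev[p0 + 1L]
      base <- rb[jj]
    }
    sel <- which(refC)
    if (!length(sel)) next
    acc[[length(acc) + 1L]] <- data.table::data.table(
      bin = read_bin[i], read_pos = jj[sel],
      context = ifelse(cx[sel] == "CpG", "CpG", "nonCpG"),
      ct = base[sel] == "T", covered = TRUE)
  }
  if (!length(acc)) {
    return(structure(data.table::data.table(bin = integer(), read_pos = integer(),
                                            context = character(), covered = integer(),
                                            ct = integer(), rate = numeric()),
                     class = c("damage_profile", "data.table", "data.frame")))
  }
  d <- data.table::rbindlist(acc)
  out <- d[, .(covered = .N, ct = sum(ct)), by = .(bin, read_pos, context)]
  out[, rate := ct / covered]
  data.table::setorder(out, bin, read_pos, context)
  class(out) <- c("damage_profile", class(out))
  out
}
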