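#' Build a three-letter (bisulfite-converted) reference index
#'
#' Bisulfite-style alignment collapses the C/T distinction: the reference is
#' converted in silico into an original-top (OT) view (C replaced by T) and
#' an original-bottom (OB) view (reverse complement, then C replaced by T),
#' and reads are collapsed the same way before matching. A k-mer seed table
#' over both views supports seeded exact-candidate lookup; with
#' `max_mismatch = 2` at the 30-bp minimum read length, `k = 10` lets three
#' disjoint seeds guarantee (pigeonhole) that every hit within the mismatch
#' budget is found.
#'
#' @param genome a `toy_genome`.
#' @param k seed k-mer length.
#' @return object of class `converted_index`.
#' @export
converted_index <- function(genome, k = 10L) {
  seq <- genome$sequence
  L <- nchar(seq)
  ot <- chartr("C", "T", seq)
  rc <- revcomp_string(seq)
  ob <- chartr("C", "T", rc)
  kmer_table <- function(view) {
    starts <- seq_len(nchar(view) - k + 1L)
    data.table::data.table(kmer = substring(view, starts, starts + k - 1L),
                           pos = starts)
  }
  tab <- data.table::rbindlist(list(
    OT = kmer_table(ot), OB = kmer_table(ob)), idcol = "view")
  data.table::setkey(tab, kmer)
  structure(list(genome_name = genome$name, length = L, k = as.integer(k),
                 views = c(OT = ot, OB = ob), seeds = tab),
            class = "converted_index")
}

#' @export
print.converted_index <- function(x, ...) {
  cat(sprintf("<converted_index> %s: %d bp, k = %d\n",
              x$genome_name, x$length, x$k))
  invisible(x)
}

revcomp_string <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Align reads to the converted reference
#'
#' Reads are collapsed C to T and matched against both reference views by
#' k-mer seeding (three evenly spaced seeds) followed by full Hamming
#' verification of every candidate offset. The best hit is the minimal
#' mismatch count within `max_mismatch`; a unique best hit gets MAPQ 37,
#' tied best hits MAPQ 0, no hit is unmapped. Alignments are reported in
#' forward genome coordinates; OB-view positions are mapped back through the
#' reverse complement. Original (uncollapsed) read bases are kept by the
#' caller for methylation calling.
#'
#' @param reads character vector of read sequences (or a `data.table` with
#'   `read_id` and `seq`).
#' @param index a [converted_index()].
#' @param max_mismatch maximum Hamming mismatches on the collapsed alphabet.
#' @return `data.table` with one row per mapped read: `read_id`, `position`
#'   (0-based start), `end` (half-open), `strand_view` ("OT"/"OB"),
#'   `mismatches`, `mapq` (37 unique best, 0 tied), `duplicate` (FALSE;
#'   see [remove_duplicates()]). Reads shorter than `k` or without any hit
#'   are absent from the table.
#' @export
align_reads <- function(reads, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "converted_index"))
  if (is.character(reads)) {
    reads <- data.table::data.table(
      read_id = sprintf("read%07d", seq_along(reads)), seq = reads)
  }
  k <- index$k
  L <- index$length
  rl <- nchar(reads$seq)
  keep <- rl >= k
  if (!any(keep)) return(empty_alignment())
  rd <- reads[keep]
  rl <- rl[keep]
  coll <- chartr("C", "T", rd$seq)

  # three evenly spaced seeds per read (disjoint whenever length >= 3k)
  n_seed <- 3L
  seeds <- data.table::rbindlist(lapply(seq_len(n_seed), function(j) {
    off <- pmin(floor((j - 1L) * (rl - k) / (n_seed - 1L)), rl - k)
    data.table::data.table(ridx = seq_len(nrow(rd)), off = as.integer(off),
                           kmer = substring(coll, off + 1L, off + k))
  }))
  hits <- index$seeds[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty_alignment())
  hits[, cand := pos - off]                 # 1-based candidate start in view
  hits <- unique(hits[, .(ridx, view, cand)])
  hits <- hits[cand >= 1L & cand + rl[ridx] - 1L <= L]
  if (nrow(hits) == 0L) return(empty_alignment())

  hits[, mm := {
    v <- index$views[view[1]]
    mapply(function(r, s, l) hamming(substr(v, s, s + l - 1L), r),
           coll[ridx], cand, rl[ridx], USE.NAMES = FALSE)
  }, by = view]
  hits <- hits[mm <= max_mismatch]
  if (nrow(hits) == 0L) return(empty_alignment())

  best <- hits[, {
    b <- min(mm)
    tied <- sum(mm == b)
    i <- which.max(mm == b)
    .(view = view[i], cand = cand[i], mm = b,
      mapq = if (tied == 1L) 37L else 0L)
  }, by = ridx]

  len <- rl[best$ridx]
  fwd_start <- ifelse(best$view == "OT", best$cand - 1L,
                      L - (best$cand - 1L) - len)
  out <- data.table::data.table(
    read_id = rd$read_id[best$ridx],
    position = as.integer(fwd_start),
    end = as.integer(fwd_start + len),
    strand_view = best$view,
    mismatches = best$mm,
    mapq = best$mapq,
    duplicate = FALSE)
  data.table::setorder(out, position, end, strand_view, read_id)
  out
}

empty_alignment <- function() {
  data.table::data.table(read_id = character(), position = integer(),
                         end = integer(), strand_view = character(),
                         mismatches = integer(), mapq = integer(),
                         duplicate = logical())
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read one read sequence.
#' @return a one-row alignment `data.table`, or `NULL` when unmapped.
#' @export
align_read <- function(read, index, max_mismatch = 2L) {
  out <- align_reads(c(r1 = read), index, max_mismatch)
  if (nrow(out) == 0L) NULL else out
}

#' Trim 3' adapters and drop short reads
#'
#' The adapter is removed at the earliest position where an exact match of
#' at least `min_overlap` bases of the adapter prefix is found extending to
#' the read's 3' end; reads shorter than `min_len` after trimming are
#' dropped.
#'
#' @param reads `data.table` with `read_id`, `seq` (and optionally `qual`).
#' @param adapter adapter sequence (3' end).
#' @param min_len minimum retained read length, bp.
#' @param min_overlap minimum exact adapter prefix match, bp.
#' @return list with `reads` (trimmed, surviving), `n_input`, `n_trimmed`,
#'   `n_dropped`.
#' @export
trim_and_filter <- function(reads, adapter = "AGATCGGAAGAGC", min_len = 30L,
                            min_overlap = 8L) {
  if (!nzchar(adapter)) stop("trim_and_filter: empty adapter", call. = FALSE)
  seqs <- reads$seq
  n <- nchar(seqs)
  alen <- nchar(adapter)
  # earliest full-adapter occurrence anywhere in the read
  full <- regexpr(adapter, seqs, fixed = TRUE)
  trimmed_at <- ifelse(full > 0L & alen >= min_overlap, full - 1L, n)
  # partial adapter running off the 3' end: longest prefix wins (earliest cut)
  if (length(seqs) && alen - 1L >= min_overlap) {
    for (m in seq(alen - 1L, min_overlap)) {
      cand <- n - m                  # 0-based cut position for this overlap
      hit <- n >= m & cand < trimmed_at &
        substr(seqs, cand + 1L, n) == substr(adapter, 1L, m)
      trimmed_at[hit] <- cand[hit]
    }
  }
  out <- data.table::copy(reads)
  out[, seq := substr(seq, 1L, trimmed_at)]
  if ("qual" %in% names(out)) out[, qual := substr(qual, 1L, trimmed_at)]
  keep <- nchar(out$seq) >= min_len
  list(reads = out[keep],
       n_input = nrow(reads),
       n_trimmed = sum(trimmed_at < nchar(seqs)),
       n_dropped = sum(!keep))
}

#' Remove duplicate alignments
#'
#' Among alignments sharing the key (`position`, `end`, `strand_view`)
#' exactly one record survives, the lexicographically smallest `read_id`;
#' the rest are flagged `duplicate`. Idempotent. Input must be sorted by
#' the key.
#'
#' @param alignments alignment `data.table` (see [align_reads()]).
#' @return the table with `duplicate` flags set.
#' @export
remove_duplicates <- function(alignments) {
  a <- alignments
  if (!identical(order(a$position, a$end, a$strand_view), seq_len(nrow(a))))
    stop("remove_duplicates: alignments must be sorted by (position, end, strand_view)",
         call. = FALSE)
  a <- data.table::copy(a)
  a[, duplicate := read_id != min(read_id),
    by = .(position, end, strand_view)]
  a
}

#' Percent-endogenous preservation metric
#'
#' The ancient-DNA yield metric: mapped reads at mapping quality >= 30
#' divided by all raw reads, as a percentage.
#'
#' @param n_mapped_mq30 mapped reads with MAPQ >= 30.
#' @param n_raw total raw reads (including controls and decoys).
#' @return percentage in \[0, 100\].
#' @export
percent_endogenous <- function(n_mapped_mq30, n_raw) {
  if (n_raw <= 0) stop("percent_endogenous: n_raw must be > 0", call. = FALSE)
  if (n_mapped_mq30 < 0 || n_mapped_mq30 > n_raw)
    stop("percent_endogenous: need 0 <= n_mapped_mq30 <= n_raw", call. = FALSE)
  100 * n_mapped_mq30 / n_raw
}

#' Align a whole library and deduplicate
#'
#' Convenience pipeline: build the index, trim/filter, align, sort, and
#' flag duplicates.
#'
#' @param lib a [simulate_library()] result (or list with `genome`, `fastq`).
#' @param max_mismatch Hamming budget.
#' @param min_len length filter after adapter trimming.
#' @param k seed length for the index.
#' @return list with `alignments` (deduplicated flags set), `index`,
#'   `n_raw`, `pct_endogenous`.
#' @export
align_library <- function(lib, max_mismatch = 2L, min_len = 30L, k = 10L) {
  idx <- converted_index(lib$genome, k = k)
  tf <- trim_and_filter(lib$fastq, min_len = min_len)
  aln <- align_reads(tf$reads, idx, max_mismatch = max_mismatch)
  aln <- remove_duplicates(aln)
  n_raw <- nrow(lib$fastq)
  list(alignments = aln, index = idx, n_raw = n_raw,
       pct_endogenous = percent_endogenous(sum(aln$mapq >= 30), n_raw))
}
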