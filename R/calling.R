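#' Classify the sequence context of a cytosine
#'
#' On the strand carrying the C, the next base decides CpG, the base after
#' that CHG, else CHH (H = A, C or T). Cytosines within 2 bp of the strand's
#' 3' genome end that cannot be fully classified are reported CHH with a
#' truncation flag.
#'
#' @param genome a `toy_genome`.
#' @param position 0-based position of the cytosine (forward coordinates).
#' @param strand `"forward"` or `"reverse"`.
#' @return the context string, with attribute `truncated` when the genome
#'   end prevented full classification.
#' @export
classify_context <- function(genome, position, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  g <- genome_chars(genome)
  L <- length(g)
  p <- position + 1L                      # 1-based
  if (strand == "forward") {
    if (g[p] != "C") stop("classify_context: base is not C on forward strand",
                          call. = FALSE)
    n1 <- if (p + 1L <= L) g[p + 1L] else NA
    n2 <- if (p + 2L <= L) g[p + 2L] else NA
  } else {
    if (g[p] != "G") stop("classify_context: base is not C on reverse strand",
                          call. = FALSE)
    # reverse-strand neighbours run leftwards; neighbour is G iff forward is C
    n1 <- if (p - 1L >= 1L) unname(COMPLEMENT[g[p - 1L]]) else NA
    n2 <- if (p - 2L >= 1L) unname(COMPLEMENT[g[p - 2L]]) else NA
  }
  if (!is.na(n1) && n1 == "G") return("CpG")
  if (is.na(n1)) return(structure("CHH", truncated = TRUE))
  if (!is.na(n2) && n2 == "G") return("CHG")
  if (is.na(n2)) return(structure("CHH", truncated = TRUE))
  "CHH"
}

# vectorised context classification for all cytosines of both strands;
# returns lookup vectors ctx_fwd / ctx_rev indexed by 0-based position + 1
context_tables <- function(genome) {
  g <- genome_chars(genome)
  L <- length(g)
  n1 <- c(g[-1L], NA); n2 <- c(g[-(1:2)], NA, NA)
  ctx_fwd <- rep(NA_character_, L)
  isC <- g == "C"
  ctx_fwd[isC] <- ifelse(!is.na(n1[isC]) & n1[isC] == "G", "CpG",
                  ifelse(!is.na(n2[isC]) & n2[isC] == "G", "CHG", "CHH"))
  p1 <- c(NA, g[-L]); p2 <- c(NA, NA, g[-((L - 1L):L)])
  ctx_rev <- rep(NA_character_, L)
  isG <- g == "G"
  ctx_rev[isG] <- ifelse(!is.na(p1[isG]) & p1[isG] == "C", "CpG",
                  ifelse(!is.na(p2[isG]) & p2[isG] == "C", "CHG", "CHH"))
  list(fwd = ctx_fwd, rev = ctx_rev)
}

#' Pile up methylation calls from aligned converted reads
#'
#' For every deduplicated MAPQ >= 30 alignment, each reference cytosine
#' covered by the read contributes one call: read base C counts as
#' methylated, read base T as unmethylated, anything else (sequencing error)
#' is ignored. OT-view reads inform forward-strand cytosines; OB-view reads
#' inform reverse-strand cytosines (reference G positions), with the read
#' base taken on the read's own strand.
#'
#' @param alignments alignment `data.table` (deduplicated; rows with
#'   `duplicate == TRUE` or `mapq < 30` are excluded here).
#' @param reads `data.table` with `read_id`, `seq` (original, uncollapsed
#'   bases).
#' @param genome a `toy_genome`.
#' @return `data.table` of `MethylCall`s: `position` (0-based), `strand`,
#'   `context`, `n_methylated`, `n_unmethylated`.
#' @export
pileup_calls <- function(alignments, reads, genome) {
  aln <- alignments[mapq >= 30L & duplicate == FALSE]
  seqs <- reads$seq[match(aln$read_id, reads$read_id)]
  if (any(is.na(seqs))) stop("pileup_calls: alignment without matching read",
                             call. = FALSE)
  if (any(nchar(seqs) != aln$end - aln$position))
    stop("pileup_calls: read/alignment length mismatch", call. = FALSE)
  g <- genome_chars(genome)
  L <- length(g)
  nm_f <- integer(L); nu_f <- integer(L)   # forward-strand C counts, idx = pos0+1
  nm_r <- integer(L); nu_r <- integer(L)
  isC <- g == "C"; isG <- g == "G"
  for (i in seq_len(nrow(aln))) {
    s <- aln$position[i]; e <- aln$end[i]
    rb <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (aln$strand_view[i] == "OT") {
      cov <- which(isC[(s + 1L):e])              # offsets within read
      if (!length(cov)) next
      b <- rb[cov]
      idx <- s + cov
      mi <- idx[b == "C"]; ui <- idx[b == "T"]
    } else {
      cov <- which(isG[(s + 1L):e])
      if (!length(cov)) next
      b <- rb[e - s - cov + 1L]                  # read base at that position
      idx <- s + cov
      mi <- idx[b == "C"]; ui <- idx[b == "T"]
      if (length(mi)) { nm_r[mi] <- nm_r[mi] + 1L }
      if (length(ui)) { nu_r[ui] <- nu_r[ui] + 1L }
      next
    }
    if (length(mi)) nm_f[mi] <- nm_f[mi] + 1L
    if (length(ui)) nu_f[ui] <- nu_f[ui] + 1L
  }
  ctx <- context_tables(genome)
  fwd_idx <- which(nm_f + nu_f > 0L)
  rev_idx <- which(nm_r + nu_r > 0L)
  out <- data.table::rbindlist(list(
    data.table::data.table(position = fwd_idx - 1L, strand = "forward",
                           context = ctx$fwd[fwd_idx],
                           n_methylated = nm_f[fwd_idx],
                           n_unmethylated = nu_f[fwd_idx]),
    data.table::data.table(position = rev_idx - 1L, strand = "reverse",
                           context = ctx$rev[rev_idx],
                           n_methylated = nm_r[rev_idx],
                           n_unmethylated = nu_r[rev_idx])))
  data.table::setorder(out, position, strand)
  out
}

#' Build a beta track from methylation calls
#'
#' The beta value of a position is its methylation percentage,
#' `100 * n_methylated / (n_methylated + n_unmethylated)`; positions with
#' coverage below `min_coverage` are omitted.
#'
#' @param calls `data.table` from [pileup_calls()].
#' @param min_coverage minimum total calls per position.
#' @return `data.table` with `position`, `strand`, `context`, `beta`,
#'   `coverage`, sorted by position.
#' @export
beta_track <- function(calls, min_coverage = 1L) {
  cov <- calls$n_methylated + calls$n_unmethylated
  keep <- cov >= min_coverage
  out <- data.table::data.table(
    position = calls$position[keep],
    strand = calls$strand[keep],
    context = calls$context[keep],
    beta = 100 * calls$n_methylated[keep] / cov[keep],
    coverage = cov[keep])
  data.table::setorder(out, position, strand)
  out
}

#' Per-context methylation percentages
#'
#' Pooled over both strands: for CpG, CHG, CHH and non-CpG (= CHG + CHH),
#' the percentage of methylated calls among all calls in that context.
#' Contexts with no calls are `NA`.
#'
#' @param calls `data.table` from [pileup_calls()].
#' @return named numeric vector with entries `CpG`, `CHG`, `CHH`, `nonCpG`.
#' @export
context_summary <- function(calls) {
  pct <- function(sel) {
    nm <- sum(calls$n_methylated[sel]); den <- nm + sum(calls$n_unmethylated[sel])
    if (den == 0) NA_real_ else 100 * nm / den
  }
  c(CpG = pct(calls$context == "CpG"),
    CHG = pct(calls$context == "CHG"),
    CHH = pct(calls$context == "CHH"),
    nonCpG = pct(calls$context %in% c("CHG", "CHH")))
}
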