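# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact optimal partition of v into k segments by dynamic programming
# (O(n^2 k)); returns the minimal total within-segment SSE.
dp_optimal_sse <- function(v, k) {
  n <- length(v)
  cs <- c(0, cumsum(v)); css <- c(0, cumsum(v^2))
  sse <- function(i, j) {             # cost of segment v[i..j]
    s <- cs[j + 1] - cs[i]; q <- css[j + 1] - css[i]
    q - s^2 / (j - i + 1)
  }
  inf <- Inf
  D <- matrix(inf, nrow = k, ncol = n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    best <- inf
    for (t in (m - 1):(j - 1)) {
      cand <- D[m - 1, t] + sse(t + 1, j)
      if (cand < best) best <- cand
    }
    D[m, j] <- best
  }
  D[k, n]
}

# total within-segment SSE of a concrete segmentation (start indices)
segmentation_sse <- function(v, starts) {
  ends <- c(starts[-1] - 1L, length(v))
  sum(vapply(seq_along(starts), function(i) {
    x <- v[starts[i]:ends[i]]; sum((x - mean(x))^2)
  }, numeric(1)))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (tie-free samples only).
enumerate_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  u_stat <- function(xi) {
    xs <- all_v[xi]; ys <- all_v[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_stat(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_stat)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Exhaustive bisulfite-aware alignment oracle via Biostrings::matchPattern
# over every offset of both converted views.
oracle_align <- function(read, genome_seq, max_mismatch = 2L) {
  L <- nchar(genome_seq)
  ot <- chartr("C", "T", genome_seq)
  ob <- chartr("C", "T", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome_seq))))
  coll <- chartr("C", "T", read)
  len <- nchar(read)
  hits <- list()
  for (vname in c("OT", "OB")) {
    v <- if (vname == "OT") ot else ob
    m <- Biostrings::matchPattern(coll, Biostrings::DNAString(v),
                                  max.mismatch = max_mismatch)
    st <- Biostrings::start(m)
    if (length(st)) {
      mm <- vapply(st, function(s)
        sum(charToRaw(substr(v, s, s + len - 1L)) != charToRaw(coll)),
        numeric(1))
      hits[[vname]] <- data.frame(view = vname, cand = st, mm = mm)
    }
  }
  h <- do.call(rbind, hits)
  if (is.null(h) || nrow(h) == 0) return(NULL)
  b <- min(h$mm)
  hb <- h[h$mm == b, , drop = FALSE]
  first <- hb[1, ]
  pos <- if (first$view == "OT") first$cand - 1L else L - (first$cand - 1L) - len
  list(position = as.integer(pos), strand_view = first$view,
       mismatches = as.integer(b), mapq = if (nrow(hb) == 1L) 37L else 0L)
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# small ideal-chemistry config shared by several tests
ideal_config <- function(...) {
  sim_config(d_ss = 0, d_ds = 0, seq_error = 0, conv_eff = 1, overconv = 0,
             overhang_geom_p = 0.45, control_fraction = 0, endo_fraction = 1,
             ...)
}

# run simulate -> align -> call and return the per-context summary
pipeline_context_summary <- function(cfg, conversion, n_reads = NULL,
                                     genome = NULL, methylome = NULL) {
  lib <- simulate_library(cfg, conversion = conversion, n_reads = n_reads,
                          genome = genome, methylome = methylome)
  al <- align_library(lib)
  calls <- pileup_calls(al$alignments, lib$fastq, lib$genome)
  context_summary(calls)
}
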