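#' Build a toy reference genome with planted CpG islands
#'
#' Generates a random single-chromosome reference whose background CpG
#' density is thinned to roughly one CpG per 50 bp (vertebrate-like CpG
#' depletion), with `cgi_count` CpG-dense islands in which dinucleotide CG is
#' planted every 6 bp, giving an inside/outside CpG density ratio well above
#' 3x. Island intervals are 0-based half-open, sorted and non-overlapping.
#'
#' @param config a [sim_config()].
#' @return an object of class `toy_genome`: list with `name`, `sequence`
#'   (single string over ACGT), and `cgi_intervals` (data.frame with 0-based
#'   half-open `start`, `end`).
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  if (L < 1000L) stop("build_toy_genome: genome_length must be >= 1000", call. = FALSE)
  if (config$cgi_count * 1000L >= L)
    stop("build_toy_genome: cgi_count * 1000 must be < genome_length", call. = FALSE)
  set.seed(config$seed)

  g <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  # thin background CpGs: 1/16 per position iid -> ~1/50 bp after q = 0.68
  cg <- which(g[-L] == "C" & g[-1L] == "G")
  brk <- cg[stats::runif(length(cg)) < 0.68]
  if (length(brk)) g[brk + 1L] <- sample(c("A", "T"), length(brk), replace = TRUE)

  cgi <- data.frame(start = integer(0), end = integer(0))
  if (config$cgi_count > 0L) {
    w <- config$cgi_length
    block <- L %/% config$cgi_count
    if (block < w + 200L)
      stop("build_toy_genome: genome too short for requested islands", call. = FALSE)
    off <- floor(stats::runif(config$cgi_count, 100, block - w - 100))
    starts <- as.integer((seq_len(config$cgi_count) - 1L) * block + off)
    for (i in seq_along(starts)) {
      s <- starts[i]
      # island: CG planted every 6 bp with random 4-bp spacers
      n_unit <- ceiling(w / 6)
      spacer <- sample(c("A", "C", "G", "T"), 4L * n_unit, replace = TRUE)
      unit <- as.vector(rbind("C", "G",
                              matrix(spacer, nrow = 4L)))
      g[s:(s + w - 1L)] <- unit[seq_len(w)]
    }
    cgi <- data.frame(start = starts, end = starts + w)
  }

  structure(list(name = "toy1",
                 sequence = paste(g, collapse = ""),
                 cgi_intervals = cgi),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %s: %d bp, %d CGI intervals\n",
              x$name, nchar(x$sequence), nrow(x$cgi_intervals)))
  invisible(x)
}

# genome sequence as a character vector, cached conversion
genome_chars <- function(genome) strsplit(genome$sequence, "", fixed = TRUE)[[1]]

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Forward-strand CpG site positions of a genome
#'
#' @param genome a `toy_genome`.
#' @return 0-based positions p with `sequence[p] == "C"` and
#'   `sequence[p+1] == "G"` (positions of the forward-strand C).
#' @export
cpg_sites <- function(genome) {
  g <- genome_chars(genome)
  which(g[-length(g)] == "C" & g[-1L] == "G") - 1L
}

#' Test membership of positions in sorted half-open intervals
#'
#' @param pos 0-based positions.
#' @param intervals data.frame with sorted, non-overlapping 0-based half-open
#'   `start`, `end` columns.
#' @return logical vector, TRUE where `pos` falls in some `[start, end)`.
#' @export
in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  i <- findInterval(pos, intervals$start)
  i > 0L & pos < intervals$end[pmax(i, 1L)]
}

# Background methylome mixture: weight of the low component solved so the
# mass below 20% plus the mass in [71%, 90%] is exactly 0.80 (the bimodal
# osteoblast-like target).
.meth_mix <- local({
  inside <- function(a, b) stats::pbeta(0.20, a, b) +
    stats::pbeta(0.90, a, b) - stats::pbeta(0.71, a, b)
  a_lo <- 0.8; b_lo <- 10; a_hi <- 16; b_hi <- 4
  f1 <- inside(a_lo, b_lo); f2 <- inside(a_hi, b_hi)
  list(a_lo = a_lo, b_lo = b_lo, a_hi = a_hi, b_hi = b_hi,
       w_lo = (0.80 - f2) / (f1 - f2))
})

#' Generate a ground-truth methylome over the CpG sites of a genome
#'
#' Methylomes are block-structured, as in real vertebrate genomes: runs of
#' consecutive CpG sites share a regional methylation level. Background
#' sites are partitioned into blocks of geometric length (mean
#' `block_mean` sites); each block draws one beta from a bimodal mixture of
#' a hypomethylated component (Beta(0.8, 10)) and a methylated component
#' (Beta(16, 4), mean 80%), with the mixture weight calibrated analytically
#' so that 80% of background truth betas fall below 20 or inside [71, 90].
#' Each CpG island forms its own block with a low beta (Beta(0.6, 15),
#' mode at 0). One beta per CpG site, applied symmetrically to both strands.
#'
#' @param genome a `toy_genome`.
#' @param config a [sim_config()] (uses `seed`).
#' @param block_mean mean background block length in CpG sites.
#' @return a `data.frame` of class `methylome` with 0-based `pos` (forward C
#'   of the CpG), `beta` in \[0, 100\], and logical `cgi`.
#' @export
build_methylome <- function(genome, config, block_mean = 10) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  pos <- cpg_sites(genome)
  if (length(pos) == 0L)
    stop("build_methylome: genome contains no CpG site", call. = FALSE)
  set.seed(config$seed + 1L)
  cgi <- in_intervals(pos, genome$cgi_intervals)
  n <- length(pos)
  beta <- numeric(n)
  mmix <- .meth_mix
  # maximal runs of constant island status, in genome order
  run_id <- cumsum(c(TRUE, cgi[-1L] != cgi[-n]))
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (cgi[idx[1L]]) {
      beta[idx] <- 100 * stats::rbeta(1L, 0.6, 15)
    } else {
      # chop the background run into geometric blocks, one draw per block
      left <- length(idx); at <- 1L
      while (left > 0L) {
        len <- min(left, 1L + stats::rgeom(1L, 1 / block_mean))
        b <- if (stats::runif(1L) < mmix$w_lo)
          100 * stats::rbeta(1L, mmix$a_lo, mmix$b_lo)
        else
          100 * stats::rbeta(1L, mmix$a_hi, mmix$b_hi)
        beta[idx[at:(at + len - 1L)]] <- b
        at <- at + len; left <- left - len
      }
    }
  }
  out <- data.frame(pos = pos, beta = beta, cgi = cgi)
  class(out) <- c("methylome", "data.frame")
  out
}
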