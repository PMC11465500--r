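#' Ancient DNA molecules
#'
#' A `fragment_molecule` models a (possibly nicked or single-stranded)
#' double-stranded DNA fragment. Both strands are stored left-to-right in
#' genome orientation: `top_bases[i]` is the top-strand base at 0-based
#' genome position `top_start + i - 1`; `bot_bases` holds the *bottom-strand*
#' bases (complement of the reference) at `bot_start + i - 1`. The bottom
#' strand therefore reads 5' to 3' from right to left. Single-stranded
#' overhangs are the positions covered by only one strand; with the default
#' 5'-overhang convention the left overhang sits on the top strand and the
#' right overhang on the bottom strand. Per-base parallel vectors record
#' methylation and deamination events; bases are over \{A,C,G,T,U\}.
#'
#' @name fragment_molecule
#' @keywords internal
NULL

new_molecule <- function(source, top_start = NA_integer_, top_end = NA_integer_,
                         bot_start = NA_integer_, bot_end = NA_integer_,
                         top_bases = NULL, bot_bases = NULL) {
  mol <- list(
    source = source,
    top_start = top_start, top_end = top_end,
    bot_start = bot_start, bot_end = bot_end,
    top_bases = top_bases, bot_bases = bot_bases,
    top_meth = if (!is.null(top_bases)) rep(FALSE, length(top_bases)),
    bot_meth = if (!is.null(bot_bases)) rep(FALSE, length(bot_bases)),
    top_deamT = if (!is.null(top_bases)) rep(FALSE, length(top_bases)),
    bot_deamT = if (!is.null(bot_bases)) rep(FALSE, length(bot_bases)),
    top_deamU = if (!is.null(top_bases)) rep(FALSE, length(top_bases)),
    bot_deamU = if (!is.null(bot_bases)) rep(FALSE, length(bot_bases))
  )
  class(mol) <- "fragment_molecule"
  mol
}

#' @export
print.fragment_molecule <- function(x, ...) {
  cat(sprintf("<fragment_molecule> %s top [%s,%s) bot [%s,%s)\n",
              x$source, x$top_start, x$top_end, x$bot_start, x$bot_end))
  invisible(x)
}

has_strand <- function(mol, strand) !is.null(mol[[paste0(strand, "_bases")]])

# overhang lengths (left, right): bp covered by exactly one strand
overhang_lengths <- function(mol) {
  if (!has_strand(mol, "top") || !has_strand(mol, "bot")) return(c(0L, 0L))
  c(abs(mol$top_start - mol$bot_start), abs(mol$top_end - mol$bot_end))
}

# logical mask over one strand: TRUE where the position is single-stranded
ss_mask <- function(mol, strand) {
  st <- mol[[paste0(strand, "_start")]]
  en <- mol[[paste0(strand, "_end")]]
  n <- en - st
  other <- if (strand == "top") "bot" else "top"
  if (!has_strand(mol, other)) return(rep(TRUE, n))
  o_st <- mol[[paste0(other, "_start")]]
  o_en <- mol[[paste0(other, "_end")]]
  pos <- st + seq_len(n) - 1L
  pos < o_st | pos >= o_en
}

#' Draw ancient fragments from the toy genome
#'
#' Fragment lengths are lognormal(`length_mean_log`, `length_sd_log`)
#' truncated to \[20, 250\] bp; placement is uniform. Each molecule receives
#' two independent geometric single-stranded overhangs (5' convention: the
#' left overhang on the top strand, the right on the bottom strand), capped
#' at the fragment length.
#'
#' @param genome a `toy_genome`.
#' @param config a [sim_config()]; uses `fragment_count`, length and
#'   overhang parameters. Draws from the current RNG stream.
#' @return list of `fragment_molecule`s with `source = "endogenous"`.
#' @export
fragmentize <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  n <- config$fragment_count
  if (n == 0L) return(list())
  g <- genome_chars(genome)
  L <- length(g)
  comp <- COMPLEMENT

  len <- round(stats::rlnorm(n, config$length_mean_log, config$length_sd_log))
  bad <- which(len < 20 | len > 250)
  while (length(bad)) {
    len[bad] <- round(stats::rlnorm(length(bad), config$length_mean_log,
                                    config$length_sd_log))
    bad <- bad[len[bad] < 20 | len[bad] > 250]
  }
  len <- as.integer(pmin(len, L))
  start <- as.integer(floor(stats::runif(n, 0, L - len + 1)))
  oh_l <- pmin(stats::rgeom(n, config$overhang_geom_p), len)
  oh_r <- pmin(stats::rgeom(n, config$overhang_geom_p), len - oh_l)

  lapply(seq_len(n), function(i) {
    s <- start[i]; e <- s + len[i]
    tb <- g[(s + 1L):e]
    bot_len <- len[i] - oh_l[i] - oh_r[i]
    bb <- if (bot_len > 0L) {
      unname(comp[tb])[seq.int(oh_l[i] + 1L, len[i] - oh_r[i])]
    } else NULL
    new_molecule("endogenous",
                 top_start = s, top_end = e,
                 bot_start = if (bot_len > 0L) s + oh_l[i] else NA_integer_,
                 bot_end = if (bot_len > 0L) e - oh_r[i] else NA_integer_,
                 top_bases = tb, bot_bases = bb)
  })
}

#' Assign per-molecule methylation states from the truth methylome
#'
#' Every CpG cytosine (forward-strand C at a methylome position p, and the
#' paired bottom-strand C at p+1) is methylated independently with
#' probability `beta/100` of its site; non-CpG cytosines with probability
#' `noncpg_meth_rate`.
#'
#' @param fragments list of endogenous `fragment_molecule`s.
#' @param methylome a [build_methylome()] result.
#' @param config a [sim_config()].
#' @return the fragments, with methylation flags set.
#' @export
assign_methylation <- function(fragments, methylome, config) {
  if (inherits(fragments, "fragment_molecule")) {
    return(assign_methylation(list(fragments), methylome, config)[[1]])
  }
  Lmax <- max(0L, methylome$pos) + 2L
  beta_fwd <- rep(NA_real_, Lmax + 1L)       # index = 0-based pos + 1
  beta_fwd[methylome$pos + 1L] <- methylome$beta
  beta_rev <- rep(NA_real_, Lmax + 1L)
  beta_rev[methylome$pos + 2L] <- methylome$beta
  rate <- config$noncpg_meth_rate

  lapply(fragments, function(mol) {
    if (!identical(mol$source, "endogenous"))
      stop("assign_methylation: only endogenous fragments carry the genome methylome",
           call. = FALSE)
    for (strand in c("top", "bot")) {
      if (!has_strand(mol, strand)) next
      st <- mol[[paste0(strand, "_start")]]
      bases <- mol[[paste0(strand, "_bases")]]
      isC <- bases == "C"
      if (!any(isC)) next
      pos <- st + which(isC) - 1L
      b <- if (strand == "top") beta_fwd[pos + 1L] else beta_rev[pos + 1L]
      p <- ifelse(is.na(b), rate, b / 100)
      meth <- stats::runif(length(p)) < p
      m <- mol[[paste0(strand, "_meth")]]
      m[which(isC)] <- meth
      mol[[paste0(strand, "_meth")]] <- m
    }
    mol
  })
}
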