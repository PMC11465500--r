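#' Apply post-mortem cytosine deamination to molecules
#'
#' Single-stranded overhang cytosines deaminate with probability `d_ss`;
#' double-stranded cytosines with probability
#' `d_ds + (d_ss - d_ds) * exp(-d_decay * x)`, where x is the distance (bp)
#' to the nearest physical end of that strand. A deaminated unmethylated C
#' becomes U (`deamU` flag); a deaminated methylated C loses its methyl amine
#' and becomes T directly (`deamT` flag).
#'
#' @param fragments a `fragment_molecule` or list thereof.
#' @param config a [sim_config()]. Draws from the current RNG stream.
#' @return the molecule(s) with damage applied.
#' @export
apply_deamination <- function(fragments, config) {
  if (inherits(fragments, "fragment_molecule"))
    return(apply_deamination(list(fragments), config)[[1]])
  d_ss <- config$d_ss; d_ds <- config$d_ds; dec <- config$d_decay
  lapply(fragments, function(mol) {
    for (strand in c("top", "bot")) {
      if (!has_strand(mol, strand)) next
      bases <- mol[[paste0(strand, "_bases")]]
      n <- length(bases)
      isC <- bases == "C"
      if (!any(isC)) next
      i <- seq_len(n)
      dist_end <- pmin(i - 1L, n - i)
      p <- d_ds + (d_ss - d_ds) * exp(-dec * dist_end)
      p[ss_mask(mol, strand)] <- d_ss
      hit <- isC & stats::runif(n) < p
      if (!any(hit)) next
      meth <- mol[[paste0(strand, "_meth")]]
      toT <- hit & meth
      toU <- hit & !meth
      bases[toT] <- "T"
      bases[toU] <- "U"
      mol[[paste0(strand, "_bases")]] <- bases
      mol[[paste0(strand, "_deamT")]] <- mol[[paste0(strand, "_deamT")]] | toT
      mol[[paste0(strand, "_deamU")]] <- mol[[paste0(strand, "_deamU")]] | toU
    }
    mol
  })
}

#' Apply (incomplete) exonuclease VII overhang trimming
#'
#' Exonuclease VII digests single-stranded DNA from both ends; observed
#' trimming is incomplete, leaving residual overhangs. Each overhang of
#' length L is reduced to `min(L, r)`, r drawn uniformly from
#' `config$exo_residual_support` (default 3-5 bp). The double-stranded core
#' is untouched.
#'
#' @inheritParams apply_deamination
#' @return the molecule(s) with overhangs trimmed.
#' @export
apply_exovii <- function(fragments, config) {
  if (inherits(fragments, "fragment_molecule"))
    return(apply_exovii(list(fragments), config)[[1]])
  supp <- config$exo_residual_support
  trim_one <- function(mol, side) {
    if (!has_strand(mol, "top") || !has_strand(mol, "bot")) return(mol)
    if (side == "left") {
      L <- mol$bot_start - mol$top_start       # >0: top overhangs left
      ss <- if (L > 0L) "top" else "bot"
      L <- abs(L)
    } else {
      L <- mol$top_end - mol$bot_end           # >0: top overhangs right
      ss <- if (L > 0L) "top" else "bot"
      L <- abs(L)
    }
    if (L == 0L) return(mol)
    r <- supp[sample.int(length(supp), 1L)]
    cut <- L - min(L, r)
    if (cut == 0L) return(mol)
    n <- length(mol[[paste0(ss, "_bases")]])
    keep <- if (side == "left") (cut + 1L):n else 1L:(n - cut)
    for (f in c("_bases", "_meth", "_deamT", "_deamU")) {
      v <- mol[[paste0(ss, f)]]
      mol[[paste0(ss, f)]] <- v[keep]
    }
    if (side == "left") mol[[paste0(ss, "_start")]] <- mol[[paste0(ss, "_start")]] + cut
    else mol[[paste0(ss, "_end")]] <- mol[[paste0(ss, "_end")]] - cut
    mol
  }
  lapply(fragments, function(mol) trim_one(trim_one(mol, "left"), "right"))
}

#' Apply USER (UDG + endonuclease VIII) uracil excision
#'
#' Each strand is cut at every uracil, the uracil removed, and the resulting
#' pieces re-emitted as blunt single-stranded molecules; pieces shorter than
#' `min_len` are dropped. In `partial` mode uracils at the terminal position
#' of a strand escape excision with probability `terminal_retain_prob`: UDG
#' acts poorly on terminal uracils, so partial-UDG libraries keep a reduced
#' -- but not untouched -- damage signal at the very first and last base.
#' `terminal_retain_prob = 1` gives fully deterministic terminal retention.
#' Methylation-derived Ts (`deamT`) are chemically thymine and are never
#' touched.
#'
#' @param fragments a `fragment_molecule` or list thereof.
#' @param mode `"full"` or `"partial"`.
#' @param min_len minimum piece length retained (bp).
#' @param terminal_retain_prob probability a terminal uracil escapes
#'   excision in `partial` mode.
#' @return a flat list of molecules (strands without uracils stay in place;
#'   cut strands are re-emitted piecewise).
#' @export
apply_user <- function(fragments, mode = c("full", "partial"), min_len = 20L,
                       terminal_retain_prob = 0.5) {
  mode <- match.arg(mode)
  single <- inherits(fragments, "fragment_molecule")
  if (single) fragments <- list(fragments)
  per_mol <- lapply(fragments, function(mol) {
    pieces <- list()
    intact <- mol
    for (strand in c("top", "bot")) {
      if (!has_strand(mol, strand)) next
      bases <- mol[[paste0(strand, "_bases")]]
      n <- length(bases)
      u <- which(bases == "U")
      if (mode == "partial" && length(u)) {
        term <- u %in% c(1L, n)
        spared <- term & stats::runif(length(u)) < terminal_retain_prob
        u <- u[!spared]
      }
      if (length(u) == 0L) next
      # strand is cut: remove it from the intact molecule, emit pieces
      intact[paste0(strand, c("_bases", "_meth", "_deamT", "_deamU"))] <- list(NULL)
      intact[[paste0(strand, "_start")]] <- NA_integer_
      intact[[paste0(strand, "_end")]] <- NA_integer_
      bounds <- c(0L, u, n + 1L)
      st0 <- mol[[paste0(strand, "_start")]]
      for (j in seq_len(length(bounds) - 1L)) {
        a <- bounds[j] + 1L; b <- bounds[j + 1L] - 1L
        if (b - a + 1L < min_len) next
        pc <- new_molecule(mol$source)
        pc[[paste0(strand, "_start")]] <- st0 + a - 1L
        pc[[paste0(strand, "_end")]] <- st0 + b
        for (f in c("_bases", "_meth", "_deamT", "_deamU"))
          pc[[paste0(strand, f)]] <- mol[[paste0(strand, f)]][a:b]
        pieces <- c(pieces, list(pc))
      }
    }
    keep_intact <- has_strand(intact, "top") || has_strand(intact, "bot")
    if (keep_intact) c(list(intact), pieces) else pieces
  })
  out <- unlist(per_mol, recursive = FALSE, use.names = FALSE)
  if (is.null(out)) list() else out
}
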