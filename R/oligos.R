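#' Spike-in control oligonucleotides
#'
#' Two families of double-stranded control oligos are supported, mirroring
#' the controls spiked into ancient extracts before treatment:
#'
#' * methylation controls: blunt 60-bp duplexes with exactly 15 cytosines on
#'   each strand, either all methylated (`control_full`) or all unmethylated
#'   (`control_none`). Published designs fix only the length and the 15-C
#'   constraint, so the default sequences here are synthetic stand-ins built
#'   from 4-bp units each carrying one C and one G (mixed CpG and non-CpG
#'   contexts); both can be overridden.
#' * exonuclease VII controls: a 60-bp strand hybridised to the reverse
#'   complement of its middle 40 bp, leaving one 10-bp single-stranded
#'   overhang at each end. Variants carry plain bases, uracils, or methylated
#'   cytosines in the overhangs.
#'
#' @param name which control to construct.
#' @param top_sequence optional replacement 60-bp top-strand sequence.
#' @return a `fragment_molecule` (see [fragmentize()]) with `source` set to
#'   the control name.
#' @export
#' @examples
#' ctl <- control_oligo("control_full")
#' sum(strsplit(control_oligo_sequence("control_full"), "")[[1]] == "C")  # 15
control_oligo <- function(name = c("control_full", "control_none",
                                   "control_exovii", "control_exovii_U",
                                   "control_exovii_mC"),
                          top_sequence = NULL) {
  name <- match.arg(name)
  top <- if (is.null(top_sequence)) control_oligo_sequence(name) else top_sequence
  tb <- strsplit(top, "", fixed = TRUE)[[1]]
  L <- length(tb)
  if (name %in% c("control_full", "control_none")) {
    if (sum(tb == "C") != 15L || sum(tb == "G") != 15L)
      stop("methylation control strands must carry exactly 15 Cs per strand",
           call. = FALSE)
    bb <- unname(COMPLEMENT[tb])           # bottom stored left-to-right
    mol <- new_molecule(source = name, top_start = 0L, top_end = L,
                        bot_start = 0L, bot_end = L,
                        top_bases = tb, bot_bases = bb)
    if (name == "control_full") {
      mol$top_meth <- mol$top_bases == "C"
      mol$bot_meth <- mol$bot_bases == "C"
    }
    return(mol)
  }
  # exoVII constructs: bottom strand spans [10, 50) -> 10-bp overhangs
  if (L != 60L) stop("exoVII control top strand must be 60 bp", call. = FALSE)
  ov <- c(1:10, 51:60)
  if (name == "control_exovii_U") tb[ov][tb[ov] == "T"] <- "U"
  bb <- unname(COMPLEMENT[tb])
  mol <- new_molecule(source = name, top_start = 0L, top_end = 60L,
                      bot_start = 10L, bot_end = 50L,
                      top_bases = tb, bot_bases = bb[11:50])
  if (name == "control_exovii_mC") mol$top_meth[ov] <- mol$top_bases[ov] == "C"
  mol
}

#' @rdname control_oligo
#' @export
control_oligo_sequence <- function(name) {
  units <- switch(name,
    control_full = c("ACGT", "CATG", "GTCA", "TGCA"),
    control_none = c("TCGA", "GACT", "CTAG", "AGCT"),
    c("ACTG", "TGAC", "CAGT", "GTCA"))  # exoVII family shares one template
  paste(rep(units, length.out = 15L), collapse = "")
}

#' Build the spiked control molecule pool for one simulated library
#'
#' @param config a [sim_config()].
#' @param names control names to include (default: the two methylation
#'   controls).
#' @param copies number of copies of each control in the pool.
#' @return list of `fragment_molecule`s.
#' @export
control_pool <- function(config, names = c("control_full", "control_none"),
                         copies = 100L) {
  mols <- lapply(names, control_oligo)
  rep(mols, each = copies)
}
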