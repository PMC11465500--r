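#' Apply methylation conversion chemistry and emit single strands
#'
#' Each present strand of each molecule is emitted independently as a
#' converted single-stranded sequence in sequencing (5' to 3') orientation:
#'
#' * `none`: no treatment; uracils read as thymine after amplification,
#'   cytosines are untouched. No length selection.
#' * `bisulfite`: unmethylated C converted to T with probability `conv_eff`,
#'   methylated C with probability `overconv`; U always reads T. Each strand
#'   survives the harsh chemistry with probability
#'   `plogis((length - survival_L50)/survival_k)`.
#' * `emseq`: methylated C converted with probability `p_protect_fail`
#'   (protection failure), unmethylated C *retained as C* with probability
#'   `p_deam_fail` (deamination failure, read as methylated downstream);
#'   same length-dependent survival.
#'
#' @param fragments a `fragment_molecule` or list thereof.
#' @param model `"none"`, `"bisulfite"` or `"emseq"`.
#' @param config a [sim_config()]. Draws from the current RNG stream.
#' @return a `data.table` with one row per surviving strand: `source`,
#'   `start`, `end` (0-based half-open genome span, NA for controls),
#'   `strand` ("top"/"bot"), `seq` (read-orientation string over ACGT),
#'   `length`.
#' @export
apply_conversion <- function(fragments, model = c("bisulfite", "emseq", "none"),
                             config) {
  model <- match.arg(model)
  if (inherits(fragments, "fragment_molecule")) fragments <- list(fragments)
  rows <- lapply(fragments, function(mol) {
    out <- list()
    for (strand in c("top", "bot")) {
      if (!has_strand(mol, strand)) next
      bases <- mol[[paste0(strand, "_bases")]]
      n <- length(bases)
      if (model != "none") {
        surv_p <- stats::plogis((n - config$survival_L50) / config$survival_k)
        if (stats::runif(1) >= surv_p) next
        meth <- mol[[paste0(strand, "_meth")]]
        isC <- bases == "C"
        u <- stats::runif(n)
        conv <- if (model == "bisulfite") {
          isC & ifelse(meth, u < config$overconv, u < config$conv_eff)
        } else {
          isC & ifelse(meth, u < config$p_protect_fail, u >= config$p_deam_fail)
        }
        bases[conv] <- "T"
      }
      bases[bases == "U"] <- "T"
      if (strand == "bot") bases <- rev(bases)   # bottom reads right-to-left
      out[[strand]] <- list(source = mol$source,
                            start = mol[[paste0(strand, "_start")]],
                            end = mol[[paste0(strand, "_end")]],
                            strand = strand,
                            seq = paste(bases, collapse = ""),
                            length = n)
    }
    out
  })
  rows <- unlist(rows, recursive = FALSE, use.names = FALSE)
  if (length(rows) == 0L) {
    return(data.table::data.table(source = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  seq = character(), length = integer()))
  }
  data.table::rbindlist(rows)
}

#' Sequence reads from a library pool
#'
#' Models amplification and sequencing of a library of `M` unique converted
#' molecules: reads are drawn from the pool **with replacement** (the source
#' of PCR duplicates), mixed with exogenous decoy reads (uniform random
#' sequence, same length distribution) and spiked control molecules
#' according to `endo_fraction` / `control_fraction`, and each base is
#' substituted uniformly at random with probability `seq_error`.
#'
#' @param endo_pool `data.table` from [apply_conversion()] of the endogenous
#'   library (the unique-molecule pool; its row count is the library size M).
#' @param config a [sim_config()].
#' @param n_reads number of reads to emit; default sizes the run so each
#'   endogenous molecule is sequenced about once on average.
#' @param control_pool optional converted control pool (`data.table` as
#'   above); required when `control_fraction > 0`.
#' @param treatment label recorded in the truth table.
#' @return list with `fastq` (`data.table`: `read_id`, `seq`, `qual`) and
#'   `truth` (`data.table`: `read_id`, `source`, `start`, `end`, `strand`,
#'   `treatment`).
#' @export
sequence_reads <- function(endo_pool, config, n_reads = NULL,
                           control_pool = NULL, treatment = "na") {
  if (config$endo_fraction + config$control_fraction > 1 + 1e-12)
    stop("sequence_reads: endo_fraction + control_fraction must be <= 1",
         call. = FALSE)
  M <- nrow(endo_pool)
  if (is.null(n_reads)) {
    n_reads <- if (config$endo_fraction > 0)
      round(M / config$endo_fraction) else M
  }
  n_reads <- as.integer(n_reads)
  src <- sample(c("endo", "ctrl", "deco"), n_reads, replace = TRUE,
                prob = c(config$endo_fraction, config$control_fraction,
                         max(0, 1 - config$endo_fraction - config$control_fraction)))
  n_endo <- sum(src == "endo"); n_ctrl <- sum(src == "ctrl")
  n_deco <- n_reads - n_endo - n_ctrl
  if (n_endo > 0L && M == 0L)
    stop("sequence_reads: empty endogenous pool with endo_fraction > 0", call. = FALSE)
  if (n_ctrl > 0L && (is.null(control_pool) || nrow(control_pool) == 0L))
    stop("sequence_reads: control_fraction > 0 but no control pool supplied",
         call. = FALSE)

  pick <- function(pool, k) pool[sample.int(nrow(pool), k, replace = TRUE)]
  parts <- list()
  if (n_endo) parts$endo <- pick(endo_pool, n_endo)
  if (n_ctrl) parts$ctrl <- pick(control_pool, n_ctrl)
  if (n_deco) {
    len <- round(stats::rlnorm(n_deco, config$length_mean_log, config$length_sd_log))
    len <- pmax(20L, pmin(250L, as.integer(len)))
    seqs <- vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
    parts$deco <- data.table::data.table(source = "exogenous", start = NA_integer_,
                                         end = NA_integer_, strand = NA_character_,
                                         seq = seqs, length = len)
  }
  reads <- data.table::rbindlist(parts, use.names = TRUE)
  # shuffle so read order carries no source signal
  reads <- reads[sample.int(nrow(reads))]
  reads[, read_id := sprintf("read%07d", seq_len(.N))]

  if (config$seq_error > 0) {
    reads[, seq := add_seq_errors(seq, config$seq_error)]
  }
  reads[, qual := strrep("I", nchar(seq))]
  list(fastq = reads[, .(read_id, seq, qual)],
       truth = data.table::data.table(read_id = reads$read_id,
                                      source = reads$source,
                                      start = reads$start, end = reads$end,
                                      strand = reads$strand,
                                      treatment = treatment))
}

# uniform per-base substitution errors over the ACGT alphabet
add_seq_errors <- function(seqs, rate) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  vapply(chars, function(b) {
    hit <- which(stats::runif(length(b)) < rate)
    for (i in hit) {
      a <- alt[[b[i]]]
      if (!is.null(a)) b[i] <- a[sample.int(3L, 1L)]
    }
    paste(b, collapse = "")
  }, character(1))
}

#' Simulate one complete sequencing library
#'
#' Runs the full forward model for one treatment arm: toy genome and truth
#' methylome, fragmentation, methylation assignment, deamination damage,
#' optional exonuclease VII pretreatment, optional USER uracil excision,
#' methylation conversion, and sequencing with decoys and spiked controls.
#' Fully deterministic under `config$seed` (+ `seed_offset`).
#'
#' @param config a [sim_config()].
#' @param pretreatment `"none"` or `"exovii"`.
#' @param user `"none"`, `"partial"` or `"full"` USER treatment.
#' @param conversion `"none"`, `"bisulfite"` or `"emseq"`.
#' @param n_reads reads to sequence (default: see [sequence_reads()]).
#' @param controls control names to spike (see [control_pool()]); ignored
#'   when `control_fraction` is 0.
#' @param seed_offset added to `config$seed` (used to decouple arms).
#' @param genome,methylome optionally reuse a genome/methylome built outside
#'   (they are rebuilt from the config when NULL).
#' @return list with `genome`, `methylome`, `fastq`, `truth`, `config`, and
#'   the arm description.
#' @export
simulate_library <- function(config,
                             pretreatment = c("none", "exovii"),
                             user = c("none", "partial", "full"),
                             conversion = c("bisulfite", "emseq", "none"),
                             n_reads = NULL,
                             controls = c("control_full", "control_none"),
                             seed_offset = 0L,
                             genome = NULL, methylome = NULL) {
  pretreatment <- match.arg(pretreatment)
  user <- match.arg(user)
  conversion <- match.arg(conversion)
  if (is.null(genome)) genome <- build_toy_genome(config)
  if (is.null(methylome)) methylome <- build_methylome(genome, config)
  set.seed(config$seed + 2L + seed_offset)

  frags <- fragmentize(genome, config)
  frags <- assign_methylation(frags, methylome, config)
  frags <- apply_deamination(frags, config)
  ctrls <- if (config$control_fraction > 0) control_pool(config, controls) else list()
  if (pretreatment == "exovii") {
    frags <- apply_exovii(frags, config)
    if (length(ctrls)) ctrls <- apply_exovii(ctrls, config)
  }
  if (user != "none") {
    frags <- apply_user(frags, user)
    if (length(ctrls)) ctrls <- apply_user(ctrls, user)
  }
  endo_pool <- apply_conversion(frags, conversion, config)
  ctrl_pool <- if (length(ctrls)) apply_conversion(ctrls, conversion, config) else NULL
  treatment <- paste(pretreatment, user, conversion, sep = "+")
  sr <- sequence_reads(endo_pool, config, n_reads = n_reads,
                       control_pool = ctrl_pool, treatment = treatment)
  list(genome = genome, methylome = methylome,
       fastq = sr$fastq, truth = sr$truth,
       config = config,
       arm = list(pretreatment = pretreatment, user = user,
                  conversion = conversion))
}
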