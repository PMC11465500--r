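#' Simulation configuration for the ancient-DNA methylation forward model
#'
#' Bundles every rate, distribution parameter and seed of the forward
#' simulator. Defaults describe a typical moderately preserved ancient bone
#' library: ~65 bp lognormal fragments, 1-2 bp single-stranded 5' overhangs,
#' strongly end-biased cytosine deamination, 99% bisulfite conversion
#' efficiency, 5% EM-seq deamination failure, and a read pool that is 40%
#' endogenous with a 2% spike-in control fraction.
#'
#' @param seed integer seed controlling every random draw downstream.
#' @param genome_length toy genome length in bp.
#' @param cgi_count number of CpG islands planted in the toy genome.
#' @param cgi_length length of each planted island, bp.
#' @param fragment_count number of endogenous molecules to simulate.
#' @param length_mean_log,length_sd_log lognormal fragment-length parameters
#'   (log-bp); lengths are truncated to \[20, 250\] bp.
#' @param overhang_geom_p geometric parameter for single-stranded overhang
#'   lengths (support 0, 1, 2, ...; mean (1-p)/p).
#' @param d_ss per-cytosine deamination probability on single-stranded
#'   overhang positions.
#' @param d_ds baseline per-cytosine deamination probability at interior
#'   double-stranded positions.
#' @param d_decay exponential decay rate (1/bp) of the excess end deamination
#'   on the double-stranded portion; at distance x from the nearest strand end
#'   the rate is `d_ds + (d_ss - d_ds) * exp(-d_decay * x)`.
#' @param conv_eff bisulfite conversion efficiency: probability an
#'   unmethylated C is deaminated to U (read T).
#' @param overconv bisulfite over-conversion: probability a methylated C is
#'   converted anyway.
#' @param p_protect_fail EM-seq protection failure: probability a methylated C
#'   is left unprotected and converted.
#' @param p_deam_fail EM-seq deamination failure: probability an unmethylated
#'   C escapes enzymatic deamination and stays C (read as methylated).
#' @param seq_error per-base sequencing substitution error rate.
#' @param endo_fraction proportion of sequenced reads drawn from the
#'   endogenous pool.
#' @param control_fraction proportion of sequenced reads drawn from spiked-in
#'   control oligos.
#' @param survival_L50,survival_k logistic length-dependent survival through
#'   chemical/enzymatic conversion: a strand of length L survives with
#'   probability `plogis((L - survival_L50)/survival_k)`.
#' @param exo_residual_support integer set of residual overhang lengths left
#'   by incomplete exonuclease VII trimming (default 3-5 bp).
#' @param noncpg_meth_rate probability a non-CpG cytosine is methylated
#'   (vertebrate default 0).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, fragment_count = 100)
#' cfg$d_ss
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       cgi_count = 5L,
                       cgi_length = 600L,
                       fragment_count = 20000L,
                       length_mean_log = log(65),
                       length_sd_log = 0.35,
                       overhang_geom_p = 0.45,
                       d_ss = 0.5,
                       d_ds = 0.02,
                       d_decay = 0.3,
                       conv_eff = 0.99,
                       overconv = 0.01,
                       p_protect_fail = 0.01,
                       p_deam_fail = 0.05,
                       seq_error = 0.001,
                       endo_fraction = 0.4,
                       control_fraction = 0.02,
                       survival_L50 = 50,
                       survival_k = 15,
                       exo_residual_support = c(3L, 4L, 5L),
                       noncpg_meth_rate = 0) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    cgi_count = as.integer(cgi_count),
    cgi_length = as.integer(cgi_length),
    fragment_count = as.integer(fragment_count),
    length_mean_log = length_mean_log,
    length_sd_log = length_sd_log,
    overhang_geom_p = overhang_geom_p,
    d_ss = d_ss, d_ds = d_ds, d_decay = d_decay,
    conv_eff = conv_eff, overconv = overconv,
    p_protect_fail = p_protect_fail, p_deam_fail = p_deam_fail,
    seq_error = seq_error,
    endo_fraction = endo_fraction, control_fraction = control_fraction,
    survival_L50 = survival_L50, survival_k = survival_k,
    exo_residual_support = as.integer(exo_residual_support),
    noncpg_meth_rate = noncpg_meth_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("overhang_geom_p", "d_ss", "d_ds", "conv_eff", "overconv",
             "p_protect_fail", "p_deam_fail", "seq_error", "endo_fraction",
             "control_fraction", "noncpg_meth_rate")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("sim_config: `", p, "` must be a single probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$genome_length <= 0) stop("sim_config: genome_length must be > 0", call. = FALSE)
  if (cfg$fragment_count < 0) stop("sim_config: fragment_count must be >= 0", call. = FALSE)
  if (length(cfg$exo_residual_support) == 0L)
    stop("sim_config: exo_residual_support must be nonempty", call. = FALSE)
  if (cfg$endo_fraction + cfg$control_fraction > 1 + 1e-12)
    stop("sim_config: endo_fraction + control_fraction must be <= 1", call. = FALSE)
  if (cfg$d_decay < 0) stop("sim_config: d_decay must be >= 0", call. = FALSE)
  if (cfg$survival_k <= 0) stop("sim_config: survival_k must be > 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome %d bp, %d CGIs; %d fragments (lognormal meanlog %.2f)\n",
              x$genome_length, x$cgi_count, x$fragment_count, x$length_mean_log))
  cat(sprintf("  damage: d_ss %.3g, d_ds %.3g, decay %.3g/bp; overhang geom p %.2f\n",
              x$d_ss, x$d_ds, x$d_decay, x$overhang_geom_p))
  cat(sprintf("  bisulfite conv_eff %.3g / overconv %.3g; emseq fail %.3g / %.3g\n",
              x$conv_eff, x$overconv, x$p_protect_fail, x$p_deam_fail))
  cat(sprintf("  pool: %.0f%% endogenous, %.1f%% controls; seed %d\n",
              100 * x$endo_fraction, 100 * x$control_fraction, x$seed))
  invisible(x)
}

#' Read or write a simulation config as JSON
#'
#' The JSON document mirrors the `sim_config` fields one-for-one, so a config
#' file fully determines a simulation (together with the seed it contains).
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
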