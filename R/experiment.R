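#' Define a multi-arm simulated experiment
#'
#' An experiment is one simulation configuration plus a list of treatment
#' arms, each combining a pretreatment (`none`/`exovii`), a USER mode
#' (`none`/`partial`/`full`) and a conversion model
#' (`none`/`bisulfite`/`emseq`) -- mirroring the laboratory pipeline
#' variations compared in direct ancient-DNA methylation sequencing.
#'
#' @param config a [sim_config()].
#' @param arms named list; each element is a list with `pretreatment`,
#'   `user`, `conversion`. Names are the arm labels and must be unique.
#' @return an `experiment_config`.
#' @export
#' @examples
#' ec <- experiment_config(sim_config(fragment_count = 500),
#'   arms = list(bisulfite = list(conversion = "bisulfite"),
#'               emseq     = list(conversion = "emseq")))
experiment_config <- function(config, arms) {
  stopifnot(inherits(config, "sim_config"))
  if (length(arms) == 0L) stop("experiment_config: need at least one arm", call. = FALSE)
  if (is.null(names(arms)) || anyDuplicated(names(arms)) || any(names(arms) == ""))
    stop("experiment_config: arm labels must be unique and nonempty", call. = FALSE)
  arms <- lapply(arms, function(a) {
    list(pretreatment = if (is.null(a$pretreatment)) "none" else a$pretreatment,
         user = if (is.null(a$user)) "none" else a$user,
         conversion = if (is.null(a$conversion)) "none" else a$conversion)
  })
  structure(list(config = config, arms = arms), class = "experiment_config")
}

#' Run a multi-arm simulated experiment
#'
#' For every arm: simulate the library, align and deduplicate, call
#' methylation, and compute the cross-arm QC metrics (percent endogenous,
#' CpG and non-CpG methylation percentages, CGI contrast, mean aligned
#' length, unique-read fraction). Arms share the same genome and truth
#' methylome; the per-arm RNG seed is `config$seed + arm index` so arms are
#' decoupled but reproducible. Each converted arm's beta track is compared
#' to the truth methylome over segments of the truth track. A failing arm
#' is recorded with its error and the remaining arms continue.
#'
#' @param experiment an [experiment_config()].
#' @param n_reads reads per arm (default: see [sequence_reads()]).
#' @param segment_args list of extra arguments for [segment_track()].
#' @return list of class `experiment_report` with `summary` (one row per
#'   arm), `arms` (per-arm detail: library, alignments, calls, beta track,
#'   segment means), `truth_segments`, `genome`, `methylome`, `errors`.
#' @export
run_experiment <- function(experiment, n_reads = NULL, segment_args = list()) {
  stopifnot(inherits(experiment, "experiment_config"))
  cfg <- experiment$config
  genome <- build_toy_genome(cfg)
  methylome <- build_methylome(genome, cfg)
  truth_track <- data.table::data.table(position = methylome$pos,
                                        beta = methylome$beta)
  truth_segments <- do.call(segment_track,
                            c(list(truth_track), segment_args))
  truth_seg_means <- segment_means(truth_segments, truth_track)

  arm_results <- list(); errors <- list(); rows <- list()
  for (i in seq_along(experiment$arms)) {
    label <- names(experiment$arms)[i]
    arm <- experiment$arms[[i]]
    res <- tryCatch({
      lib <- simulate_library(cfg,
                              pretreatment = arm$pretreatment,
                              user = arm$user,
                              conversion = arm$conversion,
                              n_reads = n_reads,
                              seed_offset = i,
                              genome = genome, methylome = methylome)
      al <- align_library(lib)
      aln <- al$alignments
      dedup <- aln[mapq >= 30L & duplicate == FALSE]
      conv_based <- !identical(arm$conversion, "none")
      calls <- if (conv_based) pileup_calls(aln, lib$fastq, genome) else NULL
      track <- if (conv_based) beta_track(calls) else NULL
      ctxs <- if (conv_based) context_summary(calls) else
        c(CpG = NA_real_, CHG = NA_real_, CHH = NA_real_, nonCpG = NA_real_)
      cgi <- if (conv_based) cgi_contrast(calls, genome$cgi_intervals) else
        list(mc_pct_inside = NA_real_, mc_pct_outside = NA_real_,
             difference = NA_real_)
      seg_means <- if (conv_based) segment_means(truth_segments, track) else
        rep(NA_real_, nrow(truth_segments))
      rows[[label]] <- data.table::data.table(
        arm = label,
        pretreatment = arm$pretreatment, user = arm$user,
        conversion = arm$conversion,
        n_raw = al$n_raw,
        pct_endogenous = al$pct_endogenous,
        pct_unique = if (nrow(aln)) 100 * mean(!aln$duplicate) else NA_real_,
        mean_length = if (nrow(dedup)) mean(dedup$end - dedup$position) else NA_real_,
        cpg_mc_pct = ctxs[["CpG"]],
        noncpg_mc_pct = ctxs[["nonCpG"]],
        cgi_inside = cgi$mc_pct_inside, cgi_outside = cgi$mc_pct_outside,
        cgi_difference = cgi$difference)
      list(library = lib, alignments = aln, calls = calls, track = track,
           segment_means = seg_means)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[label]] <- conditionMessage(res)
      warning("arm '", label, "' failed: ", conditionMessage(res), call. = FALSE)
    } else {
      arm_results[[label]] <- res
    }
  }
  structure(list(summary = data.table::rbindlist(rows),
                 arms = arm_results,
                 truth_segments = truth_segments,
                 truth_segment_means = truth_seg_means,
                 genome = genome, methylome = methylome,
                 errors = errors),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  print(x$summary)
  if (length(x$errors))
    cat("failed arms:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
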