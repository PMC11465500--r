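tiny_genome <- function(seq) {
  structure(list(name = "toy1", sequence = seq,
                 cgi_intervals = data.frame(start = integer(0), end = integer(0))),
            class = "toy_genome")
}

test_that("context classification follows the CpG/CHG/CHH definitions", {
  g <- tiny_genome("ACGT")
  expect_equal(classify_context(g, 1L, "forward"), "CpG")
  expect_equal(classify_context(tiny_genome("ACAG"), 1L, "forward"), "CHG")
  expect_equal(classify_context(tiny_genome("ACAT"), 1L, "forward"), "CHH")
  # reverse-strand C at position 2 of ACGT: its leftward neighbour is the
  # complement of C, i.e. G -> CpG
  expect_equal(classify_context(g, 2L, "reverse"), "CpG")
  # reverse-strand C with complement(A) neighbours -> CHH
  expect_equal(classify_context(tiny_genome("AAGT"), 2L, "reverse"), "CHH")
  expect_error(classify_context(g, 0L, "forward"), "not C")
  # genome-end truncation flagged
  ctx <- classify_context(tiny_genome("AAAC"), 3L, "forward")
  expect_equal(as.character(ctx), "CHH")
  expect_true(attr(ctx, "truncated"))
})

test_that("the vectorised context table matches the scalar classifier", {
  set.seed(7)
  g <- tiny_genome(rand_dna(500))
  ctx <- paleometh:::context_tables(g)
  chars <- strsplit(g$sequence, "")[[1]]
  for (p in which(chars == "C") - 1L) {
    expect_equal(ctx$fwd[p + 1L],
                 as.character(classify_context(g, p, "forward")))
  }
  for (p in which(chars == "G") - 1L) {
    expect_equal(ctx$rev[p + 1L],
                 as.character(classify_context(g, p, "reverse")))
  }
})

test_that("pileup counts C as methylated and T as unmethylated", {
  g <- tiny_genome("AACGTACGTT")
  mk_aln <- function(view) data.table::data.table(
    read_id = "r1", position = 0L, end = 10L, strand_view = view,
    mismatches = 0L, mapq = 37L, duplicate = FALSE)
  # OT read retaining first C, converting second
  reads <- data.table::data.table(read_id = "r1", seq = "AACGTATGTT")
  calls <- pileup_calls(mk_aln("OT"), reads, g)
  fwd <- calls[calls$strand == "forward"]
  expect_equal(fwd[fwd$position == 2L]$n_methylated, 1L)
  expect_equal(fwd[fwd$position == 2L]$n_unmethylated, 0L)
  expect_equal(fwd[fwd$position == 6L]$n_methylated, 0L)
  expect_equal(fwd[fwd$position == 6L]$n_unmethylated, 1L)
  expect_equal(fwd[fwd$position == 2L]$context, "CpG")

  # OB read informs reverse-strand Cs (reference Gs)
  # bottom strand of AACGTACGTT read 5'->3' is AACGTACGTT reverse-complemented
  ob_read <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$sequence)))
  calls2 <- pileup_calls(mk_aln("OB"), data.table::data.table(read_id = "r1",
                                                              seq = ob_read), g)
  rev <- calls2[calls2$strand == "reverse"]
  expect_true(all(rev$n_methylated == 1L))   # unconverted bottom strand: all C
  expect_setequal(rev$position, c(3L, 7L))   # the Gs of the CpGs
  expect_true(all(rev$context == "CpG"))

  # non-C/T read bases at a reference C are ignored
  readsN <- data.table::data.table(read_id = "r1", seq = "AAGGTATGTT")
  callsN <- pileup_calls(mk_aln("OT"), readsN, g)
  expect_equal(nrow(callsN[callsN$position == 2L & callsN$strand == "forward"]), 0L)

  # length mismatch is a contract error
  bad <- data.table::data.table(read_id = "r1", seq = "AACGT")
  expect_error(pileup_calls(mk_aln("OT"), bad, g), "length mismatch")
})

test_that("beta track arithmetic and coverage floor", {
  calls <- data.table::data.table(
    position = c(5L, 9L), strand = "forward", context = "CpG",
    n_methylated = c(7L, 2L), n_unmethylated = c(3L, 2L))
  bt <- beta_track(calls)
  expect_equal(bt$beta, c(70, 50))
  expect_equal(bt$coverage, c(10L, 4L))
  bt5 <- beta_track(calls, min_coverage = 5L)
  expect_equal(bt5$position, 5L)             # coverage-4 position absent
})

test_that("context summary pools strands and reports NA for empty contexts", {
  calls <- data.table::data.table(
    position = c(1L, 2L, 3L), strand = c("forward", "reverse", "forward"),
    context = c("CpG", "CpG", "CHH"),
    n_methylated = c(8L, 6L, 1L), n_unmethylated = c(2L, 4L, 99L))
  cs <- context_summary(calls)
  expect_equal(unname(cs["CpG"]), 100 * 14 / 20)
  expect_equal(unname(cs["CHH"]), 1.0)
  expect_true(is.na(cs["CHG"]))
  expect_equal(unname(cs["nonCpG"]), 1.0)
})

test_that("ideal-chemistry pipeline recovers per-CpG truth betas", {
  cfg <- ideal_config(seed = 51, genome_length = 15000L, cgi_count = 1L,
                      fragment_count = 15000L)
  lib <- simulate_library(cfg, conversion = "bisulfite")
  al <- align_library(lib)
  calls <- pileup_calls(al$alignments, lib$fastq, lib$genome)
  bt <- beta_track(calls, min_coverage = 30L)
  cpg <- bt[bt$context == "CpG"]
  # map both strands back to the site's forward position
  site_pos <- ifelse(cpg$strand == "forward", cpg$position, cpg$position - 1L)
  truth <- lib$methylome$beta[match(site_pos, lib$methylome$pos)]
  keep <- !is.na(truth)
  expect_gt(sum(keep), 100)
  se <- 100 * sqrt(pmax(truth[keep] / 100 * (1 - truth[keep] / 100), 1e-9) /
                     cpg$coverage[keep])
  within3 <- abs(cpg$beta[keep] - truth[keep]) <= 3 * se + 1e-9
  expect_gt(mean(within3), 0.98)

  # calls conservation: total calls bounded by covered reference Cs
  dedup <- al$alignments[al$alignments$mapq >= 30 & !al$alignments$duplicate]
  g <- strsplit(lib$genome$sequence, "")[[1]]
  covered_c <- sum(vapply(seq_len(nrow(dedup)), function(i) {
    sel <- (dedup$position[i] + 1L):dedup$end[i]
    if (dedup$strand_view[i] == "OT") sum(g[sel] == "C") else sum(g[sel] == "G")
  }, numeric(1)))
  expect_lte(sum(calls$n_methylated + calls$n_unmethylated), covered_c)
})

test_that("end-biased damage lowers apparent CpG methylation", {
  base <- list(seed = 61, genome_length = 15000L, cgi_count = 1L,
               fragment_count = 1500L, seq_error = 0)
  n_rep <- 20L
  deltas <- vapply(seq_len(n_rep), function(r) {
    b <- base; b$seed <- base$seed + r
    cfg0 <- do.call(sim_config, c(b, list(d_ss = 0, d_ds = 0)))
    cfgD <- do.call(sim_config, c(b, list(d_ss = 0.5, d_ds = 0.02)))
    g <- build_toy_genome(cfg0); m <- build_methylome(g, cfg0)
    s0 <- pipeline_context_summary(cfg0, "bisulfite", genome = g, methylome = m)
    sD <- pipeline_context_summary(cfgD, "bisulfite", genome = g, methylome = m)
    sD[["CpG"]] - s0[["CpG"]]
  }, numeric(1))
  # mC -> T damage can only deflate the apparent beta (paired seeds)
  expect_gte(mean(deltas < 0), 0.9)
  expect_lt(mean(deltas), 0)
})
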