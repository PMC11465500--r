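# hand-built molecule helpers ------------------------------------------------

# blunt double-stranded molecule from a top-strand string
make_duplex <- function(top, start = 0L, source = "endogenous") {
  tb <- strsplit(top, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  mol <- paleometh:::new_molecule(source, top_start = start,
                                  top_end = start + length(tb),
                                  bot_start = start, bot_end = start + length(tb),
                                  top_bases = tb, bot_bases = unname(comp[tb]))
  mol
}

test_that("zero deamination rates leave molecules unchanged", {
  cfg <- sim_config(d_ss = 0, d_ds = 0)
  mol <- make_duplex("ACGTACGT")
  set.seed(1)
  out <- apply_deamination(mol, cfg)
  expect_identical(out$top_bases, mol$top_bases)
  expect_false(any(out$top_deamT | out$top_deamU | out$bot_deamT | out$bot_deamU))
})

test_that("forced deamination turns mC into T and C into U", {
  cfg <- sim_config(d_ss = 1, d_ds = 1)
  mol <- make_duplex("ACCGGT")
  mol$top_meth[2] <- TRUE                   # first C methylated
  set.seed(2)
  out <- apply_deamination(mol, cfg)
  expect_identical(out$top_bases[2], "T")   # mC deaminates directly to T
  expect_true(out$top_deamT[2])
  expect_identical(out$top_bases[3], "U")   # unmethylated C becomes U
  expect_true(out$top_deamU[3])
  # chemistry invariants: deamT only on methylated Cs, no methylated U
  expect_false(any(out$top_deamT & !mol$top_meth))
  expect_false(any(out$top_bases == "U" & out$top_meth))
})

test_that("deamination is end-biased on double-stranded fragments", {
  cfg <- sim_config(seed = 1, d_ss = 0.9, d_ds = 0.01, d_decay = 0.5,
                    genome_length = 30000L, cgi_count = 0L,
                    fragment_count = 6000L, overhang_geom_p = 1)  # blunt
  g <- build_toy_genome(cfg)
  set.seed(cfg$seed)
  frags <- fragmentize(g, cfg)
  frags <- apply_deamination(frags, cfg)
  # aggregate deamination rate at distance 0-1 vs interior (>15 bp from ends)
  tally <- function(sel_fun) {
    hit <- 0L; tot <- 0L
    for (m in frags) {
      n <- length(m$top_bases)
      d <- pmin(seq_len(n) - 1L, n - seq_len(n))
      sel <- sel_fun(d) & (m$top_bases %in% c("C", "U") | m$top_deamT)
      isdeam <- (m$top_deamU | m$top_deamT)[sel]
      hit <- hit + sum(isdeam); tot <- tot + sum(sel)
    }
    hit / tot
  }
  r_end <- tally(function(d) d <= 1)
  r_int <- tally(function(d) d > 15)
  expect_gt(r_end, 10 * r_int)
  expect_lt(abs(r_int - cfg$d_ds), 0.01)
})

test_that("exoVII reduces overhangs to min(L, residual) and spares the core", {
  cfg <- sim_config(exo_residual_support = 3L)
  ctl <- control_oligo("control_exovii")      # 10-bp overhang each end
  set.seed(3)
  out <- apply_exovii(ctl, cfg)
  expect_equal(out$bot_start - out$top_start, 3L)
  expect_equal(out$top_end - out$bot_end, 3L)
  expect_equal(length(out$top_bases), 60L - 2L * (10L - 3L))
  expect_identical(out$bot_bases, ctl$bot_bases)  # core untouched

  # min rule: overhang shorter than the residual is untouched
  mol <- make_duplex("ACGTACGTACGTACGTACGTACGTACGT")
  mol$bot_start <- mol$top_start + 2L          # 2-bp overhang
  mol$bot_bases <- mol$bot_bases[-(1:2)]
  mol$bot_meth <- mol$bot_meth[-(1:2)]
  mol$bot_deamT <- mol$bot_deamT[-(1:2)]
  mol$bot_deamU <- mol$bot_deamU[-(1:2)]
  set.seed(4)
  out <- apply_exovii(mol, cfg)
  expect_equal(out$bot_start - out$top_start, 2L)

  # blunt molecule unchanged
  blunt <- make_duplex("ACGTACGT")
  expect_identical(apply_exovii(blunt, cfg), blunt)
})

test_that("post-exoVII overhangs lie in {0,1,2} union the residual support", {
  cfg <- sim_config(seed = 12, genome_length = 30000L, cgi_count = 0L,
                    fragment_count = 3000L, overhang_geom_p = 0.2)
  g <- build_toy_genome(cfg)
  set.seed(cfg$seed)
  frags <- apply_exovii(fragmentize(g, cfg), cfg)
  oh <- unlist(lapply(frags, function(m) {
    if (is.null(m$bot_bases)) return(NULL)
    c(m$bot_start - m$top_start, m$top_end - m$bot_end)
  }))
  expect_true(all(oh %in% c(0:2, cfg$exo_residual_support)))
  expect_true(any(oh %in% cfg$exo_residual_support))  # trimming happened
})

test_that("USER excises uracils and cuts strands into pieces", {
  mol <- make_duplex("ACUGGA")
  out <- apply_user(mol, "full", min_len = 1L)
  # bottom strand (no U) stays; top strand cut into AC and GGA
  tops <- Filter(function(m) !is.null(m$top_bases), out)
  bots <- Filter(function(m) !is.null(m$bot_bases), out)
  expect_equal(length(bots), 1L)
  top_seqs <- sort(vapply(tops, function(m) paste(m$top_bases, collapse = ""),
                          character(1)))
  expect_identical(top_seqs, c("AC", "GGA"))
  # piece coordinates track the cut
  st <- sort(vapply(tops, `[[`, integer(1), "top_start"))
  expect_identical(st, c(0L, 3L))

  # no uracil -> unchanged
  clean <- make_duplex("ACGTACGT")
  expect_identical(apply_user(clean, "full"), list(clean))

  # short pieces are dropped at the default threshold
  out20 <- apply_user(mol, "full")
  expect_true(all(vapply(out20, function(m)
    length(m$top_bases) >= 20 || is.null(m$top_bases), logical(1))))
})

test_that("partial USER retains terminal uracils", {
  mol <- make_duplex("UACGG")
  out <- apply_user(mol, "partial", min_len = 1L, terminal_retain_prob = 1)
  expect_equal(length(out), 1L)
  expect_identical(paste(out[[1]]$top_bases, collapse = ""), "UACGG")

  # internal U still cuts in partial mode
  mol2 <- make_duplex("ACUGGA")
  out2 <- apply_user(mol2, "partial", min_len = 1L, terminal_retain_prob = 1)
  tops <- Filter(function(m) !is.null(m$top_bases), out2)
  expect_identical(sort(vapply(tops, function(m) paste(m$top_bases, collapse = ""),
                               character(1))), c("AC", "GGA"))
})

test_that("deamination conserves chemistry across a simulated batch", {
  cfg <- sim_config(seed = 13, genome_length = 30000L, cgi_count = 2L,
                    fragment_count = 2000L)
  g <- build_toy_genome(cfg)
  meth <- build_methylome(g, cfg)
  set.seed(cfg$seed)
  frags <- assign_methylation(fragmentize(g, cfg), meth, cfg)
  n_meth <- sum(unlist(lapply(frags, function(m) sum(m$top_meth) + sum(m$bot_meth))))
  frags <- apply_deamination(frags, cfg)
  n_deamT <- sum(unlist(lapply(frags, function(m) sum(m$top_deamT) + sum(m$bot_deamT))))
  expect_lte(n_deamT, n_meth)
  no_meth_u <- all(vapply(frags, function(m)
    !any((m$top_bases == "U") & m$top_meth) &&
      (is.null(m$bot_bases) || !any((m$bot_bases == "U") & m$bot_meth)),
    logical(1)))
  expect_true(no_meth_u)
})
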