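# Depth filtering, windowed heterozygosity, ROH calling/summary,
# pseudodiploid construction, and psmcfa export.

test_that("depth filter keeps the boundary-inclusive [mean/3, 2*mean] set and is idempotent", {
  tr <- tibble::tibble(scaffold = "s1", pos = 1:4, gt = "hom",
                       depth = c(9L, 10L, 60L, 61L))
  out <- filter_by_depth(tr, mean_depth = 30)
  expect_equal(out$depth, c(10L, 60L))

  same <- tibble::tibble(scaffold = "s1", pos = 1:5, gt = "hom",
                         depth = rep(30L, 5))
  expect_equal(nrow(filter_by_depth(same, 30)), 5)

  # idempotence with frozen bounds
  cfg <- sim_config(seed = 31, n_scaffolds = 1, scaffold_length = 2e5)
  track <- simulate_genotype_track(cfg)$track
  mu <- mean(track$depth)
  once <- filter_by_depth(track, mu)
  twice <- filter_by_depth(once, mu)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))

  # retained fraction matches a direct recount of the simulated depths
  direct <- mean(track$depth >= mu / 3 & track$depth <= 2 * mu)
  expect_equal(nrow(once) / nrow(track), direct)
  expect_equal(nrow(filter_by_depth(track[0, ], 30)), 0)
})

test_that("windowed heterozygosity tiles scaffolds and conserves counts", {
  # 2.5-Mb scaffold, 1-Mb windows -> 3 windows, third partial
  cfg <- sim_config(seed = 7, n_scaffolds = 1, scaffold_length = 2.5e6,
                    background_het_rate = 0.01)
  sim <- simulate_genotype_track(cfg)
  w <- window_heterozygosity(sim$track, sim$scaffold_lengths)
  expect_equal(nrow(w), 3)
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(w$end - w$start + 1, c(1e6, 1e6, 5e5))
  # conservation against the track totals
  expect_equal(sum(w$n_het), sum(sim$track$gt == "het"))
  expect_equal(sum(w$n_called), nrow(sim$track))

  # direct arithmetic: 1,000 called, 100 het -> het = 0.1
  tr <- tibble::tibble(scaffold = "s", pos = seq_len(1000) * 10,
                       gt = rep(c("het", rep("hom", 9)), 100), depth = 30L)
  w2 <- window_heterozygosity(tr, c(s = 1e4), window_size = 1e4)
  expect_equal(w2$het, 0.1)
  # zero-call window reports NA
  w3 <- window_heterozygosity(tr, c(s = 2e4), window_size = 1e4)
  expect_true(is.na(w3$het[2]))
})

test_that("ROH calling matches hand-enumerated runs", {
  # 40 windows of 20 kb; windows 6-35 fully homozygous -> one 600-kb run
  tr <- track_from_windows(40, qualifying = 6:35)
  runs <- call_roh(tr, c(s1 = 40 * 20000))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, 100001)
  expect_equal(runs$end, 700000)
  expect_equal(runs$length, 600000)
  expect_equal(runs$n_windows, 30L)

  # 24 consecutive qualifying windows stay below the 25-window minimum
  tr24 <- track_from_windows(40, qualifying = 6:29)
  expect_equal(nrow(call_roh(tr24, c(s1 = 40 * 20000))), 0)

  # threshold saturation: every window qualifies -> one run per scaffold
  runs_all <- call_roh(tr, c(s1 = 40 * 20000), het_threshold = 1)
  expect_equal(nrow(runs_all), 1)
  expect_equal(runs_all$n_windows, 40L)

  # a scaffold shorter than one window yields nothing
  tiny <- tibble::tibble(scaffold = "t", pos = c(10, 20), gt = "hom",
                         depth = 30L)
  expect_equal(nrow(call_roh(tiny, c(t = 50), window_size = 100,
                             min_windows = 1)),
               1) # one partial window qualifies when min_windows = 1
  expect_equal(nrow(call_roh(tiny, c(t = 50), window_size = 100)), 0)
})

test_that("zero-call windows break runs unless configured otherwise", {
  tr <- track_from_windows(40, qualifying = 6:35)
  # empty out windows 20-21 entirely
  tr_gap <- dplyr::filter(tr, !(pos > 19 * 20000 & pos <= 21 * 20000))
  runs <- call_roh(tr_gap, c(s1 = 40 * 20000))
  expect_equal(nrow(runs), 0)  # both fragments now < 25 windows
  runs2 <- call_roh(tr_gap, c(s1 = 40 * 20000),
                    empty_windows_qualify = TRUE)
  expect_equal(nrow(runs2), 1)
  expect_equal(runs2$n_windows, 30L)
})

test_that("ROH totals are monotone in threshold and minimum window count", {
  set.seed(61)
  for (i in 1:100) {
    n_win <- 60
    tr <- track_from_windows(n_win,
                             qualifying = which(runif(n_win) < 0.6))
    lens <- c(s1 = n_win * 20000)
    tot <- function(th, mw = 25) {
      r <- call_roh(tr, lens, het_threshold = th, min_windows = mw)
      sum(r$length)
    }
    expect_lte(tot(0.01), tot(0.05))
    expect_lte(tot(0.05), tot(1))
    expect_lte(tot(0.05, mw = 30), tot(0.05, mw = 10))
    froh <- summarize_roh(call_roh(tr, lens), sum(lens))$froh
    expect_gte(froh, 0)
    expect_lte(froh, 1)
  }
})

test_that("ROH summary computes Froh, bins, and the longest run", {
  runs <- tibble::tibble(scaffold = c("a", "b"),
                         start = c(1, 1), end = c(6e5, 4e5),
                         length = c(6e5, 4e5), n_windows = c(30L, 20L),
                         mean_het = c(0, 0))
  s <- summarize_roh(runs[1, ], assessed_length = 1.2e6)
  expect_equal(s$froh, 0.5)
  # only runs >= 500 kb count toward Froh
  s2 <- summarize_roh(runs, assessed_length = 2e6)
  expect_equal(s2$froh, 6e5 / 2e6)
  expect_equal(s2$n_runs_min_length, 1)
  expect_equal(s2$longest$scaffold, "a")
  expect_equal(sum(s2$bins$n), 1)
  expect_error(summarize_roh(runs, 0), "positive")
  expect_error(summarize_roh(runs, 1e5), "exceeds")
  g <- glance(s2)
  expect_equal(g$longest_bp, 6e5)
  expect_equal(g$n_runs, 2)
})

test_that("planted ROH fraction is recovered within window quantisation", {
  cfg <- sim_config(
    seed = 44, n_scaffolds = 1, scaffold_length = 4e6,
    background_het_rate = 0.1,
    roh_segments = list(
      list(scaffold = "scaffold_1", start = 500001, end = 1700000,
           residual_het_rate = 0),
      list(scaffold = "scaffold_1", start = 2500001, end = 3100000,
           residual_het_rate = 0)
    )
  )
  sim <- simulate_genotype_track(cfg)
  runs <- call_roh(sim$track, sim$scaffold_lengths)
  s <- summarize_roh(runs, assessed_length = 4e6)
  f_true <- (1.2e6 + 6e5) / 4e6
  expect_lt(abs(s$froh - f_true), 2 * 20000 / 4e6 * 2)
})

test_that("pseudodiploid sampling behaves at the forced and stochastic limits", {
  hap <- function(alleles, scaffold = "s") {
    tibble::tibble(scaffold = scaffold, pos = seq_along(alleles) * 100,
                   gt = "hom", depth = 30L, allele = alleles)
  }
  a <- hap(rep("A", 10))
  expect_true(all(make_pseudodiploid(a, a, seed = 1)$gt == "hom"))

  b <- hap(c(rep("A", 7), rep("G", 3)))
  pd <- make_pseudodiploid(a, b, seed = 1)
  expect_equal(sum(pd$gt == "het"), 3)
  expect_equal(pd$pos[pd$gt == "het"], c(8, 9, 10) * 100)

  # A hom-ref, B het at every site -> expected het fraction 0.5
  n <- 10000
  A <- tibble::tibble(scaffold = "s", pos = seq_len(n), gt = "hom",
                      depth = 30L, allele1 = "A", allele2 = "A")
  B <- tibble::tibble(scaffold = "s", pos = seq_len(n), gt = "het",
                      depth = 30L, allele1 = "A", allele2 = "G")
  pd2 <- make_pseudodiploid(A, B, seed = 2)
  expect_lt(abs(mean(pd2$gt == "het") - 0.5), 4 * sqrt(0.25 / n))

  # no shared sites -> empty with warning
  c_track <- hap(rep("A", 5), scaffold = "other")
  expect_warning(empty <- make_pseudodiploid(a, c_track), "No shared")
  expect_equal(nrow(empty), 0)

  # deterministic given seed
  expect_identical(make_pseudodiploid(A, B, seed = 2), pd2)
})

test_that("psmcfa bins follow the K/T/N convention and recount exactly", {
  tr <- tibble::tibble(scaffold = "s", pos = 1:300,
                       gt = ifelse(1:300 == 150, "het", "hom"), depth = 30L)
  f <- withr::local_tempfile(fileext = ".psmcfa")
  write_psmcfa(tr, c(s = 300), f)
  rec <- read_psmcfa(f)
  expect_equal(paste0(rec$s, collapse = ""), "TKT")

  # zero callability -> all N
  f2 <- withr::local_tempfile(fileext = ".psmcfa")
  write_psmcfa(tr[0, ], c(s = 300), f2)
  expect_equal(paste0(read_psmcfa(f2)$s, collapse = ""), "NNN")

  # K-bin count equals an independent recount on a simulated track
  cfg <- sim_config(seed = 3, n_scaffolds = 2, scaffold_length = 1e5,
                    background_het_rate = 0.01)
  sim <- simulate_genotype_track(cfg)
  f3 <- withr::local_tempfile(fileext = ".psmcfa")
  write_psmcfa(sim$track, sim$scaffold_lengths, f3)
  rec3 <- read_psmcfa(f3)
  hets <- dplyr::filter(sim$track, gt == "het")
  for (scaf in names(rec3)) {
    k_direct <- length(unique(
      floor((hets$pos[hets$scaffold == scaf] - 1) / 100)
    ))
    expect_equal(sum(rec3[[scaf]] == "K"), k_direct)
  }
  # 60-character line wrapping
  lines <- readLines(f3)
  body <- lines[!grepl("^>", lines)]
  expect_true(all(nchar(body) <= 60))
})
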