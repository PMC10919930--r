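# Per-column partial F tests, permutation machinery, and the
# low-complexity annotation.

test_that("worked example matches the explicit sums-of-squares oracle", {
  ex <- worked_example()
  fit <- fit_column_model(ex$traits, ex$alleles)
  oracle <- anova_oracle(ex$traits$log_mass, ex$alleles)
  expect_equal(fit$f_statistic, 121.5, tolerance = 1e-10)
  expect_equal(fit$f_statistic, oracle$f, tolerance = 1e-10)
  expect_equal(fit$df_num, 1L)
  expect_equal(fit$df_den, 4L)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
})

test_that("F and p are invariant to rescaling log mass (log-base change)", {
  ex <- worked_example()
  fit <- fit_column_model(ex$traits, ex$alleles)
  tr10 <- ex$traits
  tr10$log_mass <- tr10$log_mass / log(10)
  fit10 <- fit_column_model(tr10, ex$alleles)
  expect_equal(fit10$f_statistic, fit$f_statistic, tolerance = 1e-12)
  expect_equal(fit10$p_value, fit$p_value, tolerance = 1e-12)
})

test_that("engine agrees with lm/anova on random columns, both models", {
  set.seed(12)
  panel <- small_panel(5, 6)
  for (i in 1:40) {
    y <- rnorm(11, 6, 2)
    traits <- tibble::tibble(species = panel$species, mass_kg = exp(y),
                             log_mass = y, habitat = panel$habitat)
    al <- sample(c("A", "C", "G", "-", "N"), 11, replace = TRUE,
                 prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
    names(al) <- panel$species
    used <- al %in% c("A", "C", "G", "T")
    for (wh in c(FALSE, TRUE)) {
      fit <- fit_column_model(traits, al, with_habitat = wh)
      if (!fit$tested) next
      d <- data.frame(y = y[used], a = factor(al[used]),
                      h = factor(panel$habitat[used]))
      full <- if (wh) lm(y ~ h + a, d) else lm(y ~ a, d)
      red <- if (wh) lm(y ~ h, d) else lm(y ~ 1, d)
      av <- anova(red, full)
      expect_equal(fit$f_statistic, av$F[2], tolerance = 1e-9)
      expect_equal(fit$p_value, av$`Pr(>F)`[2], tolerance = 1e-9)
      expect_equal(fit$df_num, av$Df[2])
      expect_equal(fit$df_den, av$Res.Df[2])
    }
  }
})

test_that("degenerate columns are flagged, not mis-tested", {
  ex <- worked_example()
  mono <- stats::setNames(rep("A", 6), ex$traits$species)
  fit <- fit_column_model(ex$traits, mono)
  expect_false(fit$tested)
  expect_true(is.na(fit$p_value))
  expect_match(fit$flags, "monomorphic_skipped")

  # allele perfectly collinear with habitat: 0 estimable allele df
  coll <- stats::setNames(c("T", "T", "T", "C", "C", "C"),
                          ex$traits$species)
  fit2 <- fit_column_model(ex$traits, coll, with_habitat = TRUE)
  expect_false(fit2$tested)
  expect_match(fit2$flags, "collinear_skipped")

  # zero residual variance -> p = 0 with a flag
  tr0 <- ex$traits
  tr0$log_mass <- c(10, 10, 10, 2, 2, 2)
  tr0$mass_kg <- exp(tr0$log_mass)
  fit3 <- fit_column_model(tr0, ex$alleles)
  expect_true(fit3$tested)
  expect_equal(fit3$p_value, 0)
  expect_match(fit3$flags, "zero_residual")

  # singleton allele class tested but flagged
  singl <- stats::setNames(c("T", rep("C", 5)), ex$traits$species)
  fit4 <- fit_column_model(tr0, singl)
  expect_true(fit4$tested)
  expect_match(fit4$flags, "singleton_class")
})

test_that("scan is invariant to alignment row order and keeps the tested set fixed under permutation", {
  cfg <- sim_config(seed = 17, n_columns = 300)
  traits <- simulate_trait_table(cfg)
  aln <- simulate_alignment(traits, cfg)$alignment
  scan <- scan_alignment(aln, traits, annotate_lc = FALSE)
  shuffled <- aln[sample(nrow(aln)), , drop = FALSE]
  expect_equal(tidy(scan_alignment(shuffled, traits, annotate_lc = FALSE)),
               tidy(scan))
  set.seed(1)
  scan_perm <- scan_alignment(aln, permute_traits(traits),
                              annotate_lc = FALSE)
  expect_identical(scan_perm$tested, scan$tested)
  expect_error(scan_alignment(aln[, 0], traits), "non-empty")
})

test_that("permutations preserve the right multisets", {
  cfg <- sim_config(seed = 2)
  traits <- simulate_trait_table(cfg)
  set.seed(5)
  p <- permute_traits(traits, stratified = TRUE)
  for (h in c("aquatic", "terrestrial")) {
    expect_equal(sort(p$log_mass[p$habitat == h]),
                 sort(traits$log_mass[traits$habitat == h]))
  }
  expect_identical(p$habitat, traits$habitat)
  expect_identical(p$clade, traits$clade)

  two <- traits[1:2, ]
  seen <- replicate(50, paste(permute_traits(two)$log_mass, collapse = ","))
  expect_true(all(seen %in% c(
    paste(two$log_mass, collapse = ","),
    paste(rev(two$log_mass), collapse = ",")
  )))
})

test_that("FDR estimates follow the permuted-hits / original-hits definition", {
  cfg <- sim_config(
    seed = 23, n_columns = 400,
    plants = list(list(column = 7, pattern = "type1",
                       allele_a = "T", allele_b = "C"))
  )
  traits <- simulate_trait_table(cfg)
  aln <- simulate_alignment(traits, cfg)$alignment
  fdr <- estimate_fdr(aln, traits, thresholds = c(1e-8, 0.01),
                      model = "allele", n_perm = 40, n_runs = 2, seed = 9)
  expect_equal(nrow(fdr), 4)
  defined <- fdr$hits_original > 0
  expect_equal(fdr$fdr[defined],
               fdr$mean_hits_permuted[defined] / fdr$hits_original[defined])
  expect_true(all(is.na(fdr$fdr[!defined])))
  # deterministic given seed
  fdr2 <- estimate_fdr(aln, traits, thresholds = c(1e-8, 0.01),
                       model = "allele", n_perm = 40, n_runs = 2, seed = 9)
  expect_identical(tidy(fdr), tidy(fdr2))
  # runs with different seeds differ
  fdr3 <- estimate_fdr(aln, traits, thresholds = c(1e-8, 0.01),
                       model = "allele", n_perm = 40, n_runs = 2, seed = 10)
  expect_false(identical(fdr$mean_hits_permuted, fdr3$mean_hits_permuted))
})

test_that("sampled permutation hits agree with exhaustive enumeration (n = 5)", {
  set.seed(7)
  panel <- small_panel(2, 3)
  cfg <- sim_config(seed = 3, species = panel,
                    mass_log_means = c(big = 10, small = 4),
                    mass_log_sd = 1, n_columns = 60, gap_rate = 0,
                    background_minor_freq = 0.3,
                    patterns = list(p = clade_pattern("p", panel$species[1:2],
                                                      panel$species[3:5])))
  traits <- simulate_trait_table(cfg)
  aln <- simulate_alignment(traits, cfg)$alignment
  prep <- whalescan:::prepare_scan(aln, traits, "allele")
  y <- traits$log_mass
  t <- 0.05
  fcrit <- whalescan:::critical_f(prep, t)
  perms <- all_perms(5)
  Yex <- apply(perms, 1, function(ix) y[ix])
  hits_ex <- whalescan:::engine_hits(prep, Yex, fcrit)[, 1]
  B <- 20000
  Ys <- whalescan:::perm_response_matrix(y, traits$habitat, B, FALSE)
  hits_s <- whalescan:::engine_hits(prep, Ys, fcrit)[, 1]
  se <- stats::sd(hits_s) / sqrt(B)
  expect_lt(abs(mean(hits_s) - mean(hits_ex)), 3 * se)
  # every sampled hit count is one that enumeration can produce
  expect_true(all(hits_s %in% hits_ex))
})

test_that("low-complexity context is flagged and planted repeat blocks are caught", {
  aln <- rbind(ref = c(rep("A", 10), strsplit("ACGTTGCAGT", "")[[1]]),
               oth = c(rep("A", 10), strsplit("ACGTTGCAGT", "")[[1]]))
  fl <- flag_low_complexity(aln, columns = c(5, 16), w = 4)
  expect_true(fl[1])   # homopolymer window
  expect_false(fl[2])  # high-entropy window, no gaps

  cfg <- sim_config(
    seed = 13, n_columns = 400, gap_rate = 0.02,
    low_complexity_blocks = list(list(start = 101, length = 120,
                                      unit = "AT"))
  )
  sim <- simulate_alignment(simulate_trait_table(cfg), cfg)
  block_cols <- 101:220
  fl_block <- flag_low_complexity(sim$alignment, columns = block_cols)
  expect_gte(mean(fl_block), 0.9)
  # scan carries the annotation through (block interior; edges see mixed
  # windows and may legitimately escape the flag)
  scan <- scan_alignment(sim$alignment, simulate_trait_table(cfg))
  lc_cols <- scan$column[grepl("low_complexity", scan$flags)]
  expect_true(all(106:215 %in% lc_cols))
})
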