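#' Fit the per-column allele model for a single alignment column
#'
#' Models log adult body mass as a function of the column's allele (a
#' categorical factor), optionally adjusting for habitat
#' (aquatic/terrestrial). The reported p-value is the partial F test of the
#' allele factor against the reduced model (intercept only, or intercept +
#' habitat). Gaps, `N` and IUPAC ambiguity codes exclude a species from the
#' model — a gap is absence of evidence, not a fifth allele. Columns with
#' fewer than two allele classes are skipped with flag `monomorphic_skipped`;
#' columns whose allele factor is collinear with the covariate are skipped
#' with `collinear_skipped`; a perfect fit (zero residual variance) reports
#' `p_value = 0` with flag `zero_residual`.
#'
#' @param traits Trait table (tibble with `species`, `log_mass`, `habitat`).
#' @param alleles Named character vector of per-species alignment characters
#'   (names = species ids), or a one-column alignment matrix.
#' @param with_habitat Include habitat as a covariate in both models?
#' @return A one-row tibble: `model`, `f_statistic`, `p_value`, `df_num`,
#'   `df_den`, `n_used`, `n_classes`, `flags`, `tested`.
#' @export
#' @examples
#' traits <- tibble::tibble(
#'   species = letters[1:6],
#'   mass_kg = exp(c(10, 11, 12, 1, 2, 3)),
#'   log_mass = c(10, 11, 12, 1, 2, 3),
#'   habitat = rep(c("aquatic", "terrestrial"), each = 3)
#' )
#' al <- stats::setNames(c("T", "T", "T", "C", "C", "C"), letters[1:6])
#' fit_column_model(traits, al)  # F = 121.5 on (1, 4) df
fit_column_model <- function(traits, alleles, with_habitat = FALSE) {
  if (is.matrix(alleles)) {
    aln <- alleles
    if (ncol(aln) != 1) abort("`alleles` matrix must have one column.")
  } else {
    if (is.null(names(alleles))) abort("`alleles` must be named by species.")
    aln <- matrix(alleles, ncol = 1, dimnames = list(names(alleles), NULL))
  }
  model <- if (with_habitat) "allele_habitat" else "allele"
  res <- scan_alignment(aln, traits, models = model, annotate_lc = FALSE)
  res$column <- NULL
  res
}

#' Scan every alignment column for trait association
#'
#' Applies [fit_column_model()]'s partial F test to every column of the
#' alignment, for one or both models. The set of tested (non-skipped) columns
#' depends only on the alignment and habitat labels, never on the trait
#' values, so trait permutations retest exactly the same columns.
#'
#' @param aln Alignment character matrix (species row names required);
#'   species must be a subset of `traits$species`.
#' @param traits Trait table.
#' @param models Character vector among `"allele"` (allele only) and
#'   `"allele_habitat"` (allele + habitat covariate); default both.
#' @param annotate_lc Annotate columns in low-complexity context with an
#'   advisory `low_complexity` flag (never removes a column)?
#' @param lc_params Parameters passed to [flag_low_complexity()].
#' @param lc_ref_row Reference row for the low-complexity check; defaults to
#'   the first alignment row.
#' @return A tibble of class `aln_scan`: one row per column per model with
#'   `column`, `model`, `f_statistic`, `p_value`, `df_num`, `df_den`,
#'   `n_used`, `n_classes`, `flags` (semicolon-joined), `tested`.
#' @export
scan_alignment <- function(aln, traits,
                           models = c("allele", "allele_habitat"),
                           annotate_lc = TRUE,
                           lc_params = list(),
                           lc_ref_row = NULL) {
  if (!is.matrix(aln) || ncol(aln) == 0 || nrow(aln) == 0) {
    abort("`aln` must be a non-empty character matrix.")
  }
  models <- match.arg(models, c("allele", "allele_habitat"),
                      several.ok = TRUE)
  traits <- validate_trait_table(traits)
  lc <- if (isTRUE(annotate_lc)) {
    ref <- lc_ref_row %||% rownames(aln)[1]
    do.call(flag_low_complexity,
            c(list(aln = aln, ref_row = ref), lc_params))
  } else {
    rep(FALSE, ncol(aln))
  }

  out <- purrr::map_dfr(models, function(model) {
    prep <- prepare_scan(aln, traits, model)
    y <- traits$log_mass[match(prep$species, traits$species)]
    fv <- pv <- rep(NA_real_, prep$p)
    dfn <- dfd <- rep(NA_integer_, prep$p)
    flags <- prep$flags
    if (prep$p_tested > 0) {
      st <- engine_pvalues(prep, y)
      fv[prep$tested_cols] <- st$F
      pv[prep$tested_cols] <- st$p
      dfn[prep$tested_cols] <- prep$df_a
      dfd[prep$tested_cols] <- prep$df_e
      zr <- prep$tested_cols[st$zero_res]
      for (j in zr) flags[[j]] <- c(flags[[j]], "zero_residual")
    }
    for (j in which(lc)) flags[[j]] <- c(flags[[j]], "low_complexity")
    tibble(
      column = seq_len(prep$p),
      model = model,
      f_statistic = fv,
      p_value = pv,
      df_num = dfn,
      df_den = dfd,
      n_used = prep$n_used,
      n_classes = prep$n_classes,
      flags = vapply(flags, paste, character(1), collapse = ";"),
      tested = prep$tested
    )
  })
  class(out) <- c("aln_scan", class(out))
  attr(out, "n_species") <- nrow(aln)
  attr(out, "n_columns") <- ncol(aln)
  out
}

#' Permute trait values across species
#'
#' Shuffles body-mass values across species labels, either freely or
#' separately within each habitat group (stratified), leaving habitat and
#' clade assignments untouched. Stratified permutation preserves the
#' aquatic/terrestrial mass distributions and is the appropriate null when
#' habitat is a model covariate. Uses the current RNG state; seed outside.
#'
#' @param traits Trait table.
#' @param stratified Permute within habitat groups only?
#' @return A trait tibble with `mass_kg`/`log_mass` permuted.
#' @export
permute_traits <- function(traits, stratified = FALSE) {
  n <- nrow(traits)
  if (!stratified) {
    idx <- sample.int(n)
  } else {
    idx <- integer(n)
    for (g in split(seq_len(n), traits$habitat)) {
      idx[g] <- g[sample.int(length(g))]
    }
  }
  traits$mass_kg <- traits$mass_kg[idx]
  traits$log_mass <- traits$log_mass[idx]
  traits
}

#' Estimate permutation-based false discovery rates for a column scan
#'
#' For each p-value threshold `t`, counts the tested columns reaching
#' `p <= t` with the real traits (`hits_original`), repeats the identical
#' scan under trait-label permutation, and estimates
#' `FDR = mean(permuted hits) / hits_original`. When `hits_original` is zero
#' the FDR is undefined and reported as `NA`, not 0. Independent runs
#' (default 2 runs of 1,000 permutations, the conventional stability check)
#' are reported separately.
#'
#' @param aln Alignment matrix.
#' @param traits Trait table.
#' @param thresholds Numeric p-value cutoffs in (0, 1).
#' @param model `"allele"` or `"allele_habitat"`.
#' @param n_perm Permutations per run.
#' @param n_runs Number of independent runs.
#' @param stratified Permute within habitat strata?
#' @param seed Integer seed; every permutation stream derives from it.
#' @return A tibble of class `fdr_estimate`: one row per threshold per run
#'   with `model`, `threshold`, `run`, `hits_original`,
#'   `mean_hits_permuted`, `fdr`, `n_perm`, `n_tested`, `stratified`, `seed`.
#' @export
estimate_fdr <- function(aln, traits, thresholds,
                         model = c("allele", "allele_habitat"),
                         n_perm = 1000, n_runs = 2,
                         stratified = FALSE, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_perm >= 1, n_runs >= 1)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("Thresholds must lie in (0, 1).")
  }
  traits <- validate_trait_table(traits)
  prep <- prepare_scan(aln, traits, model)
  if (prep$p_tested == 0) abort("No testable columns in the alignment.")
  y <- traits$log_mass[match(prep$species, traits$species)]
  pv <- engine_pvalues(prep, y)$p
  hits_orig <- vapply(thresholds, function(t) sum(pv <= t), numeric(1))
  fcrit <- critical_f(prep, thresholds)

  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    mean_hits <- with_seed(derive_seed(seed, 100 + r), {
      total <- numeric(length(thresholds))
      done <- 0
      while (done < n_perm) {
        b <- min(250, n_perm - done)
        Y <- perm_response_matrix(y, prep$habitat, b, stratified)
        total <- total + colSums(engine_hits(prep, Y, fcrit))
        done <- done + b
      }
      total / n_perm
    })
    tibble(
      model = model, threshold = thresholds, run = r,
      hits_original = hits_orig, mean_hits_permuted = mean_hits,
      fdr = ifelse(hits_orig > 0, mean_hits / hits_orig, NA_real_),
      n_perm = n_perm, n_tested = prep$p_tested,
      stratified = stratified, seed = seed
    )
  })
  class(runs) <- c("fdr_estimate", class(runs))
  runs
}

#' Flag alignment columns in low-complexity context
#'
#' Advisory flag for columns whose local alignment context makes association
#' hits likely artifacts: within a +/-`w` column window, the flag is raised
#' when the gap fraction (over all species) exceeds `gap_cutoff`, or the
#' reference row's gap-free subsequence has at most `max_distinct` distinct
#' characters, or a mono-/di-nucleotide repeat covers more than
#' `repeat_cutoff` of it. The flag annotates; it never removes a column.
#'
#' @param aln Alignment matrix.
#' @param columns Columns to assess (default: all).
#' @param ref_row Reference row id; defaults to the first row.
#' @param w Window half-width in columns (>= 1).
#' @param gap_cutoff Maximum tolerated gap fraction.
#' @param max_distinct Distinct-character threshold for the reference
#'   subsequence.
#' @param repeat_cutoff Maximum tolerated mono/dinucleotide repeat coverage.
#' @return Logical vector over `columns`.
#' @export
flag_low_complexity <- function(aln, columns = seq_len(ncol(aln)),
                                ref_row = rownames(aln)[1],
                                w = 5, gap_cutoff = 0.3,
                                max_distinct = 2, repeat_cutoff = 0.8) {
  stopifnot(w >= 1)
  if (!ref_row %in% rownames(aln)) {
    abort(sprintf("Reference row '%s' not in alignment.", ref_row))
  }
  p <- ncol(aln)
  ref <- aln[ref_row, ]
  is_gap <- aln == "-"
  gap_count <- colSums(is_gap)
  vapply(columns, function(j) {
    win <- max(1, j - w):min(p, j + w)
    gap_frac <- sum(gap_count[win]) / (nrow(aln) * length(win))
    if (gap_frac > gap_cutoff) return(TRUE)
    s <- ref[win]
    s <- s[s != "-"]
    if (length(s) == 0) return(TRUE)
    if (length(unique(s)) <= max_distinct) return(TRUE)
    dinucleotide_coverage(s) > repeat_cutoff
  }, logical(1))
}

# Best fraction of a character vector covered by a mono- or di-nucleotide
# tandem repeat (both phases considered).
dinucleotide_coverage <- function(s) {
  n <- length(s)
  letters_here <- unique(s)
  best <- 0
  phase <- seq_len(n) %% 2
  for (a in letters_here) {
    for (b in letters_here) {
      cov <- max(mean((phase == 1) * (s == a) + (phase == 0) * (s == b)),
                 mean((phase == 0) * (s == a) + (phase == 1) * (s == b)))
      if (cov > best) best <- cov
    }
  }
  best
}
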