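# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# The six-species worked example: two allele groups with log-masses
# (10, 11, 12) vs (1, 2, 3).
worked_example <- function() {
  list(
    traits = tibble::tibble(
      species = letters[1:6],
      mass_kg = exp(c(10, 11, 12, 1, 2, 3)),
      log_mass = c(10, 11, 12, 1, 2, 3),
      habitat = rep(c("aquatic", "terrestrial"), each = 3)
    ),
    alleles = stats::setNames(c("T", "T", "T", "C", "C", "C"), letters[1:6])
  )
}

# Independent one-way ANOVA oracle via explicit sums of squares.
anova_oracle <- function(y, groups) {
  g <- split(y, groups)
  grand <- mean(y)
  ss_between <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(g) - 1
  df2 <- length(y) - length(g)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# A genotype track built from a per-window specification: one call per
# `spacing` bp, het in the windows listed in `het_windows` at `het_rate`
# within-window fraction, hom elsewhere.
track_from_windows <- function(n_windows, window_size = 20000,
                               qualifying, spacing = 200, depth = 30,
                               scaffold = "s1") {
  rows <- list()
  for (w in seq_len(n_windows)) {
    pos <- seq((w - 1) * window_size + spacing, w * window_size, by = spacing)
    # non-qualifying windows get 10% het (far above the 2.5% threshold)
    het <- if (w %in% qualifying) rep(FALSE, length(pos)) else {
      seq_along(pos) %% 10 == 0
    }
    rows[[w]] <- tibble::tibble(scaffold = scaffold, pos = pos,
                                gt = ifelse(het, "het", "hom"),
                                depth = depth)
  }
  dplyr::bind_rows(rows)
}

# All permutations of seq_len(n), as an n! x n matrix (test oracle only).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Small species panel for low-n scan tests.
small_panel <- function(n_aquatic = 3, n_terrestrial = 4) {
  tibble::tibble(
    species = paste0("sp", seq_len(n_aquatic + n_terrestrial)),
    habitat = c(rep("aquatic", n_aquatic),
                rep("terrestrial", n_terrestrial)),
    clade = c(rep("big", n_aquatic), rep("small", n_terrestrial))
  )
}
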