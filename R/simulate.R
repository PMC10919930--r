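# Synthetic-data generators. Each generator draws from its own stream derived
# from the root seed (streams: 1 = traits, 2 = alignment, 3 = genotype track),
# so the three outputs are independently reproducible.

BASES <- c("A", "C", "G", "T")

#' Simulate a species trait table
#'
#' Draws per-species log adult body mass from clade-specific Gaussian
#' distributions (`mass_log_means` +/- `mass_log_sd` on the natural-log kg
#' scale) and carries the configured habitat and clade labels through.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `species`, `mass_kg`, `log_mass`, `habitat`,
#'   `clade`; one row per species, deterministic given the config seed.
#' @export
#' @examples
#' traits <- simulate_trait_table(sim_config(seed = 7))
#' head(traits)
simulate_trait_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$species
  mu <- unname(config$mass_log_means[panel$clade])
  log_mass <- with_seed(
    derive_seed(config$seed, 1),
    mu + rnorm(nrow(panel), mean = 0, sd = config$mass_log_sd)
  )
  tibble(
    species = panel$species,
    mass_kg = exp(log_mass),
    log_mass = log_mass,
    habitat = panel$habitat,
    clade = panel$clade
  )
}

#' Simulate a species alignment with planted pattern columns
#'
#' Background columns carry a major allele plus a minor allele assigned to
#' each species independently with probability `background_minor_freq`
#' (i.i.d. across columns; no phylogenetic autocorrelation). Gaps are placed
#' at `gap_rate` per cell outside planted columns. Low-complexity blocks are
#' tandem repeats of their unit shared by all species, with an elevated gap
#' rate, emulating ambiguously aligned regions. Planted columns realise their
#' clade pattern exactly (group A gets `allele_a`, everyone else `allele_b`,
#' no gaps) and are overwritten after all random draws, so adding or removing
#' plants does not perturb the background.
#'
#' @param traits Trait table from [simulate_trait_table()]; its species set
#'   must equal the config's.
#' @param config A [sim_config()].
#' @return A list with `alignment` (species x columns character matrix over
#'   A/C/G/T/-) and `truth` (tibble of planted columns: `column`, `pattern`,
#'   `allele_a`, `allele_b`).
#' @export
simulate_alignment <- function(traits, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(traits$species, config$species$species)) {
    abort("`traits` species set must match the config species set.")
  }
  n <- nrow(config$species)
  p <- config$n_columns
  sp <- config$species$species

  lc_cols <- integer(0)
  for (b in config$low_complexity_blocks) {
    lc_cols <- c(lc_cols, seq(b$start, b$start + b$length - 1))
  }
  if (any(lc_cols < 1 | lc_cols > p)) {
    abort("Low-complexity block extends outside the alignment.")
  }
  plant_cols <- vapply(config$plants, function(x) as.integer(x$column),
                       integer(1))
  if (length(intersect(plant_cols, lc_cols)) > 0) {
    abort("A planted column collides with a low-complexity block.")
  }

  aln <- with_seed(derive_seed(config$seed, 2), {
    major_idx <- sample.int(4, p, replace = TRUE)
    minor_shift <- sample.int(3, p, replace = TRUE)
    minor_idx <- ((major_idx - 1 + minor_shift) %% 4) + 1
    m <- matrix(BASES[major_idx], nrow = n, ncol = p, byrow = TRUE)
    minor_mask <- matrix(runif(n * p) < config$background_minor_freq, n, p)
    m[minor_mask] <- matrix(BASES[minor_idx], n, p, byrow = TRUE)[minor_mask]
    gap_mask <- matrix(runif(n * p) < config$gap_rate, n, p)
    m[gap_mask] <- "-"
    # low-complexity blocks: shared tandem repeat, elevated gap rate
    for (b in config$low_complexity_blocks) {
      unit <- strsplit(toupper(b$unit), "")[[1]]
      cols <- seq(b$start, b$start + b$length - 1)
      rep_chars <- unit[((cols - b$start) %% length(unit)) + 1]
      m[, cols] <- matrix(rep_chars, n, length(cols), byrow = TRUE)
      lc_gap <- min(1, 3 * config$gap_rate + 0.1)
      extra <- matrix(runif(n * length(cols)) < lc_gap, n, length(cols))
      m[, cols][extra] <- "-"
    }
    m
  })
  rownames(aln) <- sp

  truth <- tibble(column = integer(0), pattern = character(0),
                  allele_a = character(0), allele_b = character(0))
  for (pl in config$plants) {
    pat <- config$patterns[[pl$pattern]]
    col <- rep(pl$allele_b, n)
    names(col) <- sp
    col[pat$group_a] <- pl$allele_a
    aln[, pl$column] <- col[sp]
    truth <- bind_rows(truth, tibble(
      column = as.integer(pl$column), pattern = pl$pattern,
      allele_a = pl$allele_a, allele_b = pl$allele_b
    ))
  }
  list(alignment = aln, truth = arrange(truth, .data$column))
}

#' Simulate a multi-scaffold diploid genotype track
#'
#' Places callable sites uniformly at `callable_fraction`, marks each callable
#' site heterozygous with probability `background_het_rate` (or the planted
#' segment's `residual_het_rate` inside a planted ROH), and draws read depth
#' from a negative-binomial with mean `mean_depth` and size
#' `depth_dispersion`.
#'
#' @param config A [sim_config()].
#' @return A list with `track` (tibble: `scaffold`, `pos`, `gt` in
#'   `"hom"`/`"het"`, `depth`), `truth` (tibble of planted ROH segments) and
#'   `scaffold_lengths` (named numeric vector, bp).
#' @export
simulate_genotype_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$scaffold_length
  segs <- config$roh_segments
  track <- with_seed(derive_seed(config$seed, 3), {
    pieces <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      scaf <- names(lens)[i]
      L <- lens[[i]]
      pos <- which(runif(L) < config$callable_fraction)
      het_p <- rep(config$background_het_rate, length(pos))
      for (s in segs) {
        if (s$scaffold == scaf) {
          inside <- pos >= s$start & pos <= s$end
          het_p[inside] <- s$residual_het_rate
        }
      }
      het <- runif(length(pos)) < het_p
      depth <- rnbinom(length(pos), mu = config$mean_depth,
                       size = config$depth_dispersion)
      pieces[[i]] <- tibble(
        scaffold = scaf, pos = pos,
        gt = ifelse(het, "het", "hom"),
        depth = as.integer(depth)
      )
    }
    bind_rows(pieces)
  })
  truth <- tibble(
    scaffold = vapply(segs, `[[`, character(1), "scaffold"),
    start = vapply(segs, function(s) as.numeric(s$start), numeric(1)),
    end = vapply(segs, function(s) as.numeric(s$end), numeric(1)),
    residual_het_rate = vapply(segs, `[[`, numeric(1), "residual_het_rate")
  )
  list(track = track, truth = truth, scaffold_lengths = lens)
}
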