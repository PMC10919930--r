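#' Define a clade-sharing allele pattern
#'
#' A clade pattern names a bipartition of species: a site matches the pattern
#' when every species in `group_a` shares one allele, every species in
#' `group_b` shares a different allele, and species outside both groups are
#' ignored. Patterns encode the "type 1" / "type 2" site definitions used when
#' screening a gene alignment for body-size-associated alleles: type 1 sites
#' separate the three giant whales (blue, minke, sperm) from all other
#' artiodactyls; type 2 sites separate the four largest whales plus the
#' terrestrial artiodactyls from the smaller cetaceans.
#'
#' @param name Pattern label, e.g. `"type1"`.
#' @param group_a,group_b Character vectors of species ids; disjoint and
#'   non-empty.
#' @return An object of class `clade_pattern`.
#' @export
#' @examples
#' clade_pattern("type1", c("blue_whale", "minke_whale", "sperm_whale"),
#'               c("orca", "bottlenose_dolphin"))
clade_pattern <- function(name, group_a, group_b) {
  stopifnot(is.character(name), length(name) == 1)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("Both pattern groups must be non-empty.")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    abort("Pattern groups must be disjoint.")
  }
  structure(list(name = name, group_a = group_a, group_b = group_b),
            class = "clade_pattern")
}

#' @export
print.clade_pattern <- function(x, ...) {
  cat("<clade_pattern>", x$name, "\n")
  cat("  group A:", paste(x$group_a, collapse = ", "), "\n")
  cat("  group B:", paste(x$group_b, collapse = ", "), "\n")
  invisible(x)
}

# Default species panel: 29 artiodactyls, 11 aquatic (3 giant whales, orca,
# 7 smaller cetaceans) and 18 terrestrial, mirroring the taxon sampling a
# whole-gene cetacean alignment would carry.
default_species_panel <- function() {
  aquatic <- c("blue_whale", "minke_whale", "sperm_whale", "orca",
               "bottlenose_dolphin", "vaquita", "harbor_porpoise",
               "white_sided_dolphin", "beluga", "narwhal", "finless_porpoise")
  terrestrial <- c("cattle", "water_buffalo", "yak", "bison", "goat", "sheep",
                   "pig", "alpaca", "camel", "giraffe", "okapi", "red_deer",
                   "white_tailed_deer", "reindeer", "chevrotain", "hippo",
                   "pronghorn", "muskox")
  clade <- c("large_whale", "large_whale", "large_whale", "orca",
             rep("small_cetacean", 7), rep("terrestrial", 18))
  tibble(
    species = c(aquatic, terrestrial),
    habitat = c(rep("aquatic", length(aquatic)),
                rep("terrestrial", length(terrestrial))),
    clade = clade
  )
}

default_patterns <- function(panel = default_species_panel()) {
  giant3 <- c("blue_whale", "minke_whale", "sperm_whale")
  large4 <- c(giant3, "orca")
  small_cet <- setdiff(panel$species[panel$habitat == "aquatic"], large4)
  terrestrial <- panel$species[panel$habitat == "terrestrial"]
  list(
    type1 = clade_pattern("type1", giant3, setdiff(panel$species, giant3)),
    type2 = clade_pattern("type2", c(large4, terrestrial), small_cet)
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every parameter of the three generators (trait table, alignment,
#' genotype track) with a single root seed. Each generator derives its own
#' independent random stream from the root seed, so changing, say, the list of
#' planted columns never perturbs the background alignment draws.
#'
#' Defaults emulate the study conditions the scan is designed for: 29
#' artiodactyl species (11 aquatic / 18 terrestrial) with clade-structured
#' log body mass spanning tens of kg to >100 t, an alignment with background
#' polymorphism, gaps, and optional low-complexity blocks and planted pattern
#' columns, and multi-scaffold diploid genotype tracks with ~40x mean depth
#' and background heterozygosity ~1e-3 per site.
#'
#' @param seed Integer root seed.
#' @param species Optional tibble with columns `species`, `habitat`
#'   (`"aquatic"`/`"terrestrial"`) and `clade`; defaults to a 29-species
#'   artiodactyl panel.
#' @param mass_log_means Named numeric vector: mean natural-log body mass
#'   (log kg) per clade.
#' @param mass_log_sd Standard deviation of log mass within clade (>= 0).
#' @param n_columns Number of alignment columns.
#' @param background_minor_freq Per-species probability of carrying the minor
#'   allele in a background column.
#' @param gap_rate Per-cell gap probability outside planted columns.
#' @param low_complexity_blocks List of `list(start =, length =, unit =)`
#'   tandem-repeat blocks.
#' @param plants List of `list(column =, pattern =, allele_a =, allele_b =)`
#'   planted pattern columns.
#' @param patterns Named list of [clade_pattern()] objects referenced by
#'   `plants`; defaults to the type-1/type-2 patterns over the default panel.
#' @param n_scaffolds,scaffold_length Genotype-track shape (lengths in bp;
#'   `scaffold_length` is recycled across scaffolds).
#' @param mean_depth,depth_dispersion Negative-binomial read-depth model
#'   (mean and size); overdispersed coverage stresses the depth filter.
#' @param background_het_rate Per-site heterozygosity probability at callable
#'   sites outside planted ROH.
#' @param callable_fraction Fraction of positions with a genotype call.
#' @param roh_segments List of `list(scaffold =, start =, end =,
#'   residual_het_rate =)` planted runs of homozygosity.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       species = default_species_panel(),
                       mass_log_means = c(large_whale = 10.5, orca = 8.3,
                                          small_cetacean = 5.0,
                                          terrestrial = 6.0),
                       mass_log_sd = 0.6,
                       n_columns = 2000,
                       background_minor_freq = 0.1,
                       gap_rate = 0.02,
                       low_complexity_blocks = list(),
                       plants = list(),
                       patterns = NULL,
                       n_scaffolds = 2,
                       scaffold_length = 2e6,
                       mean_depth = 40,
                       depth_dispersion = 10,
                       background_het_rate = 1e-3,
                       callable_fraction = 0.8,
                       roh_segments = list()) {
  species <- as_tibble(species)
  req <- c("species", "habitat", "clade")
  if (!all(req %in% names(species))) {
    abort("`species` needs columns species, habitat, clade.")
  }
  if (anyDuplicated(species$species)) abort("Species ids must be unique.")
  if (!all(species$habitat %in% c("aquatic", "terrestrial"))) {
    abort("habitat must be 'aquatic' or 'terrestrial'.")
  }
  if (nrow(species) < 4) abort("Need at least 4 species.")
  if (length(unique(species$habitat)) < 2) {
    abort("Need at least one species per habitat.")
  }
  missing_clades <- setdiff(unique(species$clade), names(mass_log_means))
  if (length(missing_clades) > 0) {
    abort(paste("No mass_log_mean for clade(s):",
                paste(missing_clades, collapse = ", ")))
  }
  if (!is_scalar_number(mass_log_sd) || mass_log_sd < 0) {
    abort("`mass_log_sd` must be a non-negative number.")
  }
  stop_if_not_prob(background_minor_freq, "background_minor_freq")
  stop_if_not_prob(gap_rate, "gap_rate")
  stop_if_not_prob(background_het_rate, "background_het_rate")
  stop_if_not_prob(callable_fraction, "callable_fraction")
  stopifnot(n_columns >= 1, n_scaffolds >= 1, mean_depth > 0,
            depth_dispersion > 0)

  if (is.null(patterns)) patterns <- default_patterns(species)
  names(patterns) <- vapply(patterns, `[[`, character(1), "name")

  plant_cols <- vapply(plants, function(p) as.numeric(p$column), numeric(1))
  if (length(plant_cols) > 0) {
    if (any(plant_cols < 1 | plant_cols > n_columns)) {
      abort("Planted columns must lie within [1, n_columns].")
    }
    if (anyDuplicated(plant_cols)) abort("Planted columns must be distinct.")
    for (p in plants) {
      if (!p$pattern %in% names(patterns)) {
        abort(sprintf("Plant references undefined pattern '%s'.", p$pattern))
      }
      if (identical(p$allele_a, p$allele_b)) {
        abort("Plant alleles allele_a and allele_b must differ.")
      }
      pat <- patterns[[p$pattern]]
      unknown <- setdiff(c(pat$group_a, pat$group_b), species$species)
      if (length(unknown) > 0) {
        abort(paste("Pattern species not in panel:",
                    paste(unknown, collapse = ", ")))
      }
    }
  }

  scaffold_length <- rep_len(as.numeric(scaffold_length), n_scaffolds)
  scaffold_names <- paste0("scaffold_", seq_len(n_scaffolds))
  names(scaffold_length) <- scaffold_names
  for (seg in roh_segments) {
    if (!seg$scaffold %in% scaffold_names) {
      abort(sprintf("ROH segment scaffold '%s' not in track.", seg$scaffold))
    }
    if (seg$start < 1 || seg$end > scaffold_length[[seg$scaffold]] ||
        seg$start > seg$end) {
      abort("ROH segment outside scaffold bounds.")
    }
    stop_if_not_prob(seg$residual_het_rate, "residual_het_rate")
  }
  # non-overlap per scaffold
  by_scaf <- split(roh_segments,
                   vapply(roh_segments, `[[`, character(1), "scaffold"))
  for (segs in by_scaf) {
    if (length(segs) > 1) {
      o <- order(vapply(segs, `[[`, numeric(1), "start"))
      segs <- segs[o]
      for (i in seq_len(length(segs) - 1)) {
        if (segs[[i + 1]]$start <= segs[[i]]$end) {
          abort("Planted ROH segments overlap within a scaffold.")
        }
      }
    }
  }

  structure(list(
    seed = as.integer(seed),
    species = species,
    mass_log_means = mass_log_means,
    mass_log_sd = mass_log_sd,
    n_columns = as.integer(n_columns),
    background_minor_freq = background_minor_freq,
    gap_rate = gap_rate,
    low_complexity_blocks = low_complexity_blocks,
    plants = plants,
    patterns = patterns,
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length = scaffold_length,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    background_het_rate = background_het_rate,
    callable_fraction = callable_fraction,
    roh_segments = roh_segments
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "\n")
  cat(" ", nrow(x$species), "species;", x$n_columns, "alignment columns;",
      length(x$plants), "planted sites\n")
  cat(" ", x$n_scaffolds, "scaffold(s) totalling",
      format(sum(x$scaffold_length), big.mark = ","), "bp;",
      length(x$roh_segments), "planted ROH\n")
  invisible(x)
}
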