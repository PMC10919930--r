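# End-to-end pipeline drivers. A run config is a plain list (or a YAML file
# holding one); a single root seed drives every stage through independent
# derived streams, the config is serialised verbatim into the output
# directory, and reruns with the same config reproduce byte-identical tables.

PSMC_PARAMS <- list(generation_time_years = 30.8,
                    mutation_rate_per_bp_per_generation = 1.58e-8,
                    max_coalescent_t = 15)

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  config
}

parse_patterns <- function(x) {
  if (is.null(x)) return(NULL)
  out <- lapply(names(x), function(nm) {
    p <- x[[nm]]
    if (inherits(p, "clade_pattern")) return(p)
    clade_pattern(nm, p$group_a, p$group_b)
  })
  names(out) <- names(x)
  out
}

stage_file <- function(stage, path) {
  if (!file.exists(path)) {
    abort(sprintf("%s stage: input file not found: %s", stage, path))
  }
  path
}

serializable_config <- function(config) {
  rapply(config, function(x) {
    if (inherits(x, "clade_pattern")) unclass(x) else x
  }, how = "replace")
}

write_run_log <- function(lines, outdir) {
  writeLines(c(sprintf("run at seed-driven determinism; %d entries",
                       length(lines)), lines),
             file.path(outdir, "log.txt"))
}

#' Run the full column-scan pipeline
#'
#' Simulates (or loads) an alignment and trait table, scans every column
#' under both allele models, estimates permutation FDRs, classifies
#' significant columns into clade-pattern site types, and writes all tables
#' into `outdir`: `scan.tsv`, `fdr.tsv`, `typed_sites.tsv`, optionally
#' `sites.bed`, plus the serialised config and a log. Rerunning with an
#' identical config reproduces identical tables.
#'
#' Config fields (all optional unless noted): `seed`; either `simulate`
#' (list of [sim_config()] arguments) or `alignment_fasta` + `traits_tsv`
#' (+ `patterns`: name -> list(group_a, group_b), required for real inputs);
#' `models`; `thresholds` (FDR table cutoffs); `recover_threshold` (p cutoff
#' defining the typed-site table; default `1e-4`); `n_perm` (default 1000);
#' `n_runs` (default 2); `map` (list: `ref_row`, `anchor`, `orientation`);
#' `features_bed`.
#'
#' @param config List or YAML path.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`scan`, `fdr`,
#'   `typed_sites`, `truth`, paths).
#' @export
run_scan_pipeline <- function(config, outdir) {
  config <- load_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  log <- c(sprintf("root seed: %s", seed))

  if (!is.null(config$alignment_fasta)) {
    aln <- read_alignment(stage_file("input", config$alignment_fasta),
                          format = config$alignment_format %||% "fasta")
    traits <- read_trait_table(stage_file("input", config$traits_tsv))
    truth <- NULL
    patterns <- parse_patterns(config$patterns)
    if (is.null(patterns)) {
      abort("classify stage: `patterns` required with real inputs.")
    }
    log <- c(log, sprintf("input alignment md5: %s",
                          unname(tools::md5sum(config$alignment_fasta))))
  } else {
    sc <- do.call(sim_config, c(list(seed = seed), config$simulate))
    traits <- simulate_trait_table(sc)
    sim <- simulate_alignment(traits, sc)
    aln <- sim$alignment
    truth <- sim$truth
    patterns <- sc$patterns
    write_alignment(aln, file.path(outdir, "alignment.fasta"))
    write_trait_table(traits, file.path(outdir, "traits.tsv"))
    readr::write_tsv(truth, file.path(outdir, "truth_sites.tsv"))
    log <- c(log, sprintf("simulated %d x %d alignment, %d planted sites",
                          nrow(aln), ncol(aln), nrow(truth)))
  }

  models <- config$models %||% c("allele", "allele_habitat")
  scan <- scan_alignment(aln, traits, models = models)
  readr::write_tsv(tidy(scan), file.path(outdir, "scan.tsv"))

  thresholds <- config$thresholds %||% 1e-4
  fdr <- purrr::map_dfr(models, function(m) {
    estimate_fdr(aln, traits, thresholds, model = m,
                 n_perm = config$n_perm %||% 1000,
                 n_runs = config$n_runs %||% 2,
                 stratified = identical(m, "allele_habitat"),
                 seed = derive_seed(seed, 10 + match(m, models)))
  })
  readr::write_tsv(fdr, file.path(outdir, "fdr.tsv"))

  recover_t <- config$recover_threshold %||% 1e-4
  hits <- scan |>
    filter(.data$tested, .data$p_value <= recover_t) |>
    dplyr::pull(.data$column) |>
    unique() |>
    sort()
  log <- c(log, sprintf("%d hit column(s) at p <= %g", length(hits),
                        recover_t))

  map <- NULL
  if (!is.null(config$map)) {
    map <- build_column_map(aln, config$map$ref_row, config$map$anchor,
                            config$map$orientation %||% "forward",
                            seqname = config$map$seqname %||%
                              config$map$ref_row)
  }
  typed <- classify_sites(aln, hits, patterns, map = map)
  typed <- dplyr::left_join(
    typed,
    scan |> filter(.data$tested) |>
      group_by(.data$column) |>
      summarise(min_p = min(.data$p_value), flags = .data$flags[1],
                .groups = "drop"),
    by = "column"
  )
  if (!is.null(config$features_bed)) {
    typed <- annotate_features(typed,
                               stage_file("annotate", config$features_bed))
  } else {
    typed$feature <- NA_character_
  }
  write_site_report(typed, file.path(outdir, "typed_sites.tsv"))
  if (!is.null(map)) {
    write_sites_bed(typed, map, file.path(outdir, "sites.bed"))
  }
  yaml::write_yaml(serializable_config(config),
                   file.path(outdir, "config.yaml"))
  write_run_log(log, outdir)
  invisible(list(scan = scan, fdr = fdr, typed_sites = typed, truth = truth,
                 outdir = outdir))
}

#' Run the windowed population-genomics pipeline
#'
#' Simulates (or loads) a genotype track, applies the depth filter, computes
#' windowed heterozygosity, calls and summarises runs of homozygosity, and
#' optionally builds a pseudodiploid track with a psmcfa export. Writes
#' `windows.tsv`, `roh.bed`, `roh_summary.json`, optionally
#' `pseudodiploid.tsv` + `pseudodiploid.psmcfa`, plus config and log.
#'
#' Config fields: `seed`; either `simulate` ([sim_config()] arguments) or
#' `track_tsv` + `scaffold_lengths` (named list, bp); `window_size` (default
#' 1e6); `roh` (list: `window_size`, `min_windows`, `het_threshold`,
#' `min_length`); `depth_filter` (logical, default TRUE);
#' `pseudodiploid` (list: `track_a`, `track_b` TSV paths with allele
#' columns, or `simulate_second: true` to pair the simulated track with an
#' independent replicate; optional `psmcfa: true`, `bin_size`).
#'
#' @param config List or YAML path.
#' @param outdir Output directory.
#' @return Invisibly, a list with `windows`, `roh`, `roh_summary`,
#'   `pseudodiploid` (or NULL), `truth`, paths.
#' @export
run_popgen_pipeline <- function(config, outdir) {
  config <- load_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  log <- c(sprintf("root seed: %s", seed))

  if (!is.null(config$track_tsv)) {
    track <- read_genotype_track(stage_file("input", config$track_tsv))
    lens <- unlist(config$scaffold_lengths)
    if (is.null(lens)) {
      abort("input stage: `scaffold_lengths` required with a real track.")
    }
    truth <- NULL
  } else {
    sc <- do.call(sim_config, c(list(seed = seed), config$simulate))
    sim <- simulate_genotype_track(sc)
    track <- sim$track
    lens <- sim$scaffold_lengths
    truth <- sim$truth
    write_genotype_track(track, file.path(outdir, "track.tsv"))
    if (nrow(truth) > 0) {
      readr::write_tsv(truth, file.path(outdir, "truth_roh.tsv"))
    }
    log <- c(log, sprintf("simulated track: %d called sites on %d scaffold(s)",
                          nrow(track), length(lens)))
  }

  if (!identical(config$depth_filter, FALSE) && "depth" %in% names(track)) {
    n0 <- nrow(track)
    track <- filter_by_depth(track)
    log <- c(log, sprintf("depth filter kept %d / %d sites (bounds %.1f-%.1f)",
                          nrow(track), n0,
                          attr(track, "depth_bounds")[["lower"]],
                          attr(track, "depth_bounds")[["upper"]]))
  }

  wins <- window_heterozygosity(track, lens,
                                window_size = config$window_size %||% 1e6)
  readr::write_tsv(as_tibble(unclass_first_win(wins)),
                   file.path(outdir, "windows.tsv"))

  roh_cfg <- config$roh %||% list()
  runs <- call_roh(track, lens,
                   window_size = roh_cfg$window_size %||% 20000,
                   min_windows = roh_cfg$min_windows %||% 25,
                   het_threshold = roh_cfg$het_threshold %||% 0.025)
  assessed <- roh_cfg$assessed_length %||% sum(lens)
  summ <- summarize_roh(runs, assessed_length = assessed,
                        min_length = roh_cfg$min_length %||% 5e5)
  if (nrow(runs) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = runs$scaffold,
      ranges = IRanges::IRanges(start = runs$start, end = runs$end),
      name = "ROH", score = 0
    )
    rtracklayer::export(gr, file.path(outdir, "roh.bed"), format = "BED")
  } else {
    file.create(file.path(outdir, "roh.bed"))
  }
  summary_json <- list(
    froh = summ$froh,
    froh_vs_total_length = sum(summ$runs$length[
      summ$runs$length >= summ$min_length]) / sum(lens),
    min_length = summ$min_length,
    assessed_length = summ$assessed_length,
    n_runs = nrow(runs),
    n_runs_min_length = summ$n_runs_min_length,
    bins = summ$bins,
    longest = summ$longest
  )

  pseudo <- NULL
  pd_cfg <- config$pseudodiploid
  if (!is.null(pd_cfg)) {
    if (!is.null(pd_cfg$track_a)) {
      ta <- read_genotype_track(stage_file("pseudodiploid", pd_cfg$track_a))
      tb <- read_genotype_track(stage_file("pseudodiploid", pd_cfg$track_b))
    } else {
      abort("pseudodiploid stage: provide `track_a`/`track_b` paths.")
    }
    pseudo <- make_pseudodiploid(ta, tb, seed = derive_seed(seed, 20))
    readr::write_tsv(pseudo, file.path(outdir, "pseudodiploid.tsv"))
    if (isTRUE(pd_cfg$psmcfa)) {
      write_psmcfa(pseudo, lens, file.path(outdir, "pseudodiploid.psmcfa"),
                   bin_size = pd_cfg$bin_size %||% 100)
      summary_json$psmc_params <- PSMC_PARAMS
    }
    log <- c(log, sprintf("pseudodiploid: %d shared sites, %.4g het fraction",
                          nrow(pseudo), mean(pseudo$gt == "het")))
  }

  jsonlite::write_json(summary_json, file.path(outdir, "roh_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  yaml::write_yaml(serializable_config(config),
                   file.path(outdir, "config.yaml"))
  write_run_log(log, outdir)
  invisible(list(windows = wins, roh = runs, roh_summary = summ,
                 pseudodiploid = pseudo, truth = truth, outdir = outdir))
}

unclass_first_win <- function(x) {
  class(x) <- setdiff(class(x), "het_windows")
  x
}
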