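#' Build a pseudodiploid genotype track from two individuals
#'
#' At every site called in both inputs, samples one allele uniformly at
#' random from each individual's genotype; the pseudodiploid site is
#' heterozygous exactly when the two sampled alleles differ. The coalescence
#' profile of such a composite diploid reveals when gene flow between the two
#' source populations ceased, which is why its PSMC curve diverges at the
#' split time.
#'
#' Input tracks must share a coordinate system and carry alleles: either a
#' single `allele` column (haploid consensus) or `allele1`/`allele2`
#' (diploid). Sites called in only one input are excluded — "each site" means
#' sites comparable between the two genomes.
#'
#' @param track_a,track_b Genotype tracks with allele columns.
#' @param seed Integer seed for the allele sampling.
#' @return A genotype track tibble (`scaffold`, `pos`, `gt`, `depth`,
#'   `allele1`, `allele2`); `depth` is the rounded mean of the input depths
#'   when both carry one. Empty (with a warning) if no shared sites exist.
#' @export
make_pseudodiploid <- function(track_a, track_b, seed = 1) {
  ga <- allele_matrix(track_a)
  gb <- allele_matrix(track_b)
  a <- as_tibble(track_a)
  b <- as_tibble(track_b)
  a$.row_a <- seq_len(nrow(a))
  b$.row_b <- seq_len(nrow(b))
  shared <- inner_join(select(a, "scaffold", "pos", ".row_a"),
                       select(b, "scaffold", "pos", ".row_b"),
                       by = c("scaffold", "pos"))
  if (nrow(shared) == 0) {
    warn("No shared called sites between the two tracks.")
    return(tibble(scaffold = character(0), pos = numeric(0),
                  gt = character(0), depth = integer(0),
                  allele1 = character(0), allele2 = character(0)))
  }
  n <- nrow(shared)
  picks <- with_seed(derive_seed(seed, 4), {
    list(a = sample.int(2, n, replace = TRUE),
         b = sample.int(2, n, replace = TRUE))
  })
  al_a <- ga[cbind(shared$.row_a, picks$a)]
  al_b <- gb[cbind(shared$.row_b, picks$b)]
  depth <- if ("depth" %in% names(a) && "depth" %in% names(b)) {
    as.integer(round((a$depth[shared$.row_a] + b$depth[shared$.row_b]) / 2))
  } else {
    NA_integer_
  }
  tibble(
    scaffold = shared$scaffold,
    pos = shared$pos,
    gt = ifelse(al_a == al_b, "hom", "het"),
    depth = depth,
    allele1 = al_a,
    allele2 = al_b
  ) |> arrange(.data$scaffold, .data$pos)
}

# Two-column allele matrix from a track: haploid `allele` is duplicated.
allele_matrix <- function(track) {
  track <- as_tibble(track)
  if (all(c("allele1", "allele2") %in% names(track))) {
    cbind(track$allele1, track$allele2)
  } else if ("allele" %in% names(track)) {
    cbind(track$allele, track$allele)
  } else {
    abort("Track needs an `allele` column or `allele1`/`allele2` columns.")
  }
}

#' Write a genotype track in psmcfa format
#'
#' Emits the FASTA-like consensus input consumed by PSMC: one record per
#' scaffold, one character per `bin_size` bp bin (default 100 bp), 60
#' characters per line. A bin is `K` if it contains at least one
#' heterozygous call, otherwise `T` if at least `min_called_fraction` of its
#' positions carry a call, otherwise `N`.
#'
#' @param track Genotype track tibble.
#' @param scaffold_lengths Named numeric vector (bp).
#' @param path Output path.
#' @param bin_size Bin size in bp.
#' @param min_called_fraction Minimum called fraction for a hom bin to count
#'   as `T` rather than `N`.
#' @return `path`, invisibly.
#' @export
write_psmcfa <- function(track, scaffold_lengths, path, bin_size = 100,
                         min_called_fraction = 0.5) {
  stopifnot(bin_size >= 1)
  stop_if_not_prob(min_called_fraction, "min_called_fraction")
  track <- validate_track(track)
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(sprintf("Cannot write %s", path)))
  on.exit(close(con))
  for (scaf in names(scaffold_lengths)) {
    L <- scaffold_lengths[[scaf]]
    nbin <- ceiling(L / bin_size)
    sub <- filter(track, .data$scaffold == scaf)
    bin <- floor((sub$pos - 1) / bin_size) + 1
    called <- tabulate(bin, nbins = nbin)
    hets <- tabulate(bin[sub$gt == "het"], nbins = nbin)
    bin_len <- c(rep(bin_size, nbin - 1), L - (nbin - 1) * bin_size)
    chars <- ifelse(hets > 0, "K",
                    ifelse(called >= min_called_fraction * bin_len,
                           "T", "N"))
    writeLines(paste0(">", scaf), con)
    s <- paste0(chars, collapse = "")
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a psmcfa file into per-scaffold bin characters
#'
#' Convenience reader (mainly for verification): returns a named list of
#' character vectors over `{K, T, N}`.
#'
#' @param path Path to a psmcfa file.
#' @return Named list of character vectors.
#' @export
read_psmcfa <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  recs <- split(lines[!hdr], idx[!hdr])
  names(recs) <- sub("^>", "", lines[hdr])
  lapply(recs, function(x) strsplit(paste0(x, collapse = ""), "")[[1]])
}
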