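#' Classify one alignment column against clade patterns
#'
#' A column matches a [clade_pattern()] when every group-A species shares one
#' non-missing allele, every group-B species shares a different non-missing
#' allele, and the two alleles differ. Species outside both groups are
#' ignored. Patterns are tried in list order and the first match wins. A gap,
#' `N` or ambiguity code inside a pattern group makes that pattern uncallable
#' for this column: the result is no call with a `missing-data` note rather
#' than a guess.
#'
#' @param alleles Named character vector of per-species alignment characters.
#' @param patterns List of [clade_pattern()] objects (order = precedence).
#' @return A one-row tibble: `type` (pattern name or `NA`), `allele_a`,
#'   `allele_b`, `note`.
#' @export
classify_column <- function(alleles, patterns) {
  if (is.null(names(alleles))) abort("`alleles` must be named by species.")
  notes <- character(0)
  for (pat in patterns) {
    unknown <- setdiff(c(pat$group_a, pat$group_b), names(alleles))
    if (length(unknown) > 0) {
      abort(sprintf("Pattern '%s' references unknown species: %s",
                    pat$name, paste(unknown, collapse = ", ")))
    }
    a <- alleles[pat$group_a]
    b <- alleles[pat$group_b]
    if (any(!a %in% BASES) || any(!b %in% BASES)) {
      notes <- c(notes, sprintf("%s: missing-data", pat$name))
      next
    }
    ua <- unique(a)
    ub <- unique(b)
    if (length(ua) == 1 && length(ub) == 1 && ua != ub) {
      return(tibble(type = pat$name, allele_a = ua, allele_b = ub,
                    note = NA_character_))
    }
  }
  tibble(type = NA_character_, allele_a = NA_character_,
         allele_b = NA_character_,
         note = if (length(notes) > 0) paste(notes, collapse = "; ")
                else NA_character_)
}

#' Classify a set of alignment columns into site types
#'
#' Applies [classify_column()] to each requested column and, when a column
#' map is supplied, attaches the mapped genomic coordinate of each site.
#'
#' @param aln Alignment character matrix.
#' @param columns Column indices to classify (e.g. significant scan hits).
#' @param patterns List of [clade_pattern()] objects.
#' @param map Optional [build_column_map()] for genomic coordinates.
#' @return A tibble: `column`, `type`, `allele_a`, `allele_b`, `note`, and
#'   `coordinate` (NA where unmapped or no map given).
#' @export
classify_sites <- function(aln, columns, patterns, map = NULL) {
  res <- purrr::map_dfr(columns, function(j) {
    classify_column(aln[, j], patterns)
  })
  res <- dplyr::bind_cols(tibble(column = as.integer(columns)), res)
  res$coordinate <- if (!is.null(map)) map_column(map, columns) else NA_real_
  res
}

#' Annotate typed sites with overlapping genomic features
#'
#' Labels each site with the names of all features (BED intervals) that
#' overlap its genomic coordinate, joined in sorted order; sites overlapping
#' nothing are labelled `"intergenic/unannotated"`, and sites with no mapped
#' coordinate get `NA` but are retained.
#'
#' @param sites Tibble with a `coordinate` column (1-based), e.g. from
#'   [classify_sites()].
#' @param features A `GRanges` with a `name` column, or a path to a BED file.
#' @param seqname Chromosome name the site coordinates live on; defaults to
#'   the single seqlevel of `features`.
#' @return `sites` with a `feature` column added.
#' @export
annotate_features <- function(sites, features, seqname = NULL) {
  if (is.character(features)) {
    features <- tryCatch(
      rtracklayer::import(features, format = "BED"),
      error = function(e) abort(sprintf("Malformed BED file: %s",
                                        conditionMessage(e)))
    )
  }
  sites <- as_tibble(sites)
  if (is.null(seqname)) {
    seqname <- as.character(GenomicRanges::seqnames(features)[1])
  }
  feature <- rep(NA_character_, nrow(sites))
  mapped <- which(!is.na(sites$coordinate))
  if (length(mapped) > 0 && length(features) > 0) {
    q <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = sites$coordinate[mapped], width = 1)
    )
    ov <- GenomicRanges::findOverlaps(q, features)
    labs <- vapply(seq_along(q), function(i) {
      hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
      if (length(hits) == 0) return("intergenic/unannotated")
      paste(sort(unique(features$name[hits])), collapse = "; ")
    }, character(1))
    feature[mapped] <- labs
  } else if (length(mapped) > 0) {
    feature[mapped] <- "intergenic/unannotated"
  }
  sites$feature <- feature
  sites
}

#' Write a typed-site report TSV
#'
#' One row per site with the columns a site table in a comparative body-size
#' study reports: site type, the two group alleles, genomic coordinate,
#' overlapping features, and the alignment column.
#'
#' @param sites Tibble from [classify_sites()] / [annotate_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  cols <- c("type", "allele_b", "allele_a", "coordinate", "feature", "column")
  out <- sites
  for (cn in setdiff(cols, names(out))) out[[cn]] <- NA
  out <- select(out, type = "type", small_group_allele = "allele_b",
                large_group_allele = "allele_a", coordinate = "coordinate",
                feature = "feature", alignment_column = "column")
  readr::write_tsv(out, path)
  invisible(path)
}
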