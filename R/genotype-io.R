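#' Read per-site genotype calls into a genotype track
#'
#' Two on-disk dialects are supported: a VCF with per-sample `GT` and `DP`
#' fields (parsed with vcfR; a site is `het` when the two GT alleles differ),
#' and a simple 4-column TSV (`scaffold`, `pos`, `gt` in `hom`/`het`,
#' `depth`).
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample For VCF input: sample name (default: first sample).
#' @return A genotype track tibble (`scaffold`, `pos`, `gt`, `depth`),
#'   sorted by scaffold and position.
#' @export
read_genotype_track <- function(path, format = c("tsv", "vcf"),
                                sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Genotype file not found: %s", path))
  if (format == "tsv") {
    track <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               scaffold = readr::col_character(),
                               pos = readr::col_double(),
                               gt = readr::col_character(),
                               depth = readr::col_integer()
                             ))
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )
    sample <- sample %||% colnames(gt)[1]
    if (!sample %in% colnames(gt)) {
      abort(sprintf("Sample '%s' not in VCF.", sample))
    }
    g <- gt[, sample]
    alleles <- strsplit(g, "[/|]")
    het <- vapply(alleles, function(a) {
      length(unique(a[a != "."])) > 1
    }, logical(1))
    called <- !is.na(g) & !vapply(alleles, function(a) any(a == "."),
                                  logical(1))
    track <- tibble(
      scaffold = vcfR::getCHROM(vcf),
      pos = vcfR::getPOS(vcf),
      gt = unname(ifelse(het, "het", "hom")),
      depth = unname(as.integer(dp[, sample]))
    )[called, ]
  }
  validate_track(track) |> arrange(.data$scaffold, .data$pos)
}

#' Write a genotype track as the 4-column TSV dialect
#'
#' @param track Genotype track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_track <- function(track, path) {
  track <- validate_track(track)
  readr::write_tsv(select(track, "scaffold", "pos", "gt", "depth"), path)
  invisible(path)
}
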