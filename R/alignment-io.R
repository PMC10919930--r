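# Alignment and trait-table IO. Parsing of aligned FASTA and Clustal files is
# delegated to Biostrings; the matrix representation used throughout the
# package is a plain character matrix with species ids as row names and
# 1-based column indexing.

ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read a multiple sequence alignment into a character matrix
#'
#' Reads an aligned FASTA or Clustal file, uppercases all characters,
#' normalises `.` gaps to `-`, and maps any character outside
#' A/C/G/T/N/-/IUPAC to `N` (with a message giving the count).
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A species x columns character matrix with unique row names.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Alignment file not found: %s", path))
  if (format == "fasta") {
    msa <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) abort(sprintf("Failed to parse %s as fasta: %s",
                                        path, conditionMessage(e)))
    )
    ids <- sub("\\s.*$", "", names(msa))
    seqs <- as.character(msa)
  } else {
    a <- tryCatch(
      seqinr::read.alignment(path, format = "clustal"),
      error = function(e) abort(sprintf("Failed to parse %s as clustal: %s",
                                        path, conditionMessage(e)))
    )
    ids <- a$nam
    seqs <- unlist(a$seq)
  }
  if (anyDuplicated(ids)) abort("Duplicate sequence ids in alignment.")
  if (length(unique(nchar(seqs))) != 1) {
    abort("Ragged alignment: sequences have unequal lengths.")
  }
  chars <- strsplit(toupper(unname(seqs)), "")
  m <- do.call(rbind, chars)
  rownames(m) <- ids
  m[m == "."] <- "-"
  bad <- !(m %in% ALLOWED_CHARS)
  if (any(bad)) {
    message(sum(bad), " unrecognised character(s) mapped to N")
    m[bad] <- "N"
  }
  m
}

#' Write an alignment matrix as aligned FASTA
#'
#' @param aln Character matrix with species row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste0, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- rownames(aln)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a species trait table
#'
#' Expects a TSV with columns `species`, `mass_kg`, `habitat` and optionally
#' `clade`. Computes `log_mass = ln(mass_kg)` and validates that masses are
#' positive, habitats are `"aquatic"`/`"terrestrial"` and non-missing, and
#' species ids unique.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `species`, `mass_kg`, `log_mass`,
#'   `habitat`, `clade`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Trait table not found: %s", path))
  tt <- readr::read_tsv(path, show_col_types = FALSE)
  validate_trait_table(tt)
}

#' Validate (and complete) a trait table
#'
#' @param tt A data frame with at least `species`, `mass_kg`, `habitat`.
#' @return The validated tibble with `log_mass` and `clade` columns.
#' @export
validate_trait_table <- function(tt) {
  tt <- as_tibble(tt)
  req <- c("species", "mass_kg", "habitat")
  miss <- setdiff(req, names(tt))
  if (length(miss) > 0) {
    abort(paste("Trait table missing column(s):", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tt$species)) abort("Trait table species ids must be unique.")
  bad_mass <- which(!is.finite(tt$mass_kg) | tt$mass_kg <= 0)
  if (length(bad_mass) > 0) {
    abort(sprintf("Non-positive or missing mass_kg for species: %s",
                  paste(tt$species[bad_mass], collapse = ", ")))
  }
  bad_hab <- which(is.na(tt$habitat) |
                     !tt$habitat %in% c("aquatic", "terrestrial"))
  if (length(bad_hab) > 0) {
    abort(sprintf("Invalid or missing habitat for species: %s",
                  paste(tt$species[bad_hab], collapse = ", ")))
  }
  # trust a caller-supplied log_mass (e.g. a rescaled response); derive it
  # from mass_kg only when absent
  if (!"log_mass" %in% names(tt)) tt$log_mass <- log(tt$mass_kg)
  if (!"clade" %in% names(tt)) tt$clade <- NA_character_
  select(tt, "species", "mass_kg", "log_mass", "habitat", "clade")
}

#' Write a trait table as TSV
#'
#' @param traits Trait tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  readr::write_tsv(select(traits, "species", "mass_kg", "habitat", "clade"),
                   path)
  invisible(path)
}
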