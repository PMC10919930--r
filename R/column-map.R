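# Gap-aware mapping between alignment columns and reference-genome
# coordinates. The map is anchored on one alignment row (the reference
# species): its first non-gap base sits at `anchor`, and successive non-gap
# bases advance (forward) or retreat (reverse) by one. Columns where the
# reference row carries a gap have no defensible single coordinate and map to
# NA ("unmapped").

#' Build a column-to-coordinate map from a reference alignment row
#'
#' @param aln Alignment character matrix (species x columns).
#' @param ref_row Row id (species) to anchor on.
#' @param anchor 1-based genomic coordinate of the reference row's first
#'   non-gap base.
#' @param orientation `"forward"` (coordinates increase with columns) or
#'   `"reverse"` (coordinates decrease, as when the gene lies on the minus
#'   strand of the assembly).
#' @param seqname Chromosome/scaffold name used when exporting intervals;
#'   defaults to `ref_row`.
#' @return An object of class `column_map`.
#' @export
#' @examples
#' aln <- rbind(ref = strsplit("AC--GT", "")[[1]])
#' cm <- build_column_map(aln, "ref", anchor = 101, orientation = "forward")
#' map_column(cm, 1:6)  # 101 102 NA NA 103 104
build_column_map <- function(aln, ref_row, anchor,
                             orientation = c("forward", "reverse"),
                             seqname = ref_row) {
  orientation <- match.arg(orientation)
  if (!ref_row %in% rownames(aln)) {
    abort(sprintf("Reference row '%s' not present in alignment.", ref_row))
  }
  if (!is_scalar_number(anchor) || anchor < 1) {
    abort("`anchor` must be a coordinate >= 1.")
  }
  ref <- aln[ref_row, ]
  nongap <- which(ref != "-")
  if (length(nongap) == 0) abort("Reference row is all gaps.")
  step <- if (orientation == "forward") 1 else -1
  coords <- anchor + step * (seq_along(nongap) - 1)
  if (any(coords < 1)) {
    abort("Mapped coordinates fall below 1; anchor too small for reverse map.")
  }
  col2coord <- rep(NA_real_, length(ref))
  col2coord[nongap] <- coords
  structure(list(
    ref_row = ref_row,
    seqname = seqname,
    anchor = anchor,
    orientation = orientation,
    col2coord = col2coord,
    nongap_cols = nongap,
    coord_range = range(coords)
  ), class = "column_map")
}

#' @export
print.column_map <- function(x, ...) {
  cat("<column_map>", x$seqname, x$orientation, "\n")
  cat("  ", length(x$nongap_cols), "mapped columns spanning coordinates",
      x$coord_range[1], "-", x$coord_range[2], "\n")
  invisible(x)
}

#' Map alignment columns to genomic coordinates
#'
#' @param map A [build_column_map()] object.
#' @param columns 1-based column indices.
#' @return Numeric coordinates; `NA` for columns where the reference row has
#'   a gap (unmapped).
#' @export
map_column <- function(map, columns) {
  stopifnot(inherits(map, "column_map"))
  if (any(columns < 1 | columns > length(map$col2coord))) {
    abort("Column index outside the alignment.")
  }
  map$col2coord[columns]
}

#' Map genomic coordinates to alignment columns
#'
#' @param map A [build_column_map()] object.
#' @param coords 1-based genomic coordinates within the covered span.
#' @return Integer column indices.
#' @export
map_coordinate <- function(map, coords) {
  stopifnot(inherits(map, "column_map"))
  if (any(coords < map$coord_range[1] | coords > map$coord_range[2])) {
    abort("Coordinate outside the span covered by the alignment.")
  }
  step <- if (map$orientation == "forward") 1 else -1
  offset <- (coords - map$anchor) * step
  map$nongap_cols[offset + 1]
}

#' Write typed sites as BED6
#'
#' Converts 1-based inclusive site coordinates to BED's 0-based half-open
#' convention, one length-1 interval per site. The `name` field carries the
#' site type and the strand reflects the map orientation. Sites without a
#' mapped coordinate are skipped with a message.
#'
#' @param sites Tibble with columns `coordinate` and `type` (e.g. from
#'   [classify_sites()] joined with [map_column()]).
#' @param map A [build_column_map()] object (provides seqname and strand).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, map, path) {
  sites <- as_tibble(sites)
  unmapped <- is.na(sites$coordinate)
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped site(s) skipped in BED output")
  }
  mapped <- sites[!unmapped, , drop = FALSE]
  strand <- if (map$orientation == "forward") "+" else "-"
  if (nrow(mapped) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = map$seqname,
    ranges = IRanges::IRanges(start = mapped$coordinate, width = 1),
    strand = strand,
    name = ifelse(is.na(mapped$type), "untyped", mapped$type),
    score = 0
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
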