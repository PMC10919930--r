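# Windowed heterozygosity and runs of homozygosity over per-site genotype
# calls. A genotype track is a tibble (scaffold, pos, gt in {"hom","het"},
# depth) with positions strictly increasing per scaffold; scaffold lengths
# travel alongside as a named vector.

validate_track <- function(track) {
  track <- as_tibble(track)
  req <- c("scaffold", "pos", "gt")
  miss <- setdiff(req, names(track))
  if (length(miss) > 0) {
    abort(paste("Genotype track missing column(s):",
                paste(miss, collapse = ", ")))
  }
  if (!all(track$gt %in% c("hom", "het"))) {
    abort("Genotype class must be 'hom' or 'het'.")
  }
  track
}

#' Filter genotype calls by read depth
#'
#' Retains sites whose depth lies in the boundary-inclusive interval
#' `[mean_depth / 3, 2 * mean_depth]`, the conventional filter against
#' collapsed repeats (excess depth) and unreliable calls (low depth). The
#' mean is computed once on the unfiltered input (or supplied), so the bounds
#' are frozen and the filter is idempotent.
#'
#' @param track Genotype track tibble.
#' @param mean_depth Mean depth used to set the bounds; default: mean of
#'   `track$depth`.
#' @return The filtered track (a subset of the input rows, order preserved),
#'   with the applied bounds in attributes `depth_bounds`.
#' @export
filter_by_depth <- function(track, mean_depth = NULL) {
  track <- validate_track(track)
  if (!"depth" %in% names(track)) abort("Track has no `depth` column.")
  if (nrow(track) == 0) return(track)
  mean_depth <- mean_depth %||% mean(track$depth)
  if (!is_scalar_number(mean_depth) || mean_depth <= 0) {
    abort("`mean_depth` must be positive.")
  }
  lo <- mean_depth / 3
  hi <- 2 * mean_depth
  out <- filter(track, .data$depth >= lo, .data$depth <= hi)
  attr(out, "depth_bounds") <- c(lower = lo, upper = hi)
  out
}

# Tile scaffolds into nonoverlapping windows and count calls/hets per window.
window_counts <- function(track, scaffold_lengths, window_size) {
  stopifnot(window_size >= 1)
  orphan <- setdiff(unique(track$scaffold), names(scaffold_lengths))
  if (length(orphan) > 0) {
    abort(paste("Track scaffold(s) without a length:",
                paste(orphan, collapse = ", ")))
  }
  tiles <- purrr::map_dfr(names(scaffold_lengths), function(scaf) {
    L <- scaffold_lengths[[scaf]]
    if (L < 1) return(tibble())
    starts <- seq(1, L, by = window_size)
    tibble(scaffold = scaf, start = starts,
           end = pmin(starts + window_size - 1, L))
  })
  counts <- track |>
    mutate(start = (floor((.data$pos - 1) / window_size) * window_size) + 1) |>
    group_by(.data$scaffold, .data$start) |>
    summarise(n_called = n(), n_het = sum(.data$gt == "het"),
              .groups = "drop")
  tiles |>
    left_join(counts, by = c("scaffold", "start")) |>
    mutate(
      n_called = dplyr::coalesce(.data$n_called, 0L),
      n_het = dplyr::coalesce(.data$n_het, 0L),
      partial = (.data$end - .data$start + 1) < window_size
    )
}

#' Windowed heterozygosity
#'
#' Heterozygosity per nonoverlapping window: heterozygous calls divided by
#' all called genotypes in the window (default window 1 Mb). Windows tile
#' each scaffold completely; a final short window is included and flagged
#' `partial`; a window with zero called genotypes reports `het = NA`.
#'
#' @param track Genotype track tibble (typically depth-filtered).
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param window_size Window size in bp (default 1e6).
#' @return A tibble of class `het_windows`: `scaffold`, `start`, `end`,
#'   `n_called`, `n_het`, `het`, `partial`.
#' @export
window_heterozygosity <- function(track, scaffold_lengths,
                                  window_size = 1e6) {
  track <- validate_track(track)
  out <- window_counts(track, scaffold_lengths, window_size) |>
    mutate(het = ifelse(.data$n_called > 0,
                        .data$n_het / .data$n_called, NA_real_)) |>
    select("scaffold", "start", "end", "n_called", "n_het", "het", "partial")
  class(out) <- c("het_windows", class(out))
  attr(out, "window_size") <- window_size
  out
}

#' Call runs of homozygosity
#'
#' Scores heterozygosity in nonoverlapping windows (default 20 kb) and calls
#' a run of homozygosity wherever at least `min_windows` consecutive windows
#' (default 25) have a score at or below `het_threshold` (default 0.025,
#' i.e. 2.5%). The default score is the within-window heterozygous fraction
#' `n_het / n_called`; `score = "het_per_kb"` uses heterozygous sites per kb
#' of window instead. Windows with zero called genotypes break runs by
#' default — absence of calls is not evidence of homozygosity — unless
#' `empty_windows_qualify = TRUE`.
#'
#' @param track Genotype track tibble.
#' @param scaffold_lengths Named numeric vector (bp).
#' @param window_size ROH window size in bp (default 20000).
#' @param min_windows Minimum consecutive qualifying windows (default 25).
#' @param het_threshold Maximum qualifying window score (default 0.025).
#' @param score Window score definition.
#' @param empty_windows_qualify Treat zero-call windows as qualifying?
#' @return A tibble: `scaffold`, `start`, `end`, `length`, `n_windows`,
#'   `mean_het` (pooled `n_het / n_called` within the run).
#' @export
call_roh <- function(track, scaffold_lengths, window_size = 20000,
                     min_windows = 25, het_threshold = 0.025,
                     score = c("het_fraction", "het_per_kb"),
                     empty_windows_qualify = FALSE) {
  stopifnot(window_size > 0, min_windows >= 1, het_threshold >= 0)
  score <- match.arg(score)
  track <- validate_track(track)
  wins <- window_counts(track, scaffold_lengths, window_size)
  if (nrow(wins) == 0) {
    return(tibble(scaffold = character(0), start = numeric(0),
                  end = numeric(0), length = numeric(0),
                  n_windows = integer(0), mean_het = numeric(0)))
  }
  sc <- if (score == "het_fraction") {
    ifelse(wins$n_called > 0, wins$n_het / wins$n_called, NA_real_)
  } else {
    wins$n_het / ((wins$end - wins$start + 1) / 1000)
  }
  qual <- !is.na(sc) & sc <= het_threshold
  if (empty_windows_qualify) qual[wins$n_called == 0] <- TRUE
  wins$qualifies <- qual

  out <- purrr::map_dfr(split(wins, wins$scaffold), function(ws) {
    ws <- arrange(ws, .data$start)
    r <- rle(ws$qualifies)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    keep <- r$values & r$lengths >= min_windows
    purrr::map_dfr(which(keep), function(i) {
      idx <- starts_i[i]:ends_i[i]
      tibble(
        scaffold = ws$scaffold[1],
        start = ws$start[idx[1]],
        end = ws$end[idx[length(idx)]],
        length = ws$end[idx[length(idx)]] - ws$start[idx[1]] + 1,
        n_windows = length(idx),
        mean_het = if (sum(ws$n_called[idx]) > 0) {
          sum(ws$n_het[idx]) / sum(ws$n_called[idx])
        } else NA_real_
      )
    })
  })
  if (nrow(out) == 0) {
    return(tibble(scaffold = character(0), start = numeric(0),
                  end = numeric(0), length = numeric(0),
                  n_windows = integer(0), mean_het = numeric(0)))
  }
  arrange(out, .data$scaffold, .data$start)
}

#' Summarise runs of homozygosity
#'
#' Computes the inbreeding coefficient Froh — the total length of runs at or
#' above `min_length` (default 500 kb) divided by the assessed genome length
#' — plus a run-length histogram and the longest run.
#'
#' @param runs Tibble from [call_roh()].
#' @param assessed_length Total assessed (callable) genome length in bp.
#' @param min_length Minimum run length contributing to Froh (bp).
#' @param bins Length-bin breakpoints in bp for runs >= `min_length`.
#' @return An object of class `roh_summary` with elements `runs`, `froh`,
#'   `min_length`, `assessed_length`, `bins` (tibble), `longest`,
#'   `n_runs_min_length`.
#' @export
summarize_roh <- function(runs, assessed_length, min_length = 5e5,
                          bins = c(5e5, 1e6, 2.5e6, 4e6, Inf)) {
  if (!is_scalar_number(assessed_length) || assessed_length <= 0) {
    abort("`assessed_length` must be positive.")
  }
  if (nrow(runs) > 0 && sum(runs$length) > assessed_length) {
    abort("Total run length exceeds the assessed length.")
  }
  qual <- filter(runs, .data$length >= min_length)
  froh <- sum(qual$length) / assessed_length
  breaks <- sort(unique(c(min_length, bins)))
  labels <- paste0(format_bp(breaks[-length(breaks)]), "-",
                   format_bp(breaks[-1]))
  bin_tbl <- tibble(
    bin = factor(labels, levels = labels),
    n = as.integer(table(cut(qual$length, breaks = breaks, labels = labels,
                             right = FALSE, include.lowest = TRUE)))
  )
  longest <- if (nrow(runs) > 0) runs[which.max(runs$length), ] else runs
  structure(list(
    runs = runs, froh = froh, min_length = min_length,
    assessed_length = assessed_length, bins = bin_tbl,
    longest = longest, n_runs_min_length = nrow(qual)
  ), class = "roh_summary")
}

format_bp <- function(x) {
  ifelse(is.infinite(x), "Inf",
         ifelse(x >= 1e6, paste0(x / 1e6, "Mb"), paste0(x / 1e3, "kb")))
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("<roh_summary>\n")
  cat(sprintf("  %d run(s) >= %s; Froh = %.4f over %s assessed\n",
              x$n_runs_min_length, format_bp(x$min_length), x$froh,
              format_bp(x$assessed_length)))
  if (nrow(x$longest) > 0) {
    cat(sprintf("  longest run: %s on %s (%s-%s)\n",
                format_bp(x$longest$length), x$longest$scaffold,
                format(x$longest$start, big.mark = ","),
                format(x$longest$end, big.mark = ",")))
  }
  invisible(x)
}
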