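# broom-style accessors for the package's result objects.

#' Tidy a column-scan result
#'
#' @param x An `aln_scan` tibble from [scan_alignment()].
#' @param ... Unused.
#' @return The scan table as a plain tibble (one row per column per model).
#' @method tidy aln_scan
#' @export
tidy.aln_scan <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' One-row summary of a column scan
#'
#' @param x An `aln_scan` tibble.
#' @param ... Unused.
#' @return A tibble with one row per model: columns tested/skipped, the
#'   smallest p-value and its column.
#' @method glance aln_scan
#' @export
glance.aln_scan <- function(x, ...) {
  as_tibble(unclass_first(x)) |>
    group_by(.data$model) |>
    summarise(
      n_columns = n(),
      n_tested = sum(.data$tested),
      n_skipped = sum(!.data$tested),
      min_p = suppressWarnings(min(.data$p_value, na.rm = TRUE)),
      top_column = .data$column[which.min(.data$p_value)],
      .groups = "drop"
    )
}

#' Tidy an FDR estimate table
#'
#' @param x An `fdr_estimate` tibble from [estimate_fdr()].
#' @param ... Unused.
#' @return A plain tibble, one row per threshold per run.
#' @method tidy fdr_estimate
#' @export
tidy.fdr_estimate <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' One-row-per-threshold summary of an FDR estimate
#'
#' @param x An `fdr_estimate` tibble.
#' @param ... Unused.
#' @return A tibble with runs averaged and their relative spread.
#' @method glance fdr_estimate
#' @export
glance.fdr_estimate <- function(x, ...) {
  as_tibble(unclass_first(x)) |>
    group_by(.data$model, .data$threshold) |>
    summarise(
      hits_original = .data$hits_original[1],
      mean_fdr = mean(.data$fdr),
      run_spread = if (dplyr::n() > 1 && all(is.finite(.data$fdr)) &&
                       mean(.data$fdr) > 0) {
        diff(range(.data$fdr)) / mean(.data$fdr)
      } else NA_real_,
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

#' Tidy an ROH summary
#'
#' @param x A `roh_summary` from [summarize_roh()].
#' @param ... Unused.
#' @return The run table with a `qualifies` column (length >= min_length).
#' @method tidy roh_summary
#' @export
tidy.roh_summary <- function(x, ...) {
  mutate(as_tibble(x$runs), qualifies = .data$length >= x$min_length)
}

#' One-row summary of an ROH analysis
#'
#' @param x A `roh_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `froh`, run counts, total and longest lengths.
#' @method glance roh_summary
#' @export
glance.roh_summary <- function(x, ...) {
  tibble(
    froh = x$froh,
    n_runs = nrow(x$runs),
    n_runs_min_length = x$n_runs_min_length,
    total_roh_bp = sum(x$runs$length),
    longest_bp = if (nrow(x$runs) > 0) max(x$runs$length) else 0,
    assessed_length = x$assessed_length,
    min_length = x$min_length
  )
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("aln_scan", "fdr_estimate", "het_windows"))
  x
}
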