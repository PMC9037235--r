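# Sample-level biomarkers: %PIT, pit morphometrics, splenic-function calls.

#' %PIT of a filtered object table
#'
#' The denominator is the included cells; a cell is pitted iff it has at
#' least one counted pit. With an empty denominator the percentage is
#' `NA` (explicit "undefined" marker).
#'
#' @param table a filtered `object_table` (with a `status` column).
#' @param min_cells minimum number of counted cells for the
#'   `sufficient_count` flag; default 500, the classical minimum for a
#'   manual count.
#' @return List: `n_cells_counted`, `n_pitted`, `percent_pit`,
#'   `sufficient_count`, `exclusions` (tally by reason).
#' @export
pit_count_percent <- function(table, min_cells = 500) {
  if (!"status" %in% names(table))
    stop("table must be filtered first (see apply_filters)")
  inc <- table$status == "included"
  n <- sum(inc)
  n_pitted <- sum(inc & table$pit_count >= 1)
  excl <- base::table(factor(table$status[!inc],
                       levels = c("excluded_size", "excluded_edge",
                                  "excluded_solidity")))
  list(n_cells_counted = n,
       n_pitted = n_pitted,
       percent_pit = if (n > 0) 100 * n_pitted / n else NA_real_,
       sufficient_count = n >= min_cells,
       exclusions = excl)
}

#' Pit morphometrics of a filtered object table
#'
#' @param table a filtered `object_table`.
#' @param pit_size_average `"per_pit"` (default): each pit contributes
#'   its own area as a fraction of its cell; `"per_cell"`: pit-size
#'   fractions are first averaged within each pitted cell.
#' @return List: `mean_pits_per_pitted_cell`, `max_pits_in_one_cell`,
#'   `mean_pit_size_percent_of_cell`; all `NA` when no included cell is
#'   pitted.
#' @export
pit_morphometrics <- function(table, pit_size_average = c("per_pit", "per_cell")) {
  pit_size_average <- match.arg(pit_size_average)
  if (!"status" %in% names(table))
    stop("table must be filtered first (see apply_filters)")
  inc <- table[table$status == "included", , drop = FALSE]
  pitted <- inc[inc$pit_count >= 1, , drop = FALSE]
  if (nrow(pitted) == 0) {
    return(list(mean_pits_per_pitted_cell = NA_real_,
                max_pits_in_one_cell = if (nrow(inc)) max(inc$pit_count) else NA_real_,
                mean_pit_size_percent_of_cell = NA_real_))
  }
  per_cell_fracs <- lapply(seq_len(nrow(pitted)), function(i)
    100 * unlist(pitted$pit_areas_um2[i]) / pitted$area_um2[i])
  size_pct <- switch(pit_size_average,
    per_pit = mean(unlist(per_cell_fracs)),
    per_cell = mean(vapply(per_cell_fracs, mean, numeric(1))))
  list(mean_pits_per_pitted_cell = mean(pitted$pit_count),
       max_pits_in_one_cell = max(inc$pit_count),
       mean_pit_size_percent_of_cell = size_pct)
}

#' Summarise a sample
#'
#' Combines [pit_count_percent()] and [pit_morphometrics()] and, when
#' %PIT is defined, the splenic-function call under the requested rule.
#'
#' @inheritParams pit_count_percent
#' @inheritParams pit_morphometrics
#' @param rule diagnosis rule passed to [classify_splenic_function()],
#'   or `NULL` to skip the call.
#' @return A `sample_result` (named list) with a `print` method.
#' @export
summarize_sample <- function(table, min_cells = 500, rule = "el_hoss_2018",
                             pit_size_average = c("per_pit", "per_cell")) {
  core <- pit_count_percent(table, min_cells)
  morph <- pit_morphometrics(table, pit_size_average)
  status <- if (!is.null(rule) && !is.na(core$percent_pit))
    classify_splenic_function(core$percent_pit, rule) else NA_character_
  structure(c(core, morph, list(spleen_status = status, rule = rule)),
            class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat("sample_result\n")
  cat(sprintf("  cells counted: %d (pitted: %d)%s\n", x$n_cells_counted,
              x$n_pitted,
              if (x$sufficient_count) "" else "  [below minimum count]"))
  cat(sprintf("  %%PIT: %s\n",
              if (is.na(x$percent_pit)) "undefined" else sprintf("%.2f%%", x$percent_pit)))
  if (!is.na(x$mean_pits_per_pitted_cell))
    cat(sprintf("  pits/pitted cell: %.2f (max %d); mean pit size %.3f%% of cell\n",
                x$mean_pits_per_pitted_cell, as.integer(x$max_pits_in_one_cell),
                x$mean_pit_size_percent_of_cell))
  excl <- x$exclusions
  if (sum(excl) > 0)
    cat("  excluded:", paste(names(excl)[excl > 0], excl[excl > 0],
                             sep = "=", collapse = ", "), "\n")
  if (!is.na(x$spleen_status))
    cat(sprintf("  splenic function (%s): %s\n", x$rule, x$spleen_status))
  invisible(x)
}

#' Splenic-function call from %PIT
#'
#' Two published threshold rules are implemented verbatim:
#' * `rogers_1970s`: %PIT >= 3.5 indicates loss of splenic function,
#'   otherwise normal.
#' * `el_hoss_2018`: %PIT < 1.2 predicts normal splenic function,
#'   %PIT > 4.5 predicts absent splenic function, values between are
#'   indeterminate.
#'
#' Boundary values sit exactly where the printed inequality signs put
#' them; there is no epsilon fuzzing.
#'
#' @param percent_pit %PIT value(s), in percent; must be defined
#'   (non-`NA`).
#' @param rule `"rogers_1970s"` or `"el_hoss_2018"`.
#' @return Character vector over
#'   `{"normal", "indeterminate", "loss_of_function", "absent"}`.
#' @export
classify_splenic_function <- function(percent_pit,
                                      rule = c("el_hoss_2018", "rogers_1970s")) {
  rule <- match.arg(rule)
  if (any(is.na(percent_pit))) stop("percent_pit is undefined (NA)")
  if (any(percent_pit < 0 | percent_pit > 100))
    stop("percent_pit must lie in [0, 100]")
  if (rule == "rogers_1970s") {
    ifelse(percent_pit >= 3.5, "loss_of_function", "normal")
  } else {
    ifelse(percent_pit < 1.2, "normal",
           ifelse(percent_pit > 4.5, "absent", "indeterminate"))
  }
}
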