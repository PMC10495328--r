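# Adjacent-tooth root parallelism: absolute angulation differences between
# neighboring teeth, the left/right pooling gate, and the per-jaw summary
# table with repeated-measures comparisons across the three setups.

LOCATION_LEVELS <- c("1-2", "2-3", "3-4", "4-5", "5-6", "6-7")

#' Absolute angulation differences between adjacent teeth
#'
#' For every pair of consecutive tooth positions present within a quadrant,
#' computes the absolute difference of the signed angulation values. Pairs
#' with a missing member are skipped.
#'
#' @param measurements tibble of angular measurements, with at least `fdi` and
#'   `angulation`; grouping columns (e.g. `patient`, `setup`) are preserved,
#'   and differences are computed within each `patient`/`setup` combination
#'   that is present.
#' @return a tibble with columns `jaw`, `side`, `location` (e.g. `"1-2"` for
#'   central-lateral incisor), `value` (absolute difference, degrees), plus
#'   any of `patient`, `setup` present in the input.
#' @export
adjacent_differences <- function(measurements) {
  stopifnot(is.data.frame(measurements), all(c("fdi", "angulation") %in% names(measurements)))
  keys <- intersect(c("patient", "setup"), names(measurements))
  df <- dplyr::bind_cols(
    measurements[c(keys, "fdi", "angulation")],
    fdi_info(measurements$fdi)[c("jaw", "side", "position")]
  )
  gcols <- c(keys, "jaw", "side")
  ord <- do.call(order, c(unname(as.list(df[gcols])), list(df$position)))
  df <- df[ord, , drop = FALSE]
  gid <- do.call(paste, c(df[gcols], sep = "\r"))
  i <- seq_len(nrow(df) - 1)
  same <- gid[i] == gid[i + 1] & (df$position[i + 1] - df$position[i]) == 1L
  keep <- which(same)
  out <- df[keep, gcols, drop = FALSE]
  out$location <- factor(
    paste0(df$position[keep], "-", df$position[keep + 1]),
    levels = LOCATION_LEVELS
  )
  out$value <- abs(df$angulation[keep + 1] - df$angulation[keep])
  tibble::as_tibble(out)
}

#' Left/right pooling gate
#'
#' The study pools the left and right sides of the arch into one sample per
#' location when paired t-tests on the initial-scan values reveal no
#' left/right difference at any location. This gate runs those per-location
#' paired t-tests (pairing left and right within patient) and reports whether
#' pooling is justified.
#'
#' @param initial_values tibble of initial-scan values with columns `patient`,
#'   `side` ("left"/"right"), a location column named by `location_col`, and
#'   `value`.
#' @param alpha gate significance level.
#' @param location_col name of the location column (default `"location"`).
#' @return a list with `pooled` (logical: all locations passed), `gate` (tibble
#'   with one row per jaw x location: n pairs, t, p, passed), and
#'   `failed_locations`.
#' @export
pool_left_right <- function(initial_values, alpha = 0.05, location_col = "location") {
  stopifnot(all(c("patient", "side", location_col, "value") %in% names(initial_values)))
  keys <- intersect(c("jaw", location_col), names(initial_values))
  gate <- initial_values %>%
    tidyr::pivot_wider(
      id_cols = dplyr::all_of(c("patient", keys)),
      names_from = "side", values_from = "value"
    ) %>%
    dplyr::filter(is.finite(.data$left), is.finite(.data$right)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      n = dplyr::n(),
      t = if (dplyr::n() >= 2) as.numeric(paired_t(.data$left, .data$right)$statistic) else NA_real_,
      p = if (dplyr::n() >= 2) paired_t(.data$left, .data$right)$p_value else NA_real_,
      .groups = "drop"
    )
  if (any(gate$n < 2)) {
    stop(
      "insufficient data: fewer than 2 complete left/right pairs at location(s) ",
      paste(gate[[location_col]][gate$n < 2], collapse = ", "),
      call. = FALSE
    )
  }
  gate$passed <- gate$p >= alpha
  list(
    pooled = all(gate$passed),
    gate = gate,
    failed_locations = gate[[location_col]][!gate$passed]
  )
}

#' Adjacent-tooth parallelism comparison table
#'
#' Builds the per-jaw, per-location summary of absolute adjacent-tooth
#' angulation differences across the setup conditions: mean and SD per setup,
#' the repeated-measures ANOVA p across setups (each patient-side contributing
#' one observation per location after pooling), and Bonferroni post-hoc
#' direction labels.
#'
#' @param pair_values tibble from [adjacent_differences()] with columns
#'   `patient`, `setup`, `jaw`, `side`, `location`, `value`; exactly the setups
#'   in `setups` must be present for a patient-side to be included.
#' @param setups character vector of setup conditions, in the letter order
#'   used by the post-hoc labels (a, b, c).
#' @param alpha significance level.
#' @return an object of class `os_parallelism`; `tidy()` returns the table
#'   with one row per jaw x location.
#' @export
parallelism_table <- function(pair_values,
                              setups = c("crown", "root1", "root2"),
                              alpha = 0.05) {
  stopifnot(all(c("patient", "setup", "jaw", "side", "location", "value") %in% names(pair_values)))
  df <- pair_values %>%
    dplyr::filter(.data$setup %in% setups) %>%
    dplyr::mutate(subject = paste(.data$patient, .data$side, sep = "/"))
  wide <- df %>%
    tidyr::pivot_wider(
      id_cols = c("jaw", "location", "subject"),
      names_from = "setup", values_from = "value"
    )
  complete <- stats::complete.cases(wide[setups])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    warning(sprintf(
      "excluded %d subject-location rows with unbalanced setups", n_dropped
    ), call. = FALSE)
    wide <- wide[complete, , drop = FALSE]
  }
  groups <- split(wide, list(wide$jaw, wide$location), drop = TRUE)
  rows <- dplyr::bind_rows(lapply(groups, function(g) {
    m <- as.matrix(g[setups])
    if (nrow(m) < 2) {
      stop(sprintf(
        "insufficient data for ANOVA at %s %s (need >= 2 subjects)",
        g$jaw[1], as.character(g$location[1])
      ), call. = FALSE)
    }
    res <- rm_anova(m, alpha = alpha)
    out <- list(jaw = g$jaw[1], location = g$location[1])
    for (s in setups) {
      out[[paste0(s, "_mean")]] <- mean(g[[s]])
      out[[paste0(s, "_sd")]] <- sd(g[[s]])
    }
    c(out, list(
      n = nrow(m), F = as.numeric(res$statistic), p_value = res$p_value,
      mauchly_w = res$mauchly$W, mauchly_p = res$mauchly$p_value,
      posthoc = res$posthoc
    ))
  }))
  rows <- rows[order(rows$jaw == "mandible", rows$location), , drop = FALSE]
  structure(
    list(table = rows, setups = setups, alpha = alpha, n_dropped = n_dropped),
    class = "os_parallelism"
  )
}

#' @export
print.os_parallelism <- function(x, ...) {
  cat(sprintf(
    "<os_parallelism> adjacent-tooth angulation differences, setups: %s (a, b, %s)\n",
    paste(x$setups, collapse = ", "), letters[length(x$setups)]
  ))
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}

#' @export
tidy.os_parallelism <- function(x, ...) x$table

#' @export
glance.os_parallelism <- function(x, ...) {
  tibble::tibble(
    n_locations = nrow(x$table),
    n_significant = sum(x$table$p_value < x$alpha, na.rm = TRUE),
    alpha = x$alpha,
    subjects_dropped = x$n_dropped
  )
}
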