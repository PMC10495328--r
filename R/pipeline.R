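# End-to-end study pipeline: measure angles from landmarks with the shared
# root-setup-2 occlusal frame, run the pooling gate, and assemble the
# parallelism and exposure comparison tables.

#' Measure all angular values of a cohort
#'
#' Builds each patient's occlusal frame from the root setup-2 occlusal
#' landmarks (the shared reference for all conditions of that patient) and
#' measures signed angulation and inclination for every tooth of every
#' condition.
#'
#' @param cohort an `os_cohort` from [build_cohort()], or any list with
#'   `landmarks` (tibble with patient, jaw, setup, fdi, M/D/A coordinate
#'   columns) and `occlusal` (list with `molar_right`, `molar_left`,
#'   `incisor_contact`, `apex_centroid`).
#' @return tibble: patient, jaw, setup, fdi, angulation, inclination.
#' @export
measure_cohort_angles <- function(cohort) {
  frame <- occlusal_frame(
    cohort$occlusal$molar_right, cohort$occlusal$molar_left,
    cohort$occlusal$incisor_contact, cohort$occlusal$apex_centroid
  )
  lm <- cohort$landmarks
  M <- as.matrix(lm[c("M_x", "M_y", "M_z")])
  D <- as.matrix(lm[c("D_x", "D_y", "D_z")])
  A <- as.matrix(lm[c("A_x", "A_y", "A_z")])
  gid <- paste(lm$patient, lm$jaw, lm$setup)
  mid <- (M + D) / 2
  sums <- rowsum(mid, gid)
  counts <- as.vector(rowsum(rep(1, nrow(mid)), gid))
  ctr <- (sums / counts)[gid, , drop = FALSE] # per-arch centroid, per row
  res <- measure_angles_matrix(M, D, A, frame$superior, centroid = ctr)
  tibble::new_tibble(list(
    patient = lm$patient, jaw = lm$jaw, setup = lm$setup, fdi = lm$fdi,
    angulation = res$angulation, inclination = res$inclination
  ), nrow = nrow(lm))
}

#' Run the full setup comparison study
#'
#' The complete analysis chain on a cohort: left/right pooling gate on the
#' initial-scan angulations, adjacent-tooth parallelism table with
#' repeated-measures ANOVA across the crown / root-1 / root-2 setups, and the
#' root-exposure mean (Friedman) and frequency (McNemar) tables.
#'
#' @param cohort an `os_cohort` (see [build_cohort()]).
#' @param alpha significance level used throughout.
#' @param threshold exposure frequency threshold in mm (strict).
#' @param setups the three setup conditions, in post-hoc letter order.
#' @return an object of class `os_study` with elements `angles`, `gate`,
#'   `parallelism` (class `os_parallelism`), `exposure` (class `os_exposure`).
#' @export
run_study <- function(cohort, alpha = 0.05, threshold = 2,
                      setups = c("crown", "root1", "root2")) {
  angles <- measure_cohort_angles(cohort)

  initial <- angles %>%
    dplyr::filter(.data$setup == "initial") %>%
    dplyr::bind_cols(fdi_info(.$fdi)[c("side", "position")]) %>%
    dplyr::transmute(
      patient = .data$patient, jaw = .data$jaw, side = .data$side,
      location = .data$position, value = .data$angulation
    )
  gate <- pool_left_right(initial, alpha = alpha)

  pairs <- adjacent_differences(angles %>% dplyr::filter(.data$setup %in% setups))
  par_tab <- parallelism_table(pairs, setups = setups, alpha = alpha)

  expo_tab <- exposure_tables(cohort$exposures,
    setups = setups,
    threshold = threshold, alpha = alpha
  )

  structure(
    list(
      angles = angles, gate = gate, parallelism = par_tab,
      exposure = expo_tab, alpha = alpha, threshold = threshold
    ),
    class = "os_study"
  )
}

#' @export
print.os_study <- function(x, ...) {
  cat("<os_study>\n")
  cat(sprintf(
    "Left/right pooling gate: %s (min p = %.3f)\n",
    if (x$gate$pooled) "pooled" else "NOT pooled", min(x$gate$gate$p)
  ))
  print(x$parallelism)
  print(x$exposure)
  invisible(x)
}

#' @export
tidy.os_study <- function(x, which = c("parallelism", "exposure_means",
                            "exposure_frequency", "gate"), ...) {
  which <- match.arg(which)
  switch(which,
    parallelism = tidy(x$parallelism),
    exposure_means = tidy(x$exposure, "means"),
    exposure_frequency = tidy(x$exposure, "frequency"),
    gate = x$gate$gate
  )
}

#' @export
glance.os_study <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(pooled = x$gate$pooled),
    glance(x$parallelism)[c("n_significant")] %>%
      dplyr::rename(parallelism_significant = "n_significant"),
    glance(x$exposure)[c("n_significant_friedman", "n_significant_mcnemar")]
  )
}

#' Intra-rater reliability of the angulation measurement
#'
#' Emulates the repeat-digitization reliability check: re-measures the
#' angulation of the teeth of a few randomly selected cases after perturbing
#' the landmark points with small digitization noise, and computes the
#' two-way mixed single-measure consistency ICC between the two sessions
#' (each tooth-condition measurement is a subject).
#'
#' @param cohort an `os_cohort`.
#' @param n_cases number of randomly selected patients.
#' @param digitization_sd landmark re-digitization noise SD per coordinate
#'   (mm).
#' @param seed integer seed for case selection and noise.
#' @return an `os_test` carrying the ICC.
#' @export
remeasure_icc <- function(cohort, n_cases = 4, digitization_sd = 0.15, seed = 1) {
  set.seed(seed)
  patients <- sample(unique(cohort$landmarks$patient), n_cases)
  lm1 <- cohort$landmarks %>% dplyr::filter(.data$patient %in% patients)
  coord_cols <- c(t(outer(c("M", "D", "A"), c("x", "y", "z"), paste, sep = "_")))
  lm2 <- lm1
  for (cc in coord_cols) {
    lm2[[cc]] <- lm2[[cc]] + rnorm(nrow(lm2), 0, digitization_sd)
  }
  session <- function(lm) {
    measure_cohort_angles(list(landmarks = lm, occlusal = cohort$occlusal))$angulation
  }
  icc_agreement(cbind(session1 = session(lm1), session2 = session(lm2)))
}
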