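# Landmark-file input/output. One JSON file describes one patient / jaw /
# setup: the occlusal landmark triple, per-tooth M/D/A triplets (FDI
# numbered), and optionally the crest reference discs. Units are mm,
# right-handed coordinates.

xyz_ok <- function(v) is.numeric(v) && length(v) == 3 && all(is.finite(v))

#' Write a landmark JSON file
#'
#' @param landmarks tibble with columns `fdi`, `M_x`..`A_z` (one row per
#'   tooth).
#' @param path output path.
#' @param patient_id,jaw,setup dataset identity fields.
#' @param occlusal_landmarks 3 x 3 matrix (rows: molar right, molar left,
#'   incisor contact), or NULL.
#' @param discs list of [crest_disc()] objects, or NULL.
#' @return `path`, invisibly.
#' @export
write_landmark_json <- function(landmarks, path, patient_id = "P01",
                                jaw = "maxilla", setup = "initial",
                                occlusal_landmarks = NULL, discs = NULL) {
  teeth <- lapply(seq_len(nrow(landmarks)), function(i) {
    r <- landmarks[i, ]
    list(
      fdi = as.integer(r$fdi),
      M = c(r$M_x, r$M_y, r$M_z),
      D = c(r$D_x, r$D_y, r$D_z),
      A = c(r$A_x, r$A_y, r$A_z)
    )
  })
  obj <- list(
    patient_id = patient_id, jaw = jaw, setup = setup,
    occlusal_landmarks = occlusal_landmarks, teeth = teeth
  )
  if (!is.null(discs)) {
    obj$discs <- lapply(discs, function(d) {
      list(fdi = d$fdi, origin = d$origin, normal = d$normal, radius = d$radius)
    })
  }
  # I(17) = 17 significant digits: doubles survive the round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read and validate a landmark JSON file
#'
#' @param path file path.
#' @return list with `patient_id`, `jaw`, `setup`, `occlusal_landmarks`
#'   (3 x 3 matrix or NULL), `landmarks` (tibble `fdi`, `M_x`..`A_z`) and
#'   `discs` (list of [crest_disc()] or NULL).
#' @export
read_landmark_json <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (field in c("patient_id", "jaw", "setup", "teeth")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("landmark parse error: missing field '%s'", field), call. = FALSE)
    }
  }
  if (!obj$jaw %in% c("maxilla", "mandible")) {
    stop("landmark parse error: field 'jaw' must be 'maxilla' or 'mandible'", call. = FALSE)
  }
  teeth <- lapply(obj$teeth, function(t) {
    if (is.null(t$fdi)) stop("landmark parse error: tooth without 'fdi'", call. = FALSE)
    for (pt in c("M", "D", "A")) {
      if (is.null(t[[pt]]) || !xyz_ok(as.numeric(t[[pt]]))) {
        stop(sprintf(
          "landmark parse error: fdi %s: missing or malformed point '%s'",
          t$fdi, pt
        ), call. = FALSE)
      }
    }
    tibble::tibble(
      fdi = as.integer(t$fdi),
      M_x = t$M[[1]], M_y = t$M[[2]], M_z = t$M[[3]],
      D_x = t$D[[1]], D_y = t$D[[2]], D_z = t$D[[3]],
      A_x = t$A[[1]], A_y = t$A[[2]], A_z = t$A[[3]]
    )
  })
  lm <- dplyr::bind_rows(teeth)
  fdi_info(lm$fdi) # validates the FDI range
  if (anyDuplicated(lm$fdi)) {
    stop(
      "landmark validation error: duplicate fdi ",
      paste(unique(lm$fdi[duplicated(lm$fdi)]), collapse = ", "),
      call. = FALSE
    )
  }
  occ <- NULL
  if (!is.null(obj$occlusal_landmarks)) {
    ol <- obj$occlusal_landmarks
    occ <- if (is.list(ol)) do.call(rbind, lapply(ol, as.numeric)) else as.matrix(ol)
    if (is.null(dim(occ)) || nrow(occ) != 3 || ncol(occ) != 3 || any(!is.finite(occ))) {
      stop("landmark parse error: 'occlusal_landmarks' must be 3 xyz points", call. = FALSE)
    }
    dimnames(occ) <- NULL
  }
  discs <- NULL
  if (!is.null(obj$discs)) {
    discs <- lapply(obj$discs, function(d) {
      crest_disc(as.numeric(d$origin), as.numeric(d$normal),
        radius = d$radius, fdi = d$fdi
      )
    })
  }
  list(
    patient_id = obj$patient_id, jaw = obj$jaw, setup = obj$setup,
    occlusal_landmarks = occ, landmarks = lm, discs = discs
  )
}

#' Write a cohort to disk
#'
#' One landmark JSON per patient / jaw / condition, a ground-truth manifest
#' CSV, and (for mesh-mode cohorts) binary STL files of the composite teeth
#' and trimmed bone.
#'
#' @param cohort an `os_cohort`.
#' @param dir output directory (created if needed).
#' @return tibble manifest of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  occ <- rbind(
    cohort$occlusal$molar_right, cohort$occlusal$molar_left,
    cohort$occlusal$incisor_contact
  )
  files <- list()
  grp <- cohort$landmarks %>%
    dplyr::group_by(.data$patient, .data$jaw, .data$setup) %>%
    dplyr::group_split()
  for (g in grp) {
    pid <- g$patient[1]
    jaw <- g$jaw[1]
    st <- g$setup[1]
    fn <- file.path(dir, sprintf("%s_%s_%s.json", pid, jaw, st))
    arch <- if (!is.null(cohort$arches)) cohort$arches[[pid]][[st]][[jaw]] else NULL
    write_landmark_json(g, fn,
      patient_id = pid, jaw = jaw, setup = st,
      occlusal_landmarks = occ, discs = if (is.null(arch)) NULL else unname(arch$discs)
    )
    files[[length(files) + 1]] <- tibble::tibble(patient = pid, jaw = jaw, setup = st, file = fn)
    if (!is.null(arch)) {
      bone_fn <- file.path(dir, sprintf("%s_%s_%s_bone.stl", pid, jaw, st))
      write_stl(arch$bone, bone_fn)
      for (key in names(arch$teeth)) {
        write_stl(arch$teeth[[key]], file.path(dir, sprintf(
          "%s_%s_%s_tooth%s.stl", pid, jaw, st, key
        )))
      }
    }
  }
  gt_fn <- file.path(dir, "ground_truth.csv")
  manifest <- cohort$ground_truth_angles %>%
    dplyr::left_join(
      cohort$exposures %>%
        tidyr::pivot_wider(
          id_cols = c("patient", "jaw", "setup", "fdi"),
          names_from = "side", values_from = "combined",
          names_prefix = "true_exposure_"
        ),
      by = c("patient", "jaw", "setup", "fdi")
    )
  utils::write.csv(manifest, gt_fn, row.names = FALSE)
  invisible(dplyr::bind_rows(files))
}
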