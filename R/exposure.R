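# Root-exposure measurement: sample the root surface apical to the alveolar
# crest reference disc, test each sample against the trimmed bone mesh,
# group exposed samples into connected patches, split them into
# dehiscence-type (continuous with the crest) and fenestration-type (isolated
# windows), and measure their lengths per buccal / palatal-lingual side.

#' Alveolar-crest reference disc
#'
#' Planar per-tooth reference marking the root/alveolar-crest junction, from
#' which dehiscence is measured. The normal points apically.
#'
#' @param origin point on the disc plane (mm), normally the cervical center.
#' @param normal apically-oriented normal (normalized internally).
#' @param radius disc radius (mm); informational (serialization/plots only).
#' @param fdi FDI tooth number the disc belongs to.
#' @return object of class `crest_disc`.
#' @export
crest_disc <- function(origin, normal, radius = 3, fdi = NA_integer_) {
  structure(
    list(
      origin = as_point3(origin, "origin"), normal = unit(as_point3(normal, "normal")),
      radius = radius, fdi = as.integer(fdi)
    ),
    class = "crest_disc"
  )
}

# apical signed distance from the disc plane
disc_distance <- function(points, disc) {
  as.numeric(sweep(points, 2, disc$origin) %*% disc$normal)
}

#' Sample and classify exposed root surface points
#'
#' Samples the tooth surface apical to the crest disc at the requested
#' density, labels each sample exposed when it lies outside the watertight
#' bone mesh, and groups exposed samples into connected components (single
#' linkage at one sampling-step radius). Components reaching the disc plane
#' (within one sampling step) are dehiscence-type; isolated components are
#' fenestration-type.
#'
#' @param tooth watertight [mesh3()] of the composite tooth.
#' @param bone watertight [mesh3()] of the trimmed alveolar bone.
#' @param disc the tooth's [crest_disc()].
#' @param sampling_density surface sampling density (points per mm^2); the
#'   sampling step is `1 / sqrt(sampling_density)`.
#' @return a tibble of exposed samples with columns `x`, `y`, `z`, `depth`
#'   (apical distance from the disc plane, mm), `component`, and `type`
#'   (`"dehiscence"` / `"fenestration"`); zero rows when the root is fully
#'   covered. The sampling step is attached as attribute `step`.
#' @export
exposed_root_points <- function(tooth, bone, disc, sampling_density = 25) {
  if (!is_watertight(tooth)) stop("mesh integrity error: tooth mesh is not watertight", call. = FALSE)
  if (!is_watertight(bone)) stop("mesh integrity error: bone mesh is not watertight", call. = FALSE)
  step <- 1 / sqrt(sampling_density)
  # drop faces wholly on the coronal side of the disc before sampling
  dv <- disc_distance(tooth$vertices, disc)
  keep <- rowSums(matrix(dv[tooth$faces] > 0, nrow(tooth$faces))) > 0
  sub <- mesh3(tooth$vertices, tooth$faces[keep, , drop = FALSE])
  smp <- sample_mesh_surface(sub, step)
  d <- disc_distance(smp$points, disc)
  apical <- d > 0
  pts <- smp$points[apical, , drop = FALSE]
  d <- d[apical]
  empty <- tibble::tibble(
    x = numeric(), y = numeric(), z = numeric(), depth = numeric(),
    component = integer(), type = character()
  )
  if (nrow(pts) == 0) {
    return(structure(empty, step = step))
  }
  exposed <- !points_in_mesh(pts, bone)
  pts <- pts[exposed, , drop = FALSE]
  d <- d[exposed]
  if (nrow(pts) == 0) {
    return(structure(empty, step = step))
  }
  comp <- cluster_radius_cpp(pts, step)
  touches <- tapply(d, comp, min) <= step
  out <- tibble::tibble(
    x = pts[, 1], y = pts[, 2], z = pts[, 3], depth = d,
    component = as.integer(comp),
    type = ifelse(touches[as.character(comp)], "dehiscence", "fenestration")
  )
  structure(out, step = step)
}

#' Assign exposed components to the buccal or palatal/lingual side
#'
#' Each sample is lingual when its displacement from the tooth's M-D midpoint
#' has positive dot product with the tooth's lingual reference direction,
#' buccal otherwise; each connected component is assigned the majority side of
#' its samples.
#'
#' @param points tibble from [exposed_root_points()].
#' @param midpoint the tooth's M-D midpoint.
#' @param lingual the tooth's lingual unit vector (see [lingual_reference()]).
#' @return `points` with a `side` column (`"buccal"` / `"lingual"`), assigned
#'   per component.
#' @export
assign_side <- function(points, midpoint, lingual) {
  if (nrow(points) == 0) {
    points$side <- character(0)
    return(points)
  }
  midpoint <- as_point3(midpoint, "midpoint")
  lingual <- unit(as_point3(lingual, "lingual"))
  proj <- as.numeric(sweep(as.matrix(points[c("x", "y", "z")]), 2, midpoint) %*% lingual)
  point_side <- ifelse(proj > 0, "lingual", "buccal")
  maj <- tapply(point_side, points$component, function(s) {
    if (mean(s == "buccal") >= 0.5) "buccal" else "lingual"
  })
  points$side <- as.character(maj[as.character(points$component)])
  points
}

#' Measure dehiscence and fenestration lengths
#'
#' Dehiscence (per side) is the distance from the disc plane to the
#' apical-most exposed point over the disc-contacting components of that
#' side (a point-to-plane Euclidean distance). Fenestration is the extent
#' between the uppermost and lowermost points of each isolated component
#' measured along the disc normal (the difference of their point-to-plane
#' distances), summed over that side's components. Combined = dehiscence +
#' fenestration.
#'
#' @param points side-labeled tibble from [assign_side()].
#' @param disc the tooth's [crest_disc()].
#' @param step sampling step (mm); defaults to the attribute left by
#'   [exposed_root_points()].
#' @return a tibble with one row per side: `side`, `dehiscence`,
#'   `fenestration`, `combined` (mm; zeros where nothing is exposed).
#' @export
measure_exposure <- function(points, disc, step = attr(points, "step")) {
  out <- tibble::tibble(side = c("buccal", "lingual"))
  if (is.null(step)) step <- 0.2
  measure_side <- function(s) {
    p <- points[points$side == s, , drop = FALSE]
    deh <- 0
    fen <- 0
    dh <- p[p$type == "dehiscence", , drop = FALSE]
    if (nrow(dh) > 0) deh <- max(dh$depth)
    fe <- p[p$type == "fenestration", , drop = FALSE]
    if (nrow(fe) > 0) {
      ext <- tapply(fe$depth, fe$component, function(d) max(d) - min(d))
      fen <- sum(ext)
    }
    c(dehiscence = deh, fenestration = fen)
  }
  vals <- vapply(out$side, measure_side, numeric(2))
  out$dehiscence <- unname(vals["dehiscence", ])
  out$fenestration <- unname(vals["fenestration", ])
  out$combined <- out$dehiscence + out$fenestration
  out
}

#' One-call exposure measurement for a tooth
#'
#' Runs [exposed_root_points()], [assign_side()] and [measure_exposure()] for
#' one tooth.
#'
#' @inheritParams exposed_root_points
#' @param midpoint,lingual see [assign_side()].
#' @return tibble with one row per side (see [measure_exposure()]).
#' @export
tooth_exposure <- function(tooth, bone, disc, midpoint, lingual,
                           sampling_density = 25) {
  pts <- exposed_root_points(tooth, bone, disc, sampling_density)
  pts2 <- assign_side(pts, midpoint, lingual)
  attr(pts2, "step") <- attr(pts, "step")
  measure_exposure(pts2, disc)
}

#' Classify a tooth's exposure against the reporting threshold
#'
#' A tooth is categorized by the side whose combined exposure strictly
#' exceeds the threshold (2 mm in the study's frequency table); `"none"` when
#' neither side exceeds it; when both sides exceed it the side with the larger
#' combined value is used (ties go to buccal).
#'
#' @param buccal,lingual combined exposure per side (mm); vectorized.
#' @param threshold reporting threshold (mm), strict inequality.
#' @return character vector: `"buccal"`, `"lingual"`, or `"none"`.
#' @export
classify_exposure <- function(buccal, lingual, threshold = 2) {
  stopifnot(threshold > 0, length(buccal) == length(lingual))
  dplyr::case_when(
    buccal <= threshold & lingual <= threshold ~ "none",
    lingual > threshold & (buccal <= threshold | lingual > buccal) ~ "lingual",
    TRUE ~ "buccal"
  )
}

#' Root-exposure comparison tables
#'
#' Builds the two cohort-level exposure summaries: per tooth type x jaw x
#' side, the mean/SD of combined exposure per setup with the Friedman test
#' and Bonferroni-adjusted Wilcoxon signed-rank post-hocs (each tooth is the
#' repeated-measures subject); and per setup x jaw x tooth type, the counts of
#' teeth whose exposure exceeds the threshold on the buccal / palatal-lingual
#' side (mutually exclusive categories) with the McNemar test on the paired
#' per-side indicators.
#'
#' @param exposures tibble with columns `patient`, `setup`, `fdi`, `side`
#'   (`"buccal"`/`"lingual"`), `combined` (mm).
#' @param setups setups to compare, in post-hoc letter order.
#' @param threshold frequency threshold (mm), strict.
#' @param alpha significance level.
#' @return an object of class `os_exposure` with `$means` (Friedman table) and
#'   `$frequency` (threshold/McNemar table); both are returned by `tidy()`.
#' @export
exposure_tables <- function(exposures, setups = c("crown", "root1", "root2"),
                            threshold = 2, alpha = 0.05) {
  need <- c("patient", "setup", "fdi", "side", "combined")
  stopifnot(all(need %in% names(exposures)))
  df <- exposures %>%
    dplyr::filter(.data$setup %in% setups) %>%
    dplyr::select(-dplyr::any_of(c("jaw", "type"))) %>% # re-derived from fdi
    dplyr::left_join(
      fdi_info(unique(exposures$fdi))[c("fdi", "jaw", "type")],
      by = "fdi"
    ) %>%
    dplyr::mutate(
      type = factor(.data$type, levels = c("incisor", "canine", "premolar", "molar")),
      tooth = paste(.data$patient, .data$fdi, sep = "/")
    )

  wide <- df %>%
    tidyr::pivot_wider(
      id_cols = c("jaw", "type", "side", "tooth"),
      names_from = "setup", values_from = "combined"
    )
  complete <- stats::complete.cases(wide[setups])
  if (any(!complete)) {
    warning(sprintf(
      "excluded %d tooth-side rows with unbalanced setups", sum(!complete)
    ), call. = FALSE)
    wide <- wide[complete, , drop = FALSE]
  }
  mgroups <- split(wide, list(wide$jaw, wide$type, wide$side), drop = TRUE)
  means <- dplyr::bind_rows(lapply(mgroups, function(g) {
    m <- as.matrix(g[setups])
    out <- list(jaw = g$jaw[1], type = g$type[1], side = g$side[1])
    for (s in setups) {
      out[[paste0(s, "_mean")]] <- mean(g[[s]])
      out[[paste0(s, "_sd")]] <- sd(g[[s]])
    }
    if (all(abs(m) < 1e-12) || nrow(m) < 2) {
      extra <- list(n = nrow(m), statistic = NA_real_, p_value = NA_real_, posthoc = "NA")
    } else {
      res <- friedman_wilcoxon(m, alpha = alpha)
      extra <- list(
        n = nrow(m), statistic = as.numeric(res$statistic),
        p_value = res$p_value, posthoc = res$posthoc
      )
    }
    c(out, extra)
  }))
  means <- means[order(means$jaw == "mandible", means$type, means$side), , drop = FALSE]

  fwide <- df %>%
    tidyr::pivot_wider(
      id_cols = c("setup", "jaw", "type", "tooth"),
      names_from = "side", values_from = "combined"
    )
  fgroups <- split(fwide, list(fwide$setup, fwide$jaw, fwide$type), drop = TRUE)
  freq <- dplyr::bind_rows(lapply(fgroups, function(g) {
    cat3 <- classify_exposure(g$buccal, g$lingual, threshold)
    eb <- g$buccal > threshold
    el <- g$lingual > threshold
    b <- sum(eb & !el)
    c_ <- sum(el & !eb)
    mc <- if (b + c_ == 0 && (sum(eb) + sum(el)) == 0) NULL else mcnemar_paired(b, c_)
    list(
      setup = g$setup[1], jaw = g$jaw[1], type = g$type[1],
      n = nrow(g),
      buccal = sum(cat3 == "buccal"),
      lingual = sum(cat3 == "lingual"),
      none = sum(cat3 == "none"),
      discordant_b = b, discordant_c = c_,
      p_value = if (is.null(mc)) NA_real_ else mc$p_value
    )
  }))
  freq$setup <- factor(freq$setup, levels = setups)
  freq <- freq[order(freq$setup, freq$jaw == "mandible", freq$type), , drop = FALSE]

  structure(
    list(
      means = means, frequency = freq, setups = setups,
      threshold = threshold, alpha = alpha
    ),
    class = "os_exposure"
  )
}

#' @export
print.os_exposure <- function(x, ...) {
  cat(sprintf(
    "<os_exposure> combined root exposure, setups: %s; frequency threshold > %g mm\n",
    paste(x$setups, collapse = ", "), x$threshold
  ))
  cat("Mean exposure (Friedman):\n")
  print(as.data.frame(x$means), digits = 3)
  cat("Frequency beyond threshold (McNemar):\n")
  print(as.data.frame(x$frequency), digits = 3)
  invisible(x)
}

#' @export
tidy.os_exposure <- function(x, which = c("means", "frequency"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @export
glance.os_exposure <- function(x, ...) {
  tibble::tibble(
    n_mean_rows = nrow(x$means),
    n_significant_friedman = sum(x$means$p_value < x$alpha, na.rm = TRUE),
    n_frequency_rows = nrow(x$frequency),
    n_significant_mcnemar = sum(x$frequency$p_value < x$alpha, na.rm = TRUE),
    threshold = x$threshold, alpha = x$alpha
  )
}

#' Measure root exposure for a whole generated arch
#'
#' Runs the mesh-based exposure measurement (sampling, containment,
#' component classification, side assignment, length measurement) for every
#' tooth of a mesh-mode arch (see [build_arch()] with `meshes = TRUE`).
#'
#' @param arch a mesh-mode arch: list with `landmarks`, `teeth`, `bone`,
#'   `discs`.
#' @param frame the [occlusal_frame()] used for side assignment.
#' @param sampling_density surface sampling density (points per mm^2).
#' @return tibble: `fdi`, `side`, `dehiscence`, `fenestration`, `combined`
#'   (mm).
#' @export
measure_arch_exposure <- function(arch, frame, sampling_density = 25) {
  stopifnot(!is.null(arch$teeth), !is.null(arch$bone), !is.null(arch$discs))
  lm <- arch$landmarks
  mids <- cbind(
    (lm$M_x + lm$D_x) / 2, (lm$M_y + lm$D_y) / 2, (lm$M_z + lm$D_z) / 2
  )
  out <- vector("list", nrow(lm))
  for (i in seq_len(nrow(lm))) {
    key <- as.character(lm$fdi[i])
    M <- c(lm$M_x[i], lm$M_y[i], lm$M_z[i])
    D <- c(lm$D_x[i], lm$D_y[i], lm$D_z[i])
    lingual <- lingual_reference(mids, M, D, frame)
    res <- tooth_exposure(
      arch$teeth[[key]], arch$bone, arch$discs[[key]],
      midpoint = mids[i, ], lingual = lingual,
      sampling_density = sampling_density
    )
    out[[i]] <- dplyr::bind_cols(tibble::tibble(fdi = lm$fdi[i], .rows = 2), res)
  }
  dplyr::bind_rows(out)
}
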