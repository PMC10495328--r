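#' Build the occlusal reference frame
#'
#' The occlusal plane passes through the distobuccal cusp tips of the two
#' maxillary second molars and the contact point of the maxillary central
#' incisors. Its normal is oriented toward the maxillary root apices
#' ("superior"), resolved by the side of the plane on which the centroid of
#' the maxillary apex points lies.
#'
#' @param molar_right,molar_left distobuccal cusp tips of the maxillary right
#'   and left second molars (length-3 numeric, mm).
#' @param incisor_contact contact point of the maxillary central incisors.
#' @param apex_centroid centroid of the maxillary root apices, used only to
#'   orient the normal.
#' @param tol degeneracy tolerance in mm (triangle area and point-plane
#'   distance below which the construction is rejected).
#' @return an object of class `occlusal_frame`: a list with `origin` (a point
#'   on the plane) and `superior` (unit normal pointing toward the maxillary
#'   apices).
#' @examples
#' occlusal_frame(c(10, 0, 0), c(-10, 0, 0), c(0, 30, 0), c(0, 15, 8))
#' @export
occlusal_frame <- function(molar_right, molar_left, incisor_contact,
                           apex_centroid, tol = 1e-6) {
  p1 <- as_point3(molar_right, "molar_right")
  p2 <- as_point3(molar_left, "molar_left")
  p3 <- as_point3(incisor_contact, "incisor_contact")
  ctr <- as_point3(apex_centroid, "apex_centroid")
  n0 <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n0) / 2 <= tol) {
    stop("degenerate occlusal plane: the three landmarks are (near-)collinear",
      call. = FALSE
    )
  }
  n <- unit(n0)
  d <- sum((ctr - p1) * n)
  if (abs(d) < tol) {
    stop("occlusal plane orientation is ambiguous: apex centroid lies on the plane",
      call. = FALSE
    )
  }
  structure(
    list(origin = (p1 + p2 + p3) / 3, superior = n * sign(d)),
    class = "occlusal_frame"
  )
}

#' @export
print.occlusal_frame <- function(x, ...) {
  cat("<occlusal_frame>\n")
  cat("  origin:  ", sprintf("% .3f", x$origin), "\n")
  cat("  superior:", sprintf("% .6f", x$superior), "\n")
  invisible(x)
}

#' Long axis of a tooth from its landmark triplet
#'
#' The long axis joins the midpoint of the mesial (M) and distal (D) points to
#' the apex point (A; root apex for single-rooted teeth, furcation center for
#' multi-rooted teeth).
#'
#' @param M,D,A tooth landmarks (length-3 numeric, mm).
#' @param tol degeneracy tolerance in mm.
#' @return list with `midpoint` and unit `axis` (pointing from the midpoint
#'   toward A).
#' @export
long_axis <- function(M, D, A, tol = 1e-6) {
  M <- as_point3(M, "M")
  D <- as_point3(D, "D")
  A <- as_point3(A, "A")
  if (vnorm(D - M) <= tol) {
    stop("degenerate landmarks: M and D coincide", call. = FALSE)
  }
  mid <- (M + D) / 2
  v <- A - mid
  if (vnorm(v) <= tol) {
    stop("degenerate landmarks: A coincides with the M-D midpoint", call. = FALSE)
  }
  list(midpoint = mid, axis = unit(v))
}

# shared projection-plane plumbing: unit normal of the per-tooth angulation
# plane (through M and D, perpendicular to the occlusal plane) and the
# in-occlusal-plane distal direction.
tooth_planes <- function(M, D, frame, parallel_tol = 1e-3) {
  dmu <- unit(D - M)
  s <- frame$superior
  n0 <- cross3(dmu, s)
  # |n0| = sin(angle between M->D and superior); reject near-parallel
  if (vnorm(n0) < sin(parallel_tol)) {
    stop("undefined projection plane: the M-D direction is parallel to the occlusal normal",
      call. = FALSE
    )
  }
  n <- unit(n0)
  list(normal = n, distal = unit(cross3(s, n)), superior = s)
}

#' Signed mesiodistal angulation of a tooth
#'
#' The long axis is projected onto the tooth's angulation reference plane (the
#' plane through its M and D points perpendicular to the occlusal plane); the
#' angulation is the angle between that projection and the occlusal normal,
#' positive when the apex point lies distal to the M-D midpoint. The same
#' distal-positive rule (distal = direction from M to D) applies in every
#' quadrant, so values are comparable across sides.
#'
#' @inheritParams long_axis
#' @param frame an [occlusal_frame()].
#' @param parallel_tol parallelism tolerance in radians.
#' @return signed angulation in degrees, in (-90, 90).
#' @export
angulation <- function(M, D, A, frame, tol = 1e-6, parallel_tol = 1e-3) {
  ax <- long_axis(M, D, A, tol = tol)
  pl <- tooth_planes(as_point3(M), as_point3(D), frame, parallel_tol)
  a_d <- sum(ax$axis * pl$distal)
  a_s <- sum(ax$axis * pl$superior)
  if (sqrt(a_d^2 + a_s^2) < 1e-9) {
    stop("degenerate projection: long axis is perpendicular to the angulation plane",
      call. = FALSE
    )
  }
  deg(atan2(a_d, abs(a_s)))
}

#' Signed buccolingual inclination of a tooth
#'
#' The long axis is projected onto the plane through the M-D midpoint
#' perpendicular to both the occlusal plane and the tooth's angulation plane;
#' the inclination is the angle between that projection and the occlusal
#' normal, positive when the apex point lies lingual/palatal to the M-D
#' midpoint.
#'
#' @inheritParams angulation
#' @param lingual unit vector in the occlusal plane pointing lingually at this
#'   tooth (see [lingual_reference()]).
#' @return signed inclination in degrees, in (-90, 90).
#' @export
inclination <- function(M, D, A, frame, lingual, tol = 1e-6, parallel_tol = 1e-3) {
  ax <- long_axis(M, D, A, tol = tol)
  lingual <- as_point3(lingual, "lingual")
  if (abs(sum(lingual * frame$superior)) > 1e-6) {
    stop("lingual reference must lie in the occlusal plane", call. = FALSE)
  }
  pl <- tooth_planes(as_point3(M), as_point3(D), frame, parallel_tol)
  sgn <- sum(pl$normal * lingual)
  if (abs(sgn) < 1e-9) {
    stop("lingual reference is parallel to the M-D direction", call. = FALSE)
  }
  a_n <- sum(ax$axis * pl$normal)
  a_s <- sum(ax$axis * pl$superior)
  if (sqrt(a_n^2 + a_s^2) < 1e-9) {
    stop("degenerate projection: long axis is perpendicular to the inclination plane",
      call. = FALSE
    )
  }
  deg(atan2(a_n * sign(sgn), abs(a_s)))
}

#' Lingual direction at a tooth from the arch layout
#'
#' Operationalizes "lingual" for the inclination sign rule: the unit vector in
#' the occlusal plane, perpendicular to the tooth's M-D direction, pointing
#' from the tooth's M-D midpoint toward the projection of the centroid of all
#' arch midpoints (the arch interior).
#'
#' @param arch_midpoints n x 3 matrix (n >= 3) of M-D midpoints of the arch.
#' @param M,D landmarks of the tooth of interest.
#' @param frame an [occlusal_frame()].
#' @param tol ambiguity tolerance in mm.
#' @return unit length-3 vector.
#' @export
lingual_reference <- function(arch_midpoints, M, D, frame, tol = 1e-6) {
  arch_midpoints <- as.matrix(arch_midpoints)
  if (nrow(arch_midpoints) < 3) {
    stop("need at least 3 arch midpoints to locate the arch interior", call. = FALSE)
  }
  M <- as_point3(M, "M")
  D <- as_point3(D, "D")
  mid <- (M + D) / 2
  ctr <- colMeans(arch_midpoints)
  s <- frame$superior
  w <- (ctr - mid) - sum((ctr - mid) * s) * s # in-plane displacement to centroid
  pl <- tooth_planes(M, D, frame)
  sgn <- sum(pl$normal * w)
  if (vnorm(w) < tol || abs(sgn) < tol) {
    stop("ambiguous lingual direction: tooth midpoint coincides with the arch centroid projection",
      call. = FALSE
    )
  }
  pl$normal * sign(sgn)
}

# Vectorized measurement core: M, D, A are n x 3 matrices, s the superior unit
# normal. Lingual signs are resolved against the arch-midpoint centroid.
# Returns a data.frame with angulation and inclination in degrees.
measure_angles_matrix <- function(M, D, A, s, parallel_tol = 1e-3,
                                  centroid = NULL) {
  mid <- (M + D) / 2
  axv <- A - mid
  axn <- axv / rownorms(axv)
  dm <- D - M
  dmu <- dm / rownorms(dm)
  n0 <- rowcross(dmu, s)
  nn0 <- rownorms(n0)
  if (any(nn0 < sin(parallel_tol))) {
    bad <- which(nn0 < sin(parallel_tol))
    stop(sprintf(
      "undefined projection plane for tooth row(s) %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  n <- n0 / nn0
  d_ip <- -rowcross(n, s) # s x n_i, row-wise
  d_ip <- d_ip / rownorms(d_ip)
  a_d <- rowSums(axn * d_ip)
  a_s <- as.numeric(axn %*% s)
  a_n <- rowSums(axn * n)
  if (is.null(centroid)) {
    w <- -sweep(mid, 2, colMeans(mid)) # midpoint -> arch centroid
  } else {
    w <- centroid - mid
  }
  w <- w - outer(as.numeric(w %*% s), s)
  sgn <- sign(rowSums(n * w))
  data.frame(
    angulation = deg(atan2(a_d, abs(a_s))),
    inclination = deg(atan2(a_n * sgn, abs(a_s)))
  )
}

#' Measure angulation and inclination for a whole setup
#'
#' Computes one signed angulation and inclination per tooth of an arch. When a
#' patient's three setup conditions are measured, the same occlusal frame
#' (built from the bone-aware "root setup-2" model) must be passed for every
#' setup so that angular values are comparable across setups.
#'
#' @param landmarks a data frame with one row per tooth and columns `fdi`,
#'   `M_x`, `M_y`, `M_z`, `D_x`, `D_y`, `D_z`, `A_x`, `A_y`, `A_z`
#'   (coordinates in mm). Extra columns are carried through.
#' @param frame the shared [occlusal_frame()].
#' @param setup_label label recorded for these measurements (one of `"crown"`,
#'   `"root1"`, `"root2"`, `"initial"` in the study design; free-form allowed).
#' @param parallel_tol parallelism tolerance in radians.
#' @return a tibble with columns `fdi`, `setup`, `angulation`, `inclination`
#'   (degrees, distal- and lingual-positive), plus carried-through columns.
#' @export
measure_setup <- function(landmarks, frame, setup_label = "initial",
                          parallel_tol = 1e-3) {
  stopifnot(is.data.frame(landmarks))
  if (nrow(landmarks) == 0) {
    return(tibble::tibble(
      fdi = integer(), setup = character(),
      angulation = numeric(), inclination = numeric()
    ))
  }
  need <- c(t(outer(c("M", "D", "A"), c("x", "y", "z"), paste, sep = "_")))
  miss <- setdiff(c("fdi", need), names(landmarks))
  if (length(miss) > 0) {
    stop("landmark table is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  M <- as.matrix(landmarks[, c("M_x", "M_y", "M_z")])
  D <- as.matrix(landmarks[, c("D_x", "D_y", "D_z")])
  A <- as.matrix(landmarks[, c("A_x", "A_y", "A_z")])
  res <- tryCatch(
    measure_angles_matrix(M, D, A, frame$superior, parallel_tol),
    error = function(e) {
      stop(sprintf(
        "measurement failed (fdi context: %s): %s",
        paste(landmarks$fdi, collapse = ","), conditionMessage(e)
      ), call. = FALSE)
    }
  )
  out <- tibble::tibble(
    fdi = as.integer(landmarks$fdi),
    setup = setup_label,
    angulation = res$angulation,
    inclination = res$inclination
  )
  extra <- setdiff(names(landmarks), c("fdi", need))
  if (length(extra) > 0) out <- dplyr::bind_cols(landmarks[extra], out)
  out
}

#' FDI helper columns
#'
#' Splits FDI two-digit tooth numbers into jaw, side and position-in-quadrant,
#' and assigns the conventional tooth type.
#'
#' @param fdi integer vector of FDI numbers (11-17, 21-27, 31-37, 41-47).
#' @return a tibble with columns `fdi`, `jaw` ("maxilla"/"mandible"), `side`
#'   ("right"/"left"), `position` (1-7) and `type`
#'   ("incisor"/"canine"/"premolar"/"molar").
#' @export
fdi_info <- function(fdi) {
  fdi <- as.integer(fdi)
  q <- fdi %/% 10L
  pos <- fdi %% 10L
  if (any(!q %in% 1:4) || any(!pos %in% 1:7)) {
    stop("FDI numbers must be in 11-17, 21-27, 31-37, 41-47", call. = FALSE)
  }
  tibble::tibble(
    fdi = fdi,
    jaw = ifelse(q %in% c(1L, 2L), "maxilla", "mandible"),
    side = ifelse(q %in% c(1L, 4L), "right", "left"),
    position = pos,
    type = dplyr::case_when(
      pos %in% 1:2 ~ "incisor",
      pos == 3 ~ "canine",
      pos %in% 4:5 ~ "premolar",
      TRUE ~ "molar"
    )
  )
}
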