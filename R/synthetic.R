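# Seeded synthetic cohorts: parametric frustum-crown / cone-root teeth placed
# on a parabolic arch, with landmark triplets, canonical occlusal landmarks,
# per-tooth alveolar bone blocks with designable dehiscence / fenestration
# defects, and three setup conditions with exact ground truth.
#
# The generator's purpose is validation: every measured quantity depends only
# on landmarks and surfaces, so simple solids with analytic ground truth are
# sufficient (and make the oracles exact). It emulates the *structure* of a
# clinical dataset (14 teeth per jaw, three setups plus an initial scan, 16
# patients), not anatomic shape realism.

#' Parametric tooth template
#'
#' Frustum crown plus cone root, in template coordinates: x mesiodistal
#' (toward distal), y buccolingual (toward lingual), z along the tooth axis
#' (toward the apex). The cervical center is the origin; M and D sit at the
#' cervical level so the M-D midpoint is exactly the origin and the template
#' long axis is exactly +z. The apex landmark A is the cone apex for
#' single-rooted teeth or a configured furcation point for multi-rooted ones.
#'
#' @param fdi FDI tooth number.
#' @param crown_height,crown_occlusal_radius,crown_cervical_radius crown
#'   frustum dimensions (mm).
#' @param md_halfwidth half of the mesiodistal crown width (mm); M/D offset.
#' @param root_length,root_radius root cone dimensions (mm).
#' @param multi_root place A at `furcation_fraction * root_length` instead of
#'   the apex (defaults to TRUE for molars).
#' @param furcation_fraction fractional root height of the furcation center.
#' @return object of class `tooth_template`.
#' @export
tooth_template <- function(fdi,
                           crown_height = 8, crown_occlusal_radius = 3.8,
                           crown_cervical_radius = 3, md_halfwidth = 3,
                           root_length = 12, root_radius = 2,
                           multi_root = fdi_info(fdi)$type == "molar",
                           furcation_fraction = 0.35) {
  if (root_length <= 0 || crown_height <= 0 || md_halfwidth <= 0 ||
    root_radius <= 0 || crown_cervical_radius <= 0) {
    stop("degenerate tooth template dimensions", call. = FALSE)
  }
  a_z <- if (multi_root) furcation_fraction * root_length else root_length
  structure(
    list(
      fdi = as.integer(fdi),
      crown_height = crown_height,
      crown_occlusal_radius = crown_occlusal_radius,
      crown_cervical_radius = crown_cervical_radius,
      md_halfwidth = md_halfwidth,
      root_length = root_length,
      root_radius = root_radius,
      multi_root = multi_root,
      M = c(-md_halfwidth, 0, 0),
      D = c(md_halfwidth, 0, 0),
      A = c(0, 0, a_z)
    ),
    class = "tooth_template"
  )
}

template_mesh <- function(tpl, n_seg = 24) {
  revolve_mesh(
    profile_r = c(tpl$crown_occlusal_radius, tpl$crown_cervical_radius, tpl$root_radius, 0),
    profile_z = c(-tpl$crown_height, 0, 0, tpl$root_length),
    n_seg = n_seg
  )
}

#' Pose a tooth template
#'
#' Applies a rigid pose (rotation about the cervical center plus translation)
#' to a template, returning the posed landmarks and, optionally, the posed
#' watertight mesh.
#'
#' @param template a [tooth_template()].
#' @param R 3 x 3 orthogonal pose matrix mapping template axes to world axes.
#' @param origin world position of the cervical center (mm).
#' @param mesh also build the posed triangle mesh.
#' @param n_seg angular resolution of the mesh.
#' @return list with `landmarks` (one-row tibble: fdi, M_x..A_z) and `mesh`
#'   (a [mesh3()] or `NULL`).
#' @export
build_tooth <- function(template, R = diag(3), origin = c(0, 0, 0),
                        mesh = FALSE, n_seg = 24) {
  stopifnot(inherits(template, "tooth_template"))
  origin <- as_point3(origin)
  pose <- function(p) as.numeric(origin + R %*% p)
  M <- pose(template$M)
  D <- pose(template$D)
  A <- pose(template$A)
  lm <- tibble::tibble(
    fdi = template$fdi,
    M_x = M[1], M_y = M[2], M_z = M[3],
    D_x = D[1], D_y = D[2], D_z = D[3],
    A_x = A[1], A_y = A[2], A_z = A[3]
  )
  m <- if (mesh) transform_mesh(template_mesh(template, n_seg), R, origin) else NULL
  list(landmarks = lm, mesh = m)
}

# Mesiodistal crown widths (mm) by position 1..7; loosely anatomic, shared by
# both jaws for layout simplicity.
ARCH_WIDTHS <- c(8.5, 6.8, 7.6, 7.0, 7.0, 10.2, 10.2)
ARCH_GAP <- 0.4

# Parabolic arch y = 40 - x^2 / 40 at z = 0, walked by arc length. Returns
# per-tooth center, distal tangent and lingual (arch-interior) direction.
arch_layout <- function(jaw = c("maxilla", "mandible")) {
  jaw <- match.arg(jaw)
  if (!is.null(.arch_cache[[jaw]])) {
    return(.arch_cache[[jaw]])
  }
  quadrants <- if (jaw == "maxilla") c(right = 1L, left = 2L) else c(right = 4L, left = 3L)
  xg <- seq(0, 45, by = 0.01)
  yg <- 40 - xg^2 / 40
  sg <- c(0, cumsum(sqrt(diff(xg)^2 + diff(yg)^2)))
  halfw <- ARCH_WIDTHS / 2
  centers_s <- cumsum(c(halfw[1], head(halfw, -1) + halfw[-1] + ARCH_GAP))
  rows <- list()
  for (side in names(quadrants)) {
    sgn <- if (side == "right") 1 else -1
    for (p in 1:7) {
      x0 <- sgn * stats::approx(sg, xg, xout = centers_s[p])$y
      y0 <- 40 - x0^2 / 40
      slope <- -x0 / 20
      t2 <- sign(x0) * c(1, slope) / sqrt(1 + slope^2) # away from midline
      l2 <- c(-t2[2], t2[1])
      if (sum(l2 * (c(0, 20) - c(x0, y0))) < 0) l2 <- -l2 # toward arch interior
      rows[[paste(side, p)]] <- tibble::tibble(
        fdi = quadrants[[side]] * 10L + p, side = side, position = p,
        x = x0, y = y0,
        t_x = t2[1], t_y = t2[2], l_x = l2[1], l_y = l2[2]
      )
    }
  }
  .arch_cache[[jaw]] <- dplyr::bind_rows(rows)
  .arch_cache[[jaw]]
}

.arch_cache <- new.env(parent = emptyenv())

# Closed-form posed landmarks for a whole arch (the per-tooth pose reduces to
# a few trigonometric column combinations; see pose_rotation for the matrix
# form used in mesh mode).
arch_landmarks_fast <- function(lay, sigma, designed, crest_z, distalization,
                                root_length = 12, furcation_fraction = 0.35) {
  ord <- match(lay$fdi, designed$fdi)
  alpha <- rad(designed$ang[ord])
  gamma <- rad(designed$inc[ord])
  beta <- atan(tan(gamma) * cos(alpha))
  w <- (ARCH_WIDTHS[lay$position] - 1) / 2
  a_z <- ifelse(lay$position >= 6, furcation_fraction * root_length, root_length)
  t3 <- cbind(lay$t_x, lay$t_y, 0)
  l3 <- cbind(lay$l_x, lay$l_y, 0)
  a3 <- cbind(0, 0, rep(sigma, nrow(lay)))
  shift <- ifelse(lay$position >= 6, distalization, 0)
  C <- cbind(lay$x + shift * lay$t_x, lay$y + shift * lay$t_y, crest_z)
  dvec <- cos(alpha) * t3 - sin(alpha) * a3
  axis <- cos(beta) * (cos(alpha) * a3 + sin(alpha) * t3) + sin(beta) * l3
  M <- C - w * dvec
  D <- C + w * dvec
  A <- C + a_z * axis
  tibble::new_tibble(list(
    fdi = lay$fdi,
    M_x = M[, 1], M_y = M[, 2], M_z = M[, 3],
    D_x = D[, 1], D_y = D[, 2], D_z = D[, 3],
    A_x = A[, 1], A_y = A[, 2], A_z = A[, 3]
  ), nrow = nrow(lay))
}

# canonical occlusal landmarks of the synthetic arch (z = 0 occlusal plane):
# distobuccal cusps of the maxillary second molars and the incisor contact,
# plus the apex-centroid orientation point.
arch_occlusal_landmarks <- function(buccal_offset = 3) {
  lay <- arch_layout("maxilla")
  m7r <- lay[lay$side == "right" & lay$position == 7, ]
  m7l <- lay[lay$side == "left" & lay$position == 7, ]
  list(
    molar_right = c(m7r$x - buccal_offset * m7r$l_x, m7r$y - buccal_offset * m7r$l_y, 0),
    molar_left = c(m7l$x - buccal_offset * m7l$l_x, m7l$y - buccal_offset * m7l$l_y, 0),
    incisor_contact = c(0, 40, 0),
    apex_centroid = c(0, 20, 12)
  )
}

#' Setup scenario definition
#'
#' The noise dispersions and designed root-exposure program of one setup
#' condition of the synthetic study.
#'
#' @param label setup label (`"initial"`, `"crown"`, `"root1"`, `"root2"`).
#' @param ang_sd,inc_sd per-tooth angulation / inclination noise SD (degrees).
#' @param exposure data frame of designed defects with columns `fdi`, `side`
#'   (`"buccal"`/`"lingual"`), `type` (`"dehiscence"`/`"fenestration"`) and
#'   `depth` (mm), or NULL for none.
#' @param distalization posterior shift of the molars along the arch tangent
#'   (mm).
#' @return object of class `setup_scenario`.
#' @export
setup_scenario <- function(label, ang_sd = 2, inc_sd = 2, exposure = NULL,
                           distalization = 0) {
  stopifnot(ang_sd >= 0, inc_sd >= 0, distalization >= 0)
  if (!is.null(exposure)) {
    stopifnot(
      all(c("fdi", "side", "type", "depth") %in% names(exposure)),
      all(exposure$depth >= 0),
      all(exposure$side %in% c("buccal", "lingual")),
      all(exposure$type %in% c("dehiscence", "fenestration"))
    )
  }
  structure(
    list(
      label = label, ang_sd = ang_sd, inc_sd = inc_sd,
      exposure = exposure, distalization = distalization
    ),
    class = "setup_scenario"
  )
}

# solve the pose rotation that realizes designed measured angles exactly:
# inclination pre-rotation about the mesiodistal axis (beta solved so the
# projected inclination equals the target), then angulation rotation about
# the buccolingual axis. Extrinsic composition keeps the M-D segment inside
# the span of the distal and vertical axes, which the measurement's
# projection planes rely on.
pose_rotation <- function(t3, l3, a3, ang_deg, inc_deg) {
  beta <- deg(atan(tan(rad(inc_deg)) * cos(rad(ang_deg))))
  s1 <- sign(sum(cross3(l3, a3) * t3))
  s2 <- sign(sum(cross3(t3, a3) * l3))
  B <- cbind(t3, l3, a3)
  R_inc <- rotation_about(t3, s2 * beta)
  R_ang <- rotation_about(l3, s1 * ang_deg)
  R_ang %*% R_inc %*% B
}

# z-intervals (distance from crest, apical-positive) of remaining bone on one
# side after carving the designed defects; bone_span is the full extent.
carve_side <- function(defects, bone_span, mid_root) {
  ivs <- list(c(0, bone_span))
  cut_out <- function(ivs, lo, hi) {
    out <- list()
    for (iv in ivs) {
      if (hi <= iv[1] || lo >= iv[2]) {
        out <- c(out, list(iv))
      } else {
        if (lo > iv[1]) out <- c(out, list(c(iv[1], lo)))
        if (hi < iv[2]) out <- c(out, list(c(hi, iv[2])))
      }
    }
    out
  }
  if (!is.null(defects) && nrow(defects) > 0) {
    for (i in seq_len(nrow(defects))) {
      d <- defects$depth[i]
      if (d <= 0) next
      if (defects$type[i] == "dehiscence") {
        ivs <- cut_out(ivs, 0, d)
      } else {
        ivs <- cut_out(ivs, mid_root - d / 2, mid_root + d / 2)
      }
    }
  }
  ivs[vapply(ivs, function(iv) iv[2] - iv[1] > 1e-9, logical(1))]
}

# per-tooth alveolar bone: axis-aligned (in the tooth's horizontal frame)
# blocks from the crest apically, with defect intervals removed per side.
bone_blocks_for_tooth <- function(center_xy, t2, l2, crest_z, sigma, defects,
                                  half_t = 4.2, half_l = 5.5, bone_span = 14,
                                  mid_root = 6) {
  Rz <- cbind(c(t2[1], t2[2], 0), c(l2[1], l2[2], 0), c(0, 0, 1))
  meshes <- list()
  for (side in c("buccal", "lingual")) {
    lrange <- if (side == "buccal") c(-half_l, 0) else c(0, half_l)
    defs <- if (is.null(defects)) NULL else defects[defects$side == side, , drop = FALSE]
    for (iv in carve_side(defs, bone_span, mid_root)) {
      z1 <- crest_z + sigma * iv[1]
      z2 <- crest_z + sigma * iv[2]
      b <- box_mesh(
        c(-half_t, lrange[1], min(z1, z2)),
        c(half_t, lrange[2], max(z1, z2))
      )
      meshes <- c(meshes, list(transform_mesh(b, Rz, c(center_xy, 0))))
    }
  }
  meshes
}

merge_meshes <- function(meshes) {
  nv <- 0L
  verts <- list()
  faces <- list()
  for (m in meshes) {
    verts <- c(verts, list(m$vertices))
    faces <- c(faces, list(m$faces + nv))
    nv <- nv + nrow(m$vertices)
  }
  mesh3(do.call(rbind, verts), do.call(rbind, faces))
}

#' Build one synthetic arch for one setup condition
#'
#' Places the 14 teeth of a jaw on the parabolic arch with the designed
#' angulation/inclination per tooth, records exact ground truth, and (in mesh
#' mode) builds posed tooth meshes, crest discs and the carved alveolar bone.
#'
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param scenario a [setup_scenario()]; its noise SDs are used to draw
#'   designed angles unless `designed` is supplied.
#' @param designed optional tibble (fdi, ang, inc) of designed angles in
#'   degrees, overriding the scenario draw.
#' @param meshes build tooth/bone meshes and crest discs (slower).
#' @param seed optional integer seed for the angle draw.
#' @param crown_height,root_length,n_seg template geometry shared by all teeth.
#' @return list with `landmarks` (tibble), `ground_truth` (tibble: fdi, side,
#'   designed angles and per-side designed exposure), and in mesh mode
#'   `teeth` (named list of [mesh3()]), `bone` ([mesh3()]), `discs` (named
#'   list of [crest_disc()]).
#' @export
build_arch <- function(jaw = c("maxilla", "mandible"), scenario = setup_scenario("initial"),
                       designed = NULL, meshes = FALSE, seed = NULL,
                       crown_height = 8, root_length = 12, n_seg = 24) {
  jaw <- match.arg(jaw)
  if (!is.null(seed)) set.seed(seed)
  lay <- arch_layout(jaw)
  sigma <- if (jaw == "maxilla") 1 else -1
  crest_z <- sigma * crown_height
  if (is.null(designed)) {
    designed <- tibble::tibble(
      fdi = lay$fdi,
      ang = rnorm(nrow(lay), 0, scenario$ang_sd),
      inc = rnorm(nrow(lay), 0, scenario$inc_sd)
    )
  }
  prog <- scenario$exposure
  lmk <- arch_landmarks_fast(lay, sigma, designed, crest_z,
    scenario$distalization,
    root_length = root_length
  )
  ord <- match(lay$fdi, designed$fdi)
  n <- nrow(lay)
  side_of <- rep(c("buccal", "lingual"), n)
  fdi_of <- rep(lay$fdi, each = 2)
  prog_len <- function(type) {
    out <- numeric(2 * n)
    if (is.null(prog) || nrow(prog) == 0) {
      return(out)
    }
    sel <- prog$type == type
    if (any(sel)) {
      agg <- rowsum(prog$depth[sel], paste(prog$fdi[sel], prog$side[sel]))
      idx <- match(paste(fdi_of, side_of), rownames(agg))
      out[!is.na(idx)] <- agg[idx[!is.na(idx)], 1]
    }
    out
  }
  gt <- tibble::new_tibble(list(
    fdi = fdi_of,
    ang = rep(designed$ang[ord], each = 2),
    inc = rep(designed$inc[ord], each = 2),
    side = side_of,
    dehiscence = prog_len("dehiscence"),
    fenestration = prog_len("fenestration")
  ), nrow = length(fdi_of))
  gt$combined <- gt$dehiscence + gt$fenestration
  teeth <- list()
  discs <- list()
  bone_parts <- list()
  if (meshes) {
    for (i in seq_len(n)) {
      row <- lay[i, ]
      des <- designed[designed$fdi == row$fdi, ]
      tpl <- tooth_template(row$fdi,
        crown_height = crown_height,
        md_halfwidth = (ARCH_WIDTHS[row$position] - 1) / 2,
        root_length = root_length
      )
      t3 <- c(row$t_x, row$t_y, 0)
      l3 <- c(row$l_x, row$l_y, 0)
      a3 <- c(0, 0, sigma)
      shift <- if (row$position >= 6) scenario$distalization else 0
      center <- c(row$x + shift * row$t_x, row$y + shift * row$t_y, crest_z)
      R <- pose_rotation(t3, l3, a3, des$ang, des$inc)
      bt <- build_tooth(tpl, R, center, mesh = TRUE, n_seg = n_seg)
      key <- as.character(row$fdi)
      teeth[[key]] <- bt$mesh
      discs[[key]] <- crest_disc(center, R %*% c(0, 0, 1), fdi = row$fdi)
      defects <- if (!is.null(prog)) prog[prog$fdi == row$fdi, , drop = FALSE] else NULL
      bone_parts <- c(bone_parts, bone_blocks_for_tooth(
        center[1:2], c(row$t_x, row$t_y), c(row$l_x, row$l_y),
        crest_z, sigma, defects
      ))
    }
  }
  out <- list(
    jaw = jaw, setup = scenario$label,
    landmarks = lmk,
    ground_truth = gt
  )
  if (meshes) {
    out$teeth <- teeth
    out$discs <- discs
    out$bone <- merge_meshes(bone_parts)
  }
  out
}

#' Effect configuration of a synthetic cohort
#'
#' Distributional description of the three setup conditions plus the initial
#' scan: a shared per-tooth anatomic component (`tooth_sd`), per-setup
#' residual dispersions, and a per-setup zero-inflated exposure model
#' (per-tooth probability of a defect, half-normal depth, fenestration share).
#' The defaults mirror the study's qualitative structure: the crown-only
#' setup has larger angulation dispersion and designed posterior exposures,
#' the root setups are more parallel, and the bone-aware root setup-2 has
#' near-zero exposure.
#'
#' @param tooth_sd SD (degrees) of the per-tooth component shared by all
#'   setups of a patient (drives the repeated-measures correlation).
#' @param ang_sd,inc_sd named per-setup residual SDs (degrees).
#' @param exposure_prob named per-setup probability that a tooth-side carries
#'   a defect.
#' @param depth_mean,depth_sd parameters of the half-normal defect depth (mm).
#' @param fenestration_share probability that a defect is a fenestration
#'   rather than a dehiscence.
#' @return object of class `effect_config`.
#' @export
effect_config <- function(tooth_sd = 2.8,
                          ang_sd = c(initial = 3.3, crown = 3.3, root1 = 1.6, root2 = 1.6),
                          inc_sd = c(initial = 3.0, crown = 3.0, root1 = 1.6, root2 = 1.6),
                          exposure_prob = c(crown = 0.25, root1 = 0.22, root2 = 0.01),
                          depth_mean = 2.2, depth_sd = 1.2,
                          fenestration_share = 0.3) {
  stopifnot(
    all(c("initial", "crown", "root1", "root2") %in% names(ang_sd)),
    all(c("crown", "root1", "root2") %in% names(exposure_prob))
  )
  structure(
    list(
      tooth_sd = tooth_sd, ang_sd = ang_sd, inc_sd = inc_sd,
      exposure_prob = exposure_prob, depth_mean = depth_mean,
      depth_sd = depth_sd, fenestration_share = fenestration_share
    ),
    class = "effect_config"
  )
}

#' Null effect configuration
#'
#' All setup conditions share identical distributions (no parallelism effect,
#' identical continuous exposure distributions on both sides), for type-I
#' error calibration of the downstream comparisons.
#'
#' @param depth_mean,depth_sd half-normal exposure magnitude parameters; the
#'   defaults put roughly half the teeth beyond the 2 mm frequency threshold
#'   so the McNemar stage sees informative discordance.
#' @return an [effect_config()].
#' @export
null_effect_config <- function(depth_mean = 2, depth_sd = 1.2) {
  effect_config(
    tooth_sd = 2.8,
    ang_sd = c(initial = 2.5, crown = 2.5, root1 = 2.5, root2 = 2.5),
    inc_sd = c(initial = 2.5, crown = 2.5, root1 = 2.5, root2 = 2.5),
    exposure_prob = c(crown = 1, root1 = 1, root2 = 1),
    depth_mean = depth_mean, depth_sd = depth_sd,
    fenestration_share = 0.3
  )
}

#' Build a synthetic cohort
#'
#' Generates a seeded multi-patient dataset: per patient, an initial scan and
#' three setup conditions for both jaws, with exact per-tooth ground-truth
#' angles and per-side designed exposures. Landmark-level mode (the default)
#' carries landmarks and ground-truth exposures; mesh mode additionally
#' builds tooth/bone meshes and crest discs per patient and setup.
#'
#' @param n_patients number of patients (>= 2).
#' @param effects an [effect_config()].
#' @param seed integer seed; regeneration with the same seed is identical.
#' @param meshes build meshes (slow; intended for small n).
#' @return an object of class `os_cohort`: `landmarks` (tibble over patients,
#'   jaws, setups), `occlusal` (canonical occlusal landmark set), `exposures`
#'   (ground-truth per tooth-side), `ground_truth_angles`, and `arches`
#'   (nested list, only in mesh mode).
#' @export
build_cohort <- function(n_patients = 16, effects = effect_config(), seed = 1,
                         meshes = FALSE,
                         conditions = c("initial", "crown", "root1", "root2")) {
  stopifnot(n_patients >= 2, all(conditions %in% c("initial", "crown", "root1", "root2")))
  set.seed(seed)
  setups <- conditions
  lay_m <- arch_layout("maxilla")
  lay_n <- arch_layout("mandible")
  all_fdi <- c(lay_m$fdi, lay_n$fdi)
  lmk <- list()
  gta <- list()
  expo <- list()
  arches <- if (meshes) list() else NULL
  for (pat in seq_len(n_patients)) {
    pid <- sprintf("P%02d", pat)
    base_ang <- rnorm(length(all_fdi), 0, effects$tooth_sd)
    base_inc <- rnorm(length(all_fdi), 0, effects$tooth_sd)
    names(base_ang) <- names(base_inc) <- as.character(all_fdi)
    if (meshes) arches[[pid]] <- list()
    cand_fdi <- rep(all_fdi, 2)
    cand_side <- rep(c("buccal", "lingual"), each = length(all_fdi))
    jaw_sel <- list(
      maxilla = match(lay_m$fdi, all_fdi),
      mandible = match(lay_n$fdi, all_fdi)
    )
    for (st in setups) {
      ang <- base_ang + rnorm(length(all_fdi), 0, effects$ang_sd[[st]])
      inc <- base_inc + rnorm(length(all_fdi), 0, effects$inc_sd[[st]])
      prog <- NULL
      if (st != "initial") {
        p_def <- effects$exposure_prob[[st]]
        hit <- runif(length(cand_fdi)) < p_def
        depth <- abs(rnorm(length(cand_fdi), effects$depth_mean, effects$depth_sd))
        is_fen <- runif(length(cand_fdi)) < effects$fenestration_share
        prog <- data.frame(
          fdi = cand_fdi[hit], side = cand_side[hit],
          type = ifelse(is_fen[hit], "fenestration", "dehiscence"),
          depth = pmin(depth[hit], 5)
        )
      }
      for (jaw in c("maxilla", "mandible")) {
        jl <- if (jaw == "maxilla") lay_m else lay_n
        sel <- jaw_sel[[jaw]]
        sc <- setup_scenario(st,
          exposure = if (is.null(prog)) NULL else prog[prog$fdi %in% jl$fdi, , drop = FALSE],
          distalization = if (st == "initial") 0 else 2
        )
        arch <- build_arch(jaw, sc,
          designed = data.frame(fdi = all_fdi[sel], ang = ang[sel], inc = inc[sel]),
          meshes = meshes
        )
        nr <- nrow(arch$landmarks)
        lmk[[length(lmk) + 1]] <- tibble::new_tibble(
          c(
            list(
              patient = rep(pid, nr), jaw = rep(jaw, nr), setup = rep(st, nr)
            ),
            as.list(arch$landmarks)
          ),
          nrow = nr
        )
        gt <- arch$ground_truth
        keep <- !duplicated(gt$fdi)
        nk <- sum(keep)
        gta[[length(gta) + 1]] <- tibble::new_tibble(list(
          patient = rep(pid, nk), jaw = rep(jaw, nk), setup = rep(st, nk),
          fdi = gt$fdi[keep], true_ang = gt$ang[keep], true_inc = gt$inc[keep]
        ), nrow = nk)
        if (st != "initial") {
          ng <- nrow(gt)
          expo[[length(expo) + 1]] <- tibble::new_tibble(
            c(
              list(patient = rep(pid, ng), jaw = rep(jaw, ng), setup = rep(st, ng)),
              as.list(gt[c("fdi", "side", "dehiscence", "fenestration", "combined")])
            ),
            nrow = ng
          )
        }
        if (meshes) arches[[pid]][[st]][[jaw]] <- arch
      }
    }
  }
  structure(
    list(
      landmarks = dplyr::bind_rows(lmk),
      occlusal = arch_occlusal_landmarks(),
      exposures = dplyr::bind_rows(expo),
      ground_truth_angles = dplyr::bind_rows(gta),
      arches = arches,
      effects = effects, seed = seed, n_patients = n_patients
    ),
    class = "os_cohort"
  )
}

#' @export
print.os_cohort <- function(x, ...) {
  cat(sprintf(
    "<os_cohort> %d patients x 4 conditions x 2 jaws (seed %s)%s\n",
    x$n_patients, format(x$seed), if (is.null(x$arches)) "" else ", with meshes"
  ))
  invisible(x)
}
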