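# Core geometry: occlusal frame, long axis, signed angulation/inclination.

test_that("occlusal frame from axis-aligned landmarks is the z = 0 plane", {
  f <- occlusal_frame(c(10, 0, 0), c(-10, 0, 0), c(0, 30, 0), c(0, 15, 8))
  expect_equal(f$superior, c(0, 0, 1))
})

test_that("occlusal frame superior direction rotates with the landmarks", {
  set.seed(11)
  for (i in 1:20) {
    R <- random_rotation()
    f <- occlusal_frame(
      R %*% c(10, 0, 0), R %*% c(-10, 0, 0),
      R %*% c(0, 30, 0), R %*% c(0, 15, 8)
    )
    expect_equal(f$superior, as.numeric(R %*% c(0, 0, 1)), tolerance = 1e-9)
  }
})

test_that("degenerate occlusal constructions are rejected", {
  expect_error(
    occlusal_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 5)),
    "degenerate"
  )
  expect_error(
    occlusal_frame(c(10, 0, 0), c(-10, 0, 0), c(0, 30, 0), c(0, 15, 0)),
    "ambiguous"
  )
})

test_that("long axis is the midpoint-to-apex unit direction", {
  ax <- long_axis(c(-3, 0, 0), c(3, 0, 0), c(0, 0, 12))
  expect_equal(ax$midpoint, c(0, 0, 0))
  expect_equal(ax$axis, c(0, 0, 1))
  ax2 <- long_axis(c(0, 0, 0), c(4, 0, 0), c(2, 1, -10))
  expect_equal(ax2$midpoint, c(2, 0, 0))
  expect_equal(ax2$axis, c(0, 1, -10) / sqrt(101))
  expect_error(long_axis(c(-3, 0, 0), c(3, 0, 0), c(0, 0, 0)), "degenerate")
  expect_error(long_axis(c(1, 1, 1), c(1, 1, 1), c(0, 0, 5)), "degenerate")
})

test_that("angulation reproduces designed rotations with the distal-positive sign", {
  f <- make_frame_z()
  M <- c(-3, 0, 0)
  D <- c(3, 0, 0)
  expect_equal(angulation(M, D, c(0, 0, 12), f), 0)
  A10 <- c(12 * sin(pi / 18), 0, 12 * cos(pi / 18))
  expect_equal(angulation(M, D, A10, f), 10, tolerance = 1e-9)
  expect_equal(angulation(M, D, c(-A10[1], 0, A10[3]), f), -10, tolerance = 1e-9)
  # apex displaced off the angulation plane: matches the explicit projection
  A_off <- c(12 * sin(pi / 18), 2, 12 * cos(pi / 18))
  o <- oracle_angles(M, D, A_off, f$superior, c(0, 1, 0))
  expect_equal(angulation(M, D, A_off, f), unname(o["angulation"]), tolerance = 1e-9)
})

test_that("inclination reproduces designed rotations with the lingual-positive sign", {
  f <- make_frame_z()
  M <- c(-3, 0, 0)
  D <- c(3, 0, 0)
  lingual <- c(0, 1, 0)
  expect_equal(inclination(M, D, c(0, 0, 12), f, lingual), 0)
  A7 <- c(0, 12 * sin(rad <- 7 * pi / 180), 12 * cos(rad))
  expect_equal(inclination(M, D, A7, f, lingual), 7, tolerance = 1e-9)
  expect_equal(inclination(M, D, c(0, -A7[2], A7[3]), f, lingual), -7, tolerance = 1e-9)
})

test_that("angles match the brute-force projection oracle on random configurations", {
  f <- make_frame_z()
  set.seed(42)
  n_bad <- 0
  for (i in 1:1000) {
    th_ang <- runif(1, -45, 45)
    th_inc <- runif(1, -45, 45)
    # arbitrary horizontal tooth orientation and position
    phi <- runif(1, 0, 2 * pi)
    t3 <- c(cos(phi), sin(phi), 0)
    l3 <- c(-sin(phi), cos(phi), 0)
    C <- c(runif(1, -30, 30), runif(1, -10, 40), runif(1, -5, 5))
    R1 <- rotation_about(t3, th_inc)
    R2 <- rotation_about(l3, th_ang)
    R <- R2 %*% R1
    M <- C + R %*% (-3 * t3)
    D <- C + R %*% (3 * t3)
    A <- C + R %*% (12 * c(0, 0, 1))
    o <- oracle_angles(M, D, A, f$superior, l3)
    a <- angulation(M, D, A, f)
    b <- inclination(M, D, A, f, l3)
    if (abs(a - o["angulation"]) > 1e-9 || abs(b - o["inclination"]) > 1e-9) {
      n_bad <- n_bad + 1
    }
  }
  expect_equal(n_bad, 0)
})

test_that("angles are invariant under a common rigid motion", {
  set.seed(7)
  lay <- orthosetup:::arch_layout("maxilla")
  des <- tibble::tibble(fdi = lay$fdi, ang = runif(14, -10, 10), inc = runif(14, -8, 8))
  arch <- build_arch("maxilla", setup_scenario("crown"), designed = des)
  occ <- orthosetup:::arch_occlusal_landmarks()
  f0 <- occlusal_frame(occ$molar_right, occ$molar_left, occ$incisor_contact, occ$apex_centroid)
  m0 <- measure_setup(arch$landmarks, f0, "crown")
  for (i in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, 0, 20)
    lm <- arch$landmarks
    for (p in c("M", "D", "A")) {
      xyz <- as.matrix(lm[paste0(p, "_", c("x", "y", "z"))]) %*% t(R)
      xyz <- sweep(xyz, 2, t, "+")
      lm[paste0(p, "_", c("x", "y", "z"))] <- xyz
    }
    fr <- occlusal_frame(
      R %*% occ$molar_right + t, R %*% occ$molar_left + t,
      R %*% occ$incisor_contact + t, R %*% occ$apex_centroid + t
    )
    m1 <- measure_setup(lm, fr, "crown")
    expect_equal(m1$angulation, m0$angulation, tolerance = 1e-9)
    expect_equal(m1$inclination, m0$inclination, tolerance = 1e-9)
  }
})

test_that("midsagittal reflection preserves angulation values", {
  set.seed(8)
  lay <- orthosetup:::arch_layout("maxilla")
  des <- tibble::tibble(fdi = lay$fdi, ang = runif(14, -10, 10), inc = runif(14, -8, 8))
  arch <- build_arch("maxilla", setup_scenario("crown"), designed = des)
  occ <- orthosetup:::arch_occlusal_landmarks()
  f <- occlusal_frame(occ$molar_right, occ$molar_left, occ$incisor_contact, occ$apex_centroid)
  m0 <- measure_setup(arch$landmarks, f, "crown")
  lm <- arch$landmarks
  for (p in c("M", "D", "A")) lm[[paste0(p, "_x")]] <- -lm[[paste0(p, "_x")]]
  fr <- occlusal_frame(
    occ$molar_right * c(-1, 1, 1), occ$molar_left * c(-1, 1, 1),
    occ$incisor_contact * c(-1, 1, 1), occ$apex_centroid * c(-1, 1, 1)
  )
  m1 <- measure_setup(lm, fr, "crown")
  # a reflected right tooth occupies the mirrored (left) position but keeps
  # its landmark labels, so its angulation value is unchanged
  expect_equal(m1$angulation, m0$angulation, tolerance = 1e-9)
  expect_equal(m1$inclination, m0$inclination, tolerance = 1e-9)
})

test_that("degenerate projections raise errors", {
  f <- make_frame_z()
  # M-D direction parallel to the occlusal normal
  expect_error(
    angulation(c(0, 0, -3), c(0, 0, 3), c(5, 0, 0), f),
    "projection plane"
  )
  expect_error(
    measure_setup(
      tibble::tibble(
        fdi = 11, M_x = 0, M_y = 0, M_z = -3, D_x = 0, D_y = 0, D_z = 3,
        A_x = 5, A_y = 0, A_z = 0
      ),
      f
    ),
    "fdi"
  )
})

test_that("lingual reference points toward the arch interior and mirrors correctly", {
  f <- make_frame_z()
  lay <- orthosetup:::arch_layout("maxilla")
  arch <- build_arch("maxilla", setup_scenario("initial", 0, 0))
  lm <- arch$landmarks
  mids <- cbind((lm$M_x + lm$D_x) / 2, (lm$M_y + lm$D_y) / 2, (lm$M_z + lm$D_z) / 2)
  ctr <- colMeans(mids)
  for (i in seq_len(nrow(lm))) {
    lv <- lingual_reference(
      mids, c(lm$M_x[i], lm$M_y[i], lm$M_z[i]),
      c(lm$D_x[i], lm$D_y[i], lm$D_z[i]), f
    )
    expect_gt(sum(lv * (ctr - mids[i, ])), 0)
    # mirrored arch gives the mirrored lingual vector
    lv_m <- lingual_reference(
      mids %*% diag(c(-1, 1, 1)),
      c(-lm$M_x[i], lm$M_y[i], lm$M_z[i]),
      c(-lm$D_x[i], lm$D_y[i], lm$D_z[i]), f
    )
    expect_equal(lv_m, lv * c(-1, 1, 1), tolerance = 1e-9)
  }
  expect_error(
    lingual_reference(rbind(c(0, 0, 0), c(0, 0, 0)), c(-1, 0, 0), c(1, 0, 0), f),
    "at least 3"
  )
  expect_error(
    lingual_reference(rbind(c(0, 2, 0), c(0, -2, 0), c(0, 0, 0)),
      c(-1, 0, 0), c(1, 0, 0), f,
      tol = 1e-6
    ),
    "ambiguous"
  )
})

test_that("measure_setup returns empty output for an empty landmark table", {
  f <- make_frame_z()
  out <- measure_setup(tibble::tibble(), f)
  expect_equal(nrow(out), 0)
})

test_that("fdi_info classifies quadrants, sides and tooth types", {
  info <- fdi_info(c(11, 23, 35, 47))
  expect_equal(info$jaw, c("maxilla", "maxilla", "mandible", "mandible"))
  expect_equal(info$side, c("right", "left", "left", "right"))
  expect_equal(info$type, c("incisor", "canine", "premolar", "molar"))
  expect_error(fdi_info(18), "FDI")
})
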