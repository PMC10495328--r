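# Root-exposure measurement on analytic cone fixtures, side assignment,
# threshold classification, and the cohort-level tables.

test_that("a fully covered root yields no exposed points", {
  fx <- single_tooth_fixture()
  pts <- exposed_root_points(fx$tooth, fx$bone, fx$disc)
  expect_equal(nrow(pts), 0)
  res <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual)
  expect_equal(res$combined, c(0, 0))
})

test_that("designed dehiscence depths are recovered within the sampling step", {
  for (depth in c(0.5, 1, 2, 3, 5)) {
    fx <- single_tooth_fixture(data.frame(
      fdi = 11, side = "buccal", type = "dehiscence", depth = depth
    ))
    res <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual)
    step <- 1 / sqrt(25)
    got <- res$dehiscence[res$side == "buccal"]
    expect_equal(got, depth, tolerance = max(0.05, step) / depth)
    expect_equal(res$combined[res$side == "lingual"], 0)
    expect_equal(res$combined, res$dehiscence + res$fenestration)
  }
})

test_that("designed fenestration windows are recovered within the sampling step", {
  for (depth in c(1, 2, 3)) {
    fx <- single_tooth_fixture(data.frame(
      fdi = 11, side = "lingual", type = "fenestration", depth = depth
    ))
    pts <- exposed_root_points(fx$tooth, fx$bone, fx$disc)
    expect_true(all(pts$type == "fenestration")) # no disc contact
    res <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual)
    got <- res$fenestration[res$side == "lingual"]
    expect_equal(got, depth, tolerance = max(0.05, 0.2) / depth)
    expect_equal(res$dehiscence[res$side == "lingual"], 0)
    expect_equal(res$combined[res$side == "buccal"], 0)
  }
})

test_that("bone removed entirely on one side gives a single dehiscence component", {
  fx <- single_tooth_fixture(data.frame(
    fdi = 11, side = "buccal", type = "dehiscence", depth = 14
  ))
  pts <- exposed_root_points(fx$tooth, fx$bone, fx$disc)
  expect_gt(nrow(pts), 0)
  expect_true(all(pts$type == "dehiscence"))
  expect_equal(length(unique(pts$component)), 1)
})

test_that("measured lengths converge under sampling-density doubling", {
  fx <- single_tooth_fixture(data.frame(
    fdi = 11, side = c("buccal", "lingual"),
    type = c("dehiscence", "fenestration"), depth = c(3, 2)
  ))
  r25 <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual, 25)
  r50 <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual, 50)
  expect_true(all(abs(r50$combined - r25$combined) < 1 / sqrt(25)))
})

test_that("exposure measurement is rigid-motion invariant", {
  fx <- single_tooth_fixture(data.frame(
    fdi = 11, side = c("buccal", "lingual"),
    type = c("dehiscence", "fenestration"), depth = c(2.5, 1.5)
  ))
  r0 <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual)
  set.seed(31)
  R <- random_rotation()
  t <- c(5, -7, 11)
  tooth2 <- transform_mesh(fx$tooth, R, t)
  bone2 <- transform_mesh(fx$bone, R, t)
  disc2 <- crest_disc(R %*% fx$disc$origin + t, R %*% fx$disc$normal, fdi = 11)
  r1 <- tooth_exposure(
    tooth2, bone2, disc2,
    as.numeric(R %*% fx$midpoint + t), as.numeric(R %*% fx$lingual)
  )
  expect_equal(r1$dehiscence, r0$dehiscence, tolerance = 1e-9)
  expect_equal(r1$fenestration, r0$fenestration, tolerance = 1e-9)
})

test_that("deepening a dehiscence never decreases the measured value", {
  depths <- c(0.5, 1.5, 2.5, 4, 6, 9)
  got <- vapply(depths, function(d) {
    fx <- single_tooth_fixture(data.frame(
      fdi = 11, side = "buccal", type = "dehiscence", depth = d
    ))
    res <- tooth_exposure(fx$tooth, fx$bone, fx$disc, fx$midpoint, fx$lingual)
    res$dehiscence[res$side == "buccal"]
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
  # bounded by the apical-most surface point's distance from the disc
  expect_true(all(got <= 12 + 1e-9))
})

test_that("side assignment follows the lingual dot product and majority rule", {
  pts <- tibble::tibble(
    x = c(0, 0, 0.1), y = c(-2, 2, 2), z = c(5, 5, 6),
    depth = c(5, 5, 6), component = c(1L, 2L, 2L), type = "fenestration"
  )
  lab <- assign_side(pts, c(0, 0, 0), c(0, 1, 0))
  expect_equal(lab$side, c("buccal", "lingual", "lingual"))
  # straddling component goes to the majority side (60% buccal)
  pts2 <- tibble::tibble(
    x = 0, y = c(-1, -1, -1, 1, 1), z = 1:5, depth = 1:5,
    component = 1L, type = "dehiscence"
  )
  lab2 <- assign_side(pts2, c(0, 0, 0), c(0, 1, 0))
  expect_true(all(lab2$side == "buccal"))
})

test_that("threshold classification is strict and resolves two-sided exposure", {
  expect_equal(classify_exposure(2.0, 0), "none")
  expect_equal(classify_exposure(2.01, 0), "buccal")
  expect_equal(classify_exposure(0, 2.01), "lingual")
  expect_equal(classify_exposure(2.5, 3.1), "lingual")
  expect_equal(classify_exposure(3.1, 2.5), "buccal")
  expect_equal(classify_exposure(2.4, 2.4), "buccal") # tie -> buccal
  expect_equal(
    classify_exposure(c(0, 5), c(0, 0)), c("none", "buccal")
  )
})

test_that("exposure tables have conserved counts and sensible statistics", {
  set.seed(33)
  co <- build_cohort(6, effect_config(), seed = 33)
  tab <- exposure_tables(co$exposures)
  freq <- tab$frequency
  expect_true(all(freq$buccal + freq$lingual + freq$none == freq$n))
  types <- c(incisor = 4L, canine = 2L, premolar = 4L, molar = 4L)
  expect_equal(
    freq$n,
    unname(types[as.character(freq$type)]) * 6L
  )
  expect_true(all(tab$means$p_value >= 0 & tab$means$p_value <= 1, na.rm = TRUE))
  # all-zero cohort: everything "none", statistics NA
  co0 <- build_cohort(4, effect_config(
    exposure_prob = c(crown = 0, root1 = 0, root2 = 0)
  ), seed = 1)
  tab0 <- exposure_tables(co0$exposures)
  expect_true(all(tab0$frequency$none == tab0$frequency$n))
  expect_true(all(is.na(tab0$means$p_value)))
  expect_true(all(is.na(tab0$frequency$p_value)))
})

test_that("designed crown-setup exposure produces the a > c, b > c post-hoc pattern", {
  set.seed(34)
  co <- build_cohort(16, effect_config(
    exposure_prob = c(crown = 0.5, root1 = 0.45, root2 = 0)
  ), seed = 34)
  tab <- exposure_tables(co$exposures)
  sig <- tab$means[!is.na(tab$means$p_value) & tab$means$p_value < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_true(any(grepl("a > c", sig$posthoc) & grepl("b > c", sig$posthoc)))
})

test_that("mesh-measured arch exposure matches the generator's ground truth", {
  prog <- data.frame(
    fdi = c(16, 24, 11), side = c("buccal", "lingual", "lingual"),
    type = c("dehiscence", "fenestration", "dehiscence"), depth = c(3, 2, 1.5)
  )
  arch <- build_arch("maxilla", setup_scenario("crown", 0, 0, exposure = prog),
    meshes = TRUE
  )
  occ <- orthosetup:::arch_occlusal_landmarks()
  fr <- occlusal_frame(
    occ$molar_right, occ$molar_left, occ$incisor_contact, occ$apex_centroid
  )
  ex <- measure_arch_exposure(arch, fr)
  gt <- arch$ground_truth
  j <- merge(ex, gt[c("fdi", "side", "combined")], by = c("fdi", "side"))
  expect_true(all(abs(j$combined.x - j$combined.y) <= 0.2 + 1e-9))
})
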