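test_that("fixtures are bit-identical under a fixed seed", {
  a <- generate_mannequin(mannequin_spec("sagittal", 25, seed = 33,
                                         keypoint_jitter_sigma = 2, noise_sigma = 5,
                                         image_width = 120, image_height = 170))
  b <- generate_mannequin(mannequin_spec("sagittal", 25, seed = 33,
                                         keypoint_jitter_sigma = 2, noise_sigma = 5,
                                         image_width = 120, image_height = 170))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$keypoints_jittered$coords, b$keypoints_jittered$coords)
  # different seed moves the noise
  c_ <- generate_mannequin(mannequin_spec("sagittal", 25, seed = 34,
                                          keypoint_jitter_sigma = 2, noise_sigma = 5,
                                          image_width = 120, image_height = 170))
  expect_false(identical(a$image, c_$image))
})

test_that("zero trunk angle gives collinear landmarks and zero truth angles", {
  fr <- build_skeleton(mannequin_spec("frontal", 0, seed = 1))
  xs <- vapply(fr$landmarks_true[c("C7", "L5", "MA")], `[`, numeric(1), 1)
  expect_lt(max(xs) - min(xs), 1e-9)
  expect_equal(unname(fr$true_angles["PS"]), 0, tolerance = 1e-9)

  sg <- build_skeleton(mannequin_spec("sagittal", 0, seed = 1))
  expect_equal(unname(sg$true_angles["tCC"]), 0, tolerance = 1e-9)
})

test_that("sagittal flexion angle is the stored thoracic truth by construction", {
  for (ang in c(10, 40, 65)) {
    sg <- build_skeleton(mannequin_spec("sagittal", ang, seed = 2))
    expect_equal(unname(sg$true_angles["tCC"]), ang, tolerance = 1e-9)
  }
  for (ang in c(5, 15, 30)) {
    fr <- build_skeleton(mannequin_spec("frontal", ang, seed = 2))
    expect_equal(unname(fr$true_angles["PS"]), ang, tolerance = 1e-9)
  }
})

test_that("stored true angles are recomputable from the true landmarks", {
  sg <- build_skeleton(mannequin_spec("sagittal", 35, seed = 3))
  lt <- sg$landmarks_true
  expect_equal(external_angle(lt$FC, lt$L5, lt$C7),
               unname(sg$true_angles["tCC"]), tolerance = 1e-9)
  expect_equal(external_angle(lt$L5, lt$MA, lt$C7),
               unname(sg$true_angles["lCC"]), tolerance = 1e-9)
  fr <- build_skeleton(mannequin_spec("frontal", 18, seed = 3))
  lf <- fr$landmarks_true
  expect_equal(external_angle(lf$L5, lf$MA, lf$C7),
               unname(fr$true_angles["PS"]), tolerance = 1e-9)
})

test_that("noise-free renders have exactly two colors and the mask matches", {
  fx <- generate_mannequin(mannequin_spec("sagittal", 20, seed = 4,
                                          image_width = 120, image_height = 170))
  vals <- unique(as.vector(fx$image[, , 1]))
  expect_length(vals, 2)
  expect_identical(fx$image[, , 1] == mannequin_spec("sagittal")$subject_rgb[1],
                   fx$mask)
})

test_that("the rendered subject lies inside the keypoint subject box", {
  set.seed(44)
  for (i in 1:10) {
    view <- sample(c("frontal", "sagittal"), 1)
    fx <- generate_mannequin(mannequin_spec(view, runif(1, 0, 50),
                                            seed = 400 + i,
                                            image_width = 140, image_height = 200))
    box <- subject_box(fx$keypoints)
    w <- which(fx$mask, arr.ind = TRUE)
    xs <- w[, 2] - 1; ys <- w[, 1] - 1
    # allow a 2 px sliver at the box edge from rasterization
    expect_gte(min(xs), floor(box$x0) - 2)
    expect_lte(max(xs), ceiling(box$x1) + 2)
    expect_gte(min(ys), floor(box$y0) - 2)
    expect_lte(max(ys), ceiling(box$y1) + 2)
  }
})

test_that("zero-contrast fixtures are generated for failure-path testing", {
  fx <- generate_mannequin(mannequin_spec("sagittal", 20, seed = 5,
                                          subject_rgb = c(100, 100, 100),
                                          background_rgb = c(100, 100, 100),
                                          image_width = 120, image_height = 170))
  expect_length(unique(as.vector(fx$image)), 1)
  expect_gt(sum(fx$mask), 0)     # truth mask still well-defined
})

test_that("battery writes a full-factorial fixture tree with a reusable manifest", {
  out <- withr::local_tempdir()
  design <- list(view = "sagittal", image_height = c(150, 180, 210),
                 contrast = c(80, 160), angle = c(10, 30, 50),
                 n_per_cell = 2, seed = 99)
  man <- synth_battery(design, out)
  expect_equal(nrow(man), 3 * 2 * 3 * 2)
  expect_true(all(file.exists(man$image)))
  expect_true(all(file.exists(man$keypoints)))
  expect_true(all(file.exists(man$mask)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(all(is.na(man$truth_PS)))
  expect_true(all(is.finite(man$truth_tCC)))

  # same seed: identical manifest (paths aside) and identical truth
  out2 <- withr::local_tempdir()
  man2 <- synth_battery(design, out2)
  expect_equal(man$truth_tCC, man2$truth_tCC)
  expect_equal(man$bmi, man2$bmi)

  expect_error(synth_battery(list(), out), class = "format_error")
})

test_that("mannequin specs validate their ranges", {
  expect_error(mannequin_spec("sagittal", trunk_angle_deg = 90),
               class = "format_error")
  expect_error(mannequin_spec("sagittal", fulcrum_height_frac = 0),
               class = "format_error")
  expect_error(mannequin_spec("sagittal", subject_rgb = c(300, 0, 0)),
               class = "format_error")
})
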