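# The scene generator's analytic ground truth, checked against independent
# per-pixel brute-force oracles and its stated invariants.

# brute-force oracle: loop over every pixel, find the tallest blob there,
# and integrate mass/nutrients per class
oracle_nutrition <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  tab <- spec$table
  out <- c(calories = 0, mass = 0, fat = 0, carb = 0, protein = 0)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    best_h <- 0; best_ci <- 0L
    for (b in spec$blobs) {
      ct <- cos(b$rotation); st <- sin(b$rotation)
      dx <- cc - b$center[2]; dy <- r - b$center[1]
      u <- (dx * ct + dy * st) / b$axes[1]
      v <- (-dx * st + dy * ct) / b$axes[2]
      r2 <- u^2 + v^2
      if (r2 > 1) next
      h <- if (b$profile == "cap") b$height * (1 - r2) else b$height
      if (h > best_h) {
        best_h <- h
        best_ci <- match(b$class_id, tab$class_id)
      }
    }
    if (best_ci > 0L) {
      m <- best_h * spec$pixel_area * tab$density[best_ci]
      out["mass"] <- out["mass"] + m
      out["calories"] <- out["calories"] + m * tab$kcal_per_g[best_ci]
      out["fat"] <- out["fat"] + m * tab$fat_frac[best_ci]
      out["carb"] <- out["carb"] + m * tab$carb_frac[best_ci]
      out["protein"] <- out["protein"] + m * tab$protein_frac[best_ci]
    }
  }
  out
}

test_that("empty scene has a zero label and plate-only depth", {
  spec <- scene_spec(image_size = c(32, 32), blobs = list(),
                     noise = scene_noise(FALSE))
  s <- render_dish(spec)
  expect_equal(unname(s$label), rep(0, 5))
  expect_equal(s$depth, spec$camera_height - nv$plate_profile(spec),
               tolerance = 1e-12)
})

test_that("a cylindrical blob of unit height and density integrates to its pixel area", {
  tab <- ingredient_table()
  tab$density[1] <- 1
  spec <- scene_spec(image_size = c(40, 40), pixel_area = 1,
                     blobs = list(ingredient_blob(tab$class_id[1],
                                                  center = c(20, 20),
                                                  axes = c(6, 6), height = 1,
                                                  profile = "cylinder")),
                     noise = scene_noise(FALSE), table = tab)
  label <- ground_truth_nutrition(spec)
  ff <- nv$food_field(spec)
  A <- sum(ff$height > 0)          # pixels inside the footprint
  expect_equal(unname(label["mass"]), A * 1 * 1, tolerance = 1e-12)
  expect_equal(unname(label["calories"]), A * tab$kcal_per_g[1], tolerance = 1e-12)
})

test_that("labels are additive over disjoint blobs to machine precision", {
  tab <- ingredient_table()
  b1 <- ingredient_blob("rice", center = c(10, 10), axes = c(4, 3), height = 2)
  b2 <- ingredient_blob("beef", center = c(24, 24), axes = c(5, 4), height = 1.5,
                        rotation = 0.7)
  mk <- function(blobs) scene_spec(image_size = c(36, 36), blobs = blobs,
                                   noise = scene_noise(FALSE), table = tab)
  l12 <- ground_truth_nutrition(mk(list(b1, b2)))
  l1 <- ground_truth_nutrition(mk(list(b1)))
  l2 <- ground_truth_nutrition(mk(list(b2)))
  expect_equal(l12, l1 + l2, tolerance = 1e-14)
})

test_that("doubling every blob height doubles mass and every macro", {
  base <- tiny_scene(seed = 7, n_blobs = 3)
  doubled <- base
  doubled$blobs <- lapply(base$blobs, function(b) { b$height <- 2 * b$height; b })
  expect_equal(ground_truth_nutrition(doubled), 2 * ground_truth_nutrition(base),
               tolerance = 1e-12)
})

test_that("rendered labels match the per-pixel brute-force oracle exactly", {
  for (seed in c(3, 8, 15)) {
    spec <- random_scene(image_size = c(28, 28), seed = seed, n_blobs = 3,
                         overlap = TRUE, noise = scene_noise(FALSE))
    s <- render_dish(spec)
    expect_equal(s$label, oracle_nutrition(spec), tolerance = 1e-12)
  }
})

test_that("depth equals camera height minus the analytic height field without noise", {
  spec <- tiny_scene(seed = 5, n_blobs = 2)
  s <- render_dish(spec)
  surf <- nv$plate_profile(spec) + nv$food_field(spec)$height
  expect_equal(s$depth, spec$camera_height - surf, tolerance = 1e-12)
  expect_true(all(s$depth > 0 & s$depth <= spec$camera_height))
  expect_true(all(s$rgb >= 0 & s$rgb <= 1))
})

test_that("rendering is deterministic given the seed, including noise", {
  spec <- random_scene(image_size = c(24, 24), seed = 42,
                       noise = scene_noise(TRUE))
  a <- render_dish(spec)
  b <- render_dish(spec)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$depth, b$depth)
})

test_that("scene validation rejects invariant violations", {
  expect_error(scene_spec(image_size = c(32, 32), camera_height = 1,
                          blobs = list(ingredient_blob("rice", c(16, 16),
                                                       c(4, 4), height = 3))),
               "camera_height")
  expect_error(scene_spec(image_size = c(32, 32),
                          blobs = list(ingredient_blob("plutonium", c(16, 16),
                                                       c(4, 4), height = 1))),
               "unknown ingredient")
  expect_error(scene_spec(image_size = c(32, 32),
                          blobs = list(ingredient_blob("rice", c(99, 16),
                                                       c(4, 4), height = 1))),
               "bounds")
  expect_error(ingredient_blob("rice", c(1, 1), c(2, 2), height = -1), "height")
})

test_that("make_dataset splits 5:1, errors on n = 0, and is byte-deterministic", {
  expect_error(make_dataset(0), "n must be")
  d1 <- file.path(tempdir(), "nv_ds_a")
  d2 <- file.path(tempdir(), "nv_ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  ds1 <- make_dataset(6, out_dir = d1, image_size = c(24, 24), seed = 9,
                      noise = scene_noise(FALSE))
  ds2 <- make_dataset(6, out_dir = d2, image_size = c(24, 24), seed = 9,
                      noise = scene_noise(FALSE))
  expect_equal(sum(ds1$split == "train"), 5)
  expect_equal(sum(ds1$split == "test"), 1)
  expect_identical(readLines(file.path(d1, "metadata.csv")),
                   readLines(file.path(d2, "metadata.csv")))
  # different seed changes the content
  ds3 <- make_dataset(6, image_size = c(24, 24), seed = 10,
                      noise = scene_noise(FALSE))
  expect_false(identical(ds1$samples[[1]]$label, ds3$samples[[1]]$label))
})
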