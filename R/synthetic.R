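# Parametric synthetic dish scenes with analytically exact depth and
# nutrition ground truth.
#
# A scene is a plate on a table seen by an overhead camera at a known
# height (cm). Ingredients are elliptical blobs with a parametric height
# profile h(x, y) in cm; each blob carries an ingredient class that maps to
# a density (g/cm^3), an energy density (kCal/g) and macronutrient mass
# fractions. Nutrition ground truth is the exact per-pixel volume integral:
#   mass_c   = sum_{pixels of class c} h * pixel_area * density_c
#   calories = sum_c mass_c * kcal_per_g_c   (macros via mass fractions)
# The depth map is camera_height - surface_height, optionally plus sensor
# noise, so closer surfaces have smaller values, in centimeters.

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default ingredient nutrition/density table
#'
#' One row per ingredient class: density (g/cm^3 as plated), energy density
#' (kCal/g), macronutrient mass fractions (g per g of ingredient) and an RGB
#' albedo used by the renderer. Values are realistic for cooked foods; this
#' synthetic table stands in for per-ingredient database annotations.
#'
#' @return data.frame with columns class_id, density, kcal_per_g, fat_frac,
#'   carb_frac, protein_frac, albedo_r, albedo_g, albedo_b
#' @export
ingredient_table <- function() {
  tab <- data.frame(
    class_id = c("rice", "chicken", "broccoli", "carrot", "beef", "potato"),
    density = c(0.85, 1.05, 0.35, 0.64, 1.00, 0.65),
    kcal_per_g = c(1.30, 1.65, 0.35, 0.41, 2.50, 0.77),
    fat_frac = c(0.003, 0.036, 0.004, 0.002, 0.150, 0.001),
    carb_frac = c(0.280, 0.000, 0.070, 0.100, 0.000, 0.170),
    protein_frac = c(0.027, 0.310, 0.028, 0.009, 0.260, 0.020),
    albedo_r = c(0.94, 0.85, 0.23, 0.93, 0.50, 0.89),
    albedo_g = c(0.92, 0.67, 0.55, 0.45, 0.28, 0.78),
    albedo_b = c(0.84, 0.45, 0.21, 0.12, 0.20, 0.52),
    stringsAsFactors = FALSE
  )
  validate_ingredient_table(tab)
  tab
}

validate_ingredient_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("class_id", "density", "kcal_per_g", "fat_frac", "carb_frac",
                  "protein_frac") %in% names(tab)))
  if (any(tab$density <= 0)) stop("ingredient table: density must be > 0")
  fr <- tab$fat_frac + tab$carb_frac + tab$protein_frac
  if (any(tab$fat_frac < 0 | tab$carb_frac < 0 | tab$protein_frac < 0) ||
      any(tab$fat_frac > 1 | tab$carb_frac > 1 | tab$protein_frac > 1))
    stop("ingredient table: fractions must lie in [0, 1]")
  if (any(fr > 1)) stop("ingredient table: fat+carb+protein fractions exceed 1")
  invisible(tab)
}

#' Construct an ingredient blob
#'
#' @param class_id ingredient class name (must exist in the ingredient table)
#' @param center numeric (row, col) center in pixels
#' @param axes numeric (a, b) ellipse semi-axes in pixels
#' @param height maximum height of the blob in cm
#' @param rotation footprint rotation in radians
#' @param profile `"cap"` (paraboloid cap, h = height * (1 - r^2) inside the
#'   footprint) or `"cylinder"` (constant height inside the footprint)
#' @return an `ingredient_blob` list
#' @export
ingredient_blob <- function(class_id, center, axes, height,
                            rotation = 0, profile = c("cap", "cylinder")) {
  profile <- match.arg(profile)
  if (height < 0) stop("ingredient_blob: height must be >= 0")
  if (any(axes <= 0)) stop("ingredient_blob: axes must be > 0")
  structure(list(class_id = class_id, center = center, axes = axes,
                 height = height, rotation = rotation, profile = profile),
            class = "ingredient_blob")
}

#' Construct a synthetic dish scene specification
#'
#' @param image_size integer (H, W) in pixels; default 336 x 448, the input
#'   size of the fusion network
#' @param camera_height distance from camera to table plane, cm
#' @param pixel_area area of one pixel at the table plane, cm^2; default is
#'   derived from `physical_width`
#' @param physical_width table width spanned by the shorter image side, cm
#'   (used only when `pixel_area` is NULL)
#' @param plate list with `center` (row, col pixels), `radius` (pixels) and
#'   `rim_height` (cm)
#' @param blobs list of [ingredient_blob()] objects
#' @param noise list with `rgb_sd` (additive RGB noise, image units) and
#'   `depth_sd` (additive depth noise, cm); use `scene_noise(FALSE)` to
#'   disable
#' @param seed integer seed controlling the noise draws
#' @param table ingredient table, default [ingredient_table()]
#' @return a validated `scene_spec` object
#' @export
scene_spec <- function(image_size = c(336, 448), camera_height = 35,
                       pixel_area = NULL, physical_width = 30,
                       plate = NULL, blobs = list(),
                       noise = scene_noise(TRUE), seed = 1L,
                       table = ingredient_table()) {
  H <- image_size[1]; W <- image_size[2]
  if (is.null(pixel_area)) pixel_area <- (physical_width / min(H, W))^2
  if (is.null(plate))
    plate <- list(center = c(H / 2, W / 2), radius = 0.42 * min(H, W),
                  rim_height = 0.8)
  spec <- structure(list(image_size = as.integer(image_size),
                         camera_height = camera_height,
                         pixel_area = pixel_area, plate = plate,
                         blobs = blobs, noise = noise, seed = as.integer(seed),
                         table = table),
                    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

#' Noise settings for a scene
#' @param on logical; FALSE gives exactly zero noise
#' @param rgb_sd additive RGB noise standard deviation (image units in [0,1])
#' @param depth_sd additive depth noise standard deviation (cm)
#' @return list with rgb_sd and depth_sd
#' @export
scene_noise <- function(on = TRUE, rgb_sd = 0.01, depth_sd = 0.15) {
  if (!on) list(rgb_sd = 0, depth_sd = 0) else
    list(rgb_sd = rgb_sd, depth_sd = depth_sd)
}

#' Validate a scene specification
#' @param spec a `scene_spec`
#' @return the spec, invisibly; stops on violation
#' @export
validate_scene_spec <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  if (H < 4 || W < 4) stop("scene_spec: image too small")
  if (spec$pixel_area <= 0) stop("scene_spec: pixel_area must be > 0")
  max_h <- if (length(spec$blobs)) max(vapply(spec$blobs, `[[`, 0, "height")) else 0
  if (spec$camera_height <= max_h + spec$plate$rim_height)
    stop("scene_spec: camera_height must exceed max blob height + plate rim")
  for (b in spec$blobs) {
    if (!b$class_id %in% spec$table$class_id)
      stop("scene_spec: unknown ingredient class '", b$class_id, "'")
    if (b$center[1] < 1 || b$center[1] > H || b$center[2] < 1 || b$center[2] > W)
      stop("scene_spec: blob center outside image bounds")
  }
  validate_ingredient_table(spec$table)
  invisible(spec)
}

# squared normalized elliptical radius of every pixel w.r.t. a blob
blob_r2 <- function(blob, H, W) {
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- r - blob$center[1]
  dx <- c - blob$center[2]
  ct <- cos(blob$rotation); st <- sin(blob$rotation)
  u <- (dx * ct + dy * st) / blob$axes[1]
  v <- (-dx * st + dy * ct) / blob$axes[2]
  u * u + v * v
}

# height field of one blob (cm), zero outside the footprint
blob_height <- function(blob, H, W) {
  r2 <- blob_r2(blob, H, W)
  inside <- r2 <= 1
  if (blob$profile == "cap") blob$height * pmax(1 - r2, 0) * inside
  else blob$height * inside
}

# food height field and per-pixel class index (0 = none); overlapping blobs
# are resolved by the maximum height (food stacks occlude what is beneath)
food_field <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  height <- matrix(0, H, W)
  class_ix <- matrix(0L, H, W)
  for (k in seq_along(spec$blobs)) {
    h <- blob_height(spec$blobs[[k]], H, W)
    take <- h > height
    height[take] <- h[take]
    class_ix[take] <- match(spec$blobs[[k]]$class_id, spec$table$class_id)
  }
  list(height = height, class_ix = class_ix)
}

# raised rim profile of the plate (cm): a smooth bump between 0.85 R and R
plate_profile <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((r - spec$plate$center[1])^2 + (c - spec$plate$center[2])^2)
  R <- spec$plate$radius
  r_in <- 0.85 * R
  prof <- matrix(0, H, W)
  ring <- d >= r_in & d <= R
  prof[ring] <- spec$plate$rim_height *
    0.5 * (1 - cos(2 * pi * (d[ring] - r_in) / (R - r_in)))
  prof
}

#' Exact nutrition ground truth of a scene
#'
#' Integrates each ingredient's height field over its visible pixels
#' (noise-free geometry): mass is height x pixel area x density summed per
#' class; calories and macronutrients follow from the per-class energy
#' density and mass fractions.
#'
#' @param spec a `scene_spec`
#' @return named numeric vector: calories (kCal), mass, fat, carb, protein (g)
#' @export
ground_truth_nutrition <- function(spec) {
  validate_scene_spec(spec)
  ff <- food_field(spec)
  out <- c(calories = 0, mass = 0, fat = 0, carb = 0, protein = 0)
  for (ci in unique(ff$class_ix[ff$class_ix > 0])) {
    row <- spec$table[ci, ]
    vol <- sum(ff$height[ff$class_ix == ci]) * spec$pixel_area  # cm^3
    m <- vol * row$density
    out["mass"] <- out["mass"] + m
    out["calories"] <- out["calories"] + m * row$kcal_per_g
    out["fat"] <- out["fat"] + m * row$fat_frac
    out["carb"] <- out["carb"] + m * row$carb_frac
    out["protein"] <- out["protein"] + m * row$protein_frac
  }
  out
}

#' Render a dish sample from a scene specification
#'
#' Produces the (RGB, depth, nutrition) triplet. The depth map is
#' `camera_height - surface_height` in cm (closer surfaces are smaller
#' values) plus optional sensor noise; the RGB image is the per-pixel class
#' albedo under top-down Lambertian shading (brightness falls with surface
#' slope) plus optional noise. The nutrition label is always computed from
#' the exact noise-free geometry. Deterministic given `spec$seed`.
#'
#' @param spec a `scene_spec`
#' @param dish_id identifier stored in the sample, default "dish_000001"
#' @return a `dish_sample`: list(dish_id, rgb H x W x 3 in `[0,1]`,
#'   depth H x W in cm, label, camera_height, pixel_area)
#' @export
render_dish <- function(spec, dish_id = "dish_000001") {
  validate_scene_spec(spec)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ff <- food_field(spec)
  surface <- plate_profile(spec) + ff$height
  pixel_size <- sqrt(spec$pixel_area)

  # Lambertian top-down shading from the surface gradient (cm per cm)
  gx <- (cbind(surface[, -1], surface[, W]) -
           cbind(surface[, 1], surface[, -W])) / (2 * pixel_size)
  gy <- (rbind(surface[-1, ], surface[H, ]) -
           rbind(surface[1, ], surface[-H, ])) / (2 * pixel_size)
  shade <- 0.35 + 0.65 / sqrt(1 + gx^2 + gy^2)

  # albedo: table background, plate, then visible ingredient class
  r <- matrix(seq_len(H), H, W)
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((r - spec$plate$center[1])^2 + (c - spec$plate$center[2])^2)
  albedo <- array(0, dim = c(H, W, 3))
  table_col <- c(0.55, 0.45, 0.35)
  plate_col <- c(0.92, 0.92, 0.95)
  for (ch in 1:3) {
    a <- matrix(table_col[ch], H, W)
    a[d <= spec$plate$radius] <- plate_col[ch]
    albedo[, , ch] <- a
  }
  cols <- c("albedo_r", "albedo_g", "albedo_b")
  food <- ff$class_ix > 0
  for (ch in 1:3) {
    a <- albedo[, , ch]
    a[food] <- spec$table[[cols[ch]]][ff$class_ix[food]]
    albedo[, , ch] <- a
  }

  depth <- spec$camera_height - surface
  rgb <- albedo * array(shade, dim = c(H, W, 3))
  if (spec$noise$depth_sd > 0 || spec$noise$rgb_sd > 0) {
    with_seed(spec$seed, {
      if (spec$noise$depth_sd > 0)
        depth <- depth + matrix(stats::rnorm(H * W, sd = spec$noise$depth_sd), H, W)
      if (spec$noise$rgb_sd > 0)
        rgb <- rgb + array(stats::rnorm(H * W * 3, sd = spec$noise$rgb_sd),
                           dim = c(H, W, 3))
    })
  }
  depth <- pmin(pmax(depth, 1e-6), spec$camera_height)
  rgb <- pmin(pmax(rgb, 0), 1)

  structure(list(dish_id = dish_id, rgb = rgb, depth = depth,
                 label = ground_truth_nutrition(spec),
                 camera_height = spec$camera_height,
                 pixel_area = spec$pixel_area),
            class = "dish_sample")
}

#' Draw a random dish scene
#'
#' Samples a plate position, 1-4 ingredient blobs with random classes,
#' footprints and heights, and packages them as a [scene_spec()]. With
#' `overlap = FALSE` (default) blob footprints are rejection-sampled to be
#' pairwise disjoint; `overlap = TRUE` permits stacking (resolved by the
#' maximum-height rule).
#'
#' @param image_size integer (H, W)
#' @param seed integer seed (drives both scene sampling and render noise)
#' @param n_blobs number of ingredient blobs; default random in 1..4
#' @param overlap allow overlapping footprints
#' @param noise noise settings from [scene_noise()]
#' @param camera_height camera height in cm
#' @param table ingredient table
#' @return a `scene_spec`
#' @export
random_scene <- function(image_size = c(336, 448), seed = 1L, n_blobs = NULL,
                         overlap = FALSE, noise = scene_noise(TRUE),
                         camera_height = 35, table = ingredient_table()) {
  H <- image_size[1]; W <- image_size[2]
  with_seed(seed, {
    if (is.null(n_blobs)) n_blobs <- sample(1:4, 1)
    plate_center <- c(H / 2, W / 2) + stats::runif(2, -0.02, 0.02) * min(H, W)
    R <- stats::runif(1, 0.38, 0.44) * min(H, W)
    inner <- 0.72 * R  # blobs stay inside the flat part of the plate
    blobs <- list()
    tries <- 0L
    while (length(blobs) < n_blobs && tries < 200L) {
      tries <- tries + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * inner * 0.75
      ctr <- plate_center + rad * c(sin(ang), cos(ang))
      axes <- stats::runif(2, 0.16, 0.30) * R
      # keep the footprint inside the flat plate region
      if (rad + max(axes) > inner) next
      if (!overlap && length(blobs)) {
        ok <- TRUE
        for (b in blobs) {
          gap <- sqrt(sum((ctr - b$center)^2))
          if (gap < max(axes) + max(b$axes) + 1) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      blobs[[length(blobs) + 1L]] <- ingredient_blob(
        class_id = sample(table$class_id, 1),
        center = ctr, axes = axes,
        height = stats::runif(1, 0.8, 3.5),
        rotation = stats::runif(1, 0, pi),
        profile = sample(c("cap", "cylinder"), 1, prob = c(0.8, 0.2))
      )
    }
    scene_spec(image_size = image_size, camera_height = camera_height,
               plate = list(center = plate_center, radius = R, rim_height = 0.8),
               blobs = blobs, noise = noise, seed = seed, table = table)
  })
}

#' Generate a synthetic dish dataset
#'
#' Renders `n` random dishes and (optionally) writes them in the on-disk
#' layout `<root>/imagery/<dish_id>/rgb.png` (8-bit PNG) and
#' `depth_raw.tiff` (16-bit TIFF, cm-per-unit scale declared in
#' `<root>/scene_meta.yaml`), plus `<root>/metadata.csv` with header
#' `dish_id,total_calories,total_mass,total_fat,total_carb,total_protein`
#' and `<root>/splits.csv` assigning train/test. Every `(ratio+1)`-th dish
#' is a test dish, giving the default 5:1 train:test split. Deterministic
#' per seed.
#'
#' @param n number of dishes (>= 1)
#' @param out_dir output directory or NULL for in-memory only
#' @param image_size integer (H, W)
#' @param seed master seed
#' @param overlap allow overlapping blobs
#' @param noise noise settings from [scene_noise()]
#' @param split_ratio train:test ratio (default 5)
#' @param camera_height camera height in cm, shared by the whole set
#' @param table ingredient table
#' @return a `nutrition_dataset`: list(samples, split, meta, dir)
#' @export
make_dataset <- function(n, out_dir = NULL, image_size = c(336, 448),
                         seed = 1L, overlap = FALSE, noise = scene_noise(TRUE),
                         split_ratio = 5, camera_height = 35,
                         table = ingredient_table()) {
  if (n < 1) stop("make_dataset: n must be >= 1")
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- random_scene(image_size = image_size, seed = sub_seeds[i],
                         overlap = overlap, noise = noise,
                         camera_height = camera_height, table = table)
    samples[[i]] <- render_dish(spec, dish_id = sprintf("dish_%05d", i))
  }
  split <- ifelse(seq_len(n) %% (split_ratio + 1) == 0, "test", "train")
  if (n > split_ratio && !any(split == "test")) split[n] <- "test"
  meta <- list(camera_height = camera_height,
               pixel_area = samples[[1]]$pixel_area,
               image_size = as.integer(image_size),
               depth_scale = camera_height / 65535)
  ds <- structure(list(samples = samples, split = split, meta = meta,
                       dir = out_dir),
                  class = "nutrition_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

# on-disk writer for a nutrition_dataset (see make_dataset for the layout)
write_dataset <- function(ds, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("make_dataset: cannot create output directory ", out_dir)
  meta <- ds$meta
  for (s in ds$samples) {
    d <- file.path(out_dir, "imagery", s$dish_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(s$rgb, file.path(d, "rgb.png"))
    # pre-round to the 16-bit grid (the writer truncates), so the stored
    # sample is the nearest representable depth
    units <- pmin(pmax(s$depth / meta$camera_height, 0), 1)
    units <- pmin((round(units * 65535) + 0.5) / 65535, 1)
    tiff::writeTIFF(units, file.path(d, "depth_raw.tiff"),
                    bits.per.sample = 16L)
  }
  lab <- t(vapply(ds$samples, function(s) s$label, numeric(5)))
  lines <- c("dish_id,total_calories,total_mass,total_fat,total_carb,total_protein",
             vapply(seq_along(ds$samples), function(i) {
               paste0(ds$samples[[i]]$dish_id, ",",
                      paste(sprintf("%.6f", lab[i, ]), collapse = ","))
             }, ""))
  writeLines(lines, file.path(out_dir, "metadata.csv"))
  writeLines(c("dish_id,split",
               paste0(vapply(ds$samples, `[[`, "", "dish_id"), ",", ds$split)),
             file.path(out_dir, "splits.csv"))
  yaml::write_yaml(list(camera_height_cm = meta$camera_height,
                        depth_scale_cm_per_unit = meta$depth_scale,
                        pixel_area_cm2 = meta$pixel_area,
                        image_size = as.integer(meta$image_size)),
                   file.path(out_dir, "scene_meta.yaml"))
  invisible(out_dir)
}
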