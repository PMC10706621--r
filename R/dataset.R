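# Reading a dish dataset from the on-disk layout written by make_dataset():
#   <root>/imagery/<dish_id>/rgb.png        8-bit RGB
#   <root>/imagery/<dish_id>/depth_raw.tiff 16-bit depth, cm scale in sidecar
#   <root>/metadata.csv                     nutrition labels
#   <root>/splits.csv                       train/test assignment
#   <root>/scene_meta.yaml                  camera height, depth scale, pixel area

#' Read a dish dataset from disk
#'
#' Validates the metadata, drops malformed rows (non-numeric or negative
#' labels) with a warning, skips dishes whose image files are unreadable
#' (I/O failures only; no content-based cleaning is performed), and loads
#' every remaining sample into memory.
#'
#' @param root dataset directory
#' @return a `nutrition_dataset`: list(samples, split, meta, dir)
#' @export
read_dataset <- function(root) {
  csv <- file.path(root, "metadata.csv")
  if (!file.exists(csv)) stop("read_dataset: missing metadata.csv in ", root)
  md <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("dish_id", "total_calories", "total_mass", "total_fat",
            "total_carb", "total_protein")
  if (!all(need %in% names(md)))
    stop("read_dataset: metadata.csv lacks required columns")
  lab_cols <- need[-1]
  ok <- rep(TRUE, nrow(md))
  for (cn in lab_cols) {
    v <- suppressWarnings(as.numeric(md[[cn]]))
    ok <- ok & !is.na(v) & v >= 0
    md[[cn]] <- v
  }
  if (any(!ok)) {
    warning("read_dataset: dropped ", sum(!ok), " malformed metadata row(s)",
            call. = FALSE)
    md <- md[ok, , drop = FALSE]
  }

  meta_file <- file.path(root, "scene_meta.yaml")
  meta <- if (file.exists(meta_file)) yaml::read_yaml(meta_file) else list()
  camera_height <- meta$camera_height_cm %||% 35
  # recompute the cm-per-unit scale from the camera height rather than
  # trusting the sidecar's decimal rendering of it
  depth_scale <- if (!is.null(meta$camera_height_cm)) camera_height / 65535
                 else meta$depth_scale_cm_per_unit %||% (camera_height / 65535)

  split_file <- file.path(root, "splits.csv")
  split_map <- if (file.exists(split_file)) {
    sp <- utils::read.csv(split_file, stringsAsFactors = FALSE)
    stats::setNames(sp$split, sp$dish_id)
  } else NULL

  samples <- list()
  split <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(md))) {
    id <- md$dish_id[i]
    d <- file.path(root, "imagery", id)
    rgb_f <- file.path(d, "rgb.png")
    dep_f <- file.path(d, "depth_raw.tiff")
    sample <- tryCatch({
      rgb <- png::readPNG(rgb_f)
      if (length(dim(rgb)) == 2L) rgb <- array(rgb, dim = c(dim(rgb), 1L))
      if (dim(rgb)[3] > 3L) rgb <- rgb[, , 1:3, drop = FALSE]
      depth <- if (file.exists(dep_f)) {
        u <- tiff::readTIFF(dep_f)
        u * 65535 * depth_scale
      } else NULL
      structure(list(dish_id = id, rgb = rgb, depth = depth,
                     label = c(calories = md$total_calories[i],
                               mass = md$total_mass[i],
                               fat = md$total_fat[i],
                               carb = md$total_carb[i],
                               protein = md$total_protein[i]),
                     camera_height = camera_height,
                     pixel_area = meta$pixel_area_cm2 %||% NA_real_),
                class = "dish_sample")
    }, error = function(e) NULL)
    if (is.null(sample)) { skipped <- skipped + 1L; next }
    samples[[length(samples) + 1L]] <- sample
    split <- c(split,
               if (!is.null(split_map) && !is.na(split_map[id])) split_map[[id]]
               else "train")
  }
  if (skipped > 0L)
    warning("read_dataset: skipped ", skipped, " dish(es) with unreadable images",
            call. = FALSE)
  if (!length(samples)) stop("read_dataset: no readable samples in ", root)
  structure(list(samples = samples, split = unname(split),
                 meta = list(camera_height = camera_height,
                             depth_scale = depth_scale,
                             pixel_area = meta$pixel_area_cm2 %||% NA_real_,
                             image_size = dim(samples[[1]]$rgb)[1:2]),
                 dir = root),
            class = "nutrition_dataset")
}

#' @export
print.nutrition_dataset <- function(x, ...) {
  cat(sprintf("nutrition_dataset: %d dishes (%d train / %d test), %dx%d px\n",
              length(x$samples), sum(x$split == "train"),
              sum(x$split == "test"),
              x$meta$image_size[1], x$meta$image_size[2]))
  invisible(x)
}

# subset helpers used by the training loops
dataset_subset <- function(ds, which = c("train", "test")) {
  which <- match.arg(which)
  keep <- ds$split == which
  ds$samples <- ds$samples[keep]
  ds$split <- ds$split[keep]
  ds
}

dataset_labels <- function(ds) {
  t(vapply(ds$samples, function(s) s$label, numeric(5)))
}
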