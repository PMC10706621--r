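# Scaled-down ablation harness over the fusion architecture variants:
#   (a) RGB stream only          (b) depth stream only
#   (c) direct concatenation fusion (no cascade, no attention)
#   (d) (c) + multi-scale fusion cascade
#   (e) (d) + cross-modal attention block  -- the full model
# Each variant is trained and evaluated on a synthetic dish set whose mass
# is determined by the depth field, across several seeds, and the
# qualitative ordering (depth-only worst; full model at least as good as
# RGB-only) is summarized by majority vote.

ABLATION_VARIANTS <- c("a", "b", "c", "d", "e")

variant_config <- function(variant, input_size, channels, head_dim, depth_scale) {
  base <- function(...) fusion_model_config(input_size = input_size,
                                            channels = channels,
                                            head_dim = head_dim,
                                            depth_scale = depth_scale, ...)
  switch(variant,
         a = base(streams = "rgb"),
         b = base(streams = "depth"),
         c = base(streams = "rgbd", attention = FALSE, multiscale = FALSE),
         d = base(streams = "rgbd", attention = FALSE, multiscale = TRUE),
         e = base(streams = "rgbd", attention = TRUE, multiscale = TRUE),
         stop("unknown ablation variant '", variant, "'"))
}

variant_label <- function(variant) {
  switch(variant,
         a = "RGB stream", b = "Depth stream", c = "Direct fusion",
         d = "Multi-scale fusion", e = "Multi-scale + CAB")
}

#' Run the fusion ablation study on synthetic dishes
#'
#' Generates one shared synthetic dish set (4:1 train:test split giving
#' `n_train`/`n_test` dishes from `data_seed`), trains every requested
#' variant at reduced scale once per training seed, evaluates the test
#' split and tabulates per-nutrient MAE/PMAE and mean PMAE per variant. The ordering summary reports, per seed, whether
#' the depth-only stream is worst and whether the full attention model
#' reaches at or below the RGB-only mean PMAE, plus the across-seed
#' majority vote. Training uses stored (sensor) depth by default so the
#' fusion comparison is not confounded by depth-model quality.
#'
#' @param variants subset of c("a","b","c","d","e"); at least two
#' @param seeds integer vector of training seeds (weight init, batch order,
#'   augmentation)
#' @param data_seed seed of the shared synthetic dish set
#' @param n_train,n_test dishes per split
#' @param image_size synthetic image size (divisible by 32)
#' @param channels backbone channel counts
#' @param head_dim shared head width
#' @param steps optimizer steps per variant
#' @param batch_size dishes per step
#' @param lr initial Adam learning rate
#' @param depth_source `"sensor"` or `"predicted"` (requires `depth_model`)
#' @param depth_model depth model/checkpoint when `depth_source="predicted"`
#' @param camera_height camera height (cm) of the synthetic scenes
#' @param out_dir optional directory for per-seed CSV tables and a summary
#' @param verbose print progress
#' @return list with `tables` (one data.frame per seed), `summary`
#'   (aggregated mean PMAE per variant), and `ordering` (per-seed checks and
#'   majority votes)
#' @export
run_ablation <- function(variants = ABLATION_VARIANTS, seeds = c(1, 2, 3),
                         data_seed = 1L, n_train = 200, n_test = 50,
                         image_size = c(32, 32),
                         channels = c(4, 8, 16, 32, 64), head_dim = 32,
                         steps = 1000, batch_size = 8, lr = 5e-3,
                         depth_source = "sensor", depth_model = NULL,
                         camera_height = 35, out_dir = NULL, verbose = FALSE) {
  variants <- match.arg(variants, ABLATION_VARIANTS, several.ok = TRUE)
  if (length(variants) < 2) stop("run_ablation: need at least two variants")
  n <- n_train + n_test
  ratio <- n_train / n_test
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("run_ablation: n_train must be a multiple of n_test")
  ds <- make_dataset(n, image_size = image_size, seed = data_seed,
                     split_ratio = as.integer(round(ratio)),
                     camera_height = camera_height)
  tables <- list()
  ord <- data.frame(seed = seeds, depth_worst = NA, cab_le_rgb = NA)
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    rows <- list()
    for (v in variants) {
      if (verbose) message(sprintf("seed %d variant (%s)", seed, v))
      cfg <- variant_config(v, image_size, channels, head_dim,
                            depth_scale = camera_height)
      ck <- train_fusion_stage(ds, cfg, steps = steps,
                               batch_size = batch_size, lr = lr, seed = seed,
                               depth_source = depth_source,
                               depth_model = depth_model)
      rep <- evaluate_model(ck, ds, split = "test",
                            depth_source = depth_source,
                            depth_model = depth_model)
      rows[[v]] <- c(report_row(rep))
    }
    tab <- data.frame(variant = variants,
                      model = vapply(variants, variant_label, ""),
                      do.call(rbind, rows), row.names = NULL,
                      check.names = FALSE)
    tables[[as.character(seed)]] <- tab
    mp <- stats::setNames(tab$mean_pmae, tab$variant)
    if ("b" %in% variants)
      ord$depth_worst[si] <- mp[["b"]] >= max(mp)
    if (all(c("a", "e") %in% variants))
      ord$cab_le_rgb[si] <- mp[["e"]] <= mp[["a"]]
  }
  agg <- do.call(rbind, lapply(tables, function(t) t$mean_pmae))
  summary <- data.frame(variant = variants,
                        model = vapply(variants, variant_label, ""),
                        mean_pmae = colMeans(agg),
                        row.names = NULL)
  ordering <- list(per_seed = ord,
                   depth_worst_majority =
                     mean(ord$depth_worst, na.rm = TRUE) > 0.5,
                   cab_le_rgb_majority =
                     mean(ord$cab_le_rgb, na.rm = TRUE) >= 2 / 3)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(tables))
      utils::write.csv(tables[[s]],
                       file.path(out_dir, sprintf("ablation_seed%s.csv", s)),
                       row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "ablation_summary.csv"),
                     row.names = FALSE)
  }
  list(tables = tables, summary = summary, ordering = ordering)
}
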