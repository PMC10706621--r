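# YAML training configurations. Two profiles ship with the package:
# desk-scale defaults (small models, small synthetic images) that run on a
# single CPU, and full-scale recipes (profile: gpu) matching the full-scale reference
# training setup (depth: Adam 1e-5 cosine-annealed to 1e-6, 60 epochs,
# batch 8, 384px square crops; fusion: Adam 5e-5 with exponential decay
# 0.98, 150 epochs, batch 8, 336x448 inputs).

#' Load a training configuration from YAML
#'
#' @param path YAML file; see `system.file("configs", package =
#'   "nutrivision")` for the shipped profiles
#' @return named list of configuration values
#' @export
load_train_config <- function(path) {
  if (!file.exists(path)) stop("load_train_config: no such file ", path)
  yaml::read_yaml(path)
}

#' Path of a shipped configuration profile
#' @param name file name, e.g. `"fusion_desk.yaml"`
#' @return absolute path
#' @export
config_profile <- function(name) {
  p <- system.file("configs", name, package = "nutrivision")
  if (p == "") stop("config_profile: no shipped profile named ", name)
  p
}
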