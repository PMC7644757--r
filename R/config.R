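#' Run configuration with the method's standard constants
#'
#' Collects every tunable scalar of the pipeline with the published
#' defaults: 5000-nt windows, 3:1 background ratio, 4:1 train/test split,
#' 5 folds, dropout 0.5, annotation threshold 0.343 (the genome-scale
#' instance value; `"auto"` re-selects it by F1 maximisation), 11-bp
#' join/skip rules and 10-bp combine proximity.
#'
#' @param genome,labels,manifest,output_dir File paths (optional, used by
#'   the command-line driver).
#' @param window_length,background_ratio,train_fraction,folds Dataset
#'   parameters.
#' @param threshold `"auto"` or a numeric cutoff in `[0, 1]`.
#' @param join_gap,min_length,combine_proximity Region-assembly parameters.
#' @param epochs,learning_rate,batch_size,dropout Training parameters.
#' @param seed Single integer seed from which all randomness flows.
#' @return A list of class `zdna_run_config`.
#' @export
zdna_config <- function(genome = NULL, labels = NULL, manifest = NULL,
                        output_dir = NULL,
                        window_length = 5000, background_ratio = 3,
                        train_fraction = 0.8, folds = 5,
                        threshold = 0.343, join_gap = 11, min_length = 11,
                        combine_proximity = 10,
                        epochs = 40, learning_rate = 2e-3, batch_size = 8,
                        dropout = 0.5, seed = 1) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "zdna_run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$window_length >= 1, cfg$background_ratio >= 0,
            cfg$train_fraction >= 0, cfg$train_fraction <= 1,
            cfg$folds >= 2, cfg$join_gap >= 0, cfg$min_length >= 0,
            cfg$combine_proximity >= 0, cfg$epochs >= 1,
            cfg$learning_rate > 0, cfg$batch_size >= 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  if (!identical(cfg$threshold, "auto")) {
    if (!is.numeric(cfg$threshold) || cfg$threshold < 0 || cfg$threshold > 1)
      stop("threshold must be 'auto' or a number in [0, 1]")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [zdna_config()].
#'
#' @param path YAML file.
#' @return A `zdna_run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(zdna_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(zdna_config, vals)
}

#' Write the resolved configuration next to a run's outputs
#'
#' Every run records the fully resolved configuration (all defaults filled
#' in) plus the package version for provenance.
#'
#' @param config A `zdna_run_config`.
#' @param dir Output directory.
#' @return The written path, invisibly.
#' @export
write_resolved_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "resolved_config.yaml")
  out <- unclass(config)
  out$package_version <- as.character(utils::packageVersion("zdnascan"))
  yaml::write_yaml(out, path)
  invisible(path)
}
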