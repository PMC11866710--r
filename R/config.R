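# Configuration defaults, YAML loading with validation, and run manifests.

#' Default configuration
#'
#' The hyperparameter table used throughout: learning rate 1e-3 for count
#' and context features, 4e-4 for single sequence inputs, 1e-4 for combined
#' models; 256 epochs for single-feature and 512 for combined experiments;
#' batch size 32; 16 convolutional filters with candidate widths 8/10/12;
#' OPTICS xi 1e-2 (nucleotide) and 5e-3 (amino acid); positional sd cutoff
#' 0.2; detection thresholds 1 TPM and 5000 iBAQ; minimum 21 matched data
#' points.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1,
    thresholds = list(tpm_min = 1, ibaq_min = 5000),
    coverage = list(min_train = 21, holdout_points = 20),
    features = list(w_up = 6, w_down = 9),
    model = list(
      lr_counts = 1e-3, lr_sequence = 4e-4, lr_combined = 1e-4,
      epochs_single = 256, epochs_combined = 512,
      batch_size = 32, n_filters = 16, filter_widths = c(8, 10, 12),
      combine_widths = c(32, 16), branch_width = 16
    ),
    cv = list(n_repeats = 5, n_folds = 10),
    motifs = list(xi_nucleotide = 1e-2, xi_amino_acid = 5e-3,
                  std_cutoff = 0.2, min_samples = 5, trim_at = 0.1),
    crosscorr = list(min_points = 21, top_k = c(10, 20, 40), chunk = 500)
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, nm, "."))
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a YAML configuration
#'
#' Missing keys are filled from [default_config()]; unknown keys are an
#' error.  `load_config(NULL)` returns the defaults.
#'
#' @param path YAML file path or `NULL`.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

#' Write a run manifest
#'
#' Records the configuration hash, seed, package version, input-file
#' digests, timestamp and command line, sufficient to rerun a command
#' reproducibly.
#'
#' @param dir run directory.
#' @param config configuration list.
#' @param inputs character vector of input file paths to digest.
#' @param command command-line string.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_manifest <- function(dir, config, inputs = character(0), command = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  digests <- if (length(inputs) > 0)
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("ptrnet")),
    config_hash = cfg_hash,
    seed = config$seed,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
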