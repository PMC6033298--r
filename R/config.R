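#' Default run configuration
#'
#' Every tunable parameter of the pipeline, grouped per module, with the
#' package defaults. Unknown keys are rejected on validation so typos fail
#' loudly instead of silently falling back to defaults.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    stain = list(eps = 1e-6),
    threshold = list(k = 0.25, r = 0.5, p = 2, q = 10, window_radius = 15),
    watershed = list(min_seed_sep = 7, min_area = 15),
    filter = list(min_count = 5, min_mean_h = 0.02),
    cluster = list(k = 2),
    split = list(train_fraction = 0.9),
    tissue = list(patch_size = 256, purity = 0.9),
    synth = list(size = 256, noise_sd = 0.02),
    training = list(input_size = 32, filters = c(8, 16, 32, 32),
                    epochs = 20, lr = 0.1, batch_size = 32, momentum = 0.9),
    evaluation = list(threshold = 0.5),
    demo = list(n_medium_per_cluster = 60, n_high_train_per_class = 15,
                n_high_val_per_class = 25, n_high_test_per_class = 25,
                size = 64, noise_sd = 0.05,
                epochs_medium = 10, epochs_high = 15)
  )
}

check_keys <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]))
      check_keys(as.list(cfg[[nm]]), template[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

#' Validate and complete a configuration
#'
#' Checks every key (recursively) against \code{\link{default_config}} and
#' fills unset parameters with their defaults.
#'
#' @param cfg partial configuration list.
#' @return complete configuration list.
#' @export
validate_config <- function(cfg) {
  template <- default_config()
  check_keys(cfg, template)
  utils::modifyList(template, cfg)
}

#' Read / write configuration files (JSON)
#'
#' @param path file path.
#' @return \code{read_config} returns a validated, completed configuration;
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
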