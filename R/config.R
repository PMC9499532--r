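#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. The resolved
#' configuration round-trips losslessly through YAML and is embedded in
#' every run's output directory; CSV outputs carry its hash.
#'
#' @param ... overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # preprocess
    working_max = 255, input_max = 65535,
    denoise_c1 = 1.5, denoise_m = 3, denoise_c2 = 8,
    threshold = 10, min_particle_px = 20,
    register = FALSE, template_box = NULL, max_shift = 50, min_corr = 0.5,
    # segment extraction
    max_segment_len = 40, min_skeleton_px = 3,
    # cleaning
    proximity_max = 100, hard_max_factor = 2, min_cluster_size = 4,
    linearity_threshold = 0.85, anchor = "nearer", center_x = NULL,
    # traits / geometry
    pixel_size = 0.01,
    # model
    time_grid = seq(0, 336, by = 48), cut_distance = 1.75,
    fit_model = TRUE,
    # qc
    expected_frames = NULL, max_fg_fraction = 0.25,
    rng_seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a CSV with a provenance header
#'
#' Prepends a `#`-comment line carrying the package version, configuration
#' hash, and seed, then the standard CSV (UTF-8, comma separator, `.`
#' decimal, empty missing values).
#'
#' @param df data.frame.
#' @param path output path.
#' @param cfg optional `pipeline_config` (hashed into the header).
#' @param seed seed recorded in the header.
#' @export
write_csv_prov <- function(df, path, cfg = NULL, seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rhizotrack %s; config=%s; seed=%s",
                     as.character(packageVersion("rhizotrack")),
                     if (is.null(cfg)) "none" else config_hash(cfg),
                     seed), con)
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_csv_prov
#' @export
read_csv_prov <- function(path) {
  read.csv(path, comment.char = "#")
}
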