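# YAML run configuration: blocks `backbone`, `neck`, `detector`, `data`.
# Values absent from the file fall back to the packaged defaults, so a
# config file only needs to state what it changes.

#' Load a detector run configuration from YAML
#'
#' @param path YAML file; `NULL` loads the packaged default
#' @param overrides named list applied on top of the file (CLI flags)
#' @return nested configuration list of class `run_config`
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  def <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "pestdetectr"))
  usr <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- modify_list_deep(def, usr)
  cfg <- modify_list_deep(cfg, overrides)
  structure(cfg, class = "run_config")
}

modify_list_deep <- function(a, b) {
  for (nm in names(b)) {
    if (is.list(a[[nm]]) && is.list(b[[nm]])) {
      a[[nm]] <- modify_list_deep(a[[nm]], b[[nm]])
    } else {
      a[[nm]] <- b[[nm]]
    }
  }
  a
}

#' Turn a run configuration into a detector configuration
#'
#' @param rc a `run_config`
#' @return a [detector_config()]
#' @export
run_to_detector_config <- function(rc) {
  bk <- rc$backbone
  nk <- rc$neck
  dt <- rc$detector
  detector_config(
    num_classes = length(dt$classes), class_names = dt$classes,
    preset = dt$preset %||% "tiny", seed = rc$seed %||% 0L,
    backbone = backbone_config(bk$depth,
                               deformable_stages = unlist(bk$deformable_stages),
                               deformable = isTRUE(bk$deformable)),
    neck = neck_config(d = nk$channels,
                       attention = isTRUE(nk$attention),
                       attention_channels = nk$attention_channels %||% 1L,
                       literal_subsample_variant =
                         isTRUE(nk$literal_subsample_variant)),
    lr = dt$lr %||% 0.02, epochs = dt$epochs %||% 5L,
    score_thresh = dt$score_thresh %||% 0.05,
    nms_thresh = dt$nms_thresh %||% 0.5)
}

#' Persist the fully resolved configuration beside a run's outputs
#'
#' @param rc a `run_config`
#' @param out_dir run output directory
#' @export
save_run_config <- function(rc, out_dir) {
  yaml::write_yaml(unclass(rc), file.path(out_dir, "config_resolved.yaml"))
  invisible(out_dir)
}
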