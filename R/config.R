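#' Default pipeline configuration
#'
#' A nested list mirroring every tunable of the pipeline: descriptor
#' core strings and ranges, junction-box consensus strings, annotation
#' spacings and bounds, fold weights, and simulator settings.  The
#' structure round-trips through YAML for use with the command-line
#' interface.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  d <- hhr_descriptor()
  b <- box_consensus()
  p <- annotate_params()
  list(
    descriptor = list(
      core_seg_A = d$core_seg_A, core_seg_B = d$core_seg_B,
      cleavage_context = d$cleavage_context, cut_adjacent = d$cut_adjacent,
      helix1 = d$helix1, helix2 = d$helix2, helix3 = d$helix3,
      loop = d$loop, max_wobbles = d$max_wobbles,
      topologies = d$topologies,
      min_tertiary_pairs = d$min_tertiary_pairs,
      tertiary_window = d$tertiary_window,
      tertiary_wobble = d$tertiary_wobble),
    boxes = list(box3 = b$box3, box5 = b$box5,
                 max_mismatches = b$max_mismatches,
                 search_window = b$search_window),
    annotate = unclass(p),
    fold = list(weights = c(GC = 3, AU = 2, GU = 1), min_loop = 3L),
    simulate = unclass(synthetic_spec()))
}

#' Read a YAML configuration
#'
#' Missing entries fall back to [default_config()].
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge2 <- function(b, u) {
    for (k in names(u)) {
      b[[k]] <- if (is.list(b[[k]]) && is.list(u[[k]])) {
        merge2(b[[k]], u[[k]])
      } else u[[k]]
    }
    b
  }
  merge2(base, user)
}

#' Write a configuration to YAML
#' @param config nested configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build pipeline objects from a configuration list
#' @param config nested configuration list.
#' @return list with `desc`, `boxes`, `params`, `spec`.
#' @export
config_objects <- function(config) {
  d <- config$descriptor
  list(
    desc = hhr_descriptor(
      core_seg_A = d$core_seg_A, core_seg_B = d$core_seg_B,
      cleavage_context = d$cleavage_context, cut_adjacent = d$cut_adjacent,
      helix1 = d$helix1, helix2 = d$helix2, helix3 = d$helix3,
      loop = d$loop, max_wobbles = d$max_wobbles,
      topologies = d$topologies,
      min_tertiary_pairs = d$min_tertiary_pairs,
      tertiary_window = d$tertiary_window,
      tertiary_wobble = d$tertiary_wobble),
    boxes = box_consensus(box3 = config$boxes$box3, box5 = config$boxes$box5,
                          max_mismatches = config$boxes$max_mismatches,
                          search_window = config$boxes$search_window),
    params = do.call(annotate_params, config$annotate),
    spec = do.call(synthetic_spec, config$simulate))
}
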