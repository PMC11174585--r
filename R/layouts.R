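# Skeleton layouts: named joint sets with rest pose, bone list, mirror map
# and partition defaults, loaded from the structured-text (YAML) layout
# schema. Users may point read_layout() at their own file with the same
# fields.

layout_registry <- new.env(parent = emptyenv())

#' Load a registered skeleton layout
#'
#' Layouts bundle everything the package needs to know about a pose
#' estimator's output: joint names and rest pose, bone edges, left/right
#' mirror pairs, the channel semantics (which coordinate is lateral /
#' vertical / walking direction), and the default half/limb partition.
#' `"kinect25"` (Kinect V2, 3D) and `"coco17"` (COCO keypoints, 2D) ship
#' with the package.
#'
#' @param name `"kinect25"` or `"coco17"`.
#' @return An `fpgait_layout` object; see [read_layout()] for fields.
#' @export
skeleton_layout <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    abort_config("layout name must be a single string")
  }
  if (!is.null(layout_registry[[name]])) {
    return(layout_registry[[name]])
  }
  path <- system.file("extdata", "layouts", paste0(name, ".yaml"),
                      package = "fpgait")
  if (path == "") {
    abort_config("unknown skeleton layout '%s' (no registered file)", name)
  }
  layout <- read_layout(path)
  layout_registry[[name]] <- layout
  layout
}

#' Read a skeleton layout from a YAML file
#'
#' @param path Path to a layout file following the schema of the shipped
#'   `extdata/layouts/*.yaml` files (see those files for field docs).
#' @return An `fpgait_layout`: list with `name`, `channels`,
#'   `lateral_channel`, `vertical_channel`, `forward_channel`,
#'   `fps_default`, `graph` (a [skeleton_graph()]), `pose` (C x V rest
#'   pose), `side`/`part`/`swing` per joint, `mirror_perm` (length-V 1-based
#'   permutation), `center_joints`, `torso_from`, `torso_to`,
#'   `measure_joints` and `partition`.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) abort_config("layout file '%s' not found", path)
  spec <- yaml::read_yaml(path)
  for (field in c("name", "channels", "joints", "edges", "partition")) {
    if (is.null(spec[[field]])) {
      abort_config("layout file '%s' is missing field '%s'", path, field)
    }
  }
  joints <- spec$joints
  V <- length(joints)
  ids <- vapply(joints, function(j) j$id, numeric(1))
  if (!identical(as.integer(ids), seq_len(V) - 1L)) {
    abort_config("layout joints must be listed with consecutive 0-based ids")
  }
  C <- length(spec$channels)
  pose <- vapply(joints, function(j) as.numeric(j$pose), numeric(C))
  graph <- skeleton_graph(
    do.call(rbind, lapply(spec$edges, as.integer)), V,
    joint_names = vapply(joints, function(j) j$name, character(1))
  )
  mirror_perm <- seq_len(V)
  for (pair in spec$mirror_pairs %||% list()) {
    mirror_perm[pair[1] + 1L] <- pair[2] + 1L
    mirror_perm[pair[2] + 1L] <- pair[1] + 1L
  }
  partition <- lapply(spec$partition, function(p) lapply(p, as.integer))
  structure(
    list(
      name = spec$name,
      channels = unlist(spec$channels),
      n_channels = C,
      lateral_channel = spec$lateral_channel %||% 1L,
      vertical_channel = spec$vertical_channel %||% 2L,
      forward_channel = spec$forward_channel %||% C,
      fps_default = spec$fps_default %||% 30,
      graph = graph,
      pose = pose,
      side = vapply(joints, function(j) j$side, character(1)),
      part = vapply(joints, function(j) j$part, character(1)),
      swing = vapply(joints, function(j) as.numeric(j$swing %||% 0), numeric(1)),
      mirror_perm = mirror_perm,
      center_joints = as.integer(spec$center_joints %||% 0L),
      torso_from = as.integer(spec$torso_from %||% 0L),
      torso_to = as.integer(spec$torso_to %||% 0L),
      measure_joints = lapply(spec$measure_joints %||% list(), as.integer),
      partition = partition
    ),
    class = "fpgait_layout"
  )
}

#' @export
print.fpgait_layout <- function(x, ...) {
  cat(sprintf(
    "<fpgait_layout> '%s': %d joints, %d channels (%s)\n",
    x$name, x$graph$n_joints, x$n_channels, paste(x$channels, collapse = ",")
  ))
  invisible(x)
}
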