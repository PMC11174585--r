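# Exchange formats: a JSON sequence archive (the package's native
# container: version field + header + payload, full-precision numbers, one
# layout per archive) and a long-format CSV dialect for interoperability;
# JSON model checkpoints; YAML run configuration.

ARCHIVE_FORMAT <- "fpgait-archive"
ARCHIVE_VERSION <- 1L
CHECKPOINT_FORMAT <- "fpgait-model"
CHECKPOINT_VERSION <- 1L

#' Write skeleton sequences to a JSON archive
#'
#' The archive stores a header (format, version, layout name, fps, tensor
#' shape, class map) and per-sequence payloads (flattened coordinate
#' tensors at full precision, labels, provenance seeds). All sequences in
#' one archive share one layout, fps and shape; reading the file back
#' reproduces the tensors bitwise.
#'
#' @param data A `gait_dataset` (or list of `skeleton_sequence` objects).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(data, path) {
  if (!inherits(data, "gait_dataset") && is.list(data) &&
      all(vapply(data, inherits, logical(1), "skeleton_sequence"))) {
    data <- sequences_to_dataset(data)
  }
  stopifnot(is.data.frame(data), "seq" %in% names(data))
  seqs <- data$seq
  d <- dim(seqs[[1]]$values)
  fps <- seqs[[1]]$fps
  layout <- seqs[[1]]$layout
  for (s in seqs) {
    if (!identical(dim(s$values), d) || s$fps != fps ||
        !identical(s$layout, layout)) {
      abort_validation("all sequences in one archive must share layout, fps and shape")
    }
  }
  class_map <- unique(tibble::tibble(class_id = data$class_id,
                                     class_name = data$class_name))
  obj <- list(
    format = ARCHIVE_FORMAT,
    version = ARCHIVE_VERSION,
    layout = layout,
    fps = fps,
    channels = d[1], frames = d[2], joints = d[3],
    class_map = class_map,
    sequences = lapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      list(sequence_id = data$sequence_id[i],
           class_id = data$class_id[i],
           class_name = data$class_name[i],
           subject_id = data$subject_id[i],
           seed = data$seed[i],
           values = I(sprintf("%.17g", s$values)))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON sequence archive
#'
#' @param path Archive path written by [write_sequences()].
#' @return A `gait_dataset` tibble.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) abort_parse("archive '%s' not found", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_parse("cannot parse archive '%s': %s", path,
                                conditionMessage(e))
                  })
  if (!identical(obj$format, ARCHIVE_FORMAT) || is.null(obj$version)) {
    abort_parse("'%s' is not a recognised sequence archive", path)
  }
  if (obj$version > ARCHIVE_VERSION) {
    abort_parse("archive version %s is newer than supported (%d)",
                obj$version, ARCHIVE_VERSION)
  }
  d <- c(obj$channels, obj$frames, obj$joints)
  seqs <- obj$sequences
  n <- if (is.data.frame(seqs)) nrow(seqs) else length(seqs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- if (is.data.frame(seqs)) lapply(seqs, function(col) {
      if (is.list(col)) col[[i]] else col[i]
    }) else seqs[[i]]
    vals <- as.numeric(rec$values)
    if (length(vals) != prod(d)) {
      abort_parse("sequence %d payload (%d values) does not match header shape %s",
                  i, length(vals), paste(d, collapse = "x"))
    }
    s <- structure(
      list(values = array(vals, d), fps = obj$fps, label = rec$class_id,
           class_name = rec$class_name, subject_id = rec$subject_id,
           layout = obj$layout,
           provenance = list(seed = rec$seed, source = path)),
      class = "skeleton_sequence")
    rows[[i]] <- tibble::tibble(
      sequence_id = rec$sequence_id, class_id = rec$class_id,
      class_name = rec$class_name, subject_id = rec$subject_id,
      seed = rec$seed %||% NA_integer_, seq = list(s))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "layout") <- obj$layout
  attr(out, "fps") <- obj$fps
  attr(out, "frames") <- obj$frames
  class(out) <- c("gait_dataset", class(out))
  out
}

sequences_to_dataset <- function(seqs) {
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    tibble::tibble(
      sequence_id = i, class_id = s$label %||% NA_integer_,
      class_name = s$class_name %||% NA_character_,
      subject_id = s$subject_id %||% NA_character_,
      seed = s$provenance$seed %||% NA_integer_, seq = list(s))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gait_dataset", class(out))
  out
}

#' Write sequences in the long CSV dialect
#'
#' One row per (sequence, frame, joint) with columns `sequence_id`,
#' `class_id`, `frame`, `joint` (both 0-based) and one column per
#' coordinate channel. Intended for interoperability; values are rounded
#' to `digits` significant digits.
#'
#' @param data A `gait_dataset`.
#' @param path Output CSV path.
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_sequences_csv <- function(data, path, digits = 10) {
  seqs <- data$seq
  layout <- skeleton_layout(seqs[[1]]$layout)
  chan <- layout$channels
  frames <- dim(seqs[[1]]$values)[2]
  V <- dim(seqs[[1]]$values)[3]
  tabs <- lapply(seq_along(seqs), function(i) {
    v <- seqs[[i]]$values
    df <- data.frame(
      sequence_id = data$sequence_id[i],
      class_id = data$class_id[i],
      frame = rep(seq_len(frames) - 1L, times = V),
      joint = rep(seq_len(V) - 1L, each = frames)
    )
    for (c in seq_along(chan)) {
      df[[chan[c]]] <- signif(as.numeric(v[c, , ]), digits)
    }
    df
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read sequences from the long CSV dialect
#'
#' @param path CSV path written by [write_sequences_csv()].
#' @param layout Layout name of the archived skeletons.
#' @param fps Frame rate to attach.
#' @return A `gait_dataset`.
#' @export
read_sequences_csv <- function(path, layout = "kinect25", fps = 30) {
  if (!file.exists(path)) abort_parse("CSV file '%s' not found", path)
  df <- utils::read.csv(path)
  lay <- skeleton_layout(layout)
  chan <- lay$channels
  need <- c("sequence_id", "class_id", "frame", "joint", chan)
  if (!all(need %in% names(df))) {
    abort_parse("CSV is missing columns: %s",
                paste(setdiff(need, names(df)), collapse = ", "))
  }
  rows <- list()
  for (sid in unique(df$sequence_id)) {
    sub <- df[df$sequence_id == sid, ]
    frames <- max(sub$frame) + 1L
    V <- max(sub$joint) + 1L
    if (nrow(sub) != frames * V) {
      abort_parse("sequence %s has an incomplete frame/joint grid", sid)
    }
    v <- array(0, c(length(chan), frames, V))
    ord <- order(sub$joint, sub$frame)
    sub <- sub[ord, ]
    for (c in seq_along(chan)) v[c, , ] <- sub[[chan[c]]]
    s <- structure(
      list(values = v, fps = fps, label = sub$class_id[1],
           class_name = NA_character_, subject_id = NA_character_,
           layout = layout, provenance = list(source = path)),
      class = "skeleton_sequence")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sequence_id = sid, class_id = sub$class_id[1],
      class_name = NA_character_, subject_id = NA_character_,
      seed = NA_integer_, seq = list(s))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "layout") <- layout
  attr(out, "fps") <- fps
  class(out) <- c("gait_dataset", class(out))
  out
}

# ---------------------------------------------------------------------------
# model checkpoints

#' Save a model or fit as a JSON checkpoint
#'
#' Stores a version field, the model configuration and every parameter
#' array (with its dimensions) at full precision.
#'
#' @param model An `fpgcn_model` or `fpgcn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  fit_meta <- NULL
  if (inherits(model, "fpgcn_fit")) {
    fit_meta <- list(best_epoch = model$best_epoch,
                     normalize = model$normalize, detrend = model$detrend)
    model <- model$model
  }
  stopifnot(inherits(model, "fpgcn_model"))
  cfg <- model$config
  if (is.null(cfg$layout)) {
    abort_config("only layout-based models can be checkpointed")
  }
  flat <- list()
  walk <- function(x, path_) {
    if (is.list(x)) {
      for (j in seq_along(x)) {
        if (is.null(x[[j]])) next
        nm <- names(x)[j] %||% ""
        walk(x[[j]], c(path_, if (nzchar(nm)) nm else as.character(j)))
      }
    } else {
      flat[[paste(path_, collapse = "/")]] <<-
        list(dim = dim(x) %||% length(x),
             values = I(sprintf("%.17g", x)))
    }
  }
  walk(model$params, character(0))
  obj <- list(
    format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
    config = list(layout = cfg$layout, n_classes = cfg$n_classes,
                  frames = cfg$frames, channels_in = cfg$channels_in,
                  widths = cfg$widths, depth = cfg$depth,
                  variant = cfg$variant, slope = cfg$slope,
                  epsilon = cfg$epsilon, tcn_stride = cfg$tcn_stride),
    bn_running = model$bn_running,
    fit = fit_meta,
    params = flat
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON model checkpoint
#'
#' @param path Checkpoint written by [save_model()].
#' @return An `fpgcn_model` (or, when the checkpoint came from a fit, an
#'   `fpgcn_fit` wrapper usable with [predict.fpgcn_fit()]).
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort_parse("checkpoint '%s' not found", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_parse("cannot parse checkpoint '%s'", path)
                  })
  if (!identical(obj$format, CHECKPOINT_FORMAT)) {
    abort_parse("'%s' is not a model checkpoint", path)
  }
  if (obj$version > CHECKPOINT_VERSION) {
    abort_parse("checkpoint version %s is newer than supported", obj$version)
  }
  cc <- obj$config
  cfg <- model_config(layout = cc$layout, n_classes = cc$n_classes,
                      frames = cc$frames, channels_in = cc$channels_in,
                      widths = cc$widths, depth = cc$depth,
                      variant = cc$variant, slope = cc$slope,
                      epsilon = cc$epsilon, tcn_stride = cc$tcn_stride)
  model <- fpgcn_init(cfg, seed = 1L)
  for (key in names(obj$params)) {
    rec <- obj$params[[key]]
    val <- as.numeric(rec$values)
    if (length(rec$dim) > 1L) dim(val) <- rec$dim
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    model$params <- assign_path(model$params, parts, val)
  }
  model$bn_running <- list(mean = as.numeric(obj$bn_running$mean),
                           var = as.numeric(obj$bn_running$var))
  if (!is.null(obj$fit)) {
    return(structure(
      list(model = model, history = NULL,
           best_epoch = obj$fit$best_epoch,
           normalize = obj$fit$normalize %||% TRUE,
           detrend = obj$fit$detrend %||% TRUE,
           train_config = NULL),
      class = "fpgcn_fit"))
  }
  model
}

assign_path <- function(lst, parts, val) {
  key <- parts[1]
  idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
  if (length(parts) == 1L) {
    stopifnot(length(lst[[idx]]) == length(val))
    lst[[idx]] <- val
  } else {
    lst[[idx]] <- assign_path(lst[[idx]], parts[-1], val)
  }
  lst
}

# ---------------------------------------------------------------------------
# run configuration

#' Read a model + training configuration from YAML
#'
#' The file has two sections. `model`: layout, n_classes, frames, widths,
#' depth, variant, slope, epsilon, tcn_stride. `train`: learning_rate,
#' momentum, epochs, batch_size, split_ratio, label_smoothing, normalize,
#' detrend, seed. Omitted fields take the package defaults; there are no
#' configuration knobs outside this schema.
#'
#' @param path YAML file path.
#' @return List with `model` (an `fpgcn_config`) and `train` (an
#'   `fpgait_train_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config("config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$model)) abort_config("config is missing the 'model' section")
  mc <- y$model
  for (field in c("n_classes", "frames")) {
    if (is.null(mc[[field]])) {
      abort_config("config field 'model.%s' is required", field)
    }
  }
  model <- model_config(
    layout = mc$layout %||% "kinect25", n_classes = mc$n_classes,
    frames = mc$frames, channels_in = mc$channels_in,
    widths = unlist(mc$widths %||% c(64, 48, 32)), depth = mc$depth %||% 2,
    variant = mc$variant %||% "fpgcn", slope = mc$slope %||% 0.01,
    epsilon = mc$epsilon %||% 0.1, tcn_stride = mc$tcn_stride %||% 5)
  tc <- y$train %||% list()
  train <- train_config(
    learning_rate = tc$learning_rate %||% 1e-4,
    momentum = tc$momentum %||% 0.9, epochs = tc$epochs %||% 30,
    batch_size = tc$batch_size %||% 16,
    split_ratio = unlist(tc$split_ratio %||% c(8, 1, 1)),
    label_smoothing = tc$label_smoothing %||% 0.1,
    normalize = tc$normalize %||% TRUE, detrend = tc$detrend %||% TRUE,
    seed = tc$seed %||% 1L)
  list(model = model, train = train)
}
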