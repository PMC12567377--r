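# On-disk formats.
#
# EEG clips are stored as raw little-endian float64 (`.bin`, channels x
# samples, column-major) next to a JSON sidecar carrying the recording
# metadata; face frames are PNG; the manifest is CSV; configurations are
# JSON.  Feature tensors (differential entropy and topographic stacks) use
# the same bin+JSON container with their dimensions and provenance
# attributes (band edges, montage hash, clamp floor, producing config
# hash) in the sidecar.

write_array_bin <- function(x, path, attrs = list()) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(as.numeric(x)), con, size = 8, endian = "little")
  meta <- c(list(dim = dim(x) %||% length(x), storage = "float64-le"), attrs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 12)
  invisible(path)
}

read_array_bin <- function(path) {
  jf <- paste0(path, ".json"); bf <- paste0(path, ".bin")
  abort_if(!file.exists(jf), "missing sidecar: ", jf)
  abort_if(!file.exists(bf), "missing binary file: ", bf)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  n_expect <- prod(meta$dim)
  sz <- file.info(bf)$size
  abort_if(sz != 8 * n_expect, "truncated or corrupt array file ", bf,
           " (", sz, " bytes, expected ", 8 * n_expect, ")")
  con <- file(bf, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
  dim(x) <- meta$dim
  list(data = x, meta = meta)
}

#' Write a feature tensor with provenance attributes
#'
#' @param x Numeric array (e.g. windows x channels x bands DE tensor, or
#'   windows x size x size x 5 topographic stacks).
#' @param path Output path prefix (writes `path.bin` + `path.json`).
#' @param attrs Named list of attributes (band edges, montage hash, clamp
#'   floor, config hash, ...).
#' @return Invisibly, `path`.
#' @export
write_features <- function(x, path, attrs = list()) {
  write_array_bin(x, path, attrs)
}

#' Read a feature tensor, checking attributes
#'
#' @param path Path prefix as given to [write_features()].
#' @param expect Named list of attribute values to verify; mismatches
#'   raise a warning with details.
#' @return List with `data` (array) and `meta` (attributes).
#' @export
read_features <- function(path, expect = NULL) {
  out <- read_array_bin(path)
  for (nm in names(expect)) {
    got <- out$meta[[nm]]
    if (!isTRUE(all.equal(got, expect[[nm]], tolerance = 1e-9))) {
      warning("feature attribute mismatch for '", nm, "': stored ",
              paste(got, collapse = ","), ", expected ",
              paste(expect[[nm]], collapse = ","))
    }
  }
  out
}

#' Write a synthetic dataset to a directory tree
#'
#' Layout: `config.json`, `montage.csv`, `manifest.csv` (columns subject,
#' clip, emotion, window, eeg_path, frame_path), `eeg/*.bin(+json)` per
#' clip, `frames/*.png` per window.
#'
#' @param ds A `synth_dataset`.
#' @param dir Output directory (created).
#' @param layout Electrode layout to store alongside.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir, layout = default_layout()) {
  dir.create(file.path(dir, "eeg"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "frames"), showWarnings = FALSE)
  jsonlite::write_json(c(unclass(ds$config), list(config_hash = ds$config_hash)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = 12)
  write_layout(layout, file.path(dir, "montage.csv"))
  rows <- list()
  for (rec in ds$eeg) {
    stem <- sprintf("eeg/s%02d_c%02d", rec$subject_id, rec$clip_id)
    write_array_bin(rec$data, file.path(dir, stem),
                    attrs = list(sample_rate = rec$sample_rate,
                                 channel_names = rec$channel_names,
                                 subject = rec$subject_id,
                                 clip = rec$clip_id, emotion = rec$emotion,
                                 config_hash = ds$config_hash))
  }
  frame_path <- character(length(ds$faces))
  for (i in seq_along(ds$faces)) {
    f <- ds$faces[[i]]
    frame_path[i] <- sprintf("frames/s%02d_c%02d_w%03d.png",
                             f$subject_id, f$clip_id, f$window)
    png::writePNG(f$pixels, file.path(dir, frame_path[i]))
  }
  key <- paste(vapply(ds$faces, function(f) f$subject_id, 1),
               vapply(ds$faces, function(f) f$clip_id, 1),
               vapply(ds$faces, function(f) f$window, 1))
  man <- ds$manifest
  man$eeg_path <- sprintf("eeg/s%02d_c%02d.bin", man$subject, man$clip)
  man$frame_path <- frame_path[match(paste(man$subject, man$clip, man$window),
                                     key)]
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Read and validate a dataset from a manifest
#'
#' Schema violations (missing file, unknown emotion, duplicate
#' subject/clip/window key) are reported with the offending row number or
#' path.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return List with `eeg` (recordings), `faces` (frames), `labels`,
#'   `manifest`, `config` (if `config.json` is present).
#' @export
read_dataset <- function(manifest_path) {
  abort_if(!file.exists(manifest_path), "manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject", "clip", "emotion", "window", "eeg_path", "frame_path")
  abort_if(!all(need %in% names(man)), "manifest must have columns ",
           paste(need, collapse = ","))
  bad_emo <- which(!man$emotion %in% EMOTIONS)
  abort_if(length(bad_emo) > 0, "unknown emotion '", man$emotion[bad_emo[1]],
           "' at manifest row ", bad_emo[1])
  key <- paste(man$subject, man$clip, man$window)
  dup <- which(duplicated(key))
  abort_if(length(dup) > 0, "duplicate (subject, clip, window) key at row ",
           dup[1])
  for (i in seq_len(nrow(man))) {
    fp <- file.path(root, man$frame_path[i])
    abort_if(!file.exists(fp), "missing frame file: ", fp,
             " (manifest row ", i, ")")
  }
  clips <- unique(man[, c("subject", "clip", "emotion", "eeg_path")])
  eeg <- vector("list", nrow(clips))
  for (i in seq_len(nrow(clips))) {
    stem <- file.path(root, sub("\\.bin$", "", clips$eeg_path[i]))
    abort_if(!file.exists(paste0(stem, ".bin")),
             "missing EEG file: ", paste0(stem, ".bin"))
    arr <- read_array_bin(stem)
    eeg[[i]] <- eeg_recording(arr$data, arr$meta$sample_rate,
                              arr$meta$channel_names,
                              subject_id = clips$subject[i],
                              clip_id = clips$clip[i],
                              emotion = clips$emotion[i])
  }
  faces <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    px <- png::readPNG(file.path(root, man$frame_path[i]))
    faces[[i]] <- face_frame(px, subject_id = man$subject[i],
                             clip_id = man$clip[i], window = man$window[i])
  }
  cfgf <- file.path(root, "config.json")
  config <- if (file.exists(cfgf)) jsonlite::read_json(cfgf, simplifyVector = TRUE)
  labels <- unique(man[, c("subject", "clip", "emotion")])
  list(eeg = eeg, faces = faces, labels = labels,
       manifest = man[, c("subject", "clip", "emotion", "window")],
       config = config)
}

#' Hash of an electrode layout (ties features to their montage)
#'
#' @param layout An `electrode_layout`.
#' @return md5 string.
#' @export
montage_hash <- function(layout) {
  config_hash(list(names = layout$names, coords = round(layout$coords, 10)))
}

# ---------------------------------------------------------------------------
# Checkpoints

#' Save a trained model checkpoint
#'
#' All trainable parameters and normalization statistics are concatenated
#' into one raw float64 file; the JSON sidecar embeds the method, the model
#' configuration, and the per-array layout, so the checkpoint is fully
#' self-describing.
#'
#' @param model An `mmha_model`.
#' @param path Output path prefix.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  layers <- model_layers(model$network)
  chunks <- list()
  spec <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (pn in names(l$par)) {
      chunks[[length(chunks) + 1]] <- as.numeric(l$par[[pn]])
      spec[[length(spec) + 1]] <- list(layer = i, name = pn,
                                       dim = dim(l$par[[pn]]) %||%
                                         length(l$par[[pn]]))
    }
    for (sn in names(l$state %||% list())) {
      chunks[[length(chunks) + 1]] <- as.numeric(l$state[[sn]])
      spec[[length(spec) + 1]] <- list(layer = i, name = paste0("state.", sn),
                                       dim = length(l$state[[sn]]))
    }
  }
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(unlist(chunks), con, size = 8, endian = "little")
  jsonlite::write_json(list(method = model$method, cfg = unclass(model$cfg),
                            seed = model$seed, layout = spec,
                            storage = "float64-le"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path prefix as given to [save_checkpoint()].
#' @return An `mmha_model` with restored parameters (untrained history).
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  cfg <- do.call(model_config, lapply(meta$cfg, function(x)
    if (is.list(x)) lapply(x, function(y) unlist(y)) else unlist(x)))
  net <- build_model_for_method(meta$method, cfg, seed = meta$seed %||% 1)
  layers <- model_layers(net)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con), add = TRUE)
  for (sp in meta$layout) {
    d <- unlist(sp$dim)
    n <- prod(d)
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
    l <- layers[[sp$layer]]
    if (startsWith(sp$name, "state.")) {
      l$state[[sub("^state\\.", "", sp$name)]] <- vals
    } else {
      if (length(d) > 1) dim(vals) <- d
      l$par[[sp$name]] <- vals
    }
  }
  structure(list(network = net, method = meta$method, cfg = cfg,
                 history = data.frame(), epochs = 0, batch_size = NA,
                 lr = NA, optimizer = NA, seed = meta$seed %||% 1,
                 n_train = NA),
            class = "mmha_model")
}
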