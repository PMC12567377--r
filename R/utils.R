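#' @keywords internal
"_PACKAGE"

#' Canonical emotion labels
#'
#' The fixed four-class label set, in the order used for class indices
#' 1..4 throughout the package.
#' @export
EMOTIONS <- c("happy", "sad", "fear", "calm")

# Canonical EEG band table: delta, theta, alpha, beta, gamma.
BAND_NAMES <- c("delta", "theta", "alpha", "beta", "gamma")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(paste0(...), call. = FALSE)
}

#' Default EEG frequency bands
#'
#' The five canonical bands used for differential-entropy extraction:
#' delta (1-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), beta (12-30 Hz) and
#' gamma (30-50 Hz).
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name = BAND_NAMES,
    lo = c(1, 4, 8, 12, 30),
    hi = c(4, 8, 12, 30, 50),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands, sample_rate = NULL) {
  abort_if(!is.data.frame(bands) || !all(c("name", "lo", "hi") %in% names(bands)),
           "bands must be a data.frame with columns name, lo, hi")
  abort_if(any(bands$lo <= 0) || any(bands$hi <= bands$lo),
           "band edges must satisfy 0 < lo < hi")
  if (!is.null(sample_rate)) {
    abort_if(any(bands$hi >= sample_rate / 2),
             "band upper edge at or above Nyquist frequency (",
             sample_rate / 2, " Hz)")
  }
  invisible(bands)
}

#' Hash an R object via canonical JSON
#'
#' Stable content hash used to tie on-disk artifacts to the configuration
#' that produced them.
#'
#' @param x A JSON-serializable R object.
#' @return A 32-character md5 string.
#' @export
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(f))
}

# Evaluate `code` under a temporarily-set RNG seed, restoring RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Structured JSON-lines run log. Every event carries the producing config
# hash and seed so results are traceable.
#' Append a structured event to a JSON-lines run log
#'
#' @param path Log file path (created if missing).
#' @param event Short event name.
#' @param ... Named fields stored with the event.
#' @return Invisibly, the event record.
#' @export
log_event <- function(path, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), event = event),
           list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10, null = "null")
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(rec)
}
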