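#' Gaze recordings and EEG recordings
#'
#' A gaze recording is a tibble with one row per eye-tracking sample and a
#' fixed column schema: `t` (seconds on the eye-tracking clock), the 3-vector
#' triples `eye_x/eye_y/eye_z` (eye origin, world units),
#' `dir_x/dir_y/dir_z` (allocentric viewing direction),
#' `head_x/head_y/head_z` (head position), `hdir_x/hdir_y/hdir_z` (head
#' direction), `hit_x/hit_y/hit_z` (gaze-ray hit point, `NA` when the ray hit
#' nothing), `hit_object` (identifier of the hit surface, `NA` when absent),
#' `valid` (logical) and `provenance` (`"measured"`, `"interpolated"` for
#' gap-filled samples, or `"timestamp_interpolated"` for stamps inserted to
#' repair dropped frames). The nominal sampling rate travels in the
#' `nominal_rate` attribute.
#'
#' @param samples data frame holding the columns above (missing optional
#'   columns are added as `NA`).
#' @param nominal_rate nominal sampling rate in Hz (e.g. 90 for a VR headset).
#' @param meta optional named list of free-form metadata.
#'
#' @return A tibble of class `gaze_rec`.
#' @export
gaze_recording <- function(samples, nominal_rate = 90, meta = list()) {
  if (nominal_rate <= 0) abort("`nominal_rate` must be positive.", class = "vrgaze_config_error")
  samples <- as_tibble(samples)
  if (!"t" %in% names(samples)) abort("column `t` is required.", class = "vrgaze_schema_error")
  need <- c(paste0("eye_", c("x", "y", "z")), paste0("dir_", c("x", "y", "z")))
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("missing required columns: ", paste(miss, collapse = ", ")),
          class = "vrgaze_schema_error")
  }
  opt_num <- c(paste0("head_", c("x", "y", "z")), paste0("hdir_", c("x", "y", "z")),
               paste0("hit_", c("x", "y", "z")))
  for (col in opt_num) if (!col %in% names(samples)) samples[[col]] <- NA_real_
  if (!"hit_object" %in% names(samples)) samples$hit_object <- NA_character_
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  if (!"provenance" %in% names(samples)) samples$provenance <- "measured"
  if (!all(is.finite(samples$t))) abort("timestamps must be finite.", class = "vrgaze_data_error")
  bad <- which(diff(samples$t) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("timestamps must be strictly increasing; first violation at row %d.", bad[1] + 1),
          class = "vrgaze_data_error")
  }
  # a hit object without a hit point is inconsistent
  no_point <- is.na(samples$hit_x)
  samples$hit_object[no_point] <- NA_character_
  out <- samples[, c("t", paste0("eye_", c("x", "y", "z")), paste0("dir_", c("x", "y", "z")),
                     opt_num, "hit_object", "valid", "provenance",
                     setdiff(names(samples), c("t", need, opt_num, "hit_object", "valid", "provenance")))]
  structure(out, nominal_rate = nominal_rate, meta = meta,
            class = c("gaze_rec", class(out)))
}

#' @rdname gaze_recording
#' @param rec a gaze recording.
#' @export
et_rate <- function(rec) attr(rec, "nominal_rate") %||% 90

# Rebuild the class/attributes after dplyr verbs stripped them.
restore_rec <- function(new, old) {
  structure(as_tibble(new),
            nominal_rate = attr(old, "nominal_rate"),
            meta = attr(old, "meta"),
            class = c("gaze_rec", class(as_tibble(new))))
}

#' Read a gaze sample table from delimited text
#'
#' Reads a raw eye-tracking export (one row per sample, header row) into a
#' [gaze_recording()]. Because raw column layouts vary between recording
#' setups, a `column_map` names the file columns that carry each field.
#'
#' @param path file path.
#' @param column_map named list mapping fields to file column names. Required
#'   entries: `t` (one name), `eye_origin`, `eye_dir` (three names each,
#'   x/y/z order). Optional: `head_pos`, `head_dir`, `hit_point` (three names
#'   each), `hit_object`, `valid` (one name each).
#' @param delim field delimiter (default tab).
#' @param nominal_rate nominal sampling rate in Hz.
#'
#' @return A `gaze_rec` tibble.
#' @export
read_gaze_table <- function(path, column_map, delim = "\t", nominal_rate = 90) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  pick <- function(field, n) {
    cols <- column_map[[field]]
    if (is.null(cols)) return(NULL)
    if (length(cols) != n) {
      abort(sprintf("column_map$%s must name %d column(s).", field, n),
            class = "vrgaze_schema_error")
    }
    miss <- setdiff(cols, names(raw))
    if (length(miss) > 0) {
      abort(sprintf("file lacks column(s) %s mapped to field `%s`.",
                    paste(miss, collapse = ", "), field),
            class = "vrgaze_schema_error")
    }
    raw[, cols, drop = FALSE]
  }
  for (req in c("t", "eye_origin", "eye_dir")) {
    if (is.null(column_map[[req]])) {
      abort(sprintf("column_map must include `%s`.", req), class = "vrgaze_schema_error")
    }
  }
  out <- tibble(t = as.numeric(pick("t", 1)[[1]]))
  put3 <- function(out, field, prefix) {
    m <- pick(field, 3)
    if (is.null(m)) return(out)
    out[[paste0(prefix, "_x")]] <- as.numeric(m[[1]])
    out[[paste0(prefix, "_y")]] <- as.numeric(m[[2]])
    out[[paste0(prefix, "_z")]] <- as.numeric(m[[3]])
    out
  }
  out <- put3(out, "eye_origin", "eye")
  out <- put3(out, "eye_dir", "dir")
  out <- put3(out, "head_pos", "head")
  out <- put3(out, "head_dir", "hdir")
  out <- put3(out, "hit_point", "hit")
  ho <- pick("hit_object", 1)
  if (!is.null(ho)) {
    out$hit_object <- as.character(ho[[1]])
    out$hit_object[!is.na(out$hit_object) & out$hit_object == ""] <- NA_character_
  }
  vl <- pick("valid", 1)
  if (!is.null(vl)) out$valid <- parse_bool(vl[[1]])
  gaze_recording(out, nominal_rate = nominal_rate,
                 meta = list(source = path))
}

parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

#' Renormalize direction vectors to unit length
#'
#' Direction vectors exported by VR engines are often slightly off unit
#' length due to rounding in the runtime; they are recomputed and normalized
#' offline. Zero-norm (or non-finite) directions cannot be normalized and
#' mark their sample invalid instead.
#'
#' @param rec a gaze recording.
#' @return The recording with unit-norm `dir_*` and `hdir_*` columns.
#' @export
renormalize_directions <- function(rec) {
  d <- unitize(vec3(rec, "dir"))
  rec <- set_vec3(rec, "dir", d)
  bad <- attr(d, "zero") & !is.na(rec$dir_x)
  h_present <- !is.na(rec$hdir_x)
  if (any(h_present)) {
    h <- unitize(vec3(rec, "hdir"))
    rec <- set_vec3(rec, "hdir", h)
    bad <- bad | (attr(h, "zero") & h_present)
  }
  # zero-norm eye directions can also arise in the raw export: flag them too
  bad <- bad | is.na(rec$dir_x)
  rec$valid <- rec$valid & !bad
  rec
}

# -- event tables -------------------------------------------------------

event_cols <- c("kind", "t_on", "t_off", "duration_s", "peak_vel_dps",
                "amplitude_deg", "centroid_x", "centroid_y", "centroid_z",
                "hit_object")

new_event_seq <- function(df, recording_id = NA_character_) {
  df <- as_tibble(df)
  for (col in setdiff(event_cols, names(df))) {
    df[[col]] <- if (col %in% c("kind", "hit_object")) NA_character_ else NA_real_
  }
  df <- df[, c(event_cols, setdiff(names(df), event_cols))]
  structure(df, recording_id = recording_id,
            class = c("event_seq", class(df)))
}

#' Write / read a classified event table
#'
#' One row per oculomotor event with the fixed header `kind, t_on, t_off,
#' duration_s, peak_vel_dps, amplitude_deg, centroid_x, centroid_y,
#' centroid_z, hit_object`. The pair round-trips losslessly (full double
#' precision is written).
#'
#' @param seq an event sequence tibble (from [classify_gaze()] and friends).
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an event sequence tibble.
#' @export
write_events <- function(seq, path) {
  out <- as_tibble(seq)[, event_cols]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          kind = readr::col_character(),
                          hit_object = readr::col_character(),
                          .default = readr::col_double()))
  miss <- setdiff(event_cols, names(df))
  if (length(miss) > 0) {
    abort(paste0("event table lacks columns: ", paste(miss, collapse = ", ")),
          class = "vrgaze_schema_error")
  }
  new_event_seq(df)
}

# -- EEG ----------------------------------------------------------------

#' EEG recording container
#'
#' A light container for a continuous EEG segment: a channels x time numeric
#' matrix in microvolts, its sampling rate, the start time on the EEG clock,
#' and channel names.
#'
#' @param data channels x time numeric matrix (µV).
#' @param rate sampling rate in Hz.
#' @param start_t start time in seconds on the EEG clock.
#' @param channels character vector of channel names (row names).
#'
#' @return An object of class `eeg_rec`.
#' @export
eeg_recording <- function(data, rate, start_t = 0, channels = NULL) {
  data <- as.matrix(data)
  if (rate <= 0) abort("`rate` must be positive.", class = "vrgaze_config_error")
  if (is.null(channels)) channels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  if (length(channels) != nrow(data)) {
    abort("number of channel names must equal the matrix row count.",
          class = "vrgaze_data_error")
  }
  rownames(data) <- channels
  structure(list(data = data, rate = rate, start_t = start_t, channels = channels),
            class = "eeg_rec")
}

#' @export
print.eeg_rec <- function(x, ...) {
  cat(sprintf("<eeg_rec> %d channel(s) x %d samples @ %g Hz (%.3f s), start_t = %g s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate, x$start_t))
  invisible(x)
}

#' Read an EEG matrix from delimited text
#'
#' @param path delimited numeric file, no header; orientation says whether
#'   rows are channels or samples.
#' @param rate sampling rate in Hz.
#' @param start_t start time on the EEG clock, seconds.
#' @param channels optional channel names.
#' @param orientation `"channels_rows"` (default) or `"samples_rows"`.
#' @param delim field delimiter.
#' @return An [eeg_recording()].
#' @export
read_eeg_matrix <- function(path, rate, start_t = 0, channels = NULL,
                            orientation = c("channels_rows", "samples_rows"),
                            delim = "\t") {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("EEG file is empty.", class = "vrgaze_data_error")
  rows <- strsplit(lines, delim, fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    abort(sprintf("ragged EEG matrix: rows have %s fields.",
                  paste(sort(unique(lens)), collapse = "/")),
          class = "vrgaze_data_error")
  }
  m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (anyNA(m)) abort("non-numeric entries in EEG matrix.", class = "vrgaze_data_error")
  if (orientation == "samples_rows") m <- t(m)
  eeg_recording(m, rate = rate, start_t = start_t, channels = channels)
}

#' Write an EEG matrix as delimited text
#'
#' @param eeg an [eeg_recording()].
#' @param path file path.
#' @param delim field delimiter.
#' @export
write_eeg_matrix <- function(eeg, path, delim = "\t") {
  utils::write.table(eeg$data, path, sep = delim, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Long-format view of an EEG recording
#'
#' @param x an `eeg_rec`.
#' @param ... unused.
#' @return A tibble with columns `channel`, `t` (EEG clock) and `uv`.
#' @exportS3Method generics::tidy
tidy.eeg_rec <- function(x, ...) {
  nt <- ncol(x$data)
  tibble(channel = rep(x$channels, each = nt),
         t = rep(x$start_t + (seq_len(nt) - 1) / x$rate, times = nrow(x$data)),
         uv = as.vector(t(x$data)))
}
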