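VALID_TASKS <- paste0("T", 0:15)
VALID_PAL <- c("sedentary", "light", "moderate", "heavy", "athlete")
SESSION_SCHEMA <- "cogscreen-session/1"

#' Subject profile
#'
#' Demographic and anthropometric data for one subject: the inputs of the
#' basal-metabolic-rate and energy-balance computations, plus the ground
#' truth class label when known.
#'
#' @param subject_id opaque subject identifier (string).
#' @param gender `"man"` or `"woman"`.
#' @param age_years age in whole years, positive.
#' @param height_m height in metres (0.5 to 2.5).
#' @param weight_kg body weight in kilograms, positive.
#' @param pal physical activity level: one of `"sedentary"`, `"light"`,
#'   `"moderate"`, `"heavy"`, `"athlete"`.
#' @param body_fat_pct optional body fat percentage (collected, unused by
#'   the energy equations).
#' @param label optional ground truth: 0 = healthy, 1 = impaired.
#' @return an object of class `cogscreen_profile`.
#' @export
subject_profile <- function(subject_id, gender, age_years, height_m, weight_kg,
                            pal = "sedentary", body_fat_pct = NULL, label = NA) {
  gender <- match.arg(gender, c("man", "woman"))
  pal <- match.arg(pal, VALID_PAL)
  stopifnot_scalar_num(age_years, "age_years")
  stopifnot_scalar_num(height_m, "height_m")
  stopifnot_scalar_num(weight_kg, "weight_kg")
  if (age_years <= 0) abort_domain("age_years must be positive")
  if (height_m <= 0.5 || height_m >= 2.5) abort_domain("height_m out of range (0.5, 2.5)")
  if (weight_kg <= 0) abort_domain("weight_kg must be positive")
  if (!is.na(label) && !label %in% c(0, 1)) abort_validation("label must be 0, 1 or NA")
  structure(list(
    subject_id = as.character(subject_id), gender = gender,
    age_years = as.integer(age_years), height_m = as.numeric(height_m),
    weight_kg = as.numeric(weight_kg), pal = pal,
    body_fat_pct = if (is.null(body_fat_pct)) NULL else as.numeric(body_fat_pct),
    label = if (is.na(label)) NA_integer_ else as.integer(label)
  ), class = "cogscreen_profile")
}

#' Touch trajectory
#'
#' One continuous finger stroke: timestamped screen coordinates in pixels
#' (origin top-left, y increases downward — the Android convention).
#'
#' @param t_ms integer milliseconds since task start, non-decreasing.
#' @param x_px,y_px screen coordinates in pixels.
#' @param pointer_id pointer index (multi-touch); recycled.
#' @param pressure optional touch pressure in `[0, 1]`; recycled.
#' @return a tibble of class `cogscreen_trajectory` with one row per event.
#' @export
touch_trajectory <- function(t_ms, x_px, y_px, pointer_id = 0L, pressure = NA_real_) {
  n <- length(t_ms)
  if (n < 1L) abort_domain("a trajectory needs at least one event")
  if (length(x_px) != n || length(y_px) != n)
    abort_validation("t_ms, x_px, y_px must have equal length")
  if (any(t_ms < 0)) abort_domain("t_ms must be >= 0")
  if (is.unsorted(t_ms)) abort_domain("t_ms must be non-decreasing")
  out <- tibble::tibble(
    t_ms = as.numeric(t_ms), x_px = as.numeric(x_px), y_px = as.numeric(y_px),
    pointer_id = rep_len(as.integer(pointer_id), n),
    pressure = rep_len(as.numeric(pressure), n)
  )
  class(out) <- c("cogscreen_trajectory", class(out))
  out
}

is_trajectory <- function(x) inherits(x, "cogscreen_trajectory")

#' Graph layout
#'
#' Node positions (and optional text labels) plus an undirected edge set,
#' as displayed in the construction / trail-making / problem-solving tasks.
#'
#' @param nodes data frame with columns `node_id`, `x_px`, `y_px` and
#'   optionally `label`.
#' @param edges two-column matrix or data frame of node id pairs (undirected,
#'   no self loops); may have zero rows.
#' @param node_radius_px radius of the drawn node circle, used as the
#'   default hit radius.
#' @return an object of class `cogscreen_layout`.
#' @export
graph_layout <- function(nodes, edges = NULL, node_radius_px = 40) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("node_id", "x_px", "y_px") %in% names(nodes)))
    abort_validation("nodes needs columns node_id, x_px, y_px")
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) abort_validation("node ids must be unique")
  if (!"label" %in% names(nodes)) nodes$label <- nodes$node_id
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges <- tibble::tibble(from = as.character(edges[[1]]), to = as.character(edges[[2]]))
  }
  if (any(edges$from == edges$to)) abort_validation("self-loop edges are not allowed")
  if (!all(c(edges$from, edges$to) %in% nodes$node_id))
    abort_validation("edge endpoint not present among nodes")
  # canonical undirected representation: from < to, unique
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::distinct(edges)
  structure(list(nodes = nodes, edges = edges,
                 node_radius_px = as.numeric(node_radius_px)),
            class = "cogscreen_layout")
}

has_edge <- function(layout, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  any(layout$edges$from == lo & layout$edges$to == hi)
}

add_edge <- function(layout, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  if (!has_edge(layout, lo, hi))
    layout$edges <- dplyr::bind_rows(layout$edges, tibble::tibble(from = lo, to = hi))
  layout
}

remove_edge <- function(layout, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  layout$edges <- layout$edges[!(layout$edges$from == lo & layout$edges$to == hi), ]
  layout
}

#' Graph action log
#'
#' Ordered subject actions against a node layout: free-drawn strokes and
#' single node touches, each timestamped.
#'
#' @param actions list of actions, each created by [stroke_action()] or
#'   [node_touch_action()].
#' @return an object of class `cogscreen_action_log`.
#' @export
graph_action_log <- function(actions = list()) {
  ts <- vapply(actions, function(a) a$t_ms, numeric(1))
  if (length(ts) > 1 && is.unsorted(ts)) abort_domain("action timestamps must be non-decreasing")
  structure(list(actions = actions), class = "cogscreen_action_log")
}

#' @rdname graph_action_log
#' @param trajectory a [touch_trajectory()].
#' @param t_ms action timestamp (defaults to the stroke's first event).
#' @export
stroke_action <- function(trajectory, t_ms = trajectory$t_ms[1]) {
  if (!is_trajectory(trajectory)) abort_validation("stroke payload must be a trajectory")
  list(kind = "stroke", t_ms = as.numeric(t_ms), trajectory = trajectory)
}

#' @rdname graph_action_log
#' @param node_id touched node id (string).
#' @export
node_touch_action <- function(node_id, t_ms) {
  list(kind = "node_touch", t_ms = as.numeric(t_ms), node_id = as.character(node_id))
}

#' Audio clip
#'
#' Mono audio samples in `[-1, 1]` with a sampling rate (48 kHz nominal).
#'
#' @param samples numeric vector of samples.
#' @param rate_hz sampling rate in Hz, positive integer.
#' @return an object of class `cogscreen_audio`.
#' @export
audio_clip <- function(samples, rate_hz = 48000L) {
  if (!is.numeric(samples)) abort_validation("samples must be numeric")
  if (rate_hz <= 0) abort_domain("rate_hz must be positive")
  structure(list(samples = as.numeric(samples), rate_hz = as.integer(rate_hz)),
            class = "cogscreen_audio")
}

#' @export
length.cogscreen_audio <- function(x) length(x$samples)

#' Session record
#'
#' One subject visit: profile, round index (1 to 5), per-task payloads keyed
#' `T0` to `T15`, and per-task durations in seconds.
#'
#' @param profile a [subject_profile()].
#' @param round_index visit number, 1 to 5.
#' @param tasks named list of task payloads (names in `T0`..`T15`).
#' @param durations named numeric vector of per-task durations (seconds).
#' @return an object of class `cogscreen_session`.
#' @export
session_record <- function(profile, round_index = 1L, tasks = list(),
                           durations = numeric()) {
  if (!inherits(profile, "cogscreen_profile")) abort_validation("profile must be a cogscreen_profile")
  if (!round_index %in% 1:5) abort_validation("round_index must be in 1..5")
  if (length(tasks) && (is.null(names(tasks)) || !all(names(tasks) %in% VALID_TASKS)))
    abort_validation(sprintf("unknown task key: %s",
                             paste(setdiff(names(tasks), VALID_TASKS), collapse = ", ")))
  if (length(durations)) {
    if (is.null(names(durations)) || !all(names(durations) %in% VALID_TASKS))
      abort_validation("durations must be named by task key")
    if (any(durations < 0)) abort_domain("durations must be >= 0")
  }
  structure(list(profile = profile, round_index = as.integer(round_index),
                 tasks = tasks, durations = durations),
            class = "cogscreen_session")
}

## ---- JSON serialization -------------------------------------------------

encode_value <- function(x) {
  if (is_trajectory(x)) {
    list(`_type` = "trajectory", t_ms = x$t_ms, x_px = x$x_px, y_px = x$y_px,
         pointer_id = x$pointer_id, pressure = x$pressure)
  } else if (inherits(x, "cogscreen_layout")) {
    list(`_type` = "graph_layout",
         nodes = as.list(x$nodes),
         edges = if (nrow(x$edges)) unname(Map(c, x$edges$from, x$edges$to)) else list(),
         node_radius_px = x$node_radius_px)
  } else if (inherits(x, "cogscreen_action_log")) {
    list(`_type` = "action_log", actions = lapply(x$actions, function(a) {
      if (a$kind == "stroke") list(kind = "stroke", t_ms = a$t_ms,
                                   trajectory = encode_value(a$trajectory))
      else list(kind = "node_touch", t_ms = a$t_ms, node_id = a$node_id)
    }))
  } else if (is.list(x) && is.null(attr(x, "class"))) {
    lapply(x, encode_value)
  } else x
}

decode_value <- function(x) {
  if (is.list(x) && !is.null(x$`_type`)) {
    switch(x$`_type`,
      trajectory = touch_trajectory(unlist(x$t_ms), unlist(x$x_px), unlist(x$y_px),
                                    unlist(x$pointer_id) %||% 0L,
                                    unlist(x$pressure) %||% NA_real_),
      graph_layout = graph_layout(
        tibble::tibble(node_id = unlist(x$nodes$node_id),
                       x_px = unlist(x$nodes$x_px), y_px = unlist(x$nodes$y_px),
                       label = unlist(x$nodes$label)),
        if (length(x$edges)) do.call(rbind, lapply(x$edges, unlist)) else NULL,
        node_radius_px = x$node_radius_px %||% 40),
      action_log = graph_action_log(lapply(x$actions, function(a) {
        if (a$kind == "stroke") stroke_action(decode_value(a$trajectory), a$t_ms)
        else node_touch_action(a$node_id, a$t_ms)
      })),
      abort_validation(sprintf("unknown payload type '%s'", x$`_type`))
    )
  } else if (is.list(x)) {
    lapply(x, decode_value)
  } else x
}

#' Read and write session files
#'
#' Sessions are stored as a documented JSON dialect (schema
#' `"cogscreen-session/1"`). `write_session()` followed by `read_session()`
#' is the identity on the documented schema; numbers survive with full IEEE
#' double precision.
#'
#' @param path file path.
#' @return `read_session()` returns a [session_record()].
#' @export
read_session <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort_validation(
                    sprintf("malformed session JSON in '%s': %s", path, conditionMessage(e))))
  if (!identical(raw$schema, SESSION_SCHEMA))
    abort_validation(sprintf("field 'schema': expected '%s'", SESSION_SCHEMA))
  p <- raw$profile
  for (f in c("subject_id", "gender", "age_years", "height_m", "weight_kg", "pal"))
    if (is.null(p[[f]])) abort_validation(sprintf("field 'profile.%s' missing", f))
  profile <- subject_profile(p$subject_id, p$gender, p$age_years, p$height_m,
                             p$weight_kg, p$pal, p$body_fat_pct,
                             p$label %||% NA)
  tasks <- lapply(raw$tasks %||% list(), decode_value)
  durations <- unlist(raw$durations %||% list())
  if (is.null(durations)) durations <- numeric()
  session_record(profile, raw$round_index %||% 1L, tasks, durations)
}

#' @rdname read_session
#' @param session a [session_record()].
#' @export
write_session <- function(session, path) {
  p <- session$profile
  obj <- list(
    schema = SESSION_SCHEMA,
    profile = list(subject_id = p$subject_id, gender = p$gender,
                   age_years = p$age_years, height_m = p$height_m,
                   weight_kg = p$weight_kg, pal = p$pal,
                   body_fat_pct = p$body_fat_pct,
                   label = if (is.na(p$label)) NULL else p$label),
    round_index = session$round_index,
    tasks = lapply(session$tasks, encode_value),
    durations = as.list(session$durations)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

## ---- WAV IO -------------------------------------------------------------

#' Read and write PCM WAV audio
#'
#' Minimal RIFF/WAVE reader and writer for 16-bit integer and 32-bit float
#' PCM. Stereo input is averaged to mono; integer samples are scaled to
#' `[-1, 1]` by 1/32768.
#'
#' @param path file path to a `.wav` file.
#' @return `read_audio()` returns an [audio_clip()].
#' @export
read_audio <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort_validation("unsupported format: not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort_validation("unsupported format: not a RIFF/WAVE file")
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort_validation("WAV 'data' chunk precedes 'fmt '")
      if (fmt$audio_format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, 2, endian = "little") / 32768
      } else if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", size / 4, 4, endian = "little")
      } else {
        abort_validation(sprintf("unsupported WAV encoding (format %d, %d bits)",
                                 fmt$audio_format, fmt$bits))
      }
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) abort_validation("WAV file has no data chunk")
  if (fmt$channels > 1) {
    m <- matrix(samples, nrow = fmt$channels)
    samples <- colMeans(m)
  }
  audio_clip(samples, fmt$rate)
}

#' @rdname read_audio
#' @param clip an [audio_clip()].
#' @param bits 16 (integer PCM) or 32 (float PCM).
#' @export
write_audio <- function(clip, path, bits = 16L) {
  if (!inherits(clip, "cogscreen_audio")) abort_validation("clip must be a cogscreen_audio")
  if (!bits %in% c(16L, 32L)) abort_domain("bits must be 16 or 32")
  n <- length(clip$samples)
  data_size <- n * bits / 8
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 16L) 1L else 3L, 1L), con, 2, endian = "little")
  writeBin(as.integer(clip$rate_hz), con, 4, endian = "little")
  writeBin(as.integer(clip$rate_hz * bits / 8), con, 4, endian = "little")
  writeBin(c(as.integer(bits / 8), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(clip$samples * 32768))))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(clip$samples, con, 4, endian = "little")
  }
  invisible(path)
}
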