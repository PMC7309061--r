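## Canonical 238-feature schema.
## Group sizes: T1 9, T2 10, T3 28, T4 follow 22, T4 draw 22, T9 30, T10 24,
## T11 2, T12 33, T13 25, T15 4, Spelling 3, SAGE 10, Duration 16 -> 238.
## The within-group feature lists are this package's documented concrete
## choice; the published schema fixes only the group sizes.

trajectory_stat_names <- c(
  "frechet", "pct_match", "duration_s", "path_len", "len_ratio",
  "mean_speed", "sd_speed", "max_speed", "mean_dev", "sd_dev", "max_dev",
  "rmse_dev", "n_points", "mean_dt_ms", "sd_dt_ms", "tremor_power",
  "tremor_peak_hz", "tremor_amp", "mean_jerk", "pause_count",
  "start_offset", "end_offset")

schema_groups <- function() {
  list(
    T1 = as.vector(outer(c("interval_ms", "offset_px", "miss"),
                         c("2c", "3c", "5c"),
                         function(s, l) paste("t1", l, s, sep = "_"))),
    T2 = c(paste0("t2_rt_", 1:5), paste0("t2_offset_", 1:5)),
    T3 = as.vector(outer(c("rt_ms", "off_x", "off_y", "hold_ms"), 1:7,
                         function(s, o) paste0("t3_obj", o, "_", s))),
    T4_follow = paste0("t4f_", trajectory_stat_names),
    T4_draw = paste0("t4d_", trajectory_stat_names),
    T9 = paste0("t9_", c("wrong_connection", "too_few", "too_many", "existing",
                         "similarity", "parallel_fraction", "parallel_pass",
                         paste0("pair_angle_", 1:9),
                         "n_edges", "n_strokes", "mean_stroke_dur",
                         "sd_stroke_dur", "mean_stroke_len", "sd_stroke_len",
                         "mean_stroke_frechet", "sd_stroke_frechet",
                         "mean_stroke_speed", "sd_stroke_speed",
                         "total_errors", "completion", "mean_node_offset",
                         "points")),
    T10 = paste0("t10_", c("boundary_errors", "total_points", "outside_fraction",
                           "supervisor_score", "n_strokes", "duration_s",
                           "path_len", "mean_speed", "sd_speed", "mean_dt_ms",
                           "sd_dt_ms", "bbox_w", "bbox_h", "bbox_aspect",
                           "centroid_dx", "centroid_dy", "mean_radius",
                           "sd_radius", "circularity", "tremor_power",
                           "tremor_peak_hz", "mean_jerk", "pause_count",
                           "points")),
    T11 = c("t11_points", "t11_jw_average"),
    T12 = paste0("t12_", c("wrong_connection", "same_node", "outside_click",
                           "similarity", "n_paths", "completion",
                           "mean_frechet", "sd_frechet", "max_frechet",
                           "mean_path_dur", "sd_path_dur", "mean_speed",
                           "sd_speed", "total_dur", "points",
                           paste0("path_frechet_", 1:11),
                           "mean_stroke_len", "sd_stroke_len",
                           "mean_node_offset", "tremor_power", "mean_dt_ms",
                           "sd_dt_ms", "n_strokes")),
    T13 = paste0("t13_", c("same_node", "outside_zone", "rule_violation",
                           "similarity", "ops_used", "ops_left", "goal_reached",
                           "n_inserts", "n_removes", "mean_op_interval_ms",
                           "sd_op_interval_ms", "total_dur_s", "points",
                           "edge_diff", "n_touches", "error_total",
                           "error_rate", "mean_touch_offset", "sd_touch_offset",
                           "unpaired_touches", "insert_fraction",
                           "touch_rate_hz", "moves_needed", "ops_budget",
                           "efficiency")),
    T15 = c("t15_bmr", "t15_tdee", "t15_p_gained", "t15_p_balance"),
    Spelling = c("spell_jw_t7", "spell_jw_t8", "spell_jw_t11"),
    SAGE = paste0("sage_", c("t6", "t7", "t8_q3", "t8_calc", "t9", "t10",
                             "t11", "t12", "t13", "t0")),
    Duration = paste0("duration_", paste0("T", 0:15))
  )
}

#' The canonical 238-feature schema
#'
#' Ordered feature groups (with their fixed sizes 9, 10, 28, 22, 22, 30,
#' 24, 2, 33, 25, 4, 3, 10, 16, summing to 238) and the concrete per-group
#' feature names this package emits. Every extractor's output count is
#' asserted against this schema.
#'
#' @return tibble with columns `feature` and `group` (238 rows).
#' @export
feature_schema <- function() {
  g <- schema_groups()
  out <- tibble::tibble(
    feature = unlist(g, use.names = FALSE),
    group = rep(names(g), lengths(g))
  )
  stopifnot(nrow(out) == 238L, !anyDuplicated(out$feature))
  out
}

#' @rdname feature_schema
#' @export
feature_group_sizes <- function() lengths(schema_groups())

## ---- kinematic helpers ---------------------------------------------------

nearest_ref_dist <- function(x, y, rx, ry) {
  vapply(seq_along(x), function(i) sqrt(min((rx - x[i])^2 + (ry - y[i])^2)),
         numeric(1))
}

# 4-8 Hz band power / peak of an irregularly sampled deviation signal
tremor_spectrum <- function(dev, t_ms, band = c(4, 8), fs = 100) {
  if (length(dev) < 8 || diff(range(t_ms)) <= 0)
    return(c(power = 0, peak_hz = 0, amp = 0))
  ord <- order(t_ms)
  t_ms <- t_ms[ord]; dev <- dev[ord]
  tt <- seq(min(t_ms), max(t_ms), by = 1000 / fs)
  if (length(tt) < 16) return(c(power = 0, peak_hz = 0, amp = 0))
  u <- stats::approx(t_ms, dev, xout = tt, ties = mean)$y
  u <- u - mean(u)
  n <- length(u)
  sp <- Mod(stats::fft(u))^2 / n^2
  freqs <- (0:(n - 1)) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) return(c(power = 0, peak_hz = 0, amp = 0))
  pw <- 2 * sum(sp[sel])
  pk <- freqs[sel][which.max(sp[sel])]
  c(power = pw, peak_hz = pk, amp = sqrt(2 * pw))
}

trajectory_features <- function(tr, reference, radius_px) {
  pts <- as_curve(tr)
  ref <- as_curve(reference)
  dev <- nearest_ref_dist(pts$x, pts$y, ref$x, ref$y)
  dt <- diff(tr$t_ms)
  seg <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
  speed <- ifelse(dt > 0, seg / dt * 1000, 0)
  accel <- if (length(speed) > 1) diff(speed) / pmax(dt[-1], 1) * 1000 else 0
  jerk <- if (length(accel) > 1) abs(diff(accel)) else 0
  ref_len <- sum(sqrt(diff(ref$x)^2 + diff(ref$y)^2))
  path_len <- sum(seg)
  trm <- tremor_spectrum(dev, tr$t_ms)
  vals <- c(
    frechet = discrete_frechet(pts, ref),
    pct_match = percentage_match(pts, ref, radius_px),
    duration_s = (max(tr$t_ms) - min(tr$t_ms)) / 1000,
    path_len = path_len,
    len_ratio = if (ref_len > 0) path_len / ref_len else 0,
    mean_speed = mean(speed), sd_speed = stats::sd(c(speed, 0)),
    max_speed = max(c(speed, 0)),
    mean_dev = mean(dev), sd_dev = stats::sd(c(dev, 0)), max_dev = max(dev),
    rmse_dev = sqrt(mean(dev^2)),
    n_points = nrow(pts),
    mean_dt_ms = if (length(dt)) mean(dt) else 0,
    sd_dt_ms = if (length(dt) > 1) stats::sd(dt) else 0,
    tremor_power = trm[["power"]], tremor_peak_hz = trm[["peak_hz"]],
    tremor_amp = trm[["amp"]],
    mean_jerk = mean(c(jerk, 0)),
    pause_count = sum(dt > 150),
    start_offset = sqrt((pts$x[1] - ref$x[1])^2 + (pts$y[1] - ref$y[1])^2),
    end_offset = sqrt((pts$x[nrow(pts)] - ref$x[nrow(ref)])^2 +
                        (pts$y[nrow(pts)] - ref$y[nrow(ref)])^2)
  )
  stats::setNames(as.numeric(vals), trajectory_stat_names)
}

sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
mean0 <- function(x) if (length(x)) mean(x) else 0

## ---- per-task extractors -------------------------------------------------

extract_t1 <- function(payload) {
  out <- numeric(0)
  for (lay in payload$layouts) {
    taps <- lay$taps
    iv <- if (nrow(taps) > 1) mean(diff(taps$t_ms)) else 0
    off <- sqrt((taps$x_px - lay$target_x)^2 + (taps$y_px - lay$target_y)^2)
    miss <- sum(off > lay$target_radius)
    out <- c(out, iv, mean0(off), miss)
  }
  out
}

extract_t2 <- function(payload) c(payload$rt_ms, payload$offset_px)

extract_t3 <- function(payload)
  as.vector(t(as.matrix(payload[, c("rt_ms", "off_x", "off_y", "hold_ms")])))

extract_t4_half <- function(tr, reference, radius_px)
  trajectory_features(tr, reference, radius_px)

extract_t9 <- function(payload, layout, reference) {
  sc <- score_construction_3d(payload$log, reference, layout)
  strokes <- lapply(Filter(function(a) a$kind == "stroke", payload$log$actions),
                    function(a) a$trajectory)
  durs <- vapply(strokes, function(tr) (max(tr$t_ms) - min(tr$t_ms)) / 1000, numeric(1))
  lens <- vapply(strokes, function(tr)
    sum(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)), numeric(1))
  speeds <- ifelse(durs > 0, lens / durs, 0)
  # straightness of each stroke: Frechet to the chord between its endpoints
  frech <- vapply(strokes, function(tr) {
    n <- nrow(tr)
    chord <- curve2d(c(tr$x_px[1], tr$x_px[n]), c(tr$y_px[1], tr$y_px[n]))
    discrete_frechet(tr, chord)
  }, numeric(1))
  node_off <- vapply(strokes, function(tr) {
    n <- nrow(tr)
    min(nearest_ref_dist(tr$x_px[c(1, n)], tr$y_px[c(1, n)],
                         layout$nodes$x_px, layout$nodes$y_px))
  }, numeric(1))
  angles <- sc$aux$pair_angles
  angles[is.na(angles)] <- 90
  sub <- sc$aux$subject_graph
  correct <- sum(apply(reference$edges, 1, function(e) has_edge(sub, e[1], e[2])))
  c(sc$aux$wrong_connection, sc$aux$too_few, sc$aux$too_many, sc$aux$existing,
    sc$aux$similarity, sc$aux$parallel_fraction, sc$aux$parallel_pass,
    angles,
    sc$aux$n_edges, length(strokes), mean0(durs), sd0(durs), mean0(lens),
    sd0(lens), mean0(frech), sd0(frech), mean0(speeds), sd0(speeds),
    sc$aux$wrong_connection + sc$aux$too_few + sc$aux$too_many + sc$aux$existing,
    correct / max(1, nrow(reference$edges)), mean0(node_off), sc$points)
}

extract_t10 <- function(payload) {
  sc <- score_clock(payload$strokes, payload$contour, payload$supervisor_score)
  all_pts <- dplyr::bind_rows(lapply(payload$strokes, tibble::as_tibble))
  dt <- unlist(lapply(payload$strokes, function(tr) diff(tr$t_ms)))
  seg <- unlist(lapply(payload$strokes, function(tr)
    sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)))
  speed <- ifelse(dt > 0, seg / dt * 1000, 0)
  cx <- mean(payload$contour$x); cy <- mean(payload$contour$y)
  rad <- sqrt((all_pts$x_px - cx)^2 + (all_pts$y_px - cy)^2)
  bw <- diff(range(all_pts$x_px)); bh <- diff(range(all_pts$y_px))
  dur <- sum(vapply(payload$strokes, function(tr)
    (max(tr$t_ms) - min(tr$t_ms)) / 1000, numeric(1)))
  trm <- tremor_spectrum(rad, all_pts$t_ms)
  accel <- if (length(speed) > 1) abs(diff(speed)) else 0
  c(sc$aux$boundary_errors, sc$aux$total_points, sc$aux$outside_fraction,
    if (is.na(sc$aux$supervisor_score)) 0 else sc$aux$supervisor_score,
    length(payload$strokes), dur, sum(seg), mean0(speed), sd0(speed),
    mean0(dt), sd0(dt), bw, bh, if (bh > 0) bw / bh else 0,
    mean(all_pts$x_px) - cx, mean(all_pts$y_px) - cy,
    mean0(rad), sd0(rad),
    if (mean0(rad) > 0) sd0(rad) / mean0(rad) else 0,
    trm[["power"]], trm[["peak_hz"]], mean0(accel), sum(dt > 150), sc$points)
}

extract_t12 <- function(payload, layout) {
  sc <- score_trails(payload$log, layout)
  strokes <- lapply(Filter(function(a) a$kind == "stroke", payload$log$actions),
                    function(a) a$trajectory)
  durs <- vapply(strokes, function(tr) (max(tr$t_ms) - min(tr$t_ms)) / 1000, numeric(1))
  lens <- vapply(strokes, function(tr)
    sum(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)), numeric(1))
  speeds <- ifelse(durs > 0, lens / durs, 0)
  dt <- unlist(lapply(strokes, function(tr) diff(tr$t_ms)))
  node_off <- vapply(strokes, function(tr) {
    n <- nrow(tr)
    min(nearest_ref_dist(tr$x_px[c(1, n)], tr$y_px[c(1, n)],
                         layout$nodes$x_px, layout$nodes$y_px))
  }, numeric(1))
  all_dev <- unlist(lapply(strokes, function(tr) {
    n <- nrow(tr)
    chord_x <- seq(tr$x_px[1], tr$x_px[n], length.out = n)
    chord_y <- seq(tr$y_px[1], tr$y_px[n], length.out = n)
    sqrt((tr$x_px - chord_x)^2 + (tr$y_px - chord_y)^2)
  }))
  all_t <- unlist(lapply(strokes, function(tr) tr$t_ms))
  trm <- tremor_spectrum(all_dev, all_t)
  pf <- sc$aux$path_frechet
  pf11 <- rep(0, 11)
  pf11[seq_len(min(11, length(pf)))] <- pf[seq_len(min(11, length(pf)))]
  n_targets <- nrow(layout$nodes) - 1
  c(sc$aux$wrong_connection, sc$aux$same_node, sc$aux$outside_click,
    sc$aux$similarity, sc$aux$n_paths, sc$aux$n_paths / max(1, n_targets),
    mean0(pf), sd0(pf), if (length(pf)) max(pf) else 0,
    mean0(durs), sd0(durs), mean0(speeds), sd0(speeds), sum(durs), sc$points,
    pf11, mean0(lens), sd0(lens), mean0(node_off), trm[["power"]],
    mean0(dt), sd0(dt), length(strokes))
}

extract_t13 <- function(payload) {
  sc <- score_problem_solving(payload$log, payload$start, payload$goal,
                              payload$ops_budget,
                              payload$allowed_ops %||% c("insert", "remove"))
  touches <- Filter(function(a) a$kind %in% c("node_touch", "stroke"), payload$log$actions)
  ts <- vapply(touches, function(a) a$t_ms, numeric(1))
  iv <- diff(ts)
  final <- sc$aux$final_graph
  goal <- payload$goal
  key <- function(g) paste(g$edges$from, g$edges$to, sep = "|")
  edge_diff <- length(union(setdiff(key(final), key(goal)),
                            setdiff(key(goal), key(final))))
  moves_needed <- length(union(setdiff(key(payload$start), key(goal)),
                               setdiff(key(goal), key(payload$start))))
  errs <- sc$aux$same_node + sc$aux$outside_zone + sc$aux$rule_violation
  offs <- unlist(lapply(touches, function(a) {
    if (a$kind != "stroke") return(numeric(0))
    tr <- a$trajectory
    min(nearest_ref_dist(tr$x_px[1], tr$y_px[1],
                         payload$start$nodes$x_px, payload$start$nodes$y_px))
  }))
  ops <- sc$aux$ops_used
  dur <- if (length(ts)) (max(ts) - min(ts)) / 1000 else 0
  # inserts = edges present in final but not in start (net view)
  n_inserts <- length(setdiff(key(final), key(payload$start)))
  n_removes <- length(setdiff(key(payload$start), key(final)))
  c(sc$aux$same_node, sc$aux$outside_zone, sc$aux$rule_violation,
    sc$aux$similarity, ops, sc$aux$ops_left, sc$aux$goal_reached,
    n_inserts, n_removes, mean0(iv), sd0(iv), dur, sc$points, edge_diff,
    length(touches), errs, errs / max(1, length(touches)),
    mean0(offs), sd0(offs),
    max(0, length(touches) - 2 * ops - errs),
    if (ops > 0) n_inserts / max(1, n_inserts + n_removes) else 0,
    if (dur > 0) length(touches) / dur else 0,
    moves_needed, payload$ops_budget,
    if (ops > 0) moves_needed / ops else 0)
}

## ---- orchestration -------------------------------------------------------

#' Extract the 238-feature vector from a session
#'
#' Runs the geometric, cognitive and energy extractors over a session's
#' task payloads and assembles the canonical feature vector. Groups whose
#' task is missing from the session are emitted as `NA` and flagged (see
#' [impute_features()] for the training-median imputation policy).
#'
#' @param session a [session_record()].
#' @param keys answer key (see [default_answer_key()]).
#' @param schema the feature schema (defaults to [feature_schema()]).
#' @return one-row tibble: `subject_id`, `round_index`, `label`, then the
#'   238 features; attribute `missing_groups` lists imputation flags.
#' @export
extract_features <- function(session, keys = default_answer_key(),
                             schema = feature_schema()) {
  tasks <- session$tasks
  groups <- schema_groups()
  vals <- list()
  missing <- character(0)

  grab <- function(group, task, fn) {
    n <- length(groups[[group]])
    if (is.null(tasks[[task]])) {
      missing <<- c(missing, group)
      return(rep(NA_real_, n))
    }
    v <- as.numeric(fn(tasks[[task]]))
    if (length(v) != n)
      abort_validation(sprintf("group %s produced %d features, schema says %d",
                               group, length(v), n))
    v
  }

  vals$T1 <- grab("T1", "T1", extract_t1)
  vals$T2 <- grab("T2", "T2", extract_t2)
  vals$T3 <- grab("T3", "T3", extract_t3)
  vals$T4_follow <- grab("T4_follow", "T4", function(p)
    extract_t4_half(p$follow, p$reference, p$match_radius_px %||% 30))
  vals$T4_draw <- grab("T4_draw", "T4", function(p)
    extract_t4_half(p$draw, p$reference, p$match_radius_px %||% 30))
  vals$T9 <- grab("T9", "T9", function(p)
    extract_t9(p, p$layout, p$reference))
  vals$T10 <- grab("T10", "T10", extract_t10)

  t11_score <- NULL
  vals$T11 <- grab("T11", "T11", function(p) {
    dict <- keys$dictionaries[[p$category %||% names(keys$dictionaries)[1]]]
    t11_score <<- score_verbal_fluency(p$items, unlist(dict))
    c(t11_score$points, t11_score$aux$jw_average)
  })
  vals$T12 <- grab("T12", "T12", function(p) extract_t12(p, p$layout))
  vals$T13 <- grab("T13", "T13", extract_t13)
  vals$T15 <- grab("T15", "T15", function(p) {
    er <- energy_report(session$profile, p$food, p$activities)
    c(er$bmr, er$tdee, er$p_gained, er$p_balance)
  })

  # SAGE and Spelling groups reuse the scorers
  t7 <- if (!is.null(tasks$T7)) score_picture_naming(tasks$T7$answers, keys) else NULL
  t8 <- if (!is.null(tasks$T8)) score_similarities_calculation(
    tasks$T8$q3, tasks$T8$q4, tasks$T8$q5, keys) else NULL
  t6 <- if (!is.null(tasks$T6)) score_orientation(tasks$T6, keys$today) else NULL
  t0 <- if (!is.null(tasks$T0)) score_memory(tasks$T0$answer,
                                             unlist(keys$memory_phrases)) else NULL

  spell <- c(if (is.null(t7)) NA_real_ else t7$aux$jw_average,
             if (is.null(t8)) NA_real_ else t8$aux$jw_q3,
             if (is.null(t11_score)) NA_real_ else t11_score$aux$jw_average)
  if (anyNA(spell)) missing <- c(missing, "Spelling")
  vals$Spelling <- spell

  sage <- c(if (is.null(t6)) NA_real_ else t6$points,
            if (is.null(t7)) NA_real_ else t7$points,
            if (is.null(t8)) NA_real_ else t8$aux$q3_points,
            if (is.null(t8)) NA_real_ else t8$aux$calc_points,
            vals$T9[length(groups$T9)],
            vals$T10[length(groups$T10)],
            vals$T11[1],
            vals$T12[15],
            vals$T13[13],
            if (is.null(t0)) NA_real_ else t0$points)
  if (anyNA(sage)) missing <- c(missing, "SAGE")
  vals$SAGE <- sage

  dur <- session$durations[paste0("T", 0:15)]
  dur[is.na(dur)] <- 0
  vals$Duration <- as.numeric(dur)

  flat <- unlist(vals, use.names = FALSE)
  stopifnot(length(flat) == 238L)
  out <- tibble::as_tibble(as.list(stats::setNames(flat, schema$feature)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = session$profile$subject_id,
                   round_index = session$round_index,
                   label = session$profile$label),
    out)
  attr(out, "missing_groups") <- unique(missing)
  out
}

#' Median imputation of missing feature groups
#'
#' Replaces `NA` feature values by the per-column median over the table
#' (the training data under cross-validation) and appends one indicator
#' column per schema group that had any missing value.
#'
#' @param table a feature table (rows = records).
#' @param schema the feature schema.
#' @return the imputed tibble (indicator columns prefixed `miss_`).
#' @export
impute_features <- function(table, schema = feature_schema()) {
  for (g in unique(schema$group)) {
    cols <- schema$feature[schema$group == g]
    block <- table[, cols, drop = FALSE]
    if (anyNA(block)) {
      table[[paste0("miss_", g)]] <- as.numeric(!stats::complete.cases(block))
      for (cn in cols) {
        v <- table[[cn]]
        v[is.na(v)] <- stats::median(v, na.rm = TRUE)
        v[is.na(v)] <- 0
        table[[cn]] <- v
      }
    }
  }
  table
}

#' Read and write feature tables as CSV
#'
#' The header row carries the canonical feature names (plus `subject_id`,
#' `round_index`, `label`); reading validates the columns against the
#' schema and restricts `label` to 0, 1 or empty.
#'
#' @param table feature table tibble.
#' @param path CSV path.
#' @param schema the feature schema.
#' @return `read_feature_table()` returns the validated tibble.
#' @export
write_feature_table <- function(table, path, schema = feature_schema()) {
  missing_cols <- setdiff(schema$feature, names(table))
  if (length(missing_cols))
    abort_validation(sprintf("table lacks schema columns: %s",
                             paste(utils::head(missing_cols, 3), collapse = ", ")))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, schema = feature_schema()) {
  tab <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  missing_cols <- setdiff(schema$feature, names(tab))
  if (length(missing_cols))
    abort_validation(sprintf("CSV lacks schema columns: %s",
                             paste(utils::head(missing_cols, 3), collapse = ", ")))
  if ("label" %in% names(tab) && !all(tab$label %in% c(0, 1, NA)))
    abort_validation("label column must be 0, 1 or empty")
  tab
}

#' Split a feature table into a numeric matrix and labels
#'
#' @param table feature table.
#' @param schema the feature schema.
#' @return list with `X` (matrix), `y` (integer labels), `subject_id`.
#' @export
feature_matrix <- function(table, schema = feature_schema()) {
  X <- as.matrix(table[, schema$feature])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(table$label), subject_id = table$subject_id)
}
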