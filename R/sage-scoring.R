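#' Jaro and Jaro-Winkler string similarity
#'
#' Standard Jaro similarity from character matches within the sliding
#' window and half-transpositions, with the Winkler common-prefix boost
#' `jw = j + l * p * (1 - j)` (prefix length `l` capped at `max_prefix`).
#' Inputs are compared as given; scorers canonicalize first (see
#' [canonicalize_answer()]). Two empty strings compare as 1 by convention.
#'
#' @param s1,s2 strings.
#' @return similarity in `[0, 1]`.
#' @export
jaro <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  window <- max(0L, floor(max(la, lb) / 2) - 1L)
  matched_b <- rep(FALSE, lb)
  match_a <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!matched_b[j] && a[i] == b[j]) {
        matched_b[j] <- TRUE
        match_a <- c(match_a, i)
        break
      }
    }
  }
  m <- length(match_a)
  if (m == 0) return(0)
  sa <- a[match_a]
  sb <- b[matched_b]
  t <- sum(sa != sb) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

#' @rdname jaro
#' @param prefix_scale Winkler prefix scaling factor (default 0.1).
#' @param max_prefix maximum rewarded common prefix length (default 4).
#' @export
jaro_winkler <- function(s1, s2, prefix_scale = 0.1, max_prefix = 4L) {
  j <- jaro(s1, s2)
  if (j <= 0) return(j)
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  l <- 0L
  for (i in seq_len(min(length(a), length(b), max_prefix))) {
    if (a[i] == b[i]) l <- l + 1L else break
  }
  j + l * prefix_scale * (1 - j)
}

best_jw <- function(answer, candidates, prefix_scale = 0.1, max_prefix = 4L) {
  if (!length(candidates)) return(0)
  max(vapply(candidates, function(c) jaro_winkler(answer, c, prefix_scale, max_prefix),
             numeric(1)))
}

#' Task score container
#'
#' @param task_id one of `T0` to `T15`.
#' @param points integer points awarded, `0 <= points <= max_points`.
#' @param max_points maximum points for the task.
#' @param aux named list of auxiliary real values (similarities, error
#'   counts, Jaro-Winkler averages) that feed the feature table.
#' @return an object of class `cogscreen_score`.
#' @export
task_score <- function(task_id, points, max_points, aux = list()) {
  if (!task_id %in% VALID_TASKS) abort_validation(sprintf("unknown task id '%s'", task_id))
  points <- as.integer(round(points))
  if (points < 0 || points > max_points)
    abort_validation("points must satisfy 0 <= points <= max_points")
  structure(list(task_id = task_id, points = points,
                 max_points = as.integer(max_points), aux = aux),
            class = "cogscreen_score")
}

#' @export
print.cogscreen_score <- function(x, ...) {
  cat(sprintf("<%s score: %d/%d>\n", x$task_id, x$points, x$max_points))
  invisible(x)
}

#' Default answer key
#'
#' Ground truth for the scored items: picture names with accepted
#' alternates, abstract/concrete similarity terms, the arithmetic contexts,
#' category dictionaries and the memory phrases. Loaded from the package's
#' editable JSON config.
#'
#' @param path optional path to a JSON answer key; defaults to the bundled one.
#' @return a list of class `cogscreen_answer_key`.
#' @export
default_answer_key <- function(path = system.file("extdata", "answer_key.json",
                                                  package = "cogscreen")) {
  key <- jsonlite::read_json(path, simplifyVector = TRUE)
  key$today <- as.list(key$today)
  structure(key, class = "cogscreen_answer_key")
}

#' Score orientation to date (T6)
#'
#' One point per exactly matching component of (year, month, day).
#'
#' @param answer list or vector with `year`, `month`, `day`.
#' @param today same structure: the true current date.
#' @return a [task_score()] with max 3.
#' @export
score_orientation <- function(answer, today) {
  get3 <- function(x) {
    x <- as.list(x)
    v <- suppressWarnings(as.integer(c(x$year %||% x[[1]], x$month %||% x[[2]],
                                       x$day %||% x[[3]])))
    if (any(is.na(v))) abort_validation("unparsable date component")
    if (v[2] < 1 || v[2] > 12 || v[3] < 1 || v[3] > 31)
      abort_validation("calendar-invalid date")
    v
  }
  pts <- sum(get3(answer) == get3(today))
  task_score("T6", pts, 3L)
}

#' Score picture naming (T7)
#'
#' Exact match earns the point outright; otherwise the best Jaro-Winkler
#' similarity against the accepted alternates earns it when it reaches
#' `jw_threshold` (a spelling error by a subject who knows the object).
#' Raw JW values are kept as auxiliaries for the spelling feature group.
#'
#' @param answers exactly two answer strings.
#' @param key a [default_answer_key()]; uses `key$pictures`, a list of
#'   accepted-name character vectors per picture.
#' @param jw_threshold spelling-tolerance threshold (default 0.85).
#' @return a [task_score()] with max 2.
#' @export
score_picture_naming <- function(answers, key, jw_threshold = 0.85) {
  if (length(answers) != 2L) abort_validation("T7 expects exactly 2 answers")
  pics <- key$pictures[1:2]
  jw <- numeric(2); pts <- 0L
  for (i in 1:2) {
    ans <- canonicalize_answer(answers[[i]])
    cands <- canonicalize_answer(unlist(pics[[i]]))
    if (!nzchar(ans)) { jw[i] <- 0; next }
    if (ans %in% cands) { jw[i] <- 1; pts <- pts + 1L; next }
    jw[i] <- best_jw(ans, cands)
    if (jw[i] >= jw_threshold) pts <- pts + 1L
  }
  task_score("T7", pts, 2L,
             aux = list(jw_1 = jw[1], jw_2 = jw[2], jw_average = mean(jw)))
}

#' Score similarities and calculation (T8)
#'
#' Q3 (verbal similarity): 2 points for an abstract answer, 1 for a
#' concrete one, matched exactly or by Jaro-Winkler; an answer matching
#' both lists scores as abstract. Q4 (change from a bill): 1 point when the
#' answer equals `B - M` within 0.005. Q5 (coin count): 1 point for the
#' exact quotient `S / D`.
#'
#' @param q3_answer free-text similarity answer.
#' @param q4_answer numeric subtraction answer.
#' @param q5_answer numeric division answer.
#' @param key answer key with `q3_abstract`, `q3_concrete`, `q4` (fields
#'   `bill`, `amount`), `q5` (fields `sum`, `denomination`).
#' @param jw_threshold inexact-match threshold for Q3 (default 0.85).
#' @return a [task_score()] with max 4 and subscores in `aux`.
#' @export
score_similarities_calculation <- function(q3_answer, q4_answer, q5_answer, key,
                                           jw_threshold = 0.85) {
  ans <- canonicalize_answer(q3_answer)
  abs_terms <- canonicalize_answer(unlist(key$q3_abstract))
  con_terms <- canonicalize_answer(unlist(key$q3_concrete))
  jw_abs <- if (nzchar(ans)) max(best_jw(ans, abs_terms), as.numeric(ans %in% abs_terms)) else 0
  jw_con <- if (nzchar(ans)) max(best_jw(ans, con_terms), as.numeric(ans %in% con_terms)) else 0
  q3 <- if (jw_abs >= jw_threshold) 2L else if (jw_con >= jw_threshold) 1L else 0L

  expected_q4 <- key$q4$bill - key$q4$amount
  q4v <- suppressWarnings(as.numeric(q4_answer))
  q4_flag <- is.na(q4v)
  q4 <- if (!q4_flag && abs(q4v - expected_q4) <= 0.005) 1L else 0L

  expected_q5 <- key$q5$sum / key$q5$denomination
  q5v <- suppressWarnings(as.numeric(q5_answer))
  q5_flag <- is.na(q5v)
  q5 <- if (!q5_flag && q5v == expected_q5) 1L else 0L

  task_score("T8", q3 + q4 + q5, 4L,
             aux = list(q3_points = q3, q4_points = q4, q5_points = q5,
                        calc_points = q4 + q5,
                        jw_q3 = max(jw_abs, jw_con),
                        q4_invalid = as.numeric(q4_flag),
                        q5_invalid = as.numeric(q5_flag)))
}

#' Score 3-D figure construction (T9)
#'
#' Replays free-drawn strokes against the 8-node layout, maintaining four
#' error counters: wrongly connected nodes (a formed edge absent from the
#' reference figure), too few nodes in a stroke, too many nodes, and
#' re-drawing an already existing connection. Auxiliaries carry the
#' neighbor-matching similarity to the reference figure and the
#' parallel-pair score over the configured edge pairs.
#'
#' @param log a [graph_action_log()] of strokes.
#' @param reference the reference figure as a [graph_layout()] with edges.
#' @param layout the displayed node layout (edges ignored).
#' @param parallel_pairs list of reference-edge index pairs checked for
#'   parallelism (defaults to the 9 canonical cube pairs).
#' @param angle_tol_deg,match_pct see [parallel_pairs_score()].
#' @return a [task_score()] with max 2.
#' @export
score_construction_3d <- function(log, reference, layout,
                                  parallel_pairs = cube_parallel_pairs(),
                                  angle_tol_deg = 10, match_pct = 0.5) {
  if (nrow(layout$nodes) != 8L) abort_validation("T9 layout must have 8 nodes")
  subject <- graph_layout(layout$nodes, NULL, layout$node_radius_px)
  errors <- c(wrong_connection = 0L, too_few = 0L, too_many = 0L, existing = 0L)
  edge_strokes <- list()  # canonical "a|b" -> trajectory that formed the edge
  for (a in log$actions) {
    if (a$kind != "stroke") next
    ids <- resolve_stroke_nodes(a$trajectory, layout)
    if (length(ids) < 2) { errors["too_few"] <- errors["too_few"] + 1L; next }
    if (length(ids) > 2) { errors["too_many"] <- errors["too_many"] + 1L; next }
    if (has_edge(subject, ids[1], ids[2])) {
      errors["existing"] <- errors["existing"] + 1L
      next
    }
    subject <- add_edge(subject, ids[1], ids[2])
    if (!has_edge(reference, ids[1], ids[2]))
      errors["wrong_connection"] <- errors["wrong_connection"] + 1L
    edge_strokes[[paste(sort(ids), collapse = "|")]] <- a$trajectory
  }
  sim <- neighbor_matching_similarity(subject, reference)

  ref_keys <- paste(reference$edges$from, reference$edges$to, sep = "|")
  slopes <- lapply(ref_keys, function(k) {
    tr <- edge_strokes[[k]]
    if (is.null(tr)) NULL else fit_line_slope(tr)
  })
  pair_angles <- vapply(parallel_pairs, function(p) {
    s1 <- slopes[[p[1]]]; s2 <- slopes[[p[2]]]
    if (is.null(s1) || is.null(s2)) return(NA_real_)
    parallel_angle(s1$slope, s2$slope, s1$vertical, s2$vertical)
  }, numeric(1))
  fraction <- mean(!is.na(pair_angles) & pair_angles < angle_tol_deg)
  pass <- fraction >= match_pct

  pts <- if (sim >= 0.9 && pass) 2L else if (sim >= 0.6) 1L else 0L
  task_score("T9", pts, 2L, aux = c(
    as.list(errors),
    list(similarity = sim, parallel_fraction = fraction,
         parallel_pass = as.numeric(pass), pair_angles = pair_angles,
         n_edges = nrow(subject$edges), subject_graph = subject)
  ))
}

#' Score the clock drawing test (T10, automatic part)
#'
#' Counts drawn points falling outside the active contour (the boundary
#' error of the digitized clock task). The clinical clock score itself is
#' semi-automatic: when a supervisor score is supplied it is recorded
#' unchanged, otherwise points stay 0.
#'
#' @param strokes list of trajectories (or a [graph_action_log()]).
#' @param contour simple polygon as a data frame with `x`, `y` columns.
#' @param supervisor_score optional externally supplied clinical score (0-4).
#' @return a [task_score()] with max 4.
#' @export
score_clock <- function(strokes, contour, supervisor_score = NULL) {
  if (inherits(strokes, "cogscreen_action_log"))
    strokes <- lapply(Filter(function(a) a$kind == "stroke", strokes$actions),
                      function(a) a$trajectory)
  outside <- 0L; total <- 0L
  for (tr in strokes) {
    pts <- as_curve(tr)
    inside <- point_in_polygon(pts$x, pts$y, contour$x, contour$y)
    outside <- outside + sum(!inside)
    total <- total + nrow(pts)
  }
  pts <- if (is.null(supervisor_score)) 0L else as.integer(supervisor_score)
  task_score("T10", pts, 4L, aux = list(
    boundary_errors = outside, total_points = total,
    outside_fraction = if (total) outside / total else 0,
    supervisor_score = if (is.null(supervisor_score)) NA_real_ else as.numeric(supervisor_score)
  ))
}

#' Score verbal fluency (T11)
#'
#' Twelve slots in a category; an item is correct when it hits the category
#' dictionary exactly or its best Jaro-Winkler match reaches the threshold.
#' Duplicates (after canonicalization) count once. Points follow the
#' published rule: 2 for 12 distinct correct items, 1 for 10 or 11, else 0.
#' The auxiliary is the average of the 12 per-slot Jaro-Winkler scores
#' against the closest dictionary match (blank slots contribute 0).
#'
#' @param items character vector of exactly 12 entries (blanks allowed).
#' @param dictionary category word list.
#' @param jw_threshold correctness threshold (default 0.85).
#' @return a [task_score()] with max 2.
#' @export
score_verbal_fluency <- function(items, dictionary, jw_threshold = 0.85) {
  if (length(items) != 12L) abort_validation("T11 expects exactly 12 slots")
  dict <- canonicalize_answer(dictionary)
  canon <- canonicalize_answer(items)
  invalid <- vapply(canon, function(s) length(strsplit(s, " ")[[1]]) > 3, logical(1))
  jw <- numeric(12); correct <- rep(FALSE, 12)
  for (i in 1:12) {
    s <- canon[i]
    if (!nzchar(s) || invalid[i]) next
    jw[i] <- if (s %in% dict) 1 else best_jw(s, dict)
    correct[i] <- jw[i] >= jw_threshold
  }
  n_distinct_correct <- length(unique(canon[correct]))
  pts <- if (n_distinct_correct >= 12L) 2L else if (n_distinct_correct >= 10L) 1L else 0L
  task_score("T11", pts, 2L, aux = list(
    jw_average = mean(jw), n_correct = n_distinct_correct,
    n_invalid = sum(invalid)
  ))
}

#' Score modified trails (T12)
#'
#' The subject alternates numbers and letters (1-A-2-B-...). A stroke forms
#' a path only when it resolves exactly two nodes. Counters: wrongly
#' connected nodes (a formed pair that is not consecutive in the target
#' sequence, or a stroke touching three or more nodes), touching a single
#' node twice, and clicks outside any node. Auxiliaries: neighbor-matching
#' similarity against the reference chain and, per formed path, the
#' discrete Frechet distance between the stroke and the straight segment
#' joining the two node centers.
#'
#' @param log a [graph_action_log()] of strokes.
#' @param layout node layout whose `label` column carries the alternating
#'   sequence labels (see [trails_layout()]).
#' @return a [task_score()] with max 2.
#' @export
score_trails <- function(log, layout) {
  labs <- layout$nodes$label
  ord <- order(match(labs, target_trail_sequence(length(labs))))
  seq_ids <- layout$nodes$node_id[ord]
  ref_edges <- cbind(seq_ids[-length(seq_ids)], seq_ids[-1])
  reference <- graph_layout(layout$nodes, ref_edges, layout$node_radius_px)
  valid_pairs <- paste(pmin(ref_edges[, 1], ref_edges[, 2]),
                       pmax(ref_edges[, 1], ref_edges[, 2]), sep = "|")

  subject <- graph_layout(layout$nodes, NULL, layout$node_radius_px)
  errors <- c(wrong_connection = 0L, same_node = 0L, outside_click = 0L)
  path_frechet <- numeric(0)
  for (a in log$actions) {
    if (a$kind != "stroke") next
    ids <- resolve_stroke_nodes(a$trajectory, layout)
    n <- length(ids)
    if (n == 0) { errors["outside_click"] <- errors["outside_click"] + 1L; next }
    if (n == 1) { errors["same_node"] <- errors["same_node"] + 1L; next }
    if (n > 2) { errors["wrong_connection"] <- errors["wrong_connection"] + 1L; next }
    subject <- add_edge(subject, ids[1], ids[2])
    key <- paste(min(ids), max(ids), sep = "|")
    if (!key %in% valid_pairs)
      errors["wrong_connection"] <- errors["wrong_connection"] + 1L
    p1 <- layout$nodes[layout$nodes$node_id == ids[1], ]
    p2 <- layout$nodes[layout$nodes$node_id == ids[2], ]
    # densify the chord to the stroke's resolution so a perfectly straight
    # stroke scores (near) zero
    n <- max(2L, nrow(a$trajectory))
    segment <- curve2d(seq(p1$x_px, p2$x_px, length.out = n),
                       seq(p1$y_px, p2$y_px, length.out = n))
    path_frechet <- c(path_frechet, discrete_frechet(a$trajectory, segment))
  }
  sim <- neighbor_matching_similarity(subject, reference)
  pts <- if (sim >= 0.99 && sum(errors) == 0L) 2L else if (sim >= 0.6) 1L else 0L
  task_score("T12", pts, 2L, aux = c(as.list(errors), list(
    similarity = sim, path_frechet = path_frechet,
    n_paths = length(path_frechet), subject_graph = subject
  )))
}

#' Score match-puzzle problem solving (T13)
#'
#' Sequential touches of two nodes execute an insert (edge absent) or a
#' remove (edge present), subject to the puzzle's allowed operations and a
#' budget of operations; the task stops when the budget reaches zero.
#' Counters: touching the same node twice, touching outside the node zone,
#' and violating the allowed-operation rules. The auxiliary similarity
#' compares the final figure to the goal figure.
#'
#' @param log a [graph_action_log()]; node touches drive the puzzle, and
#'   stroke actions are resolved to at most one node (none counts as an
#'   outside-zone touch).
#' @param start starting figure ([graph_layout()] with edges).
#' @param goal goal figure.
#' @param ops_budget number of allowed operations.
#' @param allowed_ops subset of `c("insert", "remove")` the puzzle permits.
#' @return a [task_score()] with max 2.
#' @export
score_problem_solving <- function(log, start, goal, ops_budget,
                                  allowed_ops = c("insert", "remove")) {
  if (ops_budget < 0) abort_domain("ops_budget must be >= 0")
  current <- start
  errors <- c(same_node = 0L, outside_zone = 0L, rule_violation = 0L)
  pending <- NULL; ops_left <- as.integer(ops_budget); ops_used <- 0L
  for (a in log$actions) {
    if (ops_left <= 0L) break
    id <- if (a$kind == "node_touch") a$node_id else {
      ids <- resolve_stroke_nodes(a$trajectory, start)
      if (length(ids)) ids[1] else NA_character_
    }
    if (is.na(id) || !nzchar(id) || !id %in% start$nodes$node_id) {
      errors["outside_zone"] <- errors["outside_zone"] + 1L
      next
    }
    if (is.null(pending)) { pending <- id; next }
    if (identical(pending, id)) {
      errors["same_node"] <- errors["same_node"] + 1L
      pending <- NULL
      next
    }
    op <- if (has_edge(current, pending, id)) "remove" else "insert"
    if (!op %in% allowed_ops) {
      errors["rule_violation"] <- errors["rule_violation"] + 1L
    } else {
      current <- if (op == "insert") add_edge(current, pending, id)
                 else remove_edge(current, pending, id)
      ops_left <- ops_left - 1L
      ops_used <- ops_used + 1L
    }
    pending <- NULL
  }
  sim <- neighbor_matching_similarity(current, goal)
  goal_reached <- sim >= 1 - 1e-9 && nrow(current$edges) == nrow(goal$edges)
  pts <- if (goal_reached) 2L else if (sim >= 0.6) 1L else 0L
  task_score("T13", pts, 2L, aux = c(as.list(errors), list(
    similarity = sim, ops_used = ops_used, ops_left = ops_left,
    goal_reached = as.numeric(goal_reached), final_graph = current
  )))
}

#' Score delayed memory recall (T0)
#'
#' Two points for the exact memorized phrase (no extra wording, compared
#' after case folding and punctuation stripping), one point when the word
#' "finished" or "done" appears, zero otherwise.
#'
#' @param answer subject's text.
#' @param key_phrases accepted exact phrases.
#' @return a [task_score()] with max 2.
#' @export
score_memory <- function(answer,
                         key_phrases = c("Have you finished?", "Are you done?")) {
  ans <- canonicalize_answer(answer)
  phrases <- canonicalize_answer(key_phrases)
  pts <- if (ans %in% phrases) 2L
         else if (any(c("finished", "done") %in% strsplit(ans, " ")[[1]])) 1L
         else 0L
  task_score("T0", pts, 2L)
}

#' Encode the insights questionnaire (T5)
#'
#' The non-scored demographic/insight questionnaire is encoded into a
#' deterministic, order-stable numeric block: six yes/no indicators and two
#' ordinal severity items (0-3). Contributes no points.
#'
#' @param questionnaire named list with logical fields `memory_problems`,
#'   `thinking_problems`, `depression`, `motor_symptoms`, `stroke_history`,
#'   `personality_change` and integer fields `functional_ability` and
#'   `symptom_duration` (0-3).
#' @return named numeric vector of length 8.
#' @export
encode_insights <- function(questionnaire) {
  binary <- c("memory_problems", "thinking_problems", "depression",
              "motor_symptoms", "stroke_history", "personality_change")
  ordinal <- c("functional_ability", "symptom_duration")
  for (f in c(binary, ordinal))
    if (is.null(questionnaire[[f]])) abort_validation(sprintf("missing mandatory field '%s'", f))
  out <- c(vapply(binary, function(f) as.numeric(isTRUE(questionnaire[[f]]) ||
                                                   identical(questionnaire[[f]], 1)), numeric(1)),
           vapply(ordinal, function(f) {
             v <- as.numeric(questionnaire[[f]])
             if (is.na(v) || v < 0 || v > 3) abort_validation(sprintf("field '%s' must be 0-3", f))
             v
           }, numeric(1)))
  stats::setNames(out, c(binary, ordinal))
}

## ---- reference layouts --------------------------------------------------

#' Reference layouts for the construction and executive tasks
#'
#' `reference_cube_layout()` is the 8-node wire-frame cube (12 edges) used
#' by the 3-D construction task, drawn as two squares offset on screen.
#' `cube_parallel_pairs()` designates the 9 canonical parallel edge pairs
#' checked by the parallel-line criterion (three per edge direction).
#' `trails_layout()` lays out alternating number/letter nodes on a circle,
#' and `target_trail_sequence()` gives the intended 1-A-2-B-... order.
#'
#' @param size screen size of the figure in pixels.
#' @param origin top-left offset of the figure.
#' @return a [graph_layout()] (or a list of index pairs / character vector).
#' @export
reference_cube_layout <- function(size = 400, origin = c(100, 100)) {
  s <- size * 0.7; off <- size * 0.3
  front <- rbind(c(0, off), c(s, off), c(s, off + s), c(0, off + s))
  back <- front + cbind(rep(off, 4), rep(-off, 4))
  nodes <- tibble::tibble(
    node_id = as.character(1:8),
    x_px = origin[1] + c(front[, 1], back[, 1]),
    y_px = origin[2] + c(front[, 2], back[, 2])
  )
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  graph_layout(nodes, edges, node_radius_px = size * 0.08)
}

#' @rdname reference_cube_layout
#' @export
cube_parallel_pairs <- function() {
  list(c(1L, 3L), c(5L, 7L), c(1L, 5L),   # horizontal edges
       c(2L, 4L), c(6L, 8L), c(2L, 6L),   # vertical edges
       c(9L, 11L), c(10L, 12L), c(9L, 10L))  # depth connectors
}

#' @rdname reference_cube_layout
#' @param n_pairs number of number/letter pairs (default 6: 1-A-...-6-F).
#' @param radius_px circle radius for node placement.
#' @param center circle center.
#' @export
trails_layout <- function(n_pairs = 6L, radius_px = 300, center = c(400, 400)) {
  labels <- target_trail_sequence(2L * n_pairs)
  n <- length(labels)
  # consecutive targets sit adjacently so correct strokes hug the rim,
  # well clear of the other nodes' hit zones
  ang <- 2 * pi * seq_len(n) / n
  nodes <- tibble::tibble(
    node_id = paste0("n", seq_len(n)),
    x_px = center[1] + radius_px * cos(ang),
    y_px = center[2] + radius_px * sin(ang),
    label = labels
  )
  graph_layout(nodes, NULL, node_radius_px = 40)
}

#' @rdname reference_cube_layout
#' @param n sequence length.
#' @export
target_trail_sequence <- function(n) {
  pairs <- ceiling(n / 2)
  seq_labels <- as.vector(rbind(as.character(seq_len(pairs)), LETTERS[seq_len(pairs)]))
  seq_labels[seq_len(n)]
}
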