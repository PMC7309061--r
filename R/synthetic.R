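## Synthetic subjects, sessions, voices and cohorts with class-conditional
## impairment effects, so the full scoring + classification pipeline is
## testable without access to clinical data. Every generator is a pure
## function of (parameters, seed).

healthy_effect_defaults <- function() list(
  tremor_amp_px = 1, tremor_freq_hz = 5, jitter_px = 1.5,
  latency_shift_ms = 0, typo_rate = 0.02, error_rate = 0.03,
  voice_jitter_pct = 0.5, voice_shimmer_pct = 3, hnr_db = 25,
  calorie_shift_kcal = 0, speed_px_s = 350)

impaired_effect_defaults <- function() list(
  tremor_amp_px = 6, tremor_freq_hz = 6, jitter_px = 3,
  latency_shift_ms = 250, typo_rate = 0.15, error_rate = 0.25,
  voice_jitter_pct = 2.5, voice_shimmer_pct = 8, hnr_db = 12,
  calorie_shift_kcal = -500, speed_px_s = 220)

#' Synthetic cohort profile
#'
#' Class sizes default to the emulated study shape (89 healthy records, 61
#' impaired, from 8 + 7 subjects over up to 5 rounds). `effect_scale`
#' interpolates every impaired effect between the healthy value (0) and
#' the full impaired value (1): scale 0 gives two statistically identical
#' classes (the null-calibration setting), scale 1 the full class
#' separation.
#'
#' @param n_healthy,n_impaired record counts per class.
#' @param n_healthy_subjects,n_impaired_subjects subjects per class.
#' @param effect_scale impairment effect size multiplier in `[0, 1]`.
#' @param seed master RNG seed.
#' @return list of class `cogscreen_cohort`.
#' @export
cohort_profile <- function(n_healthy = 89L, n_impaired = 61L,
                           n_healthy_subjects = 8L, n_impaired_subjects = 7L,
                           effect_scale = 1, seed = 1L) {
  if (n_healthy < 0 || n_impaired < 0) abort_domain("counts must be >= 0")
  h <- healthy_effect_defaults()
  imp_full <- impaired_effect_defaults()
  imp <- stats::setNames(lapply(names(h), function(k)
    h[[k]] + effect_scale * (imp_full[[k]] - h[[k]])), names(h))
  structure(list(n_healthy = as.integer(n_healthy),
                 n_impaired = as.integer(n_impaired),
                 n_healthy_subjects = as.integer(n_healthy_subjects),
                 n_impaired_subjects = as.integer(n_impaired_subjects),
                 healthy = h, impaired = imp,
                 effect_scale = effect_scale, seed = as.integer(seed)),
            class = "cogscreen_cohort")
}

#' Simulate a drawn trajectory over a reference curve
#'
#' Keeps the reference's own points as the spatial base (so zero tremor
#' and zero jitter reproduce the reference exactly), synthesizes
#' monotone timestamps at the profile's drawing speed, and superimposes a
#' sinusoidal tremor in the local normal direction (amplitude and
#' frequency from the effect profile) plus white positional jitter.
#'
#' @param reference curve to trace.
#' @param effects effect list (see [cohort_profile()] fields `healthy` /
#'   `impaired`).
#' @param seed RNG seed.
#' @return a [touch_trajectory()].
#' @export
simulate_trajectory <- function(reference, effects, seed = 1L) {
  ref <- as_curve(resample_curve(reference, 400L))
  set.seed(seed)
  n <- nrow(ref)
  seg <- sqrt(diff(ref$x)^2 + diff(ref$y)^2)
  t_s <- c(0, cumsum(seg)) / max(effects$speed_px_s, 1)
  # local unit normals from the tangent direction
  dx <- c(diff(ref$x), utils::tail(diff(ref$x), 1) %||% 1)
  dy <- c(diff(ref$y), utils::tail(diff(ref$y), 1) %||% 0)
  nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
  nx <- -dy / nrm; ny <- dx / nrm
  phase <- stats::runif(1, 0, 2 * pi)
  trem <- effects$tremor_amp_px * sin(2 * pi * effects$tremor_freq_hz * t_s + phase)
  jx <- stats::rnorm(n, 0, effects$jitter_px)
  jy <- stats::rnorm(n, 0, effects$jitter_px)
  touch_trajectory(
    t_ms = round(t_s * 1000 + effects$latency_shift_ms),
    x_px = ref$x + trem * nx + jx,
    y_px = ref$y + trem * ny + jy)
}

#' Simulate a sustained voice recording
#'
#' Harmonic source built cycle by cycle: each glottal cycle's length is
#' perturbed by the jitter percentage and its amplitude by the shimmer
#' percentage; five harmonics with a 1/h rolloff are summed and white
#' noise added at the target harmonics-to-noise ratio. 48 kHz mono.
#'
#' @param effects effect list with `voice_jitter_pct`, `voice_shimmer_pct`,
#'   `hnr_db`.
#' @param duration_s clip length in seconds (>= 1).
#' @param f0_hz mean fundamental frequency.
#' @param rate_hz sampling rate (default 48000).
#' @param seed RNG seed.
#' @return an [audio_clip()].
#' @export
simulate_voice <- function(effects, duration_s = 2, f0_hz = 140,
                           rate_hz = 48000L, seed = 1L) {
  if (duration_s < 1) abort_domain("duration_s must be >= 1")
  set.seed(seed)
  n_total <- round(duration_s * rate_hz)
  x <- numeric(n_total)
  pos <- 0L
  harm <- 1:5; h_amp <- 1 / harm
  while (pos < n_total) {
    f0_cycle <- f0_hz * (1 + effects$voice_jitter_pct / 100 * stats::rnorm(1))
    f0_cycle <- max(50, min(400, f0_cycle))
    len <- max(8L, round(rate_hz / f0_cycle))
    amp <- 1 + effects$voice_shimmer_pct / 100 * stats::rnorm(1)
    ph <- 2 * pi * seq_len(len) / len
    cyc <- amp * colSums(h_amp * t(sapply(harm, function(h) sin(h * ph))))
    take <- min(len, n_total - pos)
    x[(pos + 1):(pos + take)] <- cyc[seq_len(take)]
    pos <- pos + take
  }
  x <- x / max(abs(x))
  sig_pow <- mean(x^2)
  noise_sd <- sqrt(sig_pow / 10^(effects$hnr_db / 10))
  x <- x + stats::rnorm(n_total, 0, noise_sd)
  audio_clip(0.9 * x / max(abs(x)), rate_hz)
}

## ---- text perturbation ----------------------------------------------------

apply_typos <- function(word, rate) {
  ch <- strsplit(word, "")[[1]]
  for (i in seq_along(ch)) {
    if (ch[i] == " ") next
    r <- stats::runif(1)
    if (r < rate) ch[i] <- sample(letters, 1)
    else if (r < 1.5 * rate && i < length(ch) && ch[i + 1] != " ") {
      tmp <- ch[i]; ch[i] <- ch[i + 1]; ch[i + 1] <- tmp
    }
  }
  paste(ch, collapse = "")
}

## ---- default task geometry -------------------------------------------------

default_t4_reference <- function()
  generate_spiral(center = c(400, 500), spacing_px = 80, turns = 3, n_points = 256L)

default_clock_contour <- function(radius = 310, center = c(400, 450)) {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  data.frame(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

default_t13_puzzle <- function() {
  nodes <- tibble::tibble(
    node_id = paste0("m", 1:8),
    x_px = rep(c(150, 350, 550, 750), 2),
    y_px = rep(c(200, 450), each = 4))
  start_edges <- rbind(c("m1", "m2"), c("m2", "m3"), c("m3", "m4"),
                       c("m5", "m6"), c("m6", "m7"), c("m7", "m8"),
                       c("m1", "m5"), c("m2", "m6"), c("m3", "m7"))
  goal_edges <- rbind(c("m1", "m2"), c("m2", "m3"), c("m3", "m4"),
                      c("m5", "m6"), c("m6", "m7"), c("m7", "m8"),
                      c("m1", "m5"), c("m2", "m6"), c("m4", "m8"))
  list(start = graph_layout(nodes, start_edges, 45),
       goal = graph_layout(nodes, goal_edges, 45),
       ops_budget = 4L, allowed_ops = c("insert", "remove"))
}

segment_curve <- function(x1, y1, x2, y2, n = 24L)
  curve2d(seq(x1, x2, length.out = n), seq(y1, y2, length.out = n))

node_segment <- function(layout, a, b, n = 24L) {
  pa <- layout$nodes[layout$nodes$node_id == a, ]
  pb <- layout$nodes[layout$nodes$node_id == b, ]
  segment_curve(pa$x_px, pa$y_px, pb$x_px, pb$y_px, n)
}

# stroke between two nodes with the subject's tremor, timestamps offset
tremor_stroke <- function(layout, a, b, effects, t0, seed) {
  tr <- simulate_trajectory(node_segment(layout, a, b), effects, seed)
  tr$t_ms <- tr$t_ms + t0
  stroke_action(tr)
}

## ---- full session ----------------------------------------------------------

#' Simulate one full test session
#'
#' Generates all 16 task payloads with the class-conditional effect
#' profile: tap latency and offsets, tremor-bearing spiral and drawing
#' trajectories, graph action logs with the profile's error rate, text
#' answers through the typo model, food/activity diaries with the calorie
#' balance shift, and (optionally) two synthetic voice clips.
#'
#' @param subject a [subject_profile()].
#' @param effects effect list (cohort `healthy` or `impaired` entry).
#' @param round_index visit number 1-5.
#' @param seed RNG seed.
#' @param include_voice synthesize the two T14 clips (default FALSE; the
#'   238-feature schema carries no speech group, so cohort generation
#'   skips the expensive audio synthesis unless asked).
#' @param keys answer key.
#' @return a [session_record()].
#' @export
simulate_session <- function(subject, effects, round_index = 1L, seed = 1L,
                             include_voice = FALSE,
                             keys = default_answer_key()) {
  set.seed(derive_seed(seed, 11))
  err <- effects$error_rate
  typo <- effects$typo_rate
  tasks <- list()

  # T1: 2/3/5-circle tapping layouts
  tasks$T1 <- list(layouts = lapply(c(2L, 3L, 5L), function(nc) {
    tx <- stats::runif(nc, 100, 700); ty <- stats::runif(nc, 150, 900)
    iv <- 600 + effects$latency_shift_ms + stats::rnorm(nc, 0, 60)
    off_sd <- 6 + 3 * effects$tremor_amp_px
    list(taps = tibble::tibble(
      t_ms = round(cumsum(pmax(50, iv))),
      x_px = tx + stats::rnorm(nc, 0, off_sd),
      y_px = ty + stats::rnorm(nc, 0, off_sd)),
      target_x = tx, target_y = ty, target_radius = 55)
  }))

  # T2: five rainbow touches
  tasks$T2 <- list(rt_ms = 500 + effects$latency_shift_ms + stats::rnorm(5, 0, 70),
                   offset_px = abs(stats::rnorm(5, 8 + 3 * effects$tremor_amp_px, 4)))

  # T3: seven multi-touch objects
  tasks$T3 <- tibble::tibble(
    object = 1:7,
    rt_ms = 550 + effects$latency_shift_ms + stats::rnorm(7, 0, 80),
    off_x = stats::rnorm(7, 0, 5 + 2 * effects$tremor_amp_px),
    off_y = stats::rnorm(7, 0, 5 + 2 * effects$tremor_amp_px),
    hold_ms = 120 + 0.5 * effects$latency_shift_ms + abs(stats::rnorm(7, 0, 30)))

  # T4: spiral following and free drawing
  ref <- default_t4_reference()
  draw_effects <- effects
  draw_effects$jitter_px <- effects$jitter_px * 1.5
  tasks$T4 <- list(
    reference = ref,
    follow = simulate_trajectory(ref, effects, derive_seed(seed, 12)),
    draw = simulate_trajectory(ref, draw_effects, derive_seed(seed, 13)),
    match_radius_px = 30)

  # T9: cube construction
  cube <- reference_cube_layout()
  acts <- list(); t0 <- 0
  for (k in seq_len(nrow(cube$edges))) {
    a <- cube$edges$from[k]; b <- cube$edges$to[k]
    r <- stats::runif(1)
    if (r < err / 3) {
      # too-few error: a dab near one node
      p <- cube$nodes[cube$nodes$node_id == a, ]
      tr <- touch_trajectory(t0 + c(0, 30), p$x_px + c(0, 2), p$y_px + c(0, 2))
      acts[[length(acts) + 1]] <- stroke_action(tr)
    } else if (r < 2 * err / 3) {
      # wrong connection: join a non-reference pair
      others <- setdiff(cube$nodes$node_id, c(a, b))
      w <- sample(others, 1)
      acts[[length(acts) + 1]] <- tremor_stroke(cube, a, w, effects, t0,
                                                derive_seed(seed, 20 + k))
    } else {
      acts[[length(acts) + 1]] <- tremor_stroke(cube, a, b, effects, t0,
                                                derive_seed(seed, 20 + k))
      if (r > 1 - err / 3)  # duplicate of an existing connection
        acts[[length(acts) + 1]] <- tremor_stroke(cube, a, b, effects, t0 + 1500,
                                                  derive_seed(seed, 40 + k))
    }
    t0 <- t0 + 2000
  }
  acts <- acts[order(vapply(acts, function(a) a$t_ms, numeric(1)))]
  tasks$T9 <- list(log = graph_action_log(acts), layout = cube, reference = cube)

  # T10: clock drawing inside the active contour
  contour <- default_clock_contour()
  th <- seq(0, 2 * pi, length.out = 80)
  face <- curve2d(400 + 280 * cos(th), 450 + 280 * sin(th))
  hand1 <- segment_curve(400, 450, 400 + 150 * cos(pi / 3), 450 - 150 * sin(pi / 3), 20)
  hand2 <- segment_curve(400, 450, 400 + 210 * cos(-pi / 6), 450 - 210 * sin(-pi / 6), 24)
  strokes <- lapply(seq_along(list(face, hand1, hand2)), function(i)
    simulate_trajectory(list(face, hand1, hand2)[[i]], effects,
                        derive_seed(seed, 60 + i)))
  sup <- max(0L, min(4L, round(4 - effects$tremor_amp_px / 2 + stats::rnorm(1, 0, 0.3))))
  tasks$T10 <- list(strokes = strokes, contour = contour, supervisor_score = sup)

  # T11: verbal fluency with the typo model
  dict <- unlist(keys$dictionaries[["animals"]])
  n_known <- max(0L, min(12L, round(12 - 6 * err + stats::rnorm(1, 0, 0.5))))
  words <- sample(dict, n_known)
  items <- c(vapply(words, apply_typos, character(1), rate = typo),
             rep("", 12 - n_known))
  tasks$T11 <- list(items = items, category = "animals")

  # T12: modified trails
  tl <- trails_layout()
  seq_ids <- tl$nodes$node_id[order(match(tl$nodes$label,
                                          target_trail_sequence(nrow(tl$nodes))))]
  acts <- list(); t0 <- 0
  for (k in seq_len(length(seq_ids) - 1)) {
    a <- seq_ids[k]; b <- seq_ids[k + 1]
    r <- stats::runif(1)
    if (r < err / 2) {
      wrong <- sample(setdiff(tl$nodes$node_id, c(a, b)), 1)
      acts[[length(acts) + 1]] <- tremor_stroke(tl, a, wrong, effects, t0,
                                                derive_seed(seed, 80 + k))
    } else {
      acts[[length(acts) + 1]] <- tremor_stroke(tl, a, b, effects, t0,
                                                derive_seed(seed, 80 + k))
    }
    t0 <- t0 + 2500
  }
  tasks$T12 <- list(log = graph_action_log(acts), layout = tl)

  # T13: match puzzle via node touches
  pz <- default_t13_puzzle()
  moves <- list(c("m3", "m7"), c("m4", "m8"))  # remove then insert reaches goal
  acts <- list(); t0 <- 0
  for (mv in moves) {
    if (stats::runif(1) < err) {  # fumbled: same node twice
      acts[[length(acts) + 1]] <- node_touch_action(mv[1], t0)
      acts[[length(acts) + 1]] <- node_touch_action(mv[1], t0 + 400)
      t0 <- t0 + 800
    }
    if (stats::runif(1) < err / 2) {  # touch outside any node zone
      acts[[length(acts) + 1]] <- node_touch_action("", t0)
      t0 <- t0 + 400
    }
    acts[[length(acts) + 1]] <- node_touch_action(mv[1], t0)
    acts[[length(acts) + 1]] <- node_touch_action(mv[2], t0 + 600)
    t0 <- t0 + 1200
  }
  tasks$T13 <- c(list(log = graph_action_log(acts)), pz)

  # cognitive text answers
  today <- keys$today
  tasks$T6 <- list(year = today$year,
                   month = if (stats::runif(1) < err / 2)
                     (today$month %% 12) + 1 else today$month,
                   day = if (stats::runif(1) < err)
                     (today$day %% 28) + 1 else today$day)
  pic_names <- vapply(keys$pictures[1:2], function(p) unlist(p)[1], character(1))
  tasks$T7 <- list(answers = vapply(pic_names, apply_typos, character(1), rate = typo))
  q3 <- if (stats::runif(1) < 1 - err) unlist(keys$q3_abstract)[1]
        else unlist(keys$q3_concrete)[1]
  tasks$T8 <- list(
    q3 = apply_typos(q3, typo),
    q4 = if (stats::runif(1) < 1 - err) keys$q4$bill - keys$q4$amount
         else keys$q4$bill - keys$q4$amount + sample(c(-1, 0.5, 1), 1),
    q5 = if (stats::runif(1) < 1 - err) keys$q5$sum / keys$q5$denomination
         else round(keys$q5$sum / keys$q5$denomination) + sample(1:3, 1))
  tasks$T0 <- list(answer = if (stats::runif(1) < 1 - err)
    unlist(keys$memory_phrases)[1]
    else if (stats::runif(1) < 0.5) "I am done now" else "hello")
  tasks$T5 <- list(
    memory_problems = err > 0.1, thinking_problems = err > 0.15,
    depression = FALSE, motor_symptoms = effects$tremor_amp_px > 3,
    stroke_history = FALSE, personality_change = FALSE,
    functional_ability = min(3, round(4 * err)), symptom_duration = min(3, round(4 * err)))

  # T15: diaries hitting the class's calorie balance
  b <- bmr(subject)
  td <- tdee(b, subject$pal)
  products <- default_product_table()
  mets <- default_met_table()
  target_burn <- stats::runif(1, 150, 400)
  acts15 <- products[sample.int(nrow(products), 4), ]
  target_gain <- td + effects$calorie_shift_kcal + stats::rnorm(1, 0, 80)
  share <- stats::runif(4); share <- share / sum(share)
  food <- tibble::tibble(
    name = acts15$name,
    grams = pmax(10, share * target_gain / (acts15$kcal_per_100g / 100)),
    kcal_per_100g = acts15$kcal_per_100g,
    mealtime = sample(c("breakfast", "dinner", "supper"), 4, replace = TRUE))
  act_rows <- mets[sample.int(nrow(mets), 2), ]
  minutes <- pmax(5, target_burn / (act_rows$met * subject$weight_kg / 60) / 2)
  activities <- tibble::tibble(name = act_rows$name, met = act_rows$met,
                               minutes = minutes,
                               time_of_day = sample(c("morning", "day", "evening"),
                                                    2, replace = TRUE))
  tasks$T15 <- list(food = food, activities = activities)

  if (include_voice) {
    f0 <- if (subject$gender == "man") 120 else 200
    tasks$T14 <- list(clips = lapply(1:2, function(i)
      simulate_voice(effects, duration_s = 2, f0_hz = f0,
                     seed = derive_seed(seed, 300 + i))))
  }

  base_dur <- c(T0 = 10, T1 = 20, T2 = 15, T3 = 20, T4 = 25, T5 = 60, T6 = 20,
                T7 = 30, T8 = 60, T9 = 60, T10 = 60, T11 = 90, T12 = 60,
                T13 = 60, T14 = 40, T15 = 120)
  durations <- pmax(3, base_dur * (1 + effects$latency_shift_ms / 1000) +
                      stats::rnorm(16, 0, base_dur * 0.1))
  names(durations) <- names(base_dur)

  session_record(subject, round_index, tasks, durations)
}

#' Simulate a labeled cohort and its feature table
#'
#' Distributes the requested record counts over the class's subjects
#' (round-robin rounds 1-5), simulates each session and extracts the
#' 238-feature vector, returning the labeled feature table.
#'
#' @param cohort a [cohort_profile()].
#' @param keys answer key.
#' @param include_voice forward to [simulate_session()].
#' @return tibble with `n_healthy + n_impaired` rows: `subject_id`,
#'   `round_index`, `label` and the 238 features.
#' @export
simulate_cohort <- function(cohort, keys = default_answer_key(),
                            include_voice = FALSE) {
  make_subjects <- function(n_sub, label, prefix, seed0) {
    lapply(seq_len(n_sub), function(i) {
      set.seed(derive_seed(cohort$seed, seed0 + i))
      gender <- sample(c("man", "woman"), 1)
      subject_profile(sprintf("%s%02d", prefix, i), gender,
                      age_years = sample(20:75, 1),
                      height_m = round(stats::runif(1, 1.55, 1.92), 2),
                      weight_kg = round(stats::runif(1, 52, 98), 1),
                      pal = sample(VALID_PAL[1:3], 1), label = label)
    })
  }
  healthy_subjects <- make_subjects(cohort$n_healthy_subjects, 0L, "H", 500)
  impaired_subjects <- make_subjects(cohort$n_impaired_subjects, 1L, "S", 600)

  one_class <- function(n_rec, subjects, effects, seed0) {
    if (n_rec == 0) return(NULL)
    sub_idx <- rep_len(seq_along(subjects), n_rec)
    rounds <- unlist(lapply(table(sub_idx), function(k) rep_len(1:5, k)))
    dplyr::bind_rows(lapply(seq_len(n_rec), function(r) {
      s <- simulate_session(subjects[[sub_idx[r]]], effects,
                            round_index = rounds[r],
                            seed = derive_seed(cohort$seed, seed0 + r),
                            include_voice = include_voice, keys = keys)
      extract_features(s, keys)
    }))
  }
  dplyr::bind_rows(
    one_class(cohort$n_healthy, healthy_subjects, cohort$healthy, 1000),
    one_class(cohort$n_impaired, impaired_subjects, cohort$impaired, 5000))
}

## ---- config tables ---------------------------------------------------------

#' Editable product and activity tables
#'
#' Small bundled CSV lists: product calorie norms per 100 g and activity
#' MET coefficients, both user-replaceable.
#'
#' @param path CSV path (defaults to the bundled table).
#' @return tibble.
#' @export
default_product_table <- function(path = system.file("extdata", "products.csv",
                                                     package = "cogscreen"))
  tibble::as_tibble(utils::read.csv(path))

#' @rdname default_product_table
#' @export
default_met_table <- function(path = system.file("extdata", "met_activities.csv",
                                                 package = "cogscreen"))
  tibble::as_tibble(utils::read.csv(path))
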