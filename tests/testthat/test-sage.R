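test_that("Jaro and Jaro-Winkler reproduce the published reference values", {
  expect_equal(jaro("identical", "identical"), 1)
  expect_equal(jaro_winkler("identical", "identical"), 1)
  expect_equal(jaro("abc", "xyz"), 0)
  expect_equal(jaro("MARTHA", "MARHTA"), 17 / 18, tolerance = 1e-12)   # 0.9444
  expect_equal(jaro_winkler("MARTHA", "MARHTA"), 0.9611111, tolerance = 1e-6)
  expect_equal(jaro("DIXON", "DICKSONX"), 0.7666667, tolerance = 1e-6)
  expect_equal(jaro_winkler("DIXON", "DICKSONX"), 0.8133333, tolerance = 1e-6)
  expect_equal(jaro("", ""), 1)
  expect_equal(jaro("", "abc"), 0)
})

test_that("Jaro-Winkler matches an independent implementation on random strings", {
  set.seed(31)
  alphabet <- letters[1:6]
  for (rep in 1:60) {
    s1 <- paste(sample(alphabet, sample(0:8, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(alphabet, sample(1:8, 1), replace = TRUE), collapse = "")
    o <- oracle_jw(s1, s2)
    expect_equal(jaro(s1, s2), o$jaro, tolerance = 1e-12,
                 label = sprintf("jaro('%s','%s')", s1, s2))
    expect_equal(jaro_winkler(s1, s2), o$jw, tolerance = 1e-12)
    # invariants: symmetry and the Winkler boost direction
    expect_equal(jaro(s1, s2), jaro(s2, s1))
    expect_gte(jaro_winkler(s1, s2), jaro(s1, s2))
  }
})

test_that("orientation scoring gives one point per matching date component", {
  today <- list(year = 2019, month = 5, day = 10)
  expect_equal(score_orientation(list(year = 2019, month = 5, day = 10), today)$points, 3L)
  expect_equal(score_orientation(list(year = 1999, month = 1, day = 1), today)$points, 0L)
  expect_equal(score_orientation(list(year = 2019, month = 5, day = 11), today)$points, 2L)
  expect_error(score_orientation(list(year = 2019, month = 13, day = 1), today),
               class = "cogscreen_validation_error")
})

test_that("picture naming credits spelling errors through Jaro-Winkler", {
  key <- default_answer_key()
  exact <- score_picture_naming(c("elephant", "wheelbarrow"), key)
  expect_equal(exact$points, 2L)
  expect_equal(exact$aux$jw_average, 1)

  misspelled <- score_picture_naming(c("elefant", "wheelbarrow"), key)
  expect_equal(misspelled$points, 2L)   # credited: jw above threshold
  expect_lt(misspelled$aux$jw_1, 1)
  expect_gt(misspelled$aux$jw_1, 0.9)

  blank <- score_picture_naming(c("", ""), key)
  expect_equal(blank$points, 0L)
  expect_equal(blank$aux$jw_average, 0)
  expect_error(score_picture_naming("one", key), class = "cogscreen_validation_error")
})

test_that("similarities and calculation follow the 2/1 and exact-arithmetic rules", {
  key <- default_answer_key()
  abst <- score_similarities_calculation("measuring instruments", 6.55, 9, key)
  expect_equal(abst$aux$q3_points, 2L)
  expect_equal(abst$aux$q4_points, 1L)   # 20 - 13.45 = 6.55
  expect_equal(abst$aux$q5_points, 1L)   # 2.25 / 0.25 = 9
  expect_equal(abst$points, 4L)

  conc <- score_similarities_calculation("both have numbers", 6.554, 9, key)
  expect_equal(conc$aux$q3_points, 1L)
  expect_equal(conc$aux$q4_points, 1L)   # within the 0.005 tolerance
  q4_off <- score_similarities_calculation("nonsense", 6.56, 8.99, key)
  expect_equal(q4_off$points, 0L)
  flagged <- score_similarities_calculation("tools", "not a number", "x", key)
  expect_equal(flagged$aux$q4_invalid, 1)
  expect_equal(flagged$aux$q5_invalid, 1)
})

straight_stroke <- function(layout, a, b, t0 = 0, n = 12) {
  pa <- layout$nodes[layout$nodes$node_id == a, ]
  pb <- layout$nodes[layout$nodes$node_id == b, ]
  touch_trajectory(t0 + seq(0, 220, length.out = n),
                   seq(pa$x_px, pb$x_px, length.out = n),
                   seq(pa$y_px, pb$y_px, length.out = n))
}

test_that("3-D construction replay maintains the four error counters", {
  cube <- reference_cube_layout()
  perfect <- graph_action_log(lapply(seq_len(nrow(cube$edges)), function(k)
    stroke_action(straight_stroke(cube, cube$edges$from[k], cube$edges$to[k],
                                  t0 = (k - 1) * 500))))
  sc <- score_construction_3d(perfect, cube, cube)
  expect_equal(sc$aux$wrong_connection, 0L)
  expect_equal(sc$aux$too_few, 0L)
  expect_equal(sc$aux$too_many, 0L)
  expect_equal(sc$aux$existing, 0L)
  expect_equal(sc$aux$similarity, 1)
  expect_equal(sc$points, 2L)

  one_node <- graph_action_log(list(stroke_action(
    touch_trajectory(c(0, 30), rep(cube$nodes$x_px[1], 2), rep(cube$nodes$y_px[1], 2)))))
  expect_equal(score_construction_3d(one_node, cube, cube)$aux$too_few, 1L)

  dup <- graph_action_log(list(
    stroke_action(straight_stroke(cube, "1", "2", 0)),
    stroke_action(straight_stroke(cube, "2", "1", 500))))
  expect_equal(score_construction_3d(dup, cube, cube)$aux$existing, 1L)
})

test_that("error counters are monotone in the action-log prefix", {
  cube <- reference_cube_layout()
  acts <- list(
    stroke_action(straight_stroke(cube, "1", "3", 0)),      # wrong connection
    stroke_action(touch_trajectory(c(500, 520), rep(cube$nodes$x_px[2], 2),
                                   rep(cube$nodes$y_px[2], 2))),  # too few
    stroke_action(straight_stroke(cube, "1", "2", 1000)),
    stroke_action(straight_stroke(cube, "1", "2", 1500)))   # existing
  totals <- sapply(seq_along(acts), function(k) {
    sc <- score_construction_3d(graph_action_log(acts[seq_len(k)]), cube, cube)
    with(sc$aux, wrong_connection + too_few + too_many + existing)
  })
  expect_true(all(diff(totals) >= 0))
  expect_equal(totals[4], 3)
})

test_that("clock scoring counts boundary violations and records the supervisor score", {
  contour <- data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  inside <- touch_trajectory(0:9 * 10, seq(10, 90, length.out = 10), rep(50, 10))
  expect_equal(score_clock(list(inside), contour)$aux$boundary_errors, 0)
  mixed <- touch_trajectory(0:9 * 10, seq(50, 140, length.out = 10), rep(50, 10))
  expect_equal(score_clock(list(mixed), contour)$aux$boundary_errors, 5)
  sup <- score_clock(list(inside), contour, supervisor_score = 4)
  expect_equal(sup$points, 4L)
})

test_that("verbal fluency applies the 12/10-11/other point rule", {
  dict <- unlist(default_answer_key()$dictionaries$animals)
  twelve <- score_verbal_fluency(dict[1:12], dict)
  expect_equal(twelve$points, 2L)
  expect_equal(twelve$aux$jw_average, 1)
  ten <- score_verbal_fluency(c(dict[1:10], "", ""), dict)
  expect_equal(ten$points, 1L)
  five <- score_verbal_fluency(c(dict[1:5], rep("", 7)), dict)
  expect_equal(five$points, 0L)
  dup <- score_verbal_fluency(c(dict[1:11], dict[11]), dict)
  expect_equal(dup$points, 1L)   # 11 distinct correct
  misspelled <- score_verbal_fluency(c("dogg", dict[2:12]), dict)
  expect_equal(misspelled$points, 2L)    # JW above threshold still correct
  expect_lt(misspelled$aux$jw_average, 1)
  invalid <- score_verbal_fluency(c("a b c d", dict[2:12]), dict)
  expect_equal(invalid$aux$n_invalid, 1)
  expect_error(score_verbal_fluency(dict[1:5], dict),
               class = "cogscreen_validation_error")
})

test_that("trail making forms paths only from exactly two resolved nodes", {
  tl <- trails_layout()
  ids <- tl$nodes$node_id[order(match(tl$nodes$label, target_trail_sequence(12)))]
  full <- graph_action_log(lapply(seq_len(11), function(k)
    stroke_action(straight_stroke(tl, ids[k], ids[k + 1], t0 = (k - 1) * 400))))
  sc <- score_trails(full, tl)
  expect_equal(sc$aux$similarity, 1)
  expect_equal(sc$aux$wrong_connection + sc$aux$same_node + sc$aux$outside_click, 0L)
  expect_equal(sc$aux$n_paths, 11)
  expect_true(all(sc$aux$path_frechet < 1e-9))
  expect_equal(sc$points, 2L)

  three <- graph_action_log(list(stroke_action(touch_trajectory(
    seq(0, 400, length.out = 40),
    approx(c(1, 20, 40), tl$nodes$x_px[1:3], xout = 1:40)$y,
    approx(c(1, 20, 40), tl$nodes$y_px[1:3], xout = 1:40)$y))))
  sc3 <- score_trails(three, tl)
  expect_equal(sc3$aux$wrong_connection, 1L)
  expect_equal(sc3$aux$n_paths, 0)

  off <- graph_action_log(list(stroke_action(touch_trajectory(c(0, 50), c(5, 6), c(5, 6)))))
  expect_equal(score_trails(off, tl)$aux$outside_click, 1L)
})

test_that("problem solving executes insert/remove under budget and rules", {
  pz <- cogscreen:::default_t13_puzzle()
  good <- graph_action_log(list(
    node_touch_action("m3", 0), node_touch_action("m7", 400),    # remove
    node_touch_action("m4", 900), node_touch_action("m8", 1300))) # insert
  sc <- score_problem_solving(good, pz$start, pz$goal, pz$ops_budget)
  expect_equal(sc$aux$similarity, 1)
  expect_equal(sc$aux$goal_reached, 1)
  expect_equal(sc$aux$same_node + sc$aux$outside_zone + sc$aux$rule_violation, 0L)
  expect_equal(sc$points, 2L)

  viol <- graph_action_log(list(node_touch_action("m4", 0), node_touch_action("m8", 300)))
  sc_v <- score_problem_solving(viol, pz$start, pz$goal, 4, allowed_ops = "remove")
  expect_equal(sc_v$aux$rule_violation, 1L)
  expect_equal(nrow(sc_v$aux$final_graph$edges), nrow(pz$start$edges))  # unchanged

  same <- graph_action_log(list(node_touch_action("m1", 0), node_touch_action("m1", 200)))
  expect_equal(score_problem_solving(same, pz$start, pz$goal, 4)$aux$same_node, 1L)

  # budget exhausted: later touches are ignored
  over <- graph_action_log(list(
    node_touch_action("m3", 0), node_touch_action("m7", 100),
    node_touch_action("m4", 200), node_touch_action("m8", 300)))
  sc_b <- score_problem_solving(over, pz$start, pz$goal, 1)
  expect_equal(sc_b$aux$ops_used, 1L)
  expect_equal(sc_b$aux$ops_left, 0L)
})

test_that("memory recall scores 2/1/0 per the phrase rule", {
  expect_equal(score_memory("Have you finished?")$points, 2L)
  expect_equal(score_memory("have you FINISHED")$points, 2L)  # punctuation/case folded
  expect_equal(score_memory("I am done now")$points, 1L)
  expect_equal(score_memory("hello")$points, 0L)
})

test_that("insights encoding is deterministic, order-stable and validated", {
  q <- list(memory_problems = TRUE, thinking_problems = FALSE, depression = FALSE,
            motor_symptoms = TRUE, stroke_history = FALSE, personality_change = FALSE,
            functional_ability = 2, symptom_duration = 1)
  enc <- encode_insights(q)
  expect_length(enc, 8)
  expect_identical(enc, encode_insights(q))
  expect_equal(unname(enc[c(1, 4, 7, 8)]), c(1, 1, 2, 1))
  all_no <- encode_insights(list(memory_problems = FALSE, thinking_problems = FALSE,
                                 depression = FALSE, motor_symptoms = FALSE,
                                 stroke_history = FALSE, personality_change = FALSE,
                                 functional_ability = 0, symptom_duration = 0))
  expect_true(all(all_no == 0))
  expect_error(encode_insights(q[-1]), class = "cogscreen_validation_error")
})
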