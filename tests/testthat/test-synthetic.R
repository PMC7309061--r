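test_that("trajectory simulation is exact at zero effects and seed-deterministic", {
  ref <- generate_spiral(c(200, 200), 60, 2, n_points = 120)
  tr0 <- simulate_trajectory(ref, zero_effects(), seed = 4)
  expect_lt(max(abs(tr0$x_px - ref$x)), 1e-9)
  expect_lt(max(abs(tr0$y_px - ref$y)), 1e-9)
  expect_false(is.unsorted(tr0$t_ms))

  co <- cohort_profile(seed = 1)
  a <- simulate_trajectory(ref, co$impaired, seed = 9)
  b <- simulate_trajectory(ref, co$impaired, seed = 9)
  expect_identical(a, b)
})

test_that("impaired tremor dominates healthy Frechet distance to the reference", {
  co <- cohort_profile(seed = 1)
  ref <- generate_spiral(c(300, 300), 70, 2.5, n_points = 150)
  wins <- 0L
  for (k in 1:100) {
    dh <- discrete_frechet(simulate_trajectory(ref, co$healthy, seed = k), ref)
    di <- discrete_frechet(simulate_trajectory(ref, co$impaired, seed = k), ref)
    wins <- wins + (di > dh)
  }
  expect_gte(wins, 95)
})

test_that("clean synthetic voices expose their generating fundamental", {
  co <- cohort_profile(seed = 1)
  clean <- co$healthy
  clean$voice_jitter_pct <- 0; clean$voice_shimmer_pct <- 0; clean$hnr_db <- 60
  clip <- simulate_voice(clean, duration_s = 1.5, f0_hz = 140, seed = 2)
  expect_identical(clip$rate_hz, 48000L)
  p <- pitch(clip, "ncf")
  expect_lt(abs(median(p$f0_hz[p$voiced]) - 140), 1.5)
  expect_identical(clip$samples,
                   simulate_voice(clean, duration_s = 1.5, f0_hz = 140, seed = 2)$samples)
  expect_error(simulate_voice(clean, duration_s = 0.5), class = "cogscreen_domain_error")
})

test_that("voice jitter raises the per-frame pitch spread monotonically", {
  co <- cohort_profile(seed = 1)
  spread <- sapply(c(0.3, 1.5, 4), function(j) {
    e <- co$healthy
    e$voice_jitter_pct <- j; e$voice_shimmer_pct <- 1; e$hnr_db <- 35
    clip <- simulate_voice(e, duration_s = 1.5, f0_hz = 150, seed = 11)
    p <- pitch(clip, "ncf")
    stats::sd(p$f0_hz[p$voiced])
  })
  expect_true(all(diff(spread) > 0))
})

test_that("cohort simulation honors the requested class and subject structure", {
  mini <- cohort_profile(n_healthy = 4, n_impaired = 3,
                         n_healthy_subjects = 2, n_impaired_subjects = 2, seed = 5)
  tab <- simulate_cohort(mini)
  expect_identical(nrow(tab), 7L)
  expect_identical(sum(tab$label == 0), 4L)
  expect_identical(sum(tab$label == 1), 3L)
  expect_identical(length(unique(tab$subject_id[tab$label == 0])), 2L)
  expect_true(all(tab$round_index %in% 1:5))
  expect_identical(ncol(tab), 241L)
  expect_false(anyNA(tab[, feature_schema()$feature]))
  # reproducible from the same profile
  tab2 <- simulate_cohort(mini)
  expect_equal(as.matrix(tab[, feature_schema()$feature]),
               as.matrix(tab2[, feature_schema()$feature]))
})

test_that("class-separating statistics shift with their effect parameters", {
  n <- 6
  co <- cohort_profile(seed = 3)
  sub <- subject_profile("x", "man", 50, 1.78, 82, label = 0)
  stat <- function(effects, field) {
    sapply(1:n, function(k) {
      s <- simulate_session(sub, effects, seed = 400 + k)
      v <- extract_features(s)
      v[[field]]
    })
  }
  expect_gt(mean(stat(co$impaired, "t4f_frechet")),
            mean(stat(co$healthy, "t4f_frechet")))
  expect_lt(mean(stat(co$impaired, "t11_jw_average")),
            mean(stat(co$healthy, "t11_jw_average")))
  expect_lt(mean(stat(co$impaired, "t15_p_balance")),
            mean(stat(co$healthy, "t15_p_balance")))
  expect_gt(mean(stat(co$impaired, "duration_T11")),
            mean(stat(co$healthy, "duration_T11")))
})

test_that("voice clips are attached only on request", {
  co <- cohort_profile(seed = 2)
  sub <- subject_profile("v", "woman", 30, 1.7, 60, label = 0)
  s <- simulate_session(sub, co$healthy, seed = 1)
  expect_null(s$tasks$T14)
  sv <- simulate_session(sub, co$healthy, seed = 1, include_voice = TRUE)
  expect_length(sv$tasks$T14$clips, 2)
  expect_s3_class(sv$tasks$T14$clips[[1]], "cogscreen_audio")
})
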