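test_that("track CSV parsing sorts frames and rejects malformed input", {
  d <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TRACK_ID,FRAME,POSITION_X,POSITION_Y",
               "1,2,30,0", "1,0,10,0", "1,1,20,0",
               "2,0,5,1", "2,1,6,1"), d)
  got <- read_tracks(d)
  expect_equal(unique(got$TRACK_ID), c(1, 2))
  expect_equal(got$FRAME[got$TRACK_ID == 1], 0:2)
  expect_equal(got$POSITION_X[got$TRACK_ID == 1], c(10, 20, 30))
  writeLines(c("TRACK_ID,FRAME,POSITION_X,POSITION_Y", "1,0,1,0", "1,0,2,0"), d)
  expect_error(read_tracks(d), "duplicate")
  writeLines(c("TRACK_ID,FRAME,POSITION_X,POSITION_Y", "1,0.5,1,0"), d)
  expect_error(read_tracks(d), "non-integer")
})

test_that("synthetic tracks round-trip through the CSV dialect", {
  geom <- ridge_geometry(n_ridges = 3)
  sim <- simulate_tracks(geom, 3, deflection_model(1, 0.5), pos_noise = 0.1,
                         seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, path)
  back <- read_tracks(path)
  expect_equal(back$POSITION_Y, sim$tracks$POSITION_Y, tolerance = 1e-6)
  expect_equal(nrow(back), nrow(sim$tracks))
})

test_that("ridge windowing follows the along-flow distance rule", {
  geom <- ridge_geometry(n_ridges = 1, x_first = 100, angle_deg = 0,
                         width = 10)
  track <- data.frame(TRACK_ID = 1, FRAME = 0:3,
                      POSITION_X = c(90, 96, 104, 110),
                      POSITION_Y = rep(0, 4))
  win <- ridge_windows(track, geom)
  expect_equal(win[[1]], c(2L, 3L))  # x = 96, 104 within 100 +/- 5
  # entirely upstream track gets empty windows
  up <- data.frame(TRACK_ID = 1, FRAME = 0:2, POSITION_X = c(1, 2, 3),
                   POSITION_Y = 0)
  expect_equal(lengths(ridge_windows(up, geom)), 0L)
  # shrinking the width shrinks every interval
  geom_narrow <- ridge_geometry(n_ridges = 1, x_first = 100, angle_deg = 0,
                                width = 6)
  expect_true(all(lengths(ridge_windows(track, geom_narrow)) <=
                    lengths(win)))
})

test_that("track metrics recover generator truth and are y-translation invariant", {
  geom <- ridge_geometry(n_ridges = 6)
  sim <- simulate_tracks(geom, 6, deflection_model(mean = 2, sd = 1),
                         pos_noise = 0, seed = 6)
  m <- all_track_metrics(sim$tracks, geom, fps = 2500)
  truth_cum <- rowSums(sim$truth$deflections[, 1:5])
  expect_equal(m$cum_deflection, truth_cum, tolerance = 1e-6)
  # per-ridge dwell matches within one frame
  t1 <- sim$tracks[sim$tracks$TRACK_ID == 1, ]
  per <- attr(track_metrics(t1, geom, fps = 2500), "per_ridge")
  expect_true(all(abs(per$time - sim$truth$dwells[1, ]) <= 2 / 2500))
  # translating y changes no deflection
  shifted <- sim$tracks
  shifted$POSITION_Y <- shifted$POSITION_Y + 17
  m2 <- all_track_metrics(shifted, geom, fps = 2500)
  expect_equal(m2$cum_deflection, m$cum_deflection, tolerance = 1e-9)
  # straight horizontal track: zero everywhere
  flat <- simulate_tracks(geom, 2, deflection_model(0, 0), pos_noise = 0,
                          seed = 7)
  expect_equal(all_track_metrics(flat$tracks, geom, 2500)$cum_deflection,
               c(0, 0))
})

test_that("interaction time is invariant to y position noise", {
  # straight (theta = 0) ridges: window membership depends on x only
  geom <- ridge_geometry(n_ridges = 4, angle_deg = 0)
  clean <- simulate_tracks(geom, 5, deflection_model(2, 0), pos_noise = 0,
                           seed = 8)
  m_clean <- all_track_metrics(clean$tracks, geom, 2500)
  noisy <- clean
  set.seed(1)
  noisy$tracks$POSITION_Y <- noisy$tracks$POSITION_Y + rnorm(nrow(noisy$tracks), sd = 0.3)
  m_noisy <- all_track_metrics(noisy$tracks, geom, 2500)
  expect_equal(m_noisy$cum_time, m_clean$cum_time, tolerance = 1e-9)
})

test_that("group comparison detects a stiff shift and a variance inflation", {
  geom <- ridge_geometry(n_ridges = 6)
  ctrl <- simulate_tracks(geom, 80, deflection_model(0, 2), pos_noise = 0.3,
                          seed = 10)
  shift <- simulate_tracks(geom, 80, deflection_model(2, 2), pos_noise = 0.3,
                           seed = 11)
  m_c <- all_track_metrics(ctrl$tracks, geom, 2500)
  m_s <- all_track_metrics(shift$tracks, geom, 2500)
  cmp <- summarize_track_groups(m_c, m_s)
  expect_lt(cmp$deflection$welch_p, 0.001)
  # equal means, inflated variance: BF significant, Welch not
  infl <- simulate_tracks(geom, 80, deflection_model(0, 6), pos_noise = 0.3,
                          seed = 12)
  m_i <- all_track_metrics(infl$tracks, geom, 2500)
  cmp2 <- summarize_track_groups(m_c, m_i)
  expect_lt(cmp2$deflection$bf_p, 0.01)
  expect_gt(cmp2$deflection$welch_p, 0.01)
})

test_that("outlet fractions form a simplex and track planted stiff cells", {
  geom <- ridge_geometry(n_ridges = 6)
  sim <- simulate_tracks(geom, 60, deflection_model(0, 1), pos_noise = 0.1,
                         seed = 13)
  fr <- outlet_fractions(all_track_metrics(sim$tracks, geom, 2500))
  expect_equal(sum(fr), 1)
  expect_true(all(fr >= 0))
  # all tracks ending low in y land in outlet 1
  low <- simulate_tracks(geom, 10, deflection_model(0, 0), pos_noise = 0,
                         y_start = -250, seed = 14)
  fr_low <- outlet_fractions(all_track_metrics(low$tracks, geom, 2500))
  expect_equal(unname(fr_low), c(1, 0, 0, 0, 0))
  # ~3% of cells given a large positive deflection reach outlets 4-5
  n <- 200
  mixed <- lapply(seq_len(n), function(i) {
    stiff <- i <= 6   # 3%
    s <- simulate_tracks(geom, 1,
                         deflection_model(if (stiff) 45 else 0, 0.5),
                         pos_noise = 0.1, seed = 1000 + i)
    s$tracks$TRACK_ID <- i
    s$tracks
  })
  m <- all_track_metrics(do.call(rbind, mixed), geom, 2500)
  fr_mix <- outlet_fractions(m)
  expect_equal(unname(fr_mix["outlet4"] + fr_mix["outlet5"]), 0.03,
               tolerance = 0.01)
})
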