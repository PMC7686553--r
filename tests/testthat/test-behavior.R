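test_that("binned distance sums steps per bin, additively and non-negatively", {
  geom <- circle_geometry(radius = 4000)
  wp <- data.frame(x = c(0, 3000, 3000), y = c(0, 0, 2000))
  tr <- generate_trajectory("open_field", waypoints = wp, speed = 5,
                            geometry = geom)
  bd <- binned_distance(tr, 600)
  expect_equal(bd$distance_cm[1], 3000)
  expect_equal(sum(bd$distance_cm), 5000)
  ## additivity: one 1200 s bin equals the sum of two 600 s bins
  bd2 <- binned_distance(tr, 1200)
  expect_equal(bd2$distance_cm[1], sum(bd$distance_cm[1:2]))
  expect_true(all(bd$distance_cm >= 0))
  ## stationary path
  still <- trajectory(0:10, rep(1, 11), rep(1, 11), geom)
  expect_true(all(binned_distance(still, 5)$distance_cm == 0))
  expect_warning(binned_distance(trajectory(0, 1, 1, geom)), "single")
})

test_that("epoch velocities divide distance by duration and ignore time origin", {
  geom <- circle_geometry(radius = 4000)
  wp <- data.frame(x = c(-3000, 3000), y = c(0, 0))
  tr <- generate_trajectory("open_field", waypoints = wp, speed = 5,
                            geometry = geom)
  ep <- epoch_velocity(tr, data.frame(start_s = c(0, 600),
                                      end_s = c(600, 1200)))
  expect_equal(ep$velocity_cm_s, c(5, 5), tolerance = 1e-6)
  ## uniform time translation leaves velocities unchanged
  tr2 <- tr; tr2$t <- tr2$t + 100
  ep2 <- epoch_velocity(tr2, data.frame(start_s = c(100, 700),
                                        end_s = c(700, 1300)))
  expect_equal(ep2$velocity_cm_s, ep$velocity_cm_s)
})

test_that("rotation counting recovers scripted loops and is rotation-invariant", {
  geom <- circle_geometry(radius = 50)
  th <- seq(0, 6 * pi, length.out = 600)  # 3 CCW loops of radius 5
  tr <- trajectory(seq_along(th) / 10, 5 * cos(th), 5 * sin(th), geom)
  expect_equal(count_rotations(tr, min_radius_cm = 2), 3L)
  ## straight path: none
  straight <- trajectory(1:100, seq(-40, 40, length.out = 100),
                         rep(0, 100), geom)
  expect_equal(count_rotations(straight), 0L)
  ## figure-eight: one CW + one CCW loop, counted unsigned
  t1 <- seq(0, 2 * pi, length.out = 200)
  ## left loop traversed CCW, right loop CW, smooth crossover at the origin
  x8 <- c(5 * cos(t1) - 5, 5 - 5 * cos(t1))
  y8 <- c(5 * sin(t1), 5 * sin(t1))
  tr8 <- trajectory(seq_along(x8) / 10, x8, y8, geom)
  expect_equal(count_rotations(tr8, min_radius_cm = 2), 2L)
  ## global rotation of coordinates leaves the count unchanged
  a <- pi / 5
  trr <- trajectory(tr8$t, cos(a) * x8 - sin(a) * y8,
                    sin(a) * x8 + cos(a) * y8, geom)
  expect_equal(count_rotations(trr, min_radius_cm = 2), 2L)
})

test_that("arm entries honour the 20% depth rule and same-arm collapse", {
  g <- ymaze_geometry()
  ## A(full), B(full), A(15% depth), C(full): the shallow A is ignored
  wp <- ymaze_visit_waypoints(g, c("A", "B", "A", "C"),
                              depths = c(0.9, 0.9, 0.15, 0.9))
  tr <- generate_trajectory("ymaze", waypoints = wp, speed = 5, geometry = g)
  ent <- extract_arm_entries(tr, g)
  expect_equal(ent$arm, c("A", "B", "C"))
  ## A, center, A, B collapses the repeated A
  wp2 <- ymaze_visit_waypoints(g, c("A", "A", "B"), depths = c(0.9, 0.8, 0.9))
  ent2 <- extract_arm_entries(generate_trajectory("ymaze", waypoints = wp2,
                                                  speed = 5, geometry = g), g)
  expect_equal(ent2$arm, c("A", "B"))
  ## no movement: empty sequence
  still <- trajectory(0:20, rep(0, 21), rep(0, 21), g)
  expect_equal(nrow(extract_arm_entries(still, g)), 0L)
})

test_that("alternation scoring matches hand enumeration and the exclusion rule", {
  s <- score_alternations(c("A", "B", "C", "A", "B", "C"))
  expect_equal(s$total_alternations, 5L)
  expect_equal(s$successful_alternations, 4L)
  expect_equal(s$alternation_pct, 100)
  expect_true(s$excluded)   # 5 < 20 changes
  s2 <- score_alternations(c("A", "B", "A", "B", "A"))
  expect_equal(s2$total_alternations, 4L)
  expect_equal(s2$successful_alternations, 0L)
  expect_equal(s2$alternation_pct, 0)
  ## a 20-change sequence is not excluded; a 19-change one is
  long20 <- rep(c("A", "B", "C"), 7)   # 21 entries, 20 changes
  expect_false(score_alternations(long20)$excluded)
  expect_true(score_alternations(long20[-1])$excluded)
  ## fewer than 3 entries: pct undefined, not zero
  s3 <- score_alternations(c("A", "B"))
  expect_equal(s3$successful_alternations, 0L)
  expect_true(is.na(s3$alternation_pct))
  ## permuting arm labels leaves every score unchanged
  perm <- c(A = "B", B = "C", C = "A")
  s4 <- score_alternations(unname(perm[c("A", "B", "C", "A", "B", "C")]))
  expect_equal(s4[c("total_alternations", "successful_alternations",
                    "alternation_pct")],
               s[c("total_alternations", "successful_alternations",
                   "alternation_pct")])
})

test_that("a scripted A,B,C visit sequence yields one successful triplet", {
  g <- ymaze_geometry()
  wp <- ymaze_visit_waypoints(g, c("A", "B", "C"))
  tr <- generate_trajectory("ymaze", waypoints = wp, speed = 5, geometry = g)
  sc <- score_alternations(extract_arm_entries(tr, g))
  expect_equal(sc$successful_alternations, 1L)
  expect_equal(sc$total_alternations, 2L)
})

test_that("trajectories round-trip through provenance CSV", {
  g <- ymaze_geometry()
  tr <- generate_trajectory("ymaze", duration = 5, seed = 3, geometry = g)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_table_with_provenance(path)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_match(attr(back, "provenance")[["arena"]], "ymaze")
})
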