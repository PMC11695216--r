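test_that("interval and profile validation rejects bad inputs", {
  expect_error(ablation_interval(0, 10, 5), class = "validation_error")
  expect_error(ablation_interval(60, 0, 5), class = "validation_error")
  expect_error(ablation_interval(60, 10, -1), class = "validation_error")
  expect_error(ablation_profile("X", "OVAL", list()), class = "validation_error")
  expect_error(ablation_profile("X", "BLOB",
                                list(ablation_interval(60, 10, 0))),
               class = "validation_error")
})

test_that("total_energy matches power x time in kilojoules", {
  oval <- quick_profile(list(c(60, 120, 0)), "OVAL-60W-120s", "OVAL")
  expect_equal(total_energy(oval), 7.2)
  hour <- quick_profile(list(c(60, 260, 0), c(60, 80, 40), c(60, 260, 0)),
                        "HOUR-60W-600s", "HOUR")
  expect_equal(total_energy(hour), 36.0)
  tiny <- quick_profile(list(c(1, 1, 0)))
  expect_equal(total_energy(tiny), 0.001)
})

test_that("energy is additive over concatenated profiles", {
  set.seed(11)
  for (i in 1:10) {
    ivs1 <- replicate(sample(1:4, 1),
                      c(runif(1, 10, 100), runif(1, 5, 600), runif(1, 0, 40)),
                      simplify = FALSE)
    ivs2 <- replicate(sample(1:4, 1),
                      c(runif(1, 10, 100), runif(1, 5, 600), runif(1, 0, 40)),
                      simplify = FALSE)
    p1 <- quick_profile(ivs1); p2 <- quick_profile(ivs2)
    p12 <- quick_profile(c(ivs1, ivs2))
    expect_equal(total_energy(p12), total_energy(p1) + total_energy(p2))
  }
})

test_that("interval_speed is distance over duration", {
  expect_equal(interval_speed(ablation_interval(60, 600, 50)), 50 / 600)
  expect_equal(interval_speed(ablation_interval(60, 260, 0)), 0)
  expect_equal(interval_speed(ablation_interval(60, 210, 30)), 30 / 210)
})

test_that("slow intervals discretize into 2 mm / 2 s segments with dwells", {
  prof <- quick_profile(list(c(60, 600, 50)))
  sch <- discretize(prof)
  expect_equal(sch$total_time, 600)
  expect_equal(sch$total_distance, 50)
  # 25 segments of 24 s (2 s move + 22 s dwell), each covering 2 mm
  seg_bounds <- seq(0, 600, by = 24)
  pos <- probe_position(sch, seg_bounds)
  expect_equal(diff(pos), rep(2, 25))
  # per-segment mean speed equals the commanded speed
  expect_equal(diff(pos) / diff(seg_bounds), rep(50 / 600, 25), tolerance = 1e-9)
  # move-then-dwell: after 2 s of a segment the step is complete
  expect_equal(probe_position(sch, 2), 2)
  expect_equal(probe_position(sch, 13), 2)   # mid-dwell, constant
})

test_that("static and fast intervals are not discretized", {
  static <- discretize(quick_profile(list(c(60, 120, 0)), label = "OVAL"))
  expect_equal(length(static$time), 2L)
  expect_equal(static$position, c(0, 0))
  fast <- discretize(quick_profile(list(c(60, 30, 40))))
  expect_equal(length(fast$time), 2L)        # single continuous move
  expect_equal(fast$position, c(0, 40))
})

test_that("discretization conserves time and distance for arbitrary profiles", {
  set.seed(21)
  for (i in 1:20) {
    ivs <- replicate(sample(1:4, 1),
                     c(runif(1, 20, 100), runif(1, 10, 500), runif(1, 0, 45)),
                     simplify = FALSE)
    prof <- quick_profile(ivs)
    sch <- discretize(prof)
    expect_equal(sch$total_time, total_duration(prof), tolerance = 1e-12)
    expect_equal(sch$total_distance, total_distance(prof), tolerance = 1e-12)
    expect_equal(sch$position[length(sch$position)], total_distance(prof))
    expect_true(all(diff(sch$time) > 0))
    expect_true(all(diff(sch$position) >= 0))
    # probe_position non-decreasing on a fine time grid
    pos <- probe_position(sch, seq(0, sch$total_time, length.out = 200))
    expect_true(all(diff(pos) >= -1e-9))
  }
})

test_that("partial final steps preserve per-interval mean speed", {
  prof <- quick_profile(list(c(60, 100, 5)))   # 0.05 mm/s, 5 mm = 2+2+1
  sch <- discretize(prof)
  expect_equal(sch$total_time, 100)
  expect_equal(sch$total_distance, 5)
  seg_ends <- c(40, 80, 100)                    # 2/0.05, 2/0.05, 1/0.05
  pos <- probe_position(sch, seg_ends)
  expect_equal(pos, c(2, 4, 5))
})

test_that("probe_position interpolates and range-checks", {
  sch <- discretize(quick_profile(list(c(60, 600, 50))))
  expect_equal(probe_position(sch, 0), 0)
  expect_equal(probe_position(sch, 600), 50)
  expect_error(probe_position(sch, -1), class = "range_error")
  expect_error(probe_position(sch, 601), class = "range_error")
})

test_that("profile power is piecewise constant with closed final instant", {
  prof <- quick_profile(list(c(60, 100, 0), c(80, 50, 10)), label = "TEAR")
  expect_equal(profile_power(prof, c(0, 99, 100, 149, 150, 151)),
               c(60, 60, 80, 80, 80, 0))
})

test_that("profiles round-trip through YAML files", {
  prof <- quick_profile(list(c(60, 360, 0), c(60, 210, 30), c(60, 30, 15)),
                        "TEAR-60W-600s", "TEAR")
  path <- tempfile(fileext = ".yaml")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back, prof)
})

test_that("the bundled study profiles load with correct totals", {
  profs <- study_profiles()
  expect_length(profs, 10L)
  expect_setequal(vapply(profs, `[[`, character(1), "shape_label"),
                  c(rep("OVAL", 6), "LONG", "HOUR", "TEAR", "PEAR"))
  conf <- profs[vapply(profs, `[[`, character(1), "shape_label") != "OVAL"]
  expect_true(all(vapply(conf, total_duration, numeric(1)) == 600))
})

test_that("speed_at_point picks the slowest interval at shared positions", {
  hour <- quick_profile(list(c(60, 260, 0), c(60, 80, 40), c(60, 260, 0)),
                        label = "HOUR")
  expect_equal(speed_at_point(hour, 0), 0)      # dwell dominates the start
  expect_equal(speed_at_point(hour, 20), 0.5)
  expect_equal(speed_at_point(hour, 40), 0)     # terminal dwell
  expect_error(speed_at_point(hour, 41), class = "range_error")
})
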