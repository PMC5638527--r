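flat_map <- function() build_sector_map(fundus_landmarks(0, 0, -4000, 0, "right"))

test_that("constant choroid gives the same thickness in every sector", {
  tr <- circumpapillary_trace(rep(100, 1024), rep(170, 1024), axial_scale = 2)
  st <- measure_ppct(tr, flat_map())
  expect_equal(unname(unclass(st)), rep(140, 8))
  expect_named(unclass(st), sector_names())
})

test_that("thickness is invariant to RPE undulation and absolute offset", {
  theta <- 2 * pi * (0:1023) / 1024
  rpe <- 300 + 50 * sin(theta - 0.8)
  tr1 <- circumpapillary_trace(rpe, rpe + 70, axial_scale = 2)
  tr2 <- circumpapillary_trace(rep(0, 1024), rep(70, 1024), axial_scale = 2)
  expect_equal(unclass(measure_ppct(tr1, flat_map(), 5)),
               unclass(measure_ppct(tr2, flat_map(), 5)), tolerance = 1e-12)
})

test_that("a programmed angular profile is recovered at the sector centers", {
  targets <- c(T = 167, ST = 183, S = 192, SN = 191, N = 191, IN = 173,
               I = 151, IT = 153)
  m <- flat_map()
  # build a smooth profile through the targets via independent linear
  # interpolation between sector anchors (different route than the generator)
  ang <- trace_index_to_angle(0:1023, 1024)
  anchors <- c(as.numeric(m), 360)
  vals <- c(targets[names(m)], targets[["T"]])
  prof <- approx(anchors, vals, xout = ang)$y
  tr <- circumpapillary_trace(rep(0, 1024), prof / 2.6, axial_scale = 2.6)
  st <- measure_ppct(tr, m, window_deg = 5)
  expect_equal(unname(unclass(st)), unname(targets), tolerance = 2 / 150)
  st0 <- measure_ppct(tr, m, window_deg = 0)
  expect_equal(unname(unclass(st0)), unname(targets), tolerance = 1e-6)
})

test_that("measurement is equivariant under joint rotation of trace and map", {
  set.seed(5)
  prof <- 150 + 40 * sin(2 * pi * (0:1023) / 1024 - 0.3) +
    10 * cos(4 * pi * (0:1023) / 1024)
  tr <- circumpapillary_trace(rep(0, 1024), prof / 2, axial_scale = 2)
  m <- flat_map()
  for (shift_idx in c(64, 128, 256)) {
    rot_deg <- shift_idx * 360 / 1024
    prof_rot <- c(prof[(shift_idx + 1):1024], prof[1:shift_idx])
    tr_rot <- circumpapillary_trace(rep(0, 1024), prof_rot / 2, axial_scale = 2)
    m_rot <- structure((unclass(m) - rot_deg) %% 360, class = "sector_map")
    expect_equal(unclass(measure_ppct(tr_rot, m_rot, 3)),
                 unclass(measure_ppct(tr, m, 3)), tolerance = 1e-9)
  }
})

test_that("axial scale rescales thickness linearly", {
  set.seed(9)
  d <- runif(1024, 50, 90)
  tr1 <- circumpapillary_trace(rep(0, 1024), d, axial_scale = 2)
  tr3 <- circumpapillary_trace(rep(0, 1024), d, axial_scale = 6)
  expect_equal(3 * unclass(measure_ppct(tr1, flat_map(), 4)),
               unclass(measure_ppct(tr3, flat_map(), 4)), tolerance = 1e-12)
})

test_that("trace invariants are enforced", {
  expect_error(circumpapillary_trace(rep(10, 100), rep(5, 100), 2),
               "negative choroidal thickness")
})

test_that("temporal ratio matches hand arithmetic", {
  even <- setNames(rep(180, 8), sector_names())
  expect_equal(temporal_ratio(even), 1)
  half <- setNames(c(100, rep(200, 7)), sector_names())
  expect_equal(temporal_ratio(half), 0.5)
  st <- setNames(c(166.87, 183.41, 191.59, 190.50, 190.62, 173.21,
                   151.49, 153.09), sector_names())
  # non-temporal sum 1233.91 by hand => ratio = 166.87 / (1233.91 / 7)
  expect_equal(temporal_ratio(st), 166.87 / (1233.91 / 7), tolerance = 1e-12)
  expect_equal(temporal_ratio(st), 0.9467, tolerance = 1e-4)
  expect_error(temporal_ratio(setNames(c(10, rep(0, 7)), sector_names())),
               "positive")
})
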