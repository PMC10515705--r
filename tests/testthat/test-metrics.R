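# The G1 worked-example geometry: head circle r 22 at the origin, neck axis
# along +x, AP tip (12, 5) with horizontal screw axis, LAT tip-apex 10 mm.
g1 <- generate_worked_example()

test_that("TAD is the two-view calibrated tip-apex sum", {
  expect_equal(tad(g1), sqrt(125) + 10, tolerance = 1e-9)
  # tip at the apex in both views
  mk <- function(view) view_landmarks(view, c(0, 0), 22, c(0, 0), c(1, 0),
                                      c(22, 0), c(1, 0), 12.5,
                                      calcar_point = if (view == "AP") c(-3, -15))
  expect_equal(tad(case_radiographs("x", mk("AP"), mk("LAT"))), 0)
})

test_that("Cal TAD uses the calcar-referenced axis in the AP view", {
  # calcar axis coincident with the neck axis -> Cal TAD == TAD
  ap <- view_landmarks("AP", c(0, 0), 22, c(0, 0), c(1, 0), c(12, 5), c(1, 0),
                       12.5, calcar_point = c(-10, 0))
  case <- case_radiographs("x", ap, g1$lat)
  expect_equal(cal_tad(case), tad(case), tolerance = 1e-9)
  # derived example: calcar line y = -15, tip (12, -15) on it
  ap2 <- view_landmarks("AP", c(0, 0), 22, c(0, 0), c(1, 0), c(12, -15),
                        c(1, 0), 12.5, calcar_point = c(-10, -15))
  case2 <- case_radiographs("x", ap2, g1$lat)
  expect_equal(cal_tad(case2) - 10, sqrt(484 - 225) - 12, tolerance = 1e-9)
  # calcar line outside the head
  ap3 <- view_landmarks("AP", c(0, 0), 22, c(0, 0), c(1, 0), c(12, -15),
                        c(1, 0), 12.5, calcar_point = c(-10, -30))
  expect_error(cal_tad(case_radiographs("x", ap3, g1$lat)),
               class = "mtad_invalid_landmark")
  # missing calcar point
  ap4 <- view_landmarks("AP", c(0, 0), 22, c(0, 0), c(1, 0), c(12, 5), c(1, 0),
                        12.5)
  expect_error(cal_tad(case_radiographs("x", ap4, g1$lat)),
               class = "mtad_missing_landmark")
})

test_that("modified TAD decomposes into AB + sign * BC plus the LAT term", {
  m <- modified_tad(g1)
  expect_equal(m$ab_mm, sqrt(459) - 12, tolerance = 1e-9)
  expect_equal(m$bc_mm, sqrt((22 - sqrt(459))^2 + 25), tolerance = 1e-9)
  expect_equal(m$bc_sign, 1)
  expect_equal(m$ap_part_mm, 14.45732, tolerance = 1e-4)
  expect_equal(m$mtad_mm, 24.45732, tolerance = 1e-4)
  expect_false(m$penetration)
  # mirrored to inferior: same AB and BC, sign flips
  ap_inf <- view_landmarks("AP", c(0, 0), 22, c(0, 0), c(1, 0), c(12, -5),
                           c(1, 0), 12.5, calcar_point = c(-3, -15))
  m2 <- modified_tad(case_radiographs("x", ap_inf, g1$lat))
  expect_equal(m2$ap_part_mm, 4.391249, tolerance = 1e-4)
  expect_equal(m$ap_part_mm - m2$ap_part_mm, 2 * m$bc_mm, tolerance = 1e-9)
})

test_that("a central screw collapses the modified TAD to the TAD", {
  ap <- view_landmarks("AP", c(0, 0), 22, c(-5, 0), c(1, 0), c(12, 0), c(1, 0),
                       12.5, calcar_point = c(-3, -15))
  case <- case_radiographs("x", ap, g1$lat)
  m <- modified_tad(case)
  expect_equal(m$bc_mm, 0, tolerance = 1e-9)
  expect_equal(m$bc_sign, 0)
  expect_equal(m$mtad_mm, tad(case), tolerance = 1e-9)
})

test_that("a tip beyond the far surface is flagged as penetration, not an error", {
  ap <- view_landmarks("AP", c(0, 0), 22, c(0, 0), c(1, 0), c(23, 0), c(1, 0),
                       12.5, calcar_point = c(-3, -15))
  m <- modified_tad(case_radiographs("x", ap, g1$lat))
  expect_true(m$penetration)
  expect_equal(m$ab_mm, -1, tolerance = 1e-9)
})

test_that("Parker's ratio measures the axis crossing along the head diameter", {
  # screw axis through the head centre -> 50 in both views
  mk <- function(view, tip, dir)
    view_landmarks(view, c(0, 0), 22, c(-5, 0), c(1, 0), tip, dir, 12.5,
                   calcar_point = if (view == "AP") c(-3, -15))
  central <- case_radiographs("x", mk("AP", c(12, 0), c(1, 0)),
                              mk("LAT", c(12, 0), c(1, 0)))
  expect_equal(parker_ratio(central, "AP")$ratio_pct, 50)
  expect_equal(parker_ratio(central, "LAT")$ratio_pct, 50)
  # AP crossing 60% of the way up from the inferior end: offset s = 0.2 r
  sup <- case_radiographs("x", mk("AP", c(12, 0.2 * 22), c(1, 0)),
                          mk("LAT", c(12, 0), c(1, 0)))
  expect_equal(parker_ratio(sup, "AP")$ratio_pct, 60)
  # LAT counts from the anterior end: an anterior screw scores < 50
  ant <- case_radiographs("x", mk("AP", c(12, 0), c(1, 0)),
                          mk("LAT", c(12, 0.2 * 22), c(1, 0)))
  expect_equal(parker_ratio(ant, "LAT")$ratio_pct, 40)
  # crossing below the inferior cortex -> out of range, unclamped
  low <- case_radiographs("x", mk("AP", c(12, -25), c(1, 0)),
                          mk("LAT", c(12, 0), c(1, 0)))
  pr <- parker_ratio(low, "AP")
  expect_lt(pr$ratio_pct, 0)
  expect_true(pr$out_of_range)
  # screw axis parallel to the measurement chord
  par <- case_radiographs("x", mk("AP", c(12, 0), c(0, 1)),
                          mk("LAT", c(12, 0), c(1, 0)))
  expect_error(parker_ratio(par, "AP"), class = "mtad_undefined_ratio")
})

test_that("Cleveland zones map tip position thirds onto the 3 x 3 grid", {
  mk <- function(ap_y, lat_y) {
    v <- function(view, y) view_landmarks(view, c(0, 0), 22, c(-5, 0), c(1, 0),
                                          c(5, y), c(1, 0), 12.5,
                                          calcar_point = if (view == "AP") c(-3, -15))
    case_radiographs("x", v("AP", ap_y), v("LAT", lat_y))
  }
  expect_equal(cleveland_zone(mk(0, 0))$zone, 5L)            # centre-centre
  expect_equal(cleveland_zone(mk(10, 10))$zone, 1L)          # superior-anterior
  expect_equal(cleveland_zone(mk(-10, -10))$zone, 9L)        # inferior-posterior
  expect_equal(cleveland_zone(mk(-10, 0))$zone, 8L)          # inferior-central
  out <- cleveland_zone(mk(23, 0))
  expect_true(out$out_of_head)
  # partition: random in-head tips always land in exactly one zone, all 9 occur
  set.seed(11)
  # tips at x = 5, |y| <= sqrt(22^2 - 5^2) stay inside the head circle
  ymax <- sqrt(22^2 - 5^2) - 1e-6
  zones <- replicate(400, {
    z <- cleveland_zone(mk(runif(1, -ymax, ymax), runif(1, -ymax, ymax)))
    expect_false(z$out_of_head)
    z$zone
  })
  expect_true(all(zones %in% 1:9))
  expect_setequal(unique(zones), 1:9)
})

test_that("axis-blade angle is negative for superior screw deviation", {
  mk <- function(dir) {
    ap <- view_landmarks("AP", c(0, 0), 22, c(-5, 0), c(1, 0), c(5, 0), dir,
                         12.5, calcar_point = c(-3, -15))
    case_radiographs("x", ap, g1$lat)
  }
  expect_equal(axis_blade_angle(mk(c(1, 0))), 0)
  a <- 8 * pi / 180
  expect_equal(axis_blade_angle(mk(c(cos(a), sin(a)))), -8, tolerance = 1e-9)
  expect_equal(axis_blade_angle(mk(c(cos(a), -sin(a)))), 8, tolerance = 1e-9)
})

test_that("compute_all_metrics composes the parts and captures per-metric errors", {
  row <- compute_all_metrics(g1)
  expect_equal(row$tad_mm, tad(g1))
  expect_equal(row$mtad_mm, modified_tad(g1)$mtad_mm)
  expect_equal(row$cleveland_zone, 5L)
  expect_equal(row$aba_deg, 0)
  # dropping the calcar only blanks Cal TAD
  ap_nc <- g1$ap; ap_nc$calcar_point <- NULL
  row2 <- compute_all_metrics(case_radiographs("x", ap_nc, g1$lat))
  expect_true(is.na(row2$cal_tad_mm))
  expect_match(row2$err_cal_tad, "calcar")
  expect_false(is.na(row2$tad_mm))
  expect_false(is.na(row2$mtad_mm))
})

test_that("mirror antisymmetry: reflection flips bc_sign, difference is 2 BC", {
  set.seed(21)
  for (i in 1:50) {
    gap <- random_view_draw("AP")
    glat <- random_view_draw("LAT")
    case <- case_radiographs("m", draw_to_view(gap), draw_to_view(glat))
    case_m <- case_radiographs("m", draw_to_view(mirror_draw(gap)),
                               draw_to_view(glat))
    m1 <- modified_tad(case); m2 <- modified_tad(case_m)
    expect_equal(m1$ab_mm, m2$ab_mm, tolerance = 1e-9)
    expect_equal(m1$bc_mm, m2$bc_mm, tolerance = 1e-9)
    expect_equal(m1$bc_sign, -m2$bc_sign)
    expect_equal(abs(m1$mtad_mm - m2$mtad_mm), 2 * m1$bc_mm, tolerance = 1e-9)
  }
})

test_that("all metrics are invariant under per-view magnification", {
  set.seed(31)
  for (i in 1:25) {
    gap <- random_view_draw("AP")
    glat <- random_view_draw("LAT")
    k1 <- runif(1, 0.5, 2); k2 <- runif(1, 0.5, 2)
    base <- compute_all_metrics(
      case_radiographs("m", draw_to_view(gap), draw_to_view(glat)))
    mag <- compute_all_metrics(
      case_radiographs("m", draw_to_view(gap, k1), draw_to_view(glat, k2)))
    for (col in c("tad_mm", "cal_tad_mm", "mtad_mm", "parker_ap_pct",
                  "parker_lat_pct", "aba_deg", "ab_ap_mm", "bc_ap_mm")) {
      expect_equal(mag[[col]], base[[col]], tolerance = 1e-9)
    }
    expect_equal(mag$cleveland_zone, base$cleveland_zone)
  }
})
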