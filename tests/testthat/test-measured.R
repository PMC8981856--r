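test_that("Lab colour difference matches hand-evaluated cases", {
  expect_equal(delta_e(c(50, 10, 10), c(50, 10, 10)), 0)
  expect_equal(delta_e(c(0, 0, 0), c(100, 0, 0)), 100)
  expect_equal(delta_e(c(50, 10, 10), c(53, 14, 10)), 5)  # sqrt(9 + 16)
})

test_that("CIEDE2000 agrees with an independent implementation and is symmetric", {
  set.seed(3)
  for (i in 1:25) {
    c1 <- c(runif(1, 0, 100), runif(2, -60, 60))
    c2 <- c(runif(1, 0, 100), runif(2, -60, 60))
    ours <- delta_e(c1, c2, method = "ciede2000")
    ref <- farver::compare_colour(matrix(c1, 1), matrix(c2, 1),
                                  from_space = "lab", method = "cie2000")[1, 1]
    expect_equal(ours, ref, tolerance = 1e-6)
    expect_equal(ours, delta_e(c2, c1, method = "ciede2000"), tolerance = 1e-12)
  }
  expect_equal(delta_e(c(40, 20, -10), c(40, 20, -10), method = "ciede2000"), 0)
})

test_that("period distance applies the median-year rule with floored gaps", {
  expect_equal(period_distance(c(1840, 1849), c(1840, 1849)), 0)
  expect_equal(period_distance(c(1840, 1849), c(1850, 1859)), 10)
  # open-ended bounds from the period table conventions: midpoints 1650, 1970
  expect_equal(period_distance(c(1600, 1700), c(1920, 2020)), 320)
  # floor applies when midpoints differ by a half-year
  expect_equal(period_distance(c(1800, 1809), c(1810, 1820)), 10)  # |1804.5-1815| = 10.5
  expect_error(period_distance(c(1850, 1840), c(1800, 1809)), "start")
})

test_that("great-circle distances match closed-form arcs", {
  expect_equal(geo_distance(c(12, 34), c(12, 34)), 0)
  expect_equal(geo_distance(c(0, 0), c(0, 180)), pi * 6371, tolerance = 1e-6)
  expect_equal(geo_distance(c(0, 0), c(0, 1)), 6371 * pi / 180, tolerance = 1e-6)
  expect_error(geo_distance(c(95, 0), c(0, 0)), "latitude")
})

test_that("composite regions sit at the mean of their sub-areas", {
  expect_equal(composite_region_location(data.frame(lat = 10, lon = 5)),
               c(lat = 10, lon = 5))
  expect_equal(composite_region_location(data.frame(lat = c(10, -10), lon = c(5, 5))),
               c(lat = 0, lon = 5))
  expect_equal(composite_region_location(data.frame(lat = c(45, 47), lon = c(0, 2))),
               c(lat = 46, lon = 1))
  expect_error(composite_region_location(data.frame(lat = numeric(), lon = numeric())),
               "at least one")
})

test_that("lookup tables parse, resolve composites, and reject malformed rows", {
  colours <- read_lookup_table(fx$colours, "colour")
  expect_equal(unlist(colours[colours$label == "pink", c("L", "a", "b")]),
               c(L = 75, a = 35, b = 5))

  geo <- read_lookup_table(fx$geo, "geo")
  nw <- geo[geo$label == "NW-France", ]
  expect_equal(nw$lat, mean(c(48.2, 49.1)))
  expect_equal(nw$lon, mean(c(-2.9, 0.1)))

  periods <- read_lookup_table(fx$periods, "period")
  expect_equal(unlist(periods[periods$label == "<1700", c("start", "end")]),
               c(start = 1600, end = 1700))
  expect_equal(unlist(periods[periods$label == ">1920", c("start", "end")]),
               c(start = 1920, end = 2020))

  bad_geo <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,lat,lon,areas", "X,,,Nowhere;Brittany"), bad_geo)
  expect_error(read_lookup_table(bad_geo, "geo"), "Nowhere")
  bad_num <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,L,a,b", "p,81,twenty,5"), bad_num)
  expect_error(read_lookup_table(bad_num, "colour"), "malformed")
})

test_that("measured distances are symmetric, non-negative, and mostly metric", {
  set.seed(7)
  for (i in 1:50) {
    cols <- matrix(c(runif(3, 0, 100), runif(6, -80, 80)), 3, 3)[, c(1, 2, 3)]
    cols <- cbind(runif(3, 0, 100), runif(3, -80, 80), runif(3, -80, 80))
    dAB <- delta_e(cols[1, ], cols[2, ]); dBC <- delta_e(cols[2, ], cols[3, ])
    dAC <- delta_e(cols[1, ], cols[3, ])
    expect_gte(dAB + dBC + 1e-9, dAC)          # triangle inequality (CIE76)
    expect_equal(dAB, delta_e(cols[2, ], cols[1, ]))

    pts <- cbind(runif(3, -89, 89), runif(3, -179, 179))
    gAB <- geo_distance(pts[1, ], pts[2, ]); gBC <- geo_distance(pts[2, ], pts[3, ])
    gAC <- geo_distance(pts[1, ], pts[3, ])
    expect_gte(gAB + gBC + 1e-6, gAC)
    expect_gte(gAB, 0)

    p1 <- sort(sample(1600:2020, 2)); p2 <- sort(sample(1600:2020, 2))
    pd <- period_distance(p1, p2)
    expect_identical(pd, floor(pd))            # integer for integer bounds
    expect_equal(pd, period_distance(p2, p1))
  }
})
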