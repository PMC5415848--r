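test_that("weighted shift formula and matching statuses are honoured", {
  expect_equal(weighted_shift(0.10, 0.50), 0.17)
  expect_equal(weighted_shift(-0.10, -0.50), 0.17)  # magnitudes

  free <- peak_list(1:5, c(8.1, 8.2, 8.3, 8.4, 8.5), c(110, 112, 114, 116, 118))
  same <- weighted_csp(free, free)
  expect_equal(same$delta_weighted, rep(0, 5))

  bound <- peak_list(c(1:4, 6), c(8.1, 8.2, 8.35, 8.4, 9.0),
                     c(110, 112, 114, 116, 125))
  tab <- weighted_csp(free, bound)
  expect_equal(tab$status[tab$residue == 5], "missing-in-bound")
  expect_equal(tab$status[tab$residue == 6], "missing-in-free")
  cls <- classify_csp(tab)
  measured <- tab$status == "measured"
  expect_equal(sum(measured), 4)
  mu <- mean(tab$delta_weighted[measured])
  expect_equal(unname(attr(cls, "thresholds")["mu"]), mu)

  dup <- rbind(free, peak_list(1, 9.9, 130))
  class(dup) <- c("peak_list", "data.frame")
  expect_error(weighted_csp(dup, bound), "duplicate")
})

test_that("weighted shifts are symmetric in free and bound", {
  pk <- make_peak_lists(12, list("3" = c(0.2, 1.0), "9" = c(-0.05, 0.3)),
                        jitter = 0.01, seed = 8)
  ab <- weighted_csp(pk$free, pk$bound)
  ba <- weighted_csp(pk$bound, pk$free)
  expect_equal(ab$delta_weighted, ba$delta_weighted)
})

test_that("classification reproduces the hand-computed example", {
  free <- peak_list(1:5, rep(8, 5), rep(115, 5))
  bound <- peak_list(1:5, c(8.02, 8.02, 8.02, 8.02, 8.12), rep(115, 5))
  cls <- classify_csp(weighted_csp(free, bound))
  thr <- attr(cls, "thresholds")
  expect_equal(unname(thr["mu"]), 0.04)
  expect_equal(unname(thr["mu_sigma"]), 0.04 + sqrt(0.002), tolerance = 1e-12)
  expect_equal(cls$class, c("none", "none", "none", "none", "medium"))

  # degenerate: all shifts equal -> sigma 0, every residue >= mu => strong
  allsame <- classify_csp(weighted_csp(free,
    peak_list(1:5, rep(8.05, 5), rep(115, 5))))
  expect_true(all(allsame$class == "strong"))

  expect_error(classify_csp(weighted_csp(peak_list(1, 8, 115),
                                         peak_list(1, 8.1, 115))),
               "2 measured")
})

test_that("class thresholds are scale-equivariant", {
  free <- peak_list(1:6, rep(8, 6), rep(115, 6))
  d <- c(0.01, 0.02, 0.03, 0.02, 0.15, 0.05)
  bound1 <- peak_list(1:6, 8 + d, rep(115, 6))
  bound3 <- peak_list(1:6, 8 + 3 * d, rep(115, 6))
  c1 <- classify_csp(weighted_csp(free, bound1))
  c3 <- classify_csp(weighted_csp(free, bound3))
  expect_equal(c3$class, c1$class)
  expect_equal(unname(attr(c3, "thresholds")),
               3 * unname(attr(c1, "thresholds")), tolerance = 1e-12)
})

test_that("minimal shift picks the nearest bound peak under the weighted metric", {
  free <- peak_list(1, 8.00, 115.0)
  bound <- data.frame(dH = c(8.10, 8.00), dN = c(115.0, 116.0))
  ms <- minimal_shift(free, bound)
  expect_equal(ms$matched_dH, 8.10)
  expect_equal(ms$delta_weighted, 0.10)
  expect_false(ms$tie)

  # identical sets give all-zero shifts
  free5 <- peak_list(1:5, seq(7.6, 8.4, 0.2), seq(110, 118, 2))
  expect_equal(minimal_shift(free5, free5)$delta_weighted, rep(0, 5))

  # tie: equidistant peaks resolved towards smaller dH and flagged
  tie <- minimal_shift(peak_list(1, 8.00, 115),
                       data.frame(dH = c(8.05, 7.95), dN = c(115, 115)))
  expect_true(tie$tie)
  expect_equal(tie$matched_dH, 7.95)

  expect_error(minimal_shift(free, data.frame(dH = numeric(), dN = numeric())),
               "empty")
})

test_that("minimal shift lower-bounds the assigned CSP", {
  for (seed in 1:5) {
    pk <- make_peak_lists(15, list("4" = c(0.12, 0.6), "9" = c(0.05, 0.2),
                                   "11" = c(-0.08, -0.4)),
                          jitter = 0.004, seed = seed)
    assigned <- weighted_csp(pk$free, pk$bound)
    minimal <- minimal_shift(pk$free, pk$bound)
    m <- merge(assigned[assigned$status == "measured", ], minimal,
               by = "residue", suffixes = c("_true", "_min"))
    expect_true(all(m$delta_weighted_min <= m$delta_weighted_true + 1e-12))
  }
})

test_that("CSP export writes a residue/class/color table", {
  pk <- make_peak_lists(6, list("2" = c(0.3, 1.5)))
  cls <- classify_csp(weighted_csp(pk$free, pk$bound))
  path <- withr::local_tempfile(fileext = ".csv")
  map <- export_csp_map(cls, roster = 1:6, path = path)
  expect_equal(nrow(map), 6)
  expect_true(all(map$color %in% c("white", "yellow", "orange", "red")))
  expect_equal(map$color[map$residue == 2], "red")
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_warning(export_csp_map(cls, roster = 1:5), "absent")
})

test_that("peak lists round-trip through CSV", {
  pk <- make_peak_lists(8, list("3" = c(0.1, 0.5)), jitter = 0.002,
                        seed = 13, n_sidechain = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_peak_list(pk$bound, path)
  back <- read_peak_list(path)
  expect_equal(back$residue, pk$bound$residue)
  expect_equal(back$dH, round(pk$bound$dH, 3))
  expect_equal(back$sidechain, pk$bound$sidechain)
})
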