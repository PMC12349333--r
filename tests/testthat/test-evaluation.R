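# Detection metrics and the heatmap area-of-interest measurement.

test_that("box IoU handles identity, disjointness and partial overlap", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(box_iou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)  # degenerate union
})

test_that("greedy matching yields the published TP/FP/FN semantics", {
  gts <- data.frame(image = 1, class = 0, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  perfect <- data.frame(image = 1, class = 0, conf = 0.9,
                        x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  cc <- match_and_count(perfect, gts)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(1, 0, 0))
  none <- perfect[0, ]
  cc2 <- match_and_count(none, gts)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(0, 0, 1))
  # two class-correct predictions on one ground truth: one TP, one FP
  two <- data.frame(image = 1, class = 0, conf = c(0.9, 0.8),
                    x1 = c(0, 1), y1 = c(0, 1), x2 = c(10, 10), y2 = c(10, 10))
  cc3 <- match_and_count(two, gts)
  expect_equal(c(cc3$tp, cc3$fp, cc3$fn), c(1, 1, 0))
  # wrong class never matches
  wrong <- transform(perfect, class = 1)
  cc4 <- match_and_count(wrong, gts)
  expect_equal(cc4$fn[cc4$class == 0], 1)
  expect_equal(cc4$fp[cc4$class == 1], 1)
})

test_that("precision/recall/F1 formulas and printed F1 values", {
  prf <- precision_recall_f1(8, 2, 2)
  expect_equal(prf$precision, 0.8)
  expect_equal(prf$recall, 0.8)
  expect_equal(prf$f1, 0.8)               # harmonic-mean fixed point
  expect_equal(precision_recall_f1(0, 0, 0)$f1, 0)  # 0/0 -> 0
  # the published precision/recall pairs reproduce the published F1 (2 dp)
  expect_equal(round(f1_score(98.5, 98.8), 2), 98.65)
  expect_equal(round(f1_score(98.9, 99), 2), 98.95)
  expect_equal(round(f1_score(99.7, 99.6), 2), 99.65)
})

test_that("average precision matches the brute-force envelope oracle", {
  # enumerated toy set: conf .9 TP, .8 FP, .7 TP on 2 ground truths
  conf <- c(0.9, 0.8, 0.7)
  tp <- c(TRUE, FALSE, TRUE)
  want <- ap_bruteforce(conf, tp, 2)
  expect_equal(want, 0.5 * 1 + 0.5 * (2 / 3))  # rectangle sum by hand
  expect_equal(average_precision(tp, 2), want)
  # degenerate cases
  expect_equal(average_precision(c(TRUE, TRUE), 2), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 2), 0)
  expect_equal(average_precision(logical(), 2), 0)
  # property: implementation == oracle on random ranked lists
  set.seed(201)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    tp <- runif(n) < 0.5
    ngt <- sum(tp) + sample(0:3, 1)
    if (ngt == 0) next
    conf <- sort(runif(n), decreasing = TRUE)
    expect_equal(average_precision(tp, ngt), ap_bruteforce(conf, tp, ngt),
                 tolerance = 1e-12)
  }
})

test_that("envelope AP dominates the raw trapezoid and order does not matter", {
  set.seed(202)
  trapz_ap <- function(tp, ngt) {
    ctp <- cumsum(tp); cfp <- cumsum(!tp)
    p <- c(1, ctp / (ctp + cfp)); r <- c(0, ctp / ngt)
    sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  }
  for (i in 1:20) {
    n <- sample(2:15, 1)
    tp <- runif(n) < 0.6
    ngt <- max(1, sum(tp))
    # envelope integration never falls below the trapezoid on raw points
    expect_gte(average_precision(tp, ngt) + 1e-12, trapz_ap(tp, ngt))
  }
  # metric invariance to prediction input order
  gts <- data.frame(image = c(1, 1, 2), class = c(0, 1, 0),
                    x1 = c(0, 20, 0), y1 = c(0, 20, 0),
                    x2 = c(10, 30, 10), y2 = c(10, 30, 10))
  preds <- data.frame(image = c(1, 1, 2, 2), class = c(0, 1, 0, 0),
                      conf = c(0.9, 0.6, 0.8, 0.3),
                      x1 = c(1, 21, 0, 5), y1 = c(0, 20, 1, 5),
                      x2 = c(10, 31, 10, 15), y2 = c(10, 30, 10, 15))
  e1 <- map_at(preds, gts)
  e2 <- map_at(preds[sample(nrow(preds)), ], gts)
  expect_equal(e1$map50, e2$map50)
  expect_equal(e1$map5095, e2$map5095)
})

test_that("a perfect single-confidence detector scores 1 everywhere", {
  gts <- data.frame(image = 1:4, class = c(0, 1, 0, 1),
                    x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  preds <- cbind(gts[, c("image", "class")], conf = 0.9,
                 gts[, c("x1", "y1", "x2", "y2")])
  ev <- map_at(preds, gts)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map5095, 1)
})

test_that("timing statistics follow the mean/reciprocal definitions", {
  ts <- timing_stats(c(10, 10, 10))
  expect_equal(ts$dt_ms, 10)
  expect_equal(ts$fps, 100)
  expect_equal(timing_stats(c(5, 15))$dt_ms, 10)
  expect_equal(timing_stats(11.2)$fps, 1000 / 11.2)  # ~89.3
  expect_error(timing_stats(numeric()), "at least one")
})

test_that("aoi_area: rectangle fixtures, additivity, growth monotonicity", {
  hm <- gen_heatmap(c(200, 300),
                    list(list(type = "rect", x = 50, y = 40, w = 150, h = 100,
                              intensity = 255)))
  expect_equal(aoi_area(hm, method = "pixel"), 15000)
  # the traced-contour (Green's theorem) area of a filled w x h rectangle
  # is (w-1)*(h-1): the polygon runs through the boundary pixel centers
  expect_equal(aoi_area(hm, method = "contour"), 149 * 99)
  expect_equal(aoi_area(matrix(0, 50, 50)), 0)
  two <- gen_heatmap(c(200, 300),
                     list(list(type = "rect", x = 10, y = 10, w = 40, h = 30,
                               intensity = 255),
                          list(type = "rect", x = 200, y = 120, w = 60, h = 50,
                               intensity = 255)))
  expect_equal(aoi_area(two, method = "contour"), 39 * 29 + 59 * 49)
  expect_equal(aoi_area(two, method = "pixel"), 40 * 30 + 60 * 50)
  # enlarging a hot region never decreases the measured area
  grow <- gen_heatmap(c(200, 300),
                      list(list(type = "rect", x = 40, y = 30, w = 170,
                                h = 120, intensity = 255)))
  expect_gte(aoi_area(grow, method = "contour"), aoi_area(hm, method = "contour"))
  # interior holes are filled before measuring
  holed <- hm
  holed[80:90, 100:120] <- 0
  expect_equal(aoi_area(holed, method = "pixel"), 15000)
  # a fixed threshold can be supplied instead of Otsu
  expect_equal(aoi_area(hm, threshold = 0.5, method = "pixel"), 15000)
})
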