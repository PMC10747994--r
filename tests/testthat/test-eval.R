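test_that("iou handles identical, disjoint, overlapping and degenerate boxes", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 10, 10)), "degenerate")
})

test_that("match_and_pr reproduces the hand-enumerated curves", {
  gts <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  d1 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                   score = 0.9)
  pr <- match_and_pr(d1, gts, 0.5)
  expect_equal(pr, data.frame(recall = 1, precision = 1))

  d2 <- rbind(d1, data.frame(image_id = 1, x1 = 50, y1 = 50, x2 = 60,
                             y2 = 60, score = 0.8))
  pr2 <- match_and_pr(d2, gts, 0.5)
  expect_equal(pr2$recall, c(1, 1))
  expect_equal(pr2$precision, c(1, 0.5))

  gts2 <- rbind(gts, data.frame(image_id = 1, x1 = 30, y1 = 30, x2 = 40,
                                y2 = 40))
  pr3 <- match_and_pr(d1, gts2, 0.5)
  expect_equal(pr3, data.frame(recall = 0.5, precision = 1))
})

test_that("average precision follows the 101-point envelope rule", {
  expect_equal(average_precision(data.frame(recall = 1, precision = 1)), 1)
  # a trailing FP leaves the envelope at max precision per recall
  expect_equal(average_precision(data.frame(recall = c(1, 1),
                                            precision = c(1, 0.5))), 1)
  expect_equal(average_precision(data.frame(recall = numeric(0),
                                            precision = numeric(0))), 0)
  # half recall at full precision: grid points above 0.5 contribute 0
  ap_half <- average_precision(data.frame(recall = 0.5, precision = 1))
  expect_equal(ap_half, 51 / 101)
})

test_that("average precision agrees with the step-curve integration oracle", {
  for (seed in 1:50) {
    cs <- random_eval_case(seed)
    for (t in c(0.3, 0.5, 0.75)) {
      pr <- match_and_pr(cs$dets, cs$gts, t)
      expect_equal(average_precision(pr), oracle_ap_grid(pr),
                   tolerance = 1e-9)
    }
  }
})

test_that("evaluate summarises perfect, partial-overlap and empty detectors", {
  gts <- data.frame(image_id = c(1, 2), x1 = c(0, 10), y1 = c(0, 10),
                    x2 = c(10, 30), y2 = c(10, 30))
  perfect <- cbind(gts, score = c(0.9, 0.8))
  ev <- evaluate_detections(perfect, gts)
  expect_equal(ev$ap, 1); expect_equal(ev$ap50, 1)
  expect_equal(ev$ap75, 1); expect_equal(ev$ar, 1)

  # uniform IoU 0.6: only thresholds 0.50, 0.55, 0.60 match -> AP = 3/10
  gt1 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  det06 <- data.frame(image_id = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 6,
                      score = 0.9)
  expect_equal(iou(c(0, 0, 10, 6), c(0, 0, 10, 10)), 0.6)
  ev06 <- evaluate_detections(det06, gt1)
  expect_equal(ev06$ap, 3 / 10)
  expect_equal(ev06$ap50, 1)
  expect_equal(ev06$ap75, 0)
  expect_equal(ev06$ar, 3 / 10)

  none <- data.frame(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                     x2 = numeric(0), y2 = numeric(0), score = numeric(0))
  ev0 <- evaluate_detections(none, gts)
  expect_equal(ev0$ap, 0); expect_equal(ev0$ar, 0)

  expect_error(evaluate_detections(none, none[, -6]), "no images")

  # detections with no ground truth anywhere: AP defined as 0
  evfp <- evaluate_detections(perfect, none[, -6], image_ids = c(1, 2))
  expect_equal(evfp$ap, 0)
})

test_that("eval_result invariants hold on random cases", {
  for (seed in 51:70) {
    cs <- random_eval_case(seed)
    ev <- evaluate_detections(cs$dets, cs$gts)
    expect_lte(ev$ap, ev$ap50 + 1e-12)
    expect_lte(ev$ap75, ev$ap50 + 1e-12)
    expect_equal(ev$ap, mean(ev$per_threshold))
    # monotone non-increasing in the IoU threshold
    expect_true(all(diff(ev$per_threshold) <= 1e-12))
  }
})

test_that("a low-score false positive never increases AP", {
  for (seed in 71:85) {
    cs <- random_eval_case(seed)
    ev1 <- evaluate_detections(cs$dets, cs$gts)
    fp <- data.frame(image_id = cs$dets$image_id[1], x1 = 900, y1 = 900,
                     x2 = 910, y2 = 910, score = min(cs$dets$score) / 2)
    ev2 <- evaluate_detections(rbind(cs$dets, fp), cs$gts)
    expect_true(all(ev2$per_threshold <= ev1$per_threshold + 1e-12))
  }
})

test_that("COCO-dialect annotations round-trip to corner boxes", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = list(list(id = 1L, file_name = "a.png", width = 64L,
                       height = 64L),
                  list(id = 2L, file_name = "b.png", width = 64L,
                       height = 64L)),
    annotations = list(list(id = 1L, image_id = 1L, category_id = 1L,
                            bbox = c(4.5, 8, 10, 20), area = 200,
                            iscrowd = 0L)),
    categories = list(list(id = 1L, name = "lesion"))
  ), path, auto_unbox = TRUE, digits = NA)
  cc <- read_coco_annotations(path)
  expect_equal(nrow(cc$images), 2)
  expect_equal(cc$boxes$x1, 4.5)
  expect_equal(cc$boxes$x2, 14.5)
  expect_equal(cc$boxes$y2, 28)
  unlink(path)

  res <- evaluate_detections(
    data.frame(image_id = 1, x1 = 4.5, y1 = 8, x2 = 14.5, y2 = 28,
               score = 0.7),
    cc$boxes, image_ids = c(1, 2))
  out <- tempfile(fileext = ".json")
  write_eval_result(res, out)
  back <- jsonlite::read_json(out)
  expect_equal(back$AP, 1)
  unlink(out)
})
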