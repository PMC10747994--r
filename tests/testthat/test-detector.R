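tiny_dataset <- function(n_images = 6, seed = 21, image_size = 64) {
  spec <- lesion_scene_spec(image_size = image_size, n_lesions = 1,
                            seed = seed)
  make_lesion_dataset(spec, n_images)
}

test_that("head outputs follow the anchor shape contract", {
  det <- build_detector(image_size = 64, out_channels = 8,
                        reduction_ratio = 4, seed = 2)
  img <- matrix(runif(64 * 64), 64, 64)
  fw <- abfp:::detector_fwd(det, img)
  A <- det$cfg$n_anchors
  sizes <- 64 / c(4, 8, 16, 32)
  for (l in 1:4) {
    expect_equal(dim(fw$cls[[l]]), c(A, sizes[l], sizes[l]))
    expect_equal(dim(fw$reg[[l]]), c(4 * A, sizes[l], sizes[l]))
  }
  expect_equal(nrow(det$anchors$boxes), sum(A * sizes^2))
  expect_error(build_detector(image_size = 100), "divisible")
  expect_error(abfp:::detector_fwd(det, matrix(0, 32, 32)), "64x64")
})

test_that("a zeroed classification head emits exactly the bias logit", {
  det <- build_detector(image_size = 64, out_channels = 8, seed = 3)
  det$params[["head.cls.w"]][] <- 0
  fw <- abfp:::detector_fwd(det, matrix(0.5, 64, 64))
  b <- det$params[["head.cls.b"]][1]
  for (l in 1:4) expect_true(all(abs(fw$cls[[l]] - b) < 1e-12))
})

test_that("attention on/off detectors differ by the closed-form extras", {
  on <- build_detector(image_size = 64, out_channels = 8,
                       reduction_ratio = 4, attention = TRUE, seed = 4)
  off <- build_detector(image_size = 64, out_channels = 8,
                        attention = FALSE, seed = 4)
  expect_equal(detector_param_count(on) - detector_param_count(off),
               abfp_param_count(on$neck_cfg) - abfp_param_count(off$neck_cfg))
})

test_that("anchor assignment respects the IoU thresholds and force matching", {
  det <- build_detector(image_size = 64, seed = 5)
  gt <- matrix(c(8, 8, 24, 24), ncol = 4)      # 16px box on the P2 grid
  asg <- abfp:::assign_anchors(det$anchors$boxes, gt, 0.5, 0.4)
  pos <- which(asg$labels == 1L)
  expect_gt(length(pos), 0)
  M <- abfp:::box_iou_matrix(det$anchors$boxes[pos, , drop = FALSE], gt)
  # every positive is either above threshold or the forced best anchor
  expect_gte(max(M), 0.5)
  none <- abfp:::assign_anchors(det$anchors$boxes, NULL)
  expect_true(all(none$labels == 0L))
})

test_that("box encoding inverts through decoding", {
  det <- build_detector(image_size = 64, seed = 6)
  anc <- det$anchors$boxes[c(10, 500, 1000), ]
  gt <- matrix(c(5, 6, 20, 26,
                 30, 30, 44, 47,
                 10, 40, 50, 60), ncol = 4, byrow = TRUE)
  deltas <- abfp:::encode_boxes(anc, gt)
  back <- abfp:::decode_boxes(anc, deltas)
  expect_equal(unname(back), unname(gt), tolerance = 1e-9)
})

test_that("NMS is idempotent and keeps the top-scoring of overlapping boxes", {
  set.seed(8)
  x1 <- runif(40, 0, 50); y1 <- runif(40, 0, 50)
  boxes <- cbind(x1, y1, x1 + runif(40, 5, 20), y1 + runif(40, 5, 20))
  scores <- runif(40)
  keep <- nms(boxes, scores, 0.5)
  again <- nms(boxes[keep, , drop = FALSE], scores[keep], 0.5)
  expect_equal(sort(again), seq_along(keep))
  # surviving boxes are mutually below the overlap threshold
  M <- abfp:::box_iou_matrix(boxes[keep, ], boxes[keep, ])
  diag(M) <- 0
  expect_lt(max(M), 0.5 + 1e-12)
})

test_that("zero learning rate leaves every parameter untouched", {
  ds <- tiny_dataset(4)
  det <- build_detector(image_size = 64, out_channels = 8, seed = 9)
  tc <- train_config(lr = 0, epochs = 1, lr_drops = 1, batch_size = 2,
                     seed = 10)
  out <- train_detector(det, ds, tc)
  expect_identical(out$params, det$params)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- tiny_dataset(6)
  det <- build_detector(image_size = 64, out_channels = 8, seed = 11)
  tc <- train_config(epochs = 2, lr_drops = 2, batch_size = 3,
                     warmup_iters = 2, seed = 12)
  r1 <- train_detector(det, ds, tc)
  r2 <- train_detector(det, ds, tc)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$params, r2$params)
})

test_that("one SGD step moves every parameter group through live gradients", {
  ds <- tiny_dataset(2)
  det <- build_detector(image_size = 64, out_channels = 8,
                        reduction_ratio = 4, seed = 13)
  tc <- train_config(seed = 14)
  gt <- as.matrix(ds$annotations[ds$annotations$image_id == 1,
                                 c("x1", "y1", "x2", "y2")])
  lg <- abfp:::detector_loss_grad(det, ds$images[[1]], gt, tc)
  expect_setequal(names(lg$grads), names(det$params))
  for (k in names(det$params)) {
    expect_gt(max(abs(lg$grads[[k]])), 0, label = paste("grad", k))
  }
  tc1 <- train_config(epochs = 1, lr_drops = 1, batch_size = 2,
                      warmup_iters = 1, seed = 15)
  out <- train_detector(det, ds, tc1)
  for (k in names(det$params)) {
    expect_gt(max(abs(out$params[[k]] - det$params[[k]])), 0,
              label = paste("update", k))
  }
})

test_that("training aborts with a diagnostic when the loss blows up", {
  ds <- tiny_dataset(2)
  det <- build_detector(image_size = 64, out_channels = 8, seed = 16)
  det$params[["head.reg.b"]][] <- NaN
  tc <- train_config(epochs = 1, lr_drops = 1, seed = 17)
  expect_error(train_detector(det, ds, tc), "non-finite loss")
})

test_that("an oracle that emits the ground truth verbatim scores AP 1", {
  ds <- tiny_dataset(3)
  dets <- cbind(ds$annotations[, c("image_id", "x1", "y1", "x2", "y2")],
                score = 0.9)
  ev <- evaluate_detections(dets, ds$annotations[, c("image_id", "x1", "y1",
                                                     "x2", "y2")])
  expect_equal(ev$ap, 1)
  expect_equal(ev$ar, 1)
})

test_that("an untrained zero-logit detector detects nothing", {
  ds <- tiny_dataset(3)
  det <- build_detector(image_size = 64, out_channels = 8, seed = 18)
  det$params[["head.cls.w"]][] <- 0     # scores collapse to the 1% prior
  ev <- predict_and_evaluate(det, ds)
  expect_equal(ev$ap, 0)
  expect_equal(ev$ap50, 0)
})
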