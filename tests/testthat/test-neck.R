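make_backbone_pyramid <- function(in_channels, base = 16, seed = 1) {
  set.seed(seed)
  h <- base
  levels <- lapply(in_channels, function(ic) {
    x <- array(rnorm(ic * h * h), c(ic, h, h))
    h <<- ceiling(h / 2)
    x
  })
  feature_pyramid(levels)
}

test_that("zero FPN weights map any input to zero", {
  cfg <- neck_config(c(3, 5), out_channels = 4)
  params <- fpn_params(cfg, seed = 1)
  for (k in names(params)) params[[k]] <- params[[k]] * 0
  p <- make_backbone_pyramid(c(3, 5), seed = 2)
  out <- fpn_forward(p, cfg, params)
  for (l in 1:2) expect_true(all(out$levels[[l]] == 0))
})

test_that("a hand-traced 2-level FPN reproduces lateral + upsampled top", {
  cfg <- neck_config(c(1, 1), out_channels = 1)
  params <- fpn_params(cfg, seed = 1)
  # identity 1x1 laterals
  params[["fpn.lateral1.w"]] <- array(1, c(1, 1, 1, 1))
  params[["fpn.lateral2.w"]] <- array(1, c(1, 1, 1, 1))
  params[["fpn.lateral1.b"]] <- 0; params[["fpn.lateral2.b"]] <- 0
  delta <- array(0, c(1, 3, 3, 1)); delta[1, 2, 2, 1] <- 1
  zero3 <- array(0, c(1, 3, 3, 1))
  p <- make_backbone_pyramid(c(1, 1), base = 4, seed = 3)

  # zero output convs annihilate everything
  params[["fpn.out1.w"]] <- zero3; params[["fpn.out2.w"]] <- zero3
  params[["fpn.out1.b"]] <- 0; params[["fpn.out2.b"]] <- 0
  out0 <- fpn_forward(p, cfg, params)
  expect_true(all(out0$levels[[1]] == 0) && all(out0$levels[[2]] == 0))

  # delta output convs pass the merged maps through unchanged
  params[["fpn.out1.w"]] <- delta; params[["fpn.out2.w"]] <- delta
  out <- fpn_forward(p, cfg, params)
  expect_equal(out$levels[[2]], p$levels[[2]], tolerance = 1e-12)
  up <- oracle_nearest_resize(p$levels[[2]], 4, 4)
  expect_equal(out$levels[[1]], p$levels[[1]] + up, tolerance = 1e-12)
})

test_that("FPN preserves per-level spatial shapes and rejects bad channels", {
  cfg <- neck_config(c(2, 4, 6), out_channels = 5)
  params <- fpn_params(cfg, seed = 4)
  p <- make_backbone_pyramid(c(2, 4, 6), base = 13, seed = 5)  # odd sizes too
  out <- fpn_forward(p, cfg, params)
  for (l in 1:3) {
    expect_equal(dim(out$levels[[l]])[2:3], dim(p$levels[[l]])[2:3])
    expect_equal(dim(out$levels[[l]])[1], 5)
  }
  bad <- make_backbone_pyramid(c(2, 4, 7), base = 13, seed = 6)
  expect_error(fpn_forward(bad, cfg, params), "channels")
})

test_that("injected 0.5 gates reduce the neck to input plus balanced map", {
  cfg <- neck_config(c(2, 3, 4), out_channels = 4, reduction_ratio = 2)
  fpnp <- fpn_params(cfg, seed = 7)
  p <- make_backbone_pyramid(c(2, 3, 4), seed = 8)
  fo <- fpn_forward(p, cfg, fpnp)
  out <- abfp_forward(fo, cfg, abfp_params(cfg, seed = 9),
                      gates = list(channel = 0.5, spatial = 0.5))
  bal <- integrate_pyramid(fo, cfg$intermediate_index)
  for (l in 1:3) {
    d <- dim(fo$levels[[l]])
    expect_equal(out$levels[[l]],
                 fo$levels[[l]] + oracle_rescale(bal$map, d[2], d[3]),
                 tolerance = 1e-10)
  }
})

test_that("the zero pyramid passes through the neck unchanged", {
  cfg <- neck_config(c(2, 2), out_channels = 4, reduction_ratio = 2)
  ap <- abfp_params(cfg, seed = 10)
  z <- feature_pyramid(list(array(0, c(4, 8, 8)), array(0, c(4, 4, 4))))
  out <- abfp_forward(z, cfg, ap)
  for (l in 1:2) expect_true(all(out$levels[[l]] == 0))
})

test_that("abfp_forward equals the straight-line composition of its parts", {
  cfg <- neck_config(c(2, 3, 4, 5), out_channels = 6, reduction_ratio = 2)
  fpnp <- fpn_params(cfg, seed = 11)
  ap <- abfp_params(cfg, seed = 12)
  p <- make_backbone_pyramid(c(2, 3, 4, 5), base = 16, seed = 13)
  fo <- fpn_forward(p, cfg, fpnp)
  got <- abfp_forward(fo, cfg, ap)

  cap <- channel_attention_params(6, 2, seed = 99)
  cap$w0 <- ap[["att.ch.w0"]]; cap$b0 <- ap[["att.ch.b0"]]
  cap$w1 <- ap[["att.ch.w1"]]; cap$b1 <- ap[["att.ch.b1"]]
  sap <- spatial_attention_params(seed = 98)
  sap$kernel <- ap[["att.sp.w"]]; sap$bias <- ap[["att.sp.b"]]
  bal <- integrate_pyramid(fo, cfg$intermediate_index)
  refined <- abfp_refine(bal, cap, sap)
  want <- strengthen_pyramid(fo, refined)
  for (l in 1:4) {
    expect_lt(max(abs(got$levels[[l]] - want$levels[[l]])), 1e-6)
  }
})

test_that("attention-off refinement is a single 3x3 convolution", {
  cfg <- neck_config(c(2, 3), out_channels = 4, attention = FALSE)
  ap <- abfp_params(cfg, seed = 14)
  expect_named(ap, c("att.refine.w", "att.refine.b"))
  p <- make_backbone_pyramid(c(2, 3), base = 8, seed = 15)
  fpnp <- fpn_params(cfg, seed = 16)
  fo <- fpn_forward(p, cfg, fpnp)
  got <- abfp_forward(fo, cfg, ap)
  bal <- integrate_pyramid(fo, cfg$intermediate_index)
  refined <- balanced_semantic_map(
    abfp:::conv2d_fwd(bal$map, ap[["att.refine.w"]], ap[["att.refine.b"]],
                      pad = 1L)$out,
    cfg$intermediate_index)
  want <- strengthen_pyramid(fo, refined)
  for (l in 1:2) {
    expect_lt(max(abs(got$levels[[l]] - want$levels[[l]])), 1e-8)
  }
})

test_that("the ABFP parameter count matches its closed form", {
  for (C in c(8, 16)) {
    for (bias in c(TRUE, FALSE)) {
      cfg_on <- neck_config(c(4, 4), out_channels = C, reduction_ratio = 4,
                            attention_bias = bias)
      n_on <- sum(vapply(abfp_params(cfg_on, seed = 1), length, integer(1)))
      expect_equal(n_on, abfp_param_count(cfg_on))
      cfg_off <- neck_config(c(4, 4), out_channels = C, attention = FALSE)
      n_off <- sum(vapply(abfp_params(cfg_off, seed = 1), length, integer(1)))
      expect_equal(n_off, abfp_param_count(cfg_off))
    }
  }
})

test_that("neck configurations round-trip through YAML", {
  cfg <- neck_config(c(16, 32, 64, 128), out_channels = 32,
                     intermediate_index = 3, attention = FALSE,
                     reduction_ratio = 8, upsample_mode = "bilinear",
                     attention_bias = FALSE)
  path <- tempfile(fileext = ".yaml")
  write_neck_config(cfg, path)
  expect_equal(read_neck_config(path), cfg)
  unlink(path)
})
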