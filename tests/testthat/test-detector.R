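# Detector architecture contracts, positional encoding, forward pass,
# matching/loss behaviour, and the mAP evaluator. Heavy training runs
# live in the acceptance suite.

test_that("improved conv block honors the shape contract", {
  set.seed(71)
  ns <- asNamespace("fpmdetect")
  blk <- improved_conv_block(conv_block_spec(16, 16, 64, downsample = TRUE))
  x <- array(rnorm(24 * 24 * 16), c(24, 24, 16, 2))
  out <- ns$ag_no_grad(ns$nn_forward(blk, x, TRUE))
  expect_equal(dim(out$v), c(12, 12, 64, 2))
  # zero input: finite, deterministic output through the bias/BN path
  z <- array(0, c(24, 24, 16, 1))
  o1 <- ns$ag_no_grad(ns$nn_forward(blk, z, TRUE))$v
  o2 <- ns$ag_no_grad(ns$nn_forward(blk, z, TRUE))$v
  expect_true(all(is.finite(o1)))
  expect_equal(o1, o2)
  # odd side with downsampling is a shape error
  xodd <- array(rnorm(15 * 15 * 16), c(15, 15, 16, 1))
  expect_error(ns$ag_no_grad(ns$nn_forward(blk, xodd, TRUE)))
})

test_that("gradient occupancy: improved shortcut 100%, original 25%", {
  imp <- improved_conv_block(conv_block_spec(8, 8, 32, TRUE), improved = TRUE)
  ori <- improved_conv_block(conv_block_spec(8, 8, 32, TRUE), improved = FALSE)
  occ_imp <- gradient_occupancy(imp$children$shortcut, 16, 8)
  occ_ori <- gradient_occupancy(ori$children$shortcut, 16, 8)
  expect_equal(occ_imp, 1.0)
  expect_equal(occ_ori, 0.25)
  expect_gt(occ_imp, occ_ori)
  # 2x2 pooling window variant also has full coverage
  imp2 <- improved_conv_block(conv_block_spec(8, 8, 32, TRUE), pool_k = 2L)
  expect_equal(gradient_occupancy(imp2$children$shortcut, 16, 8), 1.0)
})

test_that("backbone shape contracts hold across variants and block types", {
  ns <- asNamespace("fpmdetect")
  set.seed(72)
  x <- array(rnorm(128 * 128 * 3), c(128, 128, 3, 1))
  for (variant in c("resnet18", "resnet34", "resnet50")) {
    for (improved in c(TRUE, FALSE)) {
      bb <- build_backbone(variant, improved, base_width = 8L)
      out <- ns$ag_no_grad(ns$nn_forward(bb, x, FALSE))
      expect_equal(dim(out$v)[1:2], c(4, 4),
                   info = paste(variant, improved))
      expect_equal(dim(out$v)[3], bb$out_channels)
    }
  }
  # stride-16 option gives a 2x finer map
  bb16 <- build_backbone("resnet18", TRUE, base_width = 8L, out_stride = 16L)
  out <- ns$ag_no_grad(ns$nn_forward(bb16, x, FALSE))
  expect_equal(dim(out$v)[1:2], c(8, 8))
  expect_error(build_backbone("resnet200"), "unknown")
})

test_that("parameter counts grow with depth and differ only by the
          substituted shortcut kernels", {
  p18 <- count_params(build_backbone("resnet18", FALSE))
  p50 <- count_params(build_backbone("resnet50", FALSE))
  p101 <- count_params(build_backbone("resnet101", FALSE))
  expect_lt(p18, p50)
  expect_lt(p50, p101)
  # improved vs original resnet50: difference equals the swapped kernels.
  # per downsampling bottleneck: main 1x1 (cin*mid) -> 3x3 (9*mid^2 vs
  # 1x1 cin*mid + 3x3 9 mid^2: improved has conv1 cin*mid (1x1 s1),
  # conv2 9*mid*mid (3x3 s2); original has conv1 cin*mid (1x1 s2),
  # conv2 9*mid*mid (3x3 s1): identical. Shortcut: pool (0 params) +
  # 1x1 cin*cout vs 1x1 cin*cout: identical. So counts must be EQUAL.
  pi50 <- count_params(build_backbone("resnet50", TRUE))
  expect_equal(pi50, p50)
})

test_that("positional encoding is bounded, position-dependent, exact", {
  pe <- positional_encoding(4, 4, 32)
  expect_equal(dim(pe), c(16, 32))
  expect_gte(min(pe), -1); expect_lte(max(pe), 1)
  expect_false(isTRUE(all.equal(pe[1, ], pe[2, ])))
  # closed-form spot checks: token t = y + 4x (0-based), first half = y
  # axis; pairs (sin, cos) at frequency 1/10000^((i-1)/8)
  t <- 7; y <- t %% 4; x <- t %/% 4
  expect_equal(pe[t + 1, 1], sin(y * 1))
  expect_equal(pe[t + 1, 2], cos(y * 1))
  expect_equal(pe[t + 1, 17], sin(x * 1))
  expect_equal(pe[t + 1, 3], sin(y / 10000^(1 / 8)))
  expect_error(positional_encoding(4, 4, 33), "even")
})

test_that("forward_detect returns a normalized fixed-size prediction set", {
  cfg <- detector_config(num_queries = 10L, hidden_dim = 32L,
                         base_width = 8L, image_side = 64L)
  model <- build_detector(cfg, seed = 3)
  set.seed(73)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- forward_detect(img, model)
  expect_equal(nrow(p), 10)
  expect_true(all(is.finite(as.matrix(p))))
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_true(all(p$cx >= 0 & p$cx <= 1 & p$w >= 0 & p$w <= 1))
  expect_error(forward_detect(array(0, c(32, 32, 3)), model), "side")
})

test_that("training loss is permutation-invariant in the targets", {
  cfg <- detector_config(num_queries = 8L, hidden_dim = 32L,
                         base_width = 8L, image_side = 64L)
  model <- build_detector(cfg, seed = 4)
  set.seed(74)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  tgt <- matrix(c(0.3, 0.3, 0.2, 0.2,
                  0.7, 0.6, 0.15, 0.25,
                  0.5, 0.8, 0.1, 0.1), 3, 4, byrow = TRUE)
  l1 <- training_step(model, img, list(tgt))
  l2 <- training_step(model, img, list(tgt[c(3, 1, 2), ]))
  expect_equal(l1$loss, l2$loss, tolerance = 1e-10)
  # batch without targets is class-loss only
  l0 <- training_step(model, img, list(matrix(numeric(0), 0, 4)))
  expect_equal(l0$box_loss, 0)
  expect_gt(l0$class_loss, 0)
})

test_that("evaluate_map handles exact, empty and hand-computed cases", {
  gt <- data.frame(image_id = 1, cx = c(0.3, 0.7), cy = c(0.3, 0.7),
                   w = 0.2, h = 0.2)
  exact <- data.frame(image_id = 1, score = 1, cx = c(0.3, 0.7),
                      cy = c(0.3, 0.7), w = 0.2, h = 0.2)
  expect_equal(evaluate_map(exact, gt), 1.0)
  none <- exact[0, ]
  expect_equal(evaluate_map(none, gt), 0)
  expect_warning(m <- evaluate_map(exact, gt[0, ]), "no ground-truth")
  expect_equal(m, 0)
  # worked 3-box example: ranks 1, 2 hit, rank 3 misses, rank 4 hits.
  # PR points: (1/3, 1), (2/3, 1), (2/3, 2/3), (1, 3/4);
  # all-point AP = 1/3 * 1 + 1/3 * 1 + 1/3 * 3/4 = 0.9166667
  gt3 <- data.frame(image_id = 1, cx = c(0.2, 0.5, 0.8), cy = 0.5,
                    w = 0.1, h = 0.1)
  pr <- data.frame(image_id = 1,
                   score = c(0.9, 0.8, 0.7, 0.6),
                   cx = c(0.2, 0.5, 0.35, 0.8),  # third is a false positive
                   cy = 0.5, w = 0.1, h = 0.1)
  expect_equal(evaluate_map(pr, gt3), 1 / 3 + 1 / 3 + 1 / 3 * 3 / 4,
               tolerance = 1e-12)
})

test_that("a detector overfits one two-cell image (box term < 0.05)", {
  ns <- asNamespace("fpmdetect")
  sc <- generate_scene(detection_phantom_config(n_wbc = 2, n_rbc = c(20, 30)),
                       seed = 21)
  img <- render_color_image(sc, 64)
  tgt <- annotations_to_norm(scene_to_annotations(sc, 64))
  cfg <- detector_config(num_queries = 8L, hidden_dim = 32L, base_width = 8L,
                         image_side = 64L)
  model <- build_detector(cfg, seed = 7)
  params <- ns$collect_params(model)
  opt <- list(params = params,
              main = ns$adamw(params, lr = cfg$lr,
                              weight_decay = cfg$weight_decay),
              bb = ns$adamw(list(), lr = cfg$lr))
  batch <- array(img, c(64, 64, 3, 1))
  set.seed(75)
  box_final <- NA
  for (s in 1:200) {
    # constant-rate Adam jitters around the optimum; one step decay
    # lets the boxes settle
    if (s == 120) opt$main$lr <- cfg$lr / 5
    st <- ns$training_step_opt(model, batch, list(tgt), opt)
    box_final <- st$box_iou_loss
  }
  # per-target CIOU component below 0.05 after 200 overfitting steps
  expect_lt(box_final, 0.05)
})
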