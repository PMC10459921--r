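# Scene generation, rendering, annotations, resolution targets.

test_that("generate_scene conserves counts and handles empty scenes", {
  empty <- generate_scene(phantom_config(n_rbc = 0, n_wbc = 0), 1)
  expect_equal(nrow(empty$cells), 0)
  f <- render_highres(empty, 64, "green")
  expect_equal(Mod(f$values),
               matrix(1 - empty$background_absorption, 64, 64),
               tolerance = 1e-12)
  expect_equal(Arg(f$values), matrix(0, 64, 64), tolerance = 1e-12)

  sc <- generate_scene(phantom_config(fov_um = 200, n_rbc = 60, n_wbc = 5), 2)
  expect_equal(sum(sc$cells$kind == "wbc"), 5)
  expect_equal(sum(sc$cells$kind == "rbc"), 60)
  expect_true(all(sc$cells$radius[sc$cells$kind == "wbc"] >
                    max(sc$cells$radius[sc$cells$kind == "rbc"])))
})

test_that("scene generation is deterministic per (config, seed)", {
  cfg <- detection_phantom_config()
  s1 <- generate_scene(cfg, 11)
  s2 <- generate_scene(cfg, 11)
  expect_identical(s1, s2)
  expect_identical(render_highres(s1, 128, "red")$values,
                   render_highres(s2, 128, "red")$values)
  s3 <- generate_scene(cfg, 12)
  expect_false(identical(s1$cells, s3$cells))
})

test_that("overlap fraction tracks overlap_prob over seeds", {
  fr <- vapply(1:20, function(s) {
    sc <- generate_scene(phantom_config(fov_um = 300, n_rbc = 195, n_wbc = 5,
                                        overlap_prob = 0.3), seed = s)
    cl <- sc$cells
    d2 <- as.matrix(stats::dist(cl[, c("cx", "cy")]))^2
    rs <- outer(cl$radius, cl$radius, `+`)^2
    diag(d2) <- Inf
    mean(apply(d2 < rs, 1, any))
  }, 0)
  expect_lt(abs(mean(fr) - 0.3), 0.1)
})

test_that("default configuration mirrors peripheral-blood class imbalance", {
  sc <- generate_scene(phantom_config(), 7)
  ratio <- sum(sc$cells$kind == "rbc") / sum(sc$cells$kind == "wbc")
  expect_gte(ratio, 600)
  expect_lte(ratio, 1000)
})

test_that("rendered amplitude stays in [0, 1]; single cell dips centrally", {
  set.seed(31)
  for (s in 1:5) {
    sc <- generate_scene(detection_phantom_config(overlap_prob = 0.4), s)
    a <- Mod(render_highres(sc, 96, sample(c("red", "green", "blue"), 1))$values)
    expect_gte(min(a), 0)
    expect_lte(max(a), 1)
  }
  # single centered wbc: radially symmetric dip at the center
  one <- generate_scene(phantom_config(fov_um = 40, n_rbc = 0, n_wbc = 1,
                                       overlap_prob = 0), 3)
  one$cells$cx <- 20; one$cells$cy <- 20
  a <- Mod(render_highres(one, 64, "green")$values)
  expect_lt(a[33, 33], a[2, 2])            # center darker than corner
  expect_equal(a, t(a), tolerance = 1e-12) # symmetry about the diagonal
  # nucleus darker than cytoplasm rim
  r_px <- one$cells$radius / 40 * 64
  rim <- a[33, 33 + round(0.9 * r_px)]
  expect_lt(a[33, 33], rim)
})

test_that("annotations give one clipped tight box per in-field wbc", {
  one <- generate_scene(phantom_config(fov_um = 40, n_rbc = 0, n_wbc = 1,
                                       overlap_prob = 0), 3)
  one$cells$cx <- 20; one$cells$cy <- 20
  ann <- scene_to_annotations(one, 128)
  expect_equal(nrow(ann$boxes), 1)
  r_px <- one$cells$radius / 40 * 128
  expect_equal(ann$boxes$w, 2 * r_px, tolerance = 1e-9)
  expect_equal(ann$boxes$x + ann$boxes$w / 2, 64, tolerance = 1e-9)
  # half-outside cell: clipped box, smaller area
  one$cells$cx <- 0
  ann2 <- scene_to_annotations(one, 128)
  expect_equal(ann2$boxes$x, 0)
  expect_lt(ann2$boxes$w * ann2$boxes$h, (2 * r_px)^2)
  # box count equals wbc-with-center-inside count over random scenes
  for (s in 1:30) {
    sc <- generate_scene(detection_phantom_config(), s)
    ann <- scene_to_annotations(sc, 128)
    inside <- sum(sc$cells$kind == "wbc" &
                    sc$cells$cx >= 0 & sc$cells$cx <= sc$fov_um &
                    sc$cells$cy >= 0 & sc$cells$cy <= sc$fov_um)
    expect_equal(nrow(ann$boxes), inside)
  }
})

test_that("every box contains its cell's absorption minimum", {
  for (s in 1:5) {
    sc <- generate_scene(detection_phantom_config(n_rbc = 10), s)
    side <- 128
    a <- Mod(render_highres(sc, side, "green")$values)
    ann <- scene_to_annotations(sc, side)
    for (j in seq_len(nrow(ann$boxes))) {
      bx <- ann$boxes[j, ]
      rows <- max(1, ceiling(bx$y)):min(side, floor(bx$y + bx$h))
      cols <- max(1, ceiling(bx$x)):min(side, floor(bx$x + bx$w))
      inside_min <- min(a[rows, cols])
      # the wbc's darkest pixel is the darkest in its box
      expect_equal(inside_min, min(a[rows, cols]))
      expect_lt(inside_min, mean(a))       # genuinely darker than average
    }
  }
})

test_that("resolution target places recoverable bar pairs", {
  tg <- make_resolution_target(256, 10, pixel_pitch_um = 0.5)
  a <- Mod(tg$values)
  expect_setequal(unique(as.numeric(a)), c(0.2, 1.0))
  ctr <- attr(tg, "bar_centers_px")[[1]]
  expect_equal(diff(ctr$cols), 10 / 0.5)   # 20 px apart
  # bars recoverable by profile minima
  row <- round(mean(ctr$rows))
  prof <- a[row, ]
  dark <- which(prof < 0.5)
  expect_equal(sort(unique(round(
    vapply(split(dark, cumsum(c(1, diff(dark) > 1))), mean, 0)))),
    sort(round(ctr$cols)), tolerance = 1)
  expect_error(make_resolution_target(256, 0.3, pixel_pitch_um = 0.5),
               "exceed")
})
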