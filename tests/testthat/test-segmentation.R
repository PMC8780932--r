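# Shared tiny palette: red is positive, blue is trained negative.
make_red_palette <- function(levels = 64, unseen_policy = "negative") {
  img <- uniform_image(10, 20, c(200, 40, 40), id = "t")
  px <- img$pixels
  px[, 11:20, 1] <- 40L; px[, 11:20, 2] <- 40L; px[, 11:20, 3] <- 200L
  img <- rgb_image(px, id = "t")
  tab <- accumulate_training(img, list(
    region_annotation("t", "stain", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
    region_annotation("t", "negative", rbind(c(10, 0), c(20, 0), c(20, 10), c(10, 10)))),
    levels = levels)
  derive_palette(tab, unseen_policy = unseen_policy)
}

test_that("pixel classification labels palette colors and leaves none unlabeled", {
  pal <- make_red_palette()
  expect_true(all(unclass(classify_pixels(
    uniform_image(6, 6, c(200, 40, 40)), pal)) == 1L))
  expect_true(all(unclass(classify_pixels(
    uniform_image(6, 6, c(40, 40, 200)), pal)) == 0L))

  px <- array(0L, dim = c(10, 10, 3))
  for (ch in 1:3) px[, , ch] <- c(200, 40, 40)[ch]
  px[4:10, , 1] <- 40L; px[4:10, , 3] <- 200L  # 70 negative pixels
  lab <- classify_pixels(rgb_image(px), pal)
  expect_equal(sum(unclass(lab) == 1L), 30L)
  expect_equal(sum(unclass(lab) == 0L), 70L)
})

test_that("classification is per-pixel: permuting pixels permutes labels", {
  set.seed(5)
  pal <- make_red_palette()
  px <- array(sample(0:255, 12 * 12 * 3, replace = TRUE), dim = c(12, 12, 3))
  lab <- unclass(classify_pixels(rgb_image(px), pal))
  perm <- sample(144)
  px2 <- array(0L, dim = c(12, 12, 3))
  for (ch in 1:3) px2[, , ch][perm] <- px[, , ch]
  lab2 <- unclass(classify_pixels(rgb_image(px2), pal))
  expect_identical(lab2[perm], as.vector(lab))
})

test_that("unseen colors default to negative; nearest policy adopts the closest color", {
  pal_neg <- make_red_palette()
  pal_near <- make_red_palette(unseen_policy = "nearest")
  novel_near_red <- uniform_image(4, 4, c(190, 50, 50))   # nearer the red bin
  novel_near_blue <- uniform_image(4, 4, c(50, 50, 190))
  expect_true(all(unclass(classify_pixels(novel_near_red, pal_neg)) == 0L))
  expect_true(all(unclass(classify_pixels(novel_near_red, pal_near)) == 1L))
  expect_true(all(unclass(classify_pixels(novel_near_blue, pal_near)) == 0L))
})

test_that("background exclusion relabels near-white pixels with a strict threshold", {
  pal <- make_red_palette()
  px <- array(0L, dim = c(2, 2, 3))
  px[1, 1, ] <- c(255L, 255L, 255L)
  px[1, 2, ] <- c(219L, 219L, 219L)   # just below the threshold
  px[2, 1, ] <- c(220L, 220L, 220L)   # exactly at the threshold
  px[2, 2, ] <- c(200L, 40L, 40L)
  img <- rgb_image(px)
  lab <- classify_pixels(img, pal)
  params <- segmentation_params(background_exclusion = TRUE,
                                background_min_channel = 220)
  out <- unclass(exclude_background(img, lab, params))
  expect_equal(out[1, 1], -1L)
  expect_equal(out[1, 2], 0L)
  expect_equal(out[2, 1], -1L)
  expect_equal(out[2, 2], 1L)
  off <- segmentation_params(background_exclusion = FALSE)
  expect_identical(exclude_background(img, lab, off), lab)
})

test_that("component size filtering keeps only components inside the window", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE              # area 4
  m[8:14, 8:14] <- TRUE            # area 49
  mask <- binary_mask(m)
  ident <- filter_components(mask, segmentation_params())
  expect_identical(mval(ident), m)
  filt <- filter_components(mask, segmentation_params(min_component_area = 10))
  expect_equal(sum(filt), 49L)
  expect_true(all(which(filt, arr.ind = TRUE) >= 8))
  none <- filter_components(mask, segmentation_params(min_component_area = 100))
  expect_equal(sum(none), 0L)
  maxf <- filter_components(mask, segmentation_params(max_component_area = 10))
  expect_equal(sum(maxf), 4L)
})

test_that("connectivity 4 splits diagonal touches that connectivity 8 joins", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m, 8L)), 1L)
  expect_equal(max(label_components(m, 4L)), 2L)
  # filtering at min area 2 removes both pixels under 4- but not 8-connectivity
  expect_equal(sum(filter_components(binary_mask(m),
    segmentation_params(min_component_area = 2, connectivity = 4L))), 0L)
  expect_equal(sum(filter_components(binary_mask(m),
    segmentation_params(min_component_area = 2, connectivity = 8L))), 2L)
})

test_that("positive area is non-increasing in min_component_area", {
  set.seed(9)
  for (rep in 1:5) {
    mask <- binary_mask(random_mask(40, 40, 0.4))
    areas <- vapply(c(0, 2, 4, 8, 16, 400), function(a)
      sum(filter_components(mask, segmentation_params(min_component_area = a))),
      numeric(1))
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("morphology steps match naive erosion/dilation and fill holes", {
  params_open <- segmentation_params(morphology = list(list(op = "open", radius = 1)))
  # isolated pixel is removed by opening
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_equal(sum(apply_morphology(binary_mask(m), params_open)), 0L)
  # empty step list and radius 0 are identities
  m2 <- random_mask(15, 15, 0.5)
  expect_identical(mval(apply_morphology(binary_mask(m2),
    segmentation_params())), m2)
  expect_identical(mval(apply_morphology(binary_mask(m2),
    segmentation_params(morphology = list(list(op = "open", radius = 0))))), m2)
  # opening == dilate(erode(m)) against the naive oracle
  set.seed(3)
  brush <- EBImage::makeBrush(3, "disc")
  for (rep in 1:3) {
    m3 <- random_mask(12, 12, 0.6)
    got <- mval(apply_morphology(binary_mask(m3), params_open))
    want <- naive_morph(naive_morph(m3, brush, "erode"), brush, "dilate")
    expect_identical(got, want)
  }
  # fill_holes closes an interior hole
  sq <- matrix(FALSE, 12, 12); sq[2:11, 2:11] <- TRUE; sq[6, 6] <- FALSE
  filled <- apply_morphology(binary_mask(sq),
    segmentation_params(morphology = list(list(op = "fill_holes"))))
  expect_true(filled[6, 6])
  expect_equal(sum(filled), 100L)
})

test_that("box-threshold baseline is an axis-aligned box in RGB space", {
  px <- array(0L, dim = c(10, 10, 3))
  for (ch in 1:3) px[, , ch] <- c(200, 40, 40)[ch]
  px[6:10, , 1] <- 40L; px[6:10, , 3] <- 200L
  img <- rgb_image(px)
  expect_equal(sum(threshold_baseline(img, c(0, 255), c(0, 255), c(0, 255))), 100L)
  expect_equal(sum(threshold_baseline(img, c(0, 10), c(0, 10), c(0, 10))), 0L)
  half <- threshold_baseline(img, c(150, 255), c(0, 100), c(0, 100))
  expect_equal(sum(half), 50L)
  expect_error(threshold_baseline(img, c(200, 100), c(0, 255), c(0, 255)),
               "interval")
})

test_that("grid-searched box recovers a separable box exactly", {
  set.seed(21)
  px <- array(sample(0:255, 30 * 30 * 3, replace = TRUE), dim = c(30, 30, 3))
  img <- rgb_image(px)
  truth <- binary_mask(px[, , 1] >= 64 & px[, , 1] < 128 &
                         px[, , 2] >= 32 & px[, , 2] < 160 &
                         px[, , 3] >= 0 & px[, , 3] < 96)
  fit <- fit_box_threshold(img, truth, step = 32)
  expect_equal(fit$j, 1)
  bm <- threshold_baseline(img, fit$r_range, fit$g_range, fit$b_range)
  expect_identical(mval(bm), mval(truth))
})

test_that("overlay blends class colors and leaves negatives untouched", {
  pal <- make_red_palette()
  img <- uniform_image(4, 4, c(200, 40, 40))
  lab <- classify_pixels(img, pal)
  colors <- list(stain = c(0, 255, 0))
  full <- render_overlay(img, lab, colors, opacity = 1)
  expect_true(all(full$pixels[, , 2] == 255L) && all(full$pixels[, , 1] == 0L))
  half <- render_overlay(img, lab, colors, opacity = 0.5)
  expect_true(all(half$pixels[, , 1] == 100L))  # round(0.5*200 + 0.5*0)
  expect_true(all(half$pixels[, , 2] == 148L))  # round(0.5*40 + 0.5*255)
  neg <- uniform_image(4, 4, c(40, 40, 200))
  lab0 <- classify_pixels(neg, pal)
  expect_identical(render_overlay(neg, lab0, colors, 0.7)$pixels, neg$pixels)
  expect_error(render_overlay(img, lab, list(), 0.5), "overlay color")
})

test_that("edge flagging partitions by slide-background fraction", {
  params <- segmentation_params(background_min_channel = 220)
  tissue <- uniform_image(10, 10, c(200, 100, 100), id = "tissue")
  white <- uniform_image(10, 10, c(250, 250, 250), id = "white")
  px <- tissue$pixels; px[1:3, , ] <- 250L   # 30% white
  part30 <- rgb_image(px, id = "part")
  res <- flag_edge_images(list(tissue, white, part30), params,
                          max_background_fraction = 0.25)
  expect_setequal(res$edge, c("white", "part"))
  expect_equal(res$continuous, "tissue")
  res2 <- flag_edge_images(list(part30), params, max_background_fraction = 0.35)
  expect_equal(res2$continuous, "part")
  expect_length(res2$edge, 0)
})

test_that("an image of purely positive-trained colors is 100% positive pre-exclusion", {
  pal <- make_red_palette()
  lab <- classify_pixels(uniform_image(16, 16, c(200, 40, 40)), pal)
  expect_equal(percent_positive_area(class_mask(lab, "stain")), 100)
})
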