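test_that("quantization maps channel values to the expected uniform bins", {
  expect_equal(quantize_color(c(0, 0, 0), 32), c(0L, 0L, 0L))
  expect_equal(quantize_color(c(255, 255, 255), 32), c(31L, 31L, 31L))
  # floor(c * 32 / 256) by hand: 100 -> 12, 150 -> 18, 200 -> 25
  expect_equal(quantize_color(c(100, 150, 200), 32), c(12L, 18L, 25L))
  expect_error(quantize_color(c(0, 0, 0), 1), "levels")
  expect_error(quantize_color(c(0, 0, 0), 300), "levels")
})

test_that("quantization partitions the cube and fills every bin", {
  for (levels in c(2L, 32L, 64L, 256L)) {
    q <- quantize_color(cbind(0:255, 0:255, 0:255), levels)
    expect_true(all(q >= 0L & q <= levels - 1L))
    expect_equal(sort(unique(q[, 1])), 0:(levels - 1L))
    if (256L %% levels == 0L)  # uniform occupancy when levels divides 256
      expect_true(all(table(q[, 1]) == 256L / levels))
  }
})

test_that("rasterization handles the reference square and triangle", {
  img <- uniform_image(20, 20, c(10, 10, 10), id = "img")
  sq <- region_annotation("img", "positive",
                          rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  m <- rasterize_region(sq, img)
  expect_equal(sum(m), 100L)
  expect_true(all(which(m, arr.ind = TRUE) <= 10))

  img10 <- uniform_image(10, 10, c(10, 10, 10), id = "img")
  tri <- region_annotation("img", "positive",
                           rbind(c(0, 0), c(4, 0), c(0, 4)))
  expect_equal(sum(rasterize_region(tri, img10)), 6L)

  off <- region_annotation("img", "positive",
                           rbind(c(50, 50), c(60, 50), c(50, 60)))
  expect_error(rasterize_region(off, img10), "no pixel centers")
  mismatch <- region_annotation("other", "positive",
                                rbind(c(0, 0), c(4, 0), c(0, 4)))
  expect_error(rasterize_region(mismatch, img10), "refers to")
})

test_that("rasterization matches exhaustive point-in-polygon testing", {
  skip_if_not_installed("mgcv")
  set.seed(42)
  img <- uniform_image(32, 32, c(1, 2, 3), id = "img")
  centers <- as.matrix(expand.grid(x = 0:31 + 0.5, y = 0:31 + 0.5))
  for (rep in 1:25) {
    poly <- random_polygon(32)
    want <- mgcv::in.out(rbind(poly, poly[1, ]), centers)
    if (!any(want)) next  # degenerate draw: no pixel center covered
    ann <- region_annotation("img", "positive", poly)
    got <- rasterize_region(ann, img)
    # in.out returns in expand.grid order: x fastest -> column-major of t(m)
    expect_identical(as.vector(t(unclass(got))), as.vector(want))
  }
})

test_that("training accumulation counts pixels per (pixel, region) membership", {
  img <- uniform_image(10, 10, c(200, 40, 40), id = "img")
  pos <- region_annotation("img", "stain", rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
  neg <- region_annotation("img", "negative", rbind(c(0, 5), c(10, 5), c(10, 10), c(0, 10)))
  tab <- accumulate_training(img, list(pos, neg), levels = 64)
  expect_s3_class(tab, "color_training_table")
  expect_length(tab$keys, 1L)  # uniform color -> one entry
  expect_equal(unname(tab$counts[1, "stain"]), 50)
  expect_equal(unname(tab$counts[1, "negative"]), 50)
  expect_equal(tab$total_pixels, 100)

  # overlapping regions of different labels increment both counts
  both <- accumulate_training(img, list(pos, neg,
    region_annotation("img", "stain", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))))
  expect_equal(unname(both$counts[1, "stain"]), 150)
  expect_equal(both$total_pixels, 200)

  expect_error(accumulate_training(img, list(neg)), "no positive")
  expect_error(accumulate_training(img, list(pos)), "no negative")
})

test_that("accumulation matches a naive per-pixel membership loop", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  px <- array(sample(0:255, 24 * 24 * 3, replace = TRUE), dim = c(24, 24, 3))
  img <- rgb_image(px, id = "img")
  anns <- list(
    region_annotation("img", "stain", random_polygon(24)),
    region_annotation("img", "negative", random_polygon(24)))
  tab <- accumulate_training(img, anns, levels = 16)
  # oracle: test every pixel center against every polygon independently
  centers <- as.matrix(expand.grid(x = 0:23 + 0.5, y = 0:23 + 0.5))
  counts <- list(stain = integer(0), negative = integer(0))
  keys_seen <- numeric(0)
  for (a in anns) {
    io <- mgcv::in.out(rbind(a$polygon, a$polygon[1, ]), centers)
    sel <- which(matrix(io, 24, 24, byrow = TRUE))
    pm <- cbind(px[, , 1][sel], px[, , 2][sel], px[, , 3][sel])
    q <- floor(pm * 16 / 256)
    key <- (q[, 1] * 16 + q[, 2]) * 16 + q[, 3]
    keys_seen <- c(keys_seen, key)
    counts[[a$label]] <- c(counts[[a$label]], key)
  }
  expect_setequal(tab$keys, unique(keys_seen))
  for (k in tab$keys) {
    expect_equal(unname(tab$counts[match(k, tab$keys), "stain"]),
                 sum(counts$stain == k))
    expect_equal(unname(tab$counts[match(k, tab$keys), "negative"]),
                 sum(counts$negative == k))
  }
})

test_that("palette derivation applies the strict majority-fraction rule", {
  mk <- function(pos, neg) {
    counts <- matrix(c(pos, neg), 1, dimnames = list(NULL, c("stain", "negative")))
    stainpal:::new_training_table(64, "stain", 123, counts)
  }
  expect_equal(derive_palette(mk(10, 0))$positive$stain, 123)
  expect_error(derive_palette(mk(0, 10)), "empty palette")
  expect_equal(derive_palette(mk(6, 4), threshold = 0.5)$positive$stain, 123)
  expect_error(derive_palette(mk(6, 4), threshold = 0.7), "empty palette")
  # exactly at threshold is NOT positive (strict rule)
  expect_error(derive_palette(mk(5, 5), threshold = 0.5), "empty palette")
})

test_that("multi-class colors go to the largest class only when it holds a majority", {
  counts <- rbind(c(30, 10, 0),    # brown wins with 0.75 share
                  c(10, 30, 0),    # blue wins with 0.75 share
                  c(20, 20, 10),   # no class exceeds 0.5 -> negative
                  c(0, 0, 50))     # pure negative
  colnames(counts) <- c("brown", "blue", "negative")
  tab <- stainpal:::new_training_table(64, c("brown", "blue"), 1:4, counts)
  pal <- derive_palette(tab)
  expect_equal(pal$positive$brown, 1)
  expect_equal(pal$positive$blue, 2)
  expect_length(intersect(pal$positive$brown, pal$positive$blue), 0)
})

test_that("palette derivation is scale-invariant and deterministic", {
  set.seed(11)
  counts <- matrix(sample(0:20, 40 * 3, replace = TRUE), 40, 3,
                   dimnames = list(NULL, c("a", "b", "negative")))
  counts[1, ] <- c(10, 0, 0)  # guarantee a positive color
  keys <- sort(sample(1e5, 40))
  tab <- stainpal:::new_training_table(64, c("a", "b"), keys, counts)
  tab5 <- stainpal:::new_training_table(64, c("a", "b"), keys, counts * 5)
  p1 <- derive_palette(tab); p2 <- derive_palette(tab); p5 <- derive_palette(tab5)
  expect_identical(p1$positive, p2$positive)
  expect_identical(p1$positive, p5$positive)
})

test_that("table merging is identity on empties, doubles on self, unions disjoint", {
  img <- uniform_image(10, 10, c(200, 40, 40), id = "img")
  pos <- region_annotation("img", "stain", rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5)))
  # strict-majority palettes need the positive share above 1/2: 50 vs 40
  neg <- region_annotation("img", "negative", rbind(c(0, 5), c(10, 5), c(10, 9), c(0, 9)))
  tab <- accumulate_training(img, list(pos, neg))
  empty <- stainpal:::new_training_table(
    64, "stain", numeric(0),
    matrix(0, 0, 2, dimnames = list(NULL, c("stain", "negative"))))
  expect_equal(merge_training(tab, empty)$counts, tab$counts)
  dbl <- merge_training(tab, tab)
  expect_equal(dbl$counts, tab$counts * 2)
  expect_identical(derive_palette(dbl)$positive, derive_palette(tab)$positive)

  img2 <- uniform_image(10, 10, c(40, 40, 200), id = "img2")
  tab2 <- accumulate_training(
    img2,
    list(region_annotation("img2", "stain", rbind(c(0, 0), c(10, 0), c(10, 5), c(0, 5))),
         region_annotation("img2", "negative", rbind(c(0, 5), c(10, 5), c(10, 10), c(0, 10)))))
  u <- merge_training(tab, tab2)
  expect_setequal(u$keys, c(tab$keys, tab2$keys))  # disjoint colors union
  expect_equal(u$total_pixels, tab$total_pixels + tab2$total_pixels)

  tab16 <- accumulate_training(img, list(pos, neg), levels = 16)
  expect_error(merge_training(tab, tab16), "levels")
})

test_that("annotations and color models survive a JSON round trip", {
  anns <- list(
    region_annotation("a.png", "stain", rbind(c(0.5, 1), c(8, 0.25), c(4, 9))),
    region_annotation("a.png", "negative", rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))))
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(anns, f)
  back <- read_annotations(f)
  expect_equal(back[[1]]$polygon, anns[[1]]$polygon)
  expect_equal(back[[2]]$label, "negative")

  img <- uniform_image(25, 25, c(200, 40, 40), id = "a.png")
  tab <- accumulate_training(img, anns, classes = "stain")
  ft <- withr::local_tempfile(fileext = ".json")
  write_color_model(tab, ft)
  tab2 <- read_color_model(ft)
  expect_equal(tab2$keys, tab$keys)
  expect_equal(unname(tab2$counts), unname(tab$counts))

  # the uniform color is mostly negative here; a low threshold keeps it
  pal <- derive_palette(tab, threshold = 0.1)
  fp <- withr::local_tempfile(fileext = ".json")
  write_color_model(pal, fp)
  pal2 <- read_color_model(fp)
  expect_identical(pal2$positive, pal$positive)
  expect_equal(pal2$threshold, pal$threshold)
})
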