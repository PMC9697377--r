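make_record <- function(n = 2, w = 100, h = 80, labels = c("OF", "SLF")) {
  boxes_df <- boxes(cx = seq(20, 20 + 15 * (n - 1), length.out = n),
                    cy = rep(30, n), w = rep(10, n), h = rep(20, n),
                    label = rep_len(labels, n))
  list(image = "im.png", width = w, height = h, boxes = boxes_df)
}

test_that("VOC XML corners convert to center form on read", {
  xml <- file.path(tempdir(), "one.xml")
  rec <- list(image = "a.png", width = 100, height = 100,
              boxes = boxes_from_corners(10, 20, 30, 60, label = "OF"))
  write_voc_xml(rec, xml)
  back <- read_voc_xml(xml)
  expect_equal(back$boxes$cx, 20)
  expect_equal(back$boxes$cy, 40)
  expect_equal(back$boxes$w, 20)
  expect_equal(back$boxes$h, 40)
  expect_identical(back$boxes$label, "OF")
})

test_that("VOC XML round-trips losslessly, including edge cases", {
  dir <- tempdir()
  # zero objects -> valid record and valid XML
  empty <- list(image = "e.png", width = 64, height = 48, boxes = boxes())
  p <- file.path(dir, "empty.xml")
  write_voc_xml(empty, p)
  back <- read_voc_xml(p)
  expect_equal(nrow(back$boxes), 0)
  expect_equal(back$width, 64)
  # boxes at the image border and integer coordinates survive
  rec <- list(image = "b.png", width = 100, height = 100,
              boxes = boxes_from_corners(c(0, 50), c(0, 10), c(100, 70),
                                         c(100, 44),
                                         label = c("edge case", "OF")))
  p2 <- file.path(dir, "two.xml")
  write_voc_xml(rec, p2)
  b1 <- read_voc_xml(p2)
  write_voc_xml(b1, p2)
  b2 <- read_voc_xml(p2)
  expect_identical(b1, b2)
  expect_equal(b1$boxes[, 1:4], rec$boxes[, 1:4])
  expect_identical(b1$boxes$label, rec$boxes$label)
  # malformed files name the missing tag / bad box
  bad <- file.path(dir, "bad.xml")
  writeLines("<annotation><filename>x</filename></annotation>", bad)
  expect_error(read_voc_xml(bad), "size")
  writeLines(paste0("<annotation><filename>x</filename>",
                    "<size><width>10</width><height>10</height></size>",
                    "<object><name>a</name><bndbox><xmin>5</xmin>",
                    "<ymin>1</ymin><xmax>5</xmax><ymax>4</ymax>",
                    "</bndbox></object></annotation>"), bad)
  expect_error(read_voc_xml(bad), "xmax")
})

test_that("dataset splitting is an exact seeded floor-rule partition", {
  sp <- split_dataset(as.list(1:10), seed = 1)
  expect_length(sp$train, 9)
  expect_length(sp$test, 1)
  sp2 <- split_dataset(as.list(1:7392), seed = 5)
  expect_length(sp2$train, 6652)
  expect_length(sp2$test, 740)
  # partition law on random sizes and seeds
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:200, 1)
    sd <- sample(1e6, 1)
    sp <- split_dataset(seq_len(n), train_fraction = 0.9, seed = sd)
    expect_equal(sort(c(sp$train, sp$test)), seq_len(n))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(sp$train, floor(0.9 * n))
  }
  # reproducible per seed; different seeds permute membership
  a <- split_dataset(1:50, seed = 7)
  b <- split_dataset(1:50, seed = 7)
  expect_identical(a, b)
  d <- split_dataset(1:50, seed = 8)
  expect_length(d$train, length(a$train))
  expect_error(split_dataset(list()), "empty")
  expect_error(split_dataset(1:5, train_fraction = 1.2), "train_fraction")
})

test_that("relative size is the box/image area ratio", {
  full <- boxes(cx = 50, cy = 50, w = 100, h = 100)
  expect_equal(relative_size(full, 100, 100), 1)
  small <- boxes(cx = 10, cy = 10, w = 10, h = 10)
  expect_equal(relative_size(small, 100, 100), 0.01)
  expect_equal(relative_size(small, 100, 100, definition = "linear"), 0.1)
  expect_error(relative_size(small, 0, 100), "positive")
})

test_that("dataset statistics count images, instances and mean sizes", {
  r1 <- make_record(1, labels = "OF")
  st1 <- dataset_stats(list(r1))
  expect_equal(st1$per_class$n_images, 1)
  expect_equal(st1$per_class$n_instances, 1)
  # one image with three instances of one class
  r3 <- make_record(3, labels = "OF")
  st3 <- dataset_stats(list(r3))
  expect_equal(st3$per_class$n_images, 1)
  expect_equal(st3$per_class$n_instances, 3)
  # instance counts sum to the total box count; means match a direct loop
  recs <- list(make_record(2), make_record(3, labels = "OF"),
               make_record(1, labels = "SLF"))
  st <- dataset_stats(recs)
  expect_equal(sum(st$per_class$n_instances),
               sum(vapply(recs, function(r) nrow(r$boxes), 0)))
  direct <- unlist(lapply(recs, function(r) {
    (r$boxes$w * r$boxes$h) / (r$width * r$height)
  }))
  labs <- unlist(lapply(recs, function(r) as.character(r$boxes$label)))
  for (cl in st$per_class$class) {
    expect_equal(st$per_class$mean_rel_size[st$per_class$class == cl],
                 mean(direct[labs == cl]))
  }
  expect_error(dataset_stats(list()), "empty")
})
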