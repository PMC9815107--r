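# Ingestion, augmentation, splitting and the synthetic generator.

test_that("rotate180 and hflip are involutions with the expected index
           arithmetic", {
  set.seed(1)
  img <- array(sample(0:255, 5 * 7 * 3, replace = TRUE), c(5, 7, 3))
  expect_identical(rotate180(rotate180(img)), img)
  expect_identical(hflip(hflip(img)), img)

  # 2x2: [[a,b],[c,d]] -> [[d,c],[b,a]]
  m <- array(0, c(2, 2, 3))
  m[, , 1] <- matrix(c(1, 3, 2, 4), 2)        # rows: (a b / c d)
  r <- rotate180(m)
  expect_equal(r[, , 1], matrix(c(4, 2, 3, 1), 2))
  # 1x3 row [a, b, c] -> [c, b, a]
  row <- array(rep(c(10, 20, 30), each = 1), c(1, 3, 3))
  row[1, , 1] <- c(10, 20, 30)
  expect_equal(hflip(row)[1, , 1], c(30, 20, 10))
  # 1x1 image is a fixed point
  one <- flat_image(1, 1, c(9, 9, 9))
  expect_identical(rotate180(one), one)

  # rotate180 = hflip o vflip
  vflip <- img[rev(seq_len(5)), , , drop = FALSE]
  expect_identical(rotate180(img), hflip(vflip))
})

test_that("brightness scaling: 70% rule, identity, clipping and rounding", {
  img <- flat_image(4, 4, c(100, 100, 100))
  expect_true(all(adjust_brightness(img, 0.7) == 70))
  expect_identical(adjust_brightness(img, 1), img)
  sat <- flat_image(2, 2, c(255, 255, 255))
  expect_true(all(adjust_brightness(sat, 2) == 255))
  # round half away from zero: 5 * 0.7 = 3.5 -> 4
  expect_equal(adjust_brightness(flat_image(1, 1, c(5, 5, 5)), 0.7)[1, 1, 1], 4)
  expect_error(adjust_brightness(img, 0), "positive")
})

test_that("augmentations preserve shape and 0..255 range", {
  set.seed(2)
  img <- array(sample(0:255, 6 * 6 * 3, replace = TRUE), c(6, 6, 3))
  for (out in list(rotate180(img), hflip(img), adjust_brightness(img, 0.7),
                   adjust_brightness(img, 1.3))) {
    expect_identical(dim(out), dim(img))
    expect_true(min(out) >= 0 && max(out) <= 255)
  }
})

test_that("image folders scan deterministically and corrupt files land in the
           exclusion report", {
  root <- file.path(tempdir(), "folder_scan")
  unlink(root, recursive = TRUE)
  for (cl in c("classa", "classb")) {
    dir.create(file.path(root, cl), recursive = TRUE)
    for (i in 1:3) {
      write_image(flat_image(4, 4, c(i * 10, 50, 200)),
                  file.path(root, cl, sprintf("im%d.png", i)))
    }
  }
  man <- load_image_folder(root)
  expect_equal(nrow(man), 6)
  expect_identical(manifest_classes(man), c("classa", "classb"))
  expect_identical(as.data.frame(man), as.data.frame(load_image_folder(root)))

  # truncate one file: 5 records remain, 1 exclusion entry
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10)),
           file.path(root, "classa", "im2.png"))
  man2 <- load_image_folder(root)
  expect_equal(nrow(man2), 5)
  excl <- manifest_exclusions(man2)
  expect_equal(nrow(excl), 1)
  expect_match(excl$path, "im2\\.png")
})

test_that("augmentation emits originals plus three provenance-tagged variants
           with matching labels", {
  man <- fake_manifest(rep(c("a", "b"), each = 3))
  aug <- augment_dataset(man)
  expect_equal(nrow(aug), 24)                  # 1 + 3 variants per image
  expect_setequal(unique(aug$provenance),
                  c("original", "rotate180", "brightness0.7", "hflip"))
  # labels of variants equal source labels
  for (pv in unique(aug$provenance)) {
    expect_identical(sort(aug$label[aug$provenance == pv]),
                     sort(man$label))
  }
})

test_that("per-class cap truncates variants in deterministic order", {
  man <- fake_manifest(rep("a", 1200))
  aug <- augment_dataset(man, augment_spec(per_class_cap = 4000))
  expect_equal(nrow(aug), 4000)
  counts <- table(aug$provenance)
  expect_equal(unname(counts[c("original", "rotate180", "brightness0.7",
                               "hflip")]),
               c(1200L, 1200L, 1200L, 400L), ignore_attr = TRUE)
  # deterministic: same call, same records
  expect_identical(as.data.frame(aug),
                   as.data.frame(augment_dataset(
                     man, augment_spec(per_class_cap = 4000))))
})

test_that("splits conserve records and follow largest-remainder
           apportionment", {
  # 22,000 records at 90/10 -> 19,800 / 2,200
  big <- fake_manifest(rep(c("a", "b", "c", "d", "e"), each = 4400))
  sp <- split_dataset(big, split_spec(c(0.9, 0, 0.1), seed = 3,
                                      stratified = FALSE))
  expect_equal(nrow(sp$train), 19800)
  expect_equal(nrow(sp$val), 0)
  expect_equal(nrow(sp$test), 2200)
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(big))

  # 10 records at 8:1:1 -> 8 / 1 / 1
  ten <- fake_manifest(rep("x", 10))
  sp10 <- split_dataset(ten, split_spec(c(0.8, 0.1, 0.1), seed = 1,
                                        stratified = FALSE))
  expect_equal(sapply(sp10, nrow), c(train = 8, val = 1, test = 1))

  # disjoint partition
  all_paths <- c(sp10$train$path, sp10$val$path, sp10$test$path)
  expect_setequal(all_paths, ten$path)
  expect_equal(anyDuplicated(all_paths), 0)
})

test_that("stratified 8:1:1 on five classes of 100 gives 80/10/10 per
           class", {
  man <- fake_manifest(rep(letters[1:5], each = 100))
  sp <- split_dataset(man, split_spec(c(0.8, 0.1, 0.1), seed = 7))
  for (cl in letters[1:5]) {
    expect_equal(sum(sp$train$label == cl), 80)
    expect_equal(sum(sp$val$label == cl), 10)
    expect_equal(sum(sp$test$label == cl), 10)
  }
})

test_that("splitting is deterministic given the seed and rejects bad
           ratios", {
  man <- fake_manifest(rep(c("a", "b"), 25))
  s1 <- split_dataset(man, split_spec(seed = 11))
  s2 <- split_dataset(man, split_spec(seed = 11))
  expect_identical(as.data.frame(s1$train), as.data.frame(s2$train))
  expect_error(split_spec(c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("the synthetic generator is byte-deterministic, balanced, and
           greener than red on healthy leaves", {
  d1 <- file.path(tempdir(), "synth_det1")
  d2 <- file.path(tempdir(), "synth_det2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_synthetic_dataset(d1, n_per_class = 2,
                                   image_size = c(24, 24), seed = 5)
  m2 <- generate_synthetic_dataset(d2, n_per_class = 2,
                                   image_size = c(24, 24), seed = 5)
  expect_equal(nrow(m1), 10)
  expect_equal(unname(table(m1$label)), rep(2L, 5), ignore_attr = TRUE)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", 1e6),
                     readBin(m2$path[i], "raw", 1e6))
  }

  healthy <- m1$path[m1$label == "healthy"]
  for (fp in healthy) {
    img <- read_image(fp)
    expect_gt(mean(img[, , 2]), mean(img[, , 1]))   # green > red
  }
})

test_that("synthetic classes are separable by channel means alone", {
  dir <- tiny_dataset_dir(n_per_class = 50, size = 32, seed = 77)
  man <- load_image_folder(dir, validate = FALSE)
  feats <- t(vapply(man$path, function(fp) {
    img <- read_image(fp)
    c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
  }, numeric(3)))
  labels <- man$label
  train_ix <- unlist(lapply(split(seq_along(labels), labels), head, 25))
  test_ix <- setdiff(seq_along(labels), train_ix)
  centroids <- do.call(rbind, lapply(split(as.data.frame(feats[train_ix, ]),
                                           labels[train_ix]), colMeans))
  pred <- rownames(centroids)[apply(feats[test_ix, ], 1, function(v) {
    which.min(colSums((t(centroids) - v)^2))
  })]
  acc <- mean(pred == labels[test_ix])
  expect_gt(acc, 0.4)   # chance is 0.2 over five balanced classes
})
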