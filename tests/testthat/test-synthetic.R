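test_that("spec validation rejects impossible geometry and bad noise rates", {
  expect_error(synthetic_spec(n_informative = 2, n_classes = 5),
               "vertices")
  expect_error(synthetic_spec(class_sep = 0), "positive")
  expect_error(synthetic_spec(class_sep = -1), "positive")
  expect_error(synthetic_spec(n_informative = 30, n_features = 20),
               "exceed")
  expect_error(synthetic_spec(mislabel_rate = 0.6), "mislabel_rate")
  # study-grid corners are all accepted
  for (args in list(list(n_features = 256, n_informative = 8, n_classes = 2),
                    list(n_features = 4096, n_informative = 256, n_classes = 10),
                    list(n_features = 784, n_informative = 32, n_classes = 10))) {
    expect_s3_class(do.call(synthetic_spec, args), "mcse_spec")
  }
})

test_that("generation is deterministic and balanced to within one sample", {
  spec <- tiny_spec(n_samples = 601)
  d1 <- generate_hypercube_dataset(spec)
  d2 <- generate_hypercube_dataset(spec)
  expect_identical(d1, d2)
  counts <- table(d1$label)
  expect_length(counts, spec$n_classes)
  expect_lte(max(counts) - min(counts), 1)
  expect_false(anyNA(d1))
  expect_true(all(is.finite(feature_matrix(d1))))
  # a different seed moves the data
  d3 <- generate_hypercube_dataset(tiny_spec(n_samples = 601, seed = 43))
  expect_false(identical(d1$f1, d3$f1))
})

test_that("class centroids sit on hypercube vertices class_sep apart", {
  # oracle: empirical class means at large n, tolerance O(1/sqrt(n))
  sep <- 2.5
  spec <- synthetic_spec(n_features = 6, n_informative = 3, n_classes = 8,
                         class_sep = sep, n_samples = 16000, seed = 7)
  d <- generate_hypercube_dataset(spec)
  x <- feature_matrix(d)[, 1:3]
  centroids <- t(sapply(0:7, function(k) colMeans(x[d$label == k, ])))
  tol <- 4 / sqrt(2000) # 4 sd of the mean per coordinate
  # each centroid is a vertex: coordinates near 0 or sep
  expect_true(all(abs(centroids - round(centroids / sep) * sep) < tol))
  # all 8 vertices of the 3-cube are used exactly once (distinctness)
  verts <- round(centroids / sep)
  expect_equal(nrow(unique(verts)), 8)
  # classes whose vertices differ in exactly one coordinate have centroids
  # exactly class_sep apart (Euclidean), verified from empirical means
  for (a in 1:7) for (b in (a + 1):8) {
    if (sum(verts[a, ] != verts[b, ]) == 1) {
      dist_ab <- sqrt(sum((centroids[a, ] - centroids[b, ])^2))
      expect_lt(abs(dist_ab - sep), 3 * tol)
    }
  }
  # noise dimensions are class-independent standard gaussians
  noise_means <- sapply(4:6, function(j) abs(mean(x0 <- feature_matrix(d)[, j])))
  expect_true(all(noise_means < tol))
})

test_that("mislabel corrupts the stated fraction with never-original labels", {
  d <- generate_hypercube_dataset(tiny_spec())
  expect_identical(mislabel(d, 0), d) # rate 0 is the identity

  big <- generate_hypercube_dataset(tiny_spec(n_samples = 10000))
  m <- mislabel(big, 0.5, seed = 3)
  changed <- sum(m$label != m$true_label)
  # oracle: direct disagreement count within 3 binomial sd of the rate
  expect_lt(abs(changed - 5000), 3 * sqrt(10000 * 0.25))
  expect_identical(m$true_label, big$true_label)
  # replacements are always a *different* class
  expect_true(all(m$label[m$label != m$true_label] !=
                  m$true_label[m$label != m$true_label]))
  expect_error(mislabel(big, 0.7), "rate")
  expect_error(mislabel(big, -0.1), "rate")
  # the full study grid of rates is accepted
  for (r in c(0.001, 0.01, 0.02, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50))
    expect_s3_class(mislabel(big, r, seed = 1), "data.frame")
})

test_that("mislabel_rate in the spec flows through generation", {
  d <- generate_hypercube_dataset(tiny_spec(n_samples = 4000,
                                            mislabel_rate = 0.2))
  frac <- mean(d$label != d$true_label)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
})

test_that("CSV round-trip reproduces a dataset bitwise", {
  d <- generate_hypercube_dataset(tiny_spec(n_samples = 40, n_features = 5,
                                            n_informative = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(d, path)
  back <- load_csv_dataset(path, has_labels = TRUE)
  expect_identical(feature_matrix(back), feature_matrix(d))
  expect_identical(back$label, as.integer(d$label))
})

test_that("CSV loading validates structure", {
  p <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("a,b,c", "1,2,3", "4,5,6", "7,8,9", "0,1,2"), p)
  m <- load_csv_dataset(p)
  expect_equal(dim(feature_matrix(m)), c(4, 3))

  writeLines(c("a,b,c", "1,2,3", "4,5"), p) # ragged row
  expect_error(load_csv_dataset(p), "malformed|parsing")

  writeLines(c("a,b,c", "1,x,3", "4,5,6"), p) # non-numeric cell
  expect_error(load_csv_dataset(p), "non-numeric|malformed")

  writeLines(c("a,b,y", "1,2,7", "4,5,7", "2,1,7"), p) # constant labels
  expect_error(load_csv_dataset(p, has_labels = TRUE), "fewer than 2 classes")

  # labels re-indexed to 0..K-1 in sorted order
  writeLines(c("a,b,y", "1,2,5", "4,5,9", "2,1,5", "3,3,7"), p)
  lab <- load_csv_dataset(p, has_labels = TRUE)
  expect_identical(lab$label, c(0L, 2L, 0L, 1L))
})

test_that("classifier AUC is non-decreasing in class separation", {
  # paired seeds at class_sep 0 (no signal), 1, 5 (nearly separable)
  aucs <- sapply(c(0.001, 1, 5), function(sep) {
    spec <- tiny_spec(class_sep = sep, n_samples = 700, seed = 5)
    d <- generate_hypercube_dataset(spec)
    train_classifier(d[1:400, ], d[401:700, ], tiny_net(),
                     fast_config(epochs = 25))
  })
  expect_lt(abs(aucs[1] - 0.5), 0.08) # sep ~ 0: chance level
  expect_true(all(diff(aucs) > -0.02)) # monotone within tolerance
  expect_gt(aucs[3], 0.95)
})
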