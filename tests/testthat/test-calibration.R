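test_that("cosine distance satisfies its closed-form identities", {
  expect_equal(cosine_distance(c(2, 3), c(2, 3)), 0, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2, tolerance = 1e-12)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), class = "zero_norm")
  expect_error(cosine_distance(c(1, 2), c(1, 2, 3)), class = "length_mismatch")
})

test_that("Pearson matches hand values and affine invariance", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1.4, -0.2, 3.3, 0.8)
  expect_equal(pearson_r(x, x), 1)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    r <- pearson_r(a, b)
    expect_equal(pearson_r(2.5 * a + 7, b), r, tolerance = 1e-12)
    expect_equal(pearson_r(a, -3 * b + 1), -r, tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), class = "constant_vector")
})

test_that("k-means++ init is deterministic and spreads over separated blobs", {
  X <- four_blobs(50, 0.3, data_seed = 3)
  expect_identical(kmeans_pp_init(X, 4, seed = 9), kmeans_pp_init(X, 4, seed = 9))
  expect_identical(nrow(kmeans_pp_init(X, 1, seed = 1)), 1L)
  blob_of <- rep(1:4, each = 50)
  hits <- sapply(1:50, function(s) {
    C <- kmeans_pp_init(X, 4, seed = s)
    picked <- apply(C, 1, function(c0)
      blob_of[which.min(apply(X, 1, function(x) sum((x - c0)^2)))])
    length(unique(picked)) == 4
  })
  expect_gte(mean(hits), 0.9)
  expect_error(kmeans_pp_init(X[1:3, ], 4, seed = 1), class = "too_many_clusters")
})

test_that("cosine k-means separates directional blobs with a monotone objective", {
  X <- rbind(matrix(rnorm(100, 5, 0.2), ncol = 2),
             matrix(rnorm(100, -5, 0.2), ncol = 2))
  km <- kmeans_cosine(X, 2, seed = 2)
  truth <- rep(1:2, each = 50)
  purity <- max(mean(km$assignments == truth), mean(km$assignments == 3 - truth))
  expect_equal(purity, 1)
  expect_true(all(diff(km$objective_trace) <= 1e-10))
  # k = n: every point its own centroid, objective 0
  small <- matrix(c(1, 0, 0, 1, 2, 3, -1, 4), ncol = 2, byrow = TRUE)
  kmn <- kmeans_cosine(small, 4, seed = 1)
  expect_lt(min(kmn$objective_trace[length(kmn$objective_trace)]), 1e-10)
})

test_that("the Gaussianity check accepts one Gaussian and rejects gross bimodality", {
  acc <- sapply(1:40, function(s) {
    set.seed(s)
    gaussian_check(matrix(rnorm(1000), ncol = 2) + 5, seed = s)
  })
  expect_gte(mean(acc), 0.85)
  rej <- sapply(1:40, function(s) {
    set.seed(s)
    X <- rbind(matrix(rnorm(500, 0, 1), ncol = 2),
               matrix(rnorm(500, 10, 1), ncol = 2)) + 20
    gaussian_check(X, seed = s)
  })
  expect_lte(mean(rej), 0.05)
  expect_true(gaussian_check(matrix(rnorm(10), ncol = 2)))  # < 8 members
})

test_that("G-means finds one cluster on one Gaussian and four on four blobs", {
  one <- sapply(1:40, function(s) {
    set.seed(s)
    nrow(gmeans(matrix(rnorm(1000), ncol = 2) + 5, seed = s)$centroids)
  })
  expect_gte(mean(one == 1), 0.85)
  four <- sapply(1:20, function(s)
    nrow(gmeans(four_blobs(100, 0.5, data_seed = 1000 + s), seed = s)$centroids))
  expect_gt(mean(four == 4), 0.5)
  expect_true(all(four <= 16))
  # determinism under a fixed seed
  X <- four_blobs(40, 0.5, data_seed = 2)
  g1 <- gmeans(X, seed = 5); g2 <- gmeans(X, seed = 5)
  expect_identical(g1$centroids, g2$centroids)
  expect_identical(g1$sigma, g2$sigma)
})

test_that("profiles build one entry per subject and serialize losslessly", {
  ft <- separable_features(8, n_subjects = 2, seed = 2)
  prof <- build_profiles(ft, seed = 3)
  expect_s3_class(prof, "subject_profiles")
  expect_length(prof$profiles, 2)
  expect_setequal(vapply(prof$profiles, `[[`, "", "subject_id"),
                  unique(ft$subject_id))
  ks <- vapply(prof$profiles, function(p) nrow(p$centroids), 0L)
  expect_true(all(ks >= 1 & ks <= 16))
  path <- withr::local_tempfile(fileext = ".json")
  write_profiles(prof, path)
  back <- read_profiles(path)
  for (i in seq_along(prof$profiles)) {
    expect_equal(back$profiles[[i]]$centroids, prof$profiles[[i]]$centroids,
                 tolerance = 1e-14, ignore_attr = TRUE)
    expect_equal(back$profiles[[i]]$sigma, prof$profiles[[i]]$sigma,
                 tolerance = 1e-14, ignore_attr = TRUE)
  }
  expect_equal(back$center, prof$center, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("centroid matching maximizes |r| with a lexicographic tie rule", {
  mk_prof <- function(ids, cents) {
    structure(list(
      profiles = lapply(seq_along(ids), function(i)
        list(subject_id = ids[i], centroids = cents[[i]],
             sigma = matrix(1, nrow(cents[[i]]), ncol(cents[[i]])),
             member_count = rep(2L, nrow(cents[[i]])))),
      center = rep(0, 4), scale = rep(1, 4),
      feature_names = paste0("f", 1:4)), class = "subject_profiles")
  }
  v <- c(1, 3, 2, 4)
  prof <- mk_prof(c("A", "B"),
                  list(matrix(c(2, 4, 1, 3), nrow = 1),       # r = 0.6
                       rbind(v, c(0, 0, 1, 0))))              # exact match
  m <- match_centroid(v, prof)
  expect_identical(m$subject_id, "B")
  expect_equal(m$r, 1)
  # anticorrelated centroid wins on |r| over weak positives
  prof2 <- mk_prof(c("A", "B"), list(matrix(c(2, 4, 1, 3), nrow = 1),
                                     matrix(-v + 10, nrow = 1)))
  m2 <- match_centroid(v, prof2)
  expect_identical(m2$subject_id, "B")
  expect_equal(abs(m2$r), 1)
  # exact tie: same centroid under two subjects -> lexicographically first
  prof3 <- mk_prof(c("B", "A"), list(matrix(v + 1, nrow = 1),
                                     matrix(v + 1, nrow = 1)))
  expect_identical(match_centroid(v, prof3)$subject_id, "A")
  empty <- mk_prof(character(0), list())
  expect_error(match_centroid(v, empty), class = "empty_profiles")
})

test_that("literal calibration reproduces the printed normalized-translation arithmetic", {
  cal <- calibrate_vector(c(3, 4), c(0, 0), c(1, 1), mode = "literal")
  expect_equal(cal$d, 5)
  expect_equal(cal$dn, c(5, 5))
  expect_equal(cal$v_new, c(-2, -1))
})

test_that("directional calibration lands on the SD shell and contracts from afar", {
  C <- c(1, 2, 3); sig <- c(0.5, 0.5, 0.5)
  expect_equal(calibrate_vector(C, C, sig)$v_new, C)
  v <- C + 2 * sig
  cal <- calibrate_vector(v, C, sig)
  expect_equal(cal$v_new, C + sig * (2 * sig) / sqrt(sum((2 * sig)^2)),
               tolerance = 1e-12)
  expect_true(all(abs(cal$v_new - C) < abs(v - C)))
  # isotropic sigma: exact idempotence in distance (SD shell is fixed)
  set.seed(8)
  for (i in 1:20) {
    C <- rnorm(6); v <- rnorm(6, 0, 3); s0 <- runif(1, 0.2, 1.5)
    v1 <- calibrate_vector(v, C, rep(s0, 6))$v_new
    v2 <- calibrate_vector(v1, C, rep(s0, 6))$v_new
    expect_equal(sqrt(sum((v2 - C)^2)), sqrt(sum((v1 - C)^2)), tolerance = 1e-10)
    expect_equal(sqrt(sum((v1 - C)^2)), s0, tolerance = 1e-10)
  }
  # anisotropic sigma: calibrated distance bounded by the SD range
  for (i in 1:20) {
    C <- rnorm(6); v <- rnorm(6, 0, 3); sig <- runif(6, 0.2, 1.5)
    d1 <- sqrt(sum((calibrate_vector(v, C, sig)$v_new - C)^2))
    expect_gte(d1, min(sig) - 1e-12)
    expect_lte(d1, max(sig) + 1e-12)
  }
  # whenever d > ||sigma||, the translation strictly reduces the distance
  for (i in 1:20) {
    C <- rnorm(6); sig <- runif(6, 0.2, 1.5)
    u <- rnorm(6); u <- u / sqrt(sum(u^2))
    v <- C + u * (sqrt(sum(sig^2)) * runif(1, 1.01, 3))
    d0 <- sqrt(sum((v - C)^2))
    d1 <- sqrt(sum((calibrate_vector(v, C, sig)$v_new - C)^2))
    expect_lt(d1, d0)
  }
})

test_that("feature-table calibration is per-row, audited and mismatch-safe", {
  ft <- separable_features(8, n_subjects = 3, seed = 4)
  prof <- build_profiles(ft, seed = 5)
  test_ft <- separable_features(4, n_subjects = 2, seed = 6)
  test_ft$subject_id <- paste0("X", test_ft$subject_id)
  cal <- calibrate_features(test_ft, prof)
  expect_identical(dim(cal$features), dim(test_ft))
  expect_identical(nrow(cal$audit), nrow(test_ft))
  expect_true(all(abs(cal$audit$r) <= 1))
  expect_true(all(cal$audit$d >= 0))
  # identical vectors calibrate identically
  dup <- test_ft[c(1, 1), ]
  cal2 <- calibrate_features(dup, prof)
  expect_equal(cal2$features[1, ], cal2$features[2, ], ignore_attr = TRUE)
  # empty input -> empty output
  cal0 <- calibrate_features(test_ft[0, ], prof)
  expect_identical(nrow(cal0$features), 0L)
  bad <- test_ft; names(bad)[3] <- "not_a_feature"
  expect_error(calibrate_features(bad, prof), class = "feature_mismatch")
})

test_that("calibration moves shifted vectors closer to their matched centroids", {
  ft <- separable_features(8, n_subjects = 3, seed = 7)
  prof <- build_profiles(ft, seed = 8)
  test_ft <- separable_features(4, n_subjects = 2, seed = 9)
  fcols <- prof$feature_names
  test_ft[fcols] <- sweep(test_ft[fcols], 2, 1.15, `*`)  # affine disturbance
  cal <- calibrate_features(test_ft, prof)
  # distance from the calibrated vector to its matched centroid vs before
  d_after <- sapply(seq_len(nrow(test_ft)), function(i) {
    z <- (as.numeric(cal$features[i, fcols]) - prof$center) / prof$scale
    m <- match_centroid((as.numeric(test_ft[i, fcols]) - prof$center) / prof$scale, prof)
    sqrt(sum((z - m$centroid)^2))
  })
  expect_gt(mean(cal$audit$d > d_after), 0.8)
})
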