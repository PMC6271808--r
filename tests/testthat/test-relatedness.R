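test_that("Nei-Li similarity counts shared and private bands", {
  expect_equal(nei_li_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(nei_li_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(nei_li_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(nei_li_similarity(c(0, 0), c(0, 0)), 1)  # all-zero convention
  expect_error(nei_li_similarity(c(1, 0), c(1, 0, 1)), "length")
})

test_that("similarity matrix equals the pairwise oracle and is order-invariant", {
  m <- random_band_matrix(4, 6, seed = 5)
  expect_warning(sm <- similarity_matrix(m), NA)
  for (i in 1:4) for (j in 1:4)
    expect_equal(sm[i, j],
                 nei_li_similarity(unclass(m)[i, ], unclass(m)[j, ]))
  expect_equal(unname(diag(sm)), rep(1, 4))
  expect_equal(unclass(sm), t(unclass(sm)), tolerance = 1e-12)

  # band-order invariance
  set.seed(6)
  perm <- sample(ncol(m))
  m2 <- band_matrix(unclass(m)[, perm], primers = unname(primers(m))[perm],
                    band_ids = bands(m)[perm])
  expect_equal(unclass(similarity_matrix(m2)), unclass(sm))

  # duplicated accessions are maximally similar
  v <- unclass(m); v[2, ] <- v[1, ]
  m3 <- band_matrix(v, primers = unname(primers(m)))
  expect_equal(similarity_matrix(m3)[1, 2], 1)
})

test_that("UPGMA reproduces the hand-worked example and breaks ties deterministically", {
  d <- matrix(8, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  d[1, 2] <- d[2, 1] <- 2; diag(d) <- 0
  tr <- upgma(d)
  expect_equal(tr$heights, c(1, 4))
  expect_setequal(.subset2(tr, "labels")[-tr$merge[1, ]], c("A", "B"))

  # all equal distances: caterpillar with equal heights, stable across runs
  de <- matrix(6, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  t1 <- upgma(de); t2 <- upgma(de)
  expect_identical(t1, t2)
  expect_equal(t1$heights, rep(3, 3))
})

test_that("UPGMA recovers generating ultrametric trees and is ultrametric itself", {
  for (seed in 1:5) {
    set.seed(seed)
    # build a random ultrametric via a random tree's cophenetic distances
    m <- random_band_matrix(6, 40, seed = seed + 10)
    ref <- upgma(genetic_distance(similarity_matrix(m)))
    cd <- cophenetic_matrix(ref)
    rec <- upgma(cd)
    expect_equal(cophenetic_matrix(rec)[rownames(cd), colnames(cd)], cd,
                 tolerance = 1e-12)
    # heights nondecreasing from leaves to root
    expect_true(all(diff(ref$heights) >= -1e-12))
  }
})

test_that("UPGMA agrees with average-linkage hclust where ties are absent", {
  set.seed(21)
  x <- matrix(rnorm(7 * 5), 7)
  rownames(x) <- paste0("t", 1:7)
  d <- as.matrix(dist(x))
  tr <- upgma(d)
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(sort(2 * tr$heights), sort(hc$height), tolerance = 1e-12)
  expect_equal(cophenetic_matrix(tr)[rownames(d), rownames(d)],
               as.matrix(cophenetic(hc))[rownames(d), rownames(d)],
               tolerance = 1e-12)
})

test_that("bootstrap supports are seeded, bounded, and certain for perfect splits", {
  # every band splits {A,B} vs {C,D}: resampling cannot change the clades
  v <- rbind(A = rep(1, 10), B = rep(1, 10), C = rep(0, 10), D = rep(0, 10))
  m <- band_matrix(v, primers = rep("P", 10))
  tr <- bootstrap_supports(m, n_reps = 25, seed = 1)
  expect_equal(tr$supports, rep(100, 3))

  m2 <- random_band_matrix(6, 25, seed = 2)
  a <- bootstrap_supports(m2, n_reps = 30, seed = 9)
  b <- bootstrap_supports(m2, n_reps = 30, seed = 9)
  expect_identical(a$supports, b$supports)
  expect_true(all(a$supports >= 0 & a$supports <= 100))

  one <- bootstrap_supports(m2, n_reps = 1, seed = 3)
  expect_true(all(one$supports %in% c(0, 100)))
  expect_error(bootstrap_supports(m2, n_reps = 0), ">= 1")
})

test_that("PCoA embeds simple and planar configurations exactly", {
  # two points at distance 2 -> single axis at +/-1, 100% variance
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(p2 <- pcoa(d2, n_axes = 3), "truncating")
  expect_equal(sort(as.vector(p2$coordinates)), c(-1, 1), tolerance = 1e-9)
  expect_equal(sum(p2$percent_variance), 100, tolerance = 1e-9)

  # Euclidean distances from known planar points are reconstructed
  set.seed(8)
  pts <- matrix(rnorm(12 * 2), 12)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:12)
  fit <- pcoa(d, n_axes = 2)
  drec <- as.matrix(dist(fit$coordinates))
  expect_equal(unname(drec), unname(d), tolerance = 1e-9)

  # duplicated point -> coincident coordinates
  d3 <- as.matrix(dist(rbind(pts, pts[1, ])))
  fit3 <- pcoa(d3, n_axes = 2)
  expect_equal(fit3$coordinates[13, ], fit3$coordinates[1, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("great-circle distances hit the textbook anchors", {
  rec <- data.frame(code = c("a", "b", "c", "d"),
                    latitude = c(30, 30, 31, -30),
                    longitude = c(103, 103, 103, -77),
                    stringsAsFactors = FALSE)
  dm <- geographic_distance_matrix(rec)
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["a", "c"], 2 * pi * 6371 / 360, tolerance = 1e-3)
  expect_equal(dm["a", "d"], pi * 6371, tolerance = 1e-3)  # antipodal

  rec$latitude[2] <- NA
  dm2 <- geographic_distance_matrix(rec)
  expect_equal(attr(dm2, "excluded"), "b")
  expect_error(geographic_distance_matrix(rec[1:2, ]), "at least 2")
})

test_that("Mantel r, determinism, and label-permutation symmetry behave", {
  m <- random_band_matrix(8, 30, seed = 4)
  gd <- genetic_distance(similarity_matrix(m))
  r1 <- mantel(gd, 2 * gd, n_perm = 99, seed = 1)
  expect_equal(r1$r, 1)
  expect_lte(r1$p, 0.05)

  set.seed(12)
  other <- as.matrix(dist(matrix(rnorm(16), 8)))
  dimnames(other) <- dimnames(gd)
  a <- mantel(gd, other, n_perm = 199, seed = 7)
  b <- mantel(gd, other, n_perm = 199, seed = 7)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 200)

  # same relabeling applied to both matrices leaves r unchanged
  p <- sample(8)
  ra <- mantel(gd[p, p], other[p, p], n_perm = 9, seed = 1)$r
  expect_equal(ra, a$r, tolerance = 1e-12)

  expect_error(mantel(gd * 0, other, n_perm = 9), "zero variance")
})

test_that("sampled Mantel p matches exhaustive enumeration on 4 labels", {
  set.seed(30)
  d1 <- as.matrix(dist(matrix(rnorm(8), 4)))
  d2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(d1) <- dimnames(d2) <- list(letters[1:4], letters[1:4])
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  perms <- all_perms(4)
  r_all <- vapply(perms, function(p) cor(d1[lt], d2[p, p][lt]), 0)
  p_exact <- mean(r_all >= r_obs - 1e-12)
  res <- mantel(d1, d2, n_perm = 4999, seed = 2)
  # binomial error around the exact permutation tail
  se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(res$p - p_exact), 4 * se + 2 / 5000)
  expect_equal(res$r, r_obs, tolerance = 1e-12)
})

test_that("cross-check: our Mantel r equals vegan's", {
  m <- random_band_matrix(9, 40, seed = 13)
  gd <- genetic_distance(similarity_matrix(m))
  set.seed(14)
  geo <- as.matrix(dist(matrix(rnorm(18), 9)))
  dimnames(geo) <- dimnames(gd)
  ours <- mantel(gd, geo, n_perm = 99, seed = 3)
  veg <- vegan::mantel(as.dist(gd), as.dist(geo), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
})
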