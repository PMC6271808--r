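test_that("Shannon partition arithmetic matches hand-computed cases", {
  # two groups fixed for alternative bands: H_zone = 0, H_W = ln 2 per band
  v <- rbind(matrix(1L, 3, 6), matrix(0L, 3, 6))
  rownames(v) <- paste0("a", 1:6)
  m <- band_matrix(v, primers = rep(c("P1", "P2"), each = 3))
  g <- setNames(rep(c("g1", "g2"), each = 3), rownames(v))
  sp <- shannon_partition(m, g)
  expect_equal(unname(sp$h_zone), c(0, 0))
  expect_equal(sp$h_w, log(2))
  expect_equal(sp$h_a, 0)
  expect_equal(sp$inter_fraction, 1)
  expect_equal(sp$intra_fraction + sp$inter_fraction, 1)

  # groups of identical composition: H_A = H_W, inter fraction 0
  m2 <- random_band_matrix(4, 12, seed = 17)
  v2 <- rbind(unclass(m2), unclass(m2))
  rownames(v2) <- paste0("a", 1:8)
  m2x <- band_matrix(v2, primers = unname(primers(m2)))
  g2 <- setNames(rep(c("g1", "g2"), each = 4), rownames(v2))
  sp2 <- shannon_partition(m2x, g2)
  expect_equal(sp2$h_a, sp2$h_w, tolerance = 1e-12)
  expect_equal(sp2$inter_fraction, 0, tolerance = 1e-12)
})

test_that("Shannon partition is invariant to band order and group label names", {
  sim <- simulate_band_matrix(sim_config(seed = 23))
  m <- sim$matrix
  g <- setNames(sim$records$group, sim$records$code)
  sp <- shannon_partition(m, g)
  set.seed(23)
  perm <- sample(ncol(m))
  mp <- band_matrix(unclass(m)[, perm], primers = unname(primers(m))[perm],
                    band_ids = bands(m)[perm])
  spp <- shannon_partition(mp, g)
  expect_equal(spp$h_a, sp$h_a)
  expect_equal(spp$h_w, sp$h_w)
  g2 <- setNames(paste0("grp_", g), names(g))
  sp2 <- shannon_partition(m, g2)
  expect_equal(unname(sort(sp2$h_zone)), unname(sort(sp$h_zone)))
  expect_equal(sp2$h_a, sp$h_a)
})

test_that("pooling concavity holds on simulated datasets", {
  for (seed in 1:8) {
    sim <- simulate_band_matrix(sim_config(seed = seed,
                                           differentiation_F = 0.05 * (seed %% 3)))
    g <- setNames(sim$records$group, sim$records$code)
    sp <- shannon_partition(sim$matrix, g)
    expect_lte(sp$h_a, sp$h_w + 1e-12)
    gp <- gst_partition(sim$matrix, g)
    expect_lte(gp$h_s_bar, gp$h_t + 1e-12)
    expect_gte(gp$g_st, -1e-12)
    expect_true(all(gp$p_hat >= 0 & gp$p_hat <= 1))
  }
})

test_that("group difference test flags constructed extremes and is deterministic", {
  # group A fixed everywhere, group B maximally diverse at every band
  set.seed(31)
  nb <- 40
  a_rows <- matrix(1L, 6, nb)
  b_rows <- matrix(rep(c(0L, 1L), 3), 6, nb)  # f = 0.5 per band in B
  v <- rbind(a_rows, b_rows)
  rownames(v) <- paste0("x", 1:12)
  m <- band_matrix(v, primers = rep("P", nb))
  g <- setNames(rep(c("A", "B"), each = 6), rownames(v))
  gd <- group_difference_test(m, g, n_perm = 499, seed = 5)
  expect_lte(gd$pairs$p[1], 0.01)
  expect_false(gd$letters$alpha_0.01["A"] == gd$letters$alpha_0.01["B"])

  gd2 <- group_difference_test(m, g, n_perm = 499, seed = 5)
  expect_identical(gd2$letters, gd$letters)

  # identical groups share one letter
  v2 <- rbind(unclass(random_band_matrix(4, 30, seed = 9)),
              unclass(random_band_matrix(4, 30, seed = 9)))
  rownames(v2) <- paste0("y", 1:8)
  m2 <- band_matrix(v2, primers = rep("P", 30))
  g2 <- setNames(rep(c("A", "B"), each = 4), rownames(v2))
  gd3 <- group_difference_test(m2, g2, n_perm = 199, seed = 1)
  expect_equal(unname(gd3$letters$alpha_0.05["A"]),
               unname(gd3$letters$alpha_0.05["B"]))
})

test_that("dominant allele frequency solves the absence quadratic", {
  expect_equal(dominant_allele_freq(0.25, 0)$p, 0.5)
  expect_equal(dominant_allele_freq(1, 0)$p, 0)
  expect_equal(dominant_allele_freq(1, 0.7)$p, 0)
  expect_equal(dominant_allele_freq(0, 0.3)$p, 1)

  # numeric root-scan oracle at f = 0.2, absence 0.4
  f <- 0.2; A <- 0.4
  oracle <- uniroot(function(p) (1 - p)^2 + f * p * (1 - p) - A,
                    c(0, 1), tol = 1e-12)$root
  expect_equal(dominant_allele_freq(A, f)$p, oracle, tolerance = 1e-10)

  # residual is zero across the parameter grid
  for (f in c(0, 0.2, 0.5, 0.9, 1)) {
    A <- seq(0, 1, by = 0.1)
    p <- dominant_allele_freq(A, f)$p
    expect_equal((1 - p)^2 + f * p * (1 - p), A, tolerance = 1e-9)
  }
  expect_error(dominant_allele_freq(1.4, 0), "\\[0, 1\\]")
})

test_that("G_ST partition arithmetic reproduces supplied heterozygosities", {
  gs <- gst_summary(c(0.3621, 0.3696, 0.3720, 0.3614), 0.3841)
  expect_equal(gs$h_s_bar, 0.366275, tolerance = 1e-9)
  expect_equal(gs$ratio, 0.9536, tolerance = 5e-4)
  expect_equal(gs$g_st, 0.0464, tolerance = 5e-4)

  # identical group frequencies everywhere -> G_ST = 0
  v <- unclass(random_band_matrix(5, 20, seed = 3))
  v2 <- rbind(v, v); rownames(v2) <- paste0("a", 1:10)
  m <- band_matrix(v2, primers = rep("P", 20))
  g <- setNames(rep(c("g1", "g2"), each = 5), rownames(v2))
  gp <- gst_partition(m, g)
  expect_equal(gp$g_st, 0, tolerance = 1e-12)
})

test_that("G_ST rises monotonically with simulated differentiation", {
  med_gst <- sapply(c(0, 0.05, 0.1, 0.2), function(FF) {
    median(sapply(1:10, function(s) {
      sim <- simulate_band_matrix(sim_config(differentiation_F = FF),
                                  seed = 1000 + s)
      g <- setNames(sim$records$group, sim$records$code)
      gst_partition(sim$matrix, g)$g_st
    }))
  })
  expect_true(all(diff(med_gst) > 0))
})
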