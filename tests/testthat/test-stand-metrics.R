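test_that("per-tree basal area follows the cross-section formula", {
  expect_equal(tree_basal_area(20), pi * 0.1^2)
  expect_error(tree_basal_area(0), "positive")
  set.seed(1)
  d <- runif(50, 5, 60)
  expect_equal(sum(tree_basal_area(d)),
               sum(sapply(d, function(x) pi * (x / 200)^2)))
})

test_that("quadratic mean diameter matches independent summation", {
  expect_equal(compute_qmd(10), 10)
  expect_equal(compute_qmd(c(3, 4)), sqrt(12.5))
  expect_error(compute_qmd(numeric(0)), "empty")
  set.seed(2)
  d <- runif(1000, 5, 60)
  acc <- 0
  for (x in d) acc <- acc + x^2
  expect_equal(compute_qmd(d), sqrt(acc / 1000))
})

test_that("BAL uses strictly greater diameters and matches the loop oracle", {
  expect_equal(compute_bal(10, 0.1), 0)
  expect_equal(compute_bal(c(10, 20), 0.1), c(pi * 0.01 / 0.1, 0))
  expect_equal(compute_bal(numeric(0), 0.1), numeric(0))
  # ties contribute nothing to each other
  expect_equal(compute_bal(c(15, 15, 10), 0.1)[1:2], c(0, 0))
  set.seed(3)
  for (rep in 1:10) {
    d <- sample(round(runif(50, 5, 45), 1))  # rounded to force ties
    a <- runif(1, 0.05, 0.3)
    expect_equal(compute_bal(d, a), bal_oracle(d, a))
  }
})

test_that("diversity indices: bounds, pure-stand zero, scale invariance", {
  expect_equal(simpson_index(c(A = 30)), 0)
  expect_equal(shannon_index(c(A = 10)), 0)
  expect_equal(simpson_index(c(A = 50, B = 50)), 0.5)
  expect_equal(shannon_index(c(A = 1, B = 1)), log(2))
  expect_error(simpson_index(c(A = 0, B = 0)), "positive total")
  set.seed(4)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    counts <- setNames(sample(1:50, k), letters[1:k])
    p <- counts / sum(counts)
    expect_equal(simpson_index(counts), 1 - sum(p^2))
    expect_gte(simpson_index(counts), 0)
    expect_lte(simpson_index(counts), 1 - 1 / k)
    expect_gte(shannon_index(counts), 0)
    expect_lte(shannon_index(counts), log(k) + 1e-12)
    # doubling every count changes nothing
    expect_equal(simpson_index(2 * counts), simpson_index(counts))
    expect_equal(shannon_index(2 * counts), shannon_index(counts))
  }
  # uniform k species maximizes Shannon at log(k)
  expect_equal(shannon_index(c(a = 7, b = 7, c = 7)), log(3))
})

test_that("diversity indices agree with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (rep in 1:5) {
    counts <- sample(1:40, 4)
    expect_equal(simpson_index(counts),
                 unname(vegan::diversity(counts, index = "simpson")))
    expect_equal(shannon_index(counts),
                 unname(vegan::diversity(counts, index = "shannon")))
  }
})

test_that("Stage transforms convert degrees and guard the log domain", {
  st <- stage_transforms(0, exp(1))
  expect_equal(st$sie, 0)
  expect_equal(st$cie, 1)
  st90 <- stage_transforms(90, exp(1))
  expect_equal(st90$sie, 1)
  expect_equal(st90$cie, 0, tolerance = 1e-12)
  st47 <- stage_transforms(47, 423.8)
  expect_equal(st47$sie, sin(47 * pi / 180) * log(423.8))
  expect_equal(st47$sie, 4.4240, tolerance = 1e-4)
  expect_error(stage_transforms(10, 1), "elevation")
})

test_that("climate composites match direct arithmetic", {
  expect_equal(de_martonne(0, 5), 0)
  expect_equal(de_martonne(400, 0), 40)
  expect_equal(de_martonne(454.10, -2.94), 64.32, tolerance = 1e-3)
  expect_error(de_martonne(400, -10), "MAT")
  expect_equal(annual_heat_moisture(0, 1000), 10)
  expect_equal(annual_heat_moisture(-2.94, 454.1), 15.55, tolerance = 1e-3)
  expect_error(annual_heat_moisture(0, 0), "MAP")
  # AHM decreases in MAP at fixed MAT
  expect_true(annual_heat_moisture(0, 600) < annual_heat_moisture(0, 400))
})

test_that("dominant height averages per-species maxima", {
  d1 <- data.frame(species = c("Lg", "Lg"), height_m = c(10, 15))
  expect_equal(dominant_height(d1), 15)
  d2 <- data.frame(species = c("Lg", "Lg", "Bp"), height_m = c(10, 8, 20))
  expect_equal(dominant_height(d2), 15)
  set.seed(6)
  sp <- sample(c("a", "b", "c"), 60, replace = TRUE)
  h <- runif(60, 3, 30)
  oracle <- mean(sapply(unique(sp), function(s) max(h[sp == s])))
  expect_equal(dominant_height(data.frame(species = sp, height_m = h)), oracle)
})

test_that("compute_stand_metrics matches a hand-worked two-tree plot", {
  ds <- toy_dataset()
  m <- compute_stand_metrics(ds, "B")  # two Lg trees, D = 8 and 8
  expect_equal(m$qmd_cm, 8)
  expect_equal(m$md_cm, 8)
  expect_equal(m$ba_m2_ha, 2 * pi * 0.04^2 / 0.06)
  expect_equal(m$n_per_ha, 2 / 0.06)
  expect_equal(m$dh_m, 8)           # one species, max height 8
  expect_equal(m$sim, 0)            # pure stand
  expect_equal(m$shi, 0)
  expect_equal(unname(m$bal_by_tree), c(0, 0))  # equal diameters
  expect_equal(m$m_index, 430 / (10 - 3.5))
  st <- stage_transforms(30, 500)
  expect_equal(m$sie, st$sie)

  mA <- compute_stand_metrics(ds, "A")  # three trees, two species
  expect_equal(mA$qmd_cm, sqrt(mean(c(10, 20, 15)^2)))
  expect_gte(mA$qmd_cm, mA$md_cm)
  expect_equal(mA$dh_m, mean(c(15, 12)))  # Lg max 15, Bp max 12
  expect_equal(unname(mA$bal_by_tree),
               bal_oracle(c(10, 20, 15), 0.1))
})

test_that("plot metrics are invariant to tree ordering and QMD >= MD", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    trees <- data.frame(
      plot_id = "A",
      species = sample(c("Lg", "Bp", "Qm"), n, replace = TRUE),
      dbh_cm = runif(n, 5, 50), height_m = runif(n, 4, 30),
      stringsAsFactors = FALSE)
    plots <- data.frame(plot_id = "A", area_ha = 0.1)
    ds <- forest_dataset(trees, plots)
    m <- compute_stand_metrics(ds, "A")
    perm <- sample(n)
    ds2 <- forest_dataset(trees[perm, ], plots)
    m2 <- compute_stand_metrics(ds2, "A")
    for (f in c("qmd_cm", "md_cm", "ba_m2_ha", "dh_m", "sim", "shi")) {
      expect_equal(m[[f]], m2[[f]])
    }
    expect_gte(m$qmd_cm, m$md_cm)
    # total BAL transfer equals the pairwise larger->smaller accumulation
    received <- sum(m$bal_by_tree) * 0.1
    pair_sum <- 0
    d <- trees$dbh_cm
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (d[j] > d[i]) pair_sum <- pair_sum + pi * (d[j] / 200)^2
    }
    expect_equal(received, pair_sum)
  }
})
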