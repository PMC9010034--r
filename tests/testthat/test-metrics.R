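test_that("single-image statistics hit their golden values", {
  expect_equal(mean_value(matrix(c(0, 1, 1, 0), 2, 2)), 0.5)
  expect_equal(mean_value(matrix(0.37, 5, 5)), 0.37)
  expect_equal(std_value(matrix(0.8, 4, 4)), 0)
  expect_equal(std_value(matrix(c(0, 0, 1, 1), 2, 2)), 0.5)  # population sd
  expect_equal(average_gradient(matrix(0.2, 8, 8)), 0)
  # horizontal unit-step ramp: every interior forward difference is (1, 0)
  ramp <- matrix(rep(1:8, each = 4), 4, 8)
  expect_equal(average_gradient(ramp), sqrt(0.5))
  expect_error(average_gradient(matrix(1, 5, 1)), "2 x 2")
})

test_that("entropy follows the binned Shannon formula", {
  expect_equal(entropy(matrix(0.4, 6, 6)), 0)
  half <- matrix(c(rep(0, 32), rep(1, 32)), 8, 8)
  expect_equal(entropy(half), log(2))
  # exactly one value per default bin: maximal entropy ln 256
  uniform <- matrix((0:255 + 0.5) / 256, 16, 16)
  expect_equal(entropy(uniform), log(256))
})

test_that("each metric agrees with its independently coded naive oracle", {
  for (seed in 1:10) {
    m <- rand_img(16, 16, seed)
    m2 <- rand_img(16, 16, seed + 50)
    expect_equal(mean_value(m), sum(rev(as.vector(m))) / 256, tolerance = 1e-12)
    expect_equal(std_value(m), oracle_std(as.vector(m)), tolerance = 1e-10)
    expect_equal(average_gradient(m), oracle_ag(m), tolerance = 1e-12)
    expect_equal(entropy(m), oracle_entropy(as.vector(m)), tolerance = 1e-12)
    expect_equal(rmse(m, m2), oracle_rmse(as.vector(m), as.vector(m2)),
                 tolerance = 1e-12)
  }
  ref <- rand_img(32, 32, 3)
  dist <- pmin(pmax(ref + 0.05 * rand_img(32, 32, 4), 0), 1)
  expect_equal(vif(ref, dist, scales = 2), oracle_vif(ref, dist, scales = 2),
               tolerance = 1e-4)
})

test_that("RMSE identities hold", {
  x <- rand_img(10, 10, 1)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(matrix(0, 4, 4), matrix(0.5, 4, 4)), 0.5)
  expect_error(rmse(x, matrix(0, 3, 3)), "shape")
})

test_that("NMI equals 2 for identical images, approaches 4 for independent ones, stays in [2, 4]", {
  x <- rand_img(16, 16, 9)
  expect_equal(nmi(x, x, x), 2)
  for (seed in 1:50) {
    a <- rand_img(12, 12, seed)
    b <- rand_img(12, 12, seed + 200)
    f <- rand_img(12, 12, seed + 400)
    v <- nmi(a, b, f)
    expect_gte(v, 2); expect_lte(v, 4)
  }
  # independent uniform images at a size where the finite-sample occupancy
  # bias of the 256x256 joint histogram is small
  big1 <- rand_img(512, 512, 1)
  big2 <- rand_img(512, 512, 2)
  expect_gt(nmi(big1, big2, rand_img(512, 512, 3)), 3.9)
})

test_that("VIF is 1 at identity, decays with degradation, vanishes for constants", {
  pc <- phantom_config(ct_size = 64, seed = 4)
  x <- generate_ct_phantom(pc)$values
  expect_equal(vif(x, x), 1, tolerance = 1e-6)
  set.seed(10)
  light <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, 0.02), 64, 64), 0), 1)
  heavy <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, 0.3), 64, 64), 0), 1)
  expect_lt(vif(x, heavy), vif(x, light))
  expect_lt(vif(x, matrix(0.5, 64, 64)), 0.05)
})

test_that("metrics are permutation invariant where their formulas are", {
  m <- rand_img(12, 12, 5)
  m2 <- rand_img(12, 12, 6)
  set.seed(1); perm <- sample(144)
  shuf <- matrix(as.vector(m)[perm], 12, 12)
  shuf2 <- matrix(as.vector(m2)[perm], 12, 12)
  expect_equal(mean_value(shuf), mean_value(m))
  expect_equal(std_value(shuf), std_value(m))
  expect_equal(entropy(shuf), entropy(m))
  expect_equal(rmse(shuf, shuf2), rmse(m, m2))
})

test_that("evaluate_pair reports all seven statistics and round-trips through CSV", {
  x <- minmax_normalize(generate_ct_phantom(phantom_config(ct_size = 64, seed = 6)))
  pair <- image_pair(x, x, id = "ident")
  rep1 <- evaluate_pair(pair, x)
  expect_equal(rep1$rmse, 0)
  expect_equal(rep1$nmi, 2)
  expect_equal(rep1$vif, 1, tolerance = 1e-6)
  expect_equal(rep1$ent, entropy(x))
  expect_true(all(is.finite(unlist(rep1[c("mean", "std", "ag", "ent",
                                          "rmse", "nmi", "vif")]))))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_metric_reports(rep1, tmp)
  df <- read_metric_reports(tmp)
  expect_identical(names(df), c("id", "mean", "std", "ag", "ent", "rmse", "nmi", "vif"))
  expect_equal(df$nmi, rep1$nmi)
  expect_identical(df$mean, rep1$mean)
})
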