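bands5 <- c("delta", "theta", "alpha", "beta", "gamma")

test_that("build_normative_map computes per-cell mean and sample SD", {
  a <- make_bpt(c(0.2, 0.2, 0.2, 0.2, 0.2), "c1")
  b <- make_bpt(c(0.4, 0.15, 0.15, 0.15, 0.15), "c2")
  norm <- build_normative_map(list(a, b))
  expect_equal(unname(norm$mu[1, "delta"]), 0.3)
  expect_equal(unname(norm$sigma[1, "delta"]), sd(c(0.2, 0.4)))  # ddof = 1
  expect_equal(norm$n_controls, 2)

  ident <- build_normative_map(list(a, a, a))
  expect_true(all(ident$sigma == 0))
  expect_equal(ident$mu, a$values)
})

test_that("build_normative_map validates its inputs", {
  a <- make_bpt(c(0.2, 0.2, 0.2, 0.2, 0.2))
  expect_error(build_normative_map(list(a)), "at least 2")
  b <- a
  b$values <- rbind(b$values, r99 = rep(0.2, 5))
  b$region_ids <- rownames(b$values)
  expect_error(build_normative_map(list(a, b)), "r99")
})

test_that("normative map recovers generating Gaussian parameters", {
  set.seed(31)
  n <- 70
  mu_true <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  sd_true <- 0.01
  controls <- lapply(seq_len(n), function(k) {
    v <- matrix(abs(rnorm(10 * 5, rep(mu_true, each = 10), sd_true)), 10, 5,
                dimnames = list(sprintf("r%02d", 1:10), bands5))
    band_power_table(v / rowSums(v), sprintf("c%d", k))
  })
  norm <- build_normative_map(controls)
  se <- sd_true / sqrt(n)
  # row-normalization perturbs the target means only at O(sd^2); 3 SE + that
  expect_true(all(abs(sweep(norm$mu, 2, mu_true)) < 3 * se + 5e-4))
  expect_true(all(norm$sigma > 0.5 * sd_true & norm$sigma < 1.5 * sd_true))
})

test_that("abnormality_map implements max-|z| with argmax band", {
  mu <- matrix(0.2, 1, 5, dimnames = list("r01", bands5))
  sigma <- matrix(0.05, 1, 5, dimnames = list("r01", bands5))
  norm <- structure(list(region_ids = "r01", band_names = bands5,
                         mu = mu, sigma = sigma, n_controls = 10),
                    class = "normative_map")
  # band z-scores (+1, -3, 0.5, 2, -2)
  x <- 0.2 + 0.05 * c(1, -3, 0.5, 2, -2)
  pat <- band_power_table(matrix(x / sum(x) * 1, 1, 5,
                                 dimnames = list("r01", bands5)),
                          validate = FALSE)
  pat$values[1, ] <- x
  abn <- abnormality_map(pat, norm)
  expect_equal(unname(abn$max_abs_z), 3)
  expect_equal(abn$argmax_band, "theta")

  ident <- band_power_table(mu, validate = FALSE)
  abn0 <- abnormality_map(ident, norm)
  expect_true(all(abn0$max_abs_z == 0))
})

test_that("argmax band ties resolve to the lowest band index", {
  mu <- matrix(0.2, 1, 5, dimnames = list("r01", bands5))
  sigma <- matrix(0.05, 1, 5, dimnames = list("r01", bands5))
  norm <- structure(list(region_ids = "r01", band_names = bands5,
                         mu = mu, sigma = sigma, n_controls = 10),
                    class = "normative_map")
  pat <- band_power_table(mu + 0.05 * matrix(c(0, 2, -2, 0, 0), 1),
                          validate = FALSE)
  expect_equal(abnormality_map(pat, norm)$argmax_band, "theta")
})

test_that("zero-sigma cells give z = 0 at the mean and error off it", {
  a <- make_bpt(c(0.2, 0.2, 0.2, 0.2, 0.2), "c1")
  norm <- build_normative_map(list(a, a))      # sigma identically 0
  expect_true(all(abnormality_map(a, norm)$max_abs_z == 0))
  off <- make_bpt(c(0.25, 0.2, 0.2, 0.2, 0.15), "p1")
  expect_error(abnormality_map(off, norm), "sigma = 0")
})

test_that("z-scores are invariant to a shared positive affine transform", {
  set.seed(41)
  vals <- matrix(runif(6 * 5, 0.1, 0.3), 6, 5)
  controls <- lapply(1:6, function(k)
    band_power_table(matrix(vals[k, ], 4, 5, byrow = TRUE,
                            dimnames = list(sprintf("r%d", 1:4), bands5)) +
                       matrix(rnorm(20, 0, 0.01), 4, 5),
                     sprintf("c%d", k), validate = FALSE))
  pat <- band_power_table(controls[[1]]$values + 0.02, "p", validate = FALSE)
  z0 <- abnormality_map(pat, build_normative_map(controls))$max_abs_z

  tweak <- function(tab) {   # x -> 2.5 x + 0.03 on the alpha band only
    tab$values[, "alpha"] <- 2.5 * tab$values[, "alpha"] + 0.03
    tab
  }
  z1 <- abnormality_map(tweak(pat),
                        build_normative_map(lapply(controls, tweak)))$max_abs_z
  expect_equal(z1, z0, tolerance = 1e-12)
})

test_that("patient drawn from the normative law matches the simulated max-|z| distribution", {
  set.seed(51)
  n_reg <- 10000
  mu <- matrix(0.2, n_reg, 5,
               dimnames = list(sprintf("r%05d", seq_len(n_reg)), bands5))
  sigma <- matrix(0.01, n_reg, 5, dimnames = dimnames(mu))
  norm <- structure(list(region_ids = rownames(mu), band_names = bands5,
                         mu = mu, sigma = sigma, n_controls = 70),
                    class = "normative_map")
  pat <- band_power_table(mu + matrix(rnorm(n_reg * 5, 0, 0.01), n_reg, 5),
                          "p", validate = FALSE)
  z <- abnormality_map(pat, norm)$max_abs_z
  # independent simulation of the 5-draw max-|z| law (cohort module kernel)
  ref <- matrix(abs(rnorm(20000 * 5)), 20000)
  ref_max <- pmax(ref[, 1], ref[, 2], ref[, 3], ref[, 4], ref[, 5])
  expect_gt(suppressWarnings(ks.test(z, ref_max))$p.value, 0.01)
})

test_that("abnormality maps are deterministic and monotone in deviation", {
  a <- make_bpt(c(0.25, 0.2, 0.2, 0.2, 0.15), "c1")
  b <- make_bpt(c(0.15, 0.2, 0.2, 0.25, 0.2), "c2")
  c3 <- make_bpt(c(0.2, 0.25, 0.15, 0.2, 0.2), "c3")
  norm <- build_normative_map(list(a, b, c3))
  pat <- make_bpt(c(0.3, 0.2, 0.15, 0.2, 0.15), "p")
  m1 <- abnormality_map(pat, norm)
  m2 <- abnormality_map(pat, norm)
  expect_identical(m1, m2)

  amax <- m1$argmax_band[1]
  pat2 <- pat
  dev <- pat2$values[1, amax] - norm$mu[1, amax]
  pat2$values[1, amax] <- norm$mu[1, amax] + 1.5 * dev
  pat2 <- band_power_table(pat2$values, "p", validate = FALSE)
  expect_gte(abnormality_map(pat2, norm)$max_abs_z[1], m1$max_abs_z[1])
})
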