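# Estimator tests: diversity, divergence, FST components, scalar
# transforms, bootstrap intervals.

test_that("pi and theta_w match hand values and the brute-force pair oracle", {
  # one het diploid = two haplotypes differing at 1 of 10 callable sites
  vm <- toy_vm(matrix(c(1, rep(0, 9)), ncol = 1))
  d <- nucleotide_diversity(vm, n_callable = 10)
  expect_equal(d$pi, 0.1)

  # 2 diploids, S = 3, n_callable = 100: theta = 3/(100 * (1 + 1/2 + 1/3))
  g <- matrix(0, nrow = 5, ncol = 2)
  g[1, 1] <- 1; g[2, 2] <- 2; g[3, 1] <- 1
  d <- nucleotide_diversity(toy_vm(g), n_callable = 100)
  expect_equal(d$theta_w, 3 / (100 * (1 + 1 / 2 + 1 / 3)), tolerance = 1e-9)
  expect_equal(d$n_snps, 3L)

  # monomorphic region
  d0 <- nucleotide_diversity(toy_vm(matrix(0, 4, 3)), n_callable = 50)
  expect_equal(c(d0$pi, d0$theta_w), c(0, 0))

  # random matrices against explicit allele-pair enumeration
  set.seed(42)
  for (rep in 1:5) {
    g <- matrix(sample(c(0:2, NA), 30, replace = TRUE,
                       prob = c(.4, .3, .25, .05)), nrow = 6)
    g[1, ] <- rep(0:2, length.out = ncol(g))  # ensure called haplotypes
    d <- nucleotide_diversity(toy_vm(g), n_callable = 20)
    expect_equal(d$pi, brute_pi(g, 20), tolerance = 1e-12)
  }
})

test_that("nucleotide_diversity errors without callable haplotypes", {
  g <- matrix(NA_integer_, 3, 2)
  expect_error(nucleotide_diversity(toy_vm(g), n_callable = 10),
               "callable")
})

test_that("dxy matches forced values and the cross-pair enumeration oracle", {
  mono <- toy_vm(matrix(0, 10, 4))
  expect_equal(dxy(mono, c("S1", "S2"), c("S3", "S4"), n_callable = 10), 0)

  g <- matrix(0, 10, 4); g[1, 3:4] <- 2  # fixed difference at 1 of 10
  expect_equal(dxy(toy_vm(g), c("S1", "S2"), c("S3", "S4"),
                   n_callable = 10), 0.1)

  set.seed(7)
  g <- matrix(sample(c(0:2, NA), 80, replace = TRUE), nrow = 10)
  vm <- toy_vm(g)
  expect_equal(dxy(vm, paste0("S", 1:4), paste0("S", 5:8), n_callable = 25),
               brute_dxy(g[, 1:4], g[, 5:8], 25), tolerance = 1e-12)
  expect_error(dxy(vm, character(0), "S1", n_callable = 10), "non-empty")
  expect_error(dxy(vm, c("S1", "S2"), c("S2", "S3"), n_callable = 10),
               "disjoint")
})

test_that("Weir-Cockerham site components reproduce hand evaluations", {
  # fixed difference
  expect_equal(wc_fst_site(c(1, 0), c(0, 0), c(10, 10))$fst, 1)
  # balanced polymorphism, hand-evaluated components
  r <- wc_fst_site(c(0.5, 0.5), c(0.5, 0.5), c(10, 10))
  expect_equal(r$a, -0.0138889, tolerance = 1e-5)
  expect_equal(r$b, 0.0138889, tolerance = 1e-5)
  expect_equal(r$c, 0.25)
  expect_equal(r$fst, -0.0555556, tolerance = 1e-5)
  # unbalanced sample sizes, independently evaluated estimate
  r2 <- wc_fst_site(c(0.95, 0.10526), c(0.10, 0.10526), c(20, 19))
  expect_equal(r2$fst, 0.830, tolerance = 2e-3)
  # monomorphic site is undefined
  expect_false(wc_fst_site(c(0, 0), c(0, 0), c(10, 10))$defined)
})

test_that("multi-site FST is a ratio of sums, invariant to site order", {
  p <- cbind(c(.9, .2, .5), c(.1, .3, .5))
  h <- cbind(c(.1, .2, .5), c(.1, .4, .5))
  site <- wc_fst_site(p, h, c(12, 15))
  multi <- wc_fst_multi(site)
  expect_equal(multi$theta_hat,
               sum(site$a) / sum(site$a + site$b + site$c))
  expect_equal(wc_fst_multi(site[1, ])$theta_hat, site$fst[1])
  perm <- wc_fst_multi(site[c(3, 1, 2), ])
  expect_equal(perm$theta_hat, multi$theta_hat)
  expect_error(wc_fst_multi(site[!site$defined, ]), "no defined sites")
})

test_that("Reynolds coancestry matrix matches the hand oracle and limits", {
  # identical sample frequencies: the unbiased moment estimator is
  # slightly negative (it subtracts the sampling variance), near zero
  p_same <- cbind(c(.2, .5, .8), c(.2, .5, .8))
  expect_lt(abs(reynolds_fst(p_same, c(10, 10))[1, 2]), 0.06)
  # frequencies resampled from one pool: mean estimate near zero
  set.seed(11)
  p0 <- runif(300, 0.1, 0.9)
  ps <- cbind(rbinom(300, 20, p0) / 20, rbinom(300, 20, p0) / 20)
  expect_lt(abs(reynolds_fst(ps, c(10, 10))[1, 2]), 0.03)
  p_fix <- cbind(c(1, 1, 0), c(0, 0, 1))
  expect_gt(reynolds_fst(p_fix, c(10, 10))[1, 2], 0.95)
  p <- cbind(c(.1, .5, .9), c(.2, .4, .7))
  got <- reynolds_fst(p, c(10, 10))[1, 2]
  expect_equal(got, reynolds_oracle(p[, 1], p[, 2], 20, 20),
               tolerance = 1e-12)
  m <- reynolds_fst(cbind(a = c(.1, .2), b = c(.15, .2), c = c(.5, .6)),
                    c(8, 8, 8))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
})

test_that("scalar transforms: N_E, delta_pi, split time, clock dating", {
  ck <- clock_params()
  expect_equal(effective_population_size(3 * ck$mu, ck), 1)
  expect_equal(effective_population_size(0.0082, ck), 518659,
               tolerance = 1e-5)
  # printed whole-genome N_E implies unrounded theta; agree within 0.5%
  expect_lt(abs(effective_population_size(0.0082, ck) - 516601) / 516601,
            0.005)

  expect_equal(delta_pi(0.5, 0.5), 0)
  expect_equal(delta_pi(0.52, 0.72), -0.2778, tolerance = 1e-3)
  expect_equal(delta_pi(0.20, 0.69), -0.710, tolerance = 1e-3)
  expect_error(delta_pi(0.2, 0), "positive")

  expect_equal(split_scaled_time(0), 0)
  expect_equal(split_scaled_time(0.036), 0.01833, tolerance = 1e-3)
  expect_equal(round(split_scaled_time(0.036), 5), 0.01833)
  expect_equal(split_scaled_time(0.5), 0.34657, tolerance = 1e-4)
  expect_error(split_scaled_time(1), "fst")

  expect_equal(clock_date(0, ck), 0)
  expect_equal(clock_date(2 * ck$mu, ck), 1)
  expect_equal(clock_date(0.0334, ck), 3.169e6, tolerance = 1e-3)
  # linearity in dxy
  expect_equal(clock_date(0.02, ck) + clock_date(0.03, ck),
               clock_date(0.05, ck))
})

test_that("window bootstrap percentile interval behaves as enumerated", {
  ci <- window_bootstrap_ci(rep(3.2, 8), reps = 200, seed = 1)
  expect_equal(unname(ci), c(3.2, 3.2))
  # two equal-weight windows: resample means take values a, (a+b)/2, b
  # with probs 1/4, 1/2, 1/4; the 2.5%/97.5% percentiles are a and b
  ci2 <- window_bootstrap_ci(c(1, 3), reps = 2000, seed = 7)
  expect_equal(unname(ci2), c(1, 3))
  # weights shift the point estimate accordingly
  set.seed(2)
  v <- rnorm(40, 1); w <- runif(40, 0.5, 2)
  ci3 <- window_bootstrap_ci(v, w, reps = 500, seed = 3)
  est <- sum(v * w) / sum(w)
  expect_true(ci3["low"] <= est && est <= ci3["high"])
})

test_that("pi's small-sample correction is unbiased under binomial sampling", {
  # sites with known allele frequency p: the m/(m-1)-corrected per-site
  # pi estimator has expectation exactly 2p(1-p)
  set.seed(99)
  n_dip <- 6L
  n_sites <- 400L
  p <- runif(n_sites, 0.05, 0.95)
  g <- matrix(rbinom(n_sites * n_dip, 2, rep(p, n_dip)), nrow = n_sites)
  d <- nucleotide_diversity(toy_vm(g), n_callable = n_sites)
  target <- mean(2 * p * (1 - p))
  m <- 2 * n_dip
  per_site <- {
    ph <- rowSums(g) / m
    2 * ph * (1 - ph) * m / (m - 1)
  }
  se <- sd(per_site) / sqrt(n_sites)
  expect_lt(abs(d$pi - target), 3 * se)
})

test_that("theta_w handles per-site missingness via harmonic weights", {
  set.seed(100)
  g <- matrix(rbinom(200, 2, 0.3), nrow = 50)
  g[sample(length(g), 40)] <- NA
  d <- nucleotide_diversity(toy_vm(g), n_callable = 80)
  # independent per-site accumulation
  harm <- function(m) sum(1 / seq_len(m - 1))
  acc <- 0
  for (s in 1:50) {
    row <- g[s, ]; row <- row[!is.na(row)]
    m <- 2 * length(row)
    if (m < 2) next
    k <- sum(row)
    if (k > 0 && k < m) acc <- acc + 1 / harm(m)
  }
  expect_equal(d$theta_w, acc / 80, tolerance = 1e-12)
})

test_that("excess divergence ratio is calibrated", {
  set.seed(5)
  g <- matrix(rbinom(400, 2, 0.4), nrow = 50)  # one panmictic pool
  vm <- toy_vm(g)
  r <- excess_divergence_ratio(vm, paste0("S", 1:4), paste0("S", 5:8),
                               n_callable = 50)
  expect_equal(r, 1, tolerance = 0.1)
  g2 <- matrix(0, 20, 4); g2[, 3:4] <- 2
  expect_warning(
    r2 <- excess_divergence_ratio(toy_vm(g2), c("S1", "S2"),
                                  c("S3", "S4"), n_callable = 20),
    "infinite")
  expect_identical(r2, Inf)
})
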