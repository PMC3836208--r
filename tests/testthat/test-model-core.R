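test_that("affinity matrix has the preferred-niche block structure", {
  cfg <- model_config(q = 2, n = 2, u_h = 0.01, s_h = 1,
                      s_p = 0.5, u_p = 0.005)
  A <- build_affinity_matrix(cfg)
  expect_equal(unname(A),
               rbind(c(1.01, 0.01), c(0.01, 1.01),
                     c(0.505, 0.005), c(0.005, 0.505)))

  # zero preleukemic affinities give an all-zero preleukemic block
  A0 <- build_affinity_matrix(model_config(q = 2, n = 2, s_p = 0, u_p = 0))
  expect_true(all(A0[3:4, ] == 0))

  # default parameterization: u_h anchored at 1/n
  Ad <- build_affinity_matrix(model_config())
  expect_equal(unname(diag(Ad[1:100, ])), rep(1.01, 100))
  expect_equal(unname(Ad[1, 2]), 0.01)

  expect_error(build_affinity_matrix(model_config(q = 3, n = 2)),
               "n == q")
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(model_config(tau = 0), "tau")
  expect_error(model_config(s_p = -1), "non-negative")
  expect_error(model_config(p = c(1, 2)), "length n")
  expect_equal(model_config(q = 4)$m, 8L)
  expect_equal(reference_total(model_config()), 1e4)
})

test_that("configuration round-trips through YAML and JSON", {
  cfg <- model_config(q = 5, p = 42, tau = 6, s_p = 0.3)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(cfg, f)
    expect_equal(read_model_config(f), cfg)
  }
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(q = 2, bogus = 1), f)
  expect_error(read_model_config(f), "bogus")
})

test_that("resource rates split each niche by affinity-weighted abundance", {
  # a sole competitor takes the whole niche regardless of its affinity
  expect_equal(as.numeric(resource_rates(matrix(0.5), c = 10, p = 100)), 100)
  # two identical competitors split it evenly
  r <- resource_rates(matrix(c(0.3, 0.3)), c = c(7, 7), p = 100)
  expect_equal(as.numeric(r), c(50, 50))
  # an empty system receives nothing (zero-denominator branch)
  A <- build_affinity_matrix(model_config(q = 2, n = 2))
  expect_true(all(resource_rates(A, rep(0, 4), c(100, 100)) == 0))
})

test_that("contested niches conserve their resource supply exactly", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:8, 1)
    n <- sample(1:6, 1)
    A <- matrix(runif(m * n), m, n)
    A[sample(length(A), length(A) %/% 3)] <- 0
    c <- ifelse(runif(m) < 0.3, 0, runif(m, 0, 50))
    p <- runif(n, 0, 200)
    r <- resource_rates(A, c, p)
    contested <- colSums(A * c) > 0
    expect_equal(colSums(r)[contested], p[contested], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(colSums(r)[!contested] == 0))
    expect_true(all(r >= 0))
  }
})

test_that("resource allocation depends on relative affinities only", {
  set.seed(7)
  A <- matrix(runif(12), 4, 3)
  c <- runif(4, 0, 10)
  p <- c(100, 50, 80)
  r <- resource_rates(A, c, p)
  A2 <- A
  A2[, 2] <- A2[, 2] * 17.3  # rescale one niche column
  expect_equal(resource_rates(A2, c, p), r, tolerance = 1e-12)
})

test_that("carrying capacities are efficiency-weighted row sums", {
  r <- rbind(c(60, 40), c(10, 0))
  expect_equal(carrying_capacities(r, c(1, 1)), c(100, 10))
  expect_equal(carrying_capacities(r, c(3, 2)), c(300, 20))
  expect_equal(carrying_capacities(r * 0, c(1, 1)), c(0, 0))
})

test_that("symmetric healthy-only system has k_i = v_h * sum(p) / q", {
  cfg <- model_config()
  A <- build_affinity_matrix(cfg)
  c <- c(rep(7, 100), rep(0, 100))  # equal healthy abundances
  k <- carrying_capacities(resource_rates(A, c, cfg$p),
                           efficiency_vector(cfg))
  expect_equal(k[1:100], rep(cfg$v_h * sum(cfg$p) / cfg$q, 100),
               tolerance = 1e-12)
})

test_that("logistic right-hand side honours its zero branches", {
  expect_equal(growth_rhs(c = 100, k = 100, tau = 8), 0)
  expect_equal(growth_rhs(c = 50, k = 0, tau = 8), 0)
  expect_equal(growth_rhs(c = 50, k = 100, tau = 8), 3.125)
  expect_equal(growth_rhs(c = 0, k = 100, tau = 8), 0)
  # vectorized over species
  expect_equal(growth_rhs(c(0, 50, 10), c(100, 100, 0), 8),
               c(0, 3.125, 0))
})
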