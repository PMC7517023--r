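test_that("log hyperfactorials match direct products", {
  expect_equal(log_hyperfactorial(1), 0)
  expect_equal(log_hyperfactorial(3), log(108)) # 1^1 2^2 3^3
  expect_equal(log_hyperfactorial_sq(1), 0)
  expect_equal(log_hyperfactorial_sq(3), 4 * log(2) + 9 * log(3))
  expect_error(log_hyperfactorial(0), "whole number")
  expect_error(log_hyperfactorial_sq(2.5), "whole number")
})

test_that("uniform closed form: values, saturation and shape invariance", {
  expect_equal(s_uniform(10, 10, 1)$s, 0)
  expect_equal(s_uniform(10, 10, 0.5)$s, log(2) / log(50), tolerance = 1e-12)
  # only the product nx * ny matters
  for (rho in seq(0.05, 1, by = 0.05)) {
    expect_equal(s_uniform(40, 40, rho)$s, s_uniform(80, 20, rho)$s,
                 tolerance = 1e-12)
  }
  expect_error(s_uniform(10, 10, 0.005), "exceed 1")
  expect_error(s_uniform(10, 10, 1.2), "rho")
})

test_that("uniform closed form is monotone in rho and in size", {
  rhos <- seq(0.1, 1, by = 0.1)
  s <- s_uniform(30, 30, rhos)$s
  expect_true(all(diff(s) < 0))
  sizes <- c(10, 20, 50, 100, 300)
  at_fixed_rho <- vapply(sizes, function(n) s_uniform(n, n, 0.4)$s, numeric(1))
  expect_true(all(diff(at_fixed_rho) < 0))
})

test_that("nested packed closed form matches the empirical decomposition", {
  res <- s_nested_packed(20)
  expect_equal(res$s, 0.0567180004586183, tolerance = 1e-12)
  expect_equal(res$nm, 210)
  expect_equal(res$rho, 0.525)
  expect_equal(s_nested_packed(2)$s, entropy_decomposition(matrix_nested_packed(2))$s,
               tolerance = 1e-12)
  # rho -> 0.5 from above and S decreasing as n grows
  ns <- c(10, 50, 200, 2000)
  res <- lapply(ns, s_nested_packed)
  rhos <- vapply(res, `[[`, numeric(1), "rho")
  expect_true(all(diff(rhos) < 0))
  expect_lt(abs(rhos[4] - 0.5), 3e-4)
  expect_true(all(diff(vapply(res, `[[`, numeric(1), "s")) < 0))
})

test_that("isometric modular closed form and occupancy", {
  expect_equal(s_modular_isometric(7, 1)$s, 1) # diagonal limit
  expect_equal(occupancy_modular(2), 0.5)
  expect_equal(occupancy_modular(3), 1 / 3, tolerance = 5e-4)
  expect_equal(s_modular_isometric(120, 40)$s, log(3) / log(4800),
               tolerance = 1e-12)
  expect_equal(s_modular_isometric(120, 120)$s, 0) # single-module saturation
  expect_error(s_modular_isometric(10, 3), "divide")
  # S increases with the number of modules at fixed N
  s <- vapply(c(60, 30, 20, 10, 5, 2, 1),
              function(t) s_modular_isometric(120, t)$s, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("equal-S condition identifies matched power relationships", {
  expect_true(equal_s_condition(9, 3, 64, 8))
  expect_equal(s_modular_isometric(9, 3)$s, s_modular_isometric(64, 8)$s,
               tolerance = 1e-12)
  expect_equal(s_modular_isometric(9, 3)$s, 1 / 3, tolerance = 1e-12)
  expect_false(equal_s_condition(9, 3, 27, 3))
  expect_true(equal_s_condition(12, 4, 12, 4))
  expect_true(equal_s_condition(5, 1, 9, 1)) # diagonal class
  expect_false(equal_s_condition(5, 1, 9, 3))
})

test_that("scale invariance: S constant while H(X,Y) and I grow along log_t N = 2", {
  fams <- list(c(4, 2), c(9, 3), c(16, 4), c(25, 5), c(36, 6))
  res <- lapply(fams, function(p) s_modular_isometric(p[1], p[2]))
  s <- vapply(res, `[[`, numeric(1), "s")
  expect_equal(s, rep(1 / 3, 5), tolerance = 1e-12)
  hxy <- vapply(res, `[[`, numeric(1), "hxy")
  expect_true(all(diff(hxy) > 0))
  mi <- s * hxy
  expect_true(all(diff(mi) > 0))
})

test_that("rectangular modular closed form and its reductions", {
  expect_equal(s_modular_rect(1, 3, 5)$s, 0)
  expect_equal(s_modular_rect(4, 2, 3)$s, log(4) / log(24), tolerance = 1e-12)
  for (p in list(c(2, 3), c(3, 4), c(5, 2))) {
    expect_equal(s_modular_rect(p[1], p[2], p[2])$s,
                 s_modular_isometric(p[1] * p[2], p[2])$s, tolerance = 1e-12)
  }
  expect_error(s_modular_rect(1, 1, 1), "exceed 1")
})

test_that("increasing-module closed form matches frozen values and the generator", {
  res <- s_increasing(3)
  expect_equal(res$nm, 14)
  expect_equal(res$rho, 14 / 36, tolerance = 1e-12)
  expect_equal(res$s, 0.3146849835798618, tolerance = 1e-12)
  expect_error(s_increasing(1), "whole number >= 2")
})

test_that("compound closed form reduces to nested packed at m = 1", {
  expect_equal(s_compound(1, 9)$s, s_nested_packed(9)$s, tolerance = 1e-12)
  expect_equal(s_compound(4, 5)$s, 0.4048864897728989, tolerance = 1e-12)
})

test_that("every generator matches its closed form across a parameter grid", {
  tol <- 1e-10
  for (n in 3:12) {
    k <- withr::with_seed(n, sample(1:n, 1))
    m <- matrix_uniform_regular(n, k / n, seed = n)
    expect_equal(entropy_decomposition(m)$s, s_uniform(n, n, k / n)$s,
                 tolerance = tol)
  }
  for (n in c(2:15, 20, 30, 50, 80, 120, 200)) {
    expect_equal(entropy_decomposition(matrix_nested_packed(n))$s,
                 s_nested_packed(n)$s, tolerance = tol)
  }
  for (m in 1:5) for (t in c(1, 2, 3, 5, 8)) {
    if (m * t == 1) next
    expect_equal(entropy_decomposition(matrix_modular_isometric(m, t))$s,
                 s_modular_isometric(m * t, t)$s, tolerance = tol)
  }
  for (m in 1:5) for (tz in list(c(1, 2), c(2, 3), c(3, 2), c(4, 7))) {
    expect_equal(entropy_decomposition(matrix_modular_rect(m, tz[1], tz[2]))$s,
                 s_modular_rect(m, tz[1], tz[2])$s, tolerance = tol)
  }
  for (m in 2:21) {
    expect_equal(entropy_decomposition(matrix_modular_increasing(m))$s,
                 s_increasing(m)$s, tolerance = tol)
  }
  for (m in 1:5) for (t in c(2, 3, 5, 9)) {
    expect_equal(entropy_decomposition(matrix_compound_nested(m, t))$s,
                 s_compound(m, t)$s, tolerance = tol)
  }
})

test_that("nested matrices carry less mutual information than uniform ones", {
  for (rho in seq(0.12, 0.95, length.out = 25)) {
    m <- matrix_nested_general(20, 20, rho, seed = 7)
    achieved <- sum(m) / 400
    expect_lt(entropy_decomposition(m)$s, s_uniform(20, 20, achieved)$s)
  }
})

test_that("compound matrices carry less S than simple modular ones at matched occupancy", {
  divisors <- c(2, 3, 4, 5, 6, 8, 10, 12, 15, 20)
  for (m in c(2, 3, 4, 5, 6, 8, 10)) {
    t <- 120 / m
    rho_c <- s_compound(m, t)$rho
    m_simple <- divisors[which.min(abs(1 / divisors - rho_c))]
    expect_lt(s_compound(m, t)$s, s_modular_isometric(120, 120 / m_simple)$s)
  }
})
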