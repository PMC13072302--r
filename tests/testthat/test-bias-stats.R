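mito <- genetic_code(2)
std <- genetic_code(1)

uniform_counts <- function(code) {
  count_codons(paste(code$sense_codons, collapse = ""), code, drop_stops = TRUE)
}

one_per_family_counts <- function(code) {
  reps <- vapply(code$families, function(f) sort(f)[1], character(1))
  counts <- count_codons(strrep(paste(reps, collapse = ""), 10), code)
  counts
}

test_that("ENC hits its theoretical extremes", {
  expect_equal(as.numeric(enc_observed(uniform_counts(std), std)), 61)
  expect_equal(as.numeric(enc_observed(uniform_counts(mito), mito)), 60)
  expect_equal(as.numeric(enc_observed(one_per_family_counts(std), std)), 20)
  expect_equal(as.numeric(enc_observed(one_per_family_counts(mito), mito)), 20)
})

test_that("ENC equals the brute-force family enumeration on random counts", {
  set.seed(101)
  for (code in list(std, mito)) {
    for (rep in 1:100) {
      counts <- random_counts(code)
      got <- as.numeric(enc_observed(counts, code))
      want <- oracle_enc(counts, numcode = code$table_id)
      # the implementation caps per-class contributions at the family size
      expect_equal(got, min(want, code$max_enc), tolerance = 1e-10)
    }
  }
})

test_that("ENC stays within bounds and records the uncapped value", {
  set.seed(3)
  for (rep in 1:50) {
    counts <- random_counts(mito, min_count = 0, max_count = 5)
    e <- enc_observed(counts, mito)
    if (!is.na(e)) {
      expect_gte(as.numeric(e), 20)
      expect_lte(as.numeric(e), 60)
      expect_false(is.null(attr(e, "pre_clamp")))
    }
  }
  # a gene using each family uniformly but sparsely can overshoot before capping
  empty <- random_counts(mito)
  empty$count <- 0L
  expect_error(enc_observed(empty, mito), "empty")
})

test_that("the expected-ENC curve has the closed-form values and shape", {
  expect_equal(enc_expected(0.5), 60.5)
  # asymmetry comes only from the linear term
  expect_equal(enc_expected(0.7) - enc_expected(0.3), 0.4)
  s <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(enc_expected(s)) > 0)) # monotone up to 0.5
  grid <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(enc_expected(grid) <= 61))
  expect_equal(grid[which.max(enc_expected(grid))], 0.5)
  # the printed variant is the constant-denominator line
  expect_equal(enc_expected(0.3, formula = "as_printed"), 31.3)
  expect_error(enc_expected(1.2), "fraction")
})

test_that("ENC ratio classification honours the inclusive band edges", {
  expect_equal(enc_ratio(50, 50)$enc_ratio, 0)
  expect_equal(enc_ratio(50, 50)$driver_call, "mutation")
  r <- enc_ratio(45, 50)
  expect_equal(r$enc_ratio, 0.1)
  expect_equal(r$driver_call, "selection")
  # obs = exp * 1.05 -> ratio exactly -0.05: inside the band
  b <- enc_ratio(52.5, 50)
  expect_equal(b$enc_ratio, -0.05)
  expect_equal(b$driver_call, "mutation")
  expect_equal(enc_ratio(30, 50)$bias_strength, "strong")
  expect_equal(enc_ratio(40, 50)$bias_strength, "weak")
})

test_that("PR2 coordinates, quadrants and invariances behave", {
  centre <- pr2_point(5, 5, 7, 7)
  expect_equal(c(centre$x, centre$y), c(0.5, 0.5))
  expect_true(is.na(centre$quadrant))

  q4 <- pr2_point(a3 = 10, t3 = 30, g3 = 25, c3 = 5)
  expect_equal(q4$quadrant, 4L)

  q2 <- pr2_point(4, 0, 0, 4)
  expect_equal(c(q2$x, q2$y), c(0, 1))
  expect_equal(q2$quadrant, 2L)

  scaled <- pr2_point(100, 300, 250, 50)
  expect_equal(c(scaled$x, scaled$y), c(q4$x, q4$y))

  expect_warning(bad <- pr2_point(0, 0, 3, 4), "zero")
  expect_true(is.na(bad$y))
})

test_that("neutrality regression reproduces the degenerate textbook cases", {
  on_diag <- data.frame(gc3 = c(30, 35, 40, 45, 50), gc12 = c(30, 35, 40, 45, 50))
  f1 <- neutrality_fit(on_diag)
  expect_equal(f1$b, 1)
  expect_equal(f1$r, 1)
  expect_equal(f1$r2, 1)
  expect_equal(f1$verdict, "mutation_dominant")

  flat <- data.frame(gc3 = c(30, 35, 40, 45, 50), gc12 = rep(40, 5))
  f2 <- neutrality_fit(flat)
  expect_equal(f2$b, 0)
  expect_equal(f2$r2, 0, tolerance = 1e-12)
  expect_equal(f2$verdict, "uncorrelated")

  expect_error(neutrality_fit(on_diag[1:2, ]), "at least 3")
  degen <- data.frame(gc3 = rep(40, 5), gc12 = 1:5)
  expect_error(neutrality_fit(degen), "variance")
})

test_that("the neutrality fit recovers a shallow synthetic slope", {
  genes <- sim_neutrality_set(
    n_genes = 286, slope = 0.05, noise_sd = 0.3,
    regime = "selection_driven", seed = 424242
  )
  comp <- composition(stats::setNames(genes$cds, genes$gene))
  fit <- neutrality_fit(comp)
  expect_lt(abs(fit$b - 0.05), 0.03)
  expect_equal(fit$verdict, "selection_dominant")
  expect_equal(fit$r2, fit$r^2)
  g <- glance(fit)
  expect_equal(g$slope, fit$b)
  td <- tidy(fit)
  expect_equal(td$estimate[2], fit$b)
})

test_that("the exact binomial tail matches direct pmf summation", {
  expect_equal(binomial_test(1, 2)$p_value, 0.75)
  expect_equal(binomial_test(10, 10)$p_value, 2^-10)
  p_half <- binomial_test(10, 20)$p_value
  expect_gt(p_half, 0.5) # greater tail includes the observation

  set.seed(9)
  for (rep in 1:30) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    bt <- stats::binom.test(k, n, 0.5, alternative = "greater")
    expect_equal(binomial_test(k, n)$p_value, bt$p.value, tolerance = 1e-12)
    bt2 <- stats::binom.test(k, n, 0.5, alternative = "two.sided")
    expect_equal(
      binomial_test(k, n, alternative = "two.sided")$p_value,
      bt2$p.value,
      tolerance = 1e-12
    )
  }
})

test_that("Mann-Whitney U enumerates exactly and matches wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact enumeration")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # invariance under a monotone transform of the pooled values
  a <- c(0.2, 1.4, 3.3, 5)
  b <- c(0.9, 2.2, 4.1)
  expect_equal(
    mann_whitney_u(a, b)$p_value,
    mann_whitney_u(exp(a), exp(b))$p_value
  )

  set.seed(21)
  for (rep in 1:20) {
    a <- sample(1:1000, 5)
    b <- sample(2000:3000, 6)
    got <- mann_whitney_u(a, b)
    want <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(unname(got$p_value), unname(want$p.value), tolerance = 1e-12)
  }

  # large samples fall back to the tie-corrected normal approximation
  set.seed(22)
  a <- stats::rnorm(40)
  b <- stats::rnorm(40, 0.5)
  got <- mann_whitney_u(a, b)
  expect_equal(got$method, "normal approximation (tie-corrected)")
  want <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(unname(got$p_value), unname(want$p.value), tolerance = 1e-09)
})
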