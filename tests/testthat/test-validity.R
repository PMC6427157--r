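# Hand pooled-variance t oracle.
t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

test_that("Student's t matches the textbook pooled formula", {
  r <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- students_t(c(11, 12, 13), c(1, 2, 3))
  expect_lt(r$p_value, 0.05)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, 0, 4))
    y <- rnorm(sample(3:12, 1))
    r <- students_t(x, y)
    o <- t_oracle(x, y)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-12)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
  }
  # degenerate: zero pooled variance
  expect_equal(students_t(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(students_t(c(3, 3), c(2, 2))$p_value, 0)
})

test_that("Fisher exact test reproduces known two-sided p-values", {
  # the 80% vs 20% low-fat milk table, n = 10 + 10
  expect_equal(round(fisher_exact_2x2(8, 2, 2, 8)$p_value, 3), 0.023)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 3, 7)$p_value, 1)  # empty margin
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher exact test is invariant under transpose and label swaps", {
  set.seed(41)
  for (i in 1:30) {
    m <- matrix(sample(0:8, 4, replace = TRUE), 2)
    p <- fisher_exact_2x2(m)$p_value
    expect_equal(fisher_exact_2x2(t(m))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
})

test_that("Fisher exact p agrees with stats::fisher.test", {
  for (n in c(6, 10, 13)) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n, d = 0:n)
    combos <- combos[rowSums(combos) <= n, ]
    for (i in seq_len(nrow(combos))) {
      m <- matrix(unlist(combos[i, ]), 2, byrow = TRUE)
      expect_equal(fisher_exact_2x2(m)$p_value,
                   fisher.test(m)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("exact signed-rank p equals full sign-assignment enumeration", {
  x <- c(6.19, 6.40, 5.95, 6.60, 7.01, 5.52)
  y <- c(2.45, 2.50, 2.41, 2.62, 2.21, 2.02)
  r <- wilcoxon_signed_rank(x, y)
  # oracle: enumerate all 2^6 sign assignments directly
  d <- x - y
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  sums <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 6)), 1,
                function(s) sum(rk[s]))
  p_oracle <- 2 * min(mean(sums <= v_obs), mean(sums >= v_obs))
  expect_equal(r$p_value, min(1, p_oracle), tolerance = 1e-12)
  expect_equal(r$statistic, v_obs)

  # no-ties case agrees with the standard exact implementation
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # equal prices everywhere: no information, p = 1
  expect_equal(wilcoxon_signed_rank(rep(3, 6), rep(3, 6))$p_value, 1)
})

test_that("large-sample signed-rank matches the tie-corrected approximation", {
  set.seed(61)
  x <- round(rnorm(30, 5, 1), 1)
  y <- round(rnorm(30, 4.5, 1), 1)
  keep <- x != y
  r <- wilcoxon_signed_rank(x, y)
  o <- wilcox.test(x[keep], y[keep], paired = TRUE, exact = FALSE,
                   correct = TRUE)
  expect_equal(r$p_value, o$p.value, tolerance = 1e-12)
})

test_that("price premium is an integer percent and scale-invariant", {
  expect_identical(price_premium(6.19, 2.45), 153L)
  expect_identical(price_premium(7.07, 6.80), 4L)
  expect_identical(price_premium(5, 5), 0L)
  set.seed(71)
  for (i in 1:20) {
    a <- runif(1, 1, 20); b <- runif(1, 1, 20); k <- runif(1, 0.1, 10)
    expect_identical(price_premium(k * a, k * b), price_premium(a, b))
  }
  expect_error(price_premium(3, 0), "positive")
})

test_that("availability table reproduces store-type percentages", {
  inst <- nemss_instrument()
  audits <- dplyr::bind_rows(lapply(1:20, function(i) {
    type <- if (i <= 10) "large_supermarket" else "convenience"
    a <- blank_audit(store_id = sprintf("T%02d", i), store_type = type)
    if (i <= 10 || i == 11)  # all supermarkets + 1 convenience store
      a <- set_obs(a, "grains", available = 1L, species = 3L)
    a
  }))
  tab <- availability_table(audits, inst, rater = "R1")
  g <- tab[tab$measure_id == "grains", ]
  expect_equal(g$pct_supermarket, 100)
  expect_equal(g$pct_convenience, 10)
  expect_equal(g$p_value, fisher.test(matrix(c(10, 0, 1, 9), 2,
                                             byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # measures absent everywhere: 0% vs 0%, p = 1
  m <- tab[tab$measure_id == "milk", ]
  expect_equal(m$pct_supermarket, 0)
  expect_equal(m$pct_convenience, 0)
  expect_equal(m$p_value, 1)
  expect_equal(tab$pct_supermarket,
               100 * tab$available_supermarket / tab$n_supermarket)
  expect_error(availability_table(audits[audits$store_type == "convenience", ],
                                  inst),
               "both store types")
})

test_that("price comparison summarizes complete pairs per store", {
  inst <- nemss_instrument()
  audits <- dplyr::bind_rows(lapply(1:6, function(i) {
    type <- if (i <= 3) "large_supermarket" else "convenience"
    a <- blank_audit(store_id = sprintf("P%02d", i), store_type = type)
    set_obs(a, "grains", available = 1L, species = 3L, ph = 6.19, pr = 2.45)
  }))
  pc <- price_comparison(audits, inst, rater = "R1")
  g <- pc[pc$measure_id == "grains", ]
  expect_equal(g$n_pairs, 6L)
  expect_equal(g$mean_healthier, 6.19)
  expect_equal(g$mean_regular, 2.45)
  expect_equal(g$sd_healthier, 0)
  expect_equal(g$sd_regular, 0)
  expect_identical(g$premium_pct, 153L)
  # unpriced-in-data unit rows are emitted with undefined summaries
  expect_true(is.na(pc$p_value[pc$measure_id == "milk"]))
  expect_true(all(pc$n_pairs[pc$measure_id == "milk"] == 0L))
})

test_that("p-value formatting matches the table style", {
  expect_equal(format_p(c(0.0004, 0.023, 0.063, NA)),
               c("<0.001", "0.023", "0.063", NA))
})

test_that("total-score comparison separates the known groups", {
  inst <- nemss_instrument()
  audits <- generate_audits(default_sim_config(), seed = 17)
  tot <- total_score_comparison(audits, inst)
  expect_equal(nrow(tot), 2L)
  expect_true(all(tot$mean_supermarket > tot$mean_convenience))
  expect_true(all(tot$p_value < 0.001))
})
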