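# independent step-down oracle: for the i-th smallest of m p-values the
# adjusted value is the running maximum of 1 - (1 - p_(j))^(m - j + 1)
brute_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 0
    for (j in seq_len(i)) {
      best <- max(best, 1 - (1 - p[o[j]])^(m - j + 1))
    }
    adj[o[i]] <- min(best, 1)
  }
  adj
}

test_that("Holm-Sidak adjustment matches hand-computed values", {
  expect_equal(holm_sidak(0.01), 0.01)
  expect_equal(round(holm_sidak(c(0.01, 0.04, 0.03)), 4), c(0.0297, 0.0591, 0.0591))
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(holm_sidak(numeric(0)), numeric(0))
  expect_error(holm_sidak(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_sidak(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("Holm-Sidak agrees with the brute-force oracle and its properties", {
  set.seed(11)
  for (r in 1:200) {
    m <- sample(1:6, 1)
    p <- runif(m)
    adj <- holm_sidak(p)
    expect_equal(adj, brute_holm_sidak(p))
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # the smallest p gets exactly the single-step Sidak adjustment
    expect_equal(min(adj), 1 - (1 - min(p))^m)
    # permutation equivariance
    perm <- sample(m)
    expect_equal(holm_sidak(p[perm]), adj[perm])
  }
})

make_groups <- function(values_a, values_b, group_id = 1L) {
  dplyr::bind_rows(
    tibble::tibble(age_group = group_id, value = values_a, grp = "a"),
    tibble::tibble(age_group = group_id, value = values_b, grp = "b")
  )
}

test_that("identical samples give zero difference and p = 1", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  res <- compare_groups(make_groups(x, x), "value", "grp", "a", "b")
  expect_equal(res$diff, 0)
  expect_equal(res$p_raw, 1)
  expect_false(res$significant)
})

test_that("small strata are suppressed and leave the correction family", {
  set.seed(5)
  d <- dplyr::bind_rows(
    make_groups(rnorm(5), rnorm(20), group_id = 1L), # n_a = 5 -> suppressed
    make_groups(rnorm(20, 2), rnorm(20), group_id = 2L),
    make_groups(rnorm(20, 2), rnorm(20), group_id = 3L)
  )
  res <- compare_groups(d, "value", "grp", "a", "b")
  expect_true(res$suppressed[1])
  expect_true(is.na(res$p_raw[1]))
  expect_false(anyNA(res$p_raw[2:3]))
  # family size 2: the smallest adjusted p uses m = 2
  expect_equal(
    min(res$p_adj, na.rm = TRUE),
    1 - (1 - min(res$p_raw, na.rm = TRUE))^2
  )
  # descriptives still reported for the suppressed stratum
  expect_false(is.na(res$mean_a[1]))
})

test_that("zero variance in both groups is flagged as degenerate", {
  res <- compare_groups(
    make_groups(rep(1, 8), rep(1, 8)), "value", "grp", "a", "b"
  )
  expect_true(res$degenerate)
  expect_true(is.na(res$p_raw))
})

test_that("a planted one-SD shift is detected in every age group", {
  set.seed(42)
  d <- dplyr::bind_rows(lapply(1:10, function(g) {
    make_groups(rnorm(200, 1), rnorm(200, 0), group_id = g)
  }))
  res <- compare_groups(d, "value", "grp", "a", "b")
  expect_true(all(res$significant))
  expect_equal(res$diff, rep(1, 10), tolerance = 0.35)
})

test_that("the Welch test holds its type-I error rate under the null", {
  set.seed(1234)
  rej <- mean(replicate(2000, {
    stats::t.test(rnorm(30), rnorm(30))$p.value < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("pooled-variance t-test is available as a config option", {
  set.seed(8)
  d <- make_groups(rnorm(15), rnorm(40, sd = 4))
  welch <- compare_groups(d, "value", "grp", "a", "b")
  pooled <- compare_groups(d, "value", "grp", "a", "b", var_equal = TRUE)
  expect_false(isTRUE(all.equal(welch$p_raw, pooled$p_raw)))
})

test_that("max_group_difference finds the extremum with youngest-group ties", {
  res <- tibble::tibble(
    age_group = c(5L, 7L, 9L),
    diff = c(0.2, 1.4, 0.9),
    pct_diff = c(2, 14, 9),
    suppressed = FALSE
  )
  out <- max_group_difference(res, "absolute")
  expect_equal(out$age_group, 7L)
  expect_equal(out$value, 1.4)
  expect_equal(max_group_difference(res, "percent")$value, 14)
  # window restriction and minimisation
  expect_equal(max_group_difference(res, "absolute", window = c(8, 10))$age_group, 9L)
  expect_equal(
    max_group_difference(res, "absolute", direction = "min")$age_group, 5L
  )
  # tie -> youngest
  tie <- dplyr::mutate(res, diff = 1)
  expect_equal(max_group_difference(tie, "sds")$age_group, 5L)
  # suppressed strata never win
  res$suppressed[2] <- TRUE
  expect_equal(max_group_difference(res, "absolute")$age_group, 9L)
  expect_error(
    max_group_difference(dplyr::mutate(res, suppressed = TRUE)),
    "no non-suppressed"
  )
})
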