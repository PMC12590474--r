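test_that("detection probability matches the analytic design maths", {
  expect_equal(detection_probability(0.8, 3), 0.992)
  expect_equal(detection_probability(0, 10), 0)
  expect_equal(detection_probability(1, 1), 1)
  expect_error(detection_probability(1.2, 3), "\\[0, 1\\]")
  expect_error(detection_probability(0.5, 2.5), "integer")

  # monotone nondecreasing in both arguments
  ps <- seq(0, 1, by = 0.1)
  expect_true(all(diff(detection_probability(ps, 3)) >= 0))
  expect_true(all(diff(detection_probability(0.3, 1:10)) >= 0))

  # Monte-Carlo oracle: 1e6 seeded Bernoulli cohorts at p = 0.3, n = 4
  set.seed(51)
  hits <- matrix(stats::runif(4e6) < 0.3, ncol = 4)
  mc <- mean(rowSums(hits) > 0)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(detection_probability(0.3, 4) - mc), 3 * se)
})

test_that("penetrance estimates use exact Clopper-Pearson intervals", {
  expect_equal(estimate_penetrance(6, 10)$penetrance, 0.6)
  expect_equal(estimate_penetrance(5, 15)$penetrance, 1 / 3, tolerance = 1e-12)
  z <- estimate_penetrance(0, 8)
  expect_equal(z$penetrance, 0)
  expect_equal(z$ci_lo, 0)
  expect_error(estimate_penetrance(9, 8), "k")

  # cross-check against the independent exact-test implementation
  for (kk in c(0, 3, 6, 10)) {
    got <- estimate_penetrance(kk, 10)
    ref <- stats::binom.test(kk, 10)$conf.int
    expect_equal(c(got$ci_lo, got$ci_hi), as.numeric(ref), tolerance = 1e-10)
  }
  ci <- estimate_penetrance(0:20, 20)
  expect_true(all(ci$ci_lo <= ci$penetrance & ci$penetrance <= ci$ci_hi))
})

test_that("background rates print at the one-decimal reporting convention", {
  expect_equal(background_rate(2, 167)$label, "1.2%")
  expect_equal(background_rate(9, 403)$label, "2.2%")
  expect_equal(background_rate(0, 100)$percent, 0)
  expect_equal(background_rate(1, 16)$percent, 6.3)  # half-up, not half-even
  expect_error(background_rate(1, 0), "positive")
})

test_that("Cohen's d follows the pooled-SD formula", {
  expect_equal(cohens_d(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  a <- stats::rnorm(10); b <- stats::rnorm(12, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "undefined")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("climbing-tremor correlation supports both estimators", {
  s <- tibble::tibble(climbing_score_cm = c(0.2, 0.5, 0.8, 1.1),
                      tremor_rate_per_s = c(4, 3, 2, 1))
  expect_equal(climbing_tremor_correlation(s)$r, -1)

  set.seed(61)
  null <- tibble::tibble(climbing_score_cm = stats::rnorm(1000),
                         tremor_rate_per_s = stats::rnorm(1000))
  expect_lt(abs(climbing_tremor_correlation(null)$r), 0.1)

  set.seed(62)
  d <- tibble::tibble(climbing_score_cm = stats::runif(30),
                      tremor_rate_per_s = stats::rexp(30))
  sp <- climbing_tremor_correlation(d, method = "spearman")
  ranked <- tibble::tibble(climbing_score_cm = rank(d$climbing_score_cm),
                           tremor_rate_per_s = rank(d$tremor_rate_per_s))
  expect_equal(sp$r, climbing_tremor_correlation(ranked)$r, tolerance = 1e-10)

  flat <- tibble::tibble(climbing_score_cm = rep(1, 5),
                         tremor_rate_per_s = 1:5)
  expect_error(climbing_tremor_correlation(flat), "variance")
})

test_that("poorest-climber selection is a deterministic partial sort", {
  sc <- tibble::tibble(fly_id = c("A", "B", "C", "D"),
                       climbing_score_cm = c(0.2, 0.5, 0.9, 1.2))
  expect_setequal(select_poorest_climbers(sc, 3)$fly_id, c("A", "B", "C"))

  tied <- tibble::tibble(fly_id = c("d", "b", "c", "a"),
                         climbing_score_cm = rep(0.5, 4))
  expect_equal(select_poorest_climbers(tied, 2)$fly_id, c("a", "b"))
  expect_error(select_poorest_climbers(tied, 5), "at least")

  set.seed(71)
  for (rep in 1:10) {
    sc2 <- tibble::tibble(fly_id = sprintf("f%02d", sample(99, 20)),
                          climbing_score_cm = round(stats::runif(20), 1))
    got <- select_poorest_climbers(sc2, 3)$fly_id
    ord <- sc2[order(sc2$climbing_score_cm, sc2$fly_id), ]  # full-sort oracle
    expect_identical(got, ord$fly_id[1:3])
  }
})

test_that("group comparisons select and apply the right nonparametric tests", {
  set.seed(81)
  two <- data.frame(v = c(stats::rnorm(20), stats::rnorm(20)),
                    g = rep(c("a", "b"), each = 20))
  null_cmp <- compare_groups(two, "v", "g")
  expect_equal(glance(null_cmp)$method, "Mann-Whitney U")
  expect_gt(glance(null_cmp)$p_value, 0.05)

  sep <- data.frame(v = c(stats::rnorm(20), stats::rnorm(20, 5)),
                    g = rep(c("a", "b"), each = 20))
  expect_lt(glance(compare_groups(sep, "v", "g"))$p_value, 0.001)

  ident <- data.frame(v = rep(1, 20), g = rep(c("a", "b"), each = 10))
  expect_gt(glance(compare_groups(ident, "v", "g"))$p_value, 0.9)

  # U statistic on a 4-vs-4 toy equals the pairwise-count enumeration
  a <- c(1.3, 2.1, 7.2, 9.5); b <- c(0.4, 2.8, 3.3, 5.1)
  u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  cmp <- compare_groups(data.frame(v = c(a, b),
                                   g = rep(c("a", "b"), each = 4)), "v", "g")
  expect_equal(unname(glance(cmp)$statistic), u_brute)

  three <- data.frame(v = c(stats::rnorm(15), stats::rnorm(15, 4),
                            stats::rnorm(15)),
                      g = rep(c("ctl", "hit", "null"), each = 15))
  kcmp <- compare_groups(three, "v", "g", control = "ctl")
  expect_equal(glance(kcmp)$method, "Kruskal-Wallis")
  pw <- tidy(kcmp)
  expect_setequal(pw$group1, c("hit", "null"))
  expect_lt(pw$p_adjusted[pw$group1 == "hit"], 0.001)
  expect_gt(pw$p_adjusted[pw$group1 == "null"], 0.05)

  expect_error(compare_groups(three, "v", "g", control = "nope"), "Control")
  expect_error(compare_groups(data.frame(v = 1:3, g = "a"), "v", "g"),
               "2 nonempty")
})

test_that("Dunn post-hoc z statistics match a hand-computed example", {
  # 3 groups, n = 4 each, with one tie; rank sums computed by hand below
  v <- c(1, 3, 5, 7,   2, 4, 6, 8,   10, 11, 12, 7)
  g <- rep(c("A", "B", "C"), each = 4)
  cmp <- compare_groups(data.frame(v = v, g = g), "v", "g")
  pw <- tidy(cmp)

  r <- rank(v); N <- 12
  ties <- table(r)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  zAB <- (mean(r[g == "A"]) - mean(r[g == "B"])) / sqrt(s2 * (1 / 4 + 1 / 4))
  got <- pw$statistic[pw$group1 == "A" & pw$group2 == "B"]
  expect_equal(unname(got), unname(zAB), tolerance = 1e-12)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 3))
})

test_that("line-level screen summary flags the planted hit", {
  set.seed(91)
  mk <- function(geno, n, k, rate_pos) tibble::tibble(
    genotype = geno,
    tremor_positive = seq_len(n) <= k,
    tremor_rate_per_s = c(stats::runif(k, rate_pos * 0.8, rate_pos * 1.2),
                          rep(0, n - k)))
  flies <- dplyr::bind_rows(mk("control", 12, 0, 0),
                            mk("hitline", 12, 9, 3),
                            mk("nullline", 12, 1, 0.5))
  res <- summarize_screen(flies, control = "control")
  expect_equal(res$penetrance[res$genotype == "hitline"], 0.75)
  expect_true(res$hit[res$genotype == "hitline"])
  expect_false(res$hit[res$genotype == "nullline"])
  expect_false(res$hit[res$genotype == "control"])
  expect_true(all(res$ci_lo <= res$penetrance & res$penetrance <= res$ci_hi))
  expect_error(summarize_screen(flies, control = "absent"), "control")
})
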