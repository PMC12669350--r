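test_that("normal homoscedastic data route to the t-test, skewed data to ranks", {
  set.seed(61)
  r <- two_group_compare(rnorm(20), rnorm(20))
  expect_equal(r$test_used, "t-test")
  expect_true(all(r$gate$normality_p > 0.05))
  used <- replicate(100, two_group_compare(rlnorm(16, 0, 1.5),
                                           rlnorm(16, 0, 1.5))$test_used)
  expect_gte(mean(used == "rank-sum"), 0.9)
})

test_that("gating is a pure function of the recorded gate p-values", {
  set.seed(62)
  for (i in 1:25) {
    x <- if (i %% 2) rnorm(12) else rexp(12)
    y <- if (i %% 3) rnorm(12) else rexp(12)^2
    r <- two_group_compare(x, y)
    expected <- if (all(r$gate$normality_p > 0.05) && r$gate$variance_p > 0.05)
      "t-test" else "rank-sum"
    expect_equal(r$test_used, expected)
  }
})

test_that("group order does not change two-tailed p-values", {
  set.seed(63)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  expect_equal(two_group_compare(a, b)$p_value, two_group_compare(b, a)$p_value)
  x <- rlnorm(15); y <- rlnorm(15, 1)
  expect_equal(two_group_compare(x, y)$p_value, two_group_compare(y, x)$p_value)
})

test_that("degenerate constant groups do not crash and report the rank route", {
  r <- suppressWarnings(two_group_compare(rep(1, 5), rep(1, 6)))
  expect_equal(r$test_used, "rank-sum")
  expect_equal(r$p_value, 1)
  expect_warning(two_group_compare(rep(2, 5), c(1, 2, 3, 4, 5)), "zero-variance")
})

test_that("small groups are rejected with an informative error", {
  expect_error(two_group_compare(c(1, 2), rnorm(5)), "insufficient")
  expect_error(multi_group_compare(list(a = 1:2, b = rnorm(5), c = rnorm(5))),
               "insufficient")
})

test_that("a shifted group is flagged by the omnibus test and both pairwise contrasts", {
  set.seed(64)
  hits <- replicate(60, {
    r <- multi_group_compare(list(g1 = rnorm(16), g2 = rnorm(16),
                                  g3 = rnorm(16, 2)))
    sig <- r$p_value < 0.05
    if (!sig || is.null(r$post_hoc)) return(FALSE)
    ph <- r$post_hoc
    both <- grepl("g3", ph$pair)
    sig && all(ph$p_adjusted[both] < 0.05)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("unbalanced group sizes are supported", {
  set.seed(65)
  r <- multi_group_compare(list(g1 = rnorm(5), g2 = rnorm(16), ref = rnorm(25)))
  expect_s3_class(r, "bonemat_stat")
  expect_true(r$test_used %in% c("anova", "anova-on-ranks"))
})

test_that("Holm-Sidak adjustment matches the step-down closed form", {
  p <- c(0.01, 0.04, 0.03, 0.5)
  adj <- bonemat:::.holm_sidak(p)
  # hand-computed: sorted p (0.01, 0.03, 0.04, 0.5) with m..1 exponents
  o <- order(p)
  manual <- cummax(pmin(1 - (1 - p[o])^(4:1), 1))
  expect_equal(adj[o], manual)
  expect_true(all(adj >= p))
})

test_that("Dunn pairwise z-statistics match a hand computation with ties", {
  values <- c(1, 2, 2, 4, 5, 6, 7, 8, 9)
  glab <- factor(rep(c("a", "b", "c"), each = 3))
  d <- bonemat:::.dunn_pairwise(values, glab)
  n <- 9
  rk <- rank(values)
  ties <- table(values)
  tc <- sum(ties^3 - ties) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - tc) * (2 / 3))
  z_ab <- (mean(rk[1:3]) - mean(rk[4:6])) / se
  expect_equal(d$statistic[d$pair == "a vs b"], z_ab)
  expect_equal(d$p_raw[d$pair == "a vs b"], 2 * pnorm(abs(z_ab), lower.tail = FALSE))
})

test_that("Pearson correlation handles exact, strong, and degenerate cases", {
  x <- rnorm(10)
  expect_equal(correlate(x, x)$r, 1)
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
  set.seed(66)
  rs <- replicate(400, {
    z <- matrix(rnorm(42), 21)
    correlate(z[, 1], 0.9 * z[, 1] + sqrt(1 - 0.81) * z[, 2])$r
  })
  expect_lt(abs(mean(rs) - 0.9), 0.03)
})

test_that("independent samples reject at about the nominal rate", {
  set.seed(67)
  rej <- mean(replicate(800, correlate(rnorm(21), rnorm(21))$p_value < 0.05))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.08)
})

test_that("two-way ANOVA reports type-II main effects and gated contrasts", {
  set.seed(68)
  d <- expand.grid(group = c("G1", "G2", "CTRL"),
                   position = c("Os", "TA1", "TA2", "TA3", "In"), rep = 1:5)
  d$value <- rnorm(nrow(d), 0, 0.5) + 2 * (d$group == "G1") +
    0.3 * as.numeric(d$position)
  r <- two_way_anova(d)
  expect_lt(r$p_value, 0.001)
  expect_true(all(c("group", "position", "group:position") %in%
                    rownames(r$anova_table)))
  # the shifted group is flagged within each position
  g1 <- grepl("G1", r$post_hoc$pair)
  expect_true(all(r$post_hoc$p_adjusted[g1] < 0.05))
})

test_that("zero interaction data keep the interaction rejection near alpha", {
  set.seed(69)
  rej <- replicate(150, {
    d <- expand.grid(group = c("G1", "G2"), position = c("A", "B", "C"),
                     rep = 1:4)
    d$value <- rnorm(nrow(d)) + 0.8 * (d$group == "G1") +
      0.5 * as.numeric(d$position)
    r <- two_way_anova(d, post_hoc = FALSE)
    r$anova_table["group:position", "Pr(>F)"] < 0.05
  })
  expect_lt(mean(rej), 0.12)
  expect_gt(mean(rej), 0.005)
})

test_that("single observation per cell drops the interaction but keeps main effects", {
  d <- expand.grid(group = c("G1", "G2"), position = c("A", "B", "C"))
  d$value <- c(1.2, 2.1, 2.8, 4.4, 5.1, 6.9)
  r <- two_way_anova(d, post_hoc = FALSE)
  expect_match(r$note, "interaction")
  expect_false("group:position" %in% rownames(r$anova_table))
  expect_true(is.finite(r$p_value))
})

test_that("empty cells are rejected", {
  d <- data.frame(group = c("G1", "G1", "G2"), position = c("A", "B", "A"),
                  value = 1:3)
  expect_error(two_way_anova(d), "empty cells")
})

test_that("significance marks follow the figure conventions", {
  expect_equal(significance_marks(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
  expect_equal(significance_marks(0.004, symbol = "°"), "°°")
})
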