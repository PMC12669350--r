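#' Assumption-gated cohort comparisons
#'
#' The comparison workflow mirrors classical biomedical statistics software:
#' every comparison first checks Shapiro-Wilk normality in each group and
#' Brown-Forsythe (median-centered Levene) homogeneity of variance across
#' groups at `alpha_gate`; only if all gates pass is the parametric test
#' used, otherwise the rank-based alternative. All p-values are two-tailed.
#'
#' @name gated-tests
NULL

# Shapiro-Wilk p-value, tolerant of degenerate input
.shapiro_p <- function(x) {
  if (length(x) < 3 || length(unique(x)) == 1) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

# Brown-Forsythe equal-variance p across groups (median-centered Levene)
.brown_forsythe_p <- function(values, groups) {
  if (all(vapply(split(values, groups), function(v) length(unique(v)) == 1, TRUE)))
    return(NA_real_)
  out <- tryCatch(
    car::leveneTest(values ~ factor(groups), center = stats::median),
    error = function(e) NULL)
  if (is.null(out)) return(NA_real_)
  p <- out[["Pr(>F)"]][1]
  if (is.nan(p)) NA_real_ else p
}

# Holm-Sidak step-down adjustment of raw two-sided p-values
.holm_sidak <- function(p) {
  m <- length(p)
  if (m == 0) return(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

.stat_result <- function(test_used, statistic, p_value, normality_p,
                         variance_p, post_hoc = NULL, note = NULL) {
  structure(list(test_used = test_used, statistic = unname(statistic),
                 p_value = unname(p_value),
                 gate = list(normality_p = normality_p, variance_p = variance_p),
                 post_hoc = post_hoc, note = note),
            class = "bonemat_stat")
}

#' @export
print.bonemat_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  cat(sprintf("  gates: Shapiro-Wilk p = %s; Brown-Forsythe p = %s\n",
              paste(signif(x$gate$normality_p, 3), collapse = ", "),
              signif(x$gate$variance_p, 3)))
  if (!is.null(x$post_hoc) && nrow(x$post_hoc)) {
    cat("  post-hoc (Holm-Sidak adjusted):\n")
    for (i in seq_len(nrow(x$post_hoc)))
      cat(sprintf("    %s: p = %.4g %s\n", x$post_hoc$pair[i],
                  x$post_hoc$p_adjusted[i],
                  significance_marks(x$post_hoc$p_adjusted[i])))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Significance markers
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, else `""`.
#' @param p Numeric vector of p-values.
#' @param symbol Marker character (figures comparing the whole cohort to the
#'   reference conventionally use `"°"` instead of `"*"`).
#' @return Character vector.
#' @export
significance_marks <- function(p, symbol = "*") {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    strrep(symbol, sum(pp < c(0.05, 0.01, 0.001)))
  }, character(1))
}

#' Two-group comparison with assumption gating
#'
#' Shapiro-Wilk on each group and Brown-Forsythe across groups at
#' `alpha_gate`; both pass: pooled two-sample t-test; any fail (or a
#' degenerate zero-variance group): two-sided Mann-Whitney rank-sum test.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param alpha_gate Gate level, default 0.05.
#' @return A `bonemat_stat` result with the gate evidence recorded.
#' @export
two_group_compare <- function(a, b, alpha_gate = 0.05) {
  if (length(a) < 3 || length(b) < 3 || anyNA(a) || anyNA(b))
    stop("insufficient data: each group needs >= 3 complete values")
  norm_p <- c(.shapiro_p(a), .shapiro_p(b))
  var_p <- .brown_forsythe_p(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
  degenerate <- anyNA(c(norm_p, var_p))
  if (degenerate)
    warning("zero-variance group: routing to the rank-sum test")
  if (!degenerate && all(norm_p > alpha_gate) && var_p > alpha_gate) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    .stat_result("t-test", tt$statistic, tt$p.value, norm_p, var_p)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    if (is.na(p)) p <- 1  # both groups constant and identical
    .stat_result("rank-sum", wt$statistic, p, norm_p, var_p,
                 note = if (degenerate) "zero-variance group" else NULL)
  }
}

#' Multi-group comparison with assumption gating and post-hoc tests
#'
#' All groups normal (Shapiro-Wilk) and homoscedastic (Brown-Forsythe):
#' one-way ANOVA with Holm-Sidak-adjusted pairwise t-tests on the pooled
#' error; otherwise Kruskal-Wallis ANOVA on ranks with Dunn's pairwise
#' rank comparisons (Holm-Sidak adjusted). Post-hoc tests run only after a
#' significant omnibus test (p < 0.05).
#'
#' @param groups Named list of numeric vectors (>= 3 groups, each n >= 3).
#' @param alpha_gate Gate level, default 0.05.
#' @return A `bonemat_stat` result; `post_hoc` has columns `pair`, `p_raw`,
#'   `p_adjusted`.
#' @export
multi_group_compare <- function(groups, alpha_gate = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 3)
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 3) || anyNA(unlist(groups)))
    stop("insufficient data: each group needs >= 3 complete values")
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  norm_p <- vapply(groups, .shapiro_p, numeric(1))
  var_p <- .brown_forsythe_p(values, glab)
  degenerate <- anyNA(c(norm_p, var_p))
  if (degenerate)
    warning("zero-variance group: routing to ANOVA on ranks")
  parametric <- !degenerate && all(norm_p > alpha_gate) && var_p > alpha_gate

  if (parametric) {
    fit <- stats::aov(values ~ glab)
    tab <- summary(fit)[[1]]
    omnibus_p <- tab[["Pr(>F)"]][1]
    post <- if (omnibus_p < 0.05)
      .pairwise_pooled_t(values, glab, tab["Residuals", "Mean Sq"],
                         tab["Residuals", "Df"])
    .stat_result("anova", tab[["F value"]][1], omnibus_p, norm_p, var_p, post)
  } else {
    kw <- stats::kruskal.test(values, glab)
    post <- if (kw$p.value < 0.05) .dunn_pairwise(values, glab)
    .stat_result("anova-on-ranks", kw$statistic, kw$p.value, norm_p, var_p,
                 post, note = if (degenerate) "zero-variance group" else NULL)
  }
}

# pairwise t comparisons on the pooled ANOVA error, Holm-Sidak adjusted
.pairwise_pooled_t <- function(values, glab, mse, df) {
  lev <- levels(glab)
  cmb <- utils::combn(lev, 2)
  p_raw <- stat <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    xi <- values[glab == cmb[1, j]]
    xj <- values[glab == cmb[2, j]]
    se <- sqrt(mse * (1 / length(xi) + 1 / length(xj)))
    stat[j] <- (mean(xi) - mean(xj)) / se
    p_raw[j] <- 2 * stats::pt(abs(stat[j]), df, lower.tail = FALSE)
  }
  data.frame(pair = paste(cmb[1, ], cmb[2, ], sep = " vs "),
             statistic = stat, p_raw = p_raw,
             p_adjusted = .holm_sidak(p_raw))
}

# Dunn's z comparisons on mean ranks with tie correction, Holm-Sidak adjusted
.dunn_pairwise <- function(values, glab) {
  n <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(glab)
  rbar <- tapply(rk, glab, mean)
  ni <- tapply(rk, glab, length)
  cmb <- utils::combn(lev, 2)
  p_raw <- stat <- numeric(ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[i1]] + 1 / ni[[i2]]))
    stat[j] <- (rbar[[i1]] - rbar[[i2]]) / se
    p_raw[j] <- 2 * stats::pnorm(abs(stat[j]), lower.tail = FALSE)
  }
  data.frame(pair = paste(cmb[1, ], cmb[2, ], sep = " vs "),
             statistic = stat, p_raw = p_raw,
             p_adjusted = .holm_sidak(p_raw))
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A `bonemat_stat` with the correlation coefficient in `statistic`
#'   (also exposed as `$r`) and the two-tailed p-value.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("insufficient data: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- .stat_result("pearson", ct$estimate, ct$p.value, NA_real_, NA_real_)
  out$r <- unname(ct$estimate)
  out
}

#' Two-way ANOVA for Raman outcomes
#'
#' Fits `value ~ group * position` on the statistical-unit table and reports
#' type-II F tests for the main effects and the interaction (type II so main
#' effects are not distorted in unbalanced designs). With a single
#' observation per cell the interaction is dropped and only main effects are
#' testable. Pairwise group contrasts within each position (estimated
#' marginal means on the cell-mean model) are Holm-Sidak adjusted within
#' each position family.
#'
#' @param data `data.frame` with columns `value`, `group`, `position`.
#' @param post_hoc Run within-position pairwise contrasts? Default `TRUE`.
#' @return A `bonemat_stat`; `statistic`/`p_value` refer to the group main
#'   effect, `$anova_table` holds the full type-II table, `post_hoc` the
#'   within-position contrasts.
#' @export
two_way_anova <- function(data, post_hoc = TRUE) {
  stopifnot(all(c("value", "group", "position") %in% names(data)))
  data$group <- factor(data$group)
  data$position <- factor(data$position)
  stopifnot(nlevels(data$group) >= 2, nlevels(data$position) >= 2)
  cell_n <- table(data$group, data$position)
  if (any(cell_n == 0)) stop("empty cells: every group x position cell needs data")
  with_interaction <- all(cell_n >= 2)
  fml <- if (with_interaction) value ~ group * position else value ~ group + position
  fit <- stats::lm(fml, data = data)
  tab <- car::Anova(fit, type = 2)
  ph <- NULL
  if (post_hoc) {
    emm <- emmeans::emmeans(fit, ~ group | position)
    cts <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise",
                                                   adjust = "none")))
    ph <- do.call(rbind, lapply(split(cts, cts$position), function(d) {
      data.frame(position = d$position,
                 pair = gsub(" - ", " vs ", d$contrast),
                 estimate = d$estimate, p_raw = d$p.value,
                 p_adjusted = .holm_sidak(d$p.value))
    }))
    rownames(ph) <- NULL
  }
  out <- .stat_result("two-way-anova", tab["group", "F value"],
                      tab["group", "Pr(>F)"], NA_real_, NA_real_, ph,
                      note = if (!with_interaction)
                        "single observation per cell: interaction not estimable")
  out$anova_table <- tab
  out
}
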