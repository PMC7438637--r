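test_that("heading regression recovers exact linear responses", {
  sim <- rep(c(-10, -5, 0, 5, 10), each = 8)
  r <- fit_heading_regression(data.frame(simulated = sim, perceived = sim))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  # an exactly linear compressive response round-trips its coefficients
  r <- fit_heading_regression(
    data.frame(simulated = sim, perceived = 0.548 * sim - 0.111))
  expect_equal(r$slope, 0.548, tolerance = 1e-12)
  expect_equal(r$intercept, -0.111, tolerance = 1e-12)
  expect_equal(unname(diff(r$slope_ci)), 0, tolerance = 1e-9)
  expect_error(fit_heading_regression(
    data.frame(simulated = rep(5, 4), perceived = rnorm(4))), "distinct")
})

test_that("pooled OLS matches the closed-form normal-equations oracle", {
  set.seed(31)
  for (rep in 1:5) {
    x <- sample(c(-10, -5, 0, 5, 10), 60, replace = TRUE)
    y <- 0.6 * x + rnorm(60, 0, 2)
    r <- fit_heading_regression(data.frame(simulated = x, perceived = y))
    # independent oracle: normal equations and normal-theory CIs
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    s2 <- sum((y - a - b * x)^2) / (n - 2)
    se_b <- sqrt(s2 / sxx)
    se_a <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
    tq <- qt(0.975, n - 2)
    expect_equal(r$slope, b, tolerance = 1e-10)
    expect_equal(r$intercept, a, tolerance = 1e-10)
    expect_equal(r$slope_ci, c(b - tq * se_b, b + tq * se_b),
                 tolerance = 1e-10)
    expect_equal(r$intercept_ci, c(a - tq * se_a, a + tq * se_a),
                 tolerance = 1e-10)
  }
})

make_heading_log <- function(bias_fun, participants = paste0("p", 1:4),
                             seed = 1) {
  set.seed(seed)
  cam <- camera_model()
  sch <- build_heading_schedule(seed = seed)
  do.call(rbind, lapply(participants, function(pid) {
    perceived <- sch$heading_angle +
      bias_fun(sch$walker_condition, sch$walker_direction, pid)
    data.frame(sch, responder = pid,
               response = tan(perceived * pi / 180) * cam$viewing_distance)
  }))
}

test_that("mirror collapse signs biases by walker direction and is idempotent", {
  log <- make_heading_log(function(cond, dir, pid)
    ifelse(cond == "none", 0, ifelse(dir == "right", 2, -2)))
  col <- mirror_collapse(log)
  w <- col$walker_condition != "none"
  # rightward walker, perceived - simulated = +2 -> bias +2;
  # leftward walker, perceived - simulated = -2 -> bias +2 as well
  expect_equal(col$bias[w], rep(2, sum(w)), tolerance = 1e-9)
  expect_equal(col$bias[!w], rep(0, sum(!w)), tolerance = 1e-9)
  expect_equal(mirror_collapse(col)$bias, col$bias)
})

test_that("collapsed mean equals the half-difference of raw side means", {
  set.seed(33)
  log <- make_heading_log(function(cond, dir, pid)
    rnorm(length(cond), ifelse(dir == "right", 1, -0.5), 0.5))
  col <- mirror_collapse(log)
  w <- col$walker_condition != "none"
  err <- col$perceived - col$heading_angle
  m_r <- mean(err[w & col$walker_direction == "right"])
  m_l <- mean(err[w & col$walker_direction == "left"])
  # left/right balanced design: collapsed mean = (mean_R - mean_L) / 2
  expect_equal(mean(col$bias[w]), (m_r - m_l) / 2, tolerance = 1e-9)
})

test_that("bias summary aggregates within participants first", {
  log <- make_heading_log(function(cond, dir, pid) {
    base <- c(p1 = 1.0, p2 = 1.5, p3 = 2.0, p4 = 2.5)[pid]
    ifelse(cond == "none", 0, ifelse(dir == "right", base, -base))
  })
  col <- mirror_collapse(log)
  sm <- suppressWarnings(condition_bias_summary(col))
  expect_equal(sort(unique(round(sm$table$mean, 9))), 1.75)
  expect_equal(colMeans(sm$participant_means),
               setNames(rep(1.75, 6), colnames(sm$participant_means)))
})

test_that("bias summary CIs follow the t distribution (parameter recovery)", {
  set.seed(34)
  true_bias <- 1.3
  log <- make_heading_log(function(cond, dir, pid)
    ifelse(cond == "none", 0,
           ifelse(dir == "right", 1, -1) * rnorm(length(cond), true_bias, 2)),
    participants = paste0("p", 1:12), seed = 34)
  col <- mirror_collapse(log)
  sm <- condition_bias_summary(
    col, paired = list(c("equidistant:congruent_with_walker",
                         "equidistant:incongruent_with_walker")))
  # closed-form CI half width from the participant means
  for (j in seq_len(ncol(sm$participant_means))) {
    v <- sm$participant_means[, j]
    hw <- qt(0.975, 11) * sd(v) / sqrt(12)
    row <- sm$table[j, ]
    expect_equal(row$ci_hi - row$ci_lo, 2 * hw, tolerance = 1e-10)
    tt <- t.test(v)
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
  expect_equal(nrow(sm$paired), 1L)
  # recovered grand means sit near the programmed bias
  expect_lt(max(abs(sm$table$mean - true_bias)), 1)
})

test_that("degenerate zero-variance biases are flagged", {
  log <- make_heading_log(function(cond, dir, pid)
    ifelse(cond == "none", 0, ifelse(dir == "right", 1, -1)))
  col <- mirror_collapse(log)
  w <- capture_warnings(sm <- condition_bias_summary(col))
  expect_true(length(w) > 0 && all(grepl("degenerate", w)))
  expect_true(all(is.infinite(sm$table$t)))
  # and all-zero biases give mean 0, t 0
  log0 <- make_heading_log(function(cond, dir, pid) 0)
  w0 <- capture_warnings(sm0 <- condition_bias_summary(mirror_collapse(log0)))
  expect_true(all(grepl("degenerate", w0)))
  expect_equal(sm0$table$mean, rep(0, 6))
  expect_equal(sm0$table$t, rep(0, 6))
})

test_that("bias-summary CIs attain near-nominal coverage", {
  set.seed(35)
  hits <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    pm <- rnorm(12, 1.3, 1)
    col <- data.frame(responder = paste0("p", 1:12),
                      walker_condition = "cond", bias = pm)
    sm <- condition_bias_summary(col, conditions = "cond")
    hits <- hits + (sm$table$ci_lo <= 1.3 && 1.3 <= sm$table$ci_hi)
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("repeated-measures ANOVA handles forced epsilon bounds and null effects", {
  # two identical condition columns: no condition effect at all
  m <- cbind(a = rnorm(8), b = 0)
  m[, "b"] <- m[, "a"]
  r <- rm_anova_gg(m)
  expect_equal(r$F, 0)
  expect_equal(r$epsilon, 1)      # k = 2 forces epsilon = 1
  r2 <- rm_anova_gg(cbind(rnorm(10), rnorm(10)))
  expect_equal(r2$epsilon, 1)
  expect_error(rm_anova_gg(cbind(c(1, NA, 3), c(2, 3, 4))), "missing")
})

test_that("RM-ANOVA with GG correction matches the car mlm oracle to 1e-8", {
  skip_if_not_installed("car")
  set.seed(36)
  for (rep in 1:3) {
    m <- matrix(rnorm(12 * 7, sd = 2), 12, 7) +
      outer(rnorm(12, 0, 1.5), rep(1, 7)) +
      outer(rep(1, 12), rnorm(7, 0, 0.7))
    r <- rm_anova_gg(m)
    fit <- stats::lm(m ~ 1)
    idata <- data.frame(cond = factor(seq_len(ncol(m))))
    av <- suppressWarnings(
      summary(car::Anova(fit, idata = idata, idesign = ~cond),
              multivariate = FALSE))
    expect_equal(r$F, av$univariate.tests["cond", "F value"],
                 tolerance = 1e-8)
    expect_equal(r$epsilon, av$pval.adjustments["cond", "GG eps"],
                 tolerance = 1e-8)
    expect_equal(r$p, av$pval.adjustments["cond", "Pr(>F[GG])"],
                 tolerance = 1e-8)
    expect_equal(r$p_uncorrected, av$univariate.tests["cond", "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("proportion CIs reproduce the reported half-widths", {
  # 12 participants x 32 trials per condition
  expect_equal(proportion_ci(round(0.945 * 384), 384)$percent_half_width,
               2.3)
  expect_equal(proportion_ci(round(0.607 * 384), 384)$percent_half_width,
               4.9)
  expect_equal(proportion_ci(round(0.943 * 384), 384)$percent_half_width,
               2.3)
  expect_equal(proportion_ci(50, 100)$percent_half_width, 9.8)
  expect_equal(proportion_ci(384, 384)$half_width, 0)
  expect_error(proportion_ci(5, 0), "positive")
  expect_error(proportion_ci(-1, 10), "correct")
})

test_that("proportion CI width peaks at 0.5 and shrinks as 1/sqrt(n)", {
  n <- 200
  widths <- sapply(seq(0.05, 0.95, by = 0.05), function(p)
    proportion_ci(round(p * n), n)$half_width)
  expect_equal(which.max(widths), 10L)   # p = 0.5
  w1 <- proportion_ci(100, 200)$half_width
  w2 <- proportion_ci(200, 400)$half_width
  expect_equal(w1 / w2, sqrt(2), tolerance = 1e-12)
})
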