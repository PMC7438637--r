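#' Pooled linear regression of perceived on simulated heading
#'
#' Ordinary least squares over the accumulated no-walker trials of all
#' participants, with normal-theory 95% confidence intervals for slope and
#' intercept. A slope below 1 is the classic centre bias of heading
#' adjustment.
#'
#' @param log A heading session log (see [read_session_log()]); only
#'   no-walker trials are used. Alternatively a data.frame with numeric
#'   columns `simulated` and `perceived` (degrees).
#' @param cam A [camera_model()] used to convert screen responses to
#'   degrees when `log` is a session log.
#' @return A list of class `heading_regression`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci` (95%), `n`, and the underlying `lm` fit.
#' @export
fit_heading_regression <- function(log, cam = camera_model()) {
  if (all(c("simulated", "perceived") %in% names(log))) {
    d <- log[, c("simulated", "perceived")]
  } else {
    d <- data.frame(simulated = log$heading_angle,
                    perceived = screen_x_to_heading(log$response, cam))
    d <- d[log$walker_condition == "none", ]
  }
  if (length(unique(d$simulated)) < 2L)
    stop("need at least two distinct simulated headings")
  fit <- stats::lm(perceived ~ simulated, data = d)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_ci = unname(ci[2L, ]),
                 intercept_ci = unname(ci[1L, ]),
                 n = nrow(d), fit = fit),
            class = "heading_regression")
}

#' @export
print.heading_regression <- function(x, ...) {
  cat(sprintf(
    "heading regression (n=%d): slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f] deg\n",
    x$n, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Collapse mirror-symmetric heading trials into signed biases
#'
#' A stimulus with heading -h and a leftward walker is equivalent, by mirror
#' symmetry, to heading +h with a rightward walker. Each walker trial is
#' therefore reduced to `bias = s * (perceived - simulated)` with `s = +1`
#' for rightward and `-1` for leftward walkers: positive bias means a bias
#' in the walker's motion direction. No-walker trials pass through with the
#' unsigned error.
#'
#' @param log A heading session log.
#' @param cam A [camera_model()].
#' @return The log with added columns `perceived` (deg) and `bias` (deg).
#' @export
mirror_collapse <- function(log, cam = camera_model()) {
  if (!all(c("walker_condition", "walker_direction", "heading_angle",
             "response") %in% names(log)))
    stop("not a heading session log")
  perceived <- screen_x_to_heading(log$response, cam)
  s <- ifelse(log$walker_direction == "right", 1, -1)
  s[log$walker_condition == "none"] <- 1
  log$perceived <- perceived
  log$bias <- s * (perceived - log$heading_angle)
  log
}

#' Per-condition heading-bias summary
#'
#' Averages biases within participant and condition, then across
#' participants, with a t-based 95% confidence interval and a one-sample
#' t test against zero per condition; optional paired t tests between
#' named conditions.
#'
#' @param collapsed Output of [mirror_collapse()].
#' @param conditions Conditions to summarize (default: all walker
#'   conditions present).
#' @param paired List of length-2 character vectors naming condition pairs
#'   for paired t tests.
#' @return A list of class `bias_summary`: `table` (one row per condition:
#'   `condition`, `mean`, `ci_lo`, `ci_hi`, `t`, `p`, `n`),
#'   `participant_means` (participants x conditions matrix) and `paired`
#'   (data.frame of paired comparisons).
#' @export
condition_bias_summary <- function(collapsed, conditions = NULL,
                                   paired = list()) {
  if (is.null(conditions))
    conditions <- setdiff(unique(collapsed$walker_condition), "none")
  d <- collapsed[collapsed$walker_condition %in% conditions, ]
  participants <- sort(unique(d$responder))
  if (length(participants) < 2L) stop("need at least two participants")
  pm <- matrix(NA_real_, length(participants), length(conditions),
               dimnames = list(participants, conditions))
  for (i in seq_along(participants)) for (j in seq_along(conditions)) {
    b <- d$bias[d$responder == participants[i] &
                  d$walker_condition == conditions[j]]
    if (!length(b))
      stop(sprintf("participant %s has no trials in condition %s",
                   participants[i], conditions[j]))
    pm[i, j] <- mean(b)
  }
  n <- nrow(pm)
  tab <- do.call(rbind, lapply(seq_along(conditions), function(j) {
    m <- mean(pm[, j])
    se <- stats::sd(pm[, j]) / sqrt(n)
    if (se == 0) {
      warning("degenerate zero-variance biases in condition ",
              conditions[j])
      tt <- list(statistic = if (m == 0) 0 else sign(m) * Inf,
                 p.value = if (m == 0) 1 else 0)
      hw <- 0
    } else {
      tt <- stats::t.test(pm[, j])
      hw <- stats::qt(0.975, n - 1L) * se
    }
    data.frame(condition = conditions[j], mean = m, ci_lo = m - hw,
               ci_hi = m + hw, t = unname(tt$statistic),
               p = unname(tt$p.value), n = n)
  }))
  pt <- do.call(rbind, lapply(paired, function(pr) {
    tt <- stats::t.test(pm[, pr[1L]], pm[, pr[2L]], paired = TRUE)
    data.frame(condition_a = pr[1L], condition_b = pr[2L],
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               p = unname(tt$p.value))
  }))
  structure(list(table = tab, participant_means = pm, paired = pt),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("heading bias by condition (deg, + = toward walker motion):\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$paired) && nrow(x$paired)) {
    cat("paired comparisons:\n")
    print(x$paired, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject one-way ANOVA on a complete participants x
#' conditions matrix. Sphericity is corrected by the Greenhouse-Geisser
#' epsilon estimated from the double-centred sample covariance of the
#' conditions; the p value uses the epsilon-scaled degrees of freedom.
#'
#' @param m Numeric matrix, participants in rows, conditions in columns.
#' @return A list of class `rm_anova`: `F`, `df1`, `df2` (uncorrected),
#'   `epsilon`, `df1_gg`, `df2_gg`, `p` (GG-corrected) and `p_uncorrected`.
#' @export
rm_anova_gg <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells in the repeated-measures matrix")
  n <- nrow(m); k <- ncol(m)
  if (k < 2L || n < 2L) stop("need at least 2 participants and 2 conditions")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  # a literally null effect (identical columns) has 0/0: report F = 0
  F <- if (ms_cond == 0) 0 else ms_cond / ms_err
  S <- stats::cov(m)
  C <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k,
                                              byrow = TRUE) + mean(S)
  eps <- if (sum(C^2) > 0) sum(diag(C))^2 / (df1 * sum(C^2)) else 1
  eps <- min(1, max(eps, 1 / df1))
  structure(list(F = F, df1 = df1, df2 = df2, epsilon = eps,
                 df1_gg = eps * df1, df2_gg = eps * df2,
                 p = stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE),
                 p_uncorrected = stats::pf(F, df1, df2, lower.tail = FALSE)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "RM-ANOVA: F(%.3g, %.3g) = %.4g, GG epsilon = %.4g, p = %.4g\n",
    x$df1_gg, x$df2_gg, x$F, x$epsilon, x$p))
  invisible(x)
}

#' Normal-approximation confidence interval for a proportion
#'
#' `p_hat +/- 1.96 * sqrt(p_hat * (1 - p_hat) / n)`, the Wald interval used
#' to report percent-correct results.
#'
#' @param correct Number of correct responses.
#' @param n Number of trials.
#' @return A list of class `proportion_ci`: `p` (proportion correct), `n`,
#'   `half_width`, and `percent` / `percent_half_width` rounded half-up to
#'   one decimal as reported in text.
#' @export
proportion_ci <- function(correct, n) {
  if (n <= 0) stop("n must be positive")
  if (correct < 0 || correct > n) stop("correct must be in [0, n]")
  p <- correct / n
  hw <- 1.96 * sqrt(p * (1 - p) / n)
  structure(list(p = p, n = n, half_width = hw,
                 percent = round_half_up(100 * p, 1L),
                 percent_half_width = round_half_up(100 * hw, 1L)),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.1f%% +/- %.1f%% correct (n = %d)\n",
              x$percent, x$percent_half_width, x$n))
  invisible(x)
}

# round half away from zero, as in reported percentages
round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Percent-correct summary of a choice experiment
#'
#' Collapses a facing or articulation log across participants, facings and
#' articulation cases, per walker condition, and attaches the
#' normal-approximation 95% interval.
#'
#' @param log A facing/articulation session log.
#' @return A data.frame with one row per walker condition: `condition`,
#'   `correct`, `n`, `percent`, `percent_half_width`.
#' @export
choice_accuracy_summary <- function(log) {
  exps <- unique(log$experiment)
  if (length(exps) != 1L || !exps %in% c("facing", "articulation"))
    stop("not a facing/articulation log")
  truth <- if (exps == "facing") log$walker_direction else log$articulation
  ok <- log$response == truth
  conds <- walker_conditions()
  do.call(rbind, lapply(conds, function(cn) {
    i <- log$walker_condition == cn
    ci <- proportion_ci(sum(ok[i]), sum(i))
    data.frame(condition = cn, correct = sum(ok[i]), n = sum(i),
               percent = ci$percent,
               percent_half_width = ci$percent_half_width)
  }))
}
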