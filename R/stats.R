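#' Two-sample t statistic for token means
#'
#' The screening statistic: for species *i* with control ensemble mean and
#' variance \eqn{\mu_{i,c}, \sigma^2_{i,c}} and perturbed
#' \eqn{\mu_{i,p}, \sigma^2_{i,p}}, each over `n` runs,
#' \deqn{t_i = \frac{\mu_{i,c} - \mu_{i,p}}
#'                  {\sqrt{\sigma^2_{i,c}/n + \sigma^2_{i,p}/n}}.}
#' The sign convention is control minus perturbed. When both variances are
#' zero the statistic is 0 for equal means and signed infinity otherwise
#' (callers flag, never drop, such species).
#'
#' @param mean_c,var_c control ensemble mean and variance (vectorised).
#' @param mean_p,var_p perturbed ensemble mean and variance.
#' @param n number of runs per ensemble (at least 2).
#' @return Signed t values, same length as the inputs.
#' @export
t_value <- function(mean_c, var_c, mean_p, var_p, n) {
  stopifnot(n >= 2, all(var_c >= 0), all(var_p >= 0))
  num <- mean_c - mean_p
  den <- sqrt(var_c / n + var_p / n)
  out <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf), num / den)
  as.numeric(out)
}

#' Two-sided p value for a t statistic
#'
#' @param t t statistic (vectorised).
#' @param df degrees of freedom (default `998`, i.e. `2n - 2` for the
#'   two-ensemble comparison at `n = 500` runs).
#' @return Two-sided tail probabilities in `[0, 1]`.
#' @export
p_value <- function(t, df = 998) {
  stopifnot(df >= 1)
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Two-sided critical value of the t distribution
#'
#' The upper `1 - alpha/2` quantile: `critical_value(0.05, 500)` is 1.965 to
#' three decimals, the threshold the significance call compares `|t|`
#' against.
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom.
#' @return The positive critical value.
#' @export
critical_value <- function(alpha = 0.05, df = 500) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  stats::qt(1 - alpha / 2, df = df)
}

#' Configuration of the perturbation screen
#'
#' @param alpha nominal significance level.
#' @param critical_value threshold for the significance call on `|t|`;
#'   default 1.965, the two-sided 5% critical value at 500 degrees of
#'   freedom. Set to `NULL` to derive it as
#'   [critical_value()]`(alpha, df_for_p)`.
#' @param df_for_p degrees of freedom for p values; `NULL` (default) uses
#'   `2 * n_runs - 2`.
#' @param active_only when `TRUE` (default), species annotated `inactive`
#'   are excluded from the reported table (they remain in the raw result).
#' @param bonferroni apply a Bonferroni correction to the significance
#'   threshold (off by default: each `|t|` is compared directly to the
#'   critical value).
#' @return An object of class `spn_test_config`.
#' @export
test_config <- function(alpha = 0.05, critical_value = 1.965,
                        df_for_p = NULL, active_only = TRUE,
                        bonferroni = FALSE) {
  stopifnot(alpha > 0, alpha < 1,
            is.null(critical_value) || critical_value > 0)
  structure(
    list(alpha = alpha, critical_value = critical_value,
         df_for_p = df_for_p, active_only = active_only,
         bonferroni = bonferroni),
    class = "spn_test_config"
  )
}

#' Screen species for significant perturbation response
#'
#' Compares two ensembles at the final simulated time point (the most stable
#' one): per species, the control and perturbed means, the signed
#' [t_value()], the two-sided [p_value()], and the significance flag
#' `|t| > critical value`. Species with zero variance in both ensembles and
#' unequal means receive infinite `|t|` and are flagged in the
#' `degenerate` column rather than dropped.
#'
#' @param control,perturbed `spn_trajectory` summaries sharing species set,
#'   number of runs and number of time points.
#' @param net the [signaling_network()] the ensembles were simulated on
#'   (supplies names and active/inactive annotation); optional.
#' @param test an [test_config()].
#' @return An object of class `spn_screen`: a data.frame with one row per
#'   species (`id`, `name`, `state`, `mean_control`, `mean_perturbed`,
#'   `delta`, `t_value`, `abs_t`, `p_value`, `significant`, `degenerate`,
#'   `reported`), with the test configuration attached as attribute
#'   `"test"`. `reported` is `FALSE` for inactive species under
#'   `active_only`.
#' @export
screen_perturbation <- function(control, perturbed, net = NULL,
                                test = test_config()) {
  stopifnot(inherits(control, "spn_trajectory"),
            inherits(perturbed, "spn_trajectory"),
            inherits(test, "spn_test_config"))
  if (!identical(rownames(control$mean), rownames(perturbed$mean))) {
    stop("control and perturbed ensembles cover different species sets")
  }
  if (control$n_runs != perturbed$n_runs) {
    stop("control and perturbed ensembles have different numbers of runs")
  }
  if (ncol(control$mean) != ncol(perturbed$mean)) {
    stop("control and perturbed ensembles have different time spans")
  }
  n <- control$n_runs
  fc <- final_timepoint(control)
  fp <- final_timepoint(perturbed)
  tv <- t_value(fc$mean, fc$variance, fp$mean, fp$variance, n)
  df <- test$df_for_p %||% (2L * n - 2L)
  crit <- test$critical_value %||% critical_value(test$alpha, df)
  if (test$bonferroni) {
    crit <- critical_value(test$alpha / length(tv), df)
  }
  pv <- p_value(tv, df)

  ids <- fc$id
  if (!is.null(net)) {
    m <- match(ids, net$species$id)
    name <- net$species$name[m]
    state <- net$species$state[m]
  } else {
    name <- ids
    state <- rep("unspecified", length(ids))
  }
  res <- data.frame(
    id = ids, name = name, state = state,
    mean_control = fc$mean, mean_perturbed = fp$mean,
    delta = fp$mean - fc$mean,
    t_value = tv, abs_t = abs(tv), p_value = pv,
    significant = abs(tv) > crit,
    degenerate = !is.finite(tv),
    reported = !(test$active_only & state == "inactive"),
    stringsAsFactors = FALSE
  )
  attr(res, "test") <- test
  attr(res, "df") <- df
  attr(res, "critical") <- crit
  attr(res, "n_runs") <- n
  class(res) <- c("spn_screen", "data.frame")
  res
}

#' @export
print.spn_screen <- function(x, digits = 3, ...) {
  crit <- attr(x, "critical")
  rep <- x[x$reported, , drop = FALSE]
  cat(sprintf(
    "Perturbation screen: %d species (%d reported), |t| > %.3f, df = %d\n",
    nrow(x), nrow(rep), crit, attr(x, "df")))
  sig <- rep[rep$significant, , drop = FALSE]
  cat(sprintf("  significant: %d of %d\n", nrow(sig), nrow(rep)))
  show <- rep[order(-rep$abs_t), c("name", "mean_control", "mean_perturbed",
                                   "abs_t", "p_value", "significant")]
  print(utils::head(format(show, digits = digits), 10), row.names = FALSE)
  invisible(x)
}

#' Format p values in report style
#'
#' Values below `10^-floor` render as `"<0.001"` (for `floor = 3`), others
#' to `floor` decimals.
#'
#' @param p numeric p values.
#' @param floor number of decimals; default 3.
#' @return Character vector.
#' @export
format_p <- function(p, floor = 3) {
  cut <- 10^(-floor)
  ifelse(p < cut, sprintf("<%s", format(cut, scientific = FALSE)),
         formatC(p, digits = floor, format = "f"))
}

#' Build the combined results table for both perturbation scenarios
#'
#' One row per reported species: the control, up-regulated and down-regulated
#' ensemble means at the final time point, and the absolute t value with p
#' value for each perturbation against control. Rows are sorted by species
#' name.
#'
#' @param up screen of the up-regulation scenario against control.
#' @param down screen of the down-regulation scenario against control.
#' @param formatted when `TRUE`, return display-style columns `"|t| (p)"`
#'   with small p values rendered `"<0.001"`; when `FALSE` (default), raw
#'   numeric columns.
#' @return data.frame with columns `name`, `mean_control`, `mean_up`,
#'   `mean_down`, then either raw `t_up`, `p_up`, `t_down`, `p_down`,
#'   `sig_up`, `sig_down` or the formatted equivalents.
#' @export
results_table <- function(up, down, formatted = FALSE) {
  stopifnot(inherits(up, "spn_screen"), inherits(down, "spn_screen"))
  if (!identical(up$id, down$id)) {
    stop("up and down screens cover different species sets")
  }
  if (!isTRUE(all.equal(up$mean_control, down$mean_control))) {
    stop("up and down screens were made against different control ensembles")
  }
  keep <- up$reported & down$reported
  u <- up[keep, , drop = FALSE]
  d <- down[keep, , drop = FALSE]
  out <- data.frame(
    name = u$name,
    mean_control = u$mean_control,
    mean_up = u$mean_perturbed,
    mean_down = d$mean_perturbed,
    t_up = u$abs_t, p_up = u$p_value, sig_up = u$significant,
    t_down = d$abs_t, p_down = d$p_value, sig_down = d$significant,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  if (formatted) {
    fmt <- data.frame(
      name = out$name,
      mean_control = sprintf("%.2f", out$mean_control),
      mean_up = sprintf("%.2f", out$mean_up),
      mean_down = sprintf("%.2f", out$mean_down),
      t_p_up = sprintf("%.2f (%s)", out$t_up, format_p(out$p_up)),
      t_p_down = sprintf("%.2f (%s)", out$t_down, format_p(out$p_down)),
      stringsAsFactors = FALSE
    )
    return(fmt)
  }
  out
}
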