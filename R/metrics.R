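#' Build a 2x2 contingency table from predictions
#'
#' Tabulates binary classifier decisions against true labels in
#' signal-detection form. The positive class (label 1: "word" for the
#' lexicality head, "highly-skilled" for the group head) is treated as the
#' signal, so cells are hits (true 1, predicted 1), misses (true 1, predicted
#' 0), false alarms (true 0, predicted 1) and correct rejections.
#'
#' @param truth Integer vector of true labels (0/1).
#' @param predicted Integer vector of predicted labels (0/1).
#' @return An object of class `contingency_table`: a list with `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`, `n`.
#' @export
contingency_table <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop_input("labels must be 0/1")
  out <- list(
    hits = sum(truth == 1 & predicted == 1),
    misses = sum(truth == 1 & predicted == 0),
    false_alarms = sum(truth == 0 & predicted == 1),
    correct_rejections = sum(truth == 0 & predicted == 0),
    n = length(truth)
  )
  class(out) <- "contingency_table"
  out
}

#' Signal-detection sensitivity (d-prime) of a contingency table
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with `z` the standard-normal
#' quantile. Extreme rates of exactly 0 or 1 are replaced by `1/(2n)` and
#' `1 - 1/(2n)` respectively, where `n` is the number of trials in the
#' relevant margin, so that d-prime remains finite at ceiling performance.
#'
#' @param table A [contingency_table()].
#' @return A single numeric d-prime value.
#' @export
#' @examples
#' tb <- contingency_table(rep(c(1, 0), each = 50),
#'                         rep(c(1, 0, 1, 0), c(42, 8, 8, 42)))
#' dprime(tb)  # 2 * qnorm(0.84)
dprime <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  n_sig <- table$hits + table$misses
  n_noise <- table$false_alarms + table$correct_rejections
  if (n_sig == 0 || n_noise == 0)
    stop_input("d-prime undefined: an empty signal or noise margin")
  hr <- clamp_rate(table$hits / n_sig, n_sig)
  far <- clamp_rate(table$false_alarms / n_noise, n_noise)
  qnorm(hr) - qnorm(far)
}

clamp_rate <- function(rate, n) {
  if (rate <= 0) return(1 / (2 * n))
  if (rate >= 1) return(1 - 1 / (2 * n))
  rate
}

#' Phi coefficient of a contingency table
#'
#' The phi coefficient `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` equals the
#' Pearson correlation between the two underlying binary label vectors.
#'
#' @param table A [contingency_table()].
#' @return Numeric in `[-1, 1]`.
#' @export
phi_coefficient <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$hits; b <- table$misses
  c_ <- table$false_alarms; d <- table$correct_rejections
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0))
    stop_input("phi undefined: a zero margin in the contingency table")
  (a * d - b * c_) / sqrt(prod(margins))
}

#' Chi-squared goodness-of-fit test of accuracy against chance
#'
#' One-degree-of-freedom test of the observed correct/incorrect split against
#' the 50/50 split expected by chance, with no continuity correction.
#'
#' @param n_correct Number of correct decisions.
#' @param n_total Total number of decisions.
#' @return A list with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_vs_chance(60, 100)  # statistic 4, p ~ 0.0455
chi_square_vs_chance <- function(n_correct, n_total) {
  stopifnot(n_total >= 1)
  if (n_correct > n_total || n_correct < 0)
    stop_input("n_correct must lie in [0, n_total]")
  expected <- n_total / 2
  stat <- (n_correct - expected)^2 / expected +
    ((n_total - n_correct) - expected)^2 / expected
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Collapse a contingency table into the standard metric set
#'
#' @param table A [contingency_table()].
#' @return A list with `accuracy`, `d_prime`, `phi`, `chi_square`, `p_value`,
#'   and `n`.
#' @export
classification_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  correct <- table$hits + table$correct_rejections
  chi <- chi_square_vs_chance(correct, table$n)
  phi <- tryCatch(phi_coefficient(table), error = function(e) NA_real_)
  list(accuracy = correct / table$n,
       d_prime = dprime(table),
       phi = phi,
       chi_square = chi$statistic,
       p_value = chi$p_value,
       n = table$n)
}

#' Summarise a metric across model families
#'
#' Computes the per-metric mean, standard deviation and two-sided t-based 95%
#' confidence interval across families, plus the Pearson correlation between
#' paired per-family group and lexicality d-prime values when both are
#' supplied.
#'
#' @param metrics A data.frame with one row per family and numeric metric
#'   columns (e.g. `group_d_prime`, `lex_d_prime`, `group_accuracy`, ...).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list with `summary` (data.frame: metric, mean, sd, ci_lower,
#'   ci_upper, n) and `d_prime_correlation` (NA unless both `group_d_prime`
#'   and `lex_d_prime` columns are present).
#' @export
summarize_families <- function(metrics, conf_level = 0.95) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) < 2)
    stop_input("at least 2 families are required to summarise")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  rows <- lapply(num_cols, function(nm) {
    x <- metrics[[nm]]
    n <- sum(is.finite(x))
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    half <- if (n >= 2) qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n) else NA_real_
    data.frame(metric = nm, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half, n = n)
  })
  summary <- do.call(rbind, rows)
  dcor <- NA_real_
  if (all(c("group_d_prime", "lex_d_prime") %in% names(metrics)) &&
      sd(metrics$group_d_prime) > 0 && sd(metrics$lex_d_prime) > 0) {
    dcor <- cor(metrics$group_d_prime, metrics$lex_d_prime)
  }
  list(summary = summary, d_prime_correlation = dcor)
}
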