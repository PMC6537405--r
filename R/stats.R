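#' Welch's unequal-variance two-sample t test
#'
#' Row-wise comparisons between groups are made without assuming a
#' consistent SD: the Welch statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. When both groups are constant and
#' equal, `p = 1` by convention.
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @return list with `t_stat`, `df`, `p_raw`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b))
      return(list(t_stat = 0, df = na + nb - 2, p_raw = 1))
    return(list(t_stat = sign(mean(a) - mean(b)) * Inf,
                df = na + nb - 2, p_raw = 0))
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  list(t_stat = t_stat, df = df,
       p_raw = 2 * stats::pt(-abs(t_stat), df))
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' P values are sorted ascending and adjusted as
#' `1 - (1 - p_(i))^(m - i + 1)` with a running maximum to enforce
#' monotonicity; the step-down stopping rule marks a hypothesis significant
#' only while every earlier (smaller) adjusted p is also below `alpha`.
#' Results are returned in the input order.
#'
#' @param p_values raw p values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return data frame with `p_raw`, `p_adjusted`, `significant` in input
#'   order.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  k <- m - seq_len(m) + 1
  adj <- ifelse(k == 1L, ps, 1 - (1 - ps)^k)  # k = 1 is exactly p
  adj <- cummax(adj)
  sig <- cumprod(adj <= alpha) > 0   # step-down: stop at first failure
  out <- data.frame(p_raw = p_values,
                    p_adjusted = numeric(m),
                    significant = logical(m))
  out$p_adjusted[ord] <- adj
  out$significant[ord] <- sig
  out
}

#' Star annotation for adjusted p values
#'
#' `p < 0.05` gives `*`, `< 0.005` `**`, `< 0.0005` `***`, otherwise `ns`.
#'
#' @param p numeric vector of (adjusted) p values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.0005, "***",
         ifelse(p < 0.005, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Row-wise group comparison with Holm-Sidak correction
#'
#' Runs [welch_t()] on each labeled row (e.g. each dose level) between two
#' groups of per-repeat scores, then adjusts the family of p values with
#' [holm_sidak()] and annotates stars.
#'
#' @param values_a,values_b named lists of numeric vectors; names are the
#'   row labels and must match.
#' @param alpha family-wise error rate.
#' @return data frame of class `comparison_table` with one row per label:
#'   `label`, `mean_a`, `mean_b`, `t_stat`, `df`, `p_raw`, `p_adjusted`,
#'   `significant`, `stars`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(is.list(values_a), is.list(values_b))
  labels <- names(values_a)
  if (!identical(sort(labels), sort(names(values_b))))
    stop("group labels do not match")
  rows <- lapply(labels, function(lb) {
    w <- welch_t(values_a[[lb]], values_b[[lb]])
    data.frame(label = lb,
               mean_a = mean(values_a[[lb]]), mean_b = mean(values_b[[lb]]),
               t_stat = w$t_stat, df = w$df, p_raw = w$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  hs <- holm_sidak(out$p_raw, alpha)
  out$p_adjusted <- hs$p_adjusted
  out$significant <- hs$significant
  out$stars <- significance_stars(out$p_adjusted)
  class(out) <- c("comparison_table", "data.frame")
  out
}
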