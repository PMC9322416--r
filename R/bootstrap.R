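#' Bias-corrected accelerated (BCa) bootstrap
#'
#' Nonparametric BCa confidence intervals for decomposition statistics. The
#' resampling unit is always the male: each bootstrap replicate draws whole
#' male life histories with replacement and recomputes the statistic in
#' full, so standardized quantities are re-standardized inside every
#' replicate (the mean in the denominator is resampled jointly with the
#' variance). The bias correction `z0` counts replicates strictly below the
#' observed value (ties excluded); the acceleration `a` comes from the
#' jackknife skewness formula; quantiles are read off the empirical
#' replicate distribution by order statistics with linear interpolation
#' (R's default type-7 convention).
#'
#' @name bca-bootstrap
#' @keywords internal
NULL

#' BCa-adjusted quantile levels
#'
#' Maps nominal quantile levels `alpha` to the BCa-adjusted levels
#' `pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))`. With
#' `z0 = 0` and `a = 0` this is the identity, so the interval reduces to
#' the percentile interval.
#'
#' @param z0 bias-correction constant.
#' @param a acceleration constant.
#' @param alpha nominal quantile levels.
#' @return adjusted quantile levels.
#' @export
bca_alpha <- function(z0, a, alpha) {
  z <- stats::qnorm(alpha)
  stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
}

# acceleration from leave-one-out statistics
.jackknife_a <- function(theta_jack) {
  theta_jack <- theta_jack[!is.na(theta_jack)]
  if (length(theta_jack) < 2L) return(0)
  d <- mean(theta_jack) - theta_jack
  denom <- sum(d^2)^1.5
  if (denom == 0) return(0)
  sum(d^3) / (6 * denom)
}

#' BCa confidence intervals by resampling males
#'
#' @param data a data.frame of per-male rows, an `age_matrix`, or an atomic
#'   vector (one value per male).
#' @param statistic function of a resampled `data` returning a (possibly
#'   named) numeric vector; all statistics share the resamples.
#' @param B number of bootstrap replicates.
#' @param ci_level confidence level (default 0.95).
#' @param seed optional integer seed for reproducible resampling.
#' @param ... further arguments passed to `statistic`.
#' @return a `bootstrap_result` data.frame with one row per statistic:
#'   `statistic`, `observed`, `B`, `ci_level`, `lower`, `upper`, `z0`, `a`,
#'   and `fallback` (`TRUE` where all replicates fell on one side of the
#'   observed value and the plain percentile interval was used instead).
#' @examples
#' bca_interval(c(1, 2, 3), mean, B = 999, seed = 1)
#' @export
bca_interval <- function(data, statistic, B = 10000L, ci_level = 0.95,
                         seed = NULL, ...) {
  n <- if (inherits(data, "age_matrix")) length(data$male_ids)
       else if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2L) stop("need at least 2 males")
  if (B < 1L) stop("B must be >= 1")
  take <- function(idx) {
    if (inherits(data, "age_matrix")) subset_age_matrix(data, idx)
    else if (is.data.frame(data)) data[idx, , drop = FALSE]
    else data[idx]
  }
  t0 <- statistic(data, ...)
  K <- length(t0)
  labels <- if (!is.null(names(t0))) names(t0) else
    paste0("stat", seq_len(K))
  if (!is.null(seed)) set.seed(seed)
  safe_stat <- function(d) {
    tryCatch(statistic(d, ...), error = function(e) rep(NA_real_, K))
  }
  t_boot <- matrix(NA_real_, B, K)
  for (b in seq_len(B)) {
    t_boot[b, ] <- safe_stat(take(sample.int(n, n, replace = TRUE)))
  }
  t_jack <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    t_jack[i, ] <- safe_stat(take(seq_len(n)[-i]))
  }
  alpha <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  out <- data.frame(statistic = labels, observed = unname(t0), B = B,
                    ci_level = ci_level, lower = NA_real_, upper = NA_real_,
                    z0 = NA_real_, a = NA_real_, fallback = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    tb <- t_boot[, k]
    tb <- tb[!is.na(tb)]
    B_eff <- length(tb)
    if (B_eff == 0L || is.na(t0[k])) next
    if (all(tb == tb[1L])) {             # degenerate: point interval
      out$lower[k] <- tb[1L]
      out$upper[k] <- tb[1L]
      out$z0[k] <- 0
      out$a[k] <- 0
      next
    }
    n_below <- sum(tb < t0[k])
    a_k <- .jackknife_a(t_jack[, k])
    if (n_below == 0L || n_below == B_eff) {
      warning("all bootstrap replicates on one side of the observed ",
              "value for `", labels[k], "`; percentile fallback used")
      q <- stats::quantile(tb, alpha, names = FALSE, type = 7)
      out$fallback[k] <- TRUE
      out$z0[k] <- NA_real_
      out$a[k] <- a_k
    } else {
      z0_k <- stats::qnorm(n_below / B_eff)
      adj <- bca_alpha(z0_k, a_k, alpha)
      q <- stats::quantile(tb, adj, names = FALSE, type = 7)
      out$z0[k] <- z0_k
      out$a[k] <- a_k
    }
    out$lower[k] <- q[1L]
    out$upper[k] <- q[2L]
  }
  class(out) <- c("bootstrap_result", "data.frame")
  out
}

#' Non-overlap significance rule for two confidence intervals
#'
#' Two values are called significantly different when their confidence
#' intervals do not overlap; intervals that merely touch at a boundary
#' count as overlapping (not significant).
#'
#' @param interval_1,interval_2 numeric length-2 vectors `(lower, upper)`.
#' @return `TRUE` if the intervals are disjoint (significant difference).
#' @examples
#' overlap_significance(c(1.54, 3.04), c(1.39, 2.38))  # FALSE: they overlap
#' overlap_significance(c(0, 1), c(2, 3))              # TRUE
#' @export
overlap_significance <- function(interval_1, interval_2) {
  stopifnot(length(interval_1) == 2L, length(interval_2) == 2L,
            !anyNA(interval_1), !anyNA(interval_2),
            interval_1[1] <= interval_1[2], interval_2[1] <= interval_2[2])
  interval_1[2] < interval_2[1] || interval_2[2] < interval_1[1]
}

# rebuild the standardized column of a partition from resampled data;
# used to decorate whole tables with one shared set of resamples
.table_statistic <- function(tab) {
  method <- attr(tab, "method")
  standardize_by <- attr(tab, "standardize_by")
  denom <- attr(tab, "denom")
  switch(method,
    lifetime = function(d) {
      lifetime_partition(d, standardize_by = standardize_by,
                         denom = denom)$standardized
    },
    additive = function(d) {
      additive_partition(d, standardize_by = standardize_by,
                         denom = denom)$standardized
    },
    independent = function(d) {
      independent_partition(d, standardize = standardize_by == "within-age",
                            denom = denom)$standardized
    },
    stop("cannot bootstrap a `", method, "` table")
  )
}

#' Attach BCa confidence intervals to a decomposition table
#'
#' Re-runs the full partition (including standardization) inside every
#' bootstrap replicate of males and adds `lower` and `upper` columns for
#' the standardized values, plus a `ci_fallback` flag.
#'
#' @param tab a `decomposition_table` from [lifetime_partition()],
#'   [additive_partition()] or [independent_partition()].
#' @param data the per-male data the table was computed from: the lifetime
#'   summary data.frame for a lifetime table, or the corresponding
#'   `age_matrix` otherwise.
#' @param B number of bootstrap replicates.
#' @param ci_level confidence level.
#' @param seed integer seed for reproducible intervals.
#' @return `tab` with `lower`, `upper` and `ci_fallback` columns.
#' @export
decorate_table <- function(tab, data, B = 2000L, ci_level = 0.95,
                           seed = NULL) {
  stat <- .table_statistic(tab)
  res <- suppressWarnings(
    bca_interval(data, stat, B = B, ci_level = ci_level, seed = seed)
  )
  stopifnot(nrow(res) == nrow(tab))
  tab$lower <- res$lower
  tab$upper <- res$upper
  tab$ci_fallback <- res$fallback
  tab
}
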