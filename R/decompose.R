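#' Variance decomposition of lifetime reproductive success
#'
#' The opportunity for selection is the mean-standardized variance in
#' reproductive success, var(RS) / mean(RS)^2. Because lifetime RS is the
#' sum of lifetime extra-group (EGP) and within-group (WGP) paternity,
#'
#'   var(LRS) = var(LEGP) + var(LWGP) + 2 cov(LEGP, LWGP),
#'
#' and, with zero-padding of dead males, the lifetime variance further
#' splits into age-specific variances and within- and between-age
#' covariances of the age-specific EGP and WGP counts. These functions
#' compute the lifetime partition, the additive age-specific partition, and
#' the survivor-only ("independent") per-age partition.
#'
#' @name variance-decomposition
#' @keywords internal
NULL

# (co)variance with selectable denominator; stats::cov uses n - 1
.cov_d <- function(x, y = x, denom = "n-1") {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  v <- stats::cov(x, y)
  if (denom == "n") v <- v * (n - 1) / n
  v
}

.new_decomposition_table <- function(rows, method, standardize_by, denom,
                                     means) {
  rownames(rows) <- NULL
  structure(rows, class = c("decomposition_table", "data.frame"),
            method = method, standardize_by = standardize_by,
            denom = denom, means = means)
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat("decomposition_table (method =", attr(x, "method"),
      ", denominator =", attr(x, "denom"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}

# squared-mean denominators under the convention of `standardize_by`:
# genetic measures (EGP, WGP, RS) standardize by the RS mean, apparent by
# the RS_ap mean ("measure"); "rs" / "rs_ap" force a single denominator.
.std_denoms <- function(mean_rs, mean_rs_ap, standardize_by) {
  if (standardize_by == "none") return(NULL)
  pick <- function(measure_mean) {
    m <- switch(standardize_by,
                measure = measure_mean,
                rs = mean_rs,
                rs_ap = mean_rs_ap)
    if (!is.na(m) && m == 0) {
      stop("standardization requested but the mean is zero")
    }
    m^2
  }
  c(genetic = pick(mean_rs), apparent = pick(mean_rs_ap))
}

.apply_std <- function(rows, denoms) {
  if (is.null(denoms)) {
    rows$standardized <- rows$raw
    return(rows)
  }
  d <- ifelse(rows$component == "RS_ap", denoms[["apparent"]],
              denoms[["genetic"]])
  rows$standardized <- rows$raw / d
  rows
}

#' Partition the variance in lifetime reproductive success
#'
#' Splits var(LRS) into var(lifetime EGP), var(lifetime WGP) and twice their
#' covariance, and also reports var(LRS_ap) for the social ("apparent")
#' measure. Standardized values divide each term by a squared mean: under
#' the default `"measure"` convention the genetic terms are divided by
#' mean(LRS)^2 and the apparent term by mean(LRS_ap)^2.
#'
#' @param life per-male lifetime summaries from [aggregate_lifetime()].
#' @param standardize_by `"measure"` (default), `"rs"`, `"rs_ap"`, or
#'   `"none"`.
#' @param denom variance denominator convention, `"n-1"` (default) or `"n"`.
#' @return a `decomposition_table` with columns `component`, `term`,
#'   `level`, `age_i`, `age_j`, `mean`, `raw`, `standardized`, `percent`
#'   (share of the raw variance in LRS, or in LRS_ap for the apparent row)
#'   and `n`.
#' @examples
#' life <- data.frame(male_id = letters[1:4], cohort_year = 2000L,
#'                    lifespan_class = 1L, age_first_dominance = 1L,
#'                    lifetime_egp = c(0, 1, 2, 1),
#'                    lifetime_wgp = c(0, 1, 0, 3),
#'                    lifetime_rs = c(0, 2, 2, 4),
#'                    lifetime_rs_ap = c(0, 1, 0, 3))
#' lifetime_partition(life)
#' @export
lifetime_partition <- function(life,
                               standardize_by = c("measure", "rs", "rs_ap",
                                                  "none"),
                               denom = c("n-1", "n")) {
  standardize_by <- match.arg(standardize_by)
  denom <- match.arg(denom)
  n <- nrow(life)
  if (n < 2L) stop("need at least 2 males")
  e <- life$lifetime_egp
  w <- life$lifetime_wgp
  rs <- life$lifetime_rs
  ap <- life$lifetime_rs_ap
  stopifnot(all(rs == e + w))
  rows <- data.frame(
    component = c("EGP", "WGP", "EGPxWGP", "RS", "RS_ap"),
    term = c("variance", "variance", "2cov", "variance", "variance"),
    level = "lifetime", age_i = NA_integer_, age_j = NA_integer_,
    mean = c(mean(e), mean(w), NA, mean(rs), mean(ap)),
    raw = c(.cov_d(e, denom = denom), .cov_d(w, denom = denom),
            2 * .cov_d(e, w, denom), .cov_d(rs, denom = denom),
            .cov_d(ap, denom = denom)),
    n = n, stringsAsFactors = FALSE
  )
  denoms <- .std_denoms(mean(rs), mean(ap), standardize_by)
  rows <- .apply_std(rows, denoms)
  var_rs <- rows$raw[rows$component == "RS"]
  var_ap <- rows$raw[rows$component == "RS_ap"]
  rows$percent <- ifelse(
    rows$component == "RS_ap",
    if (var_ap != 0) 100 * rows$raw / var_ap else NA_real_,
    if (var_rs != 0) 100 * rows$raw / var_rs else NA_real_
  )
  .new_decomposition_table(rows, "lifetime", standardize_by, denom,
                           c(rs = mean(rs), rs_ap = mean(ap)))
}

#' Additive age-specific partition of the variance in lifetime RS
#'
#' With dead males zero-padded ("additive method"), the variance in lifetime
#' RS decomposes exactly into per-age variances of age-specific RS and twice
#' the between-age covariances; each age-specific RS term further splits
#' into EGP and WGP variances and their within- and between-age
#' covariances. All terms are standardized by squared *lifetime* means, so
#' the standardized terms still sum to the standardized variance in LRS.
#' Cross-component between-age rows (`2cov(EGP_i, WGP_j)`) are emitted per
#' ordered pair `i != j`.
#'
#' @param mat an additive-mode [build_age_matrix()] result.
#' @inheritParams lifetime_partition
#' @return a `decomposition_table` with per-age rows (`level = "age"`),
#'   between-age rows (`level = "between_age"`), and the marginal sums
#'   (`level` `"sum_age_specific"`, `"sum_between_age"`) plus `"lifetime"`
#'   rows computed from the row sums of the matrix.
#' @export
additive_partition <- function(mat,
                               standardize_by = c("measure", "rs", "rs_ap",
                                                  "none"),
                               denom = c("n-1", "n")) {
  standardize_by <- match.arg(standardize_by)
  denom <- match.arg(denom)
  if (!inherits(mat, "age_matrix")) stop("`mat` must be an age_matrix")
  if (mat$mode != "additive") {
    stop("additive_partition requires an additive-mode matrix")
  }
  n <- length(mat$male_ids)
  if (n < 2L) stop("need at least 2 males")
  A <- length(mat$age_classes)
  comps <- c("EGP", "WGP", "RS", "RS_ap")
  cv <- lapply(comps, function(cp) .cov_d(mat[[cp]], denom = denom))
  names(cv) <- comps
  cx <- .cov_d(mat$EGP, mat$WGP, denom)      # cross cov, [i, j] = cov(E_i, W_j)
  lrs <- rowSums(mat$RS)
  lap <- rowSums(mat$RS_ap)

  rows <- list()
  add <- function(component, term, level, age_i, age_j, mean, raw) {
    rows[[length(rows) + 1L]] <<- data.frame(
      component = component, term = term, level = level,
      age_i = age_i, age_j = age_j, mean = mean, raw = raw,
      n = n, stringsAsFactors = FALSE)
  }
  for (cp in comps) {
    mu <- colMeans(mat[[cp]])
    for (i in seq_len(A)) {
      add(cp, "variance", "age", i, NA_integer_, mu[i], cv[[cp]][i, i])
    }
  }
  for (i in seq_len(A)) {
    add("EGPxWGP", "2cov", "age", i, NA_integer_, NA_real_, 2 * cx[i, i])
  }
  for (i in seq_len(A - 1L)) {
    for (j in seq.int(i + 1L, A)) {
      for (cp in comps) {
        add(cp, "2cov", "between_age", i, j, NA_real_, 2 * cv[[cp]][i, j])
      }
      add("EGPxWGP", "2cov", "between_age", i, j, NA_real_, 2 * cx[i, j])
      add("EGPxWGP", "2cov", "between_age", j, i, NA_real_, 2 * cx[j, i])
    }
  }
  rows <- do.call(rbind, rows)

  sum_rows <- function(cp) {
    age_sum <- sum(rows$raw[rows$component == cp & rows$level == "age"])
    btw_sum <- sum(rows$raw[rows$component == cp & rows$level == "between_age"])
    life_raw <- switch(cp,
      EGP = .cov_d(rowSums(mat$EGP), denom = denom),
      WGP = .cov_d(rowSums(mat$WGP), denom = denom),
      RS = .cov_d(lrs, denom = denom),
      RS_ap = .cov_d(lap, denom = denom),
      EGPxWGP = 2 * .cov_d(rowSums(mat$EGP), rowSums(mat$WGP), denom))
    term <- if (cp == "EGPxWGP") "2cov" else "variance"
    data.frame(
      component = cp, term = term,
      level = c("sum_age_specific", "sum_between_age", "lifetime"),
      age_i = NA_integer_, age_j = NA_integer_,
      mean = c(NA, NA, switch(cp, EGP = mean(rowSums(mat$EGP)),
                              WGP = mean(rowSums(mat$WGP)), RS = mean(lrs),
                              RS_ap = mean(lap), EGPxWGP = NA_real_)),
      raw = c(age_sum, btw_sum, life_raw), n = n, stringsAsFactors = FALSE)
  }
  rows <- rbind(rows, do.call(rbind, lapply(c(comps, "EGPxWGP"), sum_rows)))

  denoms <- .std_denoms(mean(lrs), mean(lap), standardize_by)
  rows <- .apply_std(rows, denoms)
  var_rs <- .cov_d(lrs, denom = denom)
  var_ap <- .cov_d(lap, denom = denom)
  rows$percent <- ifelse(
    rows$component == "RS_ap",
    if (var_ap != 0) 100 * rows$raw / var_ap else NA_real_,
    if (var_rs != 0) 100 * rows$raw / var_rs else NA_real_
  )
  .new_decomposition_table(rows, "additive", standardize_by, denom,
                           c(rs = mean(lrs), rs_ap = mean(lap)))
}

#' Survivor-only ("independent") per-age variance partition
#'
#' For each age class, among the males still alive at that age, partitions
#' the variance in age-specific RS into EGP and WGP variances and twice
#' their covariance, and reports the variance in age-specific RS_ap.
#' Standardization is within-age: genetic terms divide by the squared
#' age-specific mean RS of survivors, the apparent term by the squared
#' age-specific mean RS_ap. Ages with fewer than two survivors, or a zero
#' within-age mean, yield `NA` (undefined, never zero).
#'
#' @param mat an independent-mode [build_age_matrix()] result.
#' @param standardize logical; divide by the squared within-age means
#'   (default) or leave raw.
#' @inheritParams lifetime_partition
#' @return a `decomposition_table` with one block of rows per age class and
#'   the number of survivors in `n`.
#' @export
independent_partition <- function(mat, standardize = TRUE,
                                  denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  if (!inherits(mat, "age_matrix")) stop("`mat` must be an age_matrix")
  if (mat$mode != "independent") {
    stop("independent_partition requires an independent-mode matrix")
  }
  rows <- list()
  for (i in mat$age_classes) {
    alive <- !is.na(mat$RS[, i])
    n_i <- sum(alive)
    e <- mat$EGP[alive, i]
    w <- mat$WGP[alive, i]
    rs <- mat$RS[alive, i]
    ap <- mat$RS_ap[alive, i]
    if (n_i < 2L) {
      raw <- rep(NA_real_, 5L)
      mu <- c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      raw <- c(.cov_d(e, denom = denom), .cov_d(w, denom = denom),
               2 * .cov_d(e, w, denom), .cov_d(rs, denom = denom),
               .cov_d(ap, denom = denom))
      mu <- c(mean(e), mean(w), NA_real_, mean(rs), mean(ap))
    }
    rows[[i]] <- data.frame(
      component = c("EGP", "WGP", "EGPxWGP", "RS", "RS_ap"),
      term = c("variance", "variance", "2cov", "variance", "variance"),
      level = "age", age_i = i, age_j = NA_integer_,
      mean = mu, raw = raw, n = n_i, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  if (standardize) {
    rows$standardized <- NA_real_
    for (i in mat$age_classes) {
      blk <- rows$age_i == i
      mu_rs <- rows$mean[blk & rows$component == "RS"]
      mu_ap <- rows$mean[blk & rows$component == "RS_ap"]
      gen <- blk & rows$component != "RS_ap"
      app <- blk & rows$component == "RS_ap"
      if (!is.na(mu_rs) && mu_rs != 0) {
        rows$standardized[gen] <- rows$raw[gen] / mu_rs^2
      }
      if (!is.na(mu_ap) && mu_ap != 0) {
        rows$standardized[app] <- rows$raw[app] / mu_ap^2
      }
    }
  } else {
    rows$standardized <- rows$raw
  }
  rows$percent <- NA_real_
  for (i in mat$age_classes) {
    blk <- rows$age_i == i
    v_rs <- rows$raw[blk & rows$component == "RS"]
    v_ap <- rows$raw[blk & rows$component == "RS_ap"]
    gen <- blk & rows$component != "RS_ap"
    if (!is.na(v_rs) && v_rs != 0) {
      rows$percent[gen] <- 100 * rows$raw[gen] / v_rs
    }
    if (length(v_ap) && !is.na(v_ap) && v_ap != 0) {
      rows$percent[blk & rows$component == "RS_ap"] <- 100
    }
  }
  .new_decomposition_table(rows, "independent",
                           if (standardize) "within-age" else "none",
                           denom, NULL)
}

#' Percentage contribution of a component to a total
#'
#' @param component,total numeric values on the same scale.
#' @param digits rounding for reporting (default nearest integer); use
#'   `NULL` to keep full precision.
#' @return `100 * component / total`, rounded to `digits`.
#' @examples
#' percent_contribution(0.71, 2.08)   # 34
#' @export
percent_contribution <- function(component, total, digits = 0) {
  if (any(total == 0)) stop("zero total")
  p <- 100 * component / total
  if (is.null(digits)) p else round(p, digits)
}

#' Ratio of two variances
#'
#' Used for the EGP:WGP ratio and the RS:RS_ap ratio comparing the genetic
#' and social opportunity for selection (lifetime or per age).
#'
#' @param numerator,denominator numeric (typically standardized variances).
#' @return `numerator / denominator`.
#' @examples
#' variance_ratio(2.08, 1.75)   # 1.19
#' @export
variance_ratio <- function(numerator, denominator) {
  if (any(denominator == 0, na.rm = TRUE)) stop("zero denominator")
  numerator / denominator
}

#' Presentation rounding for decomposition tables
#'
#' Values above 0.01 in absolute value are rounded to two decimal places;
#' smaller non-zero values are kept to one significant figure.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_report <- function(x) {
  out <- round(x, 2)
  small <- !is.na(x) & abs(x) <= 0.01 & x != 0
  out[small] <- signif(x[small], 1)
  out
}

#' Check the internal identities of a decomposition table
#'
#' Verifies, to a relative tolerance, that the emitted terms add up: the
#' lifetime partition components sum to var(LRS); the additive-method age
#' and between-age terms sum to the lifetime values per component; and
#' within each age of the independent method var(RS_i) equals
#' var(EGP_i) + var(WGP_i) + 2cov.
#'
#' @param tab a `decomposition_table`.
#' @param tol relative tolerance.
#' @return named logical vector of checks (all `TRUE` when consistent).
#' @export
check_decomposition <- function(tab, tol = 1e-9) {
  method <- attr(tab, "method")
  rel_eq <- function(a, b) {
    isTRUE(abs(a - b) <= tol * max(1, abs(a), abs(b)))
  }
  checks <- c()
  if (method == "lifetime") {
    parts <- tab$raw[tab$component %in% c("EGP", "WGP", "EGPxWGP")]
    total <- tab$raw[tab$component == "RS"]
    checks["eq1_identity"] <- rel_eq(sum(parts), total)
  } else if (method == "additive") {
    for (cp in unique(tab$component)) {
      sub <- tab[tab$component == cp, ]
      s <- sum(sub$raw[sub$level %in% c("age", "between_age")])
      life <- sub$raw[sub$level == "lifetime"]
      checks[paste0("additivity_", cp)] <- rel_eq(s, life)
    }
    life_rows <- tab[tab$level == "lifetime", ]
    checks["eq1_identity"] <- rel_eq(
      sum(life_rows$raw[life_rows$component %in% c("EGP", "WGP", "EGPxWGP")]),
      life_rows$raw[life_rows$component == "RS"])
  } else if (method == "independent") {
    for (i in unique(tab$age_i)) {
      blk <- tab[tab$age_i == i, ]
      if (all(is.na(blk$raw))) next
      checks[paste0("within_age_", i)] <- rel_eq(
        sum(blk$raw[blk$component %in% c("EGP", "WGP", "EGPxWGP")]),
        blk$raw[blk$component == "RS"])
    }
  }
  checks
}
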