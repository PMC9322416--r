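#' Mate-number / fecundity / paternity-share decomposition
#'
#' For males that obtained at least one within-group and one extra-group
#' offspring in life, each pathway total T factors as T = M * N * P, where
#' M is the number of mates with at least one offspring attributable to the
#' male's pathway, N the mean number of offspring per such mate, and P the
#' share of those offspring sired by the focal male (so the identity is
#' exact by construction). The variance in T across males is decomposed
#' into first-order terms attributable to var(M), var(N), var(P) and their
#' pairwise covariances, plus an explicit higher-order remainder, so that
#' the emitted terms always sum exactly to var(T).
#'
#' @name webster
#' @keywords internal
NULL

#' Males successful through both pathways
#'
#' @param life per-male lifetime summaries.
#' @return the subset with `lifetime_egp >= 1` and `lifetime_wgp >= 1`.
#' @export
select_successful <- function(life) {
  life[life$lifetime_egp >= 1L & life$lifetime_wgp >= 1L, , drop = FALSE]
}

#' Per-male, per-pathway mate summaries
#'
#' Aggregates a mate-level table to the (M, N, P, T) quantities of the
#' decomposition. `N` is the mean brood per mate and `P = T / (M * N)` the
#' overall share of those mates' offspring sired by the male, which makes
#' `T = M * N * P` hold exactly. Males owning a mate with a zero recorded
#' brood have an undefined `P` and are dropped with a warning.
#'
#' @param mates data.frame with columns `male_id`, `pathway`
#'   (`"within-group"` / `"extra-group"`), `mate_id`, `offspring_by_mate`,
#'   `offspring_sired`.
#' @return data.frame with columns `male_id`, `pathway`, `M`, `N`, `P`, `T`.
#' @export
mate_pathway_summary <- function(mates) {
  need <- c("male_id", "pathway", "mate_id", "offspring_by_mate",
            "offspring_sired")
  missing_cols <- setdiff(need, names(mates))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(mates$offspring_sired > mates$offspring_by_mate)) {
    stop("offspring_sired exceeds offspring_by_mate")
  }
  bad <- unique(mates$male_id[mates$offspring_by_mate == 0])
  if (length(bad)) {
    warning("excluding male(s) with a zero-brood mate (undefined P): ",
            paste(bad, collapse = ", "))
    mates <- mates[!(mates$male_id %in% bad), , drop = FALSE]
  }
  sp <- split(mates, list(mates$male_id, mates$pathway), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    m <- nrow(d)
    tot_brood <- sum(d$offspring_by_mate)
    t_pw <- sum(d$offspring_sired)
    data.frame(male_id = d$male_id[1L], pathway = d$pathway[1L],
               M = m, N = tot_brood / m, P = t_pw / tot_brood, T = t_pw,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$male_id, out$pathway), , drop = FALSE]
}

# first-order terms of var(M*N*P) about the means, for one pathway
.product_variance_terms <- function(M, N, P, denom) {
  mu <- c(M = mean(M), N = mean(N), P = mean(P))
  coef <- c(M = mu[["N"]] * mu[["P"]],
            N = mu[["M"]] * mu[["P"]],
            P = mu[["M"]] * mu[["N"]])
  vars <- c(M = .cov_d(M, denom = denom), N = .cov_d(N, denom = denom),
            P = .cov_d(P, denom = denom))
  covs <- c(MN = .cov_d(M, N, denom), MP = .cov_d(M, P, denom),
            NP = .cov_d(N, P, denom))
  terms <- c(
    var_M = coef[["M"]]^2 * vars[["M"]],
    var_N = coef[["N"]]^2 * vars[["N"]],
    var_P = coef[["P"]]^2 * vars[["P"]],
    `2cov_MN` = 2 * coef[["M"]] * coef[["N"]] * covs[["MN"]],
    `2cov_MP` = 2 * coef[["M"]] * coef[["P"]] * covs[["MP"]],
    `2cov_NP` = 2 * coef[["N"]] * coef[["P"]] * covs[["NP"]]
  )
  var_T <- .cov_d(M * N * P, denom = denom)
  c(terms, remainder = unname(var_T - sum(terms)), var_T = unname(var_T))
}

#' Decompose var(T) per pathway into M, N and P contributions
#'
#' @param summaries output of [mate_pathway_summary()], restricted to the
#'   doubly successful males (see [select_successful()]); every male must
#'   appear in both pathways.
#' @param denom variance denominator convention.
#' @param first_order if `TRUE`, drop the remainder row (classic
#'   first-order approximation); the remaining terms then no longer sum to
#'   var(T).
#' @return a data.frame with one row per term and pathway: raw value and
#'   percent of the variance in the subset's lifetime RS; cross-pathway
#'   rows report `2cov(T_wg, T_eg)`, `cov(M_wg, M_eg)` and `var(LRS)` of
#'   the subset.
#' @export
webster_decomposition <- function(summaries, denom = c("n-1", "n"),
                                  first_order = FALSE) {
  denom <- match.arg(denom)
  wg <- summaries[summaries$pathway == "within-group", , drop = FALSE]
  eg <- summaries[summaries$pathway == "extra-group", , drop = FALSE]
  ids <- intersect(wg$male_id, eg$male_id)
  if (length(ids) < 2L) stop("need at least 2 males present in both pathways")
  wg <- wg[match(ids, wg$male_id), ]
  eg <- eg[match(ids, eg$male_id), ]
  rows <- list()
  for (pw in c("within-group", "extra-group")) {
    d <- if (pw == "within-group") wg else eg
    terms <- .product_variance_terms(d$M, d$N, d$P, denom)
    if (first_order) terms <- terms[names(terms) != "remainder"]
    rows[[pw]] <- data.frame(pathway = pw, term = names(terms),
                             raw = unname(terms), stringsAsFactors = FALSE)
  }
  lrs <- wg$T + eg$T
  var_lrs <- .cov_d(lrs, denom = denom)
  cross <- data.frame(
    pathway = "cross",
    term = c("2cov_T", "cov_M", "var_LRS"),
    raw = c(2 * .cov_d(wg$T, eg$T, denom), .cov_d(wg$M, eg$M, denom),
            var_lrs),
    stringsAsFactors = FALSE)
  out <- rbind(rows[["within-group"]], rows[["extra-group"]], cross)
  out$percent <- if (var_lrs != 0) 100 * out$raw / var_lrs else NA_real_
  out$n <- length(ids)
  rownames(out) <- NULL
  structure(out, class = c("webster_table", "data.frame"), denom = denom,
            first_order = first_order)
}
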