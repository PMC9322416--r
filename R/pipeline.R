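#' Reproducible analysis pipeline
#'
#' Thin command-style wrappers that tie the stages together: simulate (or
#' read) an annual table, build the three decompositions, optionally
#' decorate them with BCa intervals, and render a plain-text report. Every
#' run echoes its configuration, and identical configurations with the same
#' seed reproduce identical output files.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Assemble a pipeline configuration
#'
#' @param input optional path to an existing annual records file; when
#'   `NULL`, records are simulated from `simulator`.
#' @param simulator a [simulator_config()] (or list of its arguments).
#' @param n_classes number of age classes for the matrices.
#' @param denom variance denominator convention.
#' @param bootstrap list with `B`, `seed`, `ci_level`; set `B = 0` to skip
#'   interval estimation.
#' @param filters optional list with `first_cohort`, `last_cohort`,
#'   `exclude_ids`.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulator = simulator_config(),
                            n_classes = 12L, denom = "n-1",
                            bootstrap = list(B = 2000L, seed = 1L,
                                             ci_level = 0.95),
                            filters = NULL, out_dir = "egpvar_out") {
  if (!inherits(simulator, "simulator_config")) {
    simulator <- do.call(simulator_config, simulator)
  }
  structure(list(input = input, simulator = simulator,
                 n_classes = as.integer(n_classes), denom = denom,
                 bootstrap = bootstrap, filters = filters,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulator %||% list()
  pipeline_config(input = raw$input,
                  simulator = do.call(simulator_config, sim),
                  n_classes = raw$n_classes %||% 12L,
                  denom = raw$denom %||% "n-1",
                  bootstrap = raw$bootstrap %||%
                    list(B = 2000L, seed = 1L, ci_level = 0.95),
                  filters = raw$filters, out_dir = raw$out_dir %||%
                    "egpvar_out")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$simulator <- unclass(out$simulator)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Simulate records and write them with a truth summary
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the written paths and the simulated
#'   objects.
#' @export
cmd_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(config$simulator)
  records_path <- file.path(config$out_dir, "records.tsv")
  write_records(pop$records, records_path)
  truth_path <- file.path(config$out_dir, "truth.json")
  jsonlite::write_json(pop$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
  invisible(list(records = records_path, truth = truth_path, pop = pop))
}

.load_records <- function(config) {
  records <- if (!is.null(config$input)) read_records(config$input) else {
    simulate_population(config$simulator)$records
  }
  f <- config$filters
  if (!is.null(f)) {
    records <- filter_cohort(records, f$first_cohort, f$last_cohort,
                             f$exclude_ids %||% character())
  }
  records
}

#' Run a variance partition and write its table
#'
#' @param config a [pipeline_config()].
#' @param method `"lifetime"`, `"additive"` or `"independent"`.
#' @param records optional pre-loaded records (otherwise read or simulated
#'   per `config`).
#' @param compare if `TRUE`, also write the RS vs RS_ap variance-ratio
#'   comparison for this method.
#' @param bootstrap if `TRUE` and `config$bootstrap$B > 0`, decorate the
#'   table with BCa intervals.
#' @return the `decomposition_table`, invisibly.
#' @export
cmd_partition <- function(config, method = c("lifetime", "additive",
                                             "independent"),
                          records = NULL, compare = FALSE,
                          bootstrap = FALSE) {
  method <- match.arg(method)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(records)) records <- .load_records(config)
  denom <- config$denom
  data <- switch(method,
    lifetime = aggregate_lifetime(records),
    additive = build_age_matrix(records, "additive", config$n_classes),
    independent = build_age_matrix(records, "independent", config$n_classes))
  tab <- switch(method,
    lifetime = lifetime_partition(data, denom = denom),
    additive = additive_partition(data, denom = denom),
    independent = independent_partition(data, denom = denom))
  checks <- check_decomposition(tab)
  for (nm in names(checks)) {
    message("invariant ", nm, ": ", if (checks[nm]) "PASS" else "FAIL")
  }
  if (!all(checks)) stop("decomposition table failed its invariant checks")
  bs <- config$bootstrap
  if (bootstrap && !is.null(bs) && bs$B > 0) {
    tab <- decorate_table(tab, data, B = bs$B, ci_level = bs$ci_level,
                          seed = bs$seed)
  }
  path <- file.path(config$out_dir, paste0(method, "_partition.tsv"))
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (compare) {
    cmp <- compare_rs_rsap(tab)
    utils::write.table(cmp,
                       file.path(config$out_dir,
                                 paste0(method, "_rs_vs_rsap.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}

#' RS vs RS_ap standardized-variance ratios from a decomposition table
#'
#' @param tab a `decomposition_table`.
#' @return data.frame with one row per level/age: standardized var(RS),
#'   var(RS_ap) and their ratio.
#' @export
compare_rs_rsap <- function(tab) {
  method <- attr(tab, "method")
  rs <- tab[tab$component == "RS" & tab$term == "variance", , drop = FALSE]
  ap <- tab[tab$component == "RS_ap" & tab$term == "variance", , drop = FALSE]
  if (method == "lifetime") {
    key <- "lifetime"
    rs_v <- rs$standardized; ap_v <- ap$standardized
  } else {
    rs <- rs[rs$level %in% c("age", "lifetime"), ]
    ap <- ap[ap$level %in% c("age", "lifetime"), ]
    key <- ifelse(is.na(rs$age_i), rs$level, paste0("age_", rs$age_i))
    rs_v <- rs$standardized
    ap_v <- ap$standardized[match(paste(rs$level, rs$age_i),
                                  paste(ap$level, ap$age_i))]
  }
  data.frame(level = key, std_var_rs = rs_v, std_var_rs_ap = ap_v,
             var_ratio = ifelse(!is.na(ap_v) & ap_v != 0, rs_v / ap_v,
                                NA_real_),
             stringsAsFactors = FALSE)
}

#' Render a plain-text report from prior pipeline outputs
#'
#' Collects the partition tables written into `out_dir` and renders a
#' markdown summary: the table analogues with presentation rounding,
#' percentage contributions of the lifetime components, and, when CI
#' columns are present, the non-overlap significance call for RS vs RS_ap.
#'
#' @param out_dir directory with `cmd_partition()` outputs.
#' @return the report path, invisibly.
#' @export
cmd_report <- function(out_dir) {
  paths <- file.path(out_dir, paste0(c("lifetime", "additive", "independent"),
                                     "_partition.tsv"))
  names(paths) <- c("lifetime", "additive", "independent")
  have <- file.exists(paths)
  if (!any(have)) stop("no partition outputs found in ", out_dir)
  lines <- c("# Variance decomposition report", "")
  fmt <- function(x) ifelse(is.na(x), "NA", format(round_report(x)))
  for (m in names(paths)[have]) {
    tab <- utils::read.table(paths[m], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    lines <- c(lines, paste0("## ", m, " partition"), "")
    if (m == "lifetime") {
      vr <- tab$raw[tab$component == "RS"]
      for (cp in c("EGP", "WGP", "EGPxWGP")) {
        r <- tab[tab$component == cp, ]
        lines <- c(lines, sprintf(
          "- %s: standardized %s (%s%% of var(LRS))", cp,
          fmt(r$standardized), round(percent_contribution(r$raw, vr))))
      }
      rs <- tab[tab$component == "RS", ]
      ap <- tab[tab$component == "RS_ap", ]
      lines <- c(lines, sprintf("- var(LRS) standardized: %s",
                                fmt(rs$standardized)),
                 sprintf("- var(LRS_ap) standardized: %s",
                         fmt(ap$standardized)),
                 sprintf("- variance ratio LRS:LRS_ap: %s",
                         fmt(variance_ratio(rs$standardized,
                                            ap$standardized))))
      if (all(c("lower", "upper") %in% names(tab))) {
        sig <- overlap_significance(c(rs$lower, rs$upper),
                                    c(ap$lower, ap$upper))
        lines <- c(lines, sprintf(
          "- LRS %s(%s, %s) vs LRS_ap (%s, %s): %s",
          "", fmt(rs$lower), fmt(rs$upper), fmt(ap$lower), fmt(ap$upper),
          if (sig) "significantly different (non-overlapping CIs)"
          else "not significantly different (overlapping CIs)"))
      } else {
        lines <- c(lines, "- (no bootstrap intervals available)")
      }
    } else {
      age <- tab[tab$level == "age" & tab$term == "variance", ]
      for (cp in unique(age$component)) {
        sub <- age[age$component == cp, ]
        lines <- c(lines, sprintf("- %s per-age standardized variance: %s",
                                  cp, paste(fmt(sub$standardized),
                                            collapse = " ")))
      }
    }
    lines <- c(lines, "")
  }
  if (!all(have)) {
    warning("missing partition output(s): ",
            paste(names(paths)[!have], collapse = ", "))
  }
  report_path <- file.path(out_dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}
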