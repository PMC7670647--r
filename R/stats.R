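# Group-level statistics: paired t-tests over subjects and Spearman rank
# correlations between subject-level AMI measures. No multiple-testing
# correction is applied; the report carries raw two-sided p-values.

#' Paired t-test over subjects
#'
#' Two-sided paired t-test of `a` versus `b` with `df = n - 1`. A
#' zero-variance difference vector is flagged `degenerate`: `t = 0, p = 1`
#' when the differences are all zero, otherwise a signed infinite t with
#' `p = 0`.
#'
#' @param a,b Per-subject paired values, equal length `>= 2`.
#' @param name Statistic label stored in the result.
#' @return A `group_result`: list with `name`, `t`, `df`, `p`, `n`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b, name = "paired_t") {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    md <- mean(d)
    res <- list(
      name = name,
      t = if (md == 0) 0 else sign(md) * Inf,
      df = n - 1L,
      p = if (md == 0) 1 else 0,
      n = n, mean_diff = md, degenerate = TRUE
    )
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(
      name = name, t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, n = n, mean_diff = mean(d), degenerate = FALSE
    )
  }
  structure(res, class = "group_result")
}

#' Spearman rank correlation over subjects
#'
#' Rank correlation with average ranks for ties. The p-value is the
#' asymptotic two-sided approximation by default; for small cohorts a
#' permutation p-value over random reshuffles of `y` is available.
#'
#' @param x,y Per-subject values, equal length `>= 4`.
#' @param p_method `"asymptotic"` or `"permutation"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @param name Statistic label.
#' @return A `group_result` with `rho`, `p`, `n`; `rho` is `NA` (flagged
#'   `degenerate`) for constant input.
#' @export
spearman <- function(x, y, p_method = c("asymptotic", "permutation"),
                     n_perm = 10000, seed = NULL, name = "spearman") {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(
      list(name = name, rho = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE),
      class = "group_result"
    ))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (p_method == "asymptotic") {
    suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
    )
  } else {
    with_rng_seed(seed, {
      rx <- rank(x)
      ry <- rank(y)
      null_rho <- replicate(n_perm, stats::cor(rx, sample(ry)))
      (1 + sum(abs(null_rho) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  structure(
    list(name = name, rho = rho, p = p, n = length(x), degenerate = FALSE),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  if (!is.null(x$t)) {
    cat(sprintf(
      "%s: t(%d) = %.3g, p = %.3g%s\n", x$name, x$df, x$t, x$p,
      if (isTRUE(x$degenerate)) " [degenerate]" else ""
    ))
  } else {
    cat(sprintf(
      "%s: rho = %.3g, p = %.3g (n = %d)%s\n", x$name,
      if (is.na(x$rho)) NA else x$rho, x$p, x$n,
      if (isTRUE(x$degenerate)) " [degenerate]" else ""
    ))
  }
  invisible(x)
}

#' Assemble the group-level report
#'
#' Takes the per-subject results table of a cohort analysis and builds
#' the full statistical report: per-hemisphere paired tests on peak
#' cross-PLV and latency (attended vs unattended), the median-split
#' paired tests, and the over-subject Spearman correlations between alpha
#' AMI and tagging AMI, and between alpha AMI and response latency.
#' Missing columns produce a noted gap rather than a failure; an empty
#' cohort returns an empty report with warnings.
#'
#' @param subjects Data frame with one row per subject; recognized
#'   columns: `alpha_ami`, `tag_ami`, `plv_att_left`, `plv_un_left`,
#'   `plv_att_right`, `plv_un_right`, `lat_att_left`, `lat_un_left`,
#'   `lat_att_right`, `lat_un_right`, `ms_diff_contra`, `ms_diff_ipsi`.
#' @param meta Optional list of provenance fields (seeds, config) stored
#'   verbatim in the report.
#' @return A `rift_report`: list with `tests`, `correlations`, `subjects`,
#'   `gaps`, `meta`.
#' @export
build_report <- function(subjects, meta = list()) {
  report <- list(
    tests = list(), correlations = list(), gaps = character(),
    subjects = subjects, meta = meta
  )
  class(report) <- "rift_report"
  if (is.null(subjects) || nrow(subjects) == 0L) {
    warning("empty cohort: report contains no statistics", call. = FALSE)
    report$gaps <- "empty cohort"
    return(report)
  }
  has <- function(...) all(c(...) %in% names(subjects))
  note_gap <- function(what) {
    report$gaps <<- c(report$gaps, what)
  }
  pt <- function(a, b, nm) paired_t(subjects[[a]], subjects[[b]], name = nm)

  if (has("plv_att_left", "plv_un_left")) {
    report$tests$plv_left <- pt("plv_att_left", "plv_un_left", "cross-PLV attended vs unattended (left sensors)")
  } else {
    note_gap("plv_left")
  }
  if (has("plv_att_right", "plv_un_right")) {
    report$tests$plv_right <- pt("plv_att_right", "plv_un_right", "cross-PLV attended vs unattended (right sensors)")
  } else {
    note_gap("plv_right")
  }
  if (has("lat_att_left", "lat_un_left")) {
    report$tests$latency_left <- pt("lat_att_left", "lat_un_left", "latency attended vs unattended (left sensors)")
  } else {
    note_gap("latency_left")
  }
  if (has("lat_att_right", "lat_un_right")) {
    report$tests$latency_right <- pt("lat_att_right", "lat_un_right", "latency attended vs unattended (right sensors)")
  } else {
    note_gap("latency_right")
  }
  if (has("ms_diff_contra")) {
    d <- subjects$ms_diff_contra
    report$tests$median_split_contra <- paired_t(d, rep(0, length(d)),
      name = "median-split tagging power, high vs low alpha (contralateral)"
    )
  } else {
    note_gap("median_split_contra")
  }
  if (has("ms_diff_ipsi")) {
    d <- subjects$ms_diff_ipsi
    report$tests$median_split_ipsi <- paired_t(d, rep(0, length(d)),
      name = "median-split tagging power, high vs low alpha (ipsilateral)"
    )
  } else {
    note_gap("median_split_ipsi")
  }
  if (has("alpha_ami", "tag_ami") && nrow(subjects) >= 4) {
    report$correlations$ami_ami <- spearman(subjects$alpha_ami, subjects$tag_ami,
      name = "alpha AMI vs tagging AMI"
    )
  } else {
    note_gap("ami_ami")
  }
  if (has("alpha_ami", "lat_att_left", "lat_un_left", "lat_att_right", "lat_un_right") &&
    nrow(subjects) >= 4) {
    mean_lat <- rowMeans(subjects[, c(
      "lat_att_left", "lat_un_left",
      "lat_att_right", "lat_un_right"
    )])
    report$correlations$ami_latency <- spearman(subjects$alpha_ami, mean_lat,
      name = "alpha AMI vs response latency"
    )
  } else {
    note_gap("ami_latency")
  }
  report
}

#' @export
print.rift_report <- function(x, ...) {
  cat("Group-level report (n =", if (is.null(x$subjects)) 0 else nrow(x$subjects), "subjects)\n")
  for (tst in x$tests) print(tst)
  for (cr in x$correlations) print(cr)
  if (length(x$gaps)) cat("gaps:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report A `rift_report`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    tests = lapply(report$tests, unclass),
    correlations = lapply(report$correlations, unclass),
    gaps = report$gaps,
    subjects = report$subjects,
    meta = report$meta
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
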