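# Group-level aggregation and comparison statistics.  The unit of
# replication is the animal: per-animal means are computed first, then
# group summaries, so per-mitochondrion counts never pseudo-replicate
# the group statistics.

#' Hierarchical group summaries
#'
#' Aggregates measurement records animal-first: the mean of each metric
#' is computed per animal, and group mean, SD and SEM are computed over
#' the per-animal means (`SEM = sd / sqrt(n)` with `n` animals).  Groups
#' with a single animal are flagged (`SEM` is undefined).
#'
#' @param records data frame of per-object measurements.
#' @param value name of the measurement column.
#' @param group_cols character vector of grouping columns (e.g. group
#'   and subtype).
#' @param animal_col name of the animal identifier column.
#' @param metric optional metric name stored in the output.
#' @return Data frame of class `group_summary` with per-group `mean`,
#'   `sd`, `sem`, `n` and the per-animal means as a list column.
#' @export
summarize_records <- function(records, value, group_cols = "group",
                              animal_col = "animal", metric = value) {
  if (nrow(records) == 0L) stop("no records to summarize")
  if (!value %in% names(records)) stop("value column not found")
  split_key <- interaction(records[group_cols], drop = TRUE, sep = "\r")
  out <- lapply(split(records, split_key), function(g) {
    am <- tapply(g[[value]], g[[animal_col]], mean)
    am <- am[!is.na(am)]
    n <- length(am)
    if (n == 0L) stop("empty group after animal aggregation")
    row <- g[1, group_cols, drop = FALSE]
    row$metric <- metric
    row$mean <- mean(am)
    row$sd <- if (n > 1L) sd(am) else NA_real_
    row$sem <- if (n > 1L) sd(am) / sqrt(n) else NA_real_
    row$n <- n
    row$flag <- if (n == 1L) "single animal: SEM undefined" else ""
    row$animal_means <- I(list(as.numeric(am)))
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("group_summary", "data.frame"))
}

#' Ratio of two group means
#'
#' Fold-change style ratio between group means of the same metric, as
#' used to compare disease against wild type.
#'
#' @param summary a [summarize_records()] result (or any data frame with
#'   the grouping columns and a `mean` column).
#' @param num,den named lists selecting the numerator and denominator
#'   rows, e.g. `list(group = "GENA348", subtype = "SSM")`.
#' @return Numeric ratio of the two group means.
#' @export
group_ratio <- function(summary, num, den) {
  pick <- function(sel) {
    keep <- rep(TRUE, nrow(summary))
    for (nm in names(sel)) keep <- keep & summary[[nm]] == sel[[nm]]
    m <- summary$mean[keep]
    if (length(m) != 1L) stop("selection does not identify one row")
    m
  }
  pick(num) / pick(den)
}

#' Comparison statistics for group designs
#'
#' Runs the comparison appropriate to the design: unpaired two-tailed
#' Student t test (`"t"`), one-way ANOVA with Tukey's multiple
#' comparison test (`"anova1_tukey"`), or two-way ANOVA with Sidak's
#' multiple comparison test (`"anova2_sidak"`, contrasting the levels of
#' `factor1` within each level of `factor2`).  The significance
#' threshold reported alongside the results is P < 0.05.
#'
#' @param data data frame with the response and factor columns.
#' @param value response column name.
#' @param design one of `"t"`, `"anova1_tukey"`, `"anova2_sidak"`.
#' @param factor1 primary factor column (groups to contrast).
#' @param factor2 secondary factor column (two-way design only).
#' @return List of class `comparison_result` with `test`, `statistic`,
#'   `p_value` and a `contrasts` data frame for the omnibus designs.
#' @export
compare_groups <- function(data, value,
                           design = c("t", "anova1_tukey",
                                      "anova2_sidak"),
                           factor1 = "group", factor2 = NULL) {
  design <- match.arg(design)
  y <- data[[value]]
  g <- factor(data[[factor1]])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (design == "t") {
    if (nlevels(g) != 2L) stop("t test needs exactly 2 groups")
    tt <- t.test(y ~ g, var.equal = TRUE)
    res <- list(test = "unpaired two-tailed Student t",
                statistic = unname(tt$statistic),
                p_value = tt$p.value, contrasts = NULL)
  } else if (design == "anova1_tukey") {
    fit <- aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    res <- list(test = "one-way ANOVA + Tukey",
                statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1],
                contrasts = data.frame(contrast = rownames(tk),
                                       diff = tk[, "diff"],
                                       p_adj = tk[, "p adj"],
                                       row.names = NULL))
  } else {
    if (is.null(factor2)) stop("two-way design needs `factor2`")
    f2 <- factor(data[[factor2]])
    if (any(table(g, f2) == 0L))
      stop("unbalanced two-way design: empty cells make the interaction inestimable")
    dd <- data.frame(y = y, A = g, B = f2)
    fit <- aov(y ~ A * B, data = dd)
    an <- summary(fit)[[1]]
    em <- emmeans::emmeans(fit, ~ A | B)
    pr <- summary(emmeans::contrast(em, method = "pairwise",
                                    adjust = "sidak"))
    res <- list(test = "two-way ANOVA + Sidak",
                statistic = an[["F value"]][seq_len(nrow(an) - 1)],
                p_value = an[["Pr(>F)"]][seq_len(nrow(an) - 1)],
                contrasts = data.frame(contrast = paste(pr$contrast, "|",
                                                        pr$B),
                                       diff = pr$estimate,
                                       p_adj = pr$p.value,
                                       row.names = NULL))
  }
  res$alpha <- 0.05
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %s, p = %s (alpha %.2f)\n", x$test,
              paste(signif(x$statistic, 4), collapse = ", "),
              paste(signif(x$p_value, 4), collapse = ", "), x$alpha))
  if (!is.null(x$contrasts)) print(x$contrasts)
  invisible(x)
}

#' Serialize summaries and comparisons
#'
#' Writes CSV and JSON renderings of group summaries (stable column
#' order) plus a provenance block with package version, R version and
#' timestamp-free configuration echo.
#'
#' @param summaries a [summarize_records()] result (possibly several
#'   rbind-ed); may have zero rows.
#' @param comparisons optional list of [compare_groups()] results.
#' @param path output path prefix; `<path>.csv` and `<path>.json` are
#'   written.
#' @param config optional configuration list echoed into the JSON.
#' @return Invisibly, the two file paths.
#' @export
render_tables <- function(summaries, comparisons = NULL, path,
                          config = list()) {
  cols <- setdiff(names(summaries), "animal_means")
  flat <- as.data.frame(summaries)[, cols, drop = FALSE]
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  write.csv(flat, csv, row.names = FALSE)
  payload <- list(
    summaries = flat,
    comparisons = lapply(comparisons, function(cp)
      list(test = cp$test, statistic = cp$statistic,
           p_value = cp$p_value, contrasts = cp$contrasts)),
    provenance = list(package = "mitomorph",
                      version = as.character(packageVersion("mitomorph")),
                      r_version = R.version.string,
                      config = config))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
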