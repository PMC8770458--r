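make_records <- function() {
  set.seed(14)
  expand.grid(animal = paste0("a", 1:3), rep = 1:20,
              group = c("WT", "MUT"),
              stringsAsFactors = FALSE) |>
    transform(value = rnorm(120, mean = ifelse(group == "WT", 10, 12)))
}

test_that("summaries aggregate animal-first with textbook SEM", {
  rec <- data.frame(animal = c("a", "b", "c"), group = "G",
                    value = c(1, 2, 3))
  sm <- summarize_records(rec, "value", "group")
  expect_equal(sm$mean, 2)
  expect_equal(sm$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(sm$n, 3)
  # one animal, one value: mean passes through, SEM flagged undefined
  one <- summarize_records(data.frame(animal = "a", group = "G",
                                      value = 5), "value", "group")
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sem))
  expect_match(one$flag, "SEM")
})

test_that("summaries are invariant to record order", {
  rec <- make_records()
  a <- summarize_records(rec, "value", "group")
  b <- summarize_records(rec[sample(nrow(rec)), ], "value", "group")
  b <- b[match(a$group, b$group), ]
  expect_equal(a$mean, b$mean)
  expect_equal(a$sem, b$sem)
})

test_that("group ratios reproduce the reported fold changes", {
  # per-subtype means as reported for the two genotypes
  sm <- data.frame(group = rep(c("WT", "GENA348"), each = 3),
                   subtype = rep(c("SSM", "IFM", "PNM"), 2),
                   metric = "volume_nm3",
                   mean = c(7.23e8, 7.29e8, 3.70e8,
                            14.23e8, 9.10e8, 4.66e8))
  ratio <- group_ratio(sm, list(group = "GENA348", subtype = "SSM"),
                       list(group = "WT", subtype = "SSM"))
  expect_equal(round(ratio, 2), 1.97)
  sa <- data.frame(group = rep(c("WT", "GENA348"), each = 3),
                   subtype = rep(c("SSM", "IFM", "PNM"), 2),
                   metric = "surface_area_nm2",
                   mean = c(4.72e6, 4.54e6, 2.92e6,
                            7.84e6, 5.46e6, 3.55e6))
  expect_equal(round(group_ratio(sa,
                                 list(group = "GENA348", subtype = "SSM"),
                                 list(group = "WT", subtype = "SSM")), 1),
               1.7)
})

test_that("the t test matches the textbook statistic", {
  x <- c(4.1, 5.2, 6.3, 5.8); y <- c(7.4, 6.9, 8.1, 7.7)
  dd <- data.frame(value = c(x, y),
                   group = rep(c("A", "B"), each = 4))
  res <- compare_groups(dd, "value", "t")
  # hand-computed pooled-variance Student t
  sp2 <- ((3) * var(x) + (3) * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 6)
  expect_lt(abs(res$statistic - t_hand), 1e-10)
  expect_lt(abs(res$p_value - p_hand), 1e-10)
  # identical groups: t = 0, p = 1
  same <- data.frame(value = rep(c(1, 2, 3), 2),
                     group = rep(c("A", "B"), each = 3))
  res0 <- compare_groups(same, "value", "t")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("one-way ANOVA with Tukey matches the reference machinery", {
  same <- data.frame(value = rep(c(1, 2, 3, 4), 3),
                     group = rep(c("A", "B", "C"), each = 4))
  res <- compare_groups(same, "value", "anova1_tukey")
  expect_equal(res$statistic, 0)
  expect_equal(nrow(res$contrasts), 3)
  # random datasets agree with independently computed p-values
  set.seed(8)
  for (i in 1:20) {
    dd <- data.frame(value = rnorm(30),
                     group = rep(c("A", "B", "C"), each = 10))
    res <- compare_groups(dd, "value", "anova1_tukey")
    fit <- aov(value ~ factor(group), data = dd)
    expect_lt(abs(res$p_value - summary(fit)[[1]][["Pr(>F)"]][1]), 1e-6)
    # Tukey p via the studentized range distribution, by hand
    ms <- summary(fit)[[1]][["Mean Sq"]][2]
    means <- tapply(dd$value, dd$group, mean)
    q <- abs(means[["A"]] - means[["B"]]) / sqrt(ms / 10)
    p_hand <- ptukey(q, nmeans = 3, df = 27, lower.tail = FALSE)
    got <- res$contrasts$p_adj[res$contrasts$contrast == "B-A"]
    expect_lt(abs(got - p_hand), 1e-6)
  }
})

test_that("two-way ANOVA applies Sidak contrasts within the second factor", {
  set.seed(9)
  dd <- expand.grid(group = c("WT", "MUT"),
                    subtype = c("SSM", "IFM", "PNM"), rep = 1:5)
  dd$value <- rnorm(nrow(dd)) + (dd$group == "MUT") * 0.8
  res <- compare_groups(dd, "value", "anova2_sidak", "group", "subtype")
  expect_equal(nrow(res$contrasts), 3)
  expect_true(all(res$contrasts$p_adj >= 0 & res$contrasts$p_adj <= 1))
  # empty cells make the interaction inestimable
  dd2 <- dd[!(dd$group == "MUT" & dd$subtype == "PNM"), ]
  expect_error(compare_groups(dd2, "value", "anova2_sidak", "group",
                              "subtype"), "inestimable")
})

test_that("rendered tables round-trip and carry the reference layout", {
  rec <- make_records()
  sm <- summarize_records(rec, "value", "group")
  dir <- withr::local_tempdir()
  paths <- render_tables(sm, NULL, file.path(dir, "tbl"))
  back <- read.csv(paths[["csv"]])
  expect_equal(back$mean, sm$mean)
  expect_equal(back$sem, sm$sem)
  # empty input: header-only CSV
  paths0 <- render_tables(sm[0, ], NULL, file.path(dir, "tbl0"))
  back0 <- read.csv(paths0[["csv"]])
  expect_equal(nrow(back0), 0)
  expect_true("mean" %in% names(back0))
  # morphology-summary layout: subtypes x metrics
  layout <- do.call(rbind, lapply(
    c("length_um", "width_um", "W_O_nm", "W_I_nm", "S_nm"),
    function(m) data.frame(group = "WT",
                           subtype = c("SSM", "IFM", "PNM"),
                           metric = m, mean = 1, sd = 1, sem = 1,
                           n = 3, flag = "")))
  pl <- render_tables(layout, NULL, file.path(dir, "tbl2"))
  shaped <- read.csv(pl[["csv"]])
  expect_equal(nrow(shaped), 15)
  expect_setequal(unique(shaped$subtype), c("SSM", "IFM", "PNM"))
})
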