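toy_table <- function(...) {
  g <- list(...)
  group_table(do.call(rbind, lapply(names(g), function(nm)
    data.frame(sample_id = paste0(nm, seq_along(g[[nm]])), group = nm,
               metric = "m", value = g[[nm]]))))
}

test_that("hydroxyproline converts to collagen content", {
  r <- collagen_from_hyp(300)
  expect_equal(r$collagen_nmol, 1)
  expect_equal(r$collagen_ug, 300)  # 1 nmol x 300 kDa
  expect_equal(collagen_from_hyp(0), list(collagen_nmol = 0,
                                          collagen_ug = 0))
  expect_error(collagen_from_hyp(-5), "nonnegative")
})

test_that("crosslink density is crosslinks per collagen molecule", {
  q <- crosslink_quant(0.5, 300)
  expect_equal(crosslink_density(q), 0.5)
  expect_equal(crosslink_density(crosslink_quant(0, 300)), 0)
  expect_warning(q0 <- crosslink_quant(0.5, 0), "undefined")
  expect_true(is.na(crosslink_density(q0)))
})

test_that("one-way ANOVA matches the textbook decomposition and aov", {
  # zero between-group variance
  a0 <- one_way_anova(toy_table(a = 1:3, b = 1:3, c = 1:3), "m")
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  # hand-computed two-group case: F = t^2 = 13.5
  a <- one_way_anova(toy_table(a = 1:3, b = 4:6), "m")
  expect_equal(a$F, 13.5, tolerance = 1e-12)
  expect_equal(a$df1, 1); expect_equal(a$df2, 4)
  expect_equal(a$p, 2 * pt(sqrt(13.5), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # unequal group sizes against the aov oracle
  set.seed(99)
  tab <- toy_table(a = rnorm(4), b = rnorm(6, 1), c = rnorm(3, 2))
  mine <- one_way_anova(tab, "m")
  orc <- summary(aov(value ~ group, data = tab))[[1]]
  expect_equal(mine$F, orc[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, orc[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_error(one_way_anova(toy_table(a = 1, b = 2:4), "m"),
               "at least 2 samples")
})

test_that("F equals t squared for two groups", {
  set.seed(4)
  for (i in 1:10) {
    tab <- toy_table(a = rnorm(3 + i %% 3), b = rnorm(4, 0.8))
    a <- one_way_anova(tab, "m")
    tt <- posthoc_ttests(tab, "m")
    expect_equal(a$F, tt$t^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p, tolerance = 1e-10)
  }
})

test_that("post hoc t-tests match t.test and flag significance", {
  tab <- toy_table(a = 1:3, b = 4:6)
  tt <- posthoc_ttests(tab, "m")
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0214, tolerance = 1e-2)
  orc <- t.test(1:3, 4:6, var.equal = TRUE)
  expect_equal(tt$t, unname(orc$statistic), tolerance = 1e-10)
  expect_equal(tt$p, orc$p.value, tolerance = 1e-10)
  expect_true(tt$significant)
  expect_equal(tt$stars, "*")
  # identical groups: t = 0, p = 1 even with zero variance
  tt0 <- posthoc_ttests(toy_table(a = c(2, 2), b = c(2, 2)), "m")
  expect_equal(tt0$t, 0); expect_equal(tt0$p, 1)
  # zero variance, unequal means: infinite-t flagged
  tti <- posthoc_ttests(toy_table(a = c(1, 1), b = c(2, 2)), "m")
  expect_true(is.infinite(tti$t))
  expect_equal(tti$p, 0)
  # Welch option against the t.test oracle
  set.seed(10)
  tabw <- toy_table(a = rnorm(5), b = rnorm(7, 1, 3))
  ttw <- posthoc_ttests(tabw, "m", welch = TRUE)
  orcw <- t.test(tabw$value[tabw$group == "a"],
                 tabw$value[tabw$group == "b"])
  expect_equal(ttw$t, unname(orcw$statistic), tolerance = 1e-10)
  expect_equal(ttw$p, orcw$p.value, tolerance = 1e-10)
})

test_that("swapping group order negates t and preserves p", {
  set.seed(12)
  x <- rnorm(4); y <- rnorm(5, 1)
  t1 <- posthoc_ttests(toy_table(a = x, b = y), "m")
  t2 <- posthoc_ttests(toy_table(a = y, b = x), "m")  # labels exchanged
  expect_equal(t1$t, -t2$t, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("star thresholds follow the configured map", {
  expect_equal(significance_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("", "*", "**", "***", "****"))
  expect_equal(significance_stars(0.03, thresholds = c(`*` = 0.01)), "")
})
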