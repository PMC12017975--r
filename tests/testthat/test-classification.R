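test_that("categorization is total with the quoted boundary semantics", {
  for (m in c("DSC", "SDSC")) {
    expect_equal(categorize(m, c(0, 0.59, 0.599999)), rep("large", 3))
    expect_equal(categorize(m, c(0.6, 0.7, 0.799999)), rep("average", 3))
    expect_equal(categorize(m, c(0.8, 0.84, 1)), rep("little", 3))
  }
  expect_equal(categorize("SDSC", 0.58), "large")
  expect_equal(categorize("HD98", c(0, 9.99)), rep("little", 2))
  expect_equal(categorize("HD98", c(10, 19.99)), rep("average", 2))
  expect_equal(categorize("HD98", c(20, 45)), rep("large", 2))
  expect_error(categorize("MDA", 1), "unknown metric|arg")
  expect_error(categorize("DSC", 1.2), "\\[0, 1\\]")
})

test_that("median differences classify with exclusive thresholds", {
  # HD98 falling from 22 to 5 mm is a relevant improvement
  d <- median_difference(22, 5, "HD98")
  expect_equal(d$difference, -17)
  expect_equal(d$category, "relevant improvement")
  # HD98 rising is a deterioration
  expect_equal(median_difference(5, 22, "HD98")$category,
               "relevant deterioration")
  # zero and at-threshold changes are not relevant
  expect_equal(median_difference(0.7, 0.7, "SDSC")$category,
               "no relevant difference")
  expect_equal(median_difference(0.6, 0.7, "DSC")$category,
               "no relevant difference")   # exactly +0.1: not relevant
  expect_equal(median_difference(10, 7, "HD98")$category,
               "no relevant difference")   # exactly -3 mm: not relevant
  expect_equal(median_difference(0.60, 0.75, "DSC")$category,
               "relevant improvement")
  # group_summary inputs work too
  gm <- group_summary(c(0.5, 0.6, 0.7))
  gp <- group_summary(c(0.7, 0.8, 0.9))
  expect_equal(median_difference(gm, gp, "SDSC")$category,
               "relevant improvement")
})

test_that("consistency requires all three metrics to agree", {
  imp <- function(m) median_difference(
    if (m == "HD98") 20 else 0.5, if (m == "HD98") 5 else 0.8, m)
  det <- function(m) median_difference(
    if (m == "HD98") 5 else 0.8, if (m == "HD98") 20 else 0.5, m)
  none <- function(m) median_difference(0.7, 0.7, m)
  expect_equal(consistency_assessment(lapply(c("SDSC", "DSC", "HD98"), imp)),
               "consistent improvement")
  expect_equal(consistency_assessment(lapply(c("SDSC", "DSC", "HD98"), det)),
               "consistent deterioration")
  expect_equal(consistency_assessment(list(imp("SDSC"), imp("DSC"),
                                           none("HD98"))),
               "mixed/none")
  expect_error(consistency_assessment(list(imp("SDSC"), imp("DSC"))),
               "exactly one")
})

test_that("group summaries report median, IQR and range", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(unname(s$range), c(1, 3))
  expect_equal(group_summary(c(1, 2, 3, 4))$median, 2.5)
  set.seed(42)
  u <- runif(100)
  expect_lt(abs(group_summary(u)$median - 0.5), 0.1)
  s2 <- group_summary(c(5, 1, 9, 3, 7))
  expect_true(s2$range[["min"]] <= s2$iqr[["lower"]] &&
                s2$iqr[["lower"]] <= s2$median &&
                s2$median <= s2$iqr[["upper"]] &&
                s2$iqr[["upper"]] <= s2$range[["max"]])
  expect_error(group_summary(numeric(0)), "at least one")
})

test_that("Mann-Whitney U matches small-sample enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  # identical samples: no separation
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 0.01)
  # tie-free random samples across sizes vs exhaustive enumeration
  set.seed(7)
  for (n1 in 1:5) for (n2 in seq(n1, 10 - n1)) {
    x <- sample(seq(1, 100), n1)
    y <- sample(setdiff(seq(1, 100), x), n2)
    got <- mann_whitney_u(x, y)
    want <- bf_mwu_exact(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12,
                 label = sprintf("p for n1=%d n2=%d", n1, n2))
  }
})

test_that("large-sample shift is detected", {
  set.seed(11)
  x <- rnorm(20)
  y <- rnorm(20, mean = 2)
  expect_lte(mann_whitney_u(x, y)$p, 0.05)
})

test_that("pooled comparison: identical groups, exclusions, contracts", {
  set.seed(3)
  n <- 10
  vals <- runif(n, 0.5, 0.9)
  recs <- data.frame(
    case_id = rep(c("c1", "c2"), each = n),
    observer_id = sprintf("o%d", 1:(2 * n)),
    group = rep(c("GTV-", "GTV+"), each = n),
    dsc = rep(vals, 2), sdsc = rep(vals, 2),
    hd98 = rep(vals * 10, 2),
    mda_mean = 1, mda_sd = 0.5,
    observer_volume = 100, reference_volume = 100
  )
  # both groups see the same values: p = 1, no relevant difference
  tab <- pooled_comparison(recs)
  expect_true(all(tab$p > 0.9))
  expect_true(all(tab$difference_category == "no relevant difference"))
  expect_error(pooled_comparison(recs, exclude_cases = c("c1", "c2")),
               "unknown case ids|no records")
  expect_error(pooled_comparison(recs, exclude_cases = "nope"), "unknown")
  sub <- recs[recs$group == "GTV-", ]
  expect_error(pooled_comparison(sub), "no records")
})

test_that("subtype restriction and partition behave set-theoretically", {
  set.seed(5)
  mk_case <- function(cid, shiftv) {
    data.frame(case_id = cid, observer_id = sprintf("%s_o%d", cid, 1:8),
               group = rep(c("GTV-", "GTV+"), each = 4),
               dsc = runif(8, 0.5, 0.9) + rep(c(0, shiftv), each = 4),
               sdsc = runif(8, 0.5, 0.9) + rep(c(0, shiftv), each = 4),
               hd98 = runif(8, 3, 15),
               mda_mean = 1, mda_sd = 1,
               observer_volume = 1, reference_volume = 1)
  }
  recs <- rbind(mk_case("c1", 0.05), mk_case("c2", 0.05),
                mk_case("c3", 0.05))
  recs$dsc <- pmin(recs$dsc, 1); recs$sdsc <- pmin(recs$sdsc, 1)
  all_sub <- list(subtype_definition("everything", c("c1", "c2", "c3")))
  tab_all <- subtype_comparison(recs, all_sub)
  tab_pool <- pooled_comparison(recs)
  expect_equal(tab_all$p, tab_pool$p)
  expect_equal(tab_all$median_1, tab_pool$median_1)
  # disjoint partition: per-subtype record counts sum to the total
  parts <- list(subtype_definition("a", "c1"),
                subtype_definition("b", c("c2", "c3")))
  tab_parts <- subtype_comparison(recs, parts)
  n_per <- tab_parts$n_1[tab_parts$metric == "SDSC"] +
    tab_parts$n_2[tab_parts$metric == "SDSC"]
  expect_equal(sum(n_per), nrow(recs))
  expect_error(subtype_comparison(recs, list(subtype_definition("x", "c9"))),
               "unknown case ids")
})

test_that("large-variation screening flags the right cases", {
  mk <- function(cid, sdsc, dsc, hd) {
    data.frame(case_id = cid, observer_id = sprintf("%s_r%d", cid, 1:3),
               group = "RAD", dsc = dsc, sdsc = sdsc, hd98 = hd,
               mda_mean = 1, mda_sd = 1, observer_volume = 1,
               reference_volume = 1)
  }
  recs <- rbind(mk("bad", 0.4, 0.5, 25),     # large on all three
                mk("mixed", 0.4, 0.85, 5),   # large on one only
                mk("good", 0.9, 0.9, 4))
  expect_equal(large_variation_cases(recs, "all"), "bad")
  expect_setequal(large_variation_cases(recs, "any"), c("bad", "mixed"))
})

test_that("case report assembles medians, categories and consistency", {
  case <- unanimous_case()
  rep <- case_report(case)
  expect_true(all(rep$categories[c("SDSC", "DSC"), ] == "little"))
  expect_true(all(rep$categories["HD98", ] == "little"))
  expect_true(all(vapply(rep$differences, function(d) d$category,
                         character(1)) == "no relevant difference"))
  expect_equal(rep$consistency, "mixed/none")
  # a case without a RAD group is rejected
  broken <- case_study("b", case$groups[c("GTV-", "GTV+")])
  expect_error(case_report(broken), "missing group")
})
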