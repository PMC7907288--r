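test_that("pairwise distance counts follow K(K-1)/2 and known geometry", {
  expect_equal(nrow(t(combn(21, 2))), 210)  # sanity on the oracle itself
  sim21 <- simulate_cohort(simulation_config("human", groups = data.frame(
    label = "EU", genotype = "euploid", treatment = "none", n = 4L,
    age_min = 1, age_max = 2), seed = 2))
  expect_equal(ncol(pairwise_distances(sim21$dataset)$distances), 210)
  sim12 <- simulate_cohort(simulation_config("mouse", seed = 2))
  expect_equal(ncol(pairwise_distances(sim12$dataset)$distances), 66)

  # unit right triangle (plus an apex to satisfy K >= 4): known distances
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.3, 0.3, 1))
  coords <- array(rep(tri, each = 2), dim = c(2, 4, 3))
  d <- landmark_dataset(coords, c("a", "b", "c", "apex"),
                        data.frame(specimen_id = c("s1", "s2")))
  dt <- pairwise_distances(d)
  expect_equal(unname(dt$distances[1, c("a-b", "a-c", "b-c")]),
               c(1, 1, sqrt(2)))
  expect_equal(dt$pair_labels[1:3], c("a-b", "a-c", "a-apex"))
})

test_that("identical groups give null statistics and zero percent significant", {
  sim <- simulate_cohort(two_group_config(10, 10, seed = 5))
  dt <- pairwise_distances(gpa_superimpose(sim$dataset))
  g <- cohort_groups(sim)
  ta <- subset_specimens(dt, g == "A")
  con <- edma_contrast(ta, ta, n_resamples = 500, seed = 3,
                       group_a = "A", group_b = "A2")
  expect_true(all(con$statistic == 1))
  expect_equal(con$percent_significant, 0)
  expect_equal(percent_significant(con), 0)
  # CIs bracket the point estimate
  expect_true(all(con$ci_low <= con$statistic + 1e-12))
  expect_true(all(con$ci_high >= con$statistic - 1e-12))
})

test_that("contrasts are deterministic given a seed and symmetric under group swap", {
  sim <- simulate_cohort(two_group_config(8, 12, delta = 0.08, seed = 9))
  dt <- pairwise_distances(gpa_superimpose(sim$dataset))
  g <- cohort_groups(sim)
  ta <- subset_specimens(dt, g == "A"); tb <- subset_specimens(dt, g == "B")
  c1 <- edma_contrast(ta, tb, n_resamples = 400, seed = 11,
                      group_a = "A", group_b = "B")
  c2 <- edma_contrast(ta, tb, n_resamples = 400, seed = 11,
                      group_a = "A", group_b = "B")
  expect_identical(c1$significant, c2$significant)
  expect_identical(c1$ci_low, c2$ci_low)
  # swap: statistics invert about the null, significance set preserved
  c3 <- edma_contrast(tb, ta, n_resamples = 400, seed = 11,
                      group_a = "B", group_b = "A")
  expect_equal(c3$statistic, 1 / c1$statistic, tolerance = 1e-12)
  expect_identical(c3$significant, c1$significant)
  expect_equal(c3$ci_low, 1 / c1$ci_high, tolerance = 1e-12)
})

test_that("a displaced landmark is flagged through its incident distances", {
  base <- make_template(12)
  n <- 18; K <- 12
  mkgrp <- function(shift, seed) {
    coords <- array(NA_real_, dim = c(n, K, 3))
    withr::with_seed(seed, {
      for (i in seq_len(n)) {
        s <- base
        s[1, ] <- s[1, ] + shift      # landmark 1 displaced
        coords[i, , ] <- s + rnorm(K * 3, sd = 0.01)
      }
    })
    landmark_dataset(coords, rownames(base),
                     data.frame(specimen_id = sprintf("g%d_%02d", seed,
                                                      seq_len(n))))
  }
  da <- pairwise_distances(mkgrp(c(0, 0, 0), 1))
  db <- pairwise_distances(mkgrp(c(0, 0.1, 0), 2))  # 10 sigma displacement
  con <- edma_contrast(da, db, n_resamples = 1000, seed = 4,
                       group_a = "ref", group_b = "shift")
  touches <- con$pairs[, 1] == 1 | con$pairs[, 2] == 1
  # nearly all distances incident to the displaced landmark are flagged,
  # the rest reject at about the nominal alpha rate
  expect_gt(mean(con$significant[touches]), 0.8)
  expect_lt(mean(con$significant[!touches]), 0.3)
  wf <- significance_wireframe(con, base)
  expect_equal(nrow(wf), sum(con$significant))
  expect_true(all(wf$from == 1 | wf$to == 1 |
                    (wf$from != 1 & wf$to != 1)))
  # star around landmark 1 dominates the wireframe
  expect_gt(mean(wf$from == 1 | wf$to == 1), 0.6)
})

test_that("power is monotone in effect size", {
  pct <- vapply(c(0, 0.05, 0.12), function(delta) {
    sim <- simulate_cohort(two_group_config(15, 15, delta = delta, seed = 21))
    dt <- pairwise_distances(gpa_superimpose(sim$dataset))
    g <- cohort_groups(sim)
    con <- edma_contrast(subset_specimens(dt, g == "A"),
                         subset_specimens(dt, g == "B"),
                         n_resamples = 500, seed = 6,
                         group_a = "A", group_b = "B")
    con$percent_significant
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_gt(pct[3], 30)
})

test_that("contrast input validation rejects mismatches and tiny groups", {
  sim <- simulate_cohort(two_group_config(6, 6, seed = 2))
  dt <- pairwise_distances(gpa_superimpose(sim$dataset))
  g <- cohort_groups(sim)
  ta <- subset_specimens(dt, g == "A"); tb <- subset_specimens(dt, g == "B")
  tb_bad <- tb; tb_bad$pair_labels <- rev(tb_bad$pair_labels)
  expect_error(edma_contrast(ta, tb_bad), "mismatched pair labels")
  expect_error(edma_contrast(subset_specimens(ta, 1:2), tb), "at least 3")
})

test_that("wireframe of an all-null contrast is empty", {
  sim <- simulate_cohort(two_group_config(10, 10, seed = 5))
  dt <- pairwise_distances(gpa_superimpose(sim$dataset))
  g <- cohort_groups(sim)
  ta <- subset_specimens(dt, g == "A")
  con <- edma_contrast(ta, ta, n_resamples = 300, seed = 3,
                       group_a = "A", group_b = "A2")
  expect_equal(nrow(significance_wireframe(con, make_template(12))), 0)
})
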