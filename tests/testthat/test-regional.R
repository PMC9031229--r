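test_that("coefficient of variation: dispersion, scale invariance, errors", {
  expect_equal(coefficient_of_variation(c(4, 4, 4)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  x <- c(1.2, 8.8, 3.3, 5.1)
  expect_equal(coefficient_of_variation(7 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "mean > 0")
})

test_that("disparity table covers national plus four regions per year", {
  sc <- score_panel(generate_indicator_panel(sim_config(seed = 2)))
  disp <- disparity_table(sc)
  expect_setequal(unique(disp$group),
                  c("national", "east", "central", "west", "northeast"))
  expect_equal(nrow(disp), 5L * 3L * 4L)  # groups x years x kinds
  expect_true(all(disp$cv >= 0))
  # regional CV must equal the CV of member provinces only
  sch <- region_scheme()
  east_2005 <- sc$A[sc$year == 2005 & sch[sc$province] == "east"]
  expect_equal(disp$cv[disp$group == "east" & disp$year == 2005 &
                         disp$kind == "A"],
               sd(east_2005) / mean(east_2005))
})

test_that("percent change reproduces the published growth arithmetic", {
  expect_equal(round(percent_change(0.5595, 0.5833), 2), 4.25)
  expect_equal(round(percent_change(0.5637, 0.6456), 2), 14.53)
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(0, 1), "positive")
  # path-reversal identity pc(a,b) = -pc(b,a) * b/a
  a <- 0.52; b <- 0.71
  expect_equal(percent_change(a, b), -percent_change(b, a) * b / a)
})

test_that("jenks breaks find the obvious splits deterministically", {
  br <- jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_length(br, 1L)
  expect_equal(as.vector(br), 3)

  # k well-separated clusters are cut between clusters
  x <- c(rnorm(10, 0), rnorm(10, 50), rnorm(10, 100))
  br3 <- jenks_breaks(x, k = 3)
  expect_equal(sum(x <= br3[1L]), 10L)
  expect_equal(sum(x <= br3[2L]), 20L)

  expect_error(jenks_breaks(c(1, 1, 2, 2), k = 3), "distinct")
  # determinism
  set.seed(31); y <- runif(40)
  expect_identical(jenks_breaks(y, 5), jenks_breaks(y, 5))
})

test_that("dynamic program attains the exhaustive-partition optimum", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(6:14, 1L)
    k <- sample(2:5, 1L)
    x <- round(runif(n, 0, 100), 2)
    if (length(unique(x)) < k) next
    br <- jenks_breaks(x, k)
    expect_equal(attr(br, "ssd"), oracle_jenks_ssd(x, k),
                 tolerance = 1e-10)
  }
  # and at a bigger n once
  x <- runif(60)
  br <- jenks_breaks(x, 5)
  # objective is consistent with the implied classification
  cls <- classify_levels(x, br)
  ssd <- sum(tapply(x, cls, function(v) sum((v - mean(v))^2)))
  expect_equal(attr(br, "ssd"), ssd, tolerance = 1e-10)
})

test_that("ties at a break fall into the lower class", {
  br <- c(3, 6)
  lv <- classify_levels(c(3, 3.0001, 6, 6.0001), br)
  expect_equal(as.integer(lv), c(1L, 2L, 2L, 3L))
})

test_that("classification shares and transitions add up", {
  sc <- score_panel(generate_indicator_panel(sim_config(seed = 12)))
  ct <- classify_and_transition(sc, k = 5, per_year = TRUE)
  # shares per year sum to 100% within one-decimal rounding
  for (yr in unique(ct$shares$year)) {
    tot <- sum(ct$shares$share_pct[ct$shares$year == yr])
    expect_lt(abs(tot - 100), 0.3)
    expect_equal(sum(ct$shares$count[ct$shares$year == yr]), 31L)
  }
  tr <- ct$transitions
  expect_equal(nrow(tr), 62L)  # 31 provinces x 2 period pairs
  expect_true(all(tr$direction %in% c("up", "down", "stable")))
  expect_true(all(!tr$leap | tr$direction != "stable"))

  # identical classifications in both waves -> all transitions stable
  flat <- sc
  flat$A <- rep(sc$A[sc$year == 2005], times = 3L)
  ct2 <- classify_and_transition(flat, k = 5)
  expect_true(all(ct2$transitions$direction == "stable"))
})

test_that("constructed moves produce the expected transition records", {
  # low -> medium -> higher for one province (two single-step ups) and a
  # lower -> high leap for another, everything else pinned stable
  provs <- province_roster()
  base <- seq(0.10, 0.70, length.out = 31)
  names(base) <- provs
  waves <- c(2005L, 2010L, 2015L)
  # five clean clusters so breaks are unambiguous
  cluster_vals <- c(low = 0.1, lower = 0.3, medium = 0.5, higher = 0.7,
                    high = 0.9)
  assign_cluster <- rep(names(cluster_vals), length.out = 31)
  names(assign_cluster) <- provs
  mk_wave <- function(yr, overrides) {
    lvl <- assign_cluster
    lvl[names(overrides)] <- overrides
    data.frame(province = provs, year = yr,
               A = cluster_vals[lvl] + seq(0, 0.02, length.out = 31),
               stringsAsFactors = FALSE)
  }
  sc <- rbind(
    mk_wave(2005L, c(Beijing = "low", Tianjin = "lower")),
    mk_wave(2010L, c(Beijing = "medium", Tianjin = "lower")),
    mk_wave(2015L, c(Beijing = "higher", Tianjin = "high")))
  ct <- classify_and_transition(sc, k = 5)
  tr <- ct$transitions
  bj <- tr[tr$province == "Beijing", ]
  expect_equal(bj$direction, c("up", "up"))
  expect_equal(bj$leap, c(TRUE, FALSE))  # low->medium is a 2-class leap
  tj <- tr[tr$province == "Tianjin", ]
  expect_equal(tj$direction, c("stable", "up"))
  expect_true(tj$leap[2L])               # lower->high jumps 3 classes
  # exactly those three leap/up events among the overridden provinces
  others <- tr[!tr$province %in% c("Beijing", "Tianjin"), ]
  expect_true(all(others$direction == "stable"))
})

test_that("class-share arithmetic over the 31-unit roster", {
  expect_equal(class_share(18), 58.1)
  expect_equal(class_share(24), 77.4)
  expect_equal(class_share(10), 32.3)
  expect_equal(round(percent_change(18, 24), 1), 33.3)
})
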