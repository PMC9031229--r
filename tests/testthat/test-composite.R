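test_that("min-max standardization honors polarity and endpoints", {
  expect_equal(as.vector(standardize_minmax(c(1, 3, 5), "positive")),
               c(0, 0.5, 1))
  # negative polarity: minimum maps to 1, maximum to 0
  neg <- standardize_minmax(c(2, 7, 4), "negative")
  expect_equal(as.vector(neg)[which.min(c(2, 7, 4))], 1)
  expect_equal(as.vector(neg)[which.max(c(2, 7, 4))], 0)
  # algebraic identity between the two polarities
  x <- c(0.3, 9.1, 4.4, 2.2, 6.6)
  expect_equal(as.vector(standardize_minmax(x, "negative")),
               1 - as.vector(standardize_minmax(x, "positive")))
  # constant column -> midpoint with a warning
  expect_warning(p <- standardize_minmax(c(4, 4, 4), "positive"),
                 "constant")
  expect_equal(as.vector(p), rep(0.5, 3))
  expect_error(standardize_minmax(numeric(0), "positive"), "empty")
})

test_that("entropy weights hit the degenerate endpoints and symmetry", {
  P <- cbind(A = c(0, 1), B = c(0.5, 0.5))
  w <- entropy_weights(P)
  expect_equal(w$entropy, c(0, 1))
  expect_equal(w$weight, c(1, 0))

  # duplicated column receives equal weight
  P2 <- cbind(a = c(0.1, 0.5, 0.9), b = c(0.1, 0.5, 0.9),
              c = c(0.9, 0.2, 0.4))
  w2 <- entropy_weights(P2)
  expect_equal(w2$weight[1L], w2$weight[2L])
  expect_equal(sum(w2$weight), 1, tolerance = 1e-12)

  expect_error(entropy_weights(cbind(x = c(0.5, 0.5), y = c(1, 1))),
               "no discriminating information")
})

test_that("entropy weights and scores match the hand-computed fixture", {
  # expected values computed by direct evaluation of the share/entropy/
  # divergence formulas on this 4 x 3 matrix (frozen)
  P <- cbind(c1 = c(0.2, 0.4, 0.6, 0.8), c2 = c(0.1, 0.9, 0.3, 0.7),
             c3 = c(1.0, 0.0, 0.5, 0.5))
  w <- entropy_weights(P)
  expect_equal(w$entropy,
               c(0.9232196723355078, 0.8375716232049936, 0.75),
               tolerance = 1e-10)
  expect_equal(w$divergence,
               c(0.07678032766449217, 0.16242837679500643, 0.25),
               tolerance = 1e-10)
  expect_equal(w$weight,
               c(0.1569479998303031, 0.3320226629541785,
                 0.5110293372155185),
               tolerance = 1e-10)
  expect_equal(unname(aggregate_scores(P, w)),
               c(0.5756212034769970, 0.3615995965908819,
                 0.4492902673921946, 0.6134889325399266),
               tolerance = 1e-10)
})

test_that("aggregation is the plain weighted sum, renormalized per scope", {
  P <- cbind(a = c(0.4, 1), b = c(0.6, 1))
  w <- data.frame(code = c("a", "b"), weight = c(0.5, 0.5))
  expect_equal(unname(aggregate_scores(P, w)), c(0.5, 1))
  # all-ones standardized rows score exactly 1
  w2 <- data.frame(code = c("a", "b"), weight = c(0.2, 0.3))
  expect_equal(unname(aggregate_scores(P, w2, renormalize = TRUE))[2L], 1)
  expect_error(aggregate_scores(P, w, scope = c("a", "zz")), "zz")
})

test_that("weights are permutation-equivariant and constant-robust", {
  set.seed(5)
  P <- matrix(runif(40), 8, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  w <- entropy_weights(P)
  # shuffling rows leaves weights unchanged
  w_rows <- entropy_weights(P[sample(8), ])
  expect_equal(w_rows$weight, w$weight)
  # shuffling columns permutes weights accordingly
  perm <- sample(5)
  w_cols <- entropy_weights(P[, perm])
  expect_equal(w_cols$weight, w$weight[perm])
  # adding a constant column: weight 0, other weights unchanged
  P3 <- cbind(P, cc = 0.7)
  w3 <- entropy_weights(P3)
  expect_equal(w3$weight[6L], 0)
  expect_equal(w3$weight[1:5], w$weight)
})

test_that("scores are invariant to positive affine rescaling of raw data", {
  cfg <- sim_config(seed = 3)
  pan <- generate_indicator_panel(cfg)
  sc1 <- score_panel(pan)
  scaled <- as.data.frame(pan)
  # rescale two raw columns (one of each polarity): y = 3x + 10
  sel <- scaled$code %in% c("DR", "AYE")
  scaled$value[sel] <- 3 * scaled$value[sel] + 10
  sc2 <- score_panel(as_panel(scaled))
  expect_equal(sc2$A, sc1$A, tolerance = 1e-12)
  expect_equal(sc2$B1, sc1$B1, tolerance = 1e-12)
})

test_that("score_panel produces 93 in-range rows and obeys dominance", {
  cfg <- sim_config(seed = 4)
  pan <- generate_indicator_panel(cfg)
  sc <- score_panel(pan)
  expect_equal(nrow(sc), 93L)
  for (col in c("B1", "B2", "B3", "A"))
    expect_true(all(sc[[col]] >= 0 & sc[[col]] <= 1))

  # a province dominating every indicator attains the maximal index
  dom <- as.data.frame(pan)
  reg <- indicator_registry()
  for (code in reg$code) {
    sel <- dom$code == code
    best <- if (reg$polarity[reg$code == code] == "negative")
      min(dom$value[sel]) - 1 else max(dom$value[sel]) + 1
    dom$value[sel & dom$province == "Shanghai"] <- best
  }
  sc_dom <- score_panel(as_panel(dom))
  expect_equal(sc_dom$province[which.max(sc_dom$A)], "Shanghai")
})

test_that("overall index decomposes exactly into weighted dimension scores", {
  cfg <- sim_config(seed = 6)
  sc <- score_panel(generate_indicator_panel(cfg))
  w <- attr(sc, "weights")
  reg <- indicator_registry()
  dim_w <- vapply(c("health", "participation", "security"), function(d)
    sum(w$weight[w$code %in% reg$code[reg$dimension == d]]), numeric(1))
  recon <- dim_w["health"] * sc$B1 + dim_w["participation"] * sc$B2 +
    dim_w["security"] * sc$B3
  expect_equal(recon, sc$A, tolerance = 1e-12)
})

test_that("pooled and per-wave scoring agree when wave margins coincide", {
  # build a panel whose waves hold identical column multisets: wave w is a
  # row permutation of wave 1, so per-wave min/max and share distributions
  # coincide and the entropy divergences differ only by a common factor
  provs <- province_roster()
  set.seed(21)
  base <- matrix(runif(31 * 16, 1, 9), 31, 16,
                 dimnames = list(NULL, indicator_registry()$code))
  rows <- list()
  for (w in seq_along(c(2005, 2010, 2015))) {
    perm <- if (w == 1L) seq_len(31) else sample(31)
    for (j in seq_len(16)) {
      rows[[length(rows) + 1L]] <- data.frame(
        province = provs, year = c(2005, 2010, 2015)[w],
        code = colnames(base)[j], value = base[perm, j],
        stringsAsFactors = FALSE)
    }
  }
  pan <- as_panel(do.call(rbind, rows))
  pooled <- score_panel(pan, pooling = "pooled")
  per_wave <- score_panel(pan, pooling = "per_wave")
  key <- function(s) s[order(s$province, s$year), c("B1", "B2", "B3", "A")]
  expect_equal(key(per_wave), key(pooled), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("score_panel rejects incomplete panels, naming the gap", {
  pan <- generate_indicator_panel(sim_config(seed = 8))
  drop <- !(pan$province == "Hainan" & pan$year == 2010 &
              pan$code == "SPP")
  expect_error(score_panel(as_panel(as.data.frame(pan)[drop, ])),
               "missing cell.*Hainan\\|2010.*SPP")
})
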