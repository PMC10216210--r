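test_that("initial grids follow the (k, 2k, 8k) convention", {
  g <- init_grids(8)
  expect_equal(g$grids$nk1, c(8L, 16L, 64L))
  expect_equal(g$grids$nk2, c(8L, 16L, 64L))
  expect_equal(g$grids$k2, c(8L, 16L, 64L))
  expect_equal(g$grids$s2, c(1 / 8, 1 / 4, 1))   # stride as a fraction of k2
  expect_equal(realize_s2(g, 64L), c(8L, 16L, 64L))
  expect_equal(g$grids$nfb, c(1L, 3L, 7L))
})

test_that("round enumeration takes the Cartesian product with clamps", {
  combos <- enumerate_round(init_grids(8))
  expect_equal(nrow(combos), 243L)            # 3^5, nothing removed
  expect_equal(attr(combos, "n_removed"), 0L)
  expect_equal(anyDuplicated(combos), 0L)
  expect_true(all(combos$s2 <= combos$k2))
  expect_true(all(combos$s2 == pmax(1, round(combos$s2_ratio * combos$k2))))

  # freezing four hyperparameters leaves the three nfb candidates
  g1 <- init_grids(8)
  g1$grids$nk1 <- 16L; g1$grids$nk2 <- 16L
  g1$grids$k2 <- 64L; g1$grids$s2 <- 1 / 8
  expect_equal(nrow(enumerate_round(g1)), 3L)

  # an absolute stride grid above every k2 candidate leaves nothing
  g2 <- init_grids(8)
  g2$s2_is_ratio <- FALSE
  g2$grids$k2 <- c(2L, 3L, 4L)
  g2$grids$s2 <- c(8L, 9L, 10L)
  expect_error(enumerate_round(g2), "no valid")
})

test_that("marginal trends classify performance orderings", {
  grid <- expand.grid(nfb = 1L, nk1 = c(8L, 16L, 64L), nk2 = 8L, k2 = 32L,
                      s2 = 8L)
  res <- tibble::as_tibble(grid)
  anchor <- list(nfb = 1L, nk2 = 8L, k2 = 32L, s2 = 8L)
  for (case in list(list(p = c(60, 70, 80), want = "increasing"),
                    list(p = c(60, 80, 70), want = "peaked"),
                    list(p = c(80, 70, 60), want = "decreasing"),
                    list(p = c(70, 70, 80), want = "peaked"))) {
    res$test_acc <- case$p
    expect_equal(as.character(marginal_trend(res, "nk1", anchor)), case$want)
  }
  expect_error(marginal_trend(res[1:2, ], "nk1", anchor,
                              values = c(8L, 16L, 64L)), "missing")
})

test_that("grid updates implement the shift and refine rules", {
  expect_equal(as.integer(next_grid(c(8, 16, 64), "increasing")),
               c(64L, 128L, 512L))
  expect_equal(as.integer(next_grid(c(8, 16, 64), "peaked")),
               c(12L, 16L, 40L))
  expect_equal(as.integer(next_grid(c(8, 16, 64), "decreasing")),
               c(1L, 4L, 8L))
  # oscillation guard: a reversal refines instead of shifting
  expect_equal(as.integer(next_grid(c(8, 16, 64), "increasing",
                                    prev_trend = "decreasing")),
               c(12L, 16L, 40L))
  # collapsed values are separated by incrementing collisions
  expect_equal(as.integer(next_grid(c(1, 2, 3), "decreasing")),
               c(1L, 2L, 3L))
})

test_that("round-2 refinements reproduce the printed stride grids", {
  # stride ratios (1/8, 1/4, 1): a decreasing trend lands on the
  # (k2/64 .. k2/8) refinement window
  dec <- next_grid(c(1 / 8, 1 / 4, 1), "decreasing", integer = FALSE)
  expect_equal(as.numeric(dec)[1], 1 / 64)
  expect_equal(as.numeric(dec)[3], 1 / 8)
  # an increasing trend clamped at s2 <= k2 collapses onto k2 itself
  inc <- next_grid(c(1 / 8, 1 / 4, 1), "increasing", upper = 1,
                   integer = FALSE)
  expect_equal(as.numeric(inc), c(1, 1, 1))
  expect_true(attr(inc, "frozen"))
  # k2 shifted up clamps at the feature width 2 * n_bins * nfb
  k2up <- next_grid(c(8, 16, 64), "increasing", upper = 220)
  expect_equal(as.integer(k2up), c(64L, 128L, 220L))
})

test_that("seed-set selection ranks by test acc, train acc, then loss", {
  res <- tibble::tibble(
    nfb = 1L, nk1 = c(8L, 16L, 64L), nk2 = 8L, k2 = 32L, s2 = 8L,
    test_acc = c(90, 95, 95), train_acc = c(99, 98, 99),
    loss = c(0.2, 0.1, 0.3))
  top <- select_seed_sets(res, 2)
  expect_equal(top$nk1, c(64L, 16L))          # acc tie -> higher train acc
  res$train_acc <- 99
  res$loss <- c(0.2, 0.3, 0.1)
  expect_equal(select_seed_sets(res, 1)$nk1, 64L)  # then lower loss
  res$test_acc <- 90; res$loss <- 0.1
  expect_equal(select_seed_sets(res, 2)$nk1, c(8L, 16L))  # enumeration order
  expect_warning(allr <- select_seed_sets(res, 5), "fewer")
  expect_equal(nrow(allr), 3L)
})

test_that("the search stops once round-over-round gains are trivial", {
  expect_false(should_stop(78))
  expect_false(should_stop(c(70, 78)))
  expect_true(should_stop(c(78.6, 79.0)))
  expect_true(should_stop(c(70, 78, 78.4)))
})

test_that("correlation diagnostics flag exact and undefined relations", {
  set.seed(10)
  combos <- enumerate_round(init_grids(8))
  res <- dplyr::mutate(combos,
                       test_acc = 2 * k2,
                       train_acc = runif(dplyr::n(), 50, 100),
                       loss = runif(dplyr::n(), 0.1, 2))
  cc <- hyperparam_correlations(res)
  r_k2 <- cc$correlations$r[cc$correlations$param == "k2" &
                            cc$correlations$metric == "test_acc"]
  expect_equal(r_k2, 1)
  # accuracy independent of nk1: |r| < 0.2 at n = 243
  res$test_acc <- runif(nrow(res), 0, 100)
  cc2 <- hyperparam_correlations(res)
  r_nk1 <- cc2$correlations$r[cc2$correlations$param == "nk1" &
                              cc2$correlations$metric == "test_acc"]
  expect_lt(abs(r_nk1), 0.2)
  expect_true(all(cc2$pairwise$test_acc_norm >= 0 &
                  cc2$pairwise$test_acc_norm <= 1))
  # constant column -> undefined, not zero
  res$nfb <- 3L
  cc3 <- hyperparam_correlations(res)
  nfb_rows <- cc3$correlations[cc3$correlations$param == "nfb", ]
  expect_true(all(is.na(nfb_rows$r)))
  expect_true(all(nfb_rows$undefined))
})

# Smooth unimodal benchmark objective over the searchable hyperparameters,
# peaked inside the initial (k, 2k, 8k) spans for nch = 8.
unimodal_objective <- function(opt = c(nk1 = 24, nk2 = 20, k2 = 48, s2 = 12)) {
  function(hp) {
    d <- sum((log2(c(hp$nk1, hp$nk2, hp$k2, hp$s2)) - log2(opt))^2)
    f <- 100 * exp(-d / 16) * exp(-0.1 * (hp$nfb - 3)^2)
    list(test_acc = f, train_acc = f, loss = 100 - f)
  }
}

test_that("two rounds of search land within 5% of a unimodal optimum", {
  obj <- unimodal_objective()
  st <- run_agd(obj, nch = 8, rounds = 1, top_m = 2)
  best <- st$best
  f_best <- best$test_acc[1]
  f_opt <- obj(hyperparam_set(3, 24, 20, 48, 12))$test_acc
  expect_gte(f_best, 0.95 * f_opt)
  expect_length(st$rounds, 2L)                # initial round + 1 refinement
  expect_equal(nrow(st$rounds[[1]]$results), 243L)
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(glance(st)$best_test_acc, f_best)
})
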