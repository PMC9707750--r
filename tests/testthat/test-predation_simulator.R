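# Monte-Carlo pairing simulation against closed-form and enumeration oracles.

test_that("single feasible pair is always accepted", {
  comm <- pair_community(10, "grabber", 5, "cryptobenthic")
  pool <- simulate_events(comm, config = simulation_config(500, 2), seed = 1)
  expect_equal(pool$acceptance, 1.0)
  expect_equal(pool$attempted, 1000)
  # traits match the closed-form single-pair values
  expect_equal(unique(pool$events$gape), 1.74, tolerance = 1e-12)
  expect_equal(unique(pool$events$depth), 1.09835700228, tolerance = 1e-9)
  expect_equal(unique(pool$events$ratio), 0.631239656484, tolerance = 1e-9)
})

test_that("single infeasible pair is always rejected", {
  # depth(10 cm crypto) / gape(10 cm grabber) = 2.2585/1.74 ~ 1.298 > 0.7
  comm <- pair_community(10, "grabber", 10, "cryptobenthic")
  pool <- simulate_events(comm, config = simulation_config(500, 2), seed = 1)
  expect_equal(pool$acceptance, 0.0)
  expect_equal(nrow(pool$events), 0)
})

test_that("no stored event violates the feasibility window or pairs a fish
           with itself", {
  comm <- toy_community(seed = 1, n = 40)
  pool <- simulate_events(comm, config = simulation_config(5000, 4), seed = 2)
  expect_true(all(pool$events$ratio >= 0.14 & pool$events$ratio <= 0.7))
  expect_true(all(pool$events$predator_id != pool$events$prey_id))
  expect_true(all(pool$events$rep %in% 1:4))
})

test_that("simulation is deterministic under a fixed seed", {
  comm <- toy_community(seed = 3, n = 30)
  a <- simulate_events(comm, config = simulation_config(2000, 3), seed = 5)
  b <- simulate_events(comm, config = simulation_config(2000, 3), seed = 5)
  expect_identical(a$events, b$events)
  c <- simulate_events(comm, config = simulation_config(2000, 3), seed = 6)
  expect_false(identical(a$events$prey_id, c$events$prey_id))
})

test_that("Monte-Carlo estimates converge to full pair enumeration", {
  comm <- toy_community(seed = 42, n = 40)
  enum <- oracle_enumerate(comm)
  exact_acc <- mean(enum$feasible)
  n_attempts <- 200000
  pool <- simulate_events(comm,
                          config = simulation_config(20000, 10), seed = 9)
  se <- sqrt(exact_acc * (1 - exact_acc) / n_attempts)
  expect_lt(abs(pool$acceptance - exact_acc), 3 * se)
  # size medians over feasible events: discrete atoms, so the MC median
  # lands on the exact enumeration median
  feas <- enum[enum$feasible, ]
  expect_equal(summarize_sizes(pool, "predator")$median,
               oracle_median(feas$predator_tl))
  expect_equal(summarize_sizes(pool, "prey")$median,
               oracle_median(feas$prey_tl))
  # per-bin prey-group contributions within 3 binomial SE of enumeration
  contrib <- prey_group_contributions(pool)
  exact <- oracle_contributions(enum)
  counts <- bin_events(pool)
  for (bin in names(exact)) {
    nb <- counts[[bin]]
    for (g in prey_groups()) {
      c_hat <- contrib$mean[contrib$bin == bin & contrib$prey_group == g]
      c_star <- exact[[bin]][[g]]
      tol <- 3 * sqrt(c_star * (1 - c_star) / max(nb, 1)) + 1e-6
      expect_lt(abs(c_hat - c_star), max(tol, 0.02))
    }
  }
})

test_that("size summaries match direct computation on the event table", {
  comm <- toy_community(seed = 10, n = 25)
  pool <- simulate_events(comm, config = simulation_config(3000, 2), seed = 3)
  s <- summarize_sizes(pool, "predator")
  expect_equal(s$median, median(pool$events$predator_tl))
  expect_equal(s$mean, mean(pool$events$predator_tl))
  expect_true(s$interval_low <= s$median && s$median <= s$interval_high)
  expect_error(summarize_sizes(empty <- reefpred:::empty_pool(10, c(5, 10))),
               "empty")
})

test_that("binning is right-closed with explicit underflow and overflow", {
  pool <- reefpred:::empty_pool(0, seq(5, 50, by = 5))
  pool$events <- data.frame(rep = 1, predator_id = 1, prey_id = 2,
                            predator_tl = c(4.9, 5.0, 5.1, 50.0, 50.1),
                            prey_tl = 1, gape = 1, depth = 0.5, ratio = 0.5,
                            prey_group = "cryptobenthic",
                            predator_group = "grabber")
  counts <- bin_events(pool)
  expect_equal(counts[["(0,5]"]], 2L)
  expect_equal(counts[["(5,10]"]], 1L)
  expect_equal(counts[["(45,50]"]], 1L)
  expect_equal(counts[["(50,Inf]"]], 1L)
  expect_equal(sum(counts), 5L)
  # uniform sizes spread evenly over bins
  set.seed(4)
  pool$events <- data.frame(rep = 1, predator_id = 1, prey_id = 2,
                            predator_tl = runif(5000, 0, 50),
                            prey_tl = 1, gape = 1, depth = 0.5, ratio = 0.5,
                            prey_group = "cryptobenthic",
                            predator_group = "grabber")
  counts <- bin_events(pool)
  inner <- counts[setdiff(names(counts), "(50,Inf]")]
  expect_true(all(abs(inner - 500) < 3 * sqrt(5000 * 0.1 * 0.9) + 1))
  expect_error(bin_events(pool, edges = c(10, 5)), "increasing")
})

test_that("contribution arithmetic normalises within every non-empty bin", {
  pool <- reefpred:::empty_pool(0, seq(5, 50, by = 5))
  pool$events <- data.frame(rep = 1, predator_id = 1, prey_id = 2,
                            predator_tl = rep(7, 10), prey_tl = 1, gape = 1,
                            depth = 0.5, ratio = 0.5,
                            prey_group = rep(c("cryptobenthic", "social"),
                                             c(9, 1)),
                            predator_group = "grabber")
  contrib <- prey_group_contributions(pool)
  bin <- "(5,10]"
  get <- function(g) contrib$mean[contrib$bin == bin & contrib$prey_group == g]
  expect_equal(get("cryptobenthic"), 0.9)
  expect_equal(get("social"), 0.1)
  expect_equal(get("epibenthic"), 0.0)
  # empty bins are flagged, not NaN
  expect_true(all(is.na(contrib$mean[!contrib$has_events])))
  expect_false(any(is.nan(contrib$mean)))
  # across a stochastic pool, every non-empty bin sums to 1
  comm <- toy_community(seed = 6, n = 35)
  pool2 <- simulate_events(comm, config = simulation_config(4000, 3), seed = 8)
  c2 <- prey_group_contributions(pool2)
  sums <- tapply(c2$mean[c2$has_events], droplevels(c2$bin[c2$has_events]), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("a prey group made infeasible for every predator contributes zero", {
  # epibenthic fish of 60 cm have depth far above every gape here
  df <- data.frame(
    species = sprintf("sp%d", 1:20),
    total_length = c(rep(8, 4), rep(2, 8), rep(60, 8)),
    prey_group = rep(c("social", "cryptobenthic", "epibenthic"), c(4, 8, 8)),
    is_predator = rep(c(TRUE, FALSE), c(4, 16)),
    predator_group = c(rep("grabber", 4), rep(NA, 16)),
    stringsAsFactors = FALSE)
  comm <- reefpred:::as_reef_community(df)
  pool <- simulate_events(comm, config = simulation_config(5000, 4), seed = 2)
  expect_gt(nrow(pool$events), 0)
  contrib <- prey_group_contributions(pool)
  epi <- contrib[contrib$prey_group == "epibenthic" & contrib$has_events, ]
  expect_true(all(epi$mean == 0))
  expect_true(all(epi$max == 0))
})

test_that("degenerate communities raise domain errors", {
  one <- pair_community(10, "grabber", 5, "cryptobenthic")[1, ]
  expect_error(simulate_events(reefpred:::as_reef_community(one)),
               "two individuals")
})
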