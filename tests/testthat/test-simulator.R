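test_that("the variation inventory and default unit design match the stimulus layout", {
  inv <- lma_variation_inventory()
  expect_equal(sum(inv$gesture == "knocking"), 24L)
  expect_equal(sum(inv$gesture == "direction"), 19L)
  expect_equal(as.vector(table(inv$category[inv$gesture == "knocking"])[
    c("Effort", "Phrasing", "Shape", "Space")]), c(7L, 3L, 6L, 8L))
  expect_equal(as.vector(table(inv$category[inv$gesture == "direction"])[
    c("Effort", "Phrasing", "Shape", "Space")]), c(7L, 3L, 6L, 3L))

  des <- lma_unit_design()
  expect_equal(nrow(des), 22L)
  expect_equal(sum(des$gesture == "knocking"), 12L)
  expect_equal(sum(des$gesture == "direction"), 10L)
  # one neutral per gesture
  expect_equal(sum(des$intended_category == "Neutral" & des$gesture == "knocking"), 1L)
  expect_equal(sum(des$intended_category == "Neutral" & des$gesture == "direction"), 1L)
  # every intended leaf is legal and consistent with its category
  g <- lma_graph()
  leaves <- enumerate_paths(g)
  for (i in seq_len(nrow(des))) {
    expect_true(des$intended_leaf[[i]] %in% leaves$leaf)
  }
  # seeded designs still respect the apportionment
  des2 <- lma_unit_design(seed = 99)
  expect_equal(table(des2$gesture, des2$intended_category),
               table(des$gesture, des$intended_category))
})

test_that("a zero-noise simulation reproduces the ground truth exactly", {
  cfg <- simulation_config(n_raters = 4, eps1 = 0, eps2 = 0, pi_swap = 0, seed = 8)
  ds <- simulate_dataset(cfg)
  g <- lma_graph()
  truth <- setNames(ds$units$intended_leaf, ds$units$unit_id)
  for (i in seq_len(nrow(ds$records))) {
    leaf <- validate_sequence(g, ds$records$answer_path[[i]])$leaf
    expect_equal(leaf, unname(truth[[ds$records$unit_id[[i]]]]))
  }
  expect_equal(alpha_by_strategy(ds, "r1_only")$alpha, 1)
})

test_that("the default design yields 18 x 22 x 2 = 792 records", {
  ds <- simulate_dataset(simulation_config(seed = 1))
  expect_equal(nrow(ds$records), 792L)
  expect_equal(length(ds$raters), 18L)
  expect_equal(nrow(write_dataset(ds)), 792L)
})

test_that("identical seeds give bit-identical serialized datasets", {
  cfg <- simulation_config(n_raters = 5, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(simulate_dataset(cfg), f1)
  write_dataset(simulate_dataset(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and the global RNG stream is left untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_dataset(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("with certain error and no category kernel, confusions are uniform", {
  # eps1 = 1, lambda = 0: round-1 draws uniform over the 26 non-true leaves
  units <- lma_unit_design()[2, ]  # a single non-neutral unit
  cfg <- simulation_config(n_raters = 500, units = units, eps1 = 1, eps2 = 1,
                           lambda = 0, pi_swap = 0, seed = 314)
  reps <- 20L
  g <- lma_graph()
  leaves <- enumerate_paths(g)
  lp <- setNames(leaves$leaf, leaves$path)
  draws <- character(0)
  for (k in seq_len(reps)) {
    cfg$seed <- 314 + k
    ds <- simulate_dataset(cfg, g)
    r1 <- ds$records$answer_path[ds$records$round == 1]
    draws <- c(draws, unname(lp[r1]))
  }
  expect_equal(length(draws), 10000L)
  expect_false(units$intended_leaf %in% draws)
  counts <- table(factor(draws, levels = setdiff(leaves$leaf, units$intended_leaf)))
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("marginal round-1 error frequency matches eps1 within binomial tolerance", {
  eps <- 0.3
  cfg <- simulation_config(n_raters = 40, eps1 = eps, eps2 = 0, pi_swap = 0,
                           seed = 55)
  ds <- simulate_dataset(cfg)
  g <- lma_graph()
  truth_path <- setNames(lmarel:::leaf_paths(g)[ds$units$intended_leaf],
                         ds$units$unit_id)
  r1 <- ds$records[ds$records$round == 1, ]
  err <- mean(r1$answer_path != unname(truth_path[r1$unit_id]))
  n <- nrow(r1)
  expect_lt(abs(err - eps), 4 * sqrt(eps * (1 - eps) / n))
})

test_that("a swap-heavy simulation favors the order-independent strategy", {
  # distinct secondary truths plus frequent priority swaps: aligning rounds
  # recovers agreement that the order-dependent reading destroys
  units <- lma_unit_design()
  second <- setNames(ifelse(units$intended_leaf == "Light", "Strong", "Light"),
                     units$unit_id)
  cfg <- simulation_config(n_raters = 10, eps1 = 0.1, eps2 = 0.1, pi_swap = 0.5,
                           secondary_truth = second, seed = 404)
  ds <- simulate_dataset(cfg)
  a_un <- alpha_by_strategy(ds, "unordered")$alpha
  a_or <- alpha_by_strategy(ds, "ordered")$alpha
  expect_gt(a_un, a_or)
})

test_that("unit designs citing leaves absent from the graph are refused", {
  units <- lma_unit_design()
  units$intended_leaf[2] <- "Forward"  # legal Space leaf
  units$intended_category[2] <- "Space"
  expect_s3_class(simulate_dataset(simulation_config(n_raters = 2, units = units, seed = 1)),
                  "annotation_dataset")
  g_small <- mini_graph()
  expect_error(simulate_dataset(simulation_config(n_raters = 2, seed = 1), g_small),
               "absent from graph")
  expect_error(simulation_config(eps1 = 1.2), "\\[0, 1\\]")
})
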