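test_that("coincidence counting follows the 1/(m-1) pairable-values definition", {
  # 2 raters, same value
  cm <- build_coincidence(list(u1 = c("c", "c")))
  expect_equal(cm$o["c", "c"], 2)
  expect_equal(cm$n, 2)
  # 2 raters, different values
  cm <- build_coincidence(list(u1 = c("c", "k")))
  expect_equal(cm$o["c", "k"], 1)
  expect_equal(cm$o["k", "c"], 1)
  expect_equal(cm$n, 2)
  # 3 raters (c, c, k): 6 ordered pairs, each weighted 1/2
  cm <- build_coincidence(list(u1 = c("c", "c", "k")))
  expect_equal(cm$o["c", "c"], 1)
  expect_equal(cm$o["c", "k"], 1)
  expect_equal(cm$o["k", "c"], 1)
  expect_equal(cm$n, 3)
  # single-value units are excluded but counted
  cm <- build_coincidence(list(u1 = c("c", "k"), u2 = "c"))
  expect_equal(cm$n_excluded, 1L)
  expect_equal(cm$n_units, 1L)
  expect_error(build_coincidence(list(u1 = "c")), "no unit")
})

test_that("coincidence conservation and marginal consistency hold on random data", {
  for (seed in 1:10) {
    vbu <- random_values_by_unit(seed)
    cm <- build_coincidence(vbu)
    expect_equal(sum(cm$o), cm$n)
    expect_equal(unname(rowSums(cm$o)), unname(cm$n_c))
    expect_identical(cm$o, t(cm$o))
    expect_true(all(cm$o >= 0))
    expect_equal(cm$n, sum(lengths(vbu)[lengths(vbu) >= 2]))
  }
})

test_that("alpha with nominal metric matches the pair-counting oracle to 1e-12", {
  checked <- 0
  seed <- 0
  while (checked < 25) {
    seed <- seed + 1
    vbu <- random_values_by_unit(seed)
    cm <- build_coincidence(vbu)
    v <- length(cm$values)
    nominal <- 1 - diag(v)
    dimnames(nominal) <- list(cm$values, cm$values)
    res <- krippendorff_alpha(cm, nominal)
    if (res$degenerate) next
    expect_equal(res$alpha, oracle_nominal_alpha(vbu), tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("alpha matches a closed-form hand computation on a 2x2 design", {
  # 2 raters, 2 units, values (c,k) then (k,c):
  # o[c,k] = o[k,c] = 2, n = 4, n_c = n_k = 2
  # D_o = 4; D_e = (2*2 + 2*2)/3 = 8/3; alpha = 1 - 4/(8/3) = -0.5
  cm <- build_coincidence(list(u1 = c("c", "k"), u2 = c("k", "c")))
  nominal <- matrix(c(0, 1, 1, 0), 2, dimnames = list(cm$values, cm$values))
  res <- krippendorff_alpha(cm, nominal)
  expect_equal(res$D_o, 4)
  expect_equal(res$D_e, 8/3)
  expect_equal(res$alpha, -0.5)
})

test_that("alpha is invariant under relabeling of the value inventory", {
  vbu <- random_values_by_unit(42)
  cm <- build_coincidence(vbu)
  dm <- lmarel:::strategy_distance_matrix(
    paste0("Yes|Effort|", c("Light", "Strong", "Bound", "Free", "Quick"))[seq_along(cm$values)],
    "simple")
  dimnames(dm) <- list(cm$values, cm$values)
  a1 <- krippendorff_alpha(cm, dm)$alpha
  perm <- rev(seq_along(cm$values))
  cm2 <- cm
  cm2$values <- cm$values[perm]
  cm2$o <- cm$o[perm, perm]
  cm2$n_c <- cm$n_c[perm]
  a2 <- krippendorff_alpha(cm2, dm[perm, perm])$alpha
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("degenerate data (one value everywhere) reports alpha 1 with a flag", {
  cm <- build_coincidence(list(u1 = c("c", "c"), u2 = c("c", "c", "c")))
  res <- krippendorff_alpha(cm, matrix(0, 1, 1, dimnames = list("c", "c")))
  expect_true(res$degenerate)
  expect_equal(res$alpha, 1)
})

test_that("unit_values implements the four round-combination strategies", {
  g <- lma_graph()
  ds <- fixture_dataset(list(
    u1 = list(r1 = c("Yes|Effort|Light", "Yes|Zone|Up"),
              r2 = c("Yes|Zone|Up", "Yes|Effort|Light")),
    u2 = list(r1 = c("No", "No"),
              r2 = "Yes|Effort|Light")  # no round 2: duplicated as (R1, R1)
  ), g)
  uv <- unit_values(ds, "r1_only")
  expect_equal(uv$values$u1, c("Yes|Effort|Light", "Yes|Zone|Up"))
  expect_equal(uv$kind, "simple")

  uv <- unit_values(ds, "ordered")
  expect_equal(uv$values$u1, c("Yes|Effort|Light::Yes|Zone|Up",
                               "Yes|Zone|Up::Yes|Effort|Light"))
  expect_equal(uv$values$u2, c("No::No", "Yes|Effort|Light::Yes|Effort|Light"))

  uv <- unit_values(ds, "unordered")
  # swapped pairs collapse onto one canonical key
  expect_equal(uv$values$u1[1], uv$values$u1[2])

  uv <- unit_values(ds, "r_optimal")
  # all R1s distinct but R2s mirror them: optimum picks agreeing sequences
  expect_equal(uv$values$u1[1], uv$values$u1[2])
  expect_s3_class(uv$selection, "data.frame")
  expect_equal(unique(uv$selection$total_distance[uv$selection$unit_id == "u1"]), 0)
  expect_error(unit_values(ds, "nonsense"))
})

test_that("optimal_selection matches an independent brute-force enumerator", {
  paths <- enumerate_paths(lma_graph())$path
  for (seed in 1:6) {
    set.seed(seed)
    m <- sample(c(2, 3, 5, 8), 1)
    r1 <- sample(paths, m, replace = TRUE)
    r2 <- sample(paths, m, replace = TRUE)
    mine <- optimal_selection(r1, r2)
    orc <- oracle_best_selection(r1, r2)
    expect_equal(mine$total, orc$total, tolerance = 1e-12)
    # identical-round raters are reported as round 1; compare achieved totals
    # and the tie-broken choice on the free raters
    free <- r1 != r2
    expect_equal(mine$choice[free], orc$choice[free],
                 label = paste("seed", seed))
  }
})

test_that("optimal_selection prefers round 1, then earlier raters, on ties", {
  # both choices achieve total 0 within each rater; all-round-1 must win
  r1 <- c("No", "No")
  r2 <- c("No", "No")
  expect_equal(optimal_selection(r1, r2)$choice, c(1L, 1L))
  # symmetric tie: (A,B) vs (B,A); totals equal for R1R1/R2R2 vs mixed?
  a <- "Yes|Effort|Light"; b <- "Yes|Effort|Strong"
  sel <- optimal_selection(c(a, b), c(b, a))
  # choices (1,1),(2,2) give d(a,b); (1,2),(2,1) give 0: minimum is unique here
  expect_equal(sel$total, 0)
  expect_equal(sel$choice, c(1L, 2L))  # lexicographically first zero selection
  # true tie: all four selections give the same total
  sel <- optimal_selection(c(a, a), c(b, b))
  expect_equal(sel$choice, c(1L, 1L))
  expect_error(optimal_selection(rep(a, 3), rep(b, 3), exhaustive_limit = 2),
               "exhaustive limit")
})

test_that("zero-noise data give alpha 1 and composite strategies order as expected", {
  cfg <- simulation_config(n_raters = 6, eps1 = 0, eps2 = 0, pi_swap = 0, seed = 2)
  ds <- simulate_dataset(cfg)
  expect_equal(alpha_by_strategy(ds, "r1_only")$alpha, 1)
  # round 2 repairing round-1 disagreement: r_optimal >= r1_only
  g <- lma_graph()
  ds2 <- fixture_dataset(list(
    u1 = list(ra = c("Yes|Effort|Light", "Yes|Zone|Up"),
              rb = c("Yes|Shape|Rising", "Yes|Zone|Up")),
    u2 = list(ra = c("Yes|Effort|Strong", "Yes|Reach|Far"),
              rb = c("No", "Yes|Reach|Far"))
  ), g)
  a_opt <- alpha_by_strategy(ds2, "r_optimal")$alpha
  a_r1 <- alpha_by_strategy(ds2, "r1_only")$alpha
  expect_gte(a_opt, a_r1)
  expect_equal(a_opt, 1)  # degenerate-or-perfect agreement after selection
})

test_that("subset alpha on a single gesture equals the overall alpha and partitions counts", {
  ds <- simulate_dataset(simulation_config(n_raters = 5, seed = 13))
  knock <- filter_dataset(ds, ds$units$unit_id[ds$units$gesture == "knocking"])
  sub <- subset_alpha(knock, "gesture", "r1_only")
  expect_named(sub, "knocking")
  expect_equal(sub$knocking$alpha, alpha_by_strategy(knock, "r1_only")$alpha)

  both <- subset_alpha(ds, "gesture", "r1_only")
  expect_equal(sum(vapply(both, function(a) a$n, numeric(1))),
               alpha_by_strategy(ds, "r1_only")$n)
})

test_that("individual similarity scores raters against the modal sequence", {
  g <- lma_graph()
  # (A, A, B) with A and B sharing 2 of 3 tokens
  ds <- fixture_dataset(list(
    u1 = list(r1 = "Yes|Effort|Light", r2 = "Yes|Effort|Light",
              r3 = "Yes|Effort|Strong")
  ), g)
  sim <- individual_similarity(ds)
  expect_equal(sim$modal$modal_path, "Yes|Effort|Light")
  expect_equal(sim$ratings$similarity, c(1, 1, 2/3))

  # all identical
  ds <- fixture_dataset(list(u1 = list(r1 = "No", r2 = "No")), g)
  expect_true(all(individual_similarity(ds)$ratings$similarity == 1))

  # modal tie: B closer on average to the unit's sequences wins
  ds <- fixture_dataset(list(
    u1 = list(r1 = "Yes|Effort|Light", r2 = "Yes|Effort|Light",
              r3 = "Yes|Effort|Strong", r4 = "Yes|Effort|Strong",
              r5 = "Yes|Shape|Rising")
  ), g)
  s1 <- individual_similarity(ds)
  s2 <- individual_similarity(ds)
  expect_identical(s1$modal, s2$modal)  # deterministic
  # remaining-tie fallback is byte order of the path string
  ds <- fixture_dataset(list(
    u1 = list(r1 = "Yes|Effort|Light", r2 = "Yes|Effort|Strong")
  ), g)
  expect_equal(individual_similarity(ds)$modal$modal_path, "Yes|Effort|Light")
})

test_that("alpha degrades monotonically with the round-1 error rate", {
  curve <- recovery_curve(epsilons = c(0, 0.25, 0.5), n_replicates = 12,
                          seed = 21, cfg = simulation_config(n_raters = 8))
  expect_equal(curve$mean_alpha[curve$eps1 == 0], 1)
  expect_true(all(diff(curve$mean_alpha) <= 0.02))
})
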