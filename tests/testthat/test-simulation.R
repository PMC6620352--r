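test_that("size classes are half-open with 5/20/40/80 bounds", {
  expect_equal(assign_size_class(c(5, 19.999, 20, 39.9, 40, 79.9, 80, 200)),
               c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_error(assign_size_class(4.99), "size class")
})

test_that("removal counts follow intensity with round-half-even fractions", {
  toy <- two_wsg_toy(n_target = 10, n_pool = 10)
  st <- community_state(toy$trees, toy$traits)
  count_for <- function(intensity) {
    set.seed(1)
    length(select_removals(st, scenario("all_lbf", intensity, "wsg_swap")))
  }
  expect_equal(count_for(1.0), 10L)
  expect_equal(count_for(0.4), 4L)

  toy7 <- two_wsg_toy(n_target = 7, n_pool = 10)
  st7 <- community_state(toy7$trees, toy7$traits)
  set.seed(1)
  expect_length(select_removals(st7, scenario("all_lbf", 0.4, "wsg_swap")), 3L)
  # 0.5 * 5 = 2.5 rounds to the even neighbour
  toy5 <- two_wsg_toy(n_target = 5, n_pool = 10)
  st5 <- community_state(toy5$trees, toy5$traits)
  set.seed(1)
  expect_length(select_removals(st5, scenario("all_lbf", 0.5, "wsg_swap")), 2L)
})

test_that("control removals match the all-LBF count and draw from all stems", {
  com <- three_species_community(n_each = 10)
  st <- community_state(com$trees, com$traits)
  set.seed(2)
  rem_ctl <- select_removals(st, scenario("control", 0.4, "wsg_swap"))
  # 20 LBF stems (PRI + TER), 40% of them
  expect_length(rem_ctl, 8L)
  # over many draws the control touches non-LBF stems too
  set.seed(3)
  drawn <- unique(unlist(replicate(30, select_removals(
    st, scenario("control", 0.4, "wsg_swap")), simplify = FALSE)))
  expect_true(any(!st$stems$is_lbf[drawn]))
})

test_that("density swap conserves the dbh multiset; full replacement the class counts", {
  com <- three_species_community(n_each = 5, dbh = 10)
  com$trees$dbh <- rep(c(10, 25, 50, 90), 5)  # spread stems over classes
  st <- community_state(com$trees, com$traits)
  scn <- scenario("all_lbf", 1, "wsg_swap")
  set.seed(4)
  rem <- select_removals(st, scn)
  sw <- replace_wsg_swap(st, rem, scn)
  expect_identical(sw$stems$dbh, st$stems$dbh)
  expect_identical(sw$stems$tag, st$stems$tag)
  expect_identical(sum(pi * (sw$stems$dbh / 2)^2), sum(pi * (st$stems$dbh / 2)^2))

  fl <- replace_full(st, rem, scn)
  expect_equal(tabulate(fl$stems$size_class, 4), st$class_counts)
  expect_equal(fl$n_stems, st$n_stems)
  # every replaced stem was cloned from the non-target pool
  expect_true(all(!fl$stems$is_lbf[rem]))

  expect_identical(replace_wsg_swap(st, integer(0), scn)$stems, st$stems)
  expect_identical(replace_full(st, integer(0), scn)$stems, st$stems)
})

test_that("a single-valued donor pool makes replacement deterministic", {
  toy <- two_wsg_toy(n_target = 6, n_pool = 4, w_l = 0.8, w_o = 0.6)
  st <- community_state(toy$trees, toy$traits)
  scn <- scenario("all_lbf", 1, "wsg_swap")
  set.seed(5)
  sw <- replace_wsg_swap(st, select_removals(st, scn), scn)
  expect_true(all(sw$stems$wsg == 0.6))
})

test_that("an empty replacement pool in a size class is a named error", {
  # LBF stems in class 3, non-targets only in class 1
  trees <- data.frame(tag = c("a", "b"), species = c("LBF1", "WIND1"),
                      dbh = c(50, 10))
  toy <- two_wsg_toy()
  st <- community_state(trees, toy$traits)
  scn <- scenario("all_lbf", 1, "wsg_swap")
  set.seed(1)
  rem <- select_removals(st, scn)
  expect_error(replace_wsg_swap(st, rem, scn), "class 3")
})

test_that("replicates reproduce the toy closed form and a zero null", {
  toy <- two_wsg_toy(n_target = 10, n_pool = 10, w_l = 0.8, w_o = 0.6)
  st <- community_state(toy$trees, toy$traits)
  reps <- run_replicates(st, scenario("all_lbf", 1, "wsg_swap"),
                         n_reps = 20, seed = 1)
  expect_equal(reps, rep(-100 / 7, 20), tolerance = 1e-12)

  null_toy <- two_wsg_toy(w_l = 0.6, w_o = 0.6)
  st0 <- community_state(null_toy$trees, null_toy$traits)
  reps0 <- run_replicates(st0, scenario("all_lbf", 1, "wsg_swap"),
                          n_reps = 10, seed = 1)
  expect_identical(reps0, rep(0, 10))
})

test_that("replicate streams are seed-stable and invariant to n_reps", {
  com <- three_species_community()
  st <- community_state(com$trees, com$traits)
  scn <- scenario("all_lbf", 0.6, "full_replace")
  a <- run_replicates(st, scn, n_reps = 12, seed = 99)
  b <- run_replicates(st, scn, n_reps = 12, seed = 99)
  expect_identical(a, b)
  short <- run_replicates(st, scn, n_reps = 5, seed = 99)
  expect_identical(a[1:5], short)
  c2 <- run_replicates(st, scn, n_reps = 12, seed = 100)
  expect_false(identical(a, c2))
})

test_that("bootstrap interval behaves on constant and shrinking inputs", {
  bs <- bootstrap_ci(rep(3.5, 10), seed = 1)
  expect_equal(c(bs$mean, bs$ci_low, bs$ci_high), rep(3.5, 3))

  set.seed(8)
  widths <- vapply(c(50, 200, 800), function(n) {
    x <- rnorm(n)
    ci <- bootstrap_ci(x, n_boot = 400, seed = 2)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # fourfold sample size roughly halves the width
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.5)
  expect_true(bootstrap_ci(rnorm(30), seed = 3)$ci_low <=
                bootstrap_ci(rnorm(30), seed = 3)$ci_high)
})

test_that("scenario expectations order as the trait structure predicts", {
  com <- three_species_community(n_each = 10)
  st <- community_state(com$trees, com$traits)
  # brute-force expectations: donors are uniform over the non-target pool
  # (all stems share one size class), and the allometry is linear in wsg
  w <- st$stems$wsg
  exp_delta <- function(target, pool) {
    100 * sum(mean(w[pool]) - w[target]) / sum(w)
  }
  pri <- which(st$stems$is_primate)
  lbf <- which(st$stems$is_lbf)
  e_pri <- exp_delta(pri, setdiff(seq_along(w), pri))
  e_lbf <- exp_delta(lbf, setdiff(seq_along(w), lbf))

  m_pri <- mean(run_replicates(st, scenario("primates_only", 1, "wsg_swap"),
                               n_reps = 400, seed = 7))
  m_lbf <- mean(run_replicates(st, scenario("all_lbf", 1, "wsg_swap"),
                               n_reps = 400, seed = 7))
  expect_equal(m_pri, e_pri, tolerance = 0.05)
  expect_equal(m_lbf, e_lbf, tolerance = 1e-9)  # single-valued pool
  expect_lt(m_lbf, m_pri)
})

test_that("the experiment grid emits one summary per combination, reproducibly", {
  syn <- generate_community(synth_config(n_species = 40, n_stems = 1500),
                            seed = 21)
  s1 <- run_experiment(syn$trees, syn$traits, n_reps = 30, n_boot = 30,
                       seed = 5)
  expect_equal(nrow(s1), 30L)
  expect_equal(nrow(unique(s1[, c("scenario", "intensity", "option")])), 30L)
  expect_true(all(s1$ci_low <= s1$ci_high))
  s2 <- run_experiment(syn$trees, syn$traits, n_reps = 30, n_boot = 30,
                       seed = 5)
  expect_identical(s1, s2)
})

test_that("the resampling procedure is unbiased across null communities", {
  # Within any one community the replicate mean converges to that
  # community's realized WSG-disperser association (sampling noise of the
  # per-species WSG draws), so unbiasedness is a property of the ensemble:
  # across independently generated delta = 0 communities the grand mean
  # carbon change is zero within its standard error.
  grand <- function(scn_name, option) {
    per_com <- vapply(1:40, function(s) {
      g <- generate_community(synth_config(n_species = 120, n_stems = 4000,
                                           delta = 0), seed = 300 + s)
      st <- community_state(g$trees, g$traits)
      mean(run_replicates(st, scenario(scn_name, 1, option),
                          n_reps = 4, seed = s))
    }, numeric(1))
    c(mean(per_com), stats::sd(per_com) / sqrt(length(per_com)))
  }
  for (combo in list(c("all_lbf", "wsg_swap"), c("control", "wsg_swap"),
                     c("all_lbf", "full_replace"))) {
    gm <- grand(combo[1], combo[2])
    expect_lt(abs(gm[1]), 3 * gm[2])
  }
})
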