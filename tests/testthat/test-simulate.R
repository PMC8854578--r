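test_that("simulators are pure functions of their seed", {
  truth <- sim_truth(data.frame(position = 50L, protection = 0.8,
                                q_low = 0.5, q_high = 0.05))
  a <- simulate_cleavage_profiles(200L, 5000L, truth, seed = 9)
  b <- simulate_cleavage_profiles(200L, 5000L, truth, seed = 9)
  expect_identical(lapply(a, `[[`, "coverage"), lapply(b, `[[`, "coverage"))
  expect_identical(lapply(a, `[[`, "starts5"), lapply(b, `[[`, "starts5"))
  r1 <- simulate_rtstop_profiles(200L, 5000L, truth, "low", seed = 9)
  r2 <- simulate_rtstop_profiles(200L, 5000L, truth, "low", seed = 9)
  expect_identical(r1$coverage, r2$coverage)
  f1 <- simulate_footprint_library(mt_mrna_annotation(),
                                   sim_truth(), 0.01, 1e6, seed = 9)
  f2 <- simulate_footprint_library(mt_mrna_annotation(),
                                   sim_truth(), 0.01, 1e6, seed = 9)
  expect_identical(f1$reads, f2$reads)
})

test_that("full protection silences the planted bond in every replicate", {
  truth <- sim_truth(data.frame(position = 80L, protection = 1,
                                q_low = 0.5, q_high = 0.05))
  profs <- simulate_cleavage_profiles(300L, 20000L, truth, seed = 4,
                                      replicates = 3L)
  for (p in profs) {
    n <- cleavage_counts(p)
    expect_equal(n[80], 0)
    expect_gt(median(n), 15)
  }
})

test_that("every simulated profile satisfies the coverage identity (100 random libraries)", {
  set.seed(60)
  for (i in 1:50) {
    L <- sample(150:400, 1)
    pos <- sample(30:(L - 30), 1)
    truth <- sim_truth(data.frame(position = pos,
                                  protection = runif(1),
                                  q_low = runif(1, 0.3, 0.8),
                                  q_high = runif(1, 0, 0.2)))
    p <- simulate_cleavage_profiles(L, 2000L, truth, seed = i,
                                    replicates = 1L)[[1]]
    expect_true(validate_profile(p))
    r <- simulate_rtstop_profiles(L, 2000L, truth,
                                  condition = sample(c("low", "high"), 1),
                                  seed = i + 500)
    expect_true(validate_profile(r))
  }
})

test_that("a null cleavage simulation scores near zero at qualified positions", {
  means <- vapply(1:10, function(s) {
    p <- simulate_cleavage_profiles(400L, 60000L, sim_truth(), phi = 0,
                                    seed = s, replicates = 1L)[[1]]
    st <- score_a(cleavage_counts(p))
    mean(st$score_a, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(means), 0.05)
})

test_that("RT-stop simulation matches an independent per-molecule oracle at the planted site", {
  site <- 150L
  q <- 0.4
  dropoff <- 0.001
  L <- 300L
  truth <- sim_truth(data.frame(position = site, protection = 0,
                                q_low = q, q_high = q))
  prof <- simulate_rtstop_profiles(L, 40000L, truth, "low",
                                   dropoff = dropoff, seed = 17)
  r_hat <- rt_stop_ratio(prof)[site]

  # oracle: plain-loop re-simulation of the stop model on uniform fragments
  set.seed(99)
  n_mol <- 40000L
  stops <- 0L; covered <- 0L
  for (m in seq_len(n_mol)) {
    repeat {
      cuts <- sort(sample(0:L, 2L))
      len <- cuts[2] - cuts[1]
      if (len >= 25 && len <= 55) break
    }
    s <- cuts[1] + 1L; e <- cuts[2]
    j <- e
    while (j > s) {
      # extension from j to j - 1 fails by stall (site) or drop-off
      stall <- (j - 1L == site) && runif(1) < q
      if (stall || runif(1) < dropoff) break
      j <- j - 1L
    }
    if (j >= site + 1L && e >= site + 1L && j <= site + 1L) stops <- stops + 1L
    if (j <= site + 1L && e >= site + 1L) covered <- covered + 1L
  }
  r_oracle <- stops / covered
  se <- sqrt(r_oracle * (1 - r_oracle) / covered)
  expect_lt(abs(r_hat - r_oracle), 3 * se + 3 * sqrt(r_hat * (1 - r_hat) / covered))
})

test_that("equal stop efficiencies give fold change 1 and the no-stall limit gives zero ratios", {
  site <- 100L
  truth_eq <- sim_truth(data.frame(position = site, protection = 0,
                                   q_low = 0.3, q_high = 0.3))
  f_site <- vapply(1:10, function(s) {
    low <- simulate_rtstop_profiles(200L, 30000L, truth_eq, "low",
                                    seed = 2 * s)
    high <- simulate_rtstop_profiles(200L, 30000L, truth_eq, "high",
                                     seed = 2 * s + 1)
    rt_stop_fold_change(rt_stop_ratio(low), rt_stop_ratio(high))[site]
  }, numeric(1))
  se <- sd(f_site) / sqrt(length(f_site))
  expect_lt(abs(mean(f_site) - 1), 3 * se + 0.02)

  # no stalls, no drop-off: starts only at fragment boundaries
  p0 <- simulate_rtstop_profiles(200L, 5000L, sim_truth(), "low",
                                 dropoff = 0, seed = 3)
  r <- rt_stop_ratio(p0)
  # every defined, positive ratio must coincide with a fragment start
  pos <- which(!is.na(r) & r > 0)
  expect_true(all(p0$starts5[pos + 1L] > 0))
})

test_that("footprint libraries recover planted occupancy contrasts", {
  ann <- mt_mrna_annotation()
  genes <- ann$genes$gene[ann$genes$category == "mRNA"]
  truth_flat <- sim_truth(occupancy_factors =
                            stats::setNames(rep(1, 13), genes))
  mk_table <- function(lib)
    expression_table(filter_footprints(lib$reads, ann)$kept, ann,
                     lib$normaliser)
  par <- simulate_footprint_library(ann, truth_flat, 0.5, 1e6, seed = 21)
  ko_same <- simulate_footprint_library(ann, truth_flat, 0.5, 1e6, seed = 22)
  occ <- occupancy(mk_table(ko_same), mk_table(par))
  se <- occ$summary["sd"] / sqrt(nrow(occ$per_gene))
  expect_lt(abs(occ$summary["mean"] - 100), 3 * unname(se))

  # zero library scale: empty library, all genes excluded
  empty <- simulate_footprint_library(ann, truth_flat, 0, 1e6, seed = 23)
  expect_equal(nrow(empty$reads), 0L)
  tab0 <- mk_table(empty)
  expect_true(all(tab0$ribo_count == 0L))
  expect_error(occupancy(mk_table(par), tab0), "no gene with positive")
})

test_that("the SILAC generator honours its null, inverse and warning contracts", {
  null <- simulate_silac_table(sim_truth(), noise_sd = 0, seed = 2)
  expect_true(all(null$table$ratio == 1))
  biased <- simulate_silac_table(sim_truth(mixing_bias = 2),
                                 noise_sd = 0, seed = 2)
  restored <- correct_mixing(biased$table, biased$whole_cell_median)
  expect_equal(restored$ratio, null$table$ratio, tolerance = 1e-12)
  expect_warning(sim_truth(data.frame(position = 5L, protection = 0,
                                      q_low = 0.1, q_high = 0.4)),
                 "low-dNTP stalling premise")
})
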