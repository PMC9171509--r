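test_that("search_space_size counts assignments exactly", {
  # explicit enumeration oracle at tiny size: each OPC -> one of 2 LTCs or none
  oracle <- nrow(expand.grid(rep(list(0:2), 3)))
  expect_identical(search_space_size(3, 2), as.character(oracle)) # 27
  expect_identical(search_space_size(0, 5), "1")
  expect_identical(search_space_size(183, 9),
                   paste0("1", strrep("0", 183))) # 10^183
  expect_identical(search_space_size(20, 9), paste0("1", strrep("0", 20)))
})

test_that("pruned_subset_iterator equals the powerset filter", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    s <- sort(rpois(n, 6), decreasing = TRUE)
    smin <- sample(0:3, 1); smax <- sample(smin:n, 1)
    lb <- runif(1, 0, 25); ub <- lb + runif(1, 0, 40)
    got <- pruned_subset_iterator(s, smin, smax, lb, ub)
    want <- naive_subset_filter(s, smin, smax, lb, ub)
    expect_identical(subset_canon(got), subset_canon(want))
  }
  # 15-OPC pool, the scale the pruning is meant for
  s <- sort(rpois(15, 5), decreasing = TRUE)
  got <- pruned_subset_iterator(s, 2, 8, 10, 30)
  want <- naive_subset_filter(s, 2, 8, 10, 30)
  expect_identical(subset_canon(got), subset_canon(want))
})

test_that("pruned_subset_iterator degenerate bands", {
  # infinite tolerance: every size-feasible subset of 6 items
  expect_length(pruned_subset_iterator(sort(rpois(6, 3), TRUE), 1, 6), 63)
  # total supply below the band: root-pruned, zero yields
  expect_length(pruned_subset_iterator(c(3, 2, 1), 1, 3, 100, 200), 0)
  expect_error(pruned_subset_iterator(c(1, 5, 2), 1, 2),
               "sorted descending", class = "validation_error")
})

test_that("enumerate_feasible_units equals the exhaustive oracle", {
  set.seed(32)
  for (rep in 1:5) {
    w <- make_line_world(12, gap_km = 10, supplies = rpois(12, 4),
                         transplants = c(20, 25))
    cfg <- optimizer_config(target_ratio = 0.5,
                            ratio_tolerance = runif(1, 0.05, 0.3),
                            size_min = sample(1:2, 1), size_max = sample(4:6, 1),
                            max_minutes = 120, shortlist_k = Inf)
    pool <- eligible_pool("LA", w$matrix, 120)
    got <- enumerate_feasible_units("LA", pool, w$activity, w$matrix, cfg)
    want <- naive_enumerate("LA", pool, w$activity, w$matrix, cfg)
    expect_setequal(unit_keys(got), unit_keys(want))
    # every returned unit re-checked against all four constraints
    for (u in got) {
      expect_true(length(u$opcs) >= cfg$size_min &&
                    length(u$opcs) <= cfg$size_max)
      expect_true(all(w$matrix[u$opcs, "LA"] <= cfg$max_minutes))
      expect_true(abs(u$ratio - cfg$target_ratio) <= cfg$ratio_tolerance)
      sup <- sum(w$activity$lungs_recovered[match(u$opcs, w$activity$id)])
      expect_equal(u$ratio, sup / 20)
    }
  }
})

test_that("enumeration respects sorting, truncation, locks and edge cases", {
  w <- make_line_world(6, gap_km = 10, supplies = c(5, 4, 3, 2, 1, 0),
                       transplants = c(10, 10))
  pool <- w$opc_ids
  cfg <- optimizer_config(ratio_tolerance = Inf, size_min = 1, size_max = 6,
                          shortlist_k = Inf)
  units <- enumerate_feasible_units("LA", pool, w$activity, w$matrix, cfg)
  expect_length(units, 63) # all non-empty subsets
  dev <- vapply(units, function(u) abs(u$ratio - 0.5), numeric(1))
  expect_true(all(diff(dev) >= -1e-12)) # sorted by distance to target

  cfg_k <- optimizer_config(ratio_tolerance = Inf, size_min = 1,
                            size_max = 6, shortlist_k = 10)
  units_k <- enumerate_feasible_units("LA", pool, w$activity, w$matrix, cfg_k)
  expect_length(units_k, 10)
  expect_true(attr(units_k, "truncated"))
  expect_identical(unit_keys(units_k), unit_keys(units[1:10]))

  # all-zero supply cannot reach the band
  w0 <- make_line_world(6, gap_km = 10, supplies = rep(0, 6))
  none <- enumerate_feasible_units("LA", w0$opc_ids, w0$activity, w0$matrix,
                                   optimizer_config(size_min = 1, size_max = 6))
  expect_length(none, 0)

  # locked OPCs are in every unit
  cfg_l <- optimizer_config(ratio_tolerance = Inf, size_min = 1, size_max = 4,
                            locked = list(LA = c("O5")), shortlist_k = Inf)
  units_l <- enumerate_feasible_units("LA", pool, w$activity, w$matrix, cfg_l)
  expect_true(all(vapply(units_l, function(u) "O5" %in% u$opcs, logical(1))))
  oracle_l <- naive_enumerate("LA", pool, w$activity, w$matrix, cfg_l)
  expect_setequal(unit_keys(units_l), unit_keys(oracle_l))

  # pool below size_min: warning, empty result
  cfg_big <- optimizer_config(size_min = 10, size_max = 15)
  expect_warning(
    empty <- enumerate_feasible_units("LA", pool, w$activity, w$matrix,
                                      cfg_big),
    "below size_min")
  expect_length(empty, 0)
})

test_that("solve_assignment picks rank-1 units when candidates are disjoint", {
  w <- make_line_world(6, supplies = c(5, 5, 5, 5, 5, 5),
                       transplants = c(20, 20))
  cand <- list(
    LA = list(list(ltc = "LA", opcs = c("O1", "O2"), ratio = 0.5,
                   total_travel_min = 30)),
    LB = list(list(ltc = "LB", opcs = c("O5", "O6"), ratio = 0.5,
                   total_travel_min = 40)))
  res <- solve_assignment(cand, w$activity, optimizer_config(size_min = 1))
  expect_equal(sort(unit_members("LA", res$map)), c("O1", "O2"))
  expect_equal(sort(unit_members("LB", res$map)), c("O5", "O6"))
  expect_equal(res$profile$summary$sd, 0)
  expect_true(res$certified)
})

test_that("solve_assignment objective equals the cartesian-product oracle", {
  set.seed(33)
  for (rep in 1:8) {
    w <- make_line_world(8, supplies = rpois(8, 5),
                         transplants = c(10, 12))
    act <- activity_table(
      c(w$opc_ids, "L1", "L2", "L3"),
      rep(c("OPC", "LTC"), c(8, 3)),
      lungs_recovered = c(w$activity$lungs_recovered[1:8], NA, NA, NA),
      transplants = c(rep(NA, 8), 10, 12, 9),
      candidates = c(rep(NA, 8), 20, 20, 20))
    cand <- random_candidates(c("L1", "L2", "L3"), w$opc_ids, act,
                              n_per_ltc = 12, seed = rep * 7)
    oracle <- cartesian_min_sd(cand)
    cfg <- optimizer_config(size_min = 1)
    if (!is.finite(oracle)) {
      expect_error(solve_assignment(cand, act, cfg),
                   class = "infeasibility_error")
    } else {
      res <- solve_assignment(cand, act, cfg)
      expect_true(res$certified)
      expect_equal(res$profile$summary$sd, oracle, tolerance = 1e-9)
    }
  }
})

test_that("symmetric supply and demand give a zero-sd profile", {
  w <- make_line_world(6, gap_km = 10, supplies = rep(4, 6),
                       transplants = c(16, 16))
  cfg <- optimizer_config(size_min = 1, size_max = 3, ratio_tolerance = 0.3)
  res <- optimize_units(w$centres, w$matrix, w$activity, cfg)
  expect_equal(res$profile$summary$sd, 0, tolerance = 1e-12)
})

test_that("row-order permutations do not change the selected map", {
  set.seed(34)
  w <- make_line_world(10, gap_km = 12, supplies = rpois(10, 5),
                       transplants = c(12, 14))
  cfg <- optimizer_config(size_min = 1, size_max = 4, ratio_tolerance = 0.4)
  res1 <- optimize_units(w$centres, w$matrix, w$activity, cfg)
  perm <- sample(nrow(w$centres))
  centres2 <- w$centres[perm, ]
  class(centres2) <- class(w$centres)
  perm_a <- sample(nrow(w$activity))
  activity2 <- w$activity[perm_a, ]
  class(activity2) <- class(w$activity)
  res2 <- optimize_units(centres2, w$matrix, activity2, cfg)
  expect_identical(sort(names(res1$map)), sort(names(res2$map)))
  expect_identical(unclass(res1$map)[sort(names(res1$map))],
                   unclass(res2$map)[sort(names(res2$map))])
})

test_that("widening the tolerance never worsens the optimal sd", {
  set.seed(35)
  for (rep in 1:4) {
    w <- make_line_world(9, gap_km = 12, supplies = rpois(9, 5),
                         transplants = c(12, 14))
    sds <- vapply(c(0.1, 0.2, 0.4, 0.8), function(tol) {
      cfg <- optimizer_config(size_min = 1, size_max = 4,
                              ratio_tolerance = tol)
      res <- suppressWarnings(
        optimize_units(w$centres, w$matrix, w$activity, cfg))
      res$profile$summary$sd
    }, numeric(1))
    expect_true(all(diff(sds) <= 1e-9))
  }
})

test_that("infeasible conflicts are reported with the smallest LTC pair", {
  act <- activity_table(c("O1", "L1", "L2"), c("OPC", "LTC", "LTC"),
                        lungs_recovered = c(5, NA, NA),
                        transplants = c(NA, 10, 10),
                        candidates = c(NA, 10, 10))
  u <- function(l) list(ltc = l, opcs = "O1", ratio = 0.5,
                        total_travel_min = 10)
  cand <- list(L1 = list(u("L1")), L2 = list(u("L2")))
  expect_error(solve_assignment(cand, act, optimizer_config(size_min = 1)),
               "\\(L1, L2\\)", class = "infeasibility_error")
})

test_that("LTCs without feasible units get the empty unit and a flag", {
  act <- activity_table(c("O1", "O2", "L1", "L2"),
                        c("OPC", "OPC", "LTC", "LTC"),
                        lungs_recovered = c(5, 5, NA, NA),
                        transplants = c(NA, NA, 10, 10),
                        candidates = c(NA, NA, 10, 10))
  cand <- list(L1 = list(list(ltc = "L1", opcs = c("O1", "O2"), ratio = 1,
                              total_travel_min = 10)),
               L2 = list())
  res <- solve_assignment(cand, act, optimizer_config(size_min = 1))
  expect_equal(res$empty_ltcs, "L2")
  expect_equal(unname(res$profile$ratios["L2"]), 0)
})
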