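make_sim_world <- function() {
  ct <- centre_table(
    c(sprintf("O%d", 1:6), "LA", "LB"),
    role = rep(c("OPC", "LTC"), c(6, 2)),
    x = c(10, 20, 30, 400, 410, 420, 15, 405), y = rep(0, 8),
    region = c("R1", "R1", "R1", "R2", "R2", "R2", "R1", "R2"))
  list(centres = ct,
       matrix = synthetic_travel_matrix(ct, 70, 0),
       map = allocation_map(c("O1", "O2", "O4"), c("LA", "LA", "LB")),
       activity = activity_table(ct$id, ct$role,
                                 lungs_recovered = c(rep(5, 6), NA, NA),
                                 transplants = c(rep(NA, 6), 10, 10),
                                 candidates = c(rep(NA, 6), 20, 20)))
}

test_that("cascade follows the tier sequences of both schemes", {
  w <- make_sim_world()
  set.seed(1)
  # immediate acceptance: one local offer
  log1 <- cascade_one_graft("O1", w$map, w$centres,
                            scheme_config("previous", hu_fraction = 0,
                                          acceptance_prob = 1))
  expect_equal(nrow(log1), 1)
  expect_equal(log1$tier, "local")
  expect_true(log1$accepted)

  # refusal everywhere: every LTC offered once, graft discarded
  log0 <- cascade_one_graft("O1", w$map, w$centres,
                            scheme_config("previous", hu_fraction = 0,
                                          acceptance_prob = 0))
  expect_setequal(log0$ltc_id, c("LA", "LB"))
  expect_equal(anyDuplicated(log0$ltc_id), 0L)
  expect_false(any(log0$accepted))

  # previous scheme: local, then same-region, then national
  expect_equal(log0$tier, c("local", "national"))
  log_unassigned <- cascade_one_graft("O3", w$map, w$centres,
                                      scheme_config("previous",
                                                    hu_fraction = 0,
                                                    acceptance_prob = 0))
  expect_equal(log_unassigned$tier[1], "regional") # O3 in LA's region, no unit

  # new scheme: unassigned OPC goes straight to the national tier
  logn <- cascade_one_graft("O3", w$map, w$centres,
                            scheme_config("new", hu_fraction = 0,
                                          acceptance_prob = 1))
  expect_equal(logn$tier[1], "national")

  # high-urgency diversion bypasses geography
  logh <- cascade_one_graft("O1", w$map, w$centres,
                            scheme_config("new", hu_fraction = 1,
                                          acceptance_prob = 1))
  expect_equal(logh$tier, "HU-national")

  expect_error(cascade_one_graft("LA", w$map, w$centres, scheme_config()),
               class = "lookup_error")
})

test_that("run_simulation conserves grafts and is reproducible", {
  w <- make_sim_world()
  stream <- stats::setNames(rep(8, 6), sprintf("O%d", 1:6))
  for (seed in c(1, 7, 42)) {
    res <- run_simulation(stream, w$map, w$centres,
                          scheme_config("previous", acceptance_prob = 0.4),
                          activity = w$activity, matrix = w$matrix,
                          seed = seed)
    m <- res$metrics
    expect_equal(m$n_transplanted + m$n_discarded, m$n_grafts)
    expect_equal(m$n_grafts, 48)
    expect_equal(sum(m$tier_counts), m$n_transplanted)
  }
  r1 <- run_simulation(stream, w$map, w$centres, scheme_config("new"),
                       activity = w$activity, matrix = w$matrix, seed = 9)
  r2 <- run_simulation(stream, w$map, w$centres, scheme_config("new"),
                       activity = w$activity, matrix = w$matrix, seed = 9)
  expect_identical(r1$log, r2$log)
})

test_that("the regional tier never appears under the new scheme", {
  w <- make_sim_world()
  stream <- stats::setNames(rep(10, 6), sprintf("O%d", 1:6))
  for (seed in 1:5) {
    res <- run_simulation(stream, w$map, w$centres,
                          scheme_config("new", acceptance_prob = 0.3),
                          seed = seed)
    expect_false(any(res$log$tier == "regional"))
    expect_equal(sum(res$metrics$tier_counts[, "regional"]), 0)
  }
})

test_that("degenerate simulations are flagged or trivial", {
  w <- make_sim_world()
  empty <- run_simulation(stats::setNames(numeric(0), character(0)),
                          w$map, w$centres, scheme_config())
  expect_true(empty$metrics$empty)

  ct1 <- centre_table(c("O1", "L1"), role = c("OPC", "LTC"),
                      x = c(0, 1), y = c(0, 0), region = "R1")
  act1 <- activity_table(ct1$id, ct1$role, lungs_recovered = c(10, NA),
                         transplants = c(NA, 5), candidates = c(NA, 5))
  res1 <- run_simulation(c(O1 = 20), allocation_map("O1", "L1"), ct1,
                         scheme_config("new", hu_fraction = 0,
                                       acceptance_prob = 1),
                         activity = act1, seed = 2)
  expect_equal(unname(res1$metrics$local_share_pct["L1"]), 100)
  expect_equal(res1$metrics$n_discarded, 0)
})

test_that("symmetric geographies share tiers equally within binomial error", {
  # two LTCs, mirrored units and equal acceptance: the transplant count of
  # each LTC is Binomial(n, 1/2) at most, so their difference stays within
  # 3 binomial sds
  ct <- centre_table(c("O1", "O2", "LA", "LB"),
                     role = c("OPC", "OPC", "LTC", "LTC"),
                     x = c(0, 100, 0, 100), y = rep(0, 4),
                     region = c("R1", "R2", "R1", "R2"))
  map <- allocation_map(c("O1", "O2"), c("LA", "LB"))
  n_grafts <- 4000
  res <- run_simulation(c(O1 = n_grafts / 2, O2 = n_grafts / 2), map, ct,
                        scheme_config("new", hu_fraction = 0.15,
                                      acceptance_prob = 0.5),
                        seed = 13)
  tx <- rowSums(res$metrics$tier_counts)
  n_tx <- sum(tx)
  expect_true(abs(tx["LA"] - n_tx / 2) <= 3 * sqrt(n_tx * 0.25))
  local_share <- res$metrics$tier_counts[, "local"] / tx
  expect_true(abs(local_share["LA"] - local_share["LB"]) <=
                3 * sqrt(0.25 / tx["LA"] + 0.25 / tx["LB"]))
})
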