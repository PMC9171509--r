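# Shared fixtures (built in code) and independent oracles.

# A small deterministic geography: OPCs on a line, two LTCs at the ends.
make_line_world <- function(n_opc = 6, gap_km = 30, supplies = NULL,
                            transplants = c(10, 10)) {
  opc_ids <- sprintf("O%d", seq_len(n_opc))
  ids <- c(opc_ids, "LA", "LB")
  role <- rep(c("OPC", "LTC"), c(n_opc, 2))
  x <- c(seq_len(n_opc) * gap_km, 0, (n_opc + 1) * gap_km)
  centres <- centre_table(ids, ids, role, x, y = rep(0, length(ids)),
                          region = ifelse(x <= n_opc * gap_km / 2, "R1", "R2"))
  matrix <- synthetic_travel_matrix(centres, speed_kmh = 60,
                                    noise_sd_min = 0)
  if (is.null(supplies)) supplies <- rep(2, n_opc)
  activity <- activity_table(
    ids, role,
    lungs_recovered = c(supplies, NA, NA),
    transplants = c(rep(NA, n_opc), transplants),
    candidates = c(rep(NA, n_opc), transplants * 2))
  list(centres = centres, matrix = matrix, activity = activity,
       opc_ids = opc_ids)
}

# Powerset filter oracle for subset enumeration (exponential; tiny n only).
naive_subset_filter <- function(supplies, size_min, size_max,
                                lb = -Inf, ub = Inf) {
  n <- length(supplies)
  out <- list()
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    k <- length(idx); tot <- sum(supplies[idx])
    if (k >= size_min && k <= size_max && tot >= lb && tot <= ub)
      out[[length(out) + 1L]] <- idx
  }
  out
}

subset_canon <- function(sets) {
  sort(vapply(sets, function(i) paste(sort(i), collapse = ","),
              character(1)))
}

# Exhaustive oracle for enumerate_feasible_units on a tiny pool.
naive_enumerate <- function(ltc, pool, activity, matrix, config) {
  tx <- activity$transplants[match(ltc, activity$id)]
  locked <- as.character(config$locked[[ltc]] %||% character(0))
  sup <- function(ids) sum(activity$lungs_recovered[match(ids, activity$id)])
  n <- length(pool)
  units <- list()
  for (mask in seq_len(2^n) - 1L) {
    ids <- pool[which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)]
    if (!all(locked %in% ids)) next
    k <- if (config$lock_size_exempt) length(setdiff(ids, locked))
         else length(ids)
    if (k < config$size_min || k > config$size_max) next
    if (any(matrix[ids, ltc] > config$max_minutes)) next
    ratio <- sup(ids) / tx
    if (abs(ratio - config$target_ratio) > config$ratio_tolerance) next
    units[[length(units) + 1L]] <- list(
      ltc = ltc, opcs = sort(ids), ratio = ratio,
      total_travel_min = sum(matrix[ids, ltc]))
  }
  units
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unit_keys <- function(units)
  vapply(units, function(u) paste(u$opcs, collapse = "|"), character(1))

# Cartesian-product oracle for solve_assignment's objective (population sd).
cartesian_min_sd <- function(candidates, fixed_zero = 0) {
  grid <- expand.grid(lapply(candidates, seq_along))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    sel <- lapply(seq_along(candidates), function(j)
      candidates[[j]][[grid[r, j]]])
    ids <- unlist(lapply(sel, `[[`, "opcs"))
    if (anyDuplicated(ids)) next
    ratios <- c(vapply(sel, `[[`, numeric(1), "ratio"),
                rep(0, fixed_zero))
    best <- min(best, sqrt(mean((ratios - mean(ratios))^2)))
  }
  best
}

# Candidate units whose ratios are consistent with an activity table.
random_candidates <- function(ltcs, opc_ids, activity, n_per_ltc, seed) {
  set.seed(seed)
  out <- lapply(ltcs, function(l) {
    tx <- activity$transplants[match(l, activity$id)]
    ks <- sample(seq_len(n_per_ltc), 1)
    units <- lapply(seq_len(ks), function(i) {
      ids <- sort(sample(opc_ids, sample(1:3, 1)))
      sup <- sum(activity$lungs_recovered[match(ids, activity$id)])
      list(ltc = l, opcs = ids, ratio = sup / tx,
           total_travel_min = round(stats::runif(1, 10, 400)))
    })
    units[!duplicated(unit_keys(units))]
  })
  names(out) <- ltcs
  out
}

# Scaled-down scenario used for multi-replicate properties: same structure
# as the default world (9 LTCs, skewed historical units, supply ~ demand
# closure) with fewer OPCs and a proportionally smaller field for runtime.
scaled_scenario <- function(seed) {
  generate_scenario(scenario_config(n_opc = 60, n_ltc = 9, field_km = 600,
                                    demand_range = c(55, 110), seed = seed))
}

scaled_optimizer_config <- function(...) {
  optimizer_config(shortlist_k = 25, search_budget = 2e3, ...)
}
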