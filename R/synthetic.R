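# Synthetic scenario generator: geographies with heterogeneous procurement
# intensity and demand, a size-skewed "historical" allocation map for
# before/after contrasts, and waitlist cohorts with calibrated competing-risk
# incidences. Embedded copies of the published per-centre table columns serve
# as plain-text fixtures.

#' Scenario configuration
#'
#' Defaults state the reference geography: 183 procurement centres and 9
#' transplant centres on a 1,000 x 1,000 km field (metropolitan-France
#' scale) travelled at 70 km/h. Procurement intensity is gamma-distributed
#' across OPCs (Poisson-gamma counts; \code{procurement_dispersion} is the
#' gamma shape — small values mean strong regional heterogeneity, the
#' disparity the redistricting corrects). Demand (transplants per LTC) is
#' drawn in \code{demand_range} independently of local supply;
#' \code{supply_demand_coupling} in [0, 1] optionally ties demand to nearby
#' supply for sensitivity tests.
#'
#' @param n_opc,n_ltc centre counts (defaults 183 and 9).
#' @param field_km side of the square field (default 1000).
#' @param speed_kmh driving speed for the travel matrix (default 70).
#' @param travel_noise_sd_min sd of travel-time noise in minutes.
#' @param mean_lungs_per_opc mean lungs recovered per OPC over the period
#'   (default 12, about 2 per year over a six-year accounting window).
#' @param procurement_dispersion gamma shape of the per-OPC intensity
#'   (default 1, strongly heterogeneous).
#' @param demand_range integer range of transplants per LTC over the period
#'   (default 150 to 350).
#' @param candidates_per_graft_range range of the candidates:transplants
#'   ratio per LTC (default 1.0 to 1.6, around the observed 1.1).
#' @param supply_demand_coupling 0 (default) for independent demand.
#' @param n_regions_side regions form an \code{n x n} grid (default 3).
#' @param seed integer seed.
#' @return List of class \code{scenario_config}.
#' @export
scenario_config <- function(n_opc = 183, n_ltc = 9, field_km = 1000,
                            speed_kmh = 70, travel_noise_sd_min = 10,
                            mean_lungs_per_opc = 12,
                            procurement_dispersion = 1,
                            demand_range = c(150, 350),
                            candidates_per_graft_range = c(1.0, 1.6),
                            supply_demand_coupling = 0,
                            n_regions_side = 3, seed = 1L) {
  if (n_ltc < 1 || n_opc < n_ltc)
    abort_la("need n_opc >= n_ltc >= 1", "validation_error")
  assert_scalar_num(field_km, "field_km", min = 1)
  assert_scalar_num(procurement_dispersion, "procurement_dispersion",
                    min = .Machine$double.eps)
  if (supply_demand_coupling < 0 || supply_demand_coupling > 1)
    abort_la("supply_demand_coupling must be in [0, 1]", "validation_error")
  structure(list(n_opc = as.integer(n_opc), n_ltc = as.integer(n_ltc),
                 field_km = field_km, speed_kmh = speed_kmh,
                 travel_noise_sd_min = travel_noise_sd_min,
                 mean_lungs_per_opc = mean_lungs_per_opc,
                 procurement_dispersion = procurement_dispersion,
                 demand_range = demand_range,
                 candidates_per_graft_range = candidates_per_graft_range,
                 supply_demand_coupling = supply_demand_coupling,
                 n_regions_side = as.integer(n_regions_side),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# historical unit sizes published for the nine centres (min 1, max 32)
HISTORICAL_UNIT_SIZES <- c(10, 23, 28, 1, 32, 1, 2, 26, 11)

#' Generate a synthetic allocation scenario
#'
#' Draws a full scenario: centre coordinates uniform on the field, a
#' synthetic travel matrix, Poisson-gamma per-OPC supply, per-LTC demand,
#' and a deliberately size-skewed "historical" allocation map whose unit
#' sizes echo the published spread (1 to 32 OPCs) — the before-state for
#' before/after equity contrasts. Fully reproducible per seed; all type
#' invariants are validated on generation.
#'
#' @param config a \code{scenario_config}.
#' @return List of class \code{scenario}: \code{centres}, \code{matrix},
#'   \code{activity}, \code{historical_map}, \code{config}.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  n_opc <- config$n_opc; n_ltc <- config$n_ltc; fk <- config$field_km
  ids <- c(sprintf("OPC%03d", seq_len(n_opc)),
           sprintf("LTC%d", seq_len(n_ltc)))
  role <- rep(c("OPC", "LTC"), c(n_opc, n_ltc))
  x <- stats::runif(n_opc + n_ltc, 0, fk)
  y <- stats::runif(n_opc + n_ltc, 0, fk)
  g <- config$n_regions_side
  region <- sprintf("R%d%d", pmin(g, 1 + floor(g * x / fk)),
                    pmin(g, 1 + floor(g * y / fk)))
  centres <- centre_table(ids, ids, role, x, y, region)

  matrix <- synthetic_travel_matrix(centres, config$speed_kmh,
                                    config$travel_noise_sd_min,
                                    seed = config$seed + 1L)

  shape <- config$procurement_dispersion
  lambda <- stats::rgamma(n_opc, shape = shape,
                          rate = shape / config$mean_lungs_per_opc)
  lungs <- stats::rpois(n_opc, lambda)

  tx_base <- sample(seq(config$demand_range[1], config$demand_range[2]),
                    n_ltc, replace = TRUE)
  if (config$supply_demand_coupling > 0) {
    # tie demand to supply within the travel threshold, for sensitivity runs
    near_supply <- vapply(sprintf("LTC%d", seq_len(n_ltc)), function(l)
      sum(lungs[match(eligible_pool(l, matrix), ids)]), numeric(1))
    scaled <- near_supply / max(near_supply) *
      diff(config$demand_range) + config$demand_range[1]
    c0 <- config$supply_demand_coupling
    tx_base <- round((1 - c0) * tx_base + c0 * scaled)
  }
  cand <- round(tx_base * stats::runif(n_ltc,
                                       config$candidates_per_graft_range[1],
                                       config$candidates_per_graft_range[2]))
  activity <- activity_table(
    id = ids, role = role,
    lungs_recovered = c(lungs, rep(NA_real_, n_ltc)),
    transplants = c(rep(NA_real_, n_opc), pmax(1, tx_base)),
    candidates = c(rep(NA_real_, n_opc), pmax(1, cand)))

  historical_map <- historical_skewed_map(centres, matrix, config)

  structure(list(centres = centres, matrix = matrix, activity = activity,
                 historical_map = historical_map, config = config),
            class = "scenario")
}

# A size-skewed historical map: unit sizes sampled from the published spread
# (scaled to the OPC budget), members taken greedily by travel time.
historical_skewed_map <- function(centres, matrix, config) {
  ltcs <- sort(ltc_ids(centres))
  sizes <- if (length(ltcs) == 9) HISTORICAL_UNIT_SIZES
           else sample(HISTORICAL_UNIT_SIZES, length(ltcs), replace = TRUE)
  budget <- length(opc_ids(centres))
  if (sum(sizes) > budget) # shrink proportionally, keep the skew
    sizes <- pmax(1, floor(sizes * budget / sum(sizes) * 0.9))
  taken <- character(0)
  pairs <- list()
  for (k in seq_along(ltcs)) {
    l <- ltcs[k]
    avail <- setdiff(rownames(matrix), taken)
    near <- avail[order(matrix[avail, l])]
    members <- utils::head(near, sizes[k])
    taken <- c(taken, members)
    if (length(members))
      pairs[[k]] <- data.frame(opc_id = members, ltc_id = l,
                               stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, pairs)
  allocation_map(df$opc_id, df$ltc_id)
}

#' Generate a synthetic waitlist cohort
#'
#' Latent exponential cause-specific hazards for transplantation and
#' death-or-delisting, calibrated so the 3-month (90-day) cumulative
#' incidences match the targets in expectation:
#' \code{CIF_k(t) = h_k/H * (1 - exp(-H t))} with \code{H = h_tx + h_death}
#' solved from the total 90-day incidence. Censoring is uniform on
#' \code{(0, censor_max)} and independent.
#'
#' @param n cohort size.
#' @param cif_transplant_3m,cif_death_3m target 90-day cumulative
#'   incidences; must be positive-summable below 1 (either may be 0).
#' @param censor_max upper bound of the uniform censoring time (days).
#' @param seed integer seed.
#' @return data.frame with columns \code{time}, \code{event}.
#' @export
generate_waitlist <- function(n, cif_transplant_3m = 0.5,
                              cif_death_3m = 0.05, censor_max = 365,
                              seed = 1L) {
  p <- cif_transplant_3m + cif_death_3m
  if (cif_transplant_3m < 0 || cif_death_3m < 0 || p >= 1)
    abort_la("target incidences must be non-negative and sum below 1",
             "validation_error")
  if (n == 0)
    return(data.frame(time = numeric(0), event = character(0),
                      stringsAsFactors = FALSE))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  if (p == 0) { # no events at all: everyone censored
    return(data.frame(time = stats::runif(n, 0, censor_max),
                      event = "censored", stringsAsFactors = FALSE))
  }
  H <- -log(1 - p) / 90
  h_tx <- H * cif_transplant_3m / p
  ev_time <- stats::rexp(n, H)
  ev_type <- ifelse(stats::runif(n) < h_tx / H, "transplant",
                    "death_or_delisting")
  cens <- stats::runif(n, 0, censor_max)
  data.frame(time = pmin(ev_time, cens),
             event = ifelse(ev_time <= cens, ev_type, "censored"),
             stringsAsFactors = FALSE)
}

#' Published per-centre table columns (embedded fixtures)
#'
#' The printed nine-centre columns of the pre-change disparity table
#' (procurement hospitals per unit, lungs recovered in the unit, candidates,
#' lung offers per candidate over 2013-2018) and the before/after offers per
#' candidate columns, plus the national cohort counts used for ratio
#' arithmetic. These are inputs (printed numbers), embedded so equity
#' summaries can be recomputed without restricted registry access.
#'
#' @return List with \code{table1} (data.frame), \code{table3_offers}
#'   (data.frame), \code{cohort_counts} (named list).
#' @export
table_fixtures <- function() {
  centres <- c("Bordeaux", "Lyon", "Marseille", "Marie Lannelongue",
               "Nantes", "Foch", "Bichat", "Strasbourg", "Toulouse")
  table1 <- data.frame(
    centre = centres,
    opc_count = c(10, 23, 28, 1, 32, 1, 2, 26, 11),
    lungs_recovered = c(39, 17, 96, 6, 54, 21, 10, 72, 19),
    candidates = c(176, 207, 287, 301, 153, 400, 308, 296, 134),
    offers_per_candidate = c(3.5, 4.4, 2.9, 2.8, 5.2, 1.4, 1.9, 2.4, 3),
    stringsAsFactors = FALSE)
  table3_offers <- data.frame(
    centre = centres,
    pre = c(3.4, 3.7, 2.6, 2.3, 4.1, 1.2, 1.6, 2.2, 3.2),
    post = c(2.8, 1.9, 1.7, 2.3, 2.5, 1.7, 1, 2.2, 2.7),
    stringsAsFactors = FALSE)
  cohort_counts <- list(
    registered_2018 = 419, transplants_2018 = 373,
    pre_candidates = 358, post_candidates = 285,
    pre_recipients = 257, post_recipients = 197)
  list(table1 = table1, table3_offers = table3_offers,
       cohort_counts = cohort_counts)
}
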