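# Offer-cascade simulator: per-graft allocation sequences under the previous
# (local -> regional -> national) and new (local -> national) schemes, and the
# allocation metrics used to compare them.

#' Scheme configuration for the offer simulator
#'
#' @param scheme \code{"previous"} (local, then same-region LTCs, then
#'   national) or \code{"new"} (local, then directly national; the regional
#'   tier is removed).
#' @param hu_fraction probability a graft is diverted to the national
#'   high-urgency tier before geographic allocation (default 0.15, the
#'   observed share of grafts allocated to high-urgency candidates).
#' @param acceptance_prob per-LTC probability of accepting an offer: a
#'   single number recycled to every LTC or a named vector by LTC id.
#'   Candidate-level selection inside a centre is not modelled; the default
#'   0.4 sits inside the reported 34-85% per-centre discard range.
#' @param national_order \code{"rotation"} (round robin over LTC ids,
#'   advancing per graft) or \code{"random"}.
#' @return List of class \code{scheme_config}.
#' @export
scheme_config <- function(scheme = c("new", "previous"), hu_fraction = 0.15,
                          acceptance_prob = 0.4,
                          national_order = c("rotation", "random")) {
  scheme <- match.arg(scheme)
  national_order <- match.arg(national_order)
  if (hu_fraction < 0 || hu_fraction > 1)
    abort_la("hu_fraction must be in [0, 1]", "validation_error")
  if (any(acceptance_prob < 0 | acceptance_prob > 1))
    abort_la("acceptance_prob must be in [0, 1]", "validation_error")
  structure(list(scheme = scheme, hu_fraction = hu_fraction,
                 acceptance_prob = acceptance_prob,
                 national_order = national_order),
            class = "scheme_config")
}

accept_prob_for <- function(ltc, config) {
  p <- config$acceptance_prob
  if (length(p) == 1 && is.null(names(p))) return(unname(p))
  if (!ltc %in% names(p))
    abort_la(paste0("no acceptance_prob for LTC ", ltc), "lookup_error")
  unname(p[[ltc]])
}

#' Simulate the offer cascade for one graft
#'
#' Runs a single graft through the tiered allocation sequence. Under the
#' previous scheme the graft is offered to its local allocation unit's LTC
#' (if the source OPC belongs to one), then to the other LTCs of the source
#' OPC's region, then nationally to all remaining LTCs. Under the new scheme
#' the regional tier is removed: local, then directly national. With
#' probability \code{hu_fraction} the graft bypasses geography on the
#' national high-urgency tier. The first accepted offer ends the cascade;
#' a graft refused everywhere is discarded.
#'
#' Uses the session RNG; seed via \code{set.seed()} or let
#' \code{\link{run_simulation}} manage seeding.
#'
#' @param opc source OPC id.
#' @param map an \code{allocation_map}.
#' @param centres a \code{centre_table} (provides regions and LTC ids).
#' @param config a \code{scheme_config}.
#' @param rotation_start index into the sorted LTC ids at which national
#'   offers start (rotation order).
#' @return data.frame, one row per offer: \code{opc_id, ltc_id, tier,
#'   accepted}; tiers are \code{"HU-national"}, \code{"local"},
#'   \code{"regional"}, \code{"national"}.
#' @export
cascade_one_graft <- function(opc, map, centres, config,
                              rotation_start = 1L) {
  i <- match(opc, centres$id)
  if (is.na(i) || centres$role[i] != "OPC")
    abort_la(paste0("unknown OPC id: ", opc), "lookup_error")
  ltcs <- sort(ltc_ids(centres))
  n_ltc <- length(ltcs)
  nat_order <- function() {
    if (config$national_order == "rotation") {
      off <- ((rotation_start - 1L) %% n_ltc)
      ltcs[(seq_len(n_ltc) + off - 1L) %% n_ltc + 1L]
    } else sample(ltcs)
  }
  offers <- list()
  offered <- character(0)
  accepted <- FALSE
  propose <- function(ltc, tier) {
    if (accepted || ltc %in% offered) return(invisible())
    ok <- stats::runif(1) < accept_prob_for(ltc, config)
    offers[[length(offers) + 1L]] <<- data.frame(
      opc_id = opc, ltc_id = ltc, tier = tier, accepted = ok,
      stringsAsFactors = FALSE)
    offered <<- c(offered, ltc)
    accepted <<- ok
    invisible()
  }

  if (stats::runif(1) < config$hu_fraction) {
    for (l in nat_order()) propose(l, "HU-national")
  } else {
    local_ltc <- if (opc %in% names(map)) unclass(map)[[opc]] else NULL
    if (!is.null(local_ltc)) propose(local_ltc, "local")
    if (config$scheme == "previous") {
      region <- centres$region[i]
      regional <- sort(intersect(
        ltcs, centres$id[centres$role == "LTC" & centres$region == region]))
      for (l in regional) propose(l, "regional")
    }
    for (l in nat_order()) propose(l, "national")
  }
  do.call(rbind, offers)
}

#' Run an offer-cascade simulation
#'
#' Streams the given per-OPC graft counts through
#' \code{\link{cascade_one_graft}} and aggregates the allocation metrics
#' used to compare schemes: per-LTC transplant counts and tier shares,
#' local-share mean and sd across LTCs, shipping distance (straight-line km
#' from source OPC to recipient LTC) mean and sd, offers received per
#' candidate per LTC, and a cold ischemia proxy (affine in shipping time).
#'
#' @param donor_stream named numeric vector: grafts per OPC id (or a
#'   data.frame with columns \code{opc_id,n}).
#' @param map an \code{allocation_map}.
#' @param centres a \code{centre_table}.
#' @param config a \code{scheme_config}.
#' @param activity optional \code{activity_table} supplying per-LTC
#'   candidate counts for the offers-per-candidate metric.
#' @param matrix optional \code{travel_matrix} for the shipping-time /
#'   ischemia proxy.
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param ischemia_intercept_min,ischemia_slope base cold ischemia time in
#'   minutes and its slope on shipping minutes (a labelled proxy, not a
#'   clinical model).
#' @return List of class \code{offer_sim_result}: \code{log} (one row per
#'   offer), \code{metrics}.
#' @export
run_simulation <- function(donor_stream, map, centres, config,
                           activity = NULL, matrix = NULL, seed = 1L,
                           ischemia_intercept_min = 240,
                           ischemia_slope = 1.0) {
  if (is.data.frame(donor_stream))
    donor_stream <- stats::setNames(donor_stream$n, donor_stream$opc_id)
  if (any(donor_stream < 0))
    abort_la("graft counts must be non-negative", "validation_error")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ltcs <- sort(ltc_ids(centres))
  rotation <- 1L
  logs <- list()
  graft_id <- 0L
  for (opc in names(donor_stream)) {
    for (g in seq_len(donor_stream[[opc]])) {
      graft_id <- graft_id + 1L
      log1 <- cascade_one_graft(opc, map, centres, config,
                                rotation_start = rotation)
      reached_national <- any(log1$tier %in% c("national", "HU-national"))
      if (reached_national && config$national_order == "rotation")
        rotation <- rotation + 1L
      log1$graft_id <- graft_id
      logs[[graft_id]] <- log1
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(opc_id = character(0), ltc_id = character(0),
               tier = character(0), accepted = logical(0),
               graft_id = integer(0))
  metrics <- offer_metrics(log, centres, activity, matrix,
                           ischemia_intercept_min, ischemia_slope,
                           n_grafts = graft_id)
  structure(list(log = log, metrics = metrics, seed = seed),
            class = "offer_sim_result")
}

offer_metrics <- function(log, centres, activity, matrix,
                          ischemia_intercept_min, ischemia_slope, n_grafts) {
  ltcs <- sort(ltc_ids(centres))
  if (n_grafts == 0 || nrow(log) == 0) {
    return(list(n_grafts = n_grafts, n_transplanted = 0, n_discarded = 0,
                empty = TRUE))
  }
  acc <- log[log$accepted, , drop = FALSE]
  tiers <- c("HU-national", "local", "regional", "national")
  tier_counts <- t(vapply(ltcs, function(l) {
    vapply(tiers, function(tr) sum(acc$ltc_id == l & acc$tier == tr),
           numeric(1))
  }, numeric(length(tiers))))
  dimnames(tier_counts) <- list(ltcs, tiers)
  tx_per_ltc <- rowSums(tier_counts)
  # local share in % per LTC, over that LTC's transplants
  local_share <- ifelse(tx_per_ltc > 0,
                        100 * tier_counts[, "local"] / tx_per_ltc, NA_real_)
  ls_ok <- local_share[!is.na(local_share)]
  local_disp <- if (length(ls_ok) >= 1)
    dispersion_summary(ls_ok, "population") else NULL

  # shipping distance over accepted grafts, straight-line km
  ship_km <- ship_min <- NULL
  if (nrow(acc)) {
    io <- match(acc$opc_id, centres$id); il <- match(acc$ltc_id, centres$id)
    ship_km <- sqrt((centres$x[io] - centres$x[il])^2 +
                    (centres$y[io] - centres$y[il])^2)
    if (!is.null(matrix))
      ship_min <- matrix[cbind(acc$opc_id, acc$ltc_id)]
  }
  offers_per_ltc <- vapply(ltcs, function(l) sum(log$ltc_id == l),
                           numeric(1))
  opc_metric <- NULL
  if (!is.null(activity)) {
    act2 <- activity
    act2$offers[match(ltcs, act2$id)] <- offers_per_ltc
    opc_vals <- vapply(ltcs, offers_per_candidate, numeric(1),
                       activity = act2)
    opc_metric <- list(per_ltc = opc_vals,
                       summary = dispersion_summary(opc_vals, "population"))
  }
  list(
    n_grafts = n_grafts,
    n_transplanted = nrow(acc),
    n_discarded = n_grafts - nrow(acc),
    tier_counts = tier_counts,
    tier_share_pct = 100 * tier_counts / max(1, nrow(acc)),
    local_share_pct = local_share,
    local_share_summary = local_disp,
    shipping_km = if (!is.null(ship_km))
      dispersion_summary(ship_km, "population") else NULL,
    cold_ischemia_min = if (!is.null(ship_min))
      dispersion_summary(ischemia_intercept_min + ischemia_slope * ship_min,
                         "population") else NULL,
    offers_received = offers_per_ltc,
    offers_per_candidate = opc_metric,
    empty = FALSE)
}
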