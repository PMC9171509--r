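# Redistricting optimizer: per-LTC enumeration of feasible local allocation
# units (branch-and-bound over supply-sorted pools) and an exact joint solver
# picking one unit per LTC, pairwise disjoint, minimizing the spread of the
# supply/demand ratios.

#' Optimizer configuration
#'
#' @param target_ratio target supply/demand ratio every unit should reach
#'   (default 0.5: each centre sourcing about half its transplant demand
#'   locally).
#' @param ratio_tolerance half-width of the acceptance band around
#'   \code{target_ratio}. Default 0.1, bracketing the observed 0.29-0.6
#'   spread of ratios around 0.5 in the reference design.
#' @param size_min,size_max unit size screen: combinations with fewer than
#'   \code{size_min} or more than \code{size_max} OPCs are withheld
#'   (defaults 5 and 15).
#' @param max_minutes driving-time eligibility threshold, minutes
#'   (default 120, i.e. "no more than 2 hours", inclusive).
#' @param locked named list, LTC id -> character vector of OPC ids that must
#'   belong to that LTC's unit (centres keeping established collaborations).
#' @param shortlist_k cap on candidate units retained per LTC for the global
#'   stage (default 200); truncation is flagged so an optimum-vs-shortlist
#'   gap can be reported.
#' @param lock_size_exempt if TRUE, locked OPCs do not count towards the
#'   size screen; by default the size constraints apply to the whole unit.
#' @param search_budget node budget for the joint branch-and-bound (default
#'   5e5). Small instances are solved exactly well within it; when the
#'   budget is exhausted the best assignment found so far is returned with
#'   \code{certified = FALSE} and a warning — standard resource-capped
#'   branch-and-bound behaviour.
#' @return List of class \code{optimizer_config}.
#' @export
optimizer_config <- function(target_ratio = 0.5, ratio_tolerance = 0.1,
                             size_min = 5, size_max = 15, max_minutes = 120,
                             locked = list(), shortlist_k = 200,
                             lock_size_exempt = FALSE,
                             search_budget = 5e5) {
  assert_scalar_num(target_ratio, "target_ratio", min = .Machine$double.eps)
  assert_scalar_num(ratio_tolerance, "ratio_tolerance", min = 0,
                    allow_inf = TRUE)
  assert_scalar_num(size_min, "size_min", min = 1)
  assert_scalar_num(size_max, "size_max", min = size_min)
  assert_scalar_num(max_minutes, "max_minutes", min = 0, allow_inf = TRUE)
  assert_scalar_num(shortlist_k, "shortlist_k", min = 1, allow_inf = TRUE)
  assert_scalar_num(search_budget, "search_budget", min = 1,
                    allow_inf = TRUE)
  structure(list(target_ratio = target_ratio,
                 ratio_tolerance = ratio_tolerance,
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 max_minutes = max_minutes, locked = locked,
                 shortlist_k = shortlist_k,
                 lock_size_exempt = isTRUE(lock_size_exempt),
                 search_budget = search_budget),
            class = "optimizer_config")
}

#' Exact size of the unconstrained assignment space
#'
#' Each OPC independently joins one of the \code{n_ltcs} units or stays
#' unassigned, so the unconstrained search space holds
#' \code{(n_ltcs + 1)^n_opcs} assignments — for the French geometry
#' (183 OPCs, 9 LTCs) exactly 10^183, the count that makes naive search
#' infeasible. Computed in exact integer arithmetic.
#'
#' @param n_opcs,n_ltcs non-negative integers.
#' @return The exact count as a decimal string.
#' @export
search_space_size <- function(n_opcs, n_ltcs) {
  assert_scalar_num(n_opcs, "n_opcs", min = 0)
  assert_scalar_num(n_ltcs, "n_ltcs", min = 0)
  big_to_string(big_pow(as.integer(n_ltcs) + 1L, as.integer(n_opcs)))
}

#' Branch-and-bound subset stream over a supply-sorted pool
#'
#' Enumerates exactly the subsets of a pool whose size lies in
#' \code{[size_min, size_max]} and whose total supply lies in
#' \code{[supply_lb, supply_ub]}, visiting only branches whose supply prefix
#' bounds can still land in the band. With the pool sorted by supply
#' descending, a branch is cut when its running supply already exceeds the
#' upper bound (supplies are non-negative, so all supersets overshoot too)
#' or when even the largest remaining completions cannot reach the lower
#' bound. The yielded set equals the unpruned powerset filter's set.
#'
#' @param supplies numeric vector of per-OPC supplies, sorted descending.
#' @param size_min,size_max subset size bounds.
#' @param supply_lb,supply_ub inclusive total-supply band (may be infinite).
#' @return List of integer index vectors into \code{supplies}.
#' @export
pruned_subset_iterator <- function(supplies, size_min, size_max,
                                   supply_lb = -Inf, supply_ub = Inf) {
  n <- length(supplies)
  if (is.unsorted(rev(supplies)))
    abort_la("supplies must be sorted descending", "validation_error")
  if (any(supplies < 0))
    abort_la("supplies must be non-negative", "validation_error")
  out <- list(); n_out <- 0L
  emit <- function(idx) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- idx
  }
  # suffix_top[i, r]: sum of the r largest supplies among positions i..n;
  # with supplies sorted descending that is supplies[i], ..., supplies[i+r-1]
  cum <- c(0, cumsum(supplies))
  top_sum <- function(i, r) {
    if (r <= 0 || i > n) return(0)
    j <- min(n, i + r - 1L)
    cum[j + 1L] - cum[i]
  }
  rec <- function(i, chosen, s) {
    k <- length(chosen)
    if (k >= size_min && s >= supply_lb && s <= supply_ub) emit(chosen)
    if (k == size_max) return()
    if (s + top_sum(i, size_max - k) < supply_lb) return() # unreachable
    j <- i
    while (j <= n) {
      s2 <- s + supplies[j]
      if (s2 <= supply_ub) {
        # enough items left to ever reach size_min?
        if (k + 1L + (n - j) >= size_min)
          rec(j + 1L, c(chosen, j), s2)
      }
      # else: supplies sorted descending, later j may still fit the band
      j <- j + 1L
    }
  }
  if (n > 0 || size_min == 0) rec(1L, integer(0), 0)
  out[seq_len(n_out)]
}

#' Enumerate feasible local allocation units for one LTC
#'
#' Brute-force enumeration of OPC combinations for \code{ltc}, accelerated
#' by the pruned subset stream: exactly the subsets of \code{pool} that
#' contain the locked OPCs, have size within the configured screen, lie
#' entirely within the travel-time threshold, and whose supply/demand ratio
#' falls within \code{target_ratio} +/- \code{ratio_tolerance}. Results are
#' sorted by distance-to-target ratio, then total travel time, then
#' lexicographic OPC-id tuple, and truncated to \code{shortlist_k} (with a
#' \code{"truncated"} attribute when the cap bites).
#'
#' @param ltc an LTC id.
#' @param pool character vector of candidate OPC ids; must be a subset of
#'   \code{eligible_pool(ltc, matrix, config$max_minutes)}.
#' @param activity an \code{activity_table}.
#' @param matrix a \code{travel_matrix}.
#' @param config an \code{optimizer_config}.
#' @return List of candidate units, each a list with elements \code{ltc},
#'   \code{opcs} (sorted ids), \code{ratio}, \code{total_travel_min}.
#' @export
enumerate_feasible_units <- function(ltc, pool, activity, matrix, config) {
  stopifnot(inherits(config, "optimizer_config"))
  elig <- eligible_pool(ltc, matrix, config$max_minutes)
  extra <- setdiff(pool, elig)
  if (length(extra))
    abort_la(paste0("pool OPC(s) outside the travel threshold for ", ltc,
                    ": ", paste(extra, collapse = ", ")), "validation_error")
  locked <- as.character(config$locked[[ltc]] %||% character(0))
  if (length(setdiff(locked, pool)))
    abort_la(paste0("locked OPC(s) not in the eligible pool for ", ltc, ": ",
                    paste(setdiff(locked, pool), collapse = ", ")),
             "validation_error")
  tx <- activity$transplants[match(ltc, activity$id)]
  if (is.na(tx) || tx < 1)
    abort_la(paste0("transplants must be >= 1 for LTC ", ltc),
             "division_guard_error")
  if (length(pool) < config$size_min) {
    warning(sprintf("pool for %s has %d OPC(s), below size_min %d: no units",
                    ltc, length(pool), config$size_min))
    return(list())
  }

  supply_of <- function(ids) {
    idx <- match(ids, activity$id)
    if (anyNA(idx))
      abort_la(paste0("OPC absent from activity table: ",
                      ids[is.na(idx)][1]), "accounting_error")
    activity$lungs_recovered[idx]
  }
  locked_supply <- sum(supply_of(locked))
  free <- setdiff(pool, locked)
  free_sup <- supply_of(free)
  ord <- order(-free_sup, free)
  free <- free[ord]; free_sup <- free_sup[ord]

  if (config$lock_size_exempt) {
    smin <- config$size_min; smax <- config$size_max
  } else {
    smin <- max(0L, config$size_min - length(locked))
    smax <- config$size_max - length(locked)
    if (smax < 0) return(list()) # more locked OPCs than size_max allows
  }
  lb <- (config$target_ratio - config$ratio_tolerance) * tx - locked_supply
  ub <- (config$target_ratio + config$ratio_tolerance) * tx - locked_supply

  subsets <- pruned_subset_iterator(free_sup, smin, min(smax, length(free)),
                                    lb, ub)
  units <- lapply(subsets, function(idx) {
    ids <- sort(c(locked, free[idx]))
    ratio <- (locked_supply + sum(free_sup[idx])) / tx
    list(ltc = ltc, opcs = ids, ratio = ratio,
         total_travel_min = sum(matrix[ids, ltc]))
  })
  if (length(units) == 0) return(units)

  dev <- vapply(units, function(u) abs(u$ratio - config$target_ratio),
                numeric(1))
  travel <- vapply(units, function(u) u$total_travel_min, numeric(1))
  key <- vapply(units, function(u) paste(u$opcs, collapse = "|"),
                character(1))
  ord <- order(dev, travel, key)
  units <- units[ord]
  truncated <- length(units) > config$shortlist_k
  if (truncated) units <- units[seq_len(config$shortlist_k)]
  attr(units, "truncated") <- truncated
  units
}

# Exact minimiser of the population variance over per-LTC ratio choices,
# ignoring disjointness. Var(x) = min_mu mean((x - mu)^2), and for fixed mu
# each LTC independently picks its achievable ratio nearest mu, so scanning
# mu over the breakpoint intervals (midpoints of adjacent achievable ratios)
# and evaluating each interval's quadratic at its clamped vertex gives the
# exact unconstrained optimum. Used as a fast path (a conflict-free scan
# selection is globally optimal) and as the root lower bound.
min_var_scan <- function(fixed, ratio_sets, n_total) {
  if (length(ratio_sets) == 0) {
    m <- if (length(fixed)) mean(fixed) else 0
    return(list(value = if (length(fixed)) sum((fixed - m)^2) / n_total else 0,
                picks = numeric(0)))
  }
  sorted_sets <- lapply(ratio_sets, function(r) sort(unique(r)))
  brk <- sort(unique(unlist(lapply(sorted_sets, function(v)
    if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)))))
  all_vals <- c(fixed, unlist(sorted_sets, use.names = FALSE))
  edges <- unique(c(min(all_vals) - 1, brk, max(all_vals) + 1))
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  K <- length(mids)
  # per interval, each LTC's nearest achievable ratio (constant on interval)
  picks <- matrix(0, K, length(sorted_sets))
  for (j in seq_along(sorted_sets)) {
    v <- sorted_sets[[j]]
    i <- findInterval(mids, v)
    lo <- v[pmax(i, 1L)]
    hi <- v[pmin(i + 1L, length(v))]
    picks[, j] <- ifelse(i == 0, v[1],
                  ifelse(i == length(v), v[length(v)],
                         ifelse(mids - lo <= hi - mids, lo, hi)))
  }
  sum_fixed <- sum(fixed); nf <- length(fixed)
  mu <- (sum_fixed + rowSums(picks)) / (nf + ncol(picks))
  mu <- pmin(pmax(mu, edges[-length(edges)]), edges[-1])
  ssq_fixed <- if (nf) outer(mu, fixed, `-`)^2 else matrix(0, K, 0)
  f <- (rowSums((picks - mu)^2) + rowSums(ssq_fixed)) / n_total
  k_best <- which.min(f)
  list(value = f[k_best], picks = picks[k_best, ])
}

#' Select one unit per LTC: disjoint, ratio-equalising
#'
#' Exact depth-first branch-and-bound over the per-LTC candidate shortlists:
#' chooses one candidate unit per LTC with pairwise-disjoint OPC sets,
#' minimizing the population standard deviation of the supply/demand ratios
#' over the fixed set of LTCs. Ties are broken by total travel time, then by
#' the lexicographic tuple of unit keys. LTCs with no candidate units
#' receive the empty unit (ratio 0) and are flagged. \code{mode
#' = "independent"} instead gives every LTC its rank-1 unit and reports
#' OPC overlaps without resolving them.
#'
#' @param candidates named list, LTC id -> list of candidate units as
#'   returned by \code{\link{enumerate_feasible_units}}.
#' @param activity an \code{activity_table}.
#' @param config an \code{optimizer_config}.
#' @param mode \code{"joint"} (default) or \code{"independent"}.
#' @param allow_empty if TRUE, the empty unit (ratio 0) is a last-resort
#'   option for every LTC, so a centre crowded out by disjointness conflicts
#'   falls back to no local unit instead of aborting the whole assignment;
#'   the number of empty units is minimized before the sd (otherwise the
#'   all-empty assignment, sd 0, would trivially win). With FALSE (default)
#'   an unresolvable conflict raises an infeasibility error naming the
#'   smallest conflicting LTC pair.
#' @return List of class \code{assignment_result}: \code{map}
#'   (\code{allocation_map}, NULL in independent mode with overlaps),
#'   \code{profile} (\code{ratio_profile}), \code{selection} (per-LTC chosen
#'   unit), \code{empty_ltcs}, \code{overlaps},
#'   \code{shortlist_truncated}.
#' @export
solve_assignment <- function(candidates, activity, config,
                             mode = c("joint", "independent"),
                             allow_empty = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "optimizer_config"))
  ltcs <- sort(names(candidates))
  n_cand <- vapply(candidates, length, integer(1))[ltcs]
  empty_ltcs <- ltcs[n_cand == 0]
  active <- ltcs[n_cand > 0]
  truncated <- any(vapply(candidates, function(x)
    isTRUE(attr(x, "truncated")), logical(1)))
  if (truncated)
    warning("shortlist_k truncated one or more candidate lists; the global ",
            "optimum is only guaranteed over the shortlists")

  finish <- function(sel) {
    pairs <- do.call(rbind, lapply(sel, function(u)
      if (length(u$opcs)) data.frame(opc_id = u$opcs, ltc_id = u$ltc,
                                     stringsAsFactors = FALSE)))
    map <- if (is.null(pairs)) allocation_map()
           else allocation_map(pairs$opc_id, pairs$ltc_id)
    prof <- ratio_profile(map, activity, ltcs = ltcs, sd_mode = "population")
    chose_empty <- names(sel)[vapply(sel, function(u)
      length(u$opcs) == 0, logical(1))]
    structure(list(map = map, profile = prof, selection = sel,
                   empty_ltcs = sort(unique(c(empty_ltcs, chose_empty))),
                   overlaps = NULL, certified = TRUE,
                   shortlist_truncated = truncated), class = "assignment_result")
  }

  if (mode == "independent") {
    sel <- lapply(active, function(l) candidates[[l]][[1]])
    names(sel) <- active
    all_opcs <- unlist(lapply(sel, `[[`, "opcs"))
    dup <- unique(all_opcs[duplicated(all_opcs)])
    overlaps <- if (length(dup)) {
      do.call(rbind, lapply(dup, function(o) data.frame(
        opc_id = o,
        ltc_ids = paste(sort(vapply(sel, function(u)
          if (o %in% u$opcs) u$ltc else NA_character_, character(1))[
            vapply(sel, function(u) o %in% u$opcs, logical(1))],
          collapse = "+")),
        stringsAsFactors = FALSE)))
    } else NULL
    if (is.null(overlaps)) {
      res <- finish(sel)
      res$overlaps <- NULL
      return(res)
    }
    return(structure(list(map = NULL, profile = NULL, selection = sel,
                          empty_ltcs = empty_ltcs, overlaps = overlaps,
                          shortlist_truncated = truncated),
                     class = "assignment_result"))
  }

  # ---- joint exact search ----
  # Objective is lexicographic: (1) fewest empty units, (2) population sd of
  # the ratios over the fixed LTC set, (3) total travel time, (4) unit-key
  # tuple. Empty units (allow_empty) are a last resort, never an
  # sd-lowering device: otherwise the all-empty assignment (every ratio 0,
  # sd 0) would "win".
  n_total <- length(ltcs)
  fixed_ratios <- rep(0, length(empty_ltcs)) # forced-empty units score 0
  # order LTCs by fewest candidates first (fail fast)
  search_order <- active[order(n_cand[active], active)]

  # fast path: exact unconstrained optimum over the real units; if its
  # selection is conflict-free it is globally optimal (0 extra empties, and
  # disjointness can only worsen the sd)
  ratio_sets <- lapply(search_order, function(l)
    vapply(candidates[[l]], `[[`, numeric(1), "ratio"))
  travel_min <- vapply(search_order, function(l)
    min(vapply(candidates[[l]], `[[`, numeric(1), "total_travel_min")),
    numeric(1))
  travel_suffix <- c(rev(cumsum(rev(travel_min))), 0)
  scan <- min_var_scan(fixed_ratios, ratio_sets, n_total)
  scan_sel <- lapply(seq_along(search_order), function(d) {
    for (u in candidates[[search_order[d]]])
      if (abs(u$ratio - scan$picks[d]) <= 1e-12) return(u)
    NULL
  })
  if (!any(vapply(scan_sel, is.null, logical(1)))) {
    all_opcs <- unlist(lapply(scan_sel, `[[`, "opcs"))
    if (!anyDuplicated(all_opcs)) {
      names(scan_sel) <- search_order
      return(finish(scan_sel[order(names(scan_sel))]))
    }
  }

  # ---- greedy first-fit (empty as last resort): upper bound on empties ----
  L <- length(search_order)
  non_conflicting <- function(d, used)
    Filter(function(u) !any(u$opcs %in% used), candidates[[search_order[d]]])
  empty_unit <- function(l) list(ltc = l, opcs = character(0), ratio = 0,
                                 total_travel_min = 0)
  greedy_sel <- list(); greedy_used <- character(0); greedy_e <- 0L
  greedy_ok <- TRUE
  for (d in seq_len(L)) {
    opts <- non_conflicting(d, greedy_used)
    if (length(opts)) {
      u <- opts[[1]]
      greedy_used <- c(greedy_used, u$opcs)
    } else if (allow_empty) {
      u <- empty_unit(search_order[d])
      greedy_e <- greedy_e + 1L
    } else { greedy_ok <- FALSE; break }
    greedy_sel <- c(greedy_sel, list(u))
  }

  nodes <- 0L
  exhausted <- FALSE
  budget <- config$search_budget
  tick <- function() {
    nodes <<- nodes + 1L
    if (nodes > budget) exhausted <<- TRUE
    exhausted
  }

  # ---- phase A: minimum achievable number of extra empty units ----
  bestE <- if (greedy_ok) greedy_e else Inf
  witnessA <- if (greedy_ok) greedy_sel else NULL
  recA <- function(d, used, e, sel) {
    if (tick()) return()
    if (e >= bestE) return()
    if (d > L) { bestE <<- e; witnessA <<- sel; return() }
    # every remaining LTC whose whole shortlist conflicts is forced empty
    forced <- 0L
    for (dd in d:L)
      if (length(non_conflicting(dd, used)) == 0) forced <- forced + 1L
    if (e + forced >= bestE) return()
    for (u in non_conflicting(d, used)) {
      if (exhausted) return()
      recA(d + 1L, c(used, u$opcs), e, c(sel, list(u)))
    }
    if (allow_empty)
      recA(d + 1L, used, e + 1L, c(sel, list(empty_unit(search_order[d]))))
  }
  if (bestE > 0) recA(1L, character(0), 0L, list())

  if (!is.finite(bestE) && L > 0) {
    # no disjoint combination: name the smallest conflicting LTC pair
    pair <- NULL
    combs <- utils::combn(sort(active), 2, simplify = FALSE)
    for (p in combs) {
      ca <- candidates[[p[1]]]; cb <- candidates[[p[2]]]
      all_conflict <- all(vapply(ca, function(a)
        all(vapply(cb, function(b) any(a$opcs %in% b$opcs), logical(1))),
        logical(1)))
      if (all_conflict) { pair <- p; break }
    }
    msg <- if (!is.null(pair))
      sprintf("no disjoint unit combination exists: every candidate pair for (%s, %s) conflicts",
              pair[1], pair[2])
    else "no disjoint unit combination exists (higher-order conflict)"
    abort_la(msg, "infeasibility_error")
  }
  e_star <- if (L > 0) bestE else 0L

  # ---- phase B: minimize the ratio sd subject to exactly e_star empties ----
  ratio_sets0 <- lapply(ratio_sets, function(r) c(r, 0))
  best <- NULL
  best_obj <- list(var = Inf, travel = Inf, key = "")
  eval_leaf <- function(sel) {
    r <- vapply(sel, `[[`, numeric(1), "ratio")
    v <- sum((c(r, fixed_ratios) - mean(c(r, fixed_ratios)))^2) / n_total
    tr <- sum(vapply(sel, `[[`, numeric(1), "total_travel_min"))
    key <- paste(vapply(sel, function(u)
      paste(u$opcs, collapse = "|"), character(1)), collapse = ";")
    better <- v < best_obj$var - 1e-12 ||
      (abs(v - best_obj$var) <= 1e-12 &&
         (tr < best_obj$travel - 1e-9 ||
            (abs(tr - best_obj$travel) <= 1e-9 && key < best_obj$key)))
    if (better) { best <<- sel; best_obj <<- list(var = v, travel = tr,
                                                  key = key) }
  }
  if (greedy_ok && greedy_e == e_star) eval_leaf(greedy_sel)

  rec <- function(d, used, e, chosen_ratios, chosen_travel, sel) {
    if (tick()) return()
    if (e > e_star) return()
    if (d > L) {
      # by phase-A minimality every completion carries exactly e_star empties
      eval_leaf(sel)
      return()
    }
    # sd bound: exact unconstrained minimum over the remaining shortlists;
    # ratio 0 stays reachable while this branch can still afford empties
    sets <- if (e < e_star) ratio_sets0[d:L] else ratio_sets[d:L]
    lb <- min_var_scan(c(chosen_ratios, fixed_ratios), sets, n_total)$value
    if (lb > best_obj$var + 1e-12) return()
    # plateau prune: cannot beat the sd strictly and the travel lower bound
    # already loses the tie-break (remaining travel >= 0 always)
    t_lb <- sum(chosen_travel) + if (e == e_star) travel_suffix[d] else 0
    if (lb > best_obj$var - 1e-12 && t_lb > best_obj$travel + 1e-9) return()
    for (u in non_conflicting(d, used)) {
      if (exhausted) return()
      rec(d + 1L, c(used, u$opcs), e, c(chosen_ratios, u$ratio),
          c(chosen_travel, u$total_travel_min), c(sel, list(u)))
    }
    if (allow_empty && e < e_star)
      rec(d + 1L, used, e + 1L, c(chosen_ratios, 0), c(chosen_travel, 0),
          c(sel, list(empty_unit(search_order[d]))))
  }
  rec(1L, character(0), 0L, numeric(0), numeric(0), list())
  if (exhausted)
    warning("search_budget exhausted: returning the best assignment found; ",
            "optimality over the shortlists is not certified")

  # budget may have run out before phase B reached a leaf: fall back to the
  # best feasible assignment seen (phase-A witness, then greedy)
  if (is.null(best)) best <- witnessA
  sel <- best %||% list()
  names(sel) <- vapply(sel, `[[`, character(1), "ltc")
  out <- finish(sel)
  out$certified <- !exhausted
  out
}

#' One-call redistricting pipeline
#'
#' Builds each LTC's eligible pool, enumerates its feasible units, and
#' solves the joint assignment.
#'
#' @param centres a \code{centre_table}.
#' @param matrix a \code{travel_matrix}.
#' @param activity an \code{activity_table}.
#' @param config an \code{optimizer_config}.
#' @param mode passed to \code{\link{solve_assignment}}.
#' @return An \code{assignment_result}.
#' @export
optimize_units <- function(centres, matrix, activity,
                           config = optimizer_config(),
                           mode = c("joint", "independent")) {
  mode <- match.arg(mode)
  ltcs <- ltc_ids(centres)
  candidates <- lapply(ltcs, function(l) {
    pool <- eligible_pool(l, matrix, config$max_minutes)
    if (length(pool) < config$size_min) return(structure(list(),
                                                         truncated = FALSE))
    enumerate_feasible_units(l, pool, activity, matrix, config)
  })
  names(candidates) <- ltcs
  solve_assignment(candidates, activity, config, mode = mode,
                   allow_empty = (mode == "joint"))
}
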