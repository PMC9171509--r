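# Supply/demand accounting: unit supply, the supply/demand ratio, and the
# dispersion summaries used as equity metrics.

#' Build a validated activity table
#'
#' Per-OPC supply counts (donor lungs recovered and transplanted over the
#' period) and per-LTC demand counts (transplants performed, listed
#' candidates, and optionally graft offers received, which the simulator
#' fills in).
#'
#' @param id centre ids.
#' @param role \code{"OPC"} or \code{"LTC"} per row.
#' @param lungs_recovered per-OPC lung counts (NA for LTC rows).
#' @param transplants per-LTC transplant counts, must be >= 1 (NA for OPCs).
#' @param candidates per-LTC candidate counts, must be >= 1 (NA for OPCs).
#' @param offers per-LTC offer counts (optional; NA allowed).
#' @return A \code{data.frame} of class \code{activity_table}.
#' @export
activity_table <- function(id, role, lungs_recovered = NA_real_,
                           transplants = NA_real_, candidates = NA_real_,
                           offers = NA_real_) {
  df <- data.frame(id = as.character(id), role = as.character(role),
                   lungs_recovered = as.numeric(lungs_recovered),
                   transplants = as.numeric(transplants),
                   candidates = as.numeric(candidates),
                   offers = as.numeric(offers), stringsAsFactors = FALSE)
  validate_activity(df)
  class(df) <- c("activity_table", "data.frame")
  df
}

validate_activity <- function(df) {
  if (anyDuplicated(df$id))
    abort_la("duplicate id in activity table", "validation_error")
  opc <- df[df$role == "OPC", , drop = FALSE]
  ltc <- df[df$role == "LTC", , drop = FALSE]
  if (any(is.na(opc$lungs_recovered)) || any(opc$lungs_recovered < 0))
    abort_la("lungs_recovered must be a non-negative count for every OPC",
             "validation_error")
  if (any(is.na(ltc$transplants)) || any(ltc$transplants < 1))
    abort_la("transplants must be >= 1 for every LTC (ratio denominator)",
             "validation_error")
  if (any(!is.na(ltc$candidates) & ltc$candidates < 1))
    abort_la("candidates must be >= 1 where given", "validation_error")
  if (any(!is.na(df$offers) & df$offers < 0))
    abort_la("offers must be non-negative", "validation_error")
  invisible(df)
}

#' Load an activity table from CSV
#'
#' Columns \code{id,role,lungs_recovered,transplants,candidates,offers};
#' role-specific columns may be blank where inapplicable.
#'
#' @param path CSV path.
#' @return An \code{activity_table}.
#' @export
load_activity <- function(path) {
  if (!file.exists(path))
    abort_la(paste0("activity file not found: ", path), "io_error")
  df <- read_csv_prov(path)
  for (col in c("lungs_recovered", "transplants", "candidates", "offers"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  activity_table(df$id, df$role, df$lungs_recovered, df$transplants,
                 df$candidates, df$offers)
}

#' Allocation maps
#'
#' An allocation map is a disjoint partial assignment of OPCs to LTC local
#' allocation units: each OPC serves at most one LTC; unassigned OPCs offer
#' directly at the national level.
#'
#' @param opc_id,ltc_id parallel vectors of assigned pairs.
#' @return Named character vector (names = OPC ids, values = LTC ids) of
#'   class \code{allocation_map}.
#' @export
allocation_map <- function(opc_id = character(0), ltc_id = character(0)) {
  opc_id <- as.character(opc_id); ltc_id <- as.character(ltc_id)
  if (length(opc_id) != length(ltc_id))
    abort_la("opc_id and ltc_id must have equal length", "validation_error")
  if (anyDuplicated(opc_id))
    abort_la(paste0("OPC assigned twice: ",
                    opc_id[duplicated(opc_id)][1]), "validation_error")
  m <- stats::setNames(ltc_id, opc_id)
  class(m) <- "allocation_map"
  m
}

#' @rdname allocation_map
#' @param path CSV path with columns \code{opc_id,ltc_id} (unassigned OPCs
#'   omitted).
#' @export
load_allocation_map <- function(path) {
  if (!file.exists(path))
    abort_la(paste0("allocation map file not found: ", path), "io_error")
  df <- read_csv_prov(path)
  allocation_map(df$opc_id, df$ltc_id)
}

map_to_df <- function(map) {
  data.frame(opc_id = names(map), ltc_id = unname(unclass(map)),
             stringsAsFactors = FALSE)
}

unit_members <- function(ltc, map) names(map)[unclass(map) == ltc]

#' Supply of a local allocation unit
#'
#' Total donor lungs recovered over the OPCs assigned to an LTC; zero for an
#' empty unit.
#'
#' @param ltc an LTC id.
#' @param map an \code{allocation_map}.
#' @param activity an \code{activity_table} covering every assigned OPC.
#' @return Numeric count.
#' @export
unit_supply <- function(ltc, map, activity) {
  members <- unit_members(ltc, map)
  if (length(members) == 0) return(0)
  idx <- match(members, activity$id)
  if (anyNA(idx))
    abort_la(paste0("OPC in map absent from activity table: ",
                    members[is.na(idx)][1]), "accounting_error")
  sum(activity$lungs_recovered[idx])
}

#' Supply/demand ratio of a transplant centre
#'
#' Donor lungs recovered within the centre's local allocation unit divided by
#' all transplants performed at the centre over the period. The redistricting
#' objective is to equalise this ratio across centres (target 0.5).
#'
#' @inheritParams unit_supply
#' @return Non-negative real.
#' @export
supply_demand_ratio <- function(ltc, map, activity) {
  tx <- activity$transplants[match(ltc, activity$id)]
  if (is.na(tx) || tx < 1)
    abort_la(paste0("transplants must be >= 1 for LTC ", ltc),
             "division_guard_error")
  unit_supply(ltc, map, activity) / tx
}

#' Graft offers per listed candidate
#'
#' @param ltc an LTC id.
#' @param activity an \code{activity_table} with \code{offers} and
#'   \code{candidates} filled for \code{ltc}.
#' @return Non-negative real.
#' @export
offers_per_candidate <- function(ltc, activity) {
  i <- match(ltc, activity$id)
  if (is.na(i)) abort_la(paste0("unknown LTC id: ", ltc), "lookup_error")
  cand <- activity$candidates[i]
  if (is.na(cand) || cand < 1)
    abort_la(paste0("candidates must be >= 1 for LTC ", ltc),
             "division_guard_error")
  off <- activity$offers[i]
  if (is.na(off)) off <- 0
  off / cand
}

#' Dispersion summary (mean, sd, min, max)
#'
#' The equity summaries reported across transplant centres. \code{sd_mode}
#' selects the denominator: \code{"sample"} (n - 1, the default; reproduces
#' the printed 12.5 and 1.2 of the pre-change disparity table) or
#' \code{"population"} (n; matches the printed post-change 0.9/0.5 sds).
#' Both conventions appear in the source reports, so the mode is explicit.
#'
#' @param values numeric vector, at least one value (two for sample sd).
#' @param sd_mode \code{"sample"} or \code{"population"}.
#' @return List with \code{mean}, \code{sd}, \code{min}, \code{max}.
#' @export
dispersion_summary <- function(values, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (length(values) == 0)
    abort_la("dispersion_summary needs at least one value", "validation_error")
  if (sd_mode == "sample" && length(values) < 2)
    abort_la("sample sd needs at least two values", "validation_error")
  m <- mean(values)
  s <- if (sd_mode == "sample") stats::sd(values)
       else sqrt(mean((values - m)^2))
  list(mean = m, sd = s, min = min(values), max = max(values))
}

#' Supply/demand ratio profile of an allocation map
#'
#' Per-LTC ratios plus their dispersion summary; the optimizer's objective is
#' the (population) sd of this profile.
#'
#' @param map an \code{allocation_map}.
#' @param activity an \code{activity_table}.
#' @param ltcs LTC ids to profile (default: all LTC rows of \code{activity}).
#' @param sd_mode sd convention, see \code{\link{dispersion_summary}}.
#' @return List of class \code{ratio_profile}: \code{ratios} (named vector)
#'   and \code{summary}.
#' @export
ratio_profile <- function(map, activity,
                          ltcs = activity$id[activity$role == "LTC"],
                          sd_mode = "population") {
  ratios <- vapply(ltcs, supply_demand_ratio, numeric(1),
                   map = map, activity = activity)
  structure(list(ratios = ratios,
                 summary = dispersion_summary(ratios, sd_mode)),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat("Supply/demand ratio profile (", length(x$ratios), " LTCs)\n", sep = "")
  print(round(x$ratios, 3))
  s <- x$summary
  cat(sprintf("mean %.3f  sd %.3f  min %.3f  max %.3f\n",
              s$mean, s$sd, s$min, s$max))
  invisible(x)
}
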