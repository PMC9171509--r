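# Centres, travel-time matrices, and travel-time eligibility pools.

#' Build a validated centre table
#'
#' A centre table holds the supply nodes (organ procurement centres, role
#' \code{"OPC"}) and demand nodes (lung transplant centres, role \code{"LTC"})
#' of a geography, with planar coordinates and a region label.
#'
#' @param id character vector of unique centre identifiers.
#' @param name display names (defaults to \code{id}).
#' @param role \code{"OPC"} or \code{"LTC"}, one per centre.
#' @param x,y numeric coordinates. Synthetic geographies use planar km;
#'   longitude/latitude input must be projected by the caller and declared
#'   via \code{coordinate_system}.
#' @param region region labels used by the regional allocation tier.
#' @param coordinate_system declared unit of \code{x}/\code{y}
#'   (\code{"km"} or \code{"degrees"}).
#' @return A \code{data.frame} of class \code{centre_table}.
#' @export
centre_table <- function(id, name = id, role, x, y, region,
                         coordinate_system = c("km", "degrees")) {
  coordinate_system <- match.arg(coordinate_system)
  df <- data.frame(id = as.character(id), name = as.character(name),
                   role = as.character(role), x = as.numeric(x),
                   y = as.numeric(y), region = as.character(region),
                   stringsAsFactors = FALSE)
  validate_centres(df)
  attr(df, "coordinate_system") <- coordinate_system
  class(df) <- c("centre_table", "data.frame")
  df
}

validate_centres <- function(df) {
  required <- c("id", "name", "role", "x", "y", "region")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_la(paste0("centre table missing column(s): ",
                    paste(missing, collapse = ", ")), "validation_error")
  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    abort_la(paste0("duplicate centre id(s): ",
                    paste(unique(dup), collapse = ", ")), "validation_error")
  bad <- which(!df$role %in% c("OPC", "LTC"))
  if (length(bad))
    abort_la(sprintf("unknown role '%s' in row %d (id %s)",
                     df$role[bad[1]], bad[1], df$id[bad[1]]),
             "validation_error")
  invisible(df)
}

#' Load centres from a CSV file
#'
#' Expects columns \code{id,name,role,x,y,region}; lines starting with
#' \code{#} are treated as comments. Duplicate ids and unknown roles are
#' rejected with an error naming the offending row.
#'
#' @param path path to a CSV file.
#' @param coordinate_system declared coordinate units (see
#'   \code{\link{centre_table}}).
#' @return A \code{centre_table}.
#' @export
load_centres <- function(path, coordinate_system = c("km", "degrees")) {
  coordinate_system <- match.arg(coordinate_system)
  if (!file.exists(path))
    abort_la(paste0("centre file not found: ", path), "io_error")
  df <- read_csv_prov(path)
  required <- c("id", "role", "x", "y", "region") # name optional, id fallback
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_la(paste0("centre table missing column(s): ",
                    paste(missing, collapse = ", ")), "validation_error")
  if (nrow(df) == 0) {
    out <- data.frame(id = character(0), name = character(0),
                      role = character(0), x = numeric(0), y = numeric(0),
                      region = character(0), stringsAsFactors = FALSE)
    attr(out, "coordinate_system") <- coordinate_system
    class(out) <- c("centre_table", "data.frame")
    return(out)
  }
  centre_table(df$id, df$name %||% df$id, df$role, df$x, df$y, df$region,
               coordinate_system)
}

opc_ids <- function(centres) centres$id[centres$role == "OPC"]
ltc_ids <- function(centres) centres$id[centres$role == "LTC"]

#' Synthetic driving-time matrix
#'
#' Stands in for a road-network travel-time matrix: directed OPC-to-LTC times
#' in minutes, computed as straight-line distance at a constant driving speed
#' plus truncated Gaussian noise. \code{time = 60 * dist_km / speed_kmh + eps},
#' \code{eps ~ N(0, noise_sd_min)} truncated at zero so entries stay
#' non-negative.
#'
#' @param centres a \code{centre_table} with at least one OPC and one LTC.
#' @param speed_kmh average driving speed, km/h.
#' @param noise_sd_min sd of the additive minute noise (0 for none).
#' @param seed integer seed; the matrix is reproducible for a fixed seed.
#' @return A numeric matrix (class \code{travel_matrix}) with OPC rows and
#'   LTC columns, entries in minutes.
#' @export
synthetic_travel_matrix <- function(centres, speed_kmh = 70,
                                    noise_sd_min = 0, seed = 1L) {
  assert_scalar_num(speed_kmh, "speed_kmh", min = .Machine$double.eps)
  assert_scalar_num(noise_sd_min, "noise_sd_min", min = 0)
  opcs <- centres[centres$role == "OPC", , drop = FALSE]
  ltcs <- centres[centres$role == "LTC", , drop = FALSE]
  if (nrow(opcs) == 0 || nrow(ltcs) == 0)
    abort_la("need at least one OPC and one LTC", "empty_input_error")
  dist <- outer(seq_len(nrow(opcs)), seq_len(nrow(ltcs)), function(i, j) {
    sqrt((opcs$x[i] - ltcs$x[j])^2 + (opcs$y[i] - ltcs$y[j])^2)
  })
  m <- 60 * dist / speed_kmh
  if (noise_sd_min > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    eps <- matrix(stats::rnorm(length(m), 0, noise_sd_min), nrow = nrow(m))
    m <- m + eps
    m[m < 0] <- 0
  }
  dimnames(m) <- list(opcs$id, ltcs$id)
  class(m) <- c("travel_matrix", class(m))
  m
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Load a travel-time matrix from long-format CSV
#'
#' Expects columns \code{opc_id,ltc_id,minutes} with every (OPC, LTC) pair
#' present exactly once and all entries non-negative.
#'
#' @param path CSV path.
#' @return A \code{travel_matrix} (OPC rows, LTC columns, minutes).
#' @export
load_travel_matrix <- function(path) {
  if (!file.exists(path))
    abort_la(paste0("travel matrix file not found: ", path), "io_error")
  df <- read_csv_prov(path)
  required <- c("opc_id", "ltc_id", "minutes")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_la(paste0("travel matrix missing column(s): ",
                    paste(missing, collapse = ", ")), "validation_error")
  validate_travel_long(df)
  opcs <- sort(unique(df$opc_id))
  ltcs <- sort(unique(df$ltc_id))
  m <- matrix(NA_real_, length(opcs), length(ltcs),
              dimnames = list(opcs, ltcs))
  m[cbind(match(df$opc_id, opcs), match(df$ltc_id, ltcs))] <- df$minutes
  class(m) <- c("travel_matrix", class(m))
  m
}

validate_travel_long <- function(df) {
  if (any(!is.finite(df$minutes)) || any(df$minutes < 0))
    abort_la("travel times must be non-negative and finite",
             "validation_error")
  key <- paste(df$opc_id, df$ltc_id)
  if (anyDuplicated(key))
    abort_la(paste0("duplicate (OPC, LTC) pair: ", key[duplicated(key)][1]),
             "validation_error")
  n_expected <- length(unique(df$opc_id)) * length(unique(df$ltc_id))
  if (nrow(df) != n_expected)
    abort_la(sprintf(
      "incomplete travel matrix: %d rows, %d (OPC, LTC) pairs expected",
      nrow(df), n_expected), "validation_error")
  invisible(df)
}

travel_matrix_to_long <- function(matrix) {
  data.frame(opc_id = rep(rownames(matrix), ncol(matrix)),
             ltc_id = rep(colnames(matrix), each = nrow(matrix)),
             minutes = as.vector(matrix), stringsAsFactors = FALSE)
}

#' Eligible procurement pool for a transplant centre
#'
#' The OPCs whose driving time to \code{ltc} does not exceed
#' \code{max_minutes}. The comparison is inclusive: a centre exactly at the
#' threshold ("no more than 2 hours") is eligible.
#'
#' @param ltc an LTC id present in the matrix columns.
#' @param matrix a \code{travel_matrix}.
#' @param max_minutes travel-time threshold in minutes (default 120).
#' @return Character vector of eligible OPC ids (matrix row order).
#' @export
eligible_pool <- function(ltc, matrix, max_minutes = 120) {
  if (!ltc %in% colnames(matrix))
    abort_la(paste0("unknown LTC id: ", ltc), "lookup_error")
  rownames(matrix)[matrix[, ltc] <= max_minutes]
}
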