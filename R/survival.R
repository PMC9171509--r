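# Non-parametric waitlist and post-transplant estimators: Kaplan-Meier
# product-limit survival and the Aalen-Johansen cumulative incidence under
# competing risks (transplant vs death-or-delisting). Point estimates only;
# at ties, events precede censorings.

WAITLIST_EVENTS <- c("transplant", "death_or_delisting", "censored")

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' For waitlist records where transplantation and death-or-delisting compete,
#' the cause-k cumulative incidence at t is
#' \code{CIF_k(t) = sum over event times t_i <= t of S(t_i-) * d_ki / n_i},
#' with \code{S} the all-cause Kaplan-Meier survivor, \code{d_ki} the cause-k
#' events at t_i and \code{n_i} the risk set. The step function is
#' right-continuous; the decomposition conserves probability:
#' \code{sum_k CIF_k(t) + S(t) = 1} at every event time.
#'
#' @param records data.frame with columns \code{time} (non-negative days
#'   from listing) and \code{event} (one of \code{"transplant"},
#'   \code{"death_or_delisting"}, \code{"censored"}).
#' @param cause the event type whose incidence is estimated.
#' @param horizon evaluation time (default 90 days, the 3-month horizon).
#' @return List of class \code{cif_estimate}: \code{times}, \code{cif}
#'   (right-continuous steps), \code{surv} (all-cause KM at the same times),
#'   \code{at_horizon}.
#' @export
cumulative_incidence <- function(records, cause = "transplant",
                                 horizon = 90) {
  validate_waitlist(records)
  if (!cause %in% WAITLIST_EVENTS[1:2])
    abort_la(paste0("unknown cause: ", cause), "validation_error")
  times <- sort(unique(records$time[records$event != "censored"]))
  n <- nrow(records)
  cif <- numeric(length(times))
  surv <- numeric(length(times))
  s_prev <- 1
  acc <- 0
  for (k in seq_along(times)) {
    t <- times[k]
    # events precede censorings at ties: risk set counts time >= t
    n_risk <- sum(records$time >= t)
    d_all <- sum(records$time == t & records$event != "censored")
    d_cause <- sum(records$time == t & records$event == cause)
    acc <- acc + s_prev * d_cause / n_risk
    s_prev <- s_prev * (1 - d_all / n_risk)
    cif[k] <- acc
    surv[k] <- s_prev
  }
  at_h <- if (length(times) == 0 || horizon < times[1]) 0
          else cif[max(which(times <= horizon))]
  structure(list(times = times, cif = cif, surv = surv, cause = cause,
                 horizon = horizon, at_horizon = at_h),
            class = "cif_estimate")
}

validate_waitlist <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    abort_la("records must be non-empty", "validation_error")
  if (any(records$time < 0))
    abort_la("times must be non-negative", "validation_error")
  if (any(!records$event %in% WAITLIST_EVENTS))
    abort_la(paste0("unknown event type: ",
                    setdiff(records$event, WAITLIST_EVENTS)[1]),
             "validation_error")
  invisible(records)
}

#' Kaplan-Meier product-limit estimator
#'
#' \code{S(t) = prod over event times t_i <= t of (1 - d_i / n_i)}; used for
#' post-transplant survival. Events precede censorings at tied times.
#'
#' @param records data.frame with columns \code{time} (non-negative days
#'   from transplant) and \code{event} (\code{"death"} or
#'   \code{"censored"}).
#' @param horizon evaluation time (default 90 days).
#' @return List of class \code{km_estimate}: \code{times}, \code{surv},
#'   \code{at_horizon}.
#' @export
kaplan_meier <- function(records, horizon = 90) {
  if (is.null(records) || nrow(records) == 0)
    abort_la("records must be non-empty", "validation_error")
  if (any(records$time < 0))
    abort_la("times must be non-negative", "validation_error")
  if (any(!records$event %in% c("death", "censored")))
    abort_la("event must be 'death' or 'censored'", "validation_error")
  times <- sort(unique(records$time[records$event == "death"]))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t <- times[k]
    n_risk <- sum(records$time >= t)
    d <- sum(records$time == t & records$event == "death")
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  at_h <- if (length(times) == 0 || horizon < times[1]) 1
          else surv[max(which(times <= horizon))]
  structure(list(times = times, surv = surv, horizon = horizon,
                 at_horizon = at_h), class = "km_estimate")
}
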