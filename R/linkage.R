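#' Filter landings receipts to albacore-dominated tickets
#'
#' Retains receipts whose albacore share of total landed weight is at least
#' \code{min_fraction} (inclusive boundary: a ticket at exactly 90 percent
#' is kept). Receipts with zero total pounds have an undefined share and are
#' excluded; their count is reported in the attached filter log.
#'
#' @param receipts long-format receipt data.frame with columns
#'   \code{ticket_id}, \code{vessel_id}, \code{timestamp}, \code{species},
#'   \code{pounds} (one row per species entry).
#' @param min_fraction minimum albacore weight share, default 0.9.
#' @param target_species species name whose share is evaluated.
#' @return receipts restricted to qualifying tickets, with attribute
#'   \code{filter_log} = counts of tickets removed by rule.
#' @export
filter_albacore_receipts <- function(receipts, min_fraction = 0.9,
                                     target_species = "albacore") {
  stopifnot(all(c("ticket_id", "species", "pounds") %in% names(receipts)))
  if (any(receipts$pounds < 0)) stop("filter_albacore_receipts: negative pounds")
  tot <- tapply(receipts$pounds, receipts$ticket_id, sum)
  alb <- tapply(ifelse(receipts$species == target_species, receipts$pounds, 0),
                receipts$ticket_id, sum)
  zero <- names(tot)[tot == 0]
  frac <- alb / tot
  keep <- names(frac)[!is.na(frac) & tot > 0 & frac >= min_fraction]
  out <- receipts[receipts$ticket_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(
    removed_below_fraction = sum(tot > 0 & frac < min_fraction),
    removed_zero_total = length(zero))
  out
}

#' Trip-length cap from inter-receipt durations
#'
#' The 75th percentile (nearest-rank) of per-vessel durations between
#' consecutive landings receipts, in days. This caps how far back in time
#' pings are attributed to a receipt, guarding against long idle or transit
#' periods between landings. When no inter-receipt durations are computable
#' the configured override (default 16 days, the value used for the U.S.
#' West Coast albacore troll fleet) is returned with a warning.
#'
#' @param receipts long-format receipt data.frame (see
#'   \code{\link{filter_albacore_receipts}}).
#' @param probs percentile of the trip-length distribution, default 0.75.
#' @param override fallback cap in days, default 16.
#' @return trip cap in days.
#' @export
compute_trip_cap <- function(receipts, probs = 0.75, override = 16) {
  if (is.null(receipts) || nrow(receipts) == 0L) {
    warning("compute_trip_cap: no receipts; using override of ", override, " days")
    return(override)
  }
  key <- unique(receipts[, c("ticket_id", "vessel_id", "timestamp")])
  durs <- unlist(lapply(split(key$timestamp, key$vessel_id), function(ts) {
    ts <- sort(unique(ts))
    if (length(ts) < 2L) return(numeric(0))
    as.numeric(diff(ts), units = "days")
  }), use.names = FALSE)
  if (length(durs) == 0L) {
    warning("compute_trip_cap: no inter-receipt durations; using override of ",
            override, " days")
    return(override)
  }
  nearest_rank_quantile(durs, probs)
}

#' Assign VMS pings to landings receipts
#'
#' For each receipt of a vessel, pings with timestamps in the half-open
#' window (max(previous receipt time, receipt time - trip cap), receipt
#' time] are attributed to that receipt. Each ping is assigned to at most
#' one receipt. When two receipts of one vessel share a timestamp, the
#' later ticket (in ticket-id order) wins pings at the shared boundary
#' instant.
#'
#' @param pings ping data.frame with at least \code{timestamp} and
#'   \code{vessel_id}; sorted internally.
#' @param receipts long-format receipt data.frame.
#' @param trip_cap cap in days (see \code{\link{compute_trip_cap}}).
#' @return \code{pings} with an added \code{ticket_id} column (NA when the
#'   ping falls in no receipt's window).
#' @export
assign_pings_to_receipts <- function(pings, receipts, trip_cap) {
  stopifnot(is.numeric(trip_cap), trip_cap > 0)
  key <- unique(receipts[, c("ticket_id", "vessel_id", "timestamp")])
  pings$ticket_id <- NA_character_
  for (v in unique(key$vessel_id)) {
    rk <- key[key$vessel_id == v, , drop = FALSE]
    rk <- rk[order(rk$timestamp, rk$ticket_id), , drop = FALSE]
    rt <- as.numeric(rk$timestamp)
    # previous *distinct* receipt time per receipt (-Inf for the first)
    prev <- vapply(seq_along(rt), function(i) {
      earlier <- rt[rt < rt[i]]
      if (length(earlier)) max(earlier) else -Inf
    }, numeric(1))
    pi <- which(pings$vessel_id == v)
    pt <- as.numeric(pings$timestamp[pi])
    # first receipt with rt >= ping time
    idx <- findInterval(pt, rt, left.open = TRUE) + 1L
    ok <- idx <= length(rt)
    # at an exact shared timestamp, the later ticket wins the boundary ping
    idx2 <- idx
    at_bound <- ok & rt[pmin(idx, length(rt))] == pt
    if (any(at_bound)) {
      last_eq <- vapply(idx[at_bound], function(i) max(which(rt == rt[i])),
                        integer(1))
      idx2[at_bound] <- last_eq
    }
    lower <- pmax(prev[pmin(idx2, length(rt))],
                  rt[pmin(idx2, length(rt))] - trip_cap * 86400)
    ok <- ok & pt > lower
    pings$ticket_id[pi[ok]] <- rk$ticket_id[idx2[ok]]
  }
  pings
}

#' Fishing-activity filters
#'
#' Keeps pings plausibly recording fishing: quality-flagged pings are
#' removed, only at-sea pings are kept, pings with a time-forward gap
#' greater than \code{max_gap} minutes (one missed hourly ping) are removed
#' as signal breaks, and only pings slower than \code{max_speed} knots
#' (strict) are classified as fishing. The filters have intersection
#' semantics, so their order does not change the result, and the operation
#' is idempotent. Records missing a required field are rejected and counted.
#'
#' @param pings ping data.frame with \code{event_type}, \code{gis_flag},
#'   \code{time_forward}, \code{speed}.
#' @param max_gap maximum time-forward, minutes (boundary retained).
#' @param max_speed fishing speed threshold, knots (boundary removed).
#' @return filtered pings with attribute \code{filter_report} giving counts
#'   removed per rule (a record failing several rules is counted in each).
#' @export
apply_fishing_filters <- function(pings, max_gap = 121, max_speed = 3.74) {
  need <- c("event_type", "gis_flag", "time_forward", "speed")
  stopifnot(all(need %in% names(pings)))
  bad <- !stats::complete.cases(pings[, need])
  ok_flag <- !bad & !pings$gis_flag
  ok_sea <- !bad & pings$event_type == "at_sea"
  ok_gap <- !bad & pings$time_forward <= max_gap
  ok_speed <- !bad & pings$speed < max_speed
  keep <- ok_flag & ok_sea & ok_gap & ok_speed
  out <- pings[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- c(
    missing_fields = sum(bad),
    gis_flagged = sum(!bad & !ok_flag),
    not_at_sea = sum(!bad & !ok_sea),
    gap_exceeded = sum(!bad & !ok_gap),
    speed_exceeded = sum(!bad & !ok_speed),
    retained = sum(keep))
  out
}

#' Allocate landed albacore pounds to assigned pings
#'
#' The albacore pounds of each receipt are distributed over its assigned
#' fishing pings proportionally to each ping's time-forward duration:
#' a 1,000-lb receipt over pings with time-forward 30 and 70 minutes yields
#' 300 and 700 lbs. Allocation conserves the receipt total exactly (up to
#' floating-point tolerance). Receipts whose assigned pings have zero total
#' time-forward cannot be allocated and are dropped with a warning.
#'
#' @param pings ping data.frame carrying \code{ticket_id} and
#'   \code{time_forward} (only rows with non-missing \code{ticket_id} are
#'   allocated).
#' @param receipts long-format receipt data.frame.
#' @param target_species species whose pounds are allocated.
#' @return pings restricted to assigned rows, with an
#'   \code{allocated_pounds} column.
#' @export
allocate_pounds <- function(pings, receipts, target_species = "albacore") {
  stopifnot("ticket_id" %in% names(pings))
  p <- pings[!is.na(pings$ticket_id), , drop = FALSE]
  if (any(p$time_forward < 0)) stop("allocate_pounds: negative time_forward")
  alb <- receipts[receipts$species == target_species, , drop = FALSE]
  lbs <- tapply(alb$pounds, alb$ticket_id, sum)
  tot_tf <- tapply(p$time_forward, p$ticket_id, sum)
  zero <- names(tot_tf)[tot_tf == 0]
  if (length(zero)) {
    warning("allocate_pounds: ", length(zero),
            " receipt(s) with zero total time-forward dropped from allocation")
    p <- p[!(p$ticket_id %in% zero), , drop = FALSE]
  }
  share <- p$time_forward / tot_tf[p$ticket_id]
  p$allocated_pounds <- as.numeric(lbs[p$ticket_id] * share)
  p <- p[!is.na(p$allocated_pounds), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Full VMS-to-landings linkage pipeline
#'
#' Runs the linkage stages in order: filter receipts to albacore-dominated
#' tickets, restrict pings to vessels holding at least one qualifying
#' receipt, derive (or accept) the trip-length cap, assign pings to
#' receipts, apply the fishing-activity filters, and allocate each
#' receipt's albacore pounds over its fishing pings.
#'
#' @param pings ping data.frame (see \code{\link{gen_scenario}} for schema).
#' @param receipts long-format receipt data.frame.
#' @param min_fraction albacore-share threshold for receipts.
#' @param trip_cap \code{"auto"} to compute the 75th-percentile cap from
#'   the receipts, or a number of days.
#' @param max_gap,max_speed fishing-filter thresholds (minutes, knots).
#' @return data.frame of class \code{linked_pings}: fishing-classified
#'   pings with \code{ticket_id} and \code{allocated_pounds}, plus
#'   attributes \code{trip_cap} and \code{filter_report}.
#' @export
link_vms_landings <- function(pings, receipts, min_fraction = 0.9,
                              trip_cap = "auto", max_gap = 121,
                              max_speed = 3.74) {
  rec <- filter_albacore_receipts(receipts, min_fraction)
  pings <- pings[pings$vessel_id %in% unique(rec$vessel_id), , drop = FALSE]
  cap <- if (identical(trip_cap, "auto")) compute_trip_cap(rec) else trip_cap
  assigned <- assign_pings_to_receipts(pings, rec, cap)
  fishing <- apply_fishing_filters(assigned, max_gap = max_gap,
                                   max_speed = max_speed)
  linked <- allocate_pounds(fishing, rec)
  attr(linked, "trip_cap") <- cap
  attr(linked, "filter_report") <- attr(fishing, "filter_report")
  class(linked) <- c("linked_pings", class(linked))
  linked
}

#' @export
print.linked_pings <- function(x, ...) {
  cat(sprintf("<linked_pings> %d fishing pings, %d receipts, %d vessels\n",
              nrow(x), length(unique(x$ticket_id)),
              length(unique(x$vessel_id))))
  cat(sprintf("  total allocated: %.0f lbs; trip cap: %.1f days\n",
              sum(x$allocated_pounds), attr(x, "trip_cap")))
  invisible(x)
}
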