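test_that("receipt filter keeps albacore-dominated tickets, boundary inclusive", {
  rec <- rbind(make_receipt("2015-08-01", "T1", albacore = 950, other = 50),
               make_receipt("2015-08-02", "T2", albacore = 890, other = 110),
               make_receipt("2015-08-03", "T3", albacore = 900, other = 100),
               make_receipt("2015-08-04", "T4", albacore = 0, other = 0))
  out <- filter_albacore_receipts(rec)
  kept <- unique(out$ticket_id)
  expect_setequal(kept, c("T1", "T3"))
  log <- attr(out, "filter_log")
  expect_equal(unname(log["removed_below_fraction"]), 1)
  expect_equal(unname(log["removed_zero_total"]), 1)
})

test_that("trip cap is the nearest-rank 75th percentile of trip lengths", {
  # one vessel, receipts spaced 2, 4, 6 and 20 days apart
  ts <- as.POSIXct("2015-07-01", tz = "UTC") + cumsum(c(0, 2, 4, 6, 20)) * 86400
  rec <- do.call(rbind, lapply(seq_along(ts), function(i)
    make_receipt(ts[i], paste0("T", i))))
  expect_equal(compute_trip_cap(rec), 6)

  # constant spacing
  ts7 <- as.POSIXct("2015-07-01", tz = "UTC") + (0:4) * 7 * 86400
  rec7 <- do.call(rbind, lapply(seq_along(ts7), function(i)
    make_receipt(ts7[i], paste0("S", i))))
  expect_equal(compute_trip_cap(rec7), 7)

  # no computable trip lengths: fall back to the 16-day override
  expect_warning(cap <- compute_trip_cap(make_receipt("2015-07-01", "T1")),
                 "override")
  expect_equal(cap, 16)
})

test_that("ping assignment uses the (prev receipt, receipt] window capped in days", {
  day0 <- as.POSIXct("2015-01-01", tz = "UTC")
  d <- function(x) day0 + x * 86400
  pings <- do.call(rbind, lapply(seq(80, 100, by = 1), function(x) make_ping(d(x))))
  rec <- rbind(make_receipt(d(95), "A"), make_receipt(d(100), "B"))
  out <- assign_pings_to_receipts(pings, rec, trip_cap = 16)
  # receipt A at day 95, no predecessor within cap: (95-16, 95] = (79, 95]
  expect_setequal(out$ticket_id[out$timestamp > d(79) & out$timestamp <= d(95)], "A")
  # receipt B at day 100, previous receipt day 95: (95, 100]
  expect_setequal(out$ticket_id[out$timestamp > d(95) & out$timestamp <= d(100)], "B")

  # far-apart receipts: cap binds, (84, 100]
  rec2 <- rbind(make_receipt(d(50), "A"), make_receipt(d(100), "B"))
  out2 <- assign_pings_to_receipts(pings, rec2, trip_cap = 16)
  expect_true(all(is.na(out2$ticket_id[out2$timestamp <= d(84)])))
  expect_setequal(out2$ticket_id[out2$timestamp > d(84)], "B")

  # single receipt: (t_R - 16 d, t_R]
  out3 <- assign_pings_to_receipts(pings, make_receipt(d(100), "B"), trip_cap = 16)
  expect_true(all(is.na(out3$ticket_id[out3$timestamp <= d(84)])))
  expect_setequal(out3$ticket_id[out3$timestamp > d(84)], "B")
})

test_that("assignment boundaries: boundary ping goes to the receipt; later ticket wins ties", {
  day0 <- as.POSIXct("2015-07-01", tz = "UTC")
  d <- function(x) day0 + x * 86400
  pings <- rbind(make_ping(d(5)), make_ping(d(7)), make_ping(d(10)))
  rec <- rbind(make_receipt(d(5), "A"), make_receipt(d(10), "B"))
  out <- assign_pings_to_receipts(pings, rec, trip_cap = 16)
  expect_equal(out$ticket_id, c("A", "B", "B"))  # ping at t=5 belongs to A, not B

  # duplicate receipt timestamps: the later ticket takes the boundary
  # instant; earlier pings stay with the earlier ticket
  rec_dup <- rbind(make_receipt(d(10), "T1"), make_receipt(d(10), "T2"))
  out2 <- assign_pings_to_receipts(rbind(make_ping(d(10)), make_ping(d(9))),
                                   rec_dup, trip_cap = 16)
  expect_equal(out2$ticket_id, c("T2", "T1"))

  # no ping is ever assigned to two receipts (partition property) and every
  # assigned ping precedes or meets its receipt
  b <- small_bundle()
  rec_f <- filter_albacore_receipts(b$receipts)
  assigned <- assign_pings_to_receipts(b$pings, rec_f, trip_cap = 16)
  expect_equal(nrow(assigned), nrow(b$pings))  # one row, at most one ticket
  key <- unique(rec_f[, c("ticket_id", "timestamp")])
  rt <- setNames(key$timestamp, key$ticket_id)
  ok <- !is.na(assigned$ticket_id)
  expect_true(all(assigned$timestamp[ok] <= rt[assigned$ticket_id[ok]]))
})

test_that("fishing filters apply boundary conventions and are idempotent", {
  base <- make_ping("2015-08-01 12:00:00")
  pings <- rbind(
    make_ping("2015-08-01 01:00:00", time_forward = 121, speed = 3.0),  # keep
    make_ping("2015-08-01 02:00:00", time_forward = 122, speed = 3.0),  # gap
    make_ping("2015-08-01 03:00:00", speed = 3.74),                     # boundary speed
    make_ping("2015-08-01 04:00:00", speed = 3.73),                     # keep
    make_ping("2015-08-01 05:00:00", event_type = "in_port", speed = 1),
    make_ping("2015-08-01 06:00:00", event_type = "departing_port"),
    make_ping("2015-08-01 07:00:00", gis_flag = TRUE))
  out <- apply_fishing_filters(pings)
  expect_equal(format(out$timestamp, "%H"), c("01", "04"))
  rep <- attr(out, "filter_report")
  expect_equal(unname(rep["gap_exceeded"]), 1)
  expect_equal(unname(rep["speed_exceeded"]), 1)
  expect_equal(unname(rep["not_at_sea"]), 2)
  expect_equal(unname(rep["gis_flagged"]), 1)

  # idempotence and monotonicity
  again <- apply_fishing_filters(out)
  expect_equal(again, out, ignore_attr = TRUE)
  expect_lte(nrow(out), nrow(pings))

  # records with missing required fields are rejected and counted
  pings$speed[1] <- NA
  out2 <- apply_fishing_filters(pings)
  expect_equal(unname(attr(out2, "filter_report")["missing_fields"]), 1)
  expect_equal(nrow(out2), 1)
})

test_that("pound allocation is proportional to time-forward and conservative", {
  day0 <- as.POSIXct("2015-08-10", tz = "UTC")
  pings <- rbind(make_ping(day0 - 7200, time_forward = 30),
                 make_ping(day0 - 3600, time_forward = 70))
  pings$ticket_id <- "T1"
  rec <- make_receipt(day0, "T1", albacore = 1000)
  out <- allocate_pounds(pings, rec)
  expect_equal(out$allocated_pounds, c(300, 700))

  # single ping takes everything
  p1 <- make_ping(day0, time_forward = 45); p1$ticket_id <- "T1"
  expect_equal(allocate_pounds(p1, rec)$allocated_pounds, 1000)

  # three-way split
  p3 <- rbind(make_ping(day0 - 10800, time_forward = 10),
              make_ping(day0 - 7200, time_forward = 10),
              make_ping(day0 - 3600, time_forward = 20))
  p3$ticket_id <- "T1"
  rec500 <- make_receipt(day0, "T1", albacore = 500)
  expect_equal(allocate_pounds(p3, rec500)$allocated_pounds, c(125, 125, 250))

  # all-zero time-forward: receipt dropped with a warning
  pz <- rbind(make_ping(day0 - 7200, time_forward = 0),
              make_ping(day0 - 3600, time_forward = 0))
  pz$ticket_id <- "T1"
  expect_warning(outz <- allocate_pounds(pz, rec), "zero total time-forward")
  expect_equal(nrow(outz), 0)
})

test_that("allocation conserves receipt totals across the synthetic fleet", {
  linked <- small_linked()
  b <- small_bundle()
  rec <- filter_albacore_receipts(b$receipts)
  alb <- rec[rec$species == "albacore", ]
  expected <- setNames(alb$pounds, alb$ticket_id)
  got <- tapply(linked$allocated_pounds, linked$ticket_id, sum)
  expect_equal(as.numeric(got), unname(expected[names(got)]),
               tolerance = 1e-9)
})

test_that("fishing classification recovers ground truth on well-separated speeds", {
  b <- small_bundle()
  out <- apply_fishing_filters(b$pings)
  predicted <- paste(b$pings$vessel_id, b$pings$timestamp) %in%
    paste(out$vessel_id, out$timestamp)
  truth <- b$ping_truth
  precision <- sum(predicted & truth) / sum(predicted)
  recall <- sum(predicted & truth) / sum(truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
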