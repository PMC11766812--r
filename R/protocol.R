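## Pump/valve protocol model: the syringe pump feeds a distribution valve
## that multiplexes one flow line across the five channels with period T, so
## each channel sees the full rate Q0 for T followed by rest for (n-1) T.

#' Pump program
#'
#' @param Q0 base pumping rate, uL/min.
#' @param period valve switching period T, s.
#' @param n_ports number of multiplexed channels.
#' @param extraction_multiplier bead-extraction rate in units of Q0
#'   (`Qf = 6 Q0` by default).
#' @param extraction_volume suspension volume produced per channel at
#'   extraction, uL.
#' @param dead_volume buffer-line internal volume between valve and chip, uL;
#'   programmed volumes reach the channel only once the line is displaced.
#' @return object of class `pump_program`.
#' @export
pump_program <- function(Q0 = 50, period = 3, n_ports = 5,
                         extraction_multiplier = 6, extraction_volume = 300,
                         dead_volume = 350) {
  if (Q0 <= 0) .stopf("Q0 must be > 0")
  if (period <= 0) .stopf("period must be > 0")
  if (n_ports < 1) .stopf("n_ports must be >= 1")
  structure(list(Q0 = Q0, period = period, n_ports = n_ports,
                 extraction_multiplier = extraction_multiplier,
                 extraction_volume = extraction_volume,
                 dead_volume = dead_volume),
            class = "pump_program")
}

#' @export
print.pump_program <- function(x, ...) {
  cat(sprintf("<pump_program> Q0 = %g uL/min, T = %g s, %d ports, Qf = %g uL/min\n",
              x$Q0, x$period, x$n_ports, extraction_rate(x)))
  invisible(x)
}

#' Average per-channel flow rate under valve multiplexing
#'
#' Each channel flows at Q0 for one period and rests for `(n_ports - 1)`
#' periods, so the duty-cycle average is `Q0 / n_ports`.
#'
#' @param program a [pump_program()].
#' @return average rate, uL/min.
#' @export
average_channel_rate <- function(program) program$Q0 / program$n_ports

#' Bead-extraction flow rate
#'
#' @param program a [pump_program()].
#' @return `extraction_multiplier * Q0`, uL/min.
#' @export
extraction_rate <- function(program)
  program$extraction_multiplier * program$Q0

#' Protocol step table
#'
#' Builds a validated step table. `mode` is one of `infuse`, `withdraw`,
#' `withdraw-then-infuse`, `manual` (manual steps carry time but no pumped
#' flow).
#'
#' @param index,name,mode,volume_per_channel,duration parallel vectors: step
#'   number, label, pump mode, volume per channel (uL), duration (min).
#' @return data frame of class `protocol_steps`.
#' @export
protocol_steps <- function(index, name, mode, volume_per_channel, duration) {
  mode <- match.arg(mode, c("infuse", "withdraw", "withdraw-then-infuse",
                            "manual"), several.ok = TRUE)
  if (any(duration < 0)) .stopf("durations must be >= 0")
  if (any(volume_per_channel < 0)) .stopf("volumes must be >= 0")
  structure(data.frame(index = as.integer(index), name = name, mode = mode,
                       volume_per_channel = volume_per_channel,
                       duration = duration, stringsAsFactors = FALSE),
            class = c("protocol_steps", "data.frame"))
}

#' Default microfluidic assay protocol
#'
#' The twelve-step immunoassay schedule: filling, air priming, magnetic
#' functionalization, sample / detection-antibody / labeling incubations with
#' washes in between, bead extraction and cytometer quantification. Total
#' 151 min.
#'
#' @return a [protocol_steps()] table.
#' @export
default_protocol <- function() {
  protocol_steps(
    index = 1:12,
    name = c("Initial filling", "Air priming", "Magnetic functionalization",
             "Wash #1", "Sample incubation", "Wash #2", "Detection antibody",
             "Wash #3", "Fluorescence labeling", "Wash #4", "Bead extraction",
             "Quantification"),
    mode = c("manual", "withdraw", "withdraw", "infuse",
             "withdraw-then-infuse", "infuse", "withdraw-then-infuse",
             "infuse", "withdraw-then-infuse", "infuse",
             "withdraw-then-infuse", "manual"),
    volume_per_channel = c(1000, 50, 15, 300, 300, 300, 300, 300, 150, 300,
                           300, 0),
    duration = c(5, 3, 3, 10, 30, 10, 30, 10, 15, 10, 15, 10))
}

#' Total assay time
#'
#' @param steps a [protocol_steps()] table (default: the full assay).
#' @return total duration, min.
#' @export
total_assay_time <- function(steps = default_protocol()) {
  if (nrow(steps) == 0L) .stopf("step list is empty")
  if (any(steps$duration < 0)) .stopf("durations must be >= 0")
  sum(steps$duration)
}

#' Per-channel flow timeline
#'
#' Piecewise-constant per-channel flow profile of the valve multiplexing:
#' during each pumped step, channel c flows at Q0 for one period T then rests
#' for `(n_ports - 1) T`, channels taking turns. Manual steps contribute no
#' flow. Withdraw rates are signed negative; `withdraw-then-infuse` steps
#' spend half the step in each direction.
#'
#' @param steps a [protocol_steps()] table.
#' @param program a [pump_program()].
#' @return data frame of class `flow_timeline` with columns `t_start`,
#'   `t_end` (s from protocol start), `channel`, `rate` (signed uL/min),
#'   `step_index`.
#' @export
schedule_timeline <- function(steps = default_protocol(),
                              program = pump_program()) {
  Tn <- program$period; n <- program$n_ports
  out <- vector("list", nrow(steps))
  t0 <- 0
  for (s in seq_len(nrow(steps))) {
    dur_s <- steps$duration[s] * 60
    if (steps$mode[s] == "manual" || dur_s == 0) { t0 <- t0 + dur_s; next }
    sgn_for <- function(frac)                      # fraction through the step
      switch(steps$mode[s],
             infuse = 1, withdraw = -1,
             `withdraw-then-infuse` = if (frac < 0.5) -1 else 1)
    starts <- seq(0, dur_s - 1e-9, by = Tn)
    ch <- (seq_along(starts) - 1) %% n + 1
    ends <- pmin(starts + Tn, dur_s)
    sg <- vapply(starts / dur_s, sgn_for, numeric(1))
    out[[s]] <- data.frame(t_start = t0 + starts, t_end = t0 + ends,
                           channel = ch, rate = sg * program$Q0,
                           step_index = steps$index[s])
    t0 <- t0 + dur_s
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  structure(res, class = c("flow_timeline", "data.frame"))
}

#' Integrate delivered volume from a timeline
#'
#' Signed volume pumped through each channel (uL); the syringe balance is the
#' total across channels.
#'
#' @param timeline a [schedule_timeline()] result.
#' @return data frame with `channel`, `delivered_uL`.
#' @export
timeline_delivered_volume <- function(timeline) {
  vol <- tapply((timeline$t_end - timeline$t_start) / 60 * timeline$rate,
                timeline$channel, sum)
  data.frame(channel = as.integer(names(vol)), delivered_uL = as.numeric(vol),
             row.names = NULL)
}

#' Read / write protocol tables as CSV
#'
#' Columns `index, name, mode, volume_per_channel, duration` (volumes in uL,
#' durations in min).
#'
#' @param path file path.
#' @return for the reader, a [protocol_steps()] table.
#' @export
read_protocol_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "mode", "volume_per_channel", "duration")
  if (!all(need %in% names(df)))
    .stopf("protocol CSV must have columns %s", paste(need, collapse = ", "))
  protocol_steps(df$index, df$name, df$mode, df$volume_per_channel,
                 df$duration)
}

#' @rdname read_protocol_csv
#' @param steps a [protocol_steps()] table.
#' @export
write_protocol_csv <- function(steps, path) {
  utils::write.csv(as.data.frame(steps), path, row.names = FALSE)
  invisible(path)
}
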