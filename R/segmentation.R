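#' Detect screen-touch points
#'
#' Touches are local maxima of the raw screen-axis position that (i) exceed
#' the whole-recording mean plus `touch_height_sd` standard deviations of that
#' coordinate and (ii) are at least `touch_min_separation` frames from every
#' other retained touch. When two candidates fall closer than the minimum
#' separation the higher one wins (height is the touch signature), implemented
#' by greedy acceptance in decreasing height order.
#'
#' @param rec a [recording()].
#' @param cfg a [pipeline_config()].
#' @return integer vector of touch frame indices, increasing; empty (with a
#'   warning) when no candidate clears the height rule.
#' @export
detect_touches <- function(rec, cfg = pipeline_config()) {
  validate_recording(rec)
  p <- rec$position[, rec$screen_axis]
  cand <- local_maxima(p)
  thr <- mean(p) + cfg$touch_height_sd * stats::sd(p)
  cand <- cand[p[cand] >= thr]
  if (length(cand) == 0L) {
    warning("no touch points found (no position maximum above mean + ",
            cfg$touch_height_sd, " SD)", call. = FALSE)
    return(integer(0))
  }
  keep <- integer(0)
  for (i in cand[order(-p[cand], cand)]) {
    if (all(abs(i - keep) >= cfg$touch_min_separation)) keep <- c(keep, i)
  }
  sort(keep)
}

# frames at which the signed series v changes direction.  Runs of sign(v) are
# collapsed; a zero run resolves to its first frame.  A zero run whose
# flanking signs are equal (a pause without reversal) is not a change; zero
# runs at the series boundary count (motion onset / cessation), as does the
# boundary frame 1 when the series starts mid-rest.
direction_changes <- function(v) {
  r <- rle(as.integer(sign(v)))
  starts <- cumsum(c(1L, utils::head(r$lengths, -1L)))
  m <- length(r$values)
  if (m < 2L) return(integer(0))
  out <- integer(0)
  for (j in 2:m) {
    cur <- r$values[j]
    if (cur != 0L) {
      if (r$values[j - 1L] != 0L) out <- c(out, starts[j])       # direct flip
      if (j == 2L && r$values[1L] == 0L) out <- c(out, 1L)       # leading rest
    } else {
      prev <- r$values[j - 1L]
      nxt <- if (j < m) r$values[j + 1L] else NA_integer_
      if (is.na(nxt) || nxt != prev) out <- c(out, starts[j])
    }
  }
  sort(unique(out))
}

#' Select forward-and-backward motion cycles
#'
#' For each touch, a start point (before) and a stop point (after) are chosen
#' among frames where the screen-axis velocity changes direction, subject to:
#' at least `startstop_min_gap` frames from the touch (inclusive); screen-axis
#' displacement at most `displacement_fraction` of the maximum displacement in
#' the inter-touch segment (measured from the resting level by default, see
#' [pipeline_config()]); speed at most the reference mean speed. Among
#' qualifying candidates the one nearest the touch is taken. Touches with no
#' qualifying start or stop contribute no cycle. Boundary touches use the
#' recording edges as their outer segment limits.
#'
#' @param rec a [recording()].
#' @param speed the [speed_profile()] of `rec`.
#' @param touches integer vector from [detect_touches()].
#' @param cfg a [pipeline_config()].
#' @return an object of class `speakr_cycles`: data frame `cycles` with
#'   columns `start`, `touch`, `stop`, `duration`, `max_speed`; plus
#'   `n_cycles`, `mean_cycle_length`, `sample_rate`, and a `dropped` log.
#' @export
select_cycles <- function(rec, speed, touches, cfg = pipeline_config()) {
  n <- nrow(rec$position)
  p <- rec$position[, rec$screen_axis]
  vperp <- speed$velocity[, rec$screen_axis]
  cand <- direction_changes(vperp)
  mean_speed_rec <- mean(speed$speed)
  dropped <- character(0)
  rows <- list()
  if (length(touches) >= 2L) {
    for (m in seq_along(touches)) {
      tc <- touches[m]
      lo <- if (m > 1L) touches[m - 1L] else 1L
      hi <- if (m < length(touches)) touches[m + 1L] else n

      qualifying <- function(seg_lo, seg_hi) {
        cc <- cand[cand >= seg_lo & cand <= seg_hi]
        if (length(cc) == 0L) return(integer(0))
        seg <- seg_lo:seg_hi
        ref_speed <- if (cfg$speed_reference == "segment") mean(speed$speed[seg]) else mean_speed_rec
        if (cfg$displacement_reference == "rest") {
          base <- min(p[seg])
          maxdisp <- p[tc] - base
          disp <- p[cc] - base
        } else {
          maxdisp <- max(abs(p[tc] - p[seg]))
          disp <- abs(p[tc] - p[cc])
        }
        ok <- abs(cc - tc) >= cfg$startstop_min_gap &
          speed$speed[cc] <= ref_speed &
          (maxdisp <= 0 | disp <= cfg$displacement_fraction * maxdisp)
        cc[ok]
      }

      qs <- qualifying(lo, tc)
      qs <- qs[qs <= tc - cfg$startstop_min_gap]
      qe <- qualifying(tc, hi)
      qe <- qe[qe >= tc + cfg$startstop_min_gap]
      if (length(qs) == 0L || length(qe) == 0L) {
        dropped <- c(dropped, sprintf(
          "touch %d (frame %d): no qualifying %s point", m, tc,
          if (length(qs) == 0L) "start" else "stop"))
        next
      }
      rows[[length(rows) + 1L]] <- c(start = max(qs), touch = tc, stop = min(qe))
    }
  }
  cyc <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    data.frame(start = integer(0), touch = integer(0), stop = integer(0))
  # enforce non-overlap (interiors disjoint); truncate the earlier stop if needed
  if (nrow(cyc) > 1L) for (i in seq_len(nrow(cyc) - 1L)) {
    if (cyc$stop[i] > cyc$start[i + 1L]) {
      dropped <- c(dropped, sprintf("cycle %d stop truncated from %d to %d (overlap)",
                                    i, cyc$stop[i], cyc$start[i + 1L]))
      cyc$stop[i] <- cyc$start[i + 1L]
    }
  }
  for (msg in dropped) speakr_log(msg, verbose_only = TRUE)
  cycle_set(cyc, speed, dropped = dropped)
}

#' Construct a cycle set
#'
#' @param cycles data frame with integer columns `start`, `touch`, `stop`.
#' @param speed the associated `speakr_speed` (used for per-cycle max speed).
#' @param dropped character log of rejected candidates.
#' @return an object of class `speakr_cycles`.
#' @export
cycle_set <- function(cycles, speed, dropped = character(0)) {
  cyc <- as.data.frame(cycles)[, c("start", "touch", "stop")]
  if (nrow(cyc)) {
    stopifnot(all(cyc$start < cyc$touch), all(cyc$touch < cyc$stop))
    if (nrow(cyc) > 1L) stopifnot(all(diff(cyc$start) > 0),
                                  all(utils::head(cyc$stop, -1) <= utils::tail(cyc$start, -1)))
    cyc$duration <- cyc$stop - cyc$start + 1L
    cyc$max_speed <- vapply(seq_len(nrow(cyc)),
                            function(i) max(speed$speed[cyc$start[i]:cyc$stop[i]]),
                            numeric(1))
  } else {
    cyc$duration <- integer(0)
    cyc$max_speed <- numeric(0)
  }
  structure(list(cycles = cyc, n_cycles = nrow(cyc),
                 mean_cycle_length = if (nrow(cyc)) mean(cyc$duration) else NA_real_,
                 sample_rate = speed$sample_rate, dropped = dropped),
            class = "speakr_cycles")
}

#' @export
print.speakr_cycles <- function(x, ...) {
  cat(sprintf("<speakr_cycles> %d cycles, mean length %.1f frames\n",
              x$n_cycles, x$mean_cycle_length))
  invisible(x)
}

#' Remove outlier cycles
#'
#' Drops cycles longer than `cycle_max_duration` frames or with maximum speed
#' below `cycle_min_maxspeed` m/s (both thresholds inclusive on the kept
#' side). Idempotent.
#'
#' @param cs a `speakr_cycles` from [select_cycles()].
#' @param speed the associated `speakr_speed`.
#' @param cfg a [pipeline_config()].
#' @return a `speakr_cycles` containing only compliant cycles.
#' @export
remove_outlier_cycles <- function(cs, speed, cfg = pipeline_config()) {
  cyc <- cs$cycles
  bad <- cyc$duration > cfg$cycle_max_duration | cyc$max_speed < cfg$cycle_min_maxspeed
  if (any(bad))
    speakr_log(sprintf("removed %d outlier cycle(s): %d over %d frames, %d under %.2g m/s",
                       sum(bad), sum(cyc$duration > cfg$cycle_max_duration),
                       cfg$cycle_max_duration,
                       sum(cyc$max_speed < cfg$cycle_min_maxspeed),
                       cfg$cycle_min_maxspeed))
  cycle_set(cyc[!bad, , drop = FALSE], speed,
            dropped = c(cs$dropped,
                        sprintf("outlier cycle removed at touch frame %d", cyc$touch[bad])))
}

#' Per-cycle summary table
#'
#' @param cs a `speakr_cycles`.
#' @return data frame with `cycle_index`, `start`, `touch`, `stop`,
#'   `duration_frames`, `max_speed`.
#' @export
cycle_table <- function(cs) {
  data.frame(cycle_index = seq_len(cs$n_cycles),
             start = cs$cycles$start, touch = cs$cycles$touch,
             stop = cs$cycles$stop, duration_frames = cs$cycles$duration,
             max_speed = cs$cycles$max_speed)
}
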