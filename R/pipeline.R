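# Signal pipeline: raw multi-channel resistance traces -> segmented per-cell,
# per-zone pulses with features.

#' Analysis-pipeline control parameters
#'
#' Collects every tunable of the trace-processing and fitting stages with its
#' default. Defaults assume 10 kHz sampling and pulse content below ~130 Hz.
#'
#' @param cutoff Low-pass cutoff, Hz (zero-phase Butterworth, order
#'   `filter_order`).
#' @param filter_order Butterworth order.
#' @param median_window_s Moving-median window, s. The default (0.3 ms,
#'   i.e. the minimal 3-sample window at 10 kHz) rejects isolated spikes
#'   while leaving the harmonic-rich in-pulse waveform essentially
#'   undistorted; wider windows flatten oscillation extrema and bias the
#'   fitted moduli at the higher strain frequencies.
#' @param baseline_block_s Block length for the robust baseline tracker, s.
#' @param baseline_quantile Quantile used by the rough (first-pass)
#'   baseline (block-wise, smoothed across blocks). The default median is
#'   robust to pulses of either sign; pulses occupy well under half of any
#'   smoothing window at the design throughput.
#' @param mask_k Pulse-mask threshold in robust standard deviations.
#' @param mask_floor Relative floor of the pulse-mask threshold (fraction of
#'   the baseline level), so near-noiseless traces mask only genuine pulses.
#' @param mask_dilate_s Dilation applied to the pulse mask, s.
#' @param threshold_mad Event-detection threshold in multiples of the MAD of
#'   the normalized trace.
#' @param threshold_floor Absolute lower bound of the detection threshold
#'   (relative resistance units), used when the trace is noise-free.
#' @param min_duration_s Minimum pulse duration, s.
#' @param gap_close_s Sub-threshold gaps shorter than this inside a pulse
#'   are bridged, s. Must exceed the longest sub-threshold excursion within
#'   a pulse (about half the slowest strain period) and stay far below the
#'   inter-cell spacing.
#' @param max_gap_s Maximum allowed gap between consecutive channels of one
#'   cell during cross-channel matching, s.
#' @param edge_guard_s Samples within this distance of a detected pulse edge
#'   are excluded from plateau means and stress fits (filter transients), s.
#' @param refine Logical; refine each zone pulse's entry time and transit
#'   time by minimizing the rheological fit residual (recommended - edge
#'   timing from threshold crossings alone is not phase-accurate).
#' @param refine_t0_s,refine_T_s Search half-widths for the refinement, s.
#' @param partition_scale,partition_mode Pressure-partition model settings
#'   (must match the physical device / simulator).
#' @param detection_gpp Loss-modulus detection threshold, Pa: a cell with a
#'   fitted G'' below this in at least one zone is flagged `below_detection`.
#' @return A list of class `nps_control`.
#' @export
nps_control <- function(cutoff = 2000, filter_order = 4,
                        median_window_s = 3e-4,
                        baseline_block_s = 0.5, baseline_quantile = 0.5,
                        mask_k = 4, mask_floor = 5e-5, mask_dilate_s = 0.005,
                        threshold_mad = 5, threshold_floor = 1e-4,
                        min_duration_s = 0.005, gap_close_s = 0.05,
                        max_gap_s = 0.5, edge_guard_s = 0.005,
                        refine = TRUE, refine_t0_s = 0.002,
                        refine_T_s = 0.004,
                        partition_scale = 1,
                        partition_mode = c("time-resolved", "constant"),
                        detection_gpp = 0.1) {
  structure(list(cutoff = cutoff, filter_order = filter_order,
    median_window_s = median_window_s, baseline_block_s = baseline_block_s,
    baseline_quantile = baseline_quantile, mask_k = mask_k,
    mask_floor = mask_floor, mask_dilate_s = mask_dilate_s, threshold_mad = threshold_mad,
    threshold_floor = threshold_floor, min_duration_s = min_duration_s,
    gap_close_s = gap_close_s, max_gap_s = max_gap_s,
    edge_guard_s = edge_guard_s, refine = refine,
    refine_t0_s = refine_t0_s, refine_T_s = refine_T_s,
    partition_scale = partition_scale,
    partition_mode = match.arg(partition_mode),
    detection_gpp = detection_gpp), class = "nps_control")
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, so pulse timing is
#' not shifted and the DC gain is exactly one.
#'
#' @param x Numeric vector (one channel).
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order Butterworth order.
#' @return Filtered vector of the same length.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 2000, order = 4) {
  if (cutoff <= 0 || cutoff >= sample_rate / 2) {
    abort("`cutoff` must lie strictly between 0 and the Nyquist frequency.",
      class = "nps_config_error")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  # odd-reflection padding suppresses startup/teardown transients
  n <- length(x)
  p <- min(n - 1, 10L * as.integer(ceiling(sample_rate / cutoff)) + 50L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

#' Moving-median despiking
#'
#' Running median with an odd window; removes isolated spikes shorter than
#' half the window while preserving steps and monotone segments.
#'
#' @param x Numeric vector.
#' @param window Odd integer window length (samples), at least 3.
#' @return Despiked vector.
#' @export
moving_median <- function(x, window) {
  if (window < 3 || window %% 2 == 0) {
    abort("`window` must be an odd integer >= 3.", class = "nps_config_error")
  }
  if (window > length(x)) {
    abort("`window` is longer than the trace.", class = "nps_config_error")
  }
  as.numeric(runmed(x, window, endrule = "median"))
}

#' Baseline estimation and normalization of one channel
#'
#' Two-pass robust baseline tracker. A first pass takes a block-wise
#' quantile (by default the median, smoothed across neighbouring blocks),
#' which tracks slow drift while ignoring pulses that occupy a minority of
#' each smoothing window. Samples deviating from this rough baseline in
#' either direction by more than `mask_k` robust standard deviations are
#' masked (with dilation) - pulses raise the resistance on average, but
#' large oscillatory responses can swing below baseline within a pulse - and
#' the final baseline interpolates the block medians of the unmasked
#' samples, anchored at their median positions, so it is unbiased under
#' linear drift and bridges pulses smoothly.
#'
#' @param x Numeric vector (one resistance channel, ohm).
#' @param sample_rate Sampling rate, Hz.
#' @param block_s Block length, s; the trace must span at least two blocks.
#' @param q Rough-pass quantile.
#' @param mask_k Pulse-mask threshold (robust SDs).
#' @param mask_floor Relative floor of the mask threshold (fraction of the
#'   baseline level), for near-noiseless traces.
#' @param mask_dilate_s Mask dilation, s.
#' @return A list with `dR_over_R` (normalized series) and `baseline` (ohm).
#' @export
baseline_normalize <- function(x, sample_rate, block_s = 0.5, q = 0.5,
                               mask_k = 4, mask_floor = 5e-5,
                               mask_dilate_s = 0.005) {
  n <- length(x)
  if (median(abs(x)) == 0) {
    abort("Degenerate baseline: channel is identically zero.",
      class = "nps_baseline_error")
  }
  block <- max(16L, as.integer(round(block_s * sample_rate)))
  nb <- n %/% block
  if (nb < 2) {
    abort("Trace shorter than the baseline window.", class = "nps_baseline_error")
  }
  bi <- pmin((seq_len(n) - 1L) %/% block + 1L, nb)
  centers <- (seq_len(nb) - 0.5) * block
  idx <- seq_len(n)

  xs <- split(x, bi)
  bq <- vapply(xs, quantile, numeric(1), probs = q, names = FALSE, type = 7)
  k <- min(9L, if (nb %% 2 == 1L) nb else nb - 1L)
  rough_b <- if (k >= 3) as.numeric(runmed(bq, k, endrule = "median")) else bq
  rough <- approx(centers, rough_b, xout = idx, rule = 2)$y

  resid <- x - rough
  s <- mad(resid)
  thr <- max(mask_k * s, mask_floor * median(abs(x)))
  mask <- abs(resid) > thr
  d <- as.integer(round(mask_dilate_s * sample_rate))
  if (d > 0 && any(mask)) {
    cs <- cumsum(as.integer(mask))
    lo <- pmax(idx - d, 1L); hi <- pmin(idx + d, n)
    mask <- (cs[hi] - cs[lo] + as.integer(mask[lo])) > 0L
  }

  # anchor each block's median at the median position of its unmasked
  # samples, not the block centre: during a pulse the unmasked samples sit at
  # the block edges and a centre anchor would bias the baseline under drift
  ms <- split(mask, bi)
  is <- split(idx, bi)
  stat <- vapply(seq_len(nb), function(b) {
    ok_b <- !ms[[b]]
    if (sum(ok_b) < 0.1 * block) c(NA_real_, NA_real_)
    else c(median(xs[[b]][ok_b]), median(is[[b]][ok_b]))
  }, numeric(2))
  vals <- stat[1, ]; pos <- stat[2, ]
  ok <- !is.na(vals)
  baseline <- if (sum(ok) < 4) {
    approx(centers, rough_b, xout = idx, rule = 2)$y
  } else {
    # natural cubic spline: linear interpolation across a masked pulse leaves
    # an O(gap^2) error under curved drift, which is the accuracy floor of
    # the whole stress reconstruction
    stats::spline(pos[ok], vals[ok], xout = idx, method = "natural")$y
  }
  if (any(baseline <= 0)) {
    abort("Degenerate baseline: non-positive baseline estimate.",
      class = "nps_baseline_error")
  }
  list(dR_over_R = (x - baseline) / baseline, baseline = baseline)
}

# filter + despike + normalize every channel of a trace tibble
.normalize_trace <- function(trace, geometry, control) {
  sr <- geometry$sample_rate
  chans <- setdiff(names(trace), "t")
  win <- as.integer(round(control$median_window_s * sr))
  if (win %% 2 == 0) win <- win + 1L
  win <- max(win, 3L)
  norm <- trace["t"]
  for (ch in chans) {
    y <- lowpass_filter(trace[[ch]], sr, control$cutoff, control$filter_order)
    y <- moving_median(y, win)
    norm[[ch]] <- baseline_normalize(y, sr, control$baseline_block_s,
      control$baseline_quantile, control$mask_k, control$mask_floor,
      control$mask_dilate_s)$dR_over_R
  }
  norm
}

# threshold one normalized channel into pulse runs
.channel_runs <- function(drr, t, sr, control) {
  thr <- max(control$threshold_mad * mad(drr), control$threshold_floor)
  mask <- drr > thr
  r <- rle(mask)
  # bridge short sub-threshold gaps between pulses
  gap <- as.integer(round(control$gap_close_s * sr))
  if (length(r$lengths) > 2) {
    inner <- which(!r$values & r$lengths < gap)
    inner <- inner[inner > 1 & inner < length(r$values)]
    if (length(inner)) {
      r$values[inner] <- TRUE
      r <- rle(rep.int(r$values, r$lengths))
    }
  }
  min_len <- max(2L, as.integer(round(control$min_duration_s * sr)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(i0 = starts[keep], i1 = ends[keep],
    t_start = t[starts[keep]], t_end = t[ends[keep]])
}

# guarded interior of a run
.guard_idx <- function(i0, i1, sr, guard_s) {
  gsamp <- as.integer(round(guard_s * sr))
  lo <- i0 + gsamp; hi <- i1 - gsamp
  if (hi - lo < 8) { # fall back to the middle half for very short pulses
    span <- i1 - i0
    lo <- i0 + span %/% 4; hi <- i1 - span %/% 4
  }
  lo:hi
}

#' Detect and match cell-transit events across channels
#'
#' Thresholds each normalized channel at `threshold_mad` MADs (with a floor
#' for noise-free traces), bridges brief sub-threshold gaps, discards runs
#' shorter than the minimum duration, and then matches pulses across channels
#' by causal ordering: each sizing-pore pulse opens a cell, and its zone
#' pulses must follow in zone order within `max_gap_s` of the previous
#' channel. Cells whose device occupancy overlaps another cell's are flagged
#' `coincident`; cells missing a zone pulse are flagged `incomplete`. Both
#' are excluded from rheological fitting downstream.
#'
#' @param trace Raw trace tibble (`t` plus one resistance column per
#'   channel, pore first then zones in order).
#' @param geometry The device [device_geometry()]; channel count must match.
#' @param control An [nps_control()].
#' @return A list of class `nps_events`: `cells` (per-cell pore features and
#'   flags), `pulses` (per cell x zone, with an in-pulse sample tibble in the
#'   `samples` list-column), and `unmatched` (orphan pulses).
#' @export
detect_events <- function(trace, geometry, control = nps_control()) {
  stopifnot(inherits(geometry, "nps_geometry"))
  nz <- nrow(geometry$zones)
  chans <- setdiff(names(trace), "t")
  if (length(chans) != nz + 1) {
    abort(sprintf("Trace has %d signal channels but geometry expects %d (pore + %d zones).",
      length(chans), nz + 1, nz), class = "nps_config_error")
  }
  sr <- geometry$sample_rate
  norm <- .normalize_trace(trace, geometry, control)
  tt <- norm$t

  runs <- lapply(chans, function(ch) .channel_runs(norm[[ch]], tt, sr, control))
  names(runs) <- chans

  pore_runs <- runs[[1]]
  used <- lapply(runs, function(r) rep(FALSE, nrow(r)))

  cells <- list(); pulses <- list()
  cid <- 0L
  for (k in seq_len(nrow(pore_runs))) {
    cid <- cid + 1L
    pr <- pore_runs[k, ]
    gi <- .guard_idx(pr$i0, pr$i1, sr, control$edge_guard_s)
    cell <- tibble::tibble(cell_id = cid,
      pore_start = pr$t_start, pore_end = pr$t_end,
      pore_mean_drr = mean(norm[[chans[1]]][gi]),
      complete = TRUE, coincident = FALSE)
    prev_end <- pr$t_end
    zrows <- list()
    for (z in seq_len(nz)) {
      ch <- chans[z + 1]
      cand <- which(!used[[ch]] &
        runs[[ch]]$t_start > prev_end - 2 / sr &
        runs[[ch]]$t_start <= prev_end + control$max_gap_s)
      if (!length(cand)) { cell$complete <- FALSE; break }
      j <- cand[1]
      used[[ch]][j] <- TRUE
      zr <- runs[[ch]][j, ]
      smp <- tibble::tibble(t = tt[zr$i0:zr$i1], drr = norm[[ch]][zr$i0:zr$i1])
      gz <- .guard_idx(zr$i0, zr$i1, sr, control$edge_guard_s)
      zrows[[z]] <- tibble::tibble(cell_id = cid, zone = z,
        t_start = zr$t_start, t_end = zr$t_end,
        n_samples = zr$i1 - zr$i0 + 1L,
        mean_drr = mean(norm[[ch]][gz]),
        samples = list(smp))
      prev_end <- zr$t_end
    }
    used[[1]][k] <- TRUE
    cells[[cid]] <- cell
    if (length(zrows)) pulses[[cid]] <- dplyr::bind_rows(zrows)
  }
  cells <- dplyr::bind_rows(cells)
  pulses <- dplyr::bind_rows(pulses)

  # coincidence: overlapping device occupancy between consecutive cells
  if (nrow(cells) > 1) {
    occ_end <- vapply(cells$cell_id, function(id) {
      pe <- pulses$t_end[pulses$cell_id == id]
      if (length(pe)) max(pe) else cells$pore_end[cells$cell_id == id]
    }, numeric(1))
    for (i in seq_len(nrow(cells) - 1)) {
      if (occ_end[i] > cells$pore_start[i + 1]) {
        cells$coincident[c(i, i + 1)] <- TRUE
      }
    }
  }

  unmatched <- purrr::imap_dfr(runs, function(r, ch) {
    if (all(used[[ch]])) return(NULL)
    dplyr::mutate(r[!used[[ch]], c("t_start", "t_end")], channel = ch,
      .before = 1)
  })

  structure(list(cells = cells, pulses = pulses, unmatched = unmatched,
    n_channels = nz + 1), class = "nps_events")
}

#' @export
print.nps_events <- function(x, ...) {
  cat(sprintf("<nps_events> %d cells (%d complete, %d coincident), %d orphan pulses\n",
    nrow(x$cells), sum(x$cells$complete), sum(x$cells$coincident),
    if (is.null(x$unmatched)) 0L else nrow(x$unmatched)))
  invisible(x)
}

#' Per-zone pulse features
#'
#' Computes, for every (cell, zone) pulse, the transit time, velocity
#' (`L_zone / transit`), applied strain frequency (`velocity / L_p`), the
#' mean relative blockage, and the amplitude and entry phase of the in-pulse
#' oscillation obtained by least squares at the applied frequency. Pulses
#' shorter than one strain period are flagged `insufficient_periods`;
#' oscillation-free pulses are flagged `zero_amplitude` (phase undefined).
#'
#' @param events An [detect_events()] result.
#' @param geometry The device geometry.
#' @param control An [nps_control()].
#' @return A tibble with one row per (cell, zone).
#' @export
extract_zone_features <- function(events, geometry, control = nps_control()) {
  stopifnot(inherits(events, "nps_events"))
  if (!nrow(events$pulses)) return(tibble::tibble())
  sr <- geometry$sample_rate
  purrr::pmap_dfr(events$pulses, function(cell_id, zone, t_start, t_end,
                                          n_samples, mean_drr, samples) {
    zg <- geometry$zones[zone, ]
    transit <- t_end - t_start
    v <- zg$L_zone / transit
    f <- v / zg$L_p
    omega <- 2 * pi * f
    gsamp <- as.integer(round(control$edge_guard_s * sr))
    lo <- gsamp + 1L; hi <- nrow(samples) - gsamp
    if (hi - lo < 8) { # middle half for very short pulses
      lo <- 1L + nrow(samples) %/% 4; hi <- nrow(samples) - nrow(samples) %/% 4
    }
    smp <- samples[lo:hi, ]
    tau <- smp$t - t_start
    X <- cbind(1, cos(omega * tau), sin(omega * tau))
    b <- tryCatch(stats::.lm.fit(X, smp$drr)$coefficients,
      error = function(e) c(NA_real_, NA_real_, NA_real_))
    amp <- sqrt(b[2]^2 + b[3]^2)
    zero_amp <- is.na(amp) || amp < 1e-3 * max(abs(b[1]), 1e-12)
    tibble::tibble(cell_id = cell_id, zone = zone,
      transit_time = transit, velocity = v, f_applied = f,
      mean_drr = mean_drr,
      osc_amplitude = amp,
      osc_phase = if (zero_amp) NA_real_ else atan2(b[3], b[2]),
      n_samples = n_samples,
      insufficient_periods = transit * f < 1,
      zero_amplitude = zero_amp)
  })
}
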