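# Scan-path core: a continuous-time Markov chain over the four face AOIs
# and the background. Fixation durations are lognormal; saccade durations
# follow the main sequence on AOI-center distances. The same core drives
# both bias calibration (event level only) and the full sample-level
# generator, so calibrated expectations transfer exactly.

# Draw one column index per row proportional to row weights.
sample_categorical <- function(w) {
  cw <- w
  for (j in 2:ncol(cw)) cw[, j] <- cw[, j - 1] + cw[, j]
  u <- runif(nrow(cw)) * cw[, ncol(cw)]
  rowSums(u > cw[, -ncol(cw), drop = FALSE]) + 1L
}

# Simulate n trials of the parallel-display scan path.
# bias_mat: n x 4 logical, TRUE where a grid location holds a familiar
# face; m1/m2: transition-weight (or duration) multipliers applied to
# biased locations before/after 1,000 ms. Returns one row per event.
sim_chain <- function(bias_mat, m1, m2, config,
                      geometry = screen_geometry(), t_max = 5000) {
  n <- nrow(bias_mat)
  boxes <- geometry$boxes[match(GRID_LOCATIONS, geometry$boxes$aoi), ]
  cx <- c(boxes$cx, 0)
  cy <- c(boxes$cy, 0)
  mu <- log(config$fixation_median)
  sg <- config$fixation_sigma
  state <- rep(5L, n)
  t <- rep(0, n)
  active <- rep(TRUE, n)
  recs <- vector("list", 200L)
  k <- 0L
  while (any(active)) {
    idx <- which(active)
    t_start <- t[idx]
    state_start <- state[idx]
    dur <- rlnorm(length(idx), mu, sg)
    if (config$bias_mechanism == "duration") {
      on_bias <- state_start <= 4L & bias_mat[cbind(idx, pmin(state_start, 4L))]
      m_now <- ifelse(t_start < 1000, m1, m2)
      dur[on_bias] <- dur[on_bias] * m_now[on_bias]
    }
    fix_end <- pmin(t_start + dur, t_max)
    cont <- fix_end < t_max
    ci <- idx[cont]
    fix_offset <- fix_end
    if (length(ci) > 0) {
      m_now <- ifelse(fix_end[cont] < 1000, m1, m2)
      w <- matrix(1, length(ci), 5)
      w[, 5] <- config$background_weight
      if (config$bias_mechanism == "transition") {
        bm <- bias_mat[ci, , drop = FALSE]
        for (j in 1:4) w[, j] <- ifelse(bm[, j], m_now, 1)
      }
      w[cbind(seq_along(ci), state[ci])] <- 0
      nxt <- sample_categorical(w)
      amp <- sqrt((cx[nxt] - cx[state[ci]])^2 + (cy[nxt] - cy[state[ci]])^2)
      sdur <- config$saccade_intercept + config$saccade_slope * amp
      # a saccade that would outlast the display (or leave a fixation too
      # short to resolve at the sampling rate) never launches: the final
      # fixation is held to the display offset instead, so trials always
      # end in a fixation and events tile [0, t_max] exactly
      launches <- fix_end[cont] + sdur + 20 < t_max
      fix_offset[cont][!launches] <- t_max
      li <- ci[launches]
      if (length(li) > 0) {
        k <- k + 1L
        recs[[k]] <- data.frame(trial = li, event = "saccade",
                                state = nxt[launches],
                                onset = fix_end[cont][launches],
                                offset = (fix_end[cont] + sdur)[launches])
        t[li] <- (fix_end[cont] + sdur)[launches]
        state[li] <- nxt[launches]
      }
      held <- ci[!launches]
      t[held] <- t_max
      active[held] <- FALSE
    }
    k <- k + 1L
    recs[[k]] <- data.frame(trial = idx, event = "fixation",
                            state = state_start, onset = t_start,
                            offset = fix_offset)
    done <- idx[!cont]
    t[done] <- t_max
    active[done] <- FALSE
  }
  out <- do.call(rbind, recs[seq_len(k)])
  out <- out[order(out$trial, out$onset), ]
  rownames(out) <- NULL
  out
}

# Mean famous-minus-unknown dwell-proportion difference in one phase,
# with the familiar face at top_left, over n simulated trials.
chain_dwell_diff <- function(m1, m2, n, phase, config, geometry) {
  bias_mat <- matrix(FALSE, n, 4)
  bias_mat[, 1] <- TRUE
  ev <- sim_chain(bias_mat, m1, m2, config, geometry)
  fx <- ev[ev$event == "fixation" & ev$state <= 4, ]
  win <- PHASE_WINDOWS[[as.character(phase)]]
  ov <- interval_overlap(fx$onset, fx$offset, win[1], win[2])
  fam <- rowsum(ov * (fx$state == 1L), fx$trial)
  unk <- rowsum(ov * (fx$state != 1L), fx$trial) / 3
  mean(fam - unk) / PHASE_DURATION[[as.character(phase)]]
}

.stmcit_cache <- new.env(parent = emptyenv())

#' Calibrate the familiarity bias multiplier
#'
#' Finds the transition-weight (or duration) multiplier applied to the
#' familiar face's AOI so that the expected famous-minus-unknown
#' dwell-proportion difference in the requested phase equals `theta`.
#' Calibration solves for the multiplier by bisection against a
#' common-random-number Monte Carlo estimate of the chain's expected
#' dwell difference, then verifies the result on an independent
#' simulation (at least 10,000 trials, enlarged until the Monte Carlo
#' standard error supports the +/-0.005 tolerance). Results are cached
#' per configuration.
#'
#' @param theta Target signed dwell-proportion difference, `|theta| < 0.75`.
#' @param phase 1 (200-1,000 ms) or 2 (1,001-5,000 ms).
#' @param config A [gaze_config()].
#' @param geometry A [screen_geometry()].
#' @param m_phase1 Multiplier already in force during phase 1 (used when
#'   calibrating phase 2, whose starting state depends on phase-1
#'   dynamics).
#' @param n_calib,n_verify Monte Carlo sizes for search and verification.
#' @param tol Verification tolerance on the dwell difference.
#' @return The scalar multiplier.
#' @export
#' @examples
#' calibrate_bias(0, 1, gaze_config())  # unbiased chain needs no scaling
calibrate_bias <- function(theta, phase, config = gaze_config(),
                           geometry = screen_geometry(), m_phase1 = 1,
                           n_calib = 50000, n_verify = 10000, tol = 0.005) {
  stopifnot(phase %in% c(1, 2))
  if (abs(theta) >= 0.75) {
    abort(
      "theta is outside the attainable range (|theta| < 0.75) for four AOIs.",
      class = "stmcit_bounds_error"
    )
  }
  if (theta == 0) return(1)
  key <- rlang::hash(list(
    theta, phase, m_phase1,
    config[c("fixation_median", "fixation_sigma", "saccade_intercept",
             "saccade_slope", "background_weight", "bias_mechanism")],
    geometry$center_eccentricity, geometry$picture_width,
    geometry$picture_height
  ))
  if (!is.null(.stmcit_cache[[key]])) return(.stmcit_cache[[key]])

  f <- function(m, n, seed) {
    m1 <- if (phase == 1) m else m_phase1
    m2 <- if (phase == 2) m else 1
    withr::with_seed(seed, chain_dwell_diff(m1, m2, n, phase, config, geometry))
  }
  lo <- log(1e-3)
  hi <- log(1e3)
  d_lo <- f(exp(lo), n_calib, 2024001L)
  d_hi <- f(exp(hi), n_calib, 2024001L)
  if (theta < d_lo || theta > d_hi) {
    abort(
      paste0("theta = ", theta, " (phase ", phase, ") is not attainable ",
             "under this configuration."),
      class = "stmcit_bounds_error"
    )
  }
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (f(exp(mid), n_calib, 2024001L) < theta) lo <- mid else hi <- mid
  }
  m_star <- exp((lo + hi) / 2)

  # independent verification; grow n until the MC standard error is small
  # relative to the tolerance, then check the contract
  n_v <- n_verify
  repeat {
    d_v <- f(m_star, n_v, 2024777L)
    se_v <- 0.35 / sqrt(n_v)  # conservative per-trial SD bound
    if (abs(d_v - theta) <= tol || n_v >= 16 * n_verify) break
    if (abs(d_v - theta) > tol + 3 * se_v) break
    n_v <- n_v * 4
  }
  if (abs(d_v - theta) > tol) {
    abort(
      paste0("Bias calibration failed to converge for theta = ", theta,
             " (phase ", phase, "): simulated difference ", round(d_v, 4)),
      class = "stmcit_config_error"
    )
  }
  .stmcit_cache[[key]] <- m_star
  m_star
}
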