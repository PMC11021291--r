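#' Configuration of the synthetic gaze generator
#'
#' Bundles every tunable parameter of the simulator. The familiarity
#' effect sizes `theta_orient` and `theta_avoid` are the expected
#' famous-minus-unknown dwell-proportion differences in the first
#' (200-1,000 ms) and second (1,001-5,000 ms) phase of the parallel
#' display; their defaults are the group means reported for the test
#' (+0.06 and -0.06). Oculomotor micro-parameters (fixation-duration
#' distribution, saccade main sequence, positional noise) are generator
#' assumptions, not empirical claims; behavioral defaults (reaction
#' times, accuracies, no-response rate) follow the reported single-face
#' response statistics.
#'
#' @param theta_orient Expected phase-1 dwell-proportion difference
#'   (signed, in `[-1, 1]`).
#' @param theta_avoid Same for phase 2.
#' @param fixation_median,fixation_sigma Lognormal fixation-duration
#'   parameters (median in ms; sigma on the log scale).
#' @param saccade_intercept,saccade_slope Saccade main sequence:
#'   duration (ms) = intercept + slope x amplitude (deg).
#' @param noise_sd Positional scatter of fixations around the AOI center
#'   (degrees; realized as a constant offset per fixation).
#' @param tremor_sd Per-sample oculomotor tremor (degrees).
#' @param background_weight Relative transition weight of the background
#'   state against 1 per face AOI.
#' @param blink_rate Expected number of blinks per trial.
#' @param blink_range Blink duration range (ms, uniform).
#' @param rt_mean_famous,rt_sd_famous,rt_mean_unknown,rt_sd_unknown
#'   Single-face reaction-time model (ms) by effective familiarity.
#' @param acc_famous,acc_unknown Correct-response probabilities.
#' @param no_response_rate Probability of exceeding the 5,000-ms response
#'   deadline.
#' @param false_recognition_rate Per-face probability that an unknown
#'   face is judged famous in the post-test.
#' @param miss_rate Per-face probability that a famous face is not
#'   recognized in the post-test.
#' @param bias_mechanism `"transition"` (default) biases the scan-path
#'   transition probabilities toward/away from the familiar face;
#'   `"duration"` instead rescales fixation durations on it.
#' @return A validated list of class `cit_gaze_config`.
#' @export
#' @examples
#' cfg <- gaze_config(theta_orient = 0.06, theta_avoid = -0.06)
gaze_config <- function(theta_orient = 0.06,
                        theta_avoid = -0.06,
                        fixation_median = 250,
                        fixation_sigma = 0.4,
                        saccade_intercept = 21,
                        saccade_slope = 2.2,
                        noise_sd = 0.3,
                        tremor_sd = 0.005,
                        background_weight = 0.15,
                        blink_rate = 0.2,
                        blink_range = c(100, 300),
                        rt_mean_famous = 1005.5,
                        rt_sd_famous = 187.8,
                        rt_mean_unknown = 1288.7,
                        rt_sd_unknown = 225,
                        acc_famous = 0.97,
                        acc_unknown = 0.87,
                        no_response_rate = 0.0046,
                        false_recognition_rate = 0.01,
                        miss_rate = 0.01,
                        bias_mechanism = c("transition", "duration")) {
  cfg <- list(
    theta_orient = theta_orient, theta_avoid = theta_avoid,
    fixation_median = fixation_median, fixation_sigma = fixation_sigma,
    saccade_intercept = saccade_intercept, saccade_slope = saccade_slope,
    noise_sd = noise_sd, tremor_sd = tremor_sd,
    background_weight = background_weight,
    blink_rate = blink_rate, blink_range = blink_range,
    rt_mean_famous = rt_mean_famous, rt_sd_famous = rt_sd_famous,
    rt_mean_unknown = rt_mean_unknown, rt_sd_unknown = rt_sd_unknown,
    acc_famous = acc_famous, acc_unknown = acc_unknown,
    no_response_rate = no_response_rate,
    false_recognition_rate = false_recognition_rate,
    miss_rate = miss_rate,
    bias_mechanism = match.arg(bias_mechanism)
  )
  probs <- c(cfg$acc_famous, cfg$acc_unknown, cfg$no_response_rate,
             cfg$false_recognition_rate, cfg$miss_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].",
          class = "stmcit_config_error")
  }
  if (abs(cfg$theta_orient) > 1 || abs(cfg$theta_avoid) > 1) {
    abort("theta values must lie in [-1, 1].", class = "stmcit_config_error")
  }
  pos <- c(cfg$fixation_median, cfg$fixation_sigma, cfg$saccade_intercept,
           cfg$saccade_slope, cfg$background_weight, cfg$blink_range)
  if (any(pos <= 0)) {
    abort("Durations, kinematic parameters and weights must be positive.",
          class = "stmcit_config_error")
  }
  if (cfg$noise_sd < 0 || cfg$tremor_sd < 0 || cfg$blink_rate < 0) {
    abort("Noise and blink parameters must be non-negative.",
          class = "stmcit_config_error")
  }
  structure(cfg, class = "cit_gaze_config")
}
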