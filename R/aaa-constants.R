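# Shared constants (this file collates first).

GRID_LOCATIONS <- c("top_left", "top_right", "bottom_left", "bottom_right")
CHAIN_STATES <- c(GRID_LOCATIONS, "background")
PHASE_WINDOWS <- list(`1` = c(200, 1000), `2` = c(1000, 5000))
PHASE_DURATION <- c(`1` = 800, `2` = 4000)
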