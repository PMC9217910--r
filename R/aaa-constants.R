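# Reserved variable names of the modelling framework.

MITOS_VARS <- c("mitos_walking", "mitos_swallowing",
                "mitos_communication", "mitos_breathing")
SURVIVAL_VAR <- "survival"
TBV_VAR <- "tbv"
TSO_VAR <- "tso"
TBV_BASELINE <- "baseline"
SIM_OUTCOMES <- c(MITOS_VARS, "death")
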