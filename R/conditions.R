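# Classed conditions so callers (and tests) can distinguish failure modes.
# All inherit from "swsystolic_error".

sw_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "swsystolic_error"), call = call))
}

sw_alphabet_error <- function(msg) sw_stop(msg, "sw_alphabet_error")
sw_input_error    <- function(msg) sw_stop(msg, "sw_input_error")
sw_value_error    <- function(msg) sw_stop(msg, "sw_value_error")
sw_contract_error <- function(msg) sw_stop(msg, "sw_contract_error")
sw_config_error   <- function(msg) sw_stop(msg, "sw_config_error")
sw_parse_error    <- function(msg) sw_stop(msg, "sw_parse_error")
# |s| < |q| violates the one-PE-per-query-symbol array layout
sw_constraint_error <- function(msg) sw_stop(msg, c("sw_constraint_error", "sw_input_error"))
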