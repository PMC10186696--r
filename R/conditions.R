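# Structured error conditions.
# Input problems (bad files, bad arguments, missing data) carry class
# "dielshift_input_error"; numerical/statistical failures carry
# "dielshift_estimation_error". The pipeline maps these to exit codes 2 and 3.

stop_input <- function(msg, ...) {
  stop(structure(
    class = c("dielshift_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_estimation <- function(msg, ...) {
  stop(structure(
    class = c("dielshift_estimation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
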