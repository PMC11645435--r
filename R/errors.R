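# Classed conditions so callers (and the CLI) can map failures to categories
# without parsing messages.

.tegrnStop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "tegrn_error"), call = call))
}

.stopUsage <- function(msg) .tegrnStop(msg, "tegrn_usage_error")
.stopParse <- function(msg) .tegrnStop(msg, "tegrn_parse_error")
.stopFormat <- function(msg) .tegrnStop(msg, "tegrn_format_error")
.stopDuplicate <- function(msg) .tegrnStop(msg, "tegrn_duplicate_error")
.stopLength <- function(msg) .tegrnStop(msg, "tegrn_length_error")
.stopValue <- function(msg) .tegrnStop(msg, "tegrn_value_error")
.stopInsufficient <- function(msg) .tegrnStop(msg, "tegrn_insufficient_data_error")
.stopBounds <- function(msg) .tegrnStop(msg, "tegrn_bounds_error")
.stopIO <- function(msg) .tegrnStop(msg, "tegrn_io_error")
.stopCapability <- function(msg) .tegrnStop(msg, "tegrn_capability_error")
.stopDegenerate <- function(msg) .tegrnStop(msg, "tegrn_degenerate_error")
.stopCompute <- function(msg) .tegrnStop(msg, "tegrn_compute_error")

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
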