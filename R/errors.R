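#' @title Package error conditions
#' @description brainseg signals typed conditions so callers can distinguish
#'   contract violations (shape mismatches, unlabeled file names, degenerate
#'   training data, ...) from ordinary R errors. All classes inherit from
#'   `brainseg_error`.
#' @name brainseg-errors
#' @keywords internal
NULL

bs_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "brainseg_error", "error"),
                      call = call))
}

stop_shape <- function(msg) bs_stop("brainseg_shape_error", msg)
stop_format <- function(msg) bs_stop("brainseg_format_error", msg)
stop_arity <- function(msg) bs_stop("brainseg_arity_error", msg)
stop_size <- function(msg) bs_stop("brainseg_size_error", msg)
stop_spec <- function(msg) bs_stop("brainseg_spec_error", msg)
stop_unlabeled <- function(msg) bs_stop("brainseg_unlabeled_name_error", msg)
stop_degenerate <- function(msg) bs_stop("brainseg_degenerate_data_error", msg)
stop_io <- function(msg) bs_stop("brainseg_io_error", msg)
stop_usage <- function(msg) bs_stop("brainseg_usage_error", msg)
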