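# internal helpers: classed errors, logging, small numeric utilities

clfc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eegclfcnet_error")))
}

#' Package logging
#'
#' Timestamped, level-filtered log lines written to standard error.
#' The active level is taken from `options(eegclfcnet.log_level = ...)`
#' (one of `"debug"`, `"info"`, `"warn"`, `"error"`; default `"info"`).
#'
#' @param level Severity of the message.
#' @param ... Parts pasted into the message.
#' @return Invisibly, `NULL`.
#' @export
clfc_log <- function(level = c("info", "debug", "warn", "error"), ...) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  active <- getOption("eegclfcnet.log_level", "info")
  if (ranks[[level]] < ranks[[active]]) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(..., collapse = "")))
  invisible(NULL)
}

# stopifnot-style check with a classed condition
check_that <- function(ok, msg, class = "contract_error") {
  if (!isTRUE(ok)) clfc_error(msg, class)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

# derive a stream seed below 2^31 from a base seed and a label
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}
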