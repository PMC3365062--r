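# Internal helpers shared across modules.

# Signal a classed error so callers/tests can distinguish failure modes.
stop_weevil <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "weevil_error", "error", "condition")))
}

warn_weevil <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

# Observer indicator names used throughout (reference level: obs1).
OBSERVER_INDICATORS <- c("observer_2", "observer_3", "observer_4")
OBSERVER_LEVELS <- paste0("obs", 1:4)
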