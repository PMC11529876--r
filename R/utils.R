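## Internal helpers shared across modules.

# Run `expr` under a deterministic RNG state without disturbing the
# caller's stream.  All stochastic operations in the package funnel
# through this so that a spec seed implies bit-identical output.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

bit_range <- function(bit_depth) {
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  c(0, 2^bit_depth - 1)
}

clip_range <- function(x, bit_depth) {
  r <- bit_range(bit_depth)
  x[x < r[1]] <- r[1]
  x[x > r[2]] <- r[2]
  x
}

# Quantize a float image back onto the integer grey-level grid.
quantize <- function(x, bit_depth) {
  clip_range(round(x), bit_depth)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

config_error <- function(...) {
  stop(structure(class = c("emmosaic_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

format_error <- function(...) {
  stop(structure(class = c("emmosaic_format_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# Minimal leveled logger (message-based so callers can suppress it).
.log_state <- new.env(parent = emptyenv())
.log_state$level <- "info"

#' Set the package log level
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return the previous level, invisibly.
#' @export
emma_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- .log_state$level
  .log_state$level <- level
  invisible(old)
}

log_msg <- function(level, fmt, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[.log_state$level]] &&
      .log_state$level != "quiet")
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
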