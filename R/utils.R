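# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Wrap degrees to [-180, 180).
wrap_deg <- function(x) ((x + 180) %% 360) - 180

# Absolute circular distance in degrees, in [0, 180].
circ_dist_deg <- function(a, b) abs(wrap_deg(a - b))

#' Phase bin layout
#'
#' Low-frequency phase is discretized into 18 bins of 20 degrees spanning
#' \[-180, 180) degrees. `pac_bin_centers()` returns the 18 bin centers
#' (-170, -150, ..., 170); `pac_bin_edges()` the 19 edges.
#'
#' @return Numeric vector of bin centers (length 18) or edges (length 19),
#'   in degrees.
#' @export
pac_bin_centers <- function() seq(-170, 170, by = 20)

#' @rdname pac_bin_centers
#' @export
pac_bin_edges <- function() seq(-180, 180, by = 20)

# Map phase in degrees to bin index 1..18; input is wrapped first.
phase_bin_index <- function(phase_deg) {
  p <- wrap_deg(phase_deg)
  idx <- floor((p + 180) / 20) + 1L
  pmin(pmax(as.integer(idx), 1L), 18L)
}

# Error condition used when a recording cannot supply the required number of
# segments; run_pipeline() catches this class to exclude (not abort on) a file.
insufficient_data_error <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("pacdev_insufficient_data", "error", "condition"),
    list(message = msg, call = call)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
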