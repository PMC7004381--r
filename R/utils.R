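#' Evaluate an expression with a temporary RNG seed
#'
#' Saves any existing `.Random.seed`, seeds the generator, evaluates the
#' expression and restores the previous RNG state, so seeded operations do
#' not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Write a provenance sidecar for an output artifact
#'
#' Every writer in the package records the operation, its parameters and any
#' seed next to the artifact as `<path>.provenance.json`, so results can be
#' traced back to the exact call that produced them.
#'
#' @param path path of the artifact the sidecar describes.
#' @param operation character name of the operation.
#' @param parameters named list of parameters (seeds included).
#' @return invisibly, the sidecar path.
#' @export
write_provenance <- function(path, operation, parameters = list()) {
  sidecar <- paste0(path, ".provenance.json")
  payload <- list(
    operation = operation,
    parameters = parameters,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(sidecar)
}

# Derive a stream of distinct sub-seeds from one master seed.  Keeps every
# derived seed inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
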