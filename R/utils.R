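#' Derive a child seed from a master seed and a stage name
#'
#' All randomness in the package flows from one integer seed. Each stage
#' (simulation, swarm, bootstrap, ...) derives its own child seed from the
#' master seed and a stage key, so stages can be re-run independently and
#' reordering one stage never perturbs another.
#'
#' @param seed Master integer seed.
#' @param key Character stage key (e.g. \code{"swarm"}, \code{"bootstrap"}).
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  # multiplicative string hash mod the Mersenne prime 2^31 - 1
  x <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(key)) x <- (x * 31 + b) %% 2147483647
  as.integer(x)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded stages do not
#' perturb surrounding randomness.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One structured log line per pipeline stage
#'
#' Writes a single line to stderr (and optionally a run log file) with the
#' stage name and \code{key=value} fields, e.g. input/output shapes and
#' parameters.
#' @param stage Stage name.
#' @param ... Named scalar fields.
#' @param file Optional path of a run-log file to append to.
#' @return Invisibly, the formatted line.
#' @export
log_stage <- function(stage, ..., file = NULL) {
  fields <- list(...)
  kv <- if (length(fields)) {
    paste(names(fields), vapply(fields, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  } else ""
  line <- sprintf("[tepscore] %s %s", stage, kv)
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

# row-wise means/variances without apply() overhead
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

#' Stable content hash of an R object
#'
#' Canonicalises the object as JSON (fixed digit count) and hashes the text
#' with MD5; used to assert that locked biomarker panels are immutable.
#' @param x Object serialisable by \code{jsonlite::toJSON}.
#' @return Character MD5 digest.
#' @export
content_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, null = "null",
                          force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
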