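# Structured conditions so callers (and the CLI) can map failures to
# categories without string matching. All inherit from "phylostrat_error".

ph_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "phylostrat_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ph_parse_error      <- function(msg) ph_error(msg, "phylostrat_parse_error")
ph_validation_error <- function(msg) ph_error(msg, "phylostrat_validation_error")
ph_argument_error   <- function(msg) ph_error(msg, "phylostrat_argument_error")
ph_lookup_error     <- function(msg) ph_error(msg, "phylostrat_lookup_error")
ph_format_error     <- function(msg) ph_error(msg, "phylostrat_format_error")
ph_io_error         <- function(msg) ph_error(msg, "phylostrat_io_error")

ph_check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || is.na(path))
    ph_argument_error("file path must be a single string")
  if (!file.exists(path))
    ph_io_error(sprintf("file not found: '%s'", path))
  invisible(path)
}

# Read a text file, dropping '#'-prefixed comment lines and blank lines.
ph_read_lines <- function(path, comment = "#") {
  ph_check_file(path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment) & nzchar(trimws(lines))
  structure(lines[keep], line_numbers = which(keep))
}

# Full-precision numeric formatting so written files round-trip bit-exactly.
ph_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  ints <- !is.na(x) & is.finite(x) & x == round(x) & abs(x) < 1e15
  out[ints] <- sprintf("%.0f", x[ints])
  out
}

# Evaluate an expression with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    ph_argument_error("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
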