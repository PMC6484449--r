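`%||%` <- function(x, y) if (is.null(x)) y else x

#' Path to a file packaged with consentlink
#' @param ... path components under `inst/extdata`
#' @return absolute file path
#' @keywords internal
cl_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "consentlink", mustWork = TRUE)
  path
}

# ISO 8601 calendar date handling; forms are dated, never timestamped.
cl_parse_date <- function(x, what = "date") {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NULL)
  if (inherits(x, "Date")) return(x)
  if (!is.character(x) || !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)) {
    stop(sprintf("invalid %s: expected an ISO 8601 calendar date, got %s",
                 what, deparse(x)), call. = FALSE)
  }
  d <- as.Date(x, format = "%Y-%m-%d")
  if (is.na(d)) {
    stop(sprintf("invalid %s: %s is not a real calendar date", what, x),
         call. = FALSE)
  }
  d
}

cl_is_date_string <- function(x) {
  is.character(x) && length(x) == 1 && grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &&
    !is.na(as.Date(x, format = "%Y-%m-%d"))
}

cl_format_date <- function(d) format(as.Date(d), "%Y-%m-%d")

# Age in completed years at `on`, civil convention (birthday anniversary).
cl_age_years <- function(date_of_birth, on) {
  dob <- as.POSIXlt(as.Date(date_of_birth))
  at <- as.POSIXlt(as.Date(on))
  age <- at$year - dob$year
  before_birthday <- (at$mon < dob$mon) || (at$mon == dob$mon && at$mday < dob$mday)
  if (before_birthday) age <- age - 1L
  age
}

# Run `expr` with the global RNG seeded, restoring any prior RNG state on exit.
# Callers therefore see no RNG side effects: one generator per call.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Drop NULLs and zero-length unnamed entries from a list (canonical form).
cl_compact <- function(x) {
  if (!is.list(x)) return(x)
  x[!vapply(x, is.null, logical(1))]
}
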