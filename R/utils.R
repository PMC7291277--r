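# Internal helpers shared across modules.

mhl_stop <- function(msg, class = "mhl_error") {
  stop(structure(
    class = c(class, "mhl_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Read a UTF-8, tab-separated table with a mandatory header row.
# Lines starting with "#" are comments and skipped.  Returns all columns
# as character; callers coerce and validate.
read_tsv_table <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) {
    mhl_stop(sprintf("file not found: %s", path), "mhl_io_error")
  }
  df <- utils::read.table(
    path,
    header = TRUE, sep = "\t", quote = "", comment.char = "#",
    colClasses = "character", stringsAsFactors = FALSE,
    encoding = "UTF-8", blank.lines.skip = TRUE, check.names = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    mhl_stop(
      sprintf(
        "%s: missing required column(s): %s",
        path, paste(missing, collapse = ", ")
      ),
      "mhl_schema_error"
    )
  }
  df
}

write_tsv_table <- function(df, path) {
  utils::write.table(
    df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    fileEncoding = "UTF-8"
  )
}

# Parse strictly integer character vectors; non-integer tokens become NA.
parse_int <- function(x) {
  ok <- grepl("^[+-]?[0-9]+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out
}

# Single shared validator for 1-based inclusive coordinate pairs.
validate_coords <- function(start, end, context, lines = NULL) {
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    mhl_stop(
      sprintf("%s: non-integer coordinate at row %d", context, where),
      "mhl_row_error"
    )
  }
  bad <- which(start < 1L | start > end)
  if (length(bad) > 0) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    mhl_stop(
      sprintf(
        "%s: invalid 1-based inclusive interval (start=%d, end=%d) at row %d",
        context, start[bad[1]], end[bad[1]], where
      ),
      "mhl_row_error"
    )
  }
  invisible(TRUE)
}

# Deterministic seeding for generator code: set the RNG locally and restore
# the caller's RNG state on exit.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
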