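# Internal helpers shared across modules.

# Classed condition so callers can distinguish validation failures.
dr_stop <- function(class, msg) {
  stop(structure(
    class = c(class, "dynrange_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Natural-numeric ordering of file names: sort by the first integer found in
# the basename, ties broken lexicographically. "t2.csv" sorts before
# "t10.csv".
natural_order <- function(paths) {
  base <- basename(paths)
  digits <- vapply(base, function(b) {
    hit <- regmatches(b, regexpr("[0-9]+", b))
    if (length(hit) == 0) NA_character_ else hit
  }, character(1))
  num <- suppressWarnings(as.numeric(digits))
  order(num, base, na.last = TRUE)
}

# Headerless numeric CSV matrix. NA/NaN mark permanently uninhabitable cells.
read_matrix_csv <- function(path) {
  if (!file.exists(path)) {
    dr_stop("dynrange_missing_file", sprintf("file not found: %s", path))
  }
  df <- utils::read.table(path, sep = ",", header = FALSE,
                          na.strings = c("NA", "NaN", "nan", ""),
                          colClasses = "numeric",
                          strip.white = TRUE)
  ok <- tryCatch(as.matrix(df), warning = function(w) w)
  if (!is.numeric(ok)) {
    dr_stop("dynrange_bad_value", sprintf("non-numeric cell in %s", path))
  }
  m <- unname(as.matrix(df))
  storage.mode(m) <- "double"
  m
}

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

# Two-column headerless key,value CSV used for configuration and species
# files. Returns a named character vector.
read_keyvalue_csv <- function(path) {
  if (!file.exists(path)) {
    dr_stop("dynrange_missing_file", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    dr_stop("dynrange_bad_value", sprintf("empty key/value file: %s", path))
  }
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    dr_stop("dynrange_bad_value",
            sprintf("line without 'key,value' structure in %s: %s",
                    path, lines[bad][1]))
  }
  keys <- trimws(vapply(parts, `[`, character(1), 1))
  vals <- trimws(vapply(parts, `[`, character(1), 2))
  stats::setNames(vals, keys)
}

parse_number <- function(x, key) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    dr_stop("dynrange_bad_value",
            sprintf("value for '%s' is not a number: '%s'", key, x))
  }
  v
}

parse_integer <- function(x, key) {
  v <- parse_number(x, key)
  if (v != round(v)) {
    dr_stop("dynrange_bad_value",
            sprintf("value for '%s' is not an integer: '%s'", key, x))
  }
  as.integer(v)
}

parse_flag <- function(x, key) {
  v <- tolower(trimws(as.character(x)))
  if (v %in% c("true", "t", "1", "yes")) return(TRUE)
  if (v %in% c("false", "f", "0", "no")) return(FALSE)
  dr_stop("dynrange_bad_value",
          sprintf("value for '%s' is not true/false: '%s'", key, x))
}

parse_enum <- function(x, key, levels) {
  x <- trimws(as.character(x))
  if (!x %in% levels) {
    dr_stop("dynrange_bad_value",
            sprintf("value for '%s' must be one of %s, got '%s'",
                    key, paste(levels, collapse = "/"), x))
  }
  x
}
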