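#' Read / write a profile text file
#'
#' Profiles are exchanged as plain text with two whitespace-separated
#' numeric columns (position mm, density); lines starting with `#` are
#' comments. The writer uses 17 significant digits so a write/read round
#' trip is bit identical. Files with descending positions are reversed on
#' read (with a message), matching the canonical ascending order.
#'
#' @param path file path.
#' @return `read_profile()` returns a [sampled_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("read_profile: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("read_profile: no data lines in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad))
    stop("read_profile: expected 2 columns on line ", idx[bad[1]],
         " of ", path)
  num <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2L, byrow = TRUE)
  nabad <- which(rowSums(is.na(num)) > 0)
  if (length(nabad))
    stop("read_profile: non-numeric value on line ", idx[nabad[1]],
         " of ", path)
  pos <- num[, 1]; val <- num[, 2]
  if (length(pos) >= 2 && all(diff(pos) < 0)) {
    message("read_profile: descending positions; profile reversed")
    pos <- rev(pos); val <- rev(val)
  }
  sampled_profile(pos, val)
}

#' @rdname read_profile
#' @param profile a [sampled_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sampled_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cortiprof profile: position_mm density",
               sprintf("%.17g %.17g", profile$positions, profile$values)),
             con)
  invisible(path)
}

# 32-bit FNV-1a hash of a string, for lightweight config provenance.
# Kept in double arithmetic: xor only touches the low byte, and the 32-bit
# product is split 16/16 to stay within exact double integer range.
.fnv1a <- function(s) {
  h <- 2166136261
  for (byte in as.integer(charToRaw(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), byte)
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write / read a thickness estimate as JSON
#'
#' All numeric fields are serialized at full precision; the record carries
#' the method tag, flags, diagnostics, and a hash of the serialized
#' configuration for provenance. The packaged schema
#' (`inst/extdata/estimate-schema.json`) lists the required fields;
#' [validate_estimate()] checks a record against it.
#'
#' @param e a `thickness_estimate`.
#' @param path file path.
#' @param config optional named list describing the run; embedded verbatim.
#' @return `write_estimate()` returns `path` invisibly; `read_estimate()`
#'   the parsed list.
#' @export
write_estimate <- function(e, path, config = list()) {
  stopifnot(inherits(e, "thickness_estimate"))
  rec <- list(
    method = e$method,
    thickness = e$thickness,
    half_thickness = e$half_thickness,
    K_used = e$K_used,
    bmc_cort = e$bmc_cort,
    regularized = e$regularized,
    diagnostics = e$diagnostics[!vapply(e$diagnostics, is.null, TRUE)],
    config = config
  )
  rec$config_hash <- .fnv1a(jsonlite::toJSON(config, digits = I(17),
                                             auto_unbox = TRUE))
  jsonlite::write_json(rec, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_estimate
#' @export
read_estimate <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_estimate
#' @param record a list as returned by [read_estimate()].
#' @export
validate_estimate <- function(record) {
  schema_path <- system.file("extdata", "estimate-schema.json",
                             package = "cortiprof")
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  missing <- setdiff(schema$required, names(record))
  if (length(missing))
    stop("estimate record is missing required field(s): ",
         paste(missing, collapse = ", "))
  for (f in names(schema$types)) {
    if (!f %in% names(record)) next
    want <- schema$types[[f]]
    ok <- switch(want,
                 number = is.numeric(record[[f]]) || is.null(record[[f]]),
                 string = is.character(record[[f]]),
                 boolean = is.logical(record[[f]]),
                 TRUE)
    if (!ok) stop("estimate field `", f, "` should be of type ", want)
  }
  invisible(TRUE)
}

#' Serialize a measurement as JSON
#'
#' @param m a [lat50_measure()] result.
#' @param path file path.
#' @return `read_measurement()` returns the `lat50_measurement`.
#' @export
write_measurement <- function(m, path) {
  stopifnot(inherits(m, "lat50_measurement"))
  jsonlite::write_json(unclass(m), path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "lat50_measurement")
}

# Minimal "key: value" config reader (numbers parsed, rest kept as strings).
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("read_config: malformed line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
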