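## Tabular input/output: check-in event streams, subject attribute tables,
## pair statistics, and network export/import.
##
## All files are comma-separated UTF-8 with a mandatory header row.
## Subject and location identifiers are opaque strings and are never parsed.

# ---- event streams ---------------------------------------------------------

#' Read a check-in event stream
#'
#' Reads a CSV file with columns `subject_id`, `timestamp`, `location_id`
#' into an event stream. Each row records one check-in: a subject appeared
#' at a location at a time point (second resolution).
#'
#' @param path path to a CSV file with header
#'   `subject_id,timestamp,location_id`.
#' @param timestamp_dialect one of `"auto"`, `"iso8601"`, `"epoch_seconds"`.
#'   With `"auto"`, a column made entirely of digit strings is treated as
#'   epoch seconds, anything else as ISO-8601 (`YYYY-MM-DD HH:MM:SS`, a `T`
#'   separator is accepted).
#' @return an `event_stream`: a `data.table` with character `subject_id`,
#'   `POSIXct` (UTC) `timestamp` and character `location_id`, rows in file
#'   order. The number of records `Z` is `nrow()`.
#' @export
read_events <- function(path,
                        timestamp_dialect = c("auto", "iso8601",
                                              "epoch_seconds")) {
  timestamp_dialect <- match.arg(timestamp_dialect)
  if (!file.exists(path)) {
    svcn_abort("io_error", sprintf("event file not found: %s", path))
  }
  dt <- data.table::fread(path, colClasses = "character",
                          header = TRUE, sep = ",", encoding = "UTF-8")
  required <- c("subject_id", "timestamp", "location_id")
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    svcn_abort("schema_error",
               sprintf("event file %s lacks column(s): %s",
                       path, paste(missing, collapse = ", ")))
  }
  dt <- dt[, required, with = FALSE]
  if (nrow(dt) == 0L) {
    return(new_event_stream(dt[, list(subject_id = character(),
                                      timestamp = as_utc(numeric(0)),
                                      location_id = character())]))
  }
  bad <- which(is.na(dt$subject_id) | dt$subject_id == "" |
               is.na(dt$location_id) | dt$location_id == "")
  if (length(bad)) {
    svcn_abort("parse_error",
               sprintf("empty subject_id/location_id at line %d of %s",
                       bad[1L] + 1L, path))
  }
  ts <- parse_timestamps(dt$timestamp, timestamp_dialect)
  if (anyNA(ts)) {
    line <- which(is.na(ts))[1L]
    svcn_abort("parse_error",
               sprintf("unparseable timestamp '%s' at line %d of %s",
                       dt$timestamp[line], line + 1L, path))
  }
  dt[, timestamp := ts]
  new_event_stream(dt)
}

#' Construct an event stream from in-memory columns
#'
#' @param subject_id character vector of subject identifiers.
#' @param timestamp `POSIXct` or numeric (epoch seconds) vector.
#' @param location_id character vector of location identifiers.
#' @return an `event_stream` (see [read_events()]).
#' @export
event_stream <- function(subject_id, timestamp, location_id) {
  if (is.numeric(timestamp)) timestamp <- as_utc(timestamp)
  stopifnot(inherits(timestamp, "POSIXct"))
  dt <- data.table::data.table(subject_id = as.character(subject_id),
                               timestamp = timestamp,
                               location_id = as.character(location_id))
  if (nrow(dt) && (anyNA(dt$subject_id) || any(dt$subject_id == "") ||
                   anyNA(dt$location_id) || any(dt$location_id == "") ||
                   anyNA(dt$timestamp))) {
    svcn_abort("parse_error", "event fields must be non-empty and parseable")
  }
  new_event_stream(dt)
}

#' Write an event stream to CSV
#'
#' Timestamps are written as ISO-8601 UTC so that
#' `read_events(path, "iso8601")` round-trips exactly at second resolution.
#'
#' @param events an `event_stream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  out <- data.table::data.table(
    subject_id = events$subject_id,
    timestamp = format(events$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    location_id = events$location_id)
  data.table::fwrite(out, path)
  invisible(path)
}

new_event_stream <- function(dt) {
  data.table::setattr(dt, "class",
                      c("event_stream", class(data.table::data.table())))
  dt[]
}

as_utc <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

parse_timestamps <- function(x, dialect) {
  if (dialect == "auto") {
    dialect <- if (all(grepl("^[0-9]+$", x))) "epoch_seconds" else "iso8601"
  }
  if (dialect == "epoch_seconds") {
    num <- suppressWarnings(as.numeric(x))
    num[!grepl("^[0-9]+$", x)] <- NA_real_
    return(as_utc(num))
  }
  iso <- sub("T", " ", x, fixed = TRUE)
  out <- rep(as_utc(NA_real_), length(iso))
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(iso[todo], fmt, tz = "UTC"))
  }
  out
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d records, %d subjects, %d locations\n",
              nrow(x), data.table::uniqueN(x$subject_id),
              data.table::uniqueN(x$location_id)))
  if (nrow(x)) NextMethod()
  invisible(x)
}

# ---- attribute tables ------------------------------------------------------

#' Read a subject attribute table
#'
#' Reads a CSV with a `subject_id` column plus one or more attribute
#' columns. Columns whose non-missing values are all numeric are tagged
#' `scalar` and converted to numeric; all others are tagged `categorical`
#' and kept as character. The tags drive which assortativity coefficient
#' applies downstream.
#'
#' @param path path to the CSV file.
#' @return an `attribute_table`: a `data.frame` with one row per subject,
#'   rownames = subject ids, and an `"attr_types"` attribute mapping column
#'   name to `"scalar"` or `"categorical"`.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) {
    svcn_abort("io_error", sprintf("attribute file not found: %s", path))
  }
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          sep = ",", encoding = "UTF-8")
  if (!"subject_id" %in% names(dt) || ncol(dt) < 2L) {
    svcn_abort("schema_error",
               "attribute file needs subject_id plus >=1 attribute column")
  }
  if (anyDuplicated(dt$subject_id)) {
    dup <- dt$subject_id[duplicated(dt$subject_id)][1L]
    svcn_abort("integrity_error",
               sprintf("duplicate subject_id '%s' in %s", dup, path))
  }
  attribute_table(as.data.frame(dt))
}

#' Construct an attribute table from a data frame
#'
#' @param df data frame with a `subject_id` column; remaining columns are
#'   attributes. Numeric-valued columns become scalar attributes.
#' @return an `attribute_table` (see [read_attributes()]).
#' @export
attribute_table <- function(df) {
  stopifnot(is.data.frame(df), "subject_id" %in% names(df))
  if (anyDuplicated(df$subject_id)) {
    svcn_abort("integrity_error", "duplicate subject_id in attribute table")
  }
  df <- as.data.frame(df)
  cols <- setdiff(names(df), "subject_id")
  types <- vapply(cols, function(cn) {
    v <- df[[cn]]
    if (is.numeric(v)) return("scalar")
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num[!is.na(v) & v != ""])) "scalar" else "categorical"
  }, character(1))
  for (cn in cols[types == "scalar"]) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  for (cn in cols[types == "categorical"]) {
    df[[cn]] <- as.character(df[[cn]])
  }
  rownames(df) <- df$subject_id
  structure(df, attr_types = types,
            class = c("attribute_table", "data.frame"))
}

#' Write an attribute table to CSV
#' @param attrs an `attribute_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(attrs, path) {
  data.table::fwrite(as.data.frame(attrs), path)
  invisible(path)
}

#' Attribute type tags of an attribute table
#' @param attrs an `attribute_table`.
#' @return named character vector, `"scalar"` or `"categorical"` per column.
#' @export
attribute_types <- function(attrs) attr(attrs, "attr_types")

# ---- pair statistics -------------------------------------------------------

#' Write pair co-occurrence statistics to CSV
#'
#' Emits columns `subject_a,subject_b,x_obs,x_exp,p_value,significant` with
#' `subject_a < subject_b` lexicographically and p-values in scientific
#' notation with 7 significant digits.
#'
#' @param pairs a data frame of pair statistics as produced by
#'   [build_svcn()] (`$pair_stats`) or [count_cooccurrences()] after
#'   p-value annotation; needs columns `i`, `j`, `x_obs`, `x_exp`,
#'   `p_value` and optionally `significant`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_stats <- function(pairs, path) {
  need <- c("i", "j", "x_obs", "x_exp", "p_value")
  if (!all(need %in% names(pairs))) {
    svcn_abort("schema_error",
               sprintf("pair stats need columns: %s",
                       paste(need, collapse = ", ")))
  }
  op <- order_pair(as.character(pairs$i), as.character(pairs$j))
  out <- data.frame(
    subject_a = op$a, subject_b = op$b,
    x_obs = pairs$x_obs,
    x_exp = formatC(pairs$x_exp, format = "e", digits = 6),
    p_value = formatC(pairs$p_value, format = "e", digits = 6),
    significant = if ("significant" %in% names(pairs)) {
      tolower(as.character(pairs$significant))
    } else NA,
    stringsAsFactors = FALSE)
  out <- out[order(out$subject_a, out$subject_b), , drop = FALSE]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read pair statistics written by [write_pair_stats()]
#' @param path CSV path.
#' @return data frame with columns `i`, `j`, `x_obs`, `x_exp`, `p_value`,
#'   `significant`.
#' @export
read_pair_stats <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  data.frame(i = as.character(dt$subject_a), j = as.character(dt$subject_b),
             x_obs = as.numeric(dt$x_obs), x_exp = as.numeric(dt$x_exp),
             p_value = as.numeric(dt$p_value),
             significant = as.logical(dt$significant),
             stringsAsFactors = FALSE)
}

# ---- network export / import ----------------------------------------------

#' Export a validated network
#'
#' `"graphml"` writes the full attributed graph including isolated nodes
#' (singleton subjects are part of the network and its component census);
#' `"edgelist_csv"` writes only the validated edges as a two-column CSV
#' `subject_a,subject_b`.
#'
#' @param svcn an `svcn_result` (from [build_svcn()]) or an `igraph` object.
#' @param path output path.
#' @param format `"edgelist_csv"` or `"graphml"`.
#' @param attributes optional `attribute_table`; its columns are attached
#'   as node properties in GraphML output.
#' @return `path`, invisibly.
#' @export
write_network <- function(svcn, path, format = c("edgelist_csv", "graphml"),
                          attributes = NULL) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("edgelist_csv", "graphml")) {
    svcn_abort("parameter_error",
               sprintf("unknown network format '%s'", format))
  }
  format <- match.arg(format)
  g <- if (inherits(svcn, "igraph")) svcn else as_igraph(svcn, attributes)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    op <- order_pair(el[, 1L], el[, 2L])
    out <- data.frame(subject_a = op$a, subject_b = op$b,
                      stringsAsFactors = FALSE)
    out <- out[order(out$subject_a, out$subject_b), , drop = FALSE]
    data.table::fwrite(out, path)
  }
  invisible(path)
}

#' Read a network from GraphML
#' @param path GraphML file as written by [write_network()].
#' @return an `igraph` object with any node attributes present.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read a two-column edge list CSV as an undirected graph
#'
#' Accepts reference tie networks (e.g. self-reported friendships) given as
#' `subject_a,subject_b` rows; a header is expected. Self-loops and
#' duplicate dyads are collapsed.
#'
#' @param path CSV path.
#' @param nodes optional character vector of node names to include even if
#'   isolated.
#' @return an undirected simple `igraph` graph.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE,
                          sep = ",", encoding = "UTF-8")
  if (ncol(dt) < 2L) {
    svcn_abort("schema_error", "edge list needs >=2 columns")
  }
  graph_from_edges(dt[[1L]], dt[[2L]], nodes)
}

#' Build an undirected simple graph from edge endpoint vectors
#' @param from,to character vectors of endpoints.
#' @param nodes optional nodes to include even when isolated.
#' @return an undirected simple `igraph` graph.
#' @export
graph_from_edges <- function(from, to, nodes = NULL) {
  verts <- unique(c(nodes, from, to))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  igraph::simplify(g)
}
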