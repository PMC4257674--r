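#' Read a landmark table
#'
#' Landmark tables are UTF-8 text, comma- or tab-delimited, with header
#' `id,x_um,y_um,z_um,feature_class,confidence`; `feature_class` and
#' `confidence` are optional (defaulting to `OTHER` and 1) and lines
#' starting with `#` are ignored. Coordinates are physical micrometres.
#'
#' @param path file path.
#' @param geometry optional [volume_geometry()] to attach.
#' @param name set name; defaults to the file name.
#' @param ... passed to [landmark_set()] (e.g. `min_separation`).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, geometry = NULL, name = basename(path),
                           ...) {
  tab <- read_delim_table(path,
                          required = c("id", "x_um", "y_um", "z_um"),
                          optional = c("feature_class", "confidence"))
  for (cc in c("x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(tab$data[[cc]]))
    if (any(is.na(v) & !is.na(tab$data[[cc]]))) {
      bad <- which(is.na(v) & !is.na(tab$data[[cc]]))[1]
      stop(sprintf("non-numeric value '%s' in column %s at line %d of %s",
                   tab$data[[cc]][bad], cc, tab$lines[bad], path),
           call. = FALSE)
    }
    tab$data[[cc]] <- v
  }
  df <- data.frame(id = tab$data$id, x = tab$data$x_um, y = tab$data$y_um,
                   z = tab$data$z_um, stringsAsFactors = FALSE)
  if (!is.null(tab$data$feature_class)) df$feature_class <- tab$data$feature_class
  if (!is.null(tab$data$confidence)) {
    df$confidence <- suppressWarnings(as.numeric(tab$data$confidence))
  }
  landmark_set(df, geometry = geometry, name = name, ...)
}

#' Write a landmark table
#'
#' @param set a [landmark_set()].
#' @param path output file path.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(set, path, sep = ",") {
  stopifnot(inherits(set, "landmark_set"))
  lm <- set$landmarks
  out <- data.frame(id = lm$id,
                    x_um = format(lm$x, digits = 17, trim = TRUE,
                                  scientific = FALSE),
                    y_um = format(lm$y, digits = 17, trim = TRUE,
                                  scientific = FALSE),
                    z_um = format(lm$z, digits = 17, trim = TRUE,
                                  scientific = FALSE),
                    feature_class = lm$feature_class,
                    confidence = lm$confidence,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a multi-polyline fiber table
#'
#' Format: delimited text with header `fiber_id,x_um,y_um,z_um`; rows of a
#' fiber are consecutive and ordered along the fiber.
#'
#' @param path file path.
#' @return A [fiber_set()].
#' @export
read_fibers <- function(path) {
  tab <- read_delim_table(path,
                          required = c("fiber_id", "x_um", "y_um", "z_um"))
  d <- tab$data
  for (cc in c("x_um", "y_um", "z_um")) d[[cc]] <- as.numeric(d[[cc]])
  ids <- unique(d$fiber_id)
  polylines <- lapply(ids, function(fid) {
    as.matrix(d[d$fiber_id == fid, c("x_um", "y_um", "z_um")])
  })
  names(polylines) <- ids
  fiber_set(polylines)
}

#' Write a fiber set as a multi-polyline table
#'
#' @param fibers a [fiber_set()].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_fibers <- function(fibers, path, sep = ",") {
  stopifnot(inherits(fibers, "fiber_set"))
  ids <- names(fibers$polylines)
  if (is.null(ids)) ids <- sprintf("F%d", seq_along(fibers$polylines))
  rows <- do.call(rbind, lapply(seq_along(fibers$polylines), function(i) {
    p <- fibers$polylines[[i]]
    data.frame(fiber_id = ids[i], x_um = p[, 1], y_um = p[, 2],
               z_um = p[, 3], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Shared delimited-text reader: skips '#' comments, autodetects comma/tab,
# checks the header, and keeps original line numbers for error messages.
read_delim_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- which(keep)
  if (length(lines) < 1L) stop("empty table: ", path, call. = FALSE)
  header_line <- raw[lines[1]]
  sep <- if (grepl("\t", header_line)) "\t" else ","
  split_row <- function(s) {
    cells <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    gsub('^"|"$', "", cells)
  }
  header <- split_row(header_line)
  miss <- setdiff(required, header)
  if (length(miss)) {
    stop(sprintf("%s: header lacks column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  cells <- lapply(raw[body], split_row)
  n_bad <- vapply(cells, length, 1L) != length(header)
  if (any(n_bad)) {
    stop(sprintf("%s: line %d has %d fields, expected %d", path,
                 body[n_bad][1], length(cells[[which(n_bad)[1]]]),
                 length(header)), call. = FALSE)
  }
  data <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(data) <- header
  list(data = data[, intersect(c(required, optional, header), header),
                   drop = FALSE],
       lines = body)
}
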