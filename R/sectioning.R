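SECTION_KINDS <- c("THICK_LM", "THIN_EM", "SEMITHICK_TOMO")

#' Serial-sectioning scheme
#'
#' A scheme is an ordered list of blocks, each cutting `count` sections of
#' a given nominal `thickness_nm` and kind: 500 nm thick sections for
#' light-microscopy overview (`THICK_LM`), 60 nm thin sections for TEM
#' (`THIN_EM`), or 240-300 nm semi-thick sections for electron tomography
#' (`SEMITHICK_TOMO`). The trailing `repeat_unit` blocks are repeated
#' `repeat_count` times, expressing periodic alternating series. Section
#' thickness is treated as exact (nominal); `thickness_scale` (default 1)
#' can calibrate for systematic compression.
#'
#' @param blocks data.frame with columns `count` (integer >= 1),
#'   `thickness_nm` (> 0), `kind`.
#' @param repeat_unit optional data.frame in the same format: the periodic
#'   unit appended after `blocks`.
#' @param repeat_count how many times `repeat_unit` is repeated (0 = none).
#' @param thickness_scale multiplicative calibration on all thicknesses.
#' @return An object of class `sectioning_scheme`.
#' @export
sectioning_scheme <- function(blocks, repeat_unit = NULL, repeat_count = 0L,
                              thickness_scale = 1) {
  check_blocks <- function(b, what) {
    b <- as.data.frame(b, stringsAsFactors = FALSE)
    stopifnot(all(c("count", "thickness_nm", "kind") %in% names(b)))
    b$count <- as.integer(b$count)
    b$thickness_nm <- as.numeric(b$thickness_nm)
    b$kind <- as.character(b$kind)
    if (any(b$count < 1L)) stop(what, ": counts must be >= 1", call. = FALSE)
    if (any(b$thickness_nm <= 0)) {
      stop(what, ": thicknesses must be > 0", call. = FALSE)
    }
    if (!all(b$kind %in% SECTION_KINDS)) {
      stop(what, ": kind must be one of ",
           paste(SECTION_KINDS, collapse = ", "), call. = FALSE)
    }
    b[, c("count", "thickness_nm", "kind")]
  }
  blocks <- check_blocks(blocks, "blocks")
  repeat_count <- as.integer(repeat_count)
  stopifnot(repeat_count >= 0L, thickness_scale > 0)
  if (repeat_count > 0L) {
    stopifnot(!is.null(repeat_unit))
    repeat_unit <- check_blocks(repeat_unit, "repeat_unit")
  } else {
    repeat_unit <- NULL
  }
  structure(list(blocks = blocks, repeat_unit = repeat_unit,
                 repeat_count = repeat_count,
                 thickness_scale = thickness_scale),
            class = "sectioning_scheme")
}

#' @export
print.sectioning_scheme <- function(x, ...) {
  cat(sprintf(
    "<sectioning_scheme> %d sections, total depth %.3f um (%d lead-in blocks%s)\n",
    n_sections(x), total_depth(x), nrow(x$blocks),
    if (x$repeat_count > 0L) {
      sprintf(" + %d repeats of a %d-block unit", x$repeat_count,
              nrow(x$repeat_unit))
    } else ""))
  invisible(x)
}

# Expanded per-section blocks: one row per section.
expand_scheme <- function(scheme) {
  b <- scheme$blocks
  if (scheme$repeat_count > 0L) {
    b <- rbind(b, do.call(rbind, replicate(scheme$repeat_count,
                                           scheme$repeat_unit,
                                           simplify = FALSE)))
  }
  data.frame(
    thickness_um = rep(b$thickness_nm, b$count) / 1000 *
      scheme$thickness_scale,
    kind = rep(b$kind, b$count),
    stringsAsFactors = FALSE)
}

#' Per-section depth table
#'
#' @param scheme a [sectioning_scheme()].
#' @return data.frame `index` (1-based from the block face), `z_start`,
#'   `z_end` (um, half-open `(z_start, z_end]` intervals that abut
#'   exactly), `kind`.
#' @export
section_table <- function(scheme) {
  ex <- expand_scheme(scheme)
  z_end <- cumsum(ex$thickness_um)
  data.frame(index = seq_len(nrow(ex)),
             z_start = c(0, z_end[-length(z_end)]),
             z_end = z_end,
             kind = ex$kind,
             stringsAsFactors = FALSE)
}

#' Number of sections in a scheme (after repeat expansion)
#' @param scheme a [sectioning_scheme()].
#' @return integer.
#' @export
n_sections <- function(scheme) nrow(expand_scheme(scheme))

#' Total depth of a scheme in micrometres
#' @param scheme a [sectioning_scheme()].
#' @return numeric, um.
#' @export
total_depth <- function(scheme) sum(expand_scheme(scheme)$thickness_um)

#' Depth interval of one section
#'
#' @param scheme a [sectioning_scheme()].
#' @param section_index 1-based index from the block face.
#' @return numeric length-2: `(z_start, z_end]` in um.
#' @export
depth_of <- function(scheme, section_index) {
  tab <- section_table(scheme)
  section_index <- as.integer(section_index)
  if (section_index < 1L || section_index > nrow(tab)) {
    stop(sprintf("section index out of range: scheme has %d sections",
                 nrow(tab)), call. = FALSE)
  }
  c(z_start = tab$z_start[section_index], z_end = tab$z_end[section_index])
}

#' Alternating thick/thin sectioning scheme
#'
#' The screening strategy for a target tens of micrometres deep: an
#' approach run of 500 nm thick sections for light-microscopy correlation,
#' followed by repeated series of thin EM sections interleaved with thick
#' correlation sections. The defaults reproduce the published run of this
#' strategy: 180 approach sections then 10 series of 10 x 60 nm thin + 2 x
#' 500 nm thick.
#'
#' @param approach_count number of 500 nm approach sections (>= 0).
#' @param n_series number of repeated thin+thick series.
#' @param thin_per_series,thin_nm thin EM sections per series and their
#'   thickness (nm).
#' @param thick_per_series,thick_nm thick LM sections per series and their
#'   thickness (nm).
#' @return A [sectioning_scheme()].
#' @export
alternating_scheme <- function(approach_count = 180L, n_series = 10L,
                               thin_per_series = 10L, thin_nm = 60,
                               thick_per_series = 2L, thick_nm = 500) {
  stopifnot(approach_count >= 0L)
  unit <- data.frame(count = c(thin_per_series, thick_per_series),
                     thickness_nm = c(thin_nm, thick_nm),
                     kind = c("THIN_EM", "THICK_LM"),
                     stringsAsFactors = FALSE)
  if (approach_count > 0L) {
    blocks <- data.frame(count = approach_count, thickness_nm = thick_nm,
                         kind = "THICK_LM", stringsAsFactors = FALSE)
    sectioning_scheme(blocks, repeat_unit = unit, repeat_count = n_series)
  } else {
    # no approach run: express the series as plain blocks
    sectioning_scheme(do.call(rbind, replicate(n_series, unit,
                                               simplify = FALSE)))
  }
}

#' Sections needed to cover a depth range
#'
#' @param z_range numeric length-2, um, increasing.
#' @param thickness_nm section thickness, nm.
#' @return integer: `ceiling(range length / thickness)`.
#' @export
sections_covering <- function(z_range, thickness_nm) {
  z_range <- as.numeric(z_range)
  stopifnot(length(z_range) == 2L, thickness_nm > 0)
  if (z_range[2] <= z_range[1]) {
    stop("z_range must be increasing and non-degenerate", call. = FALSE)
  }
  as.integer(ceiling((z_range[2] - z_range[1]) / (thickness_nm / 1000) -
                       1e-9))
}

#' Write a sectioning scheme to a YAML file
#'
#' @param scheme a [sectioning_scheme()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "sectioning_scheme"))
  rows <- function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(count = df$count[i], thickness_nm = df$thickness_nm[i],
           kind = df$kind[i])
    })
  }
  yaml::write_yaml(list(
    blocks = rows(scheme$blocks),
    repeat_unit = if (!is.null(scheme$repeat_unit)) rows(scheme$repeat_unit),
    repeat_count = scheme$repeat_count,
    thickness_scale = scheme$thickness_scale), path)
  invisible(path)
}

#' Read a sectioning scheme written by [write_scheme()]
#'
#' @param path file path.
#' @return A [sectioning_scheme()].
#' @export
read_scheme <- function(path) {
  p <- yaml::read_yaml(path)
  to_df <- function(lst) {
    do.call(rbind, lapply(lst, function(b) {
      data.frame(count = as.integer(b$count),
                 thickness_nm = as.numeric(b$thickness_nm),
                 kind = as.character(b$kind), stringsAsFactors = FALSE)
    }))
  }
  sectioning_scheme(to_df(p$blocks),
                    repeat_unit = if (!is.null(p$repeat_unit)) {
                      to_df(p$repeat_unit)
                    },
                    repeat_count = p$repeat_count %||% 0L,
                    thickness_scale = p$thickness_scale %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
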