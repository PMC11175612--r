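#' Containers for the acquisition layer
#'
#' \code{image_stack} wraps a 3-D grayscale array (frame, row, column) with
#' its acquisition metadata; \code{roi_rect} is a rectangle in 0-based
#' half-open pixel coordinates (rows \code{[row0, row1)}, columns
#' \code{[col0, col1)}); \code{roi_set} is a list of labelled rectangles;
#' \code{raw_trace} holds a per-frame mean grey value (MGV) series anchored
#' in hours after egg laying (hAEL).
#'
#' @param frames numeric array, dim = (n_frames, rows, cols).
#' @param frame_rate frames per second.
#' @param record_start hAEL of the first frame.
#' @return the corresponding object.
#' @export
image_stack <- function(frames, frame_rate, record_start = 0) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[1] >= 1L, frame_rate > 0, all(is.finite(frames)))
  structure(list(frames = frames, frame_rate = frame_rate,
                 record_start = record_start), class = "image_stack")
}

#' @rdname image_stack
#' @param row0,row1,col0,col1 0-based half-open pixel bounds.
#' @param label ROI label.
#' @export
roi_rect <- function(row0, row1, col0, col1, label = "roi") {
  stopifnot(row1 > row0, col1 > col0, row0 >= 0, col0 >= 0)
  structure(list(label = label, row0 = as.integer(row0),
                 row1 = as.integer(row1), col0 = as.integer(col0),
                 col1 = as.integer(col1)), class = "roi_rect")
}

#' @rdname image_stack
#' @param rois list of \code{roi_rect}; labels must be unique.
#' @export
roi_set <- function(rois) {
  stopifnot(all(vapply(rois, inherits, logical(1), "roi_rect")))
  labels <- vapply(rois, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate ROI labels: ",
                                  paste(unique(labels[duplicated(labels)]),
                                        collapse = ", "))
  structure(list(rois = rois), class = "roi_set")
}

#' @rdname image_stack
#' @param values numeric MGV per frame, finite.
#' @param embryo_label embryo identifier.
#' @param excluded exclusion flag (e.g. ROI invaded by a hatched neighbour).
#' @param exclusion_reason free-text reason when excluded.
#' @export
raw_trace <- function(values, frame_rate, record_start = 0,
                      embryo_label = "embryo", excluded = FALSE,
                      exclusion_reason = NA_character_) {
  stopifnot(length(values) >= 1L, all(is.finite(values)), frame_rate > 0)
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 record_start = record_start, embryo_label = embryo_label,
                 excluded = isTRUE(excluded),
                 exclusion_reason = exclusion_reason), class = "raw_trace")
}

#' Read and write grayscale frame stacks as multi-page TIFF
#'
#' TIFF values are stored on the [0, 1] grid the format uses; intensities
#' outside that range are rescaled on write and the applied scale and offset
#' are recorded in the returned attributes (and can be undone on load).
#' Colour pages are converted to grayscale with BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param path TIFF file path.
#' @param frame_rate,record_start acquisition metadata to attach.
#' @param scale,offset linear intensity transform applied after reading:
#'   \code{intensity = value * scale + offset} (defaults leave the stored
#'   values untouched).
#' @return \code{load_stack}: an \code{image_stack}. \code{save_stack}: the
#'   applied \code{c(scale, offset)}, invisibly.
#' @export
load_stack <- function(path, frame_rate, record_start = 0, scale = 1,
                       offset = 0) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("unreadable TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  gray <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] < 3L) p <- p[, , 1L]
      else p <- 0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
    }
    if (!all(is.finite(p))) stop("non-finite pixels in frame ", i)
    p
  })
  shp <- dim(gray[[1L]])
  if (!all(vapply(gray, function(p) identical(dim(p), shp), logical(1)))) {
    stop("frames differ in shape")
  }
  frames <- array(0, dim = c(length(gray), shp[1], shp[2]))
  for (i in seq_along(gray)) frames[i, , ] <- gray[[i]]
  image_stack(frames * scale + offset, frame_rate = frame_rate,
              record_start = record_start)
}

#' @rdname load_stack
#' @param stack an \code{image_stack}.
#' @param bits_per_sample TIFF bit depth (8, 16 or 32).
#' @export
save_stack <- function(path, stack, bits_per_sample = 16) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$frames
  lo <- min(v); hi <- max(v)
  if (lo < 0 || hi > 1) {
    span <- if (hi > lo) hi - lo else 1
    scale <- span; offset <- lo
    v <- (v - lo) / span
    message(sprintf("intensities rescaled to [0,1] for TIFF: scale=%g offset=%g",
                    scale, offset))
  } else {
    scale <- 1; offset <- 0
  }
  pages <- lapply(seq_len(dim(v)[1]), function(f) v[f, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(c(scale = scale, offset = offset))
}

#' Load a rectangular ROI set
#'
#' Accepts either the package's JSON dialect (an array of objects with
#' \code{label} and 0-based half-open \code{row0/row1/col0/col1} bounds, or
#' ImageJ-style \code{x/y/width/height}) or an ImageJ ROI archive: a
#' \code{.zip} of \code{.roi} files, or a single \code{.roi}. Only rectangle
#' ROIs are accepted. ImageJ stores rectangles as (top, left, bottom, right)
#' big-endian shorts with an exclusive bottom/right, which maps directly onto
#' the package's half-open convention.
#'
#' @param path \code{.json}, \code{.zip} or \code{.roi} file.
#' @param frame_size optional \code{c(rows, cols)}; when given, ROIs outside
#'   the frame raise an error.
#' @return an \code{roi_set}.
#' @export
load_roiset <- function(path, frame_size = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rois <- switch(ext,
    json = load_roiset_json(path),
    zip = {
      exdir <- tempfile("roiset")
      files <- utils::unzip(path, exdir = exdir)
      on.exit(unlink(exdir, recursive = TRUE))
      lapply(sort(files), parse_imagej_roi)
    },
    roi = list(parse_imagej_roi(path)),
    stop("unsupported ROI format: .", ext)
  )
  set <- roi_set(rois)
  if (!is.null(frame_size)) {
    for (r in set$rois) {
      if (r$row1 > frame_size[1] || r$col1 > frame_size[2]) {
        stop("ROI '", r$label, "' extends outside the ", frame_size[1], "x",
             frame_size[2], " frame")
      }
    }
    ov <- roi_overlaps(set)
    if (length(ov)) warning("overlapping ROIs: ", paste(ov, collapse = "; "))
  }
  set
}

load_roiset_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(spec), function(i) {
    r <- spec[[i]]
    label <- r$label %||% sprintf("roi%02d", i)
    if (!is.null(r$row0)) {
      roi_rect(r$row0, r$row1, r$col0, r$col1, label = label)
    } else if (!is.null(r$x)) {
      roi_rect(r$y, r$y + r$height, r$x, r$x + r$width, label = label)
    } else {
      stop("ROI entry ", i, " has neither row0/row1/col0/col1 nor x/y/width/height")
    }
  })
}

# ImageJ .roi rectangle: magic "Iout", version (short), type byte at offset 6
# (1 = rectangle), then top/left/bottom/right as big-endian signed shorts at
# offsets 8/10/12/14; bottom and right are exclusive.
parse_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 16L || rawToChar(raw[1:4]) != "Iout") {
    stop("not an ImageJ ROI file: ", path)
  }
  type <- as.integer(raw[7L])
  if (type != 1L) stop("non-rectangular ImageJ ROI (type ", type,
                       ") in ", basename(path), "; only rectangles supported")
  be_short <- function(off) {
    readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L, endian = "big")
  }
  top <- be_short(8L); left <- be_short(10L)
  bottom <- be_short(12L); right <- be_short(14L)
  roi_rect(top, bottom, left, right,
           label = tools::file_path_sans_ext(basename(path)))
}

roi_overlaps <- function(set) {
  rois <- set$rois
  out <- character(0)
  if (length(rois) < 2L) return(out)
  for (i in seq_len(length(rois) - 1L)) for (j in (i + 1L):length(rois)) {
    a <- rois[[i]]; b <- rois[[j]]
    if (a$row0 < b$row1 && b$row0 < a$row1 &&
        a$col0 < b$col1 && b$col0 < a$col1) {
      out <- c(out, paste(a$label, b$label, sep = "/"))
    }
  }
  out
}

#' Extract per-ROI mean grey value traces from a stack
#'
#' For each ROI and frame, the arithmetic mean of the pixel intensities
#' inside the rectangle — the multi-measure step of the original ImageJ
#' workflow.
#'
#' @param stack an \code{image_stack}.
#' @param rois an \code{roi_set} (or a single \code{roi_rect}).
#' @return a list of \code{raw_trace}, one per ROI, frame-aligned.
#' @export
extract_mgv <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"))
  if (inherits(rois, "roi_rect")) rois <- roi_set(list(rois))
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(stack$frames)
  traces <- lapply(rois$rois, function(r) {
    if (r$row1 > d[2] || r$col1 > d[3]) {
      stop("ROI '", r$label, "' outside stack bounds")
    }
    sub <- stack$frames[, (r$row0 + 1L):r$row1, (r$col0 + 1L):r$col1,
                        drop = FALSE]
    raw_trace(rowMeans(sub, dims = 1L), frame_rate = stack$frame_rate,
              record_start = stack$record_start, embryo_label = r$label)
  })
  names(traces) <- vapply(rois$rois, `[[`, character(1), "label")
  traces
}

#' Read and write per-embryo trace tables
#'
#' Tab-separated tables with a strictly increasing \code{time_hAEL} column
#' and one column per embryo label. Metadata (frame rate, record start,
#' exclusion flags with reasons) is carried in a \code{#key: value} header
#' block so a write/read round trip preserves the traces exactly.
#'
#' @param traces list of \code{raw_trace} with a common timebase.
#' @param path output/input file.
#' @return \code{read_traces}: a named list of \code{raw_trace}.
#' @export
write_traces <- function(traces, path) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "raw_trace")))
  fr <- unique(vapply(traces, `[[`, numeric(1), "frame_rate"))
  rs <- unique(vapply(traces, `[[`, numeric(1), "record_start"))
  ns <- unique(vapply(traces, function(t) length(t$values), integer(1)))
  if (length(fr) != 1L || length(rs) != 1L || length(ns) != 1L) {
    stop("traces must share frame_rate, record_start and length")
  }
  labels <- vapply(traces, `[[`, character(1), "embryo_label")
  excluded <- labels[vapply(traces, `[[`, logical(1), "excluded")]
  reasons <- vapply(traces[vapply(traces, `[[`, logical(1), "excluded")],
                    `[[`, character(1), "exclusion_reason")
  header <- c(
    sprintf("#frame_rate: %.17g", fr),
    sprintf("#record_start: %.17g", rs),
    if (length(excluded)) sprintf("#excluded: %s",
      paste(sprintf("%s=%s", excluded, reasons), collapse = "; "))
  )
  times <- rs + (seq_len(ns) - 1L) / fr / 3600
  tab <- do.call(cbind, c(list(time_hAEL = times),
                          lapply(traces, `[[`, "values")))
  colnames(tab) <- c("time_hAEL", labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace table not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- regmatches(h, regexec("^#([^:]+): *(.*)$", h))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- kv[3L]
  }
  if (is.null(meta$frame_rate)) stop("missing #frame_rate header in ", path)
  fr <- as.numeric(meta$frame_rate)
  rs <- as.numeric(meta$record_start %||% "0")
  body <- lines[setdiff(seq_along(lines), hdr)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (anyNA(tab)) {
    bad <- which(is.na(tab), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", bad[1L], ", column '",
         colnames(tab)[bad[2L]], "' in ", path)
  }
  if (!"time_hAEL" %in% colnames(tab)) stop("no time_hAEL column in ", path)
  times <- tab$time_hAEL
  if (any(diff(times) <= 0)) stop("time_hAEL column is not strictly increasing")
  excl <- list()
  if (!is.null(meta$excluded)) {
    for (e in strsplit(meta$excluded, "; *")[[1L]]) {
      kv <- strsplit(e, "=", fixed = TRUE)[[1L]]
      excl[[kv[1L]]] <- kv[2L]
    }
  }
  labels <- setdiff(colnames(tab), "time_hAEL")
  traces <- lapply(labels, function(lab) {
    raw_trace(tab[[lab]], frame_rate = fr, record_start = rs,
              embryo_label = lab, excluded = lab %in% names(excl),
              exclusion_reason = excl[[lab]] %||% NA_character_)
  })
  names(traces) <- labels
  traces
}

#' Convert a frame index to hours after egg laying
#'
#' \code{hAEL = record_start + frame / frame_rate / 3600} with 0-based frames.
#'
#' @param frame 0-based frame index.
#' @param frame_rate frames per second.
#' @param record_start hAEL of frame 0.
#' @return time in hAEL.
#' @export
frame_to_hael <- function(frame, frame_rate, record_start = 0) {
  record_start + frame / frame_rate / 3600
}
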