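# Event-stream file I/O, slicing, label alignment, balancing and splitting.

.dialectFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("feather", "arrow", "ipc")) "arrow" else "csv"
}

#' Read an event stream from disk
#'
#' Two dialects are supported. \code{"csv"}: a plain-text file with a
#' \code{# width=W height=H} comment line followed by a \code{t,x,y,p}
#' header and integer columns. \code{"arrow"}: an Arrow IPC (Feather) file
#' with four typed columns \code{t,x,y,p} and \code{width}/\code{height}
#' recorded in the schema metadata. The dialect defaults from the file
#' extension. Events are re-sorted by timestamp on read.
#'
#' @param path file to read.
#' @param dialect \code{"csv"} or \code{"arrow"} (default: from extension).
#' @param width,height sensor geometry, overriding any geometry stored in
#'   the file (required when the file carries none).
#' @return An \linkS4class{EventStream}.
#' @seealso [writeEvents()]
#' @export
readEvents <- function(path, dialect = .dialectFromPath(path),
                       width = NULL, height = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "arrow") {
    tbl <- arrow::read_feather(path, as_data_frame = FALSE)
    meta <- tbl$metadata
    if (is.null(width)) width <- as.numeric(meta[["width"]])
    if (is.null(height)) height <- as.numeric(meta[["height"]])
    ev <- as.data.frame(tbl)
  } else {
    first <- readLines(path, n = 1L)
    skip <- 0L
    if (length(first) == 1L && startsWith(first, "#")) {
      m <- regmatches(first, gregexpr("(width|height)=([0-9.]+)", first))[[1]]
      kv <- strsplit(m, "=", fixed = TRUE)
      for (p in kv) {
        if (p[1] == "width" && is.null(width)) width <- as.numeric(p[2])
        if (p[1] == "height" && is.null(height)) height <- as.numeric(p[2])
      }
      skip <- 1L
    }
    if (length(readLines(path, n = skip + 1L)) <= skip) {
      ev <- data.frame(t = numeric(), x = numeric(), y = numeric(),
                       p = numeric())
    } else {
      ev <- as.data.frame(data.table::fread(path, skip = skip, header = TRUE))
      need <- c("t", "x", "y", "p")
      if (!all(need %in% names(ev)))
        stop("malformed event file (expected header t,x,y,p): ", path)
      for (nm in need)
        if (!is.numeric(ev[[nm]]))
          ev[[nm]] <- suppressWarnings(as.numeric(ev[[nm]]))
      bad <- which(!stats::complete.cases(ev[need]))
      if (length(bad))
        stop(sprintf("malformed row %d in %s", bad[1] + skip + 1L, path))
    }
  }
  if (is.null(width) || is.null(height) || is.na(width) || is.na(height))
    stop("sensor geometry not found in file; pass width/height")
  EventStream(ev, width = width, height = height)
}

#' Write an event stream to disk
#'
#' @param stream an \linkS4class{EventStream}.
#' @param path output file; dialect chosen from the extension unless given.
#' @param dialect \code{"csv"} or \code{"arrow"}.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(stream, path, dialect = .dialectFromPath(path)) {
  stopifnot(is(stream, "EventStream"))
  ev <- stream@events
  if (dialect == "arrow") {
    tbl <- arrow::arrow_table(
      t = as.integer(ev$t), x = as.integer(ev$x),
      y = as.integer(ev$y), p = as.integer(ev$p))
    tbl$metadata <- list(width = as.character(stream@width),
                         height = as.character(stream@height))
    arrow::write_feather(tbl, path)
  } else {
    con <- file(path, "w")
    writeLines(sprintf("# width=%g height=%g", stream@width, stream@height),
               con)
    close(con)
    data.table::fwrite(
      data.frame(t = as.integer(ev$t), x = as.integer(ev$x),
                 y = as.integer(ev$y), p = as.integer(ev$p)),
      path, append = TRUE, col.names = TRUE)
  }
  invisible(path)
}

#' Slice an event stream to a half-open time window
#'
#' Returns the events with \eqn{t \in [t0, t1)}. Timestamps are preserved
#' unless \code{rezero = TRUE}, in which case \code{t0} is subtracted from
#' every timestamp and the span starts at 0.
#'
#' @param stream an \linkS4class{EventStream}.
#' @param t0,t1 window bounds in microseconds, \code{t0 < t1}.
#' @param rezero subtract \code{t0} from the result.
#' @return An \linkS4class{EventStream} spanning \code{[t0, t1)}.
#' @export
sliceStream <- function(stream, t0, t1, rezero = FALSE) {
  stopifnot(is(stream, "EventStream"))
  if (t0 >= t1) stop("need t0 < t1")
  ev <- stream@events
  keep <- ev$t >= t0 & ev$t < t1
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  if (rezero) {
    ev$t <- ev$t - t0
    EventStream(ev, stream@width, stream@height, tStart = 0, tEnd = t1 - t0)
  } else {
    EventStream(ev, stream@width, stream@height, tStart = t0, tEnd = t1)
  }
}

.checkIntervals <- function(intervals) {
  need <- c("tStart", "tEnd", "label")
  if (!all(need %in% names(intervals)))
    stop("intervals need columns tStart, tEnd, label")
  if (any(intervals$tStart >= intervals$tEnd))
    stop("intervals must satisfy tStart < tEnd")
  o <- order(intervals$tStart)
  iv <- intervals[o, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv$tEnd[-nrow(iv)] > iv$tStart[-1L]))
    stop("intervals overlap")
  iv
}

#' Align annotated label intervals to an event stream
#'
#' Cuts the stream at each labelled interval, yielding one
#' \linkS4class{LabeledSegment} per interval (in interval order). Segments
#' covering no events are retained; their emptiness is reported via the
#' \code{empty} attribute on the returned list.
#'
#' @param stream an \linkS4class{EventStream}.
#' @param intervals data.frame with columns \code{tStart}, \code{tEnd}
#'   (microseconds), \code{label}, and optionally \code{userId}, \code{eye}.
#'   Intervals must not overlap.
#' @param rezero rezero each segment to start at 0 (default TRUE, so every
#'   segment encodes from bin 0).
#' @return list of \linkS4class{LabeledSegment}.
#' @export
alignLabels <- function(stream, intervals, rezero = TRUE) {
  iv <- .checkIntervals(intervals)
  if (is.null(iv$userId)) iv$userId <- 1L
  if (is.null(iv$eye)) iv$eye <- "left"
  segs <- lapply(seq_len(nrow(iv)), function(i) {
    LabeledSegment(sliceStream(stream, iv$tStart[i], iv$tEnd[i],
                               rezero = rezero),
                   label = iv$label[i], userId = iv$userId[i], eye = iv$eye[i])
  })
  attr(segs, "empty") <- vapply(segs, function(s) nEvents(s) == 0L, TRUE)
  segs
}

#' Balance classes by seeded downsampling
#'
#' Draws exactly \code{nPerClass} segments per class without replacement,
#' deterministically for a given seed. Selected segments keep their original
#' relative order.
#'
#' @param segments list of \linkS4class{LabeledSegment}.
#' @param nPerClass target per-class count.
#' @param seed RNG seed.
#' @return list of \code{2 * nPerClass} segments.
#' @export
balanceClasses <- function(segments, nPerClass, seed = 1L) {
  labels <- vapply(segments, segmentLabel, "")
  keep <- withr::with_seed(seed, {
    unlist(lapply(c("fixation", "saccade"), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) < nPerClass)
        stop(sprintf("class '%s' has only %d segments (< %d)", cl,
                     length(idx), nPerClass))
      sort(sample(idx, nPerClass))
    }))
  })
  segments[sort(keep)]
}

#' Split segments into train and test sets by participant
#'
#' @param segments list of \linkS4class{LabeledSegment}.
#' @param trainUsers,testUsers disjoint integer vectors of user ids.
#' @return list with elements \code{train} and \code{test}; segments of
#'   unlisted users are excluded with a warning.
#' @export
splitByUser <- function(segments, trainUsers, testUsers) {
  if (length(intersect(trainUsers, testUsers)))
    stop("trainUsers and testUsers must be disjoint")
  users <- vapply(segments, userId, 1L)
  unassigned <- setdiff(unique(users), c(trainUsers, testUsers))
  if (length(unassigned))
    warning("excluding segments of unlisted users: ",
            paste(sort(unassigned), collapse = ", "))
  list(train = segments[users %in% trainUsers],
       test = segments[users %in% testUsers])
}

#' Read / write label-interval tables
#'
#' CSV with columns \code{tStart,tEnd,label,userId,eye}.
#'
#' @param path file path.
#' @return data.frame of intervals.
#' @export
readLabels <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' @rdname readLabels
#' @param intervals data.frame of intervals.
#' @export
writeLabels <- function(intervals, path) {
  data.table::fwrite(intervals, path)
  invisible(path)
}
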