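#' Peak threshold (tXXwYY)
#'
#' A window of \code{w} consecutive (unmasked) cytosines is footprint
#' positive when at least a fraction \code{t} of them are converted. The
#' default t40w50 requires 40 percent conversion over 50 consecutive
#' cytosines — below the ~58 percent single-strand conversion efficiency
#' (so genuine footprints are kept) and wide enough that sporadic breathing
#' conversions cannot assemble a positive window.
#'
#' @param t minimum conversion fraction, in (0, 1].
#' @param w window size in consecutive cytosines (>= 2).
#' @return An object of class \code{PeakThreshold}.
#' @export
peak_threshold <- function(t = 0.40, w = 50L) {
  stopifnot(t > 0, t <= 1, w >= 2)
  structure(list(t = t, w = as.integer(w)), class = "PeakThreshold")
}

#' Parse a threshold string such as "t40w50"
#'
#' @param text threshold in \code{tXXwYY} notation (XX percent conversion
#'   over YY consecutive cytosines).
#' @return a \code{\link{peak_threshold}}.
#' @export
parse_threshold <- function(text) {
  m <- regmatches(text, regexec("^t([0-9]+)w([0-9]+)$", text))[[1L]]
  if (length(m) != 3L) {
    stop("malformed threshold '", text,
         "': expected tXXwYY, e.g. t40w50 ",
         "(XX = minimum % cytosines converted, YY = window size in ",
         "consecutive cytosines)")
  }
  peak_threshold(as.numeric(m[2L]) / 100, as.integer(m[3L]))
}

#' @export
format.PeakThreshold <- function(x, ...) {
  sprintf("t%dw%d", as.integer(round(x$t * 100)), x$w)
}

#' @export
print.PeakThreshold <- function(x, ...) {
  cat(sprintf("PeakThreshold %s (>= %d%% converted over %d consecutive cytosines)\n",
              format(x), as.integer(round(x$t * 100)), x$w))
  invisible(x)
}

.empty_footprints <- function() {
  data.frame(read_id = character(0), strand = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             n_cytosines_in_peak = integer(0),
             n_converted_in_peak = integer(0),
             conversion_fraction = numeric(0), stringsAsFactors = FALSE)
}

#' Call footprints on one conversion track
#'
#' Masked positions are removed from the consecutive-cytosine sequence,
#' then a window of \code{w} cytosines slides one cytosine at a time over
#' the whole read (not just the homology window). Windows with conversion
#' fraction \code{>= t} are positive; maximal runs of consecutive positive
#' windows merge into one peak whose boundaries are trimmed to the
#' outermost converted cytosines within the run's coverage. Footprint
#' length is \code{end - start} (the 3' minus the 5' boundary position).
#' Reads with fewer than \code{w} unmasked cytosines, or with an unknown
#' strand call, yield no footprints.
#'
#' @param track a \code{\link{call_conversions}} track.
#' @param threshold a \code{\link{peak_threshold}}.
#' @return data.frame of footprints (possibly 0-row): read_id, strand,
#'   start, end (0-based reference positions of the boundary cytosines,
#'   closed), length, cytosine/converted counts and conversion fraction
#'   over the peak.
#' @export
call_peaks <- function(track, threshold = peak_threshold()) {
  stopifnot(inherits(threshold, "PeakThreshold"))
  if (track$strand_call == "unknown") return(.empty_footprints())
  keep <- track$status != "masked"
  p <- track$positions[keep]
  conv <- track$status[keep] == "converted"
  n <- length(p)
  w <- threshold$w
  if (n < w) return(.empty_footprints())
  cs <- cumsum(c(0L, conv))
  winsum <- cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]
  positive <- which(winsum >= threshold$t * w - 1e-9)
  if (length(positive) == 0L) return(.empty_footprints())
  runs <- split(positive, cumsum(c(1L, diff(positive) != 1L)))
  out <- lapply(runs, function(idx) {
    lo <- idx[1L]
    hi <- idx[length(idx)] + w - 1L
    conv_in <- which(conv[lo:hi]) + lo - 1L
    if (length(conv_in) == 0L) return(NULL)
    a <- conv_in[1L]
    b <- conv_in[length(conv_in)]
    data.frame(read_id = track$read_id, strand = track$strand_call,
               start = p[a], end = p[b], length = p[b] - p[a],
               n_cytosines_in_peak = b - a + 1L,
               n_converted_in_peak = sum(conv[a:b]),
               conversion_fraction = sum(conv[a:b]) / (b - a + 1L),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(.empty_footprints())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call footprints across a set of tracks
#'
#' @param tracks list of tracks.
#' @param threshold a \code{\link{peak_threshold}}.
#' @return combined footprint data.frame.
#' @export
call_peaks_all <- function(tracks, threshold = peak_threshold()) {
  out <- lapply(tracks, call_peaks, threshold = threshold)
  out <- out[vapply(out, nrow, integer(1L)) > 0L]
  if (length(out) == 0L) return(.empty_footprints())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize peak calling over a grid of thresholds
#'
#' One pass over the tracks per threshold; reports, per threshold and
#' strand, the percentage of reads with at least one footprint and a
#' footprint length summary. Used to choose an operating threshold by
#' comparing sensitivity (top strand) against background (bottom strand).
#'
#' @param tracks list of tracks.
#' @param thresholds list of \code{\link{peak_threshold}} objects (or
#'   tXXwYY strings).
#' @return data.frame with columns threshold, t, w, strand,
#'   n_total_reads, n_peak_reads, percent_peak, n_footprints,
#'   mean_length, sd_length.
#' @export
threshold_grid <- function(tracks, thresholds) {
  stopifnot(length(thresholds) >= 1L)
  thresholds <- lapply(thresholds, function(th) {
    if (is.character(th)) parse_threshold(th) else th
  })
  strand_calls <- vapply(tracks, `[[`, character(1L), "strand_call")
  rows <- lapply(thresholds, function(th) {
    fp <- call_peaks_all(tracks, th)
    do.call(rbind, lapply(c("top", "bottom"), function(s) {
      n_total <- sum(strand_calls == s)
      fps <- fp[fp$strand == s, , drop = FALSE]
      n_peak <- length(unique(fps$read_id))
      data.frame(threshold = format(th), t = th$t, w = th$w, strand = s,
                 n_total_reads = n_total, n_peak_reads = n_peak,
                 percent_peak = if (n_total > 0)
                   100 * n_peak / n_total else NA_real_,
                 n_footprints = nrow(fps),
                 mean_length = if (nrow(fps) > 0)
                   mean(fps$length) else NA_real_,
                 sd_length = if (nrow(fps) > 1)
                   stats::sd(fps$length) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detection floor implied by a reference's cytosine spacing
#'
#' The smallest footprint a threshold can call spans one window of
#' \code{w} consecutive cytosines, so its genomic extent depends on local
#' cytosine density. Returns the range of nt spans (last minus first
#' position) over all windows of \code{w} consecutive cytosines of the
#' chosen strand.
#'
#' @param reference a \code{\link{donor_reference}}.
#' @param threshold a \code{\link{peak_threshold}}.
#' @param strand \code{"top"} or \code{"bottom"}.
#' @return named numeric vector \code{c(min = , max = )} in nt.
#' @export
min_detectable_length <- function(reference, threshold = peak_threshold(),
                                  strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  pos <- if (strand == "top") reference$top_cytosine_positions else
    reference$bottom_cytosine_positions
  w <- threshold$w
  n <- length(pos)
  if (n < w) {
    stop("reference '", reference$name, "' has only ", n, " ", strand,
         "-strand cytosines, fewer than the window size ", w,
         ": no footprint can be called at this threshold")
  }
  spans <- pos[w:n] - pos[1L:(n - w + 1L)]
  c(min = min(spans), max = max(spans))
}

#' Write footprints as BED6
#'
#' Coordinates are 0-based half-open \code{[start, end + 1)} over the
#' closed cytosine interval; score is \code{round(1000 * conversion
#' fraction)}; strand is \code{+}/\code{-} for top/bottom.
#'
#' @param footprints footprint data.frame from \code{\link{call_peaks_all}}.
#' @param reference the \code{\link{donor_reference}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_footprints_bed <- function(footprints, reference, path) {
  lines <- if (nrow(footprints) > 0) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", reference$name, footprints$start,
            footprints$end + 1L, footprints$read_id,
            as.integer(round(1000 * footprints$conversion_fraction)),
            ifelse(footprints$strand == "top", "+", "-"))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write footprints as TSV with 1-based inclusive coordinates
#'
#' @param footprints footprint data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_footprints_tsv <- function(footprints, path) {
  tab <- footprints
  tab$start_1based <- tab$start + 1L
  tab$end_1based <- tab$end + 1L
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
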