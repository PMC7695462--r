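#' Percentage of reads containing a footprint
#'
#' The per-strand D-loop level: number of footprint-containing reads
#' divided by the total number of reads for that strand, times 100. A read
#' with several footprints counts once.
#'
#' @param n_peak_reads reads with at least one footprint.
#' @param n_total_reads all reads of the strand (> 0).
#' @return percentage (exact ratio; format at 2 decimals for display).
#' @export
percent_peak <- function(n_peak_reads, n_total_reads) {
  stopifnot(n_peak_reads >= 0, n_total_reads >= n_peak_reads)
  if (n_total_reads == 0) {
    stop("percent_peak is undefined for zero total reads")
  }
  100 * n_peak_reads / n_total_reads
}

#' Footprint length statistics
#'
#' Arithmetic mean and sample SD of footprint lengths (computed over
#' footprints, not reads), a histogram, and the fraction of footprints
#' exceeding a length cutoff.
#'
#' @param footprints footprint data.frame, or a numeric vector of lengths.
#' @param cutoff length cutoff in nt for the exceedance fraction.
#' @param binwidth histogram bin width in nt.
#' @return list with \code{n}, \code{mean}, \code{sd} (NA when undefined),
#'   \code{fraction_gt_cutoff}, \code{cutoff}, \code{histogram}
#'   (data.frame bin_start/bin_end/count) and \code{lengths}. An empty set
#'   gives \code{n = 0} with NA summaries, not zeroes.
#' @export
length_stats <- function(footprints, cutoff = 400, binwidth = 50) {
  lengths <- if (is.data.frame(footprints)) footprints$length else
    as.numeric(footprints)
  n <- length(lengths)
  if (n == 0L) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                fraction_gt_cutoff = NA_real_, cutoff = cutoff,
                histogram = data.frame(bin_start = numeric(0),
                                       bin_end = numeric(0),
                                       count = integer(0)),
                lengths = numeric(0)))
  }
  breaks <- seq(0, (max(lengths) %/% binwidth + 1) * binwidth,
                by = binwidth)
  counts <- as.integer(table(cut(lengths, breaks, right = FALSE)))
  list(n = n, mean = mean(lengths),
       sd = if (n > 1) stats::sd(lengths) else NA_real_,
       fraction_gt_cutoff = mean(lengths > cutoff), cutoff = cutoff,
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1L], count = counts),
       lengths = lengths)
}

#' Non-exclusive positional binning of footprints
#'
#' Bins tile the homology window from its start in \code{bin_size} nt
#' steps (the final partial bin is kept). Each footprint contributes one
#' count to every bin its closed interval [start, end] overlaps by at
#' least 1 nt; bin values are divided by the total footprint count, so
#' they need not sum to 1.
#'
#' @param footprints footprint data.frame.
#' @param reference a \code{\link{donor_reference}} (supplies the homology
#'   window).
#' @param bin_size bin width in nt.
#' @return data.frame: bin_start, bin_end (0-based half-open),
#'   n_footprints, fraction. All-zero with a warning when there are no
#'   footprints.
#' @export
bin_distribution <- function(footprints, reference, bin_size = 100) {
  h0 <- reference$homology_start
  h1 <- reference$homology_end
  starts <- seq(h0, h1 - 1L, by = bin_size)
  ends <- pmin(starts + bin_size, h1)
  bins <- IRanges::IRanges(start = starts + 1L, end = ends)
  n_fp <- nrow(footprints)
  if (n_fp == 0L) {
    warning("no footprints: returning an all-zero distribution")
    counts <- integer(length(starts))
  } else {
    fp <- IRanges::IRanges(start = footprints$start + 1L,
                           end = footprints$end + 1L)
    counts <- IRanges::countOverlaps(bins, fp, minoverlap = 1L)
  }
  data.frame(bin_start = starts, bin_end = ends, n_footprints = counts,
             fraction = if (n_fp > 0) counts / n_fp else
               rep(0, length(counts)))
}

#' Cluster footprint-containing reads 5' to 3'
#'
#' Orders reads by their first footprint's start, then end, then read id;
#' deterministic and a permutation of the input reads.
#'
#' @param footprints footprint data.frame.
#' @return character vector of read ids in display order.
#' @export
cluster_footprints <- function(footprints) {
  if (nrow(footprints) == 0L) return(character(0))
  first <- do.call(rbind, lapply(split(footprints, footprints$read_id),
                                 function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    d[1L, c("read_id", "start", "end")]
  }))
  first$read_id[order(first$start, first$end, first$read_id)]
}

#' Per-strand sample summary
#'
#' @param tracks list of tracks (kept reads).
#' @param footprints footprint data.frame for those tracks.
#' @param length_cutoff cutoff for the length-exceedance fraction, nt.
#' @return data.frame, one row per strand present: read and footprint
#'   counts, percent_peak, mean/sd length, fraction over the cutoff, and
#'   the number of reads with 2+ footprints.
#' @export
sample_summary <- function(tracks, footprints, length_cutoff = 400) {
  strand_calls <- vapply(tracks, `[[`, character(1L), "strand_call")
  do.call(rbind, lapply(c("top", "bottom"), function(s) {
    n_total <- sum(strand_calls == s)
    fps <- footprints[footprints$strand == s, , drop = FALSE]
    per_read <- table(fps$read_id)
    st <- length_stats(fps, cutoff = length_cutoff)
    data.frame(strand = s, n_total_reads = n_total,
               n_peak_reads = length(per_read),
               percent_peak = if (n_total > 0)
                 100 * length(per_read) / n_total else NA_real_,
               n_footprints = nrow(fps),
               mean_length = st$mean, sd_length = st$sd,
               fraction_gt_cutoff = st$fraction_gt_cutoff,
               length_cutoff = length_cutoff,
               n_multi_footprint_reads = sum(per_read >= 2L),
               stringsAsFactors = FALSE)
  }))
}

# Glyphs for the text footprint map. Inside a footprint, converted
# cytosines are "F" and unconverted ones "o", so a footprint is one
# contiguous glyph run and the text map parses back to exact intervals.
.MAP_GLYPHS <- c(not_covered = " ", unconverted = ".", converted = "c",
                 footprint = "F", footprint_unconverted = "o",
                 masked = "x")

#' Export a per-read footprint map
#'
#' One row per read over the strand's reference cytosines. Text glyphs:
#' space (cytosine not covered), \code{.} unconverted, \code{c} converted,
#' \code{F} converted-and-inside-a-footprint, \code{x} masked. Rows are
#' clustered 5' to 3' by first footprint (footprint-free reads follow in
#' id order). The optional PNG mirrors the published color semantics:
#' yellow cytosine columns, green conversions, red footprints, grey
#' masking. The homology window is demarcated in the text header.
#'
#' @param tracks list of tracks, all with the same strand call.
#' @param footprints footprint data.frame for those tracks.
#' @param reference a \code{\link{donor_reference}}.
#' @param txt_path output text-matrix path.
#' @param png_path optional output PNG path.
#' @return \code{txt_path}, invisibly.
#' @export
export_footprint_map <- function(tracks, footprints, reference, txt_path,
                                 png_path = NULL) {
  strands <- unique(vapply(tracks, `[[`, character(1L), "strand_call"))
  strands <- setdiff(strands, "unknown")
  if (length(strands) > 1L) {
    stop("mixed strands in one map (", paste(strands, collapse = ", "),
         "): export each strand separately")
  }
  strand <- if (length(strands) == 1L) strands else "top"
  all_pos <- if (strand == "top") reference$top_cytosine_positions else
    reference$bottom_cytosine_positions
  idx_of <- stats::setNames(seq_along(all_pos), all_pos)

  ordered_ids <- cluster_footprints(footprints)
  rest <- sort(setdiff(vapply(tracks, `[[`, character(1L), "read_id"),
                       ordered_ids))
  ids <- c(ordered_ids, rest)
  by_id <- stats::setNames(tracks, vapply(tracks, `[[`, character(1L),
                                          "read_id"))
  rows <- vapply(ids, function(id) {
    tr <- by_id[[id]]
    g <- rep(.MAP_GLYPHS[["not_covered"]], length(all_pos))
    if (length(tr$positions) > 0L) {
      j <- idx_of[as.character(tr$positions)]
      g[j] <- .MAP_GLYPHS[c(converted = "converted",
                            unconverted = "unconverted",
                            masked = "masked")[tr$status]]
      fps <- footprints[footprints$read_id == id, , drop = FALSE]
      for (k in seq_len(nrow(fps))) {
        inside <- tr$positions >= fps$start[k] & tr$positions <= fps$end[k]
        conv <- inside & tr$status == "converted"
        g[idx_of[as.character(tr$positions[conv])]] <-
          .MAP_GLYPHS[["footprint"]]
        g[idx_of[as.character(tr$positions[inside & !conv])]] <-
          .MAP_GLYPHS[["footprint_unconverted"]]
      }
    }
    paste(g, collapse = "")
  }, character(1L))

  header <- c("#dloopmapr footprint map",
              sprintf("#reference\t%s\tstrand\t%s", reference$name, strand),
              sprintf("#homology\t%d\t%d", reference$homology_start,
                      reference$homology_end),
              sprintf("#cytosine_positions\t%s",
                      paste(all_pos, collapse = ",")))
  writeLines(c(header, paste(ids, rows, sep = "\t")), txt_path)

  if (!is.null(png_path)) {
    cols <- matrix(0, nrow = max(length(ids), 1L), ncol = length(all_pos))
    palette <- list(" " = c(1, 1, 1), "." = c(1, 0.92, 0.55),
                    "c" = c(0.2, 0.7, 0.2), "F" = c(0.85, 0.1, 0.1),
                    "o" = c(0.95, 0.5, 0.5), "x" = c(0.6, 0.6, 0.6))
    img <- array(1, dim = c(max(length(ids), 1L), length(all_pos), 3L))
    for (r in seq_along(ids)) {
      g <- strsplit(rows[r], "", fixed = TRUE)[[1L]]
      for (ch in unique(g)) {
        j <- which(g == ch)
        img[r, j, 1L] <- palette[[ch]][1L]
        img[r, j, 2L] <- palette[[ch]][2L]
        img[r, j, 3L] <- palette[[ch]][3L]
      }
    }
    png::writePNG(img, png_path)
  }
  invisible(txt_path)
}

#' Parse a text footprint map back into footprint intervals
#'
#' Inverse of the text output of \code{\link{export_footprint_map}}: runs
#' of footprint glyphs per row are mapped back through the cytosine
#' position header.
#'
#' @param txt_path map path.
#' @return list with \code{positions}, \code{homology}, \code{strand} and
#'   \code{footprints} (data.frame read_id/start/end).
#' @export
parse_footprint_map <- function(txt_path) {
  lines <- readLines(txt_path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  strand <- strsplit(grep("^#reference", meta, value = TRUE),
                     "\t")[[1L]][4L]
  hom <- as.integer(strsplit(grep("^#homology", meta, value = TRUE),
                             "\t")[[1L]][2:3])
  pos <- as.integer(strsplit(strsplit(grep("^#cytosine_positions", meta,
                                           value = TRUE),
                                      "\t")[[1L]][2L], ",")[[1L]])
  fps <- lapply(body, function(ln) {
    parts <- strsplit(ln, "\t")[[1L]]
    g <- strsplit(parts[2L], "", fixed = TRUE)[[1L]]
    isf <- g %in% c(.MAP_GLYPHS[["footprint"]],
                    .MAP_GLYPHS[["footprint_unconverted"]])
    if (!any(isf)) return(NULL)
    r <- rle(isf)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(read_id = parts[1L], start = pos[starts[keep]],
               end = pos[ends[keep]], stringsAsFactors = FALSE)
  })
  fps <- fps[!vapply(fps, is.null, logical(1L))]
  list(positions = pos, homology = hom, strand = strand,
       footprints = if (length(fps) > 0)
         do.call(rbind, c(fps, list(make.row.names = FALSE))) else
           data.frame(read_id = character(0), start = integer(0),
                      end = integer(0)))
}
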