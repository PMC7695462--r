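#' Assign read strand from conversion asymmetry
#'
#' Non-denaturing bisulfite converts only the strand a read derives from,
#' so a read's origin is inferred from whether C-to-T or G-to-A conversions
#' (in reference orientation) predominate. Reads with too few conversions
#' of either kind (both counts below 6) or with counts within 10 percent of
#' each other (relative to the larger count) cannot be assigned.
#'
#' @param n_CT,n_GA conversion counts over unmasked positions.
#' @return \code{"top"}, \code{"bottom"} or \code{"unknown"}.
#' @export
assign_strand <- function(n_CT, n_GA) {
  stopifnot(n_CT >= 0, n_GA >= 0)
  if (n_CT < 6 && n_GA < 6) return("unknown")
  if (abs(n_CT - n_GA) <= 0.1 * max(n_CT, n_GA)) return("unknown")
  if (n_CT > n_GA) "top" else "bottom"
}

# Decompose one CIGAR against the reference: per-reference-position read
# base (NA over deletions), indel-derived mask ranges (+/- 5 nt, 1-based
# closed), and the reference span covered.
.walk_cigar <- function(pos, cigar, seq, buffer = 5L) {
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  read_chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  base_at <- rep(NA_character_, ref_width)  # index 1 == reference `pos`
  masks <- NULL
  if (grepl("^\\d+M$", cigar)) {
    base_at <- read_chars[seq_len(ref_width)]
  } else {
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = pos, with.ops = TRUE)[[1L]]
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
      cigar, with.ops = TRUE)[[1L]]
    ops <- names(rr)
    for (k in seq_along(ops)) {
      op <- ops[k]
      if (op %in% c("M", "=", "X")) {
        ri <- IRanges::start(rr)[k]:IRanges::end(rr)[k]
        qi <- IRanges::start(qr)[k]:IRanges::end(qr)[k]
        base_at[ri - pos + 1L] <- read_chars[qi]
      } else if (op == "D") {
        masks <- rbind(masks, c(IRanges::start(rr)[k] - buffer,
                                IRanges::end(rr)[k] + buffer))
      } else if (op == "I") {
        anchor <- IRanges::start(rr)[k] - 1L  # ref base before insertion
        masks <- rbind(masks, c(anchor - buffer, anchor + buffer))
      }
    }
  }
  list(base_at = base_at, masks = masks,
       ref_start = pos, ref_end = pos + ref_width - 1L)
}

# Status of the strand's cytosines covered by the read.
# positions: 0-based reference positions of candidate cytosines;
# converted_base / unconverted_base: e.g. "T"/"C" (top) or "A"/"G" (bottom).
.call_strand_status <- function(walk, positions, converted_base,
                                unconverted_base) {
  keep <- positions >= walk$ref_start - 1L & positions <= walk$ref_end - 1L
  p <- positions[keep]
  base <- walk$base_at[p + 2L - walk$ref_start]
  status <- rep("masked", length(p))  # deletions, mismatches to non-T/A
  status[!is.na(base) & base == converted_base] <- "converted"
  status[!is.na(base) & base == unconverted_base] <- "unconverted"
  if (!is.null(walk$masks)) {
    for (k in seq_len(nrow(walk$masks))) {
      hit <- p >= walk$masks[k, 1L] - 1L & p <= walk$masks[k, 2L] - 1L
      status[hit] <- "masked"
    }
  }
  list(positions = p, status = status)
}

#' Call per-read cytosine conversions against the donor reference
#'
#' For every reference cytosine (top-strand candidate, reference C) covered
#' by the read, the status is \code{converted} if the read shows T,
#' \code{unconverted} if C, and \code{masked} otherwise (mismatches are
#' treated as sequencing error, not evidence either way); symmetrically
#' G-to-A for the bottom-strand candidate. Reference positions within 5 nt
#' of any indel (both sides, endpoints inclusive; an insertion masks around
#' its anchor base) are masked. Conversion tallies are computed after
#' masking and the strand is then assigned via \code{\link{assign_strand}}.
#'
#' @param aln one alignment: list or one-row data.frame with
#'   \code{read_id}, \code{pos} (1-based leftmost), \code{cigar},
#'   \code{seq} (reference-orientation bases).
#' @param reference a \code{\link{donor_reference}}.
#' @param expected_length expected amplicon length in nt (defaults to the
#'   reference length).
#' @return An object of class \code{ReadConversionTrack}: positions and
#'   status of the assigned strand's cytosines (empty when the strand is
#'   unknown), both strands' candidate tracks, \code{n_CT}, \code{n_GA},
#'   masked count, expected and observed lengths.
#' @export
call_conversions <- function(aln, reference, expected_length = NULL) {
  stopifnot(inherits(reference, "DonorReference"))
  if (is.null(aln$pos) || is.na(aln$pos) || aln$pos < 1L ||
      is.null(aln$cigar) || aln$cigar == "*") {
    stop("read '", aln$read_id, "' is not aligned")
  }
  if (is.null(expected_length)) expected_length <- reference$length
  walk <- .walk_cigar(aln$pos, aln$cigar, toupper(aln$seq))
  if (walk$ref_end > reference$length) {
    stop("read '", aln$read_id, "' extends past reference '",
         reference$name, "' (", walk$ref_end, " > ", reference$length,
         "); wrong reference?")
  }
  ct <- .call_strand_status(walk, reference$top_cytosine_positions,
                            "T", "C")
  ga <- .call_strand_status(walk, reference$bottom_cytosine_positions,
                            "A", "G")
  n_CT <- sum(ct$status == "converted")
  n_GA <- sum(ga$status == "converted")
  strand <- assign_strand(n_CT, n_GA)
  chosen <- switch(strand, top = ct, bottom = ga,
                   list(positions = integer(0), status = character(0)))
  track <- list(read_id = aln$read_id,
                strand_call = strand,
                positions = chosen$positions,
                status = chosen$status,
                ct_positions = ct$positions, ct_status = ct$status,
                ga_positions = ga$positions, ga_status = ga$status,
                n_CT = n_CT, n_GA = n_GA,
                n_masked = sum(ct$status == "masked") +
                  sum(ga$status == "masked"),
                expected_length = expected_length,
                observed_length = nchar(aln$seq))
  class(track) <- "ReadConversionTrack"
  track
}

#' @export
print.ReadConversionTrack <- function(x, ...) {
  cat(sprintf(
    "ReadConversionTrack '%s': strand %s, n_CT %d, n_GA %d, %d masked, %d/%d nt\n",
    x$read_id, x$strand_call, x$n_CT, x$n_GA, x$n_masked,
    x$observed_length, x$expected_length))
  invisible(x)
}

#' Length filter for truncated reads
#'
#' Keeps a read iff its observed length is at least half the expected
#' amplicon length (boundary inclusive).
#'
#' @param track a \code{\link{call_conversions}} track.
#' @return logical.
#' @export
filter_read_length <- function(track) {
  stopifnot(track$expected_length > 0)
  track$observed_length >= 0.5 * track$expected_length
}

#' Conversion tracks for a set of aligned reads
#'
#' @param reads data.frame with \code{read_id}, \code{pos}, \code{cigar},
#'   \code{seq} (e.g. \code{simulate_dataset()$reads}).
#' @param reference a \code{\link{donor_reference}}.
#' @param expected_length see \code{\link{call_conversions}}.
#' @return list of \code{ReadConversionTrack}, named by read id.
#' @export
tracks_from_reads <- function(reads, reference, expected_length = NULL) {
  out <- lapply(seq_len(nrow(reads)), function(i) {
    call_conversions(as.list(reads[i, ]), reference, expected_length)
  })
  names(out) <- reads$read_id
  out
}

#' Conversion tracks from a SAM/BAM file
#'
#' SAM input is converted with \code{Rsamtools::asBam} and scanned; each
#' mapped record is turned into a track via \code{\link{call_conversions}}.
#'
#' @param path SAM or BAM file.
#' @param reference a \code{\link{donor_reference}}.
#' @param expected_length see \code{\link{call_conversions}}.
#' @return list of \code{ReadConversionTrack}.
#' @export
tracks_from_sam <- function(path, reference, expected_length = NULL) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "seq")))[[1L]]
  keep <- !is.na(res$pos)
  ids <- res$qname[keep]
  rnames <- as.character(res$rname)[keep]
  bad <- rnames != reference$name
  if (any(bad)) {
    stop("read '", ids[which(bad)[1L]], "' is aligned to reference '",
         rnames[which(bad)[1L]], "', not '", reference$name, "'")
  }
  seqs <- as.character(res$seq)[keep]
  pos <- res$pos[keep]
  cig <- res$cigar[keep]
  out <- lapply(seq_along(ids), function(i) {
    call_conversions(list(read_id = ids[i], pos = pos[i], cigar = cig[i],
                          seq = seqs[i]), reference, expected_length)
  })
  names(out) <- ids
  out
}

#' Conversion tracks from a plain per-read base-call table
#'
#' Alignment-free input dialect for testing and interchange: a TSV with
#' columns \code{read_id}, \code{pos} (0-based reference position of a
#' cytosine or guanine) and \code{base} (the read base observed there).
#' Optional columns \code{expected_length} and \code{observed_length}
#' (per read, first row wins) default to the reference length. Base
#' semantics match \code{\link{call_conversions}}; indel masking does not
#' apply (callers mask by reporting a base other than C/T or G/A).
#'
#' @param path TSV path.
#' @param reference a \code{\link{donor_reference}}.
#' @return list of \code{ReadConversionTrack}.
#' @export
tracks_from_tsv <- function(path, reference) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "pos", "base") %in% names(tab)))
  topC <- reference$top_cytosine_positions
  botG <- reference$bottom_cytosine_positions
  lapply(split(tab, tab$read_id), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    status_of <- function(pos_set, conv, unconv) {
      dd <- d[d$pos %in% pos_set, , drop = FALSE]
      st <- rep("masked", nrow(dd))
      st[toupper(dd$base) == conv] <- "converted"
      st[toupper(dd$base) == unconv] <- "unconverted"
      list(positions = as.integer(dd$pos), status = st)
    }
    ct <- status_of(topC, "T", "C")
    ga <- status_of(botG, "A", "G")
    n_CT <- sum(ct$status == "converted")
    n_GA <- sum(ga$status == "converted")
    strand <- assign_strand(n_CT, n_GA)
    chosen <- switch(strand, top = ct, bottom = ga,
                     list(positions = integer(0), status = character(0)))
    exp_len <- if ("expected_length" %in% names(d))
      d$expected_length[1L] else reference$length
    obs_len <- if ("observed_length" %in% names(d))
      d$observed_length[1L] else reference$length
    track <- list(read_id = d$read_id[1L], strand_call = strand,
                  positions = chosen$positions, status = chosen$status,
                  ct_positions = ct$positions, ct_status = ct$status,
                  ga_positions = ga$positions, ga_status = ga$status,
                  n_CT = n_CT, n_GA = n_GA,
                  n_masked = sum(ct$status == "masked") +
                    sum(ga$status == "masked"),
                  expected_length = exp_len, observed_length = obs_len)
    class(track) <- "ReadConversionTrack"
    track
  })
}

#' Write per-read track summaries as TSV
#'
#' One row per read: read id, strand call, conversion tallies, masked
#' count, and a run-length-encoded status string
#' (\code{<count><c|u|m>...}) over the assigned strand's cytosines.
#'
#' @param tracks list of tracks.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tracks_tsv <- function(tracks, path) {
  enc <- vapply(tracks, function(tr) {
    if (length(tr$status) == 0L) return("")
    r <- rle(substr(tr$status, 1L, 1L))
    paste0(r$lengths, r$values, collapse = "")
  }, character(1L))
  tab <- data.frame(
    read_id = vapply(tracks, `[[`, character(1L), "read_id"),
    strand_call = vapply(tracks, `[[`, character(1L), "strand_call"),
    n_CT = vapply(tracks, `[[`, numeric(1L), "n_CT"),
    n_GA = vapply(tracks, `[[`, numeric(1L), "n_GA"),
    masked_count = vapply(tracks, `[[`, numeric(1L), "n_masked"),
    status_rle = enc, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
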