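#' Construct a donor reference
#'
#' Represents the double-stranded donor molecule an amplicon is mapped to:
#' its sequence, the window of homology shared with the invading substrate,
#' and the cytosine positions of both strands indexed in one reference
#' coordinate system. Top-strand cytosines are the reference \code{C}
#' positions; bottom-strand cytosines (cytosines of the reverse complement)
#' are the reference \code{G} positions, so footprints from either strand
#' share one map axis.
#'
#' All coordinates are 0-based, half-open. \code{N} bases are never indexed
#' as cytosines.
#'
#' @param sequence DNA string (A/C/G/T/N, case-insensitive).
#' @param homology_start,homology_end homology window, 0-based half-open.
#' @param name reference identifier.
#' @return An object of class \code{DonorReference}: a list with the
#'   uppercase sequence, the homology window, and strictly increasing
#'   \code{top_cytosine_positions} / \code{bottom_cytosine_positions}.
#' @export
donor_reference <- function(sequence, homology_start, homology_end,
                            name = "donor") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_up <- toupper(sequence)
  chars <- strsplit(seq_up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop(sprintf("non-ACGTN character '%s' at position %d (0-based %d)",
                 chars[bad[1L]], bad[1L], bad[1L] - 1L))
  }
  len <- length(chars)
  if (!(homology_start < homology_end && homology_end <= len &&
        homology_start >= 0)) {
    stop("homology window out of bounds: need 0 <= start < end <= ",
         len)
  }
  obj <- list(
    name = name,
    sequence = seq_up,
    length = len,
    homology_start = as.integer(homology_start),
    homology_end = as.integer(homology_end),
    top_cytosine_positions = which(chars == "C") - 1L,
    bottom_cytosine_positions = which(chars == "G") - 1L
  )
  class(obj) <- "DonorReference"
  obj
}

#' Load a donor reference from a single-record FASTA file
#'
#' @param fasta_path path to a FASTA file containing exactly one record.
#' @param homology_window numeric length-2 vector, 0-based half-open
#'   \code{c(start, end)}. Defaults to the whole sequence.
#' @param name optional identifier; defaults to the FASTA record name.
#' @return A \code{\link{donor_reference}} object.
#' @export
load_reference <- function(fasta_path, homology_window = NULL, name = NULL) {
  if (!file.exists(fasta_path)) {
    stop("reference FASTA not found: ", fasta_path)
  }
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set))
  }
  seq <- as.character(set[[1L]])
  if (is.null(homology_window)) homology_window <- c(0L, nchar(seq))
  if (is.null(name)) {
    name <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  }
  donor_reference(seq, homology_window[1L], homology_window[2L], name = name)
}

#' Count cytosines in a DNA sequence
#'
#' Case-insensitive count of \code{C} characters; used to check substrate
#' homologies against their expected cytosine content before peak calling
#' (homologies with fewer than a window's worth of cytosines cannot host a
#' footprint).
#'
#' @param seq DNA string (may be empty).
#' @return integer count.
#' @export
count_cytosines <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  lengths(regmatches(seq, gregexpr("[Cc]", seq)))[[1L]]
}

#' Describe donor topology
#'
#' A covalently closed negatively supercoiled donor can only absorb a
#' limited amount of heteroduplex: each 10.4 bp of hDNA consumes one
#' negative supercoil, so the maximum footprint length is
#' \code{|sigma| * plasmid_length}. Linear donors are unconstrained (the
#' homology length is the only limit).
#'
#' @param sigma supercoiling density (supercoils per helical turn, signed).
#' @param plasmid_length donor length in nt.
#' @param bp_per_supercoil heteroduplex bp absorbed per supercoil (10.4).
#' @param mode \code{"supercoiled"} or \code{"linear"}.
#' @return An object of class \code{TopologyModel}.
#' @export
topology_model <- function(sigma = -0.07, plasmid_length = 3000,
                           bp_per_supercoil = 10.4,
                           mode = c("supercoiled", "linear")) {
  mode <- match.arg(mode)
  stopifnot(plasmid_length > 0, bp_per_supercoil > 0)
  obj <- list(sigma = sigma, plasmid_length = plasmid_length,
              bp_per_supercoil = bp_per_supercoil, mode = mode)
  class(obj) <- "TopologyModel"
  obj
}

#' Number of supercoils in the donor
#'
#' @param topology a \code{\link{topology_model}}.
#' @return \code{|sigma| * plasmid_length / bp_per_supercoil} (real).
#' @export
n_supercoils <- function(topology) {
  stopifnot(inherits(topology, "TopologyModel"))
  abs(topology$sigma) * topology$plasmid_length / topology$bp_per_supercoil
}

#' Maximum footprint length permitted by donor topology
#'
#' In supercoiled mode the cap is the number of supercoils times the bp of
#' heteroduplex each absorbs, i.e. \code{|sigma| * plasmid_length},
#' truncated to the homology length. In linear mode the homology length is
#' the only cap.
#'
#' @param topology a \code{\link{topology_model}}.
#' @param homology_length homology window length in nt (> 0).
#' @return maximum footprint length in nt (real; round for display).
#' @export
supercoil_capacity <- function(topology, homology_length) {
  stopifnot(inherits(topology, "TopologyModel"), homology_length > 0)
  if (topology$mode == "linear") {
    return(as.numeric(homology_length))
  }
  if (topology$sigma > 0) {
    stop("positively supercoiled donor (sigma > 0): capacity model is ",
         "defined only for negative supercoiling")
  }
  cap <- n_supercoils(topology) * topology$bp_per_supercoil
  min(as.numeric(homology_length), cap)
}

#' @export
print.DonorReference <- function(x, ...) {
  cat(sprintf(
    "DonorReference '%s': %d nt, homology [%d, %d) (%d nt), %d top / %d bottom strand cytosines\n",
    x$name, x$length, x$homology_start, x$homology_end,
    x$homology_end - x$homology_start,
    length(x$top_cytosine_positions), length(x$bottom_cytosine_positions)))
  invisible(x)
}

#' @export
print.TopologyModel <- function(x, ...) {
  if (x$mode == "supercoiled") {
    cat(sprintf(
      "TopologyModel: supercoiled, sigma = %g, L = %d nt (~%.0f supercoils, cap %.0f nt)\n",
      x$sigma, x$plasmid_length, n_supercoils(x),
      abs(x$sigma) * x$plasmid_length))
  } else {
    cat(sprintf("TopologyModel: linear, L = %d nt (no topological cap)\n",
                x$plasmid_length))
  }
  invisible(x)
}

#' Path to a packaged substrate or donor FASTA fixture
#'
#' Packaged sequences: the published substrate homologies
#' \code{"ds98-197"}, \code{"ds98-607"}, \code{"ds98-915"},
#' \code{"ds98-931"}, and \code{"donor_ds98-931_synthetic"} — a synthetic
#' 3,000 nt donor embedding the ds98-931 homology at positions
#' [1000, 1931) between randomly generated non-homologous flanks.
#'
#' @param which fixture name.
#' @return file path.
#' @export
dma_fixture <- function(which = c("ds98-931", "ds98-915", "ds98-607",
                                  "ds98-197", "donor_ds98-931_synthetic")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".fa"),
                      package = "dloopmapr", mustWork = TRUE)
  path
}

#' Homology window of the packaged synthetic donor
#'
#' @return integer length-2 vector, 0-based half-open.
#' @export
donor_homology_window <- function() c(1000L, 1931L)
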