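#' Length-law constructors for simulated D-loops
#'
#' \code{length_fixed} always emits \code{len}; \code{length_uniform} draws
#' uniformly between \code{min} and \code{max} (\code{max = NULL} means the
#' topology/homology cap, reproducing the broad length range seen on linear
#' donors); \code{length_truncnorm} draws from a normal truncated to
#' \code{[1, cap]}, the natural law for supercoiled donors where relaxation
#' concentrates lengths around the topological cap.
#'
#' @param len,min,max,mean,sd lengths in nt.
#' @return a length-model description consumed by
#'   \code{\link{simulate_dataset}}.
#' @export
length_fixed <- function(len) {
  stopifnot(len >= 1)
  structure(list(kind = "fixed", len = as.numeric(len)),
            class = "dma_length_model")
}

#' @rdname length_fixed
#' @export
length_uniform <- function(min = 100, max = NULL) {
  stopifnot(min >= 1, is.null(max) || max >= min)
  structure(list(kind = "uniform", min = as.numeric(min),
                 max = if (is.null(max)) NULL else as.numeric(max)),
            class = "dma_length_model")
}

#' @rdname length_fixed
#' @export
length_truncnorm <- function(mean = 210, sd = 50) {
  stopifnot(mean > 0, sd >= 0)
  structure(list(kind = "truncnorm", mean = as.numeric(mean),
                 sd = as.numeric(sd)),
            class = "dma_length_model")
}

#' Simulation parameters for synthetic bisulfite-footprinting datasets
#'
#' Defaults emulate the assay's measured operating point: 58 percent
#' per-cytosine conversion on the displaced strand, sporadic background
#' conversion on duplex DNA from transient breathing (0.02 per cytosine:
#' enough that under 5 percent of duplex-only reads fall below the
#' 6-conversion strand-assignment floor, as observed in real read pools,
#' yet orders of magnitude below any footprint window), roughly twofold
#' over-representation of bottom-strand reads (nicking of the converted
#' displaced strand depletes top-strand amplicons), supercoiling-capped
#' footprint lengths with 3'-biased positioning, and PacBio-style indels.
#'
#' @param n_molecules number of donor molecules (one read each).
#' @param dloop_fraction probability a molecule carries a D-loop.
#' @param topology a \code{\link{topology_model}}.
#' @param position_model \code{"three_prime_biased"} (linear ramp on the
#'   footprint 3' edge) or \code{"uniform"}.
#' @param length_model see \code{\link{length_fixed}} and friends.
#' @param conversion_efficiency per-cytosine C-to-T probability on the
#'   displaced strand inside the D-loop.
#' @param breathing_rate per-cytosine background conversion probability on
#'   duplex DNA (either strand).
#' @param bottom_to_top_read_ratio strand sampling bias; a read is
#'   top-strand with probability \code{1 / (1 + ratio)}; \code{0} samples
#'   top only.
#' @param indel_rate per-base probability of a 1-nt insertion or deletion.
#' @param truncation_fraction fraction of reads truncated below half their
#'   expected length (these fail the downstream length filter).
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return An object of class \code{SimulationConfig}.
#' @export
simulation_config <- function(n_molecules = 2000,
                              dloop_fraction = 0.15,
                              topology = topology_model(),
                              position_model = c("three_prime_biased",
                                                 "uniform"),
                              length_model = length_truncnorm(210, 50),
                              conversion_efficiency = 0.58,
                              breathing_rate = 0.02,
                              bottom_to_top_read_ratio = 2.0,
                              indel_rate = 0.001,
                              truncation_fraction = 0.01,
                              seed = 1L) {
  position_model <- match.arg(position_model)
  probs <- c(dloop_fraction, conversion_efficiency, breathing_rate,
             indel_rate, truncation_fraction)
  stopifnot(all(probs >= 0 & probs <= 1), n_molecules >= 0,
            bottom_to_top_read_ratio >= 0,
            inherits(topology, "TopologyModel"),
            inherits(length_model, "dma_length_model"))
  obj <- list(n_molecules = as.integer(n_molecules),
              dloop_fraction = dloop_fraction,
              topology = topology,
              position_model = position_model,
              length_model = length_model,
              conversion_efficiency = conversion_efficiency,
              breathing_rate = breathing_rate,
              bottom_to_top_read_ratio = bottom_to_top_read_ratio,
              indel_rate = indel_rate,
              truncation_fraction = truncation_fraction,
              seed = as.integer(seed))
  class(obj) <- "SimulationConfig"
  obj
}

# Draw one D-loop length under the configured law, capped to [1, cap].
.draw_length <- function(model, cap) {
  switch(model$kind,
    fixed = {
      if (model$len > cap) {
        stop("fixed length ", model$len, " exceeds capacity ", cap)
      }
      model$len
    },
    uniform = {
      hi <- if (is.null(model$max)) cap else min(model$max, cap)
      if (model$min > hi) {
        stop("uniform length minimum ", model$min,
             " exceeds capacity ", hi)
      }
      stats::runif(1L, model$min, hi)
    },
    truncnorm = {
      if (cap < 1) stop("capacity < 1 nt: no representable length")
      for (i in 1:100) {
        x <- stats::rnorm(1L, model$mean, model$sd)
        if (x >= 1 && x <= cap) return(x)
      }
      min(max(model$mean, 1), cap)  # pathological sd: clamp
    })
}

# Draw a footprint interval [s, e) inside the homology window.
.draw_interval <- function(config, reference, cap) {
  h0 <- reference$homology_start
  h1 <- reference$homology_end
  len <- min(round(.draw_length(config$length_model, cap)), h1 - h0)
  len <- max(len, 1L)
  ends <- (h0 + len):h1  # candidate exclusive 3' edges
  w <- if (config$position_model == "three_prime_biased") {
    seq_along(ends)  # linear ramp toward the homology 3' end
  } else {
    rep(1, length(ends))
  }
  e <- if (length(ends) == 1L) ends else sample(ends, 1L, prob = w)
  c(e - len, e)
}

# Inject 1-nt indels into a reference-orientation read sequence.
# Returns list(seq, cigar). `span` reference bases are covered.
.apply_indels <- function(chars, indel_rate) {
  span <- length(chars)
  n_ind <- stats::rbinom(1L, span, indel_rate)
  if (n_ind == 0L || span < 10L) {
    return(list(seq = paste(chars, collapse = ""),
                cigar = paste0(span, "M")))
  }
  at <- sort(sample(2:(span - 1L), min(n_ind, span - 2L)))
  is_del <- stats::runif(length(at)) < 0.5
  ops_len <- integer(0); ops_chr <- character(0)
  out <- character(0)
  prev <- 1L
  add_op <- function(len, chr) {
    if (len > 0L) { ops_len <<- c(ops_len, len); ops_chr <<- c(ops_chr, chr) }
  }
  for (k in seq_along(at)) {
    p <- at[k]
    if (is_del[k]) {           # read skips reference base p
      add_op(p - prev, "M")
      add_op(1L, "D")
      out <- c(out, chars[prev:(p - 1L)][seq_len(max(p - prev, 0L))])
      prev <- p + 1L
    } else {                   # extra read base after reference base p
      add_op(p - prev + 1L, "M")
      add_op(1L, "I")
      out <- c(out, chars[prev:p], sample(c("A", "C", "G", "T"), 1L))
      prev <- p + 1L
    }
  }
  add_op(span - prev + 1L, "M")
  if (prev <= span) out <- c(out, chars[prev:span])
  list(seq = paste(out, collapse = ""),
       cigar = paste0(ops_len, ops_chr, collapse = ""))
}

#' Simulate a bisulfite-footprinting dataset with ground truth
#'
#' Each molecule independently carries a D-loop with probability
#' \code{dloop_fraction}; D-loop intervals are drawn inside the homology
#' window under the configured position and length laws, capped by
#' \code{\link{supercoil_capacity}}. One read is emitted per molecule from
#' the top strand with probability \code{1 / (1 + ratio)}. Top-strand reads
#' convert each cytosine inside the D-loop with
#' \code{conversion_efficiency} and every other cytosine of their strand
#' with \code{breathing_rate}; bottom-strand reads (base-paired throughout)
#' convert only at \code{breathing_rate}, reported as G-to-A in reference
#' orientation. Indels and truncations are then applied, and reads are
#' emitted pre-aligned (leftmost position 1, CIGAR reflecting indels).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param reference a \code{\link{donor_reference}}.
#' @return An object of class \code{dma_simulation}: list with
#'   \code{reads} (data.frame: read_id, molecule_id, flag, pos, cigar,
#'   seq), \code{truth} (data.frame: molecule_id, read_id, has_dloop,
#'   dloop_start, dloop_end 0-based half-open, sampled_strand), the config
#'   and the reference name.
#' @export
simulate_dataset <- function(config, reference) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(reference, "DonorReference"))
  if (reference$homology_end <= reference$homology_start) {
    stop("empty homology window")
  }
  set.seed(config$seed)
  n <- config$n_molecules
  hl <- reference$homology_end - reference$homology_start
  cap <- floor(supercoil_capacity(config$topology, hl) + 1e-9)
  ref_chars <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
  topC <- reference$top_cytosine_positions       # 0-based
  botG <- reference$bottom_cytosine_positions
  L <- reference$length
  p_top <- 1 / (1 + config$bottom_to_top_read_ratio)

  reads <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    read_id <- sprintf("mol%06d", i)
    has_dloop <- stats::runif(1L) < config$dloop_fraction
    iv <- c(NA_integer_, NA_integer_)
    if (has_dloop) iv <- .draw_interval(config, reference, cap)
    strand <- if (stats::runif(1L) < p_top) "top" else "bottom"

    chars <- ref_chars
    if (strand == "top") {
      inside <- if (has_dloop) topC >= iv[1L] & topC < iv[2L] else
        rep(FALSE, length(topC))
      p <- ifelse(inside, config$conversion_efficiency,
                  config$breathing_rate)
      conv <- stats::runif(length(topC)) < p
      chars[topC[conv] + 1L] <- "T"
    } else {
      conv <- stats::runif(length(botG)) < config$breathing_rate
      chars[botG[conv] + 1L] <- "A"
    }

    if (config$truncation_fraction > 0 &&
        stats::runif(1L) < config$truncation_fraction) {
      keep_len <- max(10L, floor(stats::runif(1L, 0.10, 0.499) * L))
      chars <- chars[seq_len(keep_len)]
    }

    aln <- .apply_indels(chars, config$indel_rate)
    reads[[i]] <- data.frame(
      read_id = read_id, molecule_id = read_id,
      flag = if (strand == "top") 0L else 16L,
      pos = 1L, cigar = aln$cigar, seq = aln$seq,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      molecule_id = read_id, read_id = read_id, has_dloop = has_dloop,
      dloop_start = iv[1L], dloop_end = iv[2L], sampled_strand = strand,
      stringsAsFactors = FALSE)
  }
  out <- list(reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
              truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
              config = config, reference_name = reference$name)
  if (n == 0L) {
    out$reads <- data.frame(read_id = character(0),
                            molecule_id = character(0),
                            flag = integer(0), pos = integer(0),
                            cigar = character(0), seq = character(0))
    out$truth <- data.frame(molecule_id = character(0),
                            read_id = character(0), has_dloop = logical(0),
                            dloop_start = integer(0),
                            dloop_end = integer(0),
                            sampled_strand = character(0))
  }
  class(out) <- "dma_simulation"
  out
}

#' @export
print.dma_simulation <- function(x, ...) {
  cat(sprintf(
    "dma_simulation: %d reads on '%s' (%d with D-loop, %d top / %d bottom)\n",
    nrow(x$reads), x$reference_name, sum(x$truth$has_dloop),
    sum(x$truth$sampled_strand == "top"),
    sum(x$truth$sampled_strand == "bottom")))
  invisible(x)
}

#' Simulate a fully single-stranded spiked control
#'
#' Emulates the circular ssDNA spiked into a reaction to measure bisulfite
#' conversion efficiency: every cytosine of every read converts
#' independently with \code{conversion_efficiency}; there is no strand or
#' breathing logic.
#'
#' @param config a \code{\link{simulation_config}} (only
#'   \code{conversion_efficiency} and \code{seed} are used).
#' @param sequence the control DNA sequence.
#' @param n_reads number of reads.
#' @return list with \code{positions} (0-based cytosine positions),
#'   \code{converted} (n_reads x n_cytosines logical matrix) and
#'   \code{fraction_converted} per read.
#' @export
simulate_ssdna_control <- function(config, sequence, n_reads) {
  stopifnot(inherits(config, "SimulationConfig"), n_reads >= 0)
  set.seed(config$seed)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  pos <- which(chars == "C") - 1L
  m <- matrix(stats::runif(n_reads * length(pos)) <
                config$conversion_efficiency,
              nrow = n_reads)
  list(positions = pos, converted = m,
       fraction_converted = if (n_reads > 0 && length(pos) > 0)
         rowMeans(m) else numeric(0))
}

#' Write simulated reads as SAM
#'
#' Reads are emitted pre-aligned to the donor (POS 1-based, CIGAR carrying
#' injected indels); header declares the reference.
#'
#' @param sim a \code{\link{simulate_dataset}} result (or its \code{reads}
#'   data.frame).
#' @param reference the \code{\link{donor_reference}} reads align to.
#' @param path output SAM path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(sim, reference, path) {
  reads <- if (inherits(sim, "dma_simulation")) sim$reads else sim
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", reference$name,
                      reference$length))
  body <- if (nrow(reads) > 0) {
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            reads$read_id, reads$flag, reference$name, reads$pos,
            reads$cigar, reads$seq)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulation ground truth as BED (0-based half-open)
#'
#' @param sim a \code{\link{simulate_dataset}} result.
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
write_truth_bed <- function(sim, path) {
  tr <- sim$truth[sim$truth$has_dloop, , drop = FALSE]
  lines <- if (nrow(tr) > 0) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", sim$reference_name, tr$dloop_start,
            tr$dloop_end, tr$read_id,
            ifelse(tr$sampled_strand == "top", "+", "-"))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
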