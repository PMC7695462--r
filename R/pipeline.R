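#' Load a run configuration from YAML
#'
#' Keys: \code{reference} (FASTA path, or a packaged fixture name),
#' \code{homology_window} (two integers, 0-based half-open),
#' \code{threshold} (tXXwYY string), \code{expected_length} (optional),
#' \code{length_cutoff}, \code{bin_size}, and a \code{simulation} block
#' mirroring \code{\link{simulation_config}} arguments (with
#' \code{topology: {sigma, plasmid_length, bp_per_supercoil, mode}} and
#' \code{length_model: {kind, ...}} sub-blocks). Alternatively \code{sam}
#' points at an existing alignment file instead of simulating.
#'
#' @param path YAML file.
#' @return config list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}

.config_topology <- function(blk) {
  if (is.null(blk)) return(topology_model())
  topology_model(sigma = blk$sigma %||% -0.07,
                 plasmid_length = blk$plasmid_length %||% 3000,
                 bp_per_supercoil = blk$bp_per_supercoil %||% 10.4,
                 mode = blk$mode %||% "supercoiled")
}

.config_length_model <- function(blk) {
  if (is.null(blk)) return(length_truncnorm())
  switch(blk$kind %||% "truncnorm",
         fixed = length_fixed(blk$len),
         uniform = length_uniform(blk$min %||% 100, blk$max),
         truncnorm = length_truncnorm(blk$mean %||% 210, blk$sd %||% 50),
         stop("unknown length model kind: ", blk$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_simulation <- function(blk, seed) {
  args <- blk[intersect(names(blk),
                        c("n_molecules", "dloop_fraction",
                          "position_model", "conversion_efficiency",
                          "breathing_rate", "bottom_to_top_read_ratio",
                          "indel_rate", "truncation_fraction"))]
  args$topology <- .config_topology(blk$topology)
  args$length_model <- .config_length_model(blk$length_model)
  args$seed <- blk$seed %||% seed %||% 1L
  do.call(simulation_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full simulate/convert/call/profile pipeline
#'
#' Stages: load the reference (\code{refmodel}); simulate reads or read an
#' alignment file (\code{simulate}/\code{input}); build conversion tracks,
#' apply the truncation filter and assign strands (\code{convert}); call
#' footprints at the configured threshold (\code{peaks}); summarize and
#' export maps (\code{profile}). All artifacts are written under
#' \code{out_dir}; the run is deterministic given the seed. Stage failures
#' abort with the stage name.
#'
#' @param config config list (see \code{\link{load_run_config}}).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-strand \code{summary}, the
#'   read-accounting \code{counts} (input = kept + length-filtered +
#'   unknown-strand), \code{footprints}, \code{binned}, and output
#'   \code{paths}.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[dloopmapr] ", sprintf(...))

  reference <- .stage("refmodel", {
    ref_path <- config$reference %||% "donor_ds98-931_synthetic"
    if (!file.exists(ref_path)) {
      fixture <- system.file("extdata", paste0(ref_path, ".fa"),
                             package = "dloopmapr")
      if (nzchar(fixture)) ref_path <- fixture else
        stop("reference not found: ", config$reference)
    }
    win <- config$homology_window %||% donor_homology_window()
    load_reference(ref_path, as.integer(win))
  })
  threshold <- .stage("peaks",
                      parse_threshold(config$threshold %||% "t40w50"))

  paths <- list()
  sim <- NULL
  tracks <- .stage("convert", {
    if (!is.null(config$sam)) {
      tracks_from_sam(config$sam, reference, config$expected_length)
    } else {
      sim <- .stage("simulate", {
        scfg <- .config_simulation(config$simulation %||% list(),
                                   config$seed)
        simulate_dataset(scfg, reference)
      })
      paths$sam <- file.path(out_dir, "reads.sam")
      write_sam(sim, reference, paths$sam)
      paths$truth <- file.path(out_dir, "truth.bed")
      write_truth_bed(sim, paths$truth)
      tracks_from_reads(sim$reads, reference, config$expected_length)
    }
  })

  n_in <- length(tracks)
  keep_len <- vapply(tracks, filter_read_length, logical(1L))
  tracks_len <- tracks[keep_len]
  strands <- vapply(tracks_len, `[[`, character(1L), "strand_call")
  kept <- tracks_len[strands != "unknown"]
  counts <- list(n_input = n_in,
                 n_length_filtered = sum(!keep_len),
                 n_unknown_strand = sum(strands == "unknown"),
                 n_kept = length(kept),
                 n_kept_top = sum(strands == "top"),
                 n_kept_bottom = sum(strands == "bottom"))
  log_msg("reads: %d in, %d length-filtered, %d unknown strand, %d kept (%d top / %d bottom)",
          counts$n_input, counts$n_length_filtered,
          counts$n_unknown_strand, counts$n_kept, counts$n_kept_top,
          counts$n_kept_bottom)
  paths$tracks <- file.path(out_dir, "tracks.tsv")
  write_tracks_tsv(tracks, paths$tracks)

  footprints <- .stage("peaks", call_peaks_all(kept, threshold))
  paths$bed <- file.path(out_dir, "footprints.bed")
  write_footprints_bed(footprints, reference, paths$bed)
  paths$fp_tsv <- file.path(out_dir, "footprints.tsv")
  write_footprints_tsv(footprints, paths$fp_tsv)

  res <- .stage("profile", {
    summary <- sample_summary(kept, footprints,
                              config$length_cutoff %||% 400)
    binned <- suppressWarnings(
      bin_distribution(footprints, reference, config$bin_size %||% 100))
    paths$summary <- file.path(out_dir, "summary.tsv")
    utils::write.table(summary, paths$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$binned <- file.path(out_dir, "binned.tsv")
    utils::write.table(binned, paths$binned, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (s in c("top", "bottom")) {
      trs <- kept[vapply(kept, `[[`, character(1L),
                         "strand_call") == s]
      key <- paste0("map_", s)
      paths[[key]] <- file.path(out_dir, paste0("map_", s, ".txt"))
      export_footprint_map(trs,
                           footprints[footprints$strand == s, ,
                                      drop = FALSE],
                           reference, paths[[key]],
                           png_path = file.path(out_dir,
                                                paste0("map_", s,
                                                       ".png")))
    }
    list(summary = summary, binned = binned)
  })
  for (s in c("top", "bottom")) {
    row <- res$summary[res$summary$strand == s, ]
    log_msg("%s strand: %d/%d reads with footprint (%s%% peak at %s)",
            s, row$n_peak_reads, row$n_total_reads,
            ifelse(is.na(row$percent_peak), "NA",
                   sprintf("%.2f", row$percent_peak)),
            format(threshold))
  }
  invisible(list(summary = res$summary, binned = res$binned,
                 footprints = footprints, counts = counts,
                 tracks = tracks, kept = kept, simulation = sim,
                 reference = reference, threshold = threshold,
                 paths = paths))
}
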