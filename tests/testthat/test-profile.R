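test_that("percent_peak is the exact read fraction and rejects empty pools", {
  expect_equal(percent_peak(0, 100), 0)
  expect_equal(percent_peak(50, 200), 25)
  expect_error(percent_peak(0, 0), "undefined")
  expect_error(percent_peak(5, 3))
  # complement closes to exactly 100
  expect_equal(percent_peak(310, 2673) + percent_peak(2363, 2673), 100)
})

test_that("length statistics use footprint-level mean and sample SD", {
  one <- length_stats(c(200))
  expect_equal(one$mean, 200)
  expect_true(is.na(one$sd))  # SD undefined for a single footprint

  two <- length_stats(c(100, 300))
  expect_equal(two$mean, 200)
  expect_equal(two$sd, 141.4, tolerance = 1e-3)
  expect_equal(two$fraction_gt_cutoff, 0)  # default cutoff 400

  st <- length_stats(c(100, 450, 500, 390), cutoff = 400)
  expect_equal(st$fraction_gt_cutoff, 0.5)
  expect_equal(sum(st$histogram$count), 4)

  empty <- length_stats(numeric(0))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean))  # empty summary, not zeroes
})

test_that("binning is non-exclusive over 100 nt bins of the homology window", {
  ref <- donor_reference(strrep("A", 1000), 0, 1000)
  fp <- data.frame(read_id = "r", strand = "top", start = 150, end = 370,
                   length = 220, n_cytosines_in_peak = 10,
                   n_converted_in_peak = 10, conversion_fraction = 1)
  d <- bin_distribution(fp, ref, 100)
  expect_equal(nrow(d), 10)
  expect_equal(d$fraction[d$bin_start %in% c(100, 200, 300)], c(1, 1, 1))
  expect_equal(sum(d$fraction), 3)  # non-exclusive: overlapped bins only

  # duplication does not change the normalized distribution
  d2 <- bin_distribution(rbind(fp, fp), ref, 100)
  expect_equal(d2$fraction, d$fraction)

  # a footprint inside one bin touches exactly one bin
  fp1 <- fp; fp1$start <- 110; fp1$end <- 190
  d3 <- bin_distribution(fp1, ref, 100)
  expect_equal(sum(d3$fraction > 0), 1)

  expect_warning(d0 <- bin_distribution(fp[0, ], ref, 100),
                 "no footprints")
  expect_true(all(d0$fraction == 0))
})

test_that("the final partial bin is kept", {
  ref <- donor_reference(strrep("A", 1000), 0, 950)
  d <- bin_distribution(
    data.frame(read_id = "r", strand = "top", start = 920, end = 940,
               length = 20, n_cytosines_in_peak = 2,
               n_converted_in_peak = 2, conversion_fraction = 1),
    ref, 100)
  expect_equal(nrow(d), 10)
  expect_equal(d$bin_end[10], 950)
  expect_equal(d$fraction[10], 1)
})

test_that("simulated 3'-biased data enriches 3'-end bins", {
  ref <- test_donor()
  sim <- simulate_dataset(
    simulation_config(n_molecules = 500, dloop_fraction = 1,
                      bottom_to_top_read_ratio = 0,
                      position_model = "three_prime_biased",
                      topology = topology_model(mode = "linear"),
                      length_model = length_fixed(150),
                      indel_rate = 0, truncation_fraction = 0,
                      seed = 61), ref)
  tr <- sim$truth
  fp <- data.frame(read_id = tr$read_id, strand = "top",
                   start = tr$dloop_start, end = tr$dloop_end - 1L,
                   length = tr$dloop_end - 1L - tr$dloop_start,
                   n_cytosines_in_peak = 1, n_converted_in_peak = 1,
                   conversion_fraction = 1)
  d <- bin_distribution(fp, ref, 100)
  inner <- d$fraction[1:(nrow(d) - 1)]  # final bin is edge-affected
  expect_gt(mean(inner[(length(inner) - 2):length(inner)]),
            mean(inner[1:3]))
})

test_that("clustering orders reads 5' to 3' with stated tie-breaks", {
  fp <- data.frame(
    read_id = c("r3", "r1", "r2", "r4", "r5"),
    strand = "top",
    start = c(300, 100, 200, 100, 100),
    end = c(350, 250, 260, 200, 200),
    length = 0, n_cytosines_in_peak = 1, n_converted_in_peak = 1,
    conversion_fraction = 1)
  ord <- cluster_footprints(fp)
  expect_equal(ord, c("r4", "r5", "r1", "r2", "r3"))
  expect_setequal(ord, fp$read_id)               # permutation
  expect_equal(cluster_footprints(fp[fp$read_id %in% ord, ]), ord)
  expect_equal(cluster_footprints(fp[0, ]), character(0))
})

test_that("footprint maps round-trip through the text matrix exactly", {
  ref <- test_donor()
  sim <- simulate_dataset(
    simulation_config(n_molecules = 120, dloop_fraction = 0.5,
                      bottom_to_top_read_ratio = 0.5, seed = 71), ref)
  tracks <- tracks_from_reads(sim$reads, ref)
  keep <- vapply(tracks, filter_read_length, logical(1))
  strands <- vapply(tracks, `[[`, character(1), "strand_call")
  top <- tracks[keep & strands == "top"]
  fp <- call_peaks_all(top, peak_threshold())
  txt <- tempfile(fileext = ".txt")
  png <- tempfile(fileext = ".png")
  export_footprint_map(top, fp, ref, txt, png_path = png)
  expect_true(file.exists(png))

  back <- parse_footprint_map(txt)
  expect_equal(back$homology, c(1000L, 1931L))
  got <- back$footprints[order(back$footprints$read_id,
                               back$footprints$start), ]
  # a per-cytosine glyph row shows the union of a read's footprints:
  # merge intervals that overlap or abut in cytosine-index space
  pos <- ref$top_cytosine_positions
  want <- do.call(rbind, lapply(split(fp, fp$read_id), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(match(d$start, pos),
                                           match(d$end, pos)),
                          min.gapwidth = 1L)
    data.frame(read_id = d$read_id[1],
               start = pos[IRanges::start(ir)],
               end = pos[IRanges::end(ir)])
  }))
  want <- want[order(want$read_id, want$start), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("maps refuse mixed strands and render degenerate reads", {
  ref <- donor_reference(strrep("CA", 50), 0, 100)
  t1 <- make_track(seq(0, 98, by = 2), rep(0, 50), read_id = "r1")
  t2 <- make_track(seq(1, 99, by = 2), rep(0, 50), strand = "bottom",
                   read_id = "r2")
  expect_error(
    export_footprint_map(list(t1, t2), call_peaks_all(list(t1)), ref,
                         tempfile()),
    "mixed strands")

  txt <- tempfile()
  export_footprint_map(list(t1), call_peaks_all(list(t1)), ref, txt)
  row <- strsplit(grep("^r1", readLines(txt), value = TRUE), "\t")[[1]][2]
  expect_equal(row, strrep(".", 50))  # zero conversions: unconverted row

  full <- make_track(seq(0, 98, by = 2), rep(1, 50), read_id = "r3")
  fp <- call_peaks_all(list(full), peak_threshold(0.4, 50))
  txt2 <- tempfile()
  export_footprint_map(list(full), fp, ref, txt2)
  row2 <- strsplit(grep("^r3", readLines(txt2), value = TRUE),
                   "\t")[[1]][2]
  expect_equal(row2, strrep("F", 50))  # fully converted at threshold
})

test_that("sample_summary counts multi-footprint reads once in % peak", {
  t1 <- make_track(seq(0, 990, by = 10), rep(c(1, 1, 1, 0, 0), 20),
                   read_id = "a")
  t2 <- make_track(seq(0, 990, by = 10), rep(0, 100), read_id = "b")
  fp <- rbind(
    data.frame(read_id = "a", strand = "top", start = 0, end = 100,
               length = 100, n_cytosines_in_peak = 10,
               n_converted_in_peak = 5, conversion_fraction = 0.5),
    data.frame(read_id = "a", strand = "top", start = 500, end = 900,
               length = 400, n_cytosines_in_peak = 10,
               n_converted_in_peak = 5, conversion_fraction = 0.5))
  s <- sample_summary(list(t1, t2), fp, length_cutoff = 400)
  top <- s[s$strand == "top", ]
  expect_equal(top$n_total_reads, 2)
  expect_equal(top$n_peak_reads, 1)       # one read, two footprints
  expect_equal(top$percent_peak, 50)
  expect_equal(top$n_footprints, 2)
  expect_equal(top$n_multi_footprint_reads, 1)
  expect_equal(top$mean_length, 250)      # over footprints, not reads
})
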