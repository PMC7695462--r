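ref <- test_donor()

aln <- function(seq, pos = 1L, cigar = NULL, id = "r1") {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  list(read_id = id, pos = pos, cigar = cigar, seq = seq)
}

test_that("a read identical to the reference has no conversions", {
  tr <- call_conversions(aln(ref$sequence), ref)
  expect_equal(tr$n_CT, 0L)
  expect_equal(tr$n_GA, 0L)
  expect_true(all(tr$ct_status == "unconverted"))
  expect_true(all(tr$ga_status == "unconverted"))
  expect_equal(tr$strand_call, "unknown")  # nothing to assign from
})

test_that("C-to-T calls convert and non-T mismatches mask", {
  small <- donor_reference("ACGCA", 0, 5)
  tr <- call_conversions(aln("ATGCA"), small)
  expect_equal(tr$ct_positions, c(1L, 3L))
  expect_equal(tr$ct_status, c("converted", "unconverted"))
  expect_equal(tr$n_CT, 1L)

  tr2 <- call_conversions(aln("AGGCA"), small)  # C->G is error, not signal
  expect_equal(tr2$ct_status, c("masked", "unconverted"))
  expect_equal(tr2$n_CT, 0L)
})

test_that("a deletion masks cytosines within a 5 nt buffer on both sides", {
  # all-C reference: every position is a top-strand cytosine
  allc <- donor_reference(strrep("C", 200), 0, 200)
  # delete 0-based reference position 100 (the 101st base)
  read <- strrep("C", 199)
  tr <- call_conversions(aln(read, cigar = "100M1D99M"), allc)
  masked <- tr$ct_positions[tr$ct_status == "masked"]
  expect_setequal(masked, 95:105)
  expect_true(all(tr$ct_status[tr$ct_positions %in% c(94, 106)] ==
                    "unconverted"))
})

test_that("an insertion masks around its anchor position", {
  allc <- donor_reference(strrep("C", 200), 0, 200)
  read <- paste0(strrep("C", 100), "A", strrep("C", 100))
  tr <- call_conversions(aln(read, cigar = "100M1I100M"), allc)
  masked <- tr$ct_positions[tr$ct_status == "masked"]
  # anchor is the reference base before the insertion (0-based 99)
  expect_setequal(masked, 94:104)
})

test_that("adding an indel never increases conversion tallies", {
  set.seed(31)
  sim <- simulate_dataset(
    simulation_config(n_molecules = 15, dloop_fraction = 1,
                      indel_rate = 0, truncation_fraction = 0,
                      bottom_to_top_read_ratio = 0, seed = 21), ref)
  for (i in seq_len(5)) {
    base <- call_conversions(aln(sim$reads$seq[i]), ref)
    cut <- sample(500:2500, 1)
    with_del <- paste0(substr(sim$reads$seq[i], 1, cut),
                       substr(sim$reads$seq[i], cut + 2, 3000))
    del_tr <- call_conversions(
      aln(with_del, cigar = sprintf("%dM1D%dM", cut, 3000 - cut - 1)),
      ref)
    expect_lte(del_tr$n_CT, base$n_CT)
    expect_lte(del_tr$n_GA, base$n_GA)
  }
})

test_that("strand assignment follows the count and ambiguity rules", {
  expect_equal(assign_strand(5, 5), "unknown")    # both below floor
  expect_equal(assign_strand(100, 2), "top")      # predominant C->T
  expect_equal(assign_strand(2, 30), "bottom")    # predominant G->A
  expect_equal(assign_strand(20, 19), "unknown")  # within 10% of larger
  expect_equal(assign_strand(22, 19), "top")      # just outside 10%
  expect_equal(assign_strand(0, 0), "unknown")
  expect_equal(assign_strand(6, 0), "top")        # one count at floor

  # symmetry: swapping counts maps top <-> bottom and fixes unknown
  set.seed(7)
  for (k in 1:50) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    s1 <- assign_strand(a, b); s2 <- assign_strand(b, a)
    expect_equal(s2, switch(s1, top = "bottom", bottom = "top",
                            unknown = "unknown"))
  }
})

test_that("the truncation filter keeps reads at exactly half expected length", {
  tr <- make_track(integer(0), character(0), expected_length = 2500,
                   observed_length = 2500)
  expect_true(filter_read_length(tr))
  tr$observed_length <- 1249
  expect_false(filter_read_length(tr))
  tr$observed_length <- 1250
  expect_true(filter_read_length(tr))  # boundary inclusive
})

test_that("kept D-loop top reads carry no G-to-A signal when breathing is off", {
  sim <- simulate_dataset(
    simulation_config(n_molecules = 60, dloop_fraction = 1,
                      breathing_rate = 0, indel_rate = 0,
                      truncation_fraction = 0,
                      bottom_to_top_read_ratio = 0, seed = 33), ref)
  tracks <- tracks_from_reads(sim$reads, ref)
  for (tr in tracks) {
    expect_equal(tr$n_GA, 0L)
    expect_true(tr$strand_call %in% c("top", "unknown"))
  }
})

test_that("unknown-strand reads are a small minority under default conditions", {
  sim <- simulate_dataset(simulation_config(n_molecules = 400, seed = 55),
                          ref)
  tracks <- tracks_from_reads(sim$reads, ref)
  keep <- vapply(tracks, filter_read_length, logical(1))
  st <- vapply(tracks[keep], `[[`, character(1), "strand_call")
  expect_lt(mean(st == "unknown"), 0.05)
})

test_that("SAM input reproduces in-memory conversion tracks", {
  sim <- simulate_dataset(simulation_config(n_molecules = 25, seed = 44),
                          ref)
  mem <- tracks_from_reads(sim$reads, ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim, ref, sam)
  from_sam <- tracks_from_sam(sam, ref)
  expect_setequal(names(from_sam), names(mem))
  for (id in names(mem)) {
    expect_identical(from_sam[[id]]$status, mem[[id]]$status)
    expect_identical(from_sam[[id]]$strand_call, mem[[id]]$strand_call)
    expect_identical(from_sam[[id]]$n_CT, mem[[id]]$n_CT)
  }
  expect_error(tracks_from_sam(sam, donor_reference("ACGT", 0, 4)),
               "aligned to reference")
})

test_that("the TSV dialect builds equivalent tracks without alignments", {
  small <- donor_reference("ACGCAG", 0, 6)  # C at 1,3; G at 2,5
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("read_id\tpos\tbase",
               "r1\t1\tT", "r1\t3\tC", "r1\t2\tG", "r1\t5\tG",
               "r2\t1\tC", "r2\t3\tC", "r2\t2\tA", "r2\t5\tA"),
             tsv)
  tracks <- tracks_from_tsv(tsv, small)
  expect_equal(tracks$r1$n_CT, 1L)
  expect_equal(tracks$r1$n_GA, 0L)
  expect_equal(tracks$r2$n_GA, 2L)
  expect_equal(tracks$r2$n_CT, 0L)
})

test_that("unaligned reads and overruns are rejected", {
  expect_error(call_conversions(list(read_id = "x", pos = NA,
                                     cigar = "10M", seq = "ACGTACGTAC"),
                                ref),
               "not aligned")
  expect_error(call_conversions(aln(strrep("A", 50), pos = 2990), ref),
               "wrong reference|extends past")
})
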