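# Test helpers: minimal track construction, a brute-force peak oracle
# written independently of the package's sliding-window code, and small
# random generators.

# Build a ReadConversionTrack directly from positions + status.
make_track <- function(positions, status, strand = "top",
                       read_id = "read1", expected_length = 3000,
                       observed_length = 3000) {
  if (is.numeric(status)) {
    status <- ifelse(status == 1, "converted", "unconverted")
  }
  stopifnot(length(positions) == length(status))
  n_conv <- sum(status == "converted")
  tr <- list(read_id = read_id, strand_call = strand,
             positions = as.integer(positions), status = status,
             ct_positions = if (strand == "top") as.integer(positions)
               else integer(0),
             ct_status = if (strand == "top") status else character(0),
             ga_positions = if (strand == "bottom") as.integer(positions)
               else integer(0),
             ga_status = if (strand == "bottom") status else character(0),
             n_CT = if (strand == "top") n_conv else 0L,
             n_GA = if (strand == "bottom") n_conv else 0L,
             n_masked = sum(status == "masked"),
             expected_length = expected_length,
             observed_length = observed_length)
  class(tr) <- "ReadConversionTrack"
  tr
}

# Brute-force oracle: enumerate every window of w consecutive unmasked
# cytosines, mark it positive when its converted fraction reaches t,
# group maximal runs of consecutive positive window indices, and trim
# each run's coverage to the outermost converted cytosines. Plain loops
# throughout, no shared code with call_peaks().
oracle_peaks <- function(positions, status, t, w) {
  keep <- status != "masked"
  p <- positions[keep]
  conv <- status[keep] == "converted"
  n <- length(p)
  res <- data.frame(start = integer(0), end = integer(0))
  if (n < w) return(res)
  positive <- integer(0)
  for (i in 1:(n - w + 1)) {
    cnt <- 0
    for (j in i:(i + w - 1)) if (conv[j]) cnt <- cnt + 1
    if (cnt / w >= t - 1e-9) positive <- c(positive, i)
  }
  if (length(positive) == 0) return(res)
  run_start <- positive[1]
  prev <- positive[1]
  flush <- function(a, b) {
    cov <- a:(b + w - 1)
    conv_idx <- cov[conv[cov]]
    if (length(conv_idx) == 0) return(NULL)
    data.frame(start = p[min(conv_idx)], end = p[max(conv_idx)])
  }
  for (k in positive[-1]) {
    if (k != prev + 1) {
      res <- rbind(res, flush(run_start, prev))
      run_start <- k
    }
    prev <- k
  }
  res <- rbind(res, flush(run_start, prev))
  res
}

# Random conversion track over a random cytosine landscape.
random_track <- function(max_cytosines = 200, read_id = "rand") {
  n <- sample(0:max_cytosines, 1)
  positions <- sort(sample(0:2999, n))
  status <- sample(c("converted", "unconverted", "masked"), n,
                   replace = TRUE, prob = c(0.4, 0.5, 0.1))
  make_track(positions, status, read_id = read_id)
}

# Shared fixtures for tests that need a reference quickly.
test_donor <- function() {
  load_reference(dma_fixture("donor_ds98-931_synthetic"),
                 donor_homology_window())
}

# Local nt span of k consecutive cytosines around reference point x.
local_span <- function(positions, x, k = 10) {
  n <- length(positions)
  i <- which.min(abs(positions - x))
  j1 <- max(1, min(i - floor(k / 2), n - k))
  j2 <- min(n, j1 + k)
  positions[j2] - positions[j1]
}
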