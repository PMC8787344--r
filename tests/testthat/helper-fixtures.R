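# fixtures built in code

random_symmetric_pois <- function(n, lambda = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rpois(n * n, lambda), n)
  m <- m + t(m)
  m
}

# two-block planted matrix: strong within-block, weak between
planted_two_domain <- function(n = 12, strong = 4, weak = 1, depth = 20,
                               seed = 1) {
  half <- n / 2
  mu <- matrix(weak, n, n)
  mu[1:half, 1:half] <- strong
  mu[(half + 1):n, (half + 1):n] <- strong
  m <- random_symmetric_pois(n, 1, seed) * 0
  set.seed(seed)
  m[] <- stats::rpois(n * n, depth * mu)
  m <- m + t(m)
  diag(m) <- 0
  m
}

make_track <- function(labels, chrom = "chrT", bin_size = 10000L) {
  structure(list(labels = as.integer(labels), k = max(labels, na.rm = TRUE),
                 chrom = chrom, bin_size = as.integer(bin_size)),
            class = "ClusterTrack")
}

# random interaction-record table for DCI tests
random_records <- function(n, seed = 1, chrom = "chr1", bin_size = 10000,
                           max_bins = 200) {
  set.seed(seed)
  b1 <- sample.int(max_bins, n, replace = TRUE)
  off <- sample.int(150, n, replace = TRUE)
  data.frame(chrom = chrom,
             bin1 = (b1 - 1) * bin_size,
             bin2 = (b1 - 1 + off) * bin_size,
             distance = off * bin_size,
             count_within = stats::rpois(n, 20),
             count_outside = stats::rpois(n, 20),
             direction = sample(c("within_higher", "outside_higher"), n,
                                replace = TRUE),
             source = "selfish", z = NA_real_,
             stringsAsFactors = FALSE)
}
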