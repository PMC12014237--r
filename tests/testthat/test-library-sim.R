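test_that("flanking cuts release a doubly-ligatable target fragment", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, unit_length = 800, copies = 1,
                       background = 4000, seed = 12)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  expect_equal(nrow(sites), 2)
  frags <- digest(fg$genome$sequence, sites, cleavage_prob = 1, seed = 1)
  expect_equal(nrow(frags), 3)
  expect_equal(ligatable_ends(frags), c(0, 2, 0))
  # the middle fragment is exactly the region between the two cuts
  expect_identical(frags$sequence[2], fg$roi_seq)
  expect_equal(frags$start[2], fg$rois$start[1])
  # original termini are dephosphorylated
  expect_equal(frags$left_origin[1], "native")
  expect_false(frags$left_ligatable[1])
})

test_that("no sites or zero cleavage leaves one unligatable fragment", {
  g <- random_dna(2000, seed = 31)
  f0 <- digest(g, NULL, cleavage_prob = 1)
  expect_equal(nrow(f0), 1)
  expect_equal(ligatable_ends(f0), 0)
  expect_identical(f0$sequence, g)

  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 800, 2, 4000, seed = 13)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  fz <- digest(fg$genome$sequence, sites, cleavage_prob = 0)
  expect_equal(nrow(fz), 1)
  expect_equal(ligatable_ends(fz), 0)
})

test_that("digestion conserves the genome and balances end states", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 600, 4, 6000, seed = 14)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  for (seed in 1:20) {
    fr <- digest(fg$genome$sequence, sites, cleavage_prob = 0.6,
                 seed = seed)
    # conservation: ordered concatenation reproduces the genome
    expect_identical(paste(fr$sequence, collapse = ""),
                     fg$genome$sequence)
    # each realized cut creates exactly one ligatable and one blocked end
    n_cuts <- nrow(fr) - 1
    expect_equal(sum(ligatable_ends(fr)), n_cuts)
    n_blocked <- sum(fr$left_blocking_probe != "") +
      sum(fr$right_blocking_probe != "")
    expect_equal(n_blocked, n_cuts)
  }
})

test_that("realized cut count matches the cleavage probability", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 600, 3, 3000, seed = 15)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  k <- nrow(sites)
  p <- 0.7
  trials <- 4000
  cuts <- vapply(seq_len(trials), function(s) {
    nrow(digest(fg$genome$sequence, sites, p, seed = s)) - 1L
  }, integer(1))
  # mean realized cuts = p*k within 3 sigma of the binomial mean
  se <- sqrt(k * p * (1 - p) / trials)
  expect_lt(abs(mean(cuts) - p * k), 3 * se)
})

test_that("library sampling respects ligatable-end weights and background", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 800, 1, 4000, seed = 16)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  frags <- digest(fg$genome$sequence, sites, 1, seed = 1)

  lib0 <- sample_library(frags, 500, background_rate = 0, seed = 2)
  expect_equal(nrow(lib0), 500)
  expect_false(any(lib0$is_background))

  lib1 <- sample_library(frags, 200, background_rate = 1, seed = 3)
  expect_true(all(lib1$is_background))

  # 2 ligatable ends vs 1: sampling ratio ~ 2:1
  two <- frags[2, ]
  one <- frags[2, ]
  one$left_ligatable <- FALSE
  one$left_blocking_probe <- "x"
  one$start <- 3000  # distinguishable
  mix <- rbind(two, one)
  class(mix) <- c("library_molecules", "data.frame")
  lib <- sample_library(mix, 30000, background_rate = 0, seed = 4)
  frac_two <- mean(lib$start == two$start)
  se <- sqrt((2 / 3) * (1 / 3) / 30000)
  expect_lt(abs(frac_two - 2 / 3), 3 * se)

  none <- frags[c(1, 3), ]
  class(none) <- c("library_molecules", "data.frame")
  expect_error(sample_library(none, 10, background_rate = 0),
               "empty library")
})

test_that("error-free reads reproduce molecules up to strand", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 800, 2, 4000, seed = 17)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  frags <- digest(fg$genome$sequence, sites, 1, seed = 1)
  lib <- sample_library(frags, 300, background_rate = 0.1, seed = 5)
  sim <- simulate_reads(lib, error_model(0, 0, 0, seed = 6))
  expect_equal(nrow(sim$reads), 300)
  for (i in c(1, 57, 123, 300)) {
    mol <- lib$sequence[i]
    rd <- sim$reads$sequence[i]
    if (sim$truth$strand[i] == "+") {
      expect_identical(rd, mol)
    } else {
      expect_identical(rd, revcomp(mol))
    }
  }
  expect_equal(sum(sim$truth$n_sub + sim$truth$n_ins + sim$truth$n_del), 0)
})

test_that("substitution errors occur at the modelled rate", {
  mol <- data.frame(
    contig = "m", start = 0, end = 10000,
    sequence = random_dna(10000, seed = 41),
    left_origin = "cas9_cut", left_ligatable = TRUE,
    left_blocking_probe = "",
    right_origin = "cas9_cut", right_ligatable = FALSE,
    right_blocking_probe = "p",
    source_species = "m", is_background = FALSE, copy_weight = 1,
    stringsAsFactors = FALSE)
  class(mol) <- c("library_molecules", "data.frame")
  sim <- simulate_reads(mol, error_model(0.04, 0, 0, seed = 8))
  # only the left end is ligatable -> forward read, alignable by position
  expect_equal(sim$truth$strand, "+")
  obs <- hamming(sim$reads$sequence, mol$sequence) / 10000
  se <- sqrt(0.04 * 0.96 / 10000)
  expect_lt(abs(obs - 0.04), 3 * se)
  expect_equal(sim$truth$n_sub, hamming(sim$reads$sequence, mol$sequence))
})

test_that("read simulation is byte-deterministic under a fixed seed", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 500, 1, 2000, seed = 18)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  frags <- digest(fg$genome$sequence, sites, 1, seed = 1)
  lib <- sample_library(frags, 50, background_rate = 0.2, seed = 9)
  m <- error_model(0.03, 0.005, 0.005, seed = 10)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(lib, m), f1)
  write_fastq(simulate_reads(lib, m), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_equal(nrow(back), 50)
  expect_identical(back$sequence, read_fastq(f2)$sequence)
})

test_that("fragment length spectrum peaks at the target length", {
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 1200, 5, 30000, seed = 19)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  frags <- do.call(rbind, lapply(1:10, function(s) {
    digest(fg$genome$sequence, sites, 0.9, seed = s, contig = "genome")
  }))
  class(frags) <- c("library_molecules", "data.frame")
  lib <- sample_library(frags, 2000, background_rate = 0, seed = 11,
                        genomes = c(genome = fg$genome$sequence))
  sim <- simulate_reads(lib, error_model(0, 0, 0, seed = 12))
  h <- read_length_histogram(sim, bin_width = 100)
  modal <- attr(h, "modal_bin")
  expect_true(fg$roi_length >= modal[1] && fg$roi_length < modal[2])
})
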