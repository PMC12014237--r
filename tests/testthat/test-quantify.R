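make_refs <- function(n = 3, len = 900, seed = 500) {
  stats::setNames(
    vapply(seq_len(n), function(i) random_dna(len, seed = seed + i),
           character(1)),
    paste0("ref", LETTERS[seq_len(n)]))
}

test_that("error-free reads are fully assigned to their source reference", {
  refs <- make_refs(3)
  reads <- stats::setNames(rep(refs[["refA"]], 20),
                           sprintf("r%03d", 1:20))
  a <- assign_reads(reads, refs, min_identity = 0.98)
  expect_equal(nrow(a), 20)
  expect_true(all(a$reference == "refA"))
  expect_true(all(a$identity == 1))
  expect_equal(attr(a, "n_unassigned"), 0)
  # reverse-complement reads assign on the '-' strand
  rc <- stats::setNames(revcomp(refs[["refB"]]), "rc1")
  arc <- assign_reads(rc, refs)
  expect_equal(arc$reference, "refB")
  expect_equal(arc$strand, "-")
})

test_that("lowering the identity threshold assigns strictly more reads", {
  refs <- make_refs(2, len = 700)
  mols <- data.frame(
    read_id = sprintf("r%03d", 1:120),
    sequence = rep(refs, each = 60), stringsAsFactors = FALSE)
  sim <- simulate_reads(
    structure(data.frame(contig = rep(names(refs), each = 60), start = 0,
                         end = 700, sequence = mols$sequence,
                         left_origin = "cas9_cut", left_ligatable = TRUE,
                         left_blocking_probe = "",
                         right_origin = "cas9_cut",
                         right_ligatable = TRUE,
                         right_blocking_probe = "",
                         source_species = rep(names(refs), each = 60),
                         is_background = FALSE, copy_weight = 1,
                         stringsAsFactors = FALSE),
              class = c("library_molecules", "data.frame")),
    error_model(0.03, 0.005, 0.005, seed = 3))
  strict <- assign_reads(sim, refs, min_identity = 0.98)
  loose <- assign_reads(sim, refs, min_identity = 0.90)
  expect_gt(attr(strict, "n_unassigned"), 0)
  expect_gt(nrow(loose), nrow(strict))
  expect_equal(nrow(loose) + attr(loose, "n_unassigned"), 120)
})

test_that("best-hit rule picks the closer of two related references", {
  base <- random_dna(600, seed = 600)
  chars <- strsplit(base, "")[[1]]
  idx <- seq(1, 600, by = 5)  # mutate 20% of positions
  chars[idx] <- vapply(chars[idx], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  refs <- c(A = base, B = paste(chars, collapse = ""))
  # a read from A with a couple of errors still beats B
  read_chars <- strsplit(base, "")[[1]]
  read_chars[c(100, 300)] <- vapply(read_chars[c(100, 300)], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  a <- assign_reads(stats::setNames(paste(read_chars, collapse = ""), "r1"),
                    refs, min_identity = 0.9)
  expect_equal(a$reference, "A")
})

test_that("on-target accounting applies the 50% span-overlap rule", {
  mk <- function(s, e, strand = "+") {
    data.frame(read_id = paste0("r", s), reference = "g", identity = 1,
               ref_start = s, ref_end = e, strand = strand,
               aligned_bases = e - s, stringsAsFactors = FALSE)
  }
  roi <- c(1000, 2000)
  inside <- do.call(rbind, lapply(seq(1000, 1800, 100), function(s) {
    mk(s, s + 200)
  }))
  st <- on_target_stats(inside, roi)
  expect_equal(st$R_target, st$R_total)

  # read aligned exactly half inside counts as on-target
  boundary <- mk(900, 1100)
  expect_equal(on_target_stats(boundary, roi)$R_target, 1)
  # just under half does not
  expect_equal(on_target_stats(mk(898, 1098), roi)$R_target, 0)

  # multiple ROI copies: on-target if the rule holds for any copy
  two_rois <- data.frame(start = c(1000, 5000), end = c(2000, 6000))
  expect_equal(on_target_stats(mk(5100, 5500), two_rois)$R_target, 1)
})

test_that("enrichment score implements the fold-increase formula exactly", {
  # uniform expectation: R_target/R_total = L*N/G -> E = 1
  r <- enrichment_score(R_target = 50, R_total = 1000, G = 1e6,
                        L_target = 5000, N_target = 10)
  expect_equal(r$E, 1)

  # printed-scale inputs: 83.3% on target on a 100.2 Mbp genome
  r2 <- enrichment_score(833, 1000, 100.2e6, 4480, 55)
  expect_equal(r2$E, 0.833 * 100.2e6 / (4480 * 55), tolerance = 1e-12)
  expect_equal(round(r2$E), 339)

  r3 <- enrichment_score(0, 10, 1e6, 100, 1)
  expect_equal(r3$E, 0)
  expect_error(enrichment_score(5, 0, 1e6, 100, 1), "R_total")
  expect_error(enrichment_score(11, 10, 1e6, 100, 1), "R_target")
})

test_that("coverage profiles are normalized per aligned base", {
  a <- data.frame(read_id = "r1", reference = "g", identity = 1,
                  ref_start = 10, ref_end = 20, strand = "+",
                  aligned_bases = 10, stringsAsFactors = FALSE)
  cov <- coverage_profile(a, 30)
  expect_equal(cov$forward[11:20], rep(1 / 10, 10))
  expect_equal(sum(cov$forward > 0), 10)
  expect_equal(cov$reverse, rep(0, 30))

  empty <- a[0, ]
  cov0 <- coverage_profile(empty, 10)
  expect_equal(cov0$forward, rep(0, 10))

  # symmetric forward/reverse reads give near-equal strand profiles
  pp <- demo_probe_pair()
  fg <- flanked_genome(pp$fwd, pp$rev, 700, 1, 3000, seed = 21)
  sites <- rbind(find_cleavage_sites(fg$genome$sequence, pp$fwd, 0),
                 find_cleavage_sites(fg$genome$sequence, pp$rev, 0))
  frags <- digest(fg$genome$sequence, sites, 1, seed = 1)
  lib <- sample_library(frags, 4000, 0, seed = 22)
  sim <- simulate_reads(lib, error_model(0, 0, 0, seed = 23))
  asn <- assignments_from_truth(sim)
  covs <- coverage_profile(asn, nchar(fg$genome$sequence))
  f_total <- sum(covs$forward)
  r_total <- sum(covs$reverse)
  expect_lt(abs(f_total - r_total) / (f_total + r_total), 0.05)
})

test_that("read-length histogram bins and reports the mode", {
  h0 <- read_length_histogram(numeric(0), 100)
  expect_equal(nrow(h0), 0)
  h <- read_length_histogram(rep(4480, 25), 100)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_start, 4400)
  expect_equal(h$count, 25)
  expect_equal(attr(h, "modal_bin"), c(4400, 4500))
})

test_that("observed proportions agree across modes on balanced designs", {
  refs <- make_refs(2, len = 500)
  a <- data.frame(
    read_id = sprintf("r%02d", 1:30),
    reference = rep(c("refA", "refB"), c(20, 10)),
    identity = 1, ref_start = 0, ref_end = 500, strand = "+",
    aligned_bases = 500, stringsAsFactors = FALSE)
  pc <- observed_proportions(a, refs, mode = "read_count")
  pd <- observed_proportions(a, refs, mode = "mean_depth")
  expect_equal(as.numeric(pc), c(2 / 3, 1 / 3))
  expect_equal(as.numeric(pd), c(2 / 3, 1 / 3))
  expect_equal(sum(pc), 1)

  solo <- observed_proportions(a[a$reference == "refA", ],
                               refs["refA"])
  expect_equal(as.numeric(solo), 1)
  expect_error(observed_proportions(a[0, ], refs), "no signal")
})

test_that("rank aggregation sums within genera and preserves mass", {
  tax <- data.frame(reference = c("s1", "s2", "s3"),
                    species = c("s1", "s2", "s3"),
                    genus = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  pv <- proportion_vector(c("s1", "s2", "s3"), c(0.2, 0.3, 0.5))
  gen <- aggregate_rank(pv, tax, "genus")
  expect_equal(as.numeric(gen[c("G1", "G2")]), c(0.5, 0.5))
  spe <- aggregate_rank(pv, tax, "species")
  expect_equal(as.numeric(spe[names(pv)]), as.numeric(pv))
  bad <- proportion_vector(c("s1", "zz"), c(0.4, 0.6))
  expect_error(aggregate_rank(bad, tax, "genus"), "zz")
})

test_that("Lin's CCC penalizes location and scale shifts", {
  x <- c(1, 2, 3, 4)
  expect_equal(lin_ccc(x, x)$rho_c, 1)

  # hand-arithmetic oracle with population moments
  r <- lin_ccc(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(r$rho_c, -2 * (2 / 3) / (2 / 3 + 2 / 3 + 16))
  expect_equal(r$rho_c, -1 / 13)

  shift <- lin_ccc(x, x + 2)
  expect_equal(shift$pearson_r, 1)
  expect_lt(shift$rho_c, 1)

  # equals Pearson r exactly when means and variances match
  y <- c(2, 3, 1, 4)
  eq <- lin_ccc(x, y)
  expect_equal(eq$rho_c, eq$pearson_r)

  expect_true(abs(r$rho_c) <= abs(r$pearson_r) + 1e-12)
  expect_error(lin_ccc(c(1, 1), c(2, 2)), "constant")
  expect_error(lin_ccc(1:3, 1:4), "equal length")
})

test_that("PAF alignments import with best-hit and identity filtering", {
  paf <- withr::local_tempfile(fileext = ".paf")
  rec <- function(id, ref, s, e, m, b, strand = "+") {
    paste(id, 1000, 0, 1000, strand, ref, 5000, s, e, m, b, 60,
          sep = "\t")
  }
  writeLines(c(rec("r1", "A", 100, 1100, 995, 1005),
               rec("r1", "B", 200, 1200, 900, 1010),
               rec("r2", "B", 0, 980, 970, 990, "-"),
               rec("r3", "C", 0, 900, 700, 1000)), paf)
  a <- read_paf(paf, min_identity = 0.9)
  expect_equal(nrow(a), 2)
  expect_equal(a$reference[a$read_id == "r1"], "A")  # best identity wins
  expect_equal(a$strand[a$read_id == "r2"], "-")
  expect_equal(attr(a, "n_unassigned"), 1)  # r3 below threshold
  expect_equal(a$identity[a$read_id == "r1"], 995 / 1005)
})
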