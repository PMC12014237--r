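test_that("a constructed perfect site is found with the right cut placement", {
  p <- random_probe(21)
  s <- paste0(random_dna(20, seed = 1), p$protospacer, "AGG",
              random_dna(17, seed = 2))
  hits <- find_cleavage_sites(s, p, 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$proto_start, 20)
  expect_equal(hits$mismatch_count, 0)
  expect_equal(hits$pam_sequence, "AGG")
  # blunt cut 3 bp upstream of the PAM = protospacer start + 17
  expect_equal(hits$cut_position, 20 + 17)
})

test_that("mismatch threshold semantics are subset-monotone", {
  p <- random_probe(22)
  proto <- strsplit(p$protospacer, "")[[1]]
  proto[c(3, 15)] <- vapply(proto[c(3, 15)], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  s <- paste0(random_dna(20, seed = 3), paste(proto, collapse = ""),
              "TGG", random_dna(17, seed = 4))
  expect_equal(nrow(find_cleavage_sites(s, p, 1)), 0)
  hits <- find_cleavage_sites(s, p, 2)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatch_count, 2)
  # offsets counted from the PAM-proximal end: positions 3,15 -> 18,6
  expect_equal(sort(hits$mismatch_offsets[[1]]), c(6, 18))
})

test_that("minus-strand sites map correctly to forward coordinates", {
  p <- random_probe(23)
  embedded <- revcomp(paste0(p$protospacer, "TGG"))
  s <- paste0(random_dna(31, seed = 5), embedded, random_dna(26, seed = 6))
  hits <- find_cleavage_sites(s, p, 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  # independent brute-force oracle on the reverse complement
  oracle <- naive_scan(s, p$protospacer, 0)
  expect_equal(hits$proto_start, oracle$proto_start)
  expect_equal(hits$cut_position, oracle$cut_position)
  # PAM occupies the 3 bp 5' of the protospacer on the forward axis
  expect_equal(hits$pam_end, hits$proto_start)
  expect_equal(hits$pam_sequence, "TGG")
})

test_that("scanner agrees with the naive oracle on random instances", {
  for (i in 1:40) {
    seq_len_i <- 300 + (i * 37) %% 500
    s <- random_dna(seq_len_i, gc_content = 0.5, seed = 1000 + i)
    p <- random_probe(2000 + i)
    mm <- i %% 4
    got <- find_cleavage_sites(s, p, mm)
    want <- naive_scan(s, p$protospacer, mm)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$proto_start, want$proto_start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$cut_position, want$cut_position)
    expect_equal(got$mismatch_count, want$mismatch_count)
  }
})

test_that("scanning is strand-symmetric and monotone in the budget", {
  for (i in 1:10) {
    s <- random_dna(600, seed = 300 + i)
    p <- random_probe(400 + i)
    n <- nchar(s)
    a <- find_cleavage_sites(s, p, 2)
    b <- find_cleavage_sites(revcomp(s), p, 2)
    # sites map one-to-one with strand flipped and coordinates reflected
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      key_a <- sort(paste(a$strand, a$proto_start))
      key_b <- sort(paste(ifelse(b$strand == "+", "-", "+"),
                          n - b$proto_end))
      expect_equal(key_a, key_b)
    }
    # monotone: the k-site set is a subset of the (k+1)-site set
    for (k in 0:2) {
      sk <- find_cleavage_sites(s, p, k)
      sk1 <- find_cleavage_sites(s, p, k + 1)
      expect_true(all(paste(sk$strand, sk$proto_start) %in%
                        paste(sk1$strand, sk1$proto_start)))
    }
    # cut strictly inside the protospacer, never in the PAM
    if (nrow(a) > 0) {
      expect_true(all(a$cut_position > a$proto_start &
                        a$cut_position < a$proto_end))
    }
  }
})

test_that("subject N never matches and empty input is not an error", {
  p <- random_probe(51)
  s <- paste0(random_dna(10, seed = 1), p$protospacer, "NGG")
  # PAM 'N' pattern position requires an actual base in the subject
  expect_equal(nrow(find_cleavage_sites(s, p, 0)), 0)
  s2 <- sub("^(.{12}).", "\\1N", paste0(random_dna(10, seed = 1),
                                        p$protospacer, "AGG"))
  hits <- find_cleavage_sites(s2, p, 1)
  expect_equal(hits$mismatch_count, 1)
  expect_equal(nrow(find_cleavage_sites("", p, 0)), 0)
  expect_error(find_cleavage_sites(s, p, -1), "max_mismatches")
})

test_that("off-target report reconstructs the upstream off-target scenario", {
  p <- random_probe(61)
  # plant an imperfect site whose protospacer ends 1400 bp before the ROI
  g <- random_dna(8000, seed = 71)
  roi <- data.frame(start = 5000, end = 6500)
  site_offset <- roi$start - 1400 - 20  # protospacer ends 1400 bp before
  planted <- plant_probe_site(g, p, site_offset, "+", n_mismatches = 2,
                              seed = 3)
  rep <- off_target_report(planted$sequence, p, roi, max_mismatches = 2)
  hit <- rep[rep$mismatch_count == 2, ][1, ]
  expect_false(hit$inside_roi)
  expect_equal(hit$distance_to_roi, 1400)
  expect_equal(hit$direction, "upstream")

  # a site inside the ROI has distance 0
  planted2 <- plant_probe_site(planted, p, 5600, "+", n_mismatches = 0)
  rep2 <- off_target_report(planted2$sequence, p, roi, max_mismatches = 2)
  inside <- rep2[rep2$inside_roi, ]
  expect_true(all(inside$distance_to_roi == 0))
  expect_true(all(rep2$inside_roi == (rep2$distance_to_roi == 0)))

  # absent probe at zero mismatches: empty report
  p2 <- random_probe(62)
  rep3 <- off_target_report(random_dna(2000, seed = 72), p2, roi,
                            max_mismatches = 0)
  expect_equal(nrow(rep3), 0)

  expect_warning(
    off_target_report(planted$sequence, p,
                      data.frame(start = c(100, 150), end = c(200, 250)),
                      max_mismatches = 2),
    "merged")
})

test_that("probe conservation classifies PAM-proximal and -distal mismatches", {
  p <- random_probe(86)  # protospacer free of GG/CC dinucleotides
  perfect <- paste0(random_dna(15, seed = 1), p$protospacer, "CGG",
                    random_dna(15, seed = 2))
  # one substitution at the protospacer position adjacent to the PAM
  proto <- strsplit(p$protospacer, "")[[1]]
  proto[20] <- setdiff(c("A", "C", "G", "T"), proto[20])[1]
  prox <- paste0(random_dna(15, seed = 3), paste(proto, collapse = ""),
                 "AGG", random_dna(15, seed = 4))
  # A/T-only context: best 20-mer present but no NGG on either strand
  nopam <- paste0(random_dna(15, gc_content = 0, seed = 5),
                  p$protospacer, "ATT")

  tab <- probe_conservation(
    p, c(perfect = perfect, proximal = prox, nopam = nopam),
    max_mismatches = 2)
  expect_equal(tab$found, c(TRUE, TRUE, FALSE))
  expect_equal(tab$mismatch_count[1], 0)
  expect_equal(tab$mismatch_count[2], 1)
  expect_equal(tab$mismatch_offsets[2], "1")
  expect_equal(tab$n_proximal[2], 1)
  expect_equal(tab$n_distal[2], 0)
  expect_false(tab$pam_ok[3])
  expect_error(probe_conservation(p, character(0)), "non-empty")
})
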