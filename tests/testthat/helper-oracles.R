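# Independent oracles and small builders used across the suite.

# Naive sliding-window protospacer+PAM scanner: O(n * 20) explicit loops,
# deliberately structured unlike the vectorized implementation it checks.
naive_scan_one <- function(sequence, protospacer, max_mm, pam = "NGG") {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(protospacer, "")[[1]]
  pm <- strsplit(pam, "")[[1]]
  L <- length(p)
  P <- length(pm)
  hits <- list()
  if (length(s) < L + P) return(hits)
  for (i in seq_len(length(s) - L - P + 1)) {
    mm <- 0
    for (j in seq_len(L)) {
      if (s[i + j - 1] != p[j]) mm <- mm + 1
    }
    ok <- mm <= max_mm
    if (ok) {
      for (kk in seq_len(P)) {
        b <- s[i + L + kk - 1]
        if (pm[kk] == "N") {
          if (!b %in% c("A", "C", "G", "T")) ok <- FALSE
        } else if (b != pm[kk]) ok <- FALSE
      }
    }
    if (ok) hits[[length(hits) + 1]] <- list(start = i - 1, mm = mm)
  }
  hits
}

# Both strands, mapped to forward coordinates; returns a data.frame
# comparable to find_cleavage_sites output.
naive_scan <- function(sequence, protospacer, max_mm, pam = "NGG") {
  n <- nchar(sequence)
  fwd <- naive_scan_one(sequence, protospacer, max_mm, pam)
  rev <- naive_scan_one(revcomp(sequence), protospacer, max_mm, pam)
  rows <- list()
  for (h in fwd) {
    rows[[length(rows) + 1]] <- data.frame(
      strand = "+", proto_start = h$start,
      cut_position = h$start + 17, mismatch_count = h$mm)
  }
  for (h in rev) {
    rows[[length(rows) + 1]] <- data.frame(
      strand = "-", proto_start = n - h$start - 20,
      cut_position = n - h$start - 17, mismatch_count = h$mm)
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(0), proto_start = integer(0),
                      cut_position = integer(0),
                      mismatch_count = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$proto_start, out$strand), ]
  rownames(out) <- NULL
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_probe <- function(seed) {
  crrna_probe(paste0("p", seed), random_dna(20, seed = seed))
}

# A genome with one probe pair flanking each of `copies` marker units:
# forward-flank probe on '-' (PAM outward/left), reverse-flank on '+'
# (PAM outward/right). Returns genome, ROIs and the ROI sequence.
flanked_genome <- function(fwd, rev, unit_length = 1200, copies = 3,
                           background = 20000, seed = 42) {
  unit <- random_dna(unit_length, seed = seed)
  off_f <- 10
  off_r <- unit_length - 33
  u <- plant_probe_site(unit, fwd, off_f, strand = "-", seed = seed + 1)
  u <- plant_probe_site(u, rev, off_r, strand = "+", seed = seed + 2)
  g <- synthesize_genome(background, u$sequence, copies, seed = seed + 3,
                         contig = "genome")
  roi_start <- off_f + 6
  roi_end <- off_r + 17
  rois <- data.frame(start = g$units$start + roi_start,
                     end = g$units$start + roi_end)
  list(genome = g, rois = rois,
       roi_length = roi_end - roi_start,
       roi_seq = substr(u$sequence, roi_start + 1, roi_end))
}

demo_probe_pair <- function() {
  list(fwd = crrna_probe("nemF", "GATTCGAACCAGTCTGACCA", "forward"),
       rev = crrna_probe("nemR", "CCTGAAGTACGGATCACTTG", "reverse"))
}
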