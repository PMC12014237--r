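#' Construct a crRNA probe
#'
#' A probe is a 20-mer crRNA protospacer sequence. Cas9 guided by the probe
#' cleaves genomic sites whose 20-mer protospacer matches the crRNA
#' (possibly with mismatches) and is immediately followed by an NGG PAM on
#' the same strand, cutting bluntly 3 bp upstream of the PAM.
#'
#' @param name probe name, e.g. "nemFI", "bacRII".
#' @param protospacer DNA string of length exactly 20, alphabet A/C/G/T.
#' @param intended_flank "forward" or "reverse": which side of the region of
#'   interest the probe is designed to flank.
#' @param taxon_group taxon the probe targets (free text).
#' @return A list of class `crrna_probe`.
#' @export
crrna_probe <- function(name, protospacer, intended_flank = "forward",
                        taxon_group = "") {
  protospacer <- toupper(as.character(protospacer))
  if (nchar(protospacer) != 20) {
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  }
  assert_dna(protospacer, "protospacer")
  if (!intended_flank %in% c("forward", "reverse")) {
    stop('intended_flank must be "forward" or "reverse"', call. = FALSE)
  }
  structure(list(name = name, protospacer = protospacer,
                 intended_flank = intended_flank,
                 taxon_group = taxon_group),
            class = "crrna_probe")
}

#' @export
print.crrna_probe <- function(x, ...) {
  cat(sprintf("crRNA probe %s (%s flank): %s\n", x$name, x$intended_flank,
              x$protospacer))
  invisible(x)
}

#' Load a probe table from TSV
#'
#' @param path TSV with columns name, protospacer, intended_flank,
#'   taxon_group.
#' @return A list of `crrna_probe` objects, named by probe name.
#' @export
load_probe_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "protospacer", "intended_flank", "taxon_group")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("probe table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  probes <- lapply(seq_len(nrow(tab)), function(i) {
    crrna_probe(tab$name[i], tab$protospacer[i], tab$intended_flank[i],
                tab$taxon_group[i])
  })
  stats::setNames(probes, tab$name)
}

## Scan one strand (already oriented) for protospacer+PAM matches.
## Returns 0-based starts of the protospacer, mismatch counts and, for kept
## hits, mismatch offsets counted 1..20 from the PAM-proximal end.
scan_strand <- function(chars, proto, pam, max_mismatches) {
  n <- length(chars)
  L <- length(proto)
  P <- length(pam)
  npos <- n - L - P + 1L
  empty <- list(start = integer(0), mismatches = integer(0),
                offsets = list())
  if (npos < 1L) return(empty)
  mm <- integer(npos)
  idx <- seq_len(npos)
  for (j in seq_len(L)) {
    mm <- mm + (chars[idx + j - 1L] != proto[j])
  }
  pam_ok <- rep(TRUE, npos)
  for (k in seq_len(P)) {
    sub <- chars[idx + L + k - 1L]
    pam_ok <- pam_ok & if (pam[k] == "N") sub %in% DNA_BASES else sub == pam[k]
  }
  keep <- which(mm <= max_mismatches & pam_ok)
  if (length(keep) == 0L) return(empty)
  offsets <- lapply(keep, function(i) {
    diff <- which(chars[i:(i + L - 1L)] != proto)
    sort(L - diff + 1L)  # 1..20 counted from the PAM-proximal end
  })
  list(start = keep - 1L, mismatches = mm[keep], offsets = offsets)
}

empty_sites <- function() {
  out <- data.frame(contig = character(0), strand = character(0),
                    proto_start = integer(0), proto_end = integer(0),
                    pam_start = integer(0), pam_end = integer(0),
                    pam_sequence = character(0), cut_position = integer(0),
                    mismatch_count = integer(0), probe_name = character(0),
                    stringsAsFactors = FALSE)
  out$mismatch_offsets <- list()
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

#' Find Cas9 cleavage sites for a probe
#'
#' Scans both strands of a sequence for 20-mer protospacer matches within
#' `max_mismatches` Hamming mismatches that are immediately followed by a
#' PAM (default NGG; 'N' matches any of A/C/G/T) on the same strand. PAM
#' bases are never counted as mismatches, and an 'N' in the subject never
#' matches. Each site carries the blunt cut coordinate 3 bp 5' of the PAM,
#' i.e. between protospacer positions 17 and 18 counted from the PAM-distal
#' end.
#'
#' All intervals are 0-based half-open on the forward strand;
#' `cut_position` is a between-base index on the forward axis (cutting
#' between positions cut_position-1 and cut_position). `mismatch_offsets`
#' are counted 1..20 from the PAM-proximal end of the protospacer.
#'
#' @param sequence DNA string (alphabet A/C/G/T/N).
#' @param probe a `crrna_probe`.
#' @param max_mismatches maximum Hamming mismatches allowed (0-20).
#' @param pam_pattern PAM pattern, default "NGG"; 'N' matches any base,
#'   other letters must match exactly.
#' @param contig contig name recorded in the result.
#' @return A data.frame of class `cleavage_sites`, sorted by forward
#'   coordinate.
#' @export
find_cleavage_sites <- function(sequence, probe, max_mismatches = 0L,
                                pam_pattern = "NGG", contig = "seq") {
  stopifnot(inherits(probe, "crrna_probe"))
  if (max_mismatches < 0 || max_mismatches > 20) {
    stop("max_mismatches must be in [0, 20]", call. = FALSE)
  }
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0) return(empty_sites())
  assert_dna(sequence, "sequence", allow_n = TRUE)
  n <- nchar(sequence)
  L <- 20L
  P <- nchar(pam_pattern)
  proto <- dna_chars(probe$protospacer)
  pam <- dna_chars(toupper(pam_pattern))
  fwd_chars <- dna_chars(sequence)
  rev_chars <- dna_chars(revcomp(sequence))

  fwd <- scan_strand(fwd_chars, proto, pam, max_mismatches)
  rev <- scan_strand(rev_chars, proto, pam, max_mismatches)

  rows <- list()
  if (length(fwd$start) > 0) {
    q <- fwd$start
    rows[[1]] <- data.frame(
      contig = contig, strand = "+",
      proto_start = q, proto_end = q + L,
      pam_start = q + L, pam_end = q + L + P,
      pam_sequence = substring(sequence, q + L + 1L, q + L + P),
      cut_position = q + L - 3L,
      mismatch_count = fwd$mismatches,
      probe_name = probe$name, stringsAsFactors = FALSE
    )
    rows[[1]]$mismatch_offsets <- fwd$offsets
  }
  if (length(rev$start) > 0) {
    q <- rev$start
    rc <- revcomp(sequence)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, strand = "-",
      proto_start = n - q - L, proto_end = n - q,
      pam_start = n - q - L - P, pam_end = n - q - L,
      pam_sequence = substring(rc, q + L + 1L, q + L + P),
      cut_position = n - q - L + 3L,
      mismatch_count = rev$mismatches,
      probe_name = probe$name, stringsAsFactors = FALSE
    )
    rows[[length(rows)]]$mismatch_offsets <- rev$offsets
  }
  if (length(rows) == 0) return(empty_sites())
  out <- do.call(rbind, rows)
  out <- out[order(out$proto_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

## Merge overlapping 0-based half-open intervals; warn if any were merged.
merge_rois <- function(rois) {
  rois <- as.data.frame(rois)
  stopifnot(all(c("start", "end") %in% names(rois)))
  if (any(rois$start < 0) || any(rois$end < rois$start)) {
    stop("ROIs must be non-negative 0-based half-open intervals",
         call. = FALSE)
  }
  ir <- IRanges::IRanges(start = rois$start + 1L, end = rois$end)
  merged <- IRanges::reduce(ir)
  if (length(merged) < length(ir)) {
    warning("overlapping ROIs merged", call. = FALSE)
  }
  data.frame(start = IRanges::start(merged) - 1L,
             end = IRanges::end(merged))
}

#' Report on- and off-target cleavage sites over regions of interest
#'
#' Scans a genome with each probe and classifies every site as inside or
#' outside the given regions of interest (ROIs). Such off-target sites can
#' shorten the enriched region: a probe for one taxon may cleave another
#' taxon's genome near its target region when a similar protospacer with a
#' suitable PAM exists there.
#'
#' @param sequence genome DNA string.
#' @param probes list of `crrna_probe` objects (or a single probe).
#' @param rois data.frame with columns `start`, `end` (0-based half-open);
#'   overlapping ROIs are merged with a warning.
#' @param max_mismatches maximum mismatches for the site scan.
#' @param contig contig name.
#' @return data.frame of class `off_target_report`: one row per site with
#'   columns of `cleavage_sites` plus `inside_roi`, `distance_to_roi` (bp to
#'   the nearest ROI; 0 if inside) and `direction` ("inside", "upstream" if
#'   the site lies before the nearest ROI on the forward axis,
#'   "downstream" otherwise). Sorted by mismatch count then distance.
#' @export
off_target_report <- function(sequence, probes, rois, max_mismatches = 2L,
                              contig = "seq") {
  if (inherits(probes, "crrna_probe")) probes <- list(probes)
  rois <- merge_rois(rois)
  sites <- do.call(rbind, lapply(probes, function(p) {
    find_cleavage_sites(sequence, p, max_mismatches, contig = contig)
  }))
  if (is.null(sites) || nrow(sites) == 0) {
    out <- empty_sites()
    out$inside_roi <- logical(0)
    out$distance_to_roi <- integer(0)
    out$direction <- character(0)
    class(out) <- c("off_target_report", "data.frame")
    return(out)
  }
  dist_dir <- function(s, e) {
    # distance between site interval [s,e) and each ROI; 0 when overlapping
    gaps <- pmax(rois$start - e, s - rois$end, 0)
    i <- which.min(gaps)
    d <- gaps[i]
    dir <- if (d == 0) "inside" else if (e <= rois$start[i]) "upstream"
           else "downstream"
    list(d = d, dir = dir)
  }
  res <- Map(dist_dir, sites$proto_start, sites$proto_end)
  sites$inside_roi <- vapply(res, function(r) r$d == 0, logical(1))
  sites$distance_to_roi <- vapply(res, function(r) r$d, numeric(1))
  sites$direction <- vapply(res, function(r) r$dir, character(1))
  sites <- sites[order(sites$mismatch_count, sites$distance_to_roi), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("off_target_report", "data.frame")
  sites
}

#' Cross-reference conservation of a probe
#'
#' For each reference sequence, reports the best (fewest-mismatch)
#' PAM-adjacent site for the probe, whether it falls within the allowed
#' mismatch budget, and where the mismatches sit relative to the PAM.
#' Mismatch offsets 1-10 from the PAM are classified PAM-proximal (strong
#' effect on cleavage), 11-20 PAM-distal (weak effect). When no NGG follows
#' the best 20-mer match anywhere, the row reports the best PAM-free match
#' with `pam_ok = FALSE`.
#'
#' @param probe a `crrna_probe`.
#' @param references named character vector (or named list) of DNA strings.
#' @param max_mismatches mismatch budget defining `found`.
#' @return data.frame with one row per reference: `reference`, `found`,
#'   `mismatch_count`, `mismatch_offsets` (comma-joined, PAM-proximal end =
#'   1), `n_proximal`, `n_distal`, `pam_ok`.
#' @export
probe_conservation <- function(probe, references, max_mismatches = 4L) {
  if (length(references) == 0) stop("references must be non-empty",
                                    call. = FALSE)
  references <- unlist(references)
  one <- function(ref) {
    sites <- find_cleavage_sites(ref, probe, max_mismatches = 20L)
    if (nrow(sites) > 0) {
      best <- sites[which.min(sites$mismatch_count), ]
      offs <- best$mismatch_offsets[[1]]
      return(data.frame(
        found = best$mismatch_count <= max_mismatches,
        mismatch_count = best$mismatch_count,
        mismatch_offsets = paste(offs, collapse = ","),
        n_proximal = sum(offs <= 10), n_distal = sum(offs > 10),
        pam_ok = TRUE, stringsAsFactors = FALSE
      ))
    }
    # no PAM-adjacent site at all: report best protospacer-only match
    free <- best_free_match(ref, probe)
    data.frame(found = FALSE, mismatch_count = free$mismatches,
               mismatch_offsets = paste(free$offsets, collapse = ","),
               n_proximal = sum(free$offsets <= 10),
               n_distal = sum(free$offsets > 10),
               pam_ok = FALSE, stringsAsFactors = FALSE)
  }
  rows <- lapply(references, one)
  out <- cbind(data.frame(reference = names(references),
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

## Best protospacer match on either strand ignoring the PAM requirement.
best_free_match <- function(sequence, probe) {
  proto <- dna_chars(probe$protospacer)
  L <- length(proto)
  best <- list(mismatches = L, offsets = seq_len(L))
  for (s in list(dna_chars(toupper(sequence)),
                 dna_chars(revcomp(toupper(sequence))))) {
    npos <- length(s) - L + 1L
    if (npos < 1L) next
    mm <- integer(npos)
    idx <- seq_len(npos)
    for (j in seq_len(L)) mm <- mm + (s[idx + j - 1L] != proto[j])
    i <- which.min(mm)
    if (mm[i] < best$mismatches) {
      diff <- which(s[i:(i + L - 1L)] != proto)
      best <- list(mismatches = mm[i], offsets = sort(L - diff + 1L))
    }
  }
  best
}
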