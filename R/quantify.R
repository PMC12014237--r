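## k-mer set of one sequence (forward only)
kmer_set <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

finalize_assignments <- function(df, n_unassigned, unassigned_ids) {
  rownames(df) <- NULL
  attr(df, "n_unassigned") <- n_unassigned
  attr(df, "unassigned") <- unassigned_ids
  class(df) <- c("read_assignments", "data.frame")
  df
}

#' Assign reads to marker references
#'
#' Each read receives at most one assignment: the reference with the best
#' alignment identity (ties broken by longer aligned span, then
#' lexicographic reference name); reads whose best identity falls below
#' `min_identity` are left unassigned and counted. Identity is defined as
#' matching bases divided by alignment columns (including indel columns),
#' appropriate for indel-rich long reads.
#'
#' Candidate references are pre-screened by shared k-mer counts on both
#' strands, then scored by global unit-cost (Levenshtein) alignment:
#' identity = matches / (matches + substitutions + insertions +
#' deletions), i.e. matches over alignment columns. Reads identical to a
#' reference (or its reverse complement) short-circuit to identity 1, and
#' candidates whose length ratio caps the achievable identity below
#' `min_identity` are skipped without alignment.
#'
#' @param reads a `simulated_reads` object, a data.frame with `read_id` and
#'   `sequence`, a named character vector, or a FASTQ file path.
#' @param references named character vector of reference sequences, a
#'   `DNAStringSet`, or a FASTA file path.
#' @param min_identity minimum identity for assignment (paper-style
#'   default 0.98).
#' @param k k-mer size for the candidate pre-screen.
#' @param max_candidates maximum references aligned per read.
#' @return A data.frame of class `read_assignments` with columns `read_id`,
#'   `reference`, `identity`, `ref_start`, `ref_end` (0-based half-open),
#'   `strand`, `aligned_bases`; attributes `n_unassigned` and `unassigned`
#'   (read ids).
#' @export
assign_reads <- function(reads, references, min_identity = 0.98, k = 13L,
                         max_candidates = 3L) {
  reads <- as_read_table(reads)
  refs <- as_reference_vector(references)
  if (length(refs) == 0) stop("references must be non-empty", call. = FALSE)
  assert_fraction(min_identity, "min_identity")

  ref_names <- names(refs)
  ref_kmers <- lapply(refs, kmer_set, k = k)
  ref_rc <- vapply(refs, revcomp, character(1))
  rows <- vector("list", nrow(reads))
  unassigned <- character(0)
  for (i in seq_len(nrow(reads))) {
    seq_f <- reads$sequence[i]
    hit <- NULL
    # exact-match fast path (error-free reads)
    exact <- which(refs == seq_f)
    strand <- "+"
    if (length(exact) == 0) {
      exact <- which(ref_rc == seq_f)
      strand <- "-"
    }
    if (length(exact) > 0) {
      r <- sort(ref_names[exact])[1]
      hit <- list(reference = r, identity = 1, ref_start = 0L,
                  ref_end = nchar(refs[[r]]), strand = strand,
                  aligned_bases = nchar(refs[[r]]))
    } else {
      seq_r <- revcomp(seq_f)
      km_f <- kmer_set(seq_f, k)
      km_r <- kmer_set(seq_r, k)
      shared_f <- vapply(ref_kmers, function(ks) sum(km_f %in% ks),
                         numeric(1))
      shared_r <- vapply(ref_kmers, function(ks) sum(km_r %in% ks),
                         numeric(1))
      shared <- pmax(shared_f, shared_r)
      cand <- order(shared, decreasing = TRUE)
      cand <- cand[shared[cand] > 0]
      cand <- utils::head(cand, max_candidates)
      best <- NULL
      len_f <- nchar(seq_f)
      for (j in cand) {
        # global identity is bounded by min(len)/max(len); skip candidates
        # that cannot reach min_identity (long background slices, partial
        # digestion fragments)
        len_r <- nchar(refs[[j]])
        if (min(len_f, len_r) / max(len_f, len_r) < min_identity) next
        orient <- if (shared_f[j] >= shared_r[j]) "+" else "-"
        query <- if (orient == "+") seq_f else seq_r
        d <- utils::adist(query, refs[[j]], counts = TRUE)
        cnt <- attr(d, "counts")
        n_ins <- cnt[1, 1, "ins"]   # reference bases absent from the read
        n_del <- cnt[1, 1, "del"]   # read bases absent from the reference
        n_sub <- cnt[1, 1, "sub"]
        matches <- len_f - n_del - n_sub
        ident <- matches / (matches + n_sub + n_ins + n_del)
        span <- matches + n_sub
        rec <- list(reference = ref_names[j], identity = ident,
                    ref_start = 0L, ref_end = len_r, strand = orient,
                    aligned_bases = span)
        if (is.null(best) ||
            ident > best$identity + 1e-12 ||
            (abs(ident - best$identity) <= 1e-12 &&
             (span > best$aligned_bases ||
              (span == best$aligned_bases &&
               rec$reference < best$reference)))) {
          best <- rec
        }
      }
      if (!is.null(best) && best$identity >= min_identity) hit <- best
    }
    if (is.null(hit)) {
      unassigned <- c(unassigned, reads$read_id[i])
    } else {
      rows[[i]] <- data.frame(read_id = reads$read_id[i],
                              reference = hit$reference,
                              identity = hit$identity,
                              ref_start = hit$ref_start,
                              ref_end = hit$ref_end, strand = hit$strand,
                              aligned_bases = hit$aligned_bases,
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) {
    df <- data.frame(read_id = character(0), reference = character(0),
                     identity = numeric(0), ref_start = integer(0),
                     ref_end = integer(0), strand = character(0),
                     aligned_bases = integer(0), stringsAsFactors = FALSE)
  }
  finalize_assignments(df, length(unassigned), unassigned)
}

as_read_table <- function(reads) {
  if (inherits(reads, "simulated_reads")) return(reads$reads)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    return(read_fastq(reads))
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(reads))
    return(data.frame(read_id = ids, sequence = unname(reads),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in%
                                        names(reads)))
  reads
}

as_reference_vector <- function(references) {
  if (inherits(references, "DNAStringSet")) {
    return(stats::setNames(as.character(references), names(references)))
  }
  if (is.character(references) && length(references) == 1 &&
      file.exists(references)) {
    dna <- Biostrings::readDNAStringSet(references)
    names(dna) <- sub("\\s.*", "", names(dna))
    return(stats::setNames(as.character(dna), names(dna)))
  }
  stopifnot(is.character(references), !is.null(names(references)))
  references
}

#' Read assignments from a PAF alignment file
#'
#' Parses minimap2-dialect PAF (columns 1-12; optional tags ignored) and
#' applies the same best-hit and minimum-identity policy as
#' [assign_reads()]. Identity is residue matches (column 10) over alignment
#' block length (column 11).
#'
#' @param path PAF file path.
#' @param min_identity minimum identity for assignment.
#' @return A `read_assignments` data.frame.
#' @export
read_paf <- function(path, min_identity = 0.98) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(finalize_assignments(
      data.frame(read_id = character(0), reference = character(0),
                 identity = numeric(0), ref_start = integer(0),
                 ref_end = integer(0), strand = character(0),
                 aligned_bases = integer(0), stringsAsFactors = FALSE),
      0L, character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 12)
  if (length(bad) > 0) {
    stop(sprintf("malformed PAF record at line %d of %s", bad[1], path),
         call. = FALSE)
  }
  df <- data.frame(
    read_id = vapply(fields, `[[`, character(1), 1),
    strand = vapply(fields, `[[`, character(1), 5),
    reference = vapply(fields, `[[`, character(1), 6),
    ref_start = as.integer(vapply(fields, `[[`, character(1), 8)),
    ref_end = as.integer(vapply(fields, `[[`, character(1), 9)),
    matches = as.numeric(vapply(fields, `[[`, character(1), 10)),
    block_len = as.numeric(vapply(fields, `[[`, character(1), 11)),
    stringsAsFactors = FALSE
  )
  df$identity <- df$matches / df$block_len
  df$aligned_bases <- as.integer(df$matches)
  # best hit per read: identity, then aligned span, then reference name
  df <- df[order(df$read_id, -df$identity, -df$aligned_bases,
                 df$reference), , drop = FALSE]
  df <- df[!duplicated(df$read_id), , drop = FALSE]
  keep <- df$identity >= min_identity
  unassigned <- df$read_id[!keep]
  df <- df[keep, c("read_id", "reference", "identity", "ref_start",
                   "ref_end", "strand", "aligned_bases")]
  finalize_assignments(df, length(unassigned), unassigned)
}

normalize_rois <- function(roi) {
  if (is.numeric(roi) && length(roi) == 2) {
    roi <- data.frame(start = roi[1], end = roi[2])
  }
  if (is.list(roi) && !is.data.frame(roi)) {
    roi <- do.call(rbind, lapply(roi, function(r) {
      data.frame(start = r[1], end = r[2])
    }))
  }
  stopifnot(all(c("start", "end") %in% names(roi)))
  roi
}

#' On-target versus off-target read accounting
#'
#' A read counts as on-target when at least `min_overlap` of its aligned
#' span overlaps a target region (any copy, if several intervals are
#' given); exactly the threshold counts as on-target.
#'
#' @param assignments a `read_assignments` data.frame on one genome.
#' @param roi target region(s): c(start, end), a list of such, or a
#'   data.frame with `start`/`end` (0-based half-open).
#' @param min_overlap minimum overlapping fraction of the aligned span.
#' @return list(R_target, R_total, on_target_fraction).
#' @export
on_target_stats <- function(assignments, roi, min_overlap = 0.5) {
  roi <- normalize_rois(roi)
  R_total <- nrow(assignments)
  if (R_total == 0) return(list(R_target = 0L, R_total = 0L,
                                on_target_fraction = NaN))
  s <- assignments$ref_start
  e <- assignments$ref_end
  span <- pmax(e - s, 1L)
  frac <- rep(0, R_total)
  for (j in seq_len(nrow(roi))) {
    ov <- pmax(0, pmin(e, roi$end[j]) - pmax(s, roi$start[j]))
    frac <- pmax(frac, ov / span)
  }
  R_target <- sum(frac >= min_overlap)
  list(R_target = as.integer(R_target), R_total = as.integer(R_total),
       on_target_fraction = R_target / R_total)
}

#' Fold-enrichment of a target region
#'
#' Computes the fold increase in reads covering the target over the
#' uniform-coverage expectation:
#' E = (R_target * G) / (R_total * L_target * N_target),
#' where R_target / R_total are on-target / total reads, G the genome size
#' in bp, L_target the target-region length in bp and N_target the number
#' of copies of the target region per genome. Uniformly scattered reads
#' give E ~ 1; E has no upper bound.
#'
#' @param R_target on-target read count.
#' @param R_total total assigned read count (> 0).
#' @param G genome size in bp.
#' @param L_target target region length in bp.
#' @param N_target target copies per genome (>= 1).
#' @return A list of class `enrichment_report` holding all inputs plus `E`
#'   and `on_target_fraction`.
#' @export
enrichment_score <- function(R_target, R_total, G, L_target, N_target) {
  if (R_total <= 0) stop("R_total must be > 0", call. = FALSE)
  if (G <= 0 || L_target <= 0) stop("G and L_target must be > 0",
                                    call. = FALSE)
  if (N_target < 1) stop("N_target must be >= 1", call. = FALSE)
  if (R_target < 0 || R_target > R_total) {
    stop("R_target must lie in [0, R_total]", call. = FALSE)
  }
  structure(list(
    R_target = R_target, R_total = R_total, G = G, L_target = L_target,
    N_target = N_target,
    E = (as.numeric(R_target) * as.numeric(G)) /
      (as.numeric(R_total) * as.numeric(L_target) *
         as.numeric(N_target)),
    on_target_fraction = R_target / R_total
  ), class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "enrichment: E = %.1f-fold (%d/%d reads on target, %.1f%%; G = %.3g bp, L = %g bp, N = %d)\n",
    x$E, x$R_target, x$R_total, 100 * x$on_target_fraction, x$G,
    x$L_target, x$N_target))
  invisible(x)
}

#' Stranded per-base coverage profile
#'
#' For each position of the reference, the proportion of all aligned bases
#' in the run that cover that position on the forward and reverse strands.
#' A sharply enriched target region shows as a plateau rising at the
#' forward-probe cut site and falling at the reverse-probe cut site.
#'
#' @param assignments a `read_assignments` data.frame on one reference.
#' @param reference_length reference length in bp.
#' @return list(forward, reverse): numeric vectors of length
#'   `reference_length`.
#' @export
coverage_profile <- function(assignments, reference_length) {
  fwd <- numeric(reference_length)
  rev <- numeric(reference_length)
  add <- function(acc, s, e) {
    # cumsum difference trick over 0-based half-open intervals
    d <- numeric(reference_length + 1L)
    for (i in seq_along(s)) {
      a <- max(0L, s[i])
      b <- min(reference_length, e[i])
      if (b > a) {
        d[a + 1L] <- d[a + 1L] + 1
        d[b + 1L] <- d[b + 1L] - 1
      }
    }
    acc + cumsum(d)[seq_len(reference_length)]
  }
  is_f <- assignments$strand == "+"
  fwd <- add(fwd, assignments$ref_start[is_f], assignments$ref_end[is_f])
  rev <- add(rev, assignments$ref_start[!is_f], assignments$ref_end[!is_f])
  total <- sum(fwd) + sum(rev)
  if (total > 0) {
    fwd <- fwd / total
    rev <- rev / total
  }
  list(forward = fwd, reverse = rev)
}

#' Read-length histogram
#'
#' @param reads a `simulated_reads` object, data.frame with `sequence`, or
#'   a numeric vector of read lengths.
#' @param bin_width bin width in bp (>= 1).
#' @return data.frame (`bin_start`, `bin_end`, `count`) with attribute
#'   `modal_bin` = c(start, end) of the fullest bin.
#' @export
read_length_histogram <- function(reads, bin_width = 100L) {
  stopifnot(bin_width >= 1)
  lens <- if (is.numeric(reads)) {
    reads
  } else {
    if (inherits(reads, "simulated_reads")) reads <- reads$reads
    nchar(reads$sequence)
  }
  if (length(lens) == 0) {
    out <- data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0))
    attr(out, "modal_bin") <- NULL
    return(out)
  }
  bin <- floor(lens / bin_width)
  tab <- table(bin)
  starts <- as.integer(names(tab)) * bin_width
  out <- data.frame(bin_start = starts, bin_end = starts + bin_width,
                    count = as.integer(tab))
  out <- out[order(out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  m <- which.max(out$count)
  attr(out, "modal_bin") <- c(out$bin_start[m], out$bin_end[m])
  out
}

#' Observed community proportions from read assignments
#'
#' `read_count` mode: each reference's proportion is its share of assigned
#' reads. `mean_depth` mode: proportional to aligned bases per reference
#' divided by reference length (mean coverage depth), normalized. With
#' full-length marker reads the two modes nearly coincide.
#'
#' @param assignments a `read_assignments` data.frame.
#' @param references named character vector of reference sequences or
#'   named numeric vector of reference lengths (required for `mean_depth`;
#'   also fixes the label set, so references with zero reads report 0).
#' @param mode "read_count" or "mean_depth".
#' @return A `proportion_vector` over references.
#' @export
observed_proportions <- function(assignments, references = NULL,
                                 mode = c("read_count", "mean_depth")) {
  mode <- match.arg(mode)
  if (nrow(assignments) == 0) {
    stop("no signal: zero assigned reads", call. = FALSE)
  }
  labels <- if (!is.null(references)) names(references)
            else sort(unique(assignments$reference))
  if (mode == "read_count") {
    counts <- table(factor(assignments$reference, levels = labels))
    w <- as.numeric(counts)
  } else {
    if (is.null(references)) {
      stop("mean_depth mode requires reference lengths", call. = FALSE)
    }
    lens <- if (is.character(references)) nchar(references)
            else as.numeric(references)
    ab <- tapply(assignments$aligned_bases,
                 factor(assignments$reference, levels = labels), sum,
                 default = 0)
    w <- as.numeric(ab) / lens
  }
  proportion_vector(labels, w / sum(w))
}

#' Aggregate proportions to a taxonomic rank
#'
#' Long-read error rates can be too high to classify single reads to
#' species reliably; aggregating to genus trades resolution for accuracy.
#'
#' @param proportions a `proportion_vector` labelled by reference/species.
#' @param taxonomy a data.frame with columns `reference`, `species`,
#'   `genus` (or a named list mapping label -> c(species, genus)).
#' @param rank "species" or "genus".
#' @return A `proportion_vector` at the requested rank.
#' @export
aggregate_rank <- function(proportions, taxonomy,
                           rank = c("species", "genus")) {
  rank <- match.arg(rank)
  if (length(proportions) == 0) stop("empty proportion vector",
                                     call. = FALSE)
  if (!is.data.frame(taxonomy)) {
    taxonomy <- data.frame(
      reference = names(taxonomy),
      species = vapply(taxonomy, `[[`, character(1), 1),
      genus = vapply(taxonomy, `[[`, character(1), 2),
      stringsAsFactors = FALSE)
  }
  labels <- names(proportions)
  idx <- match(labels, taxonomy$reference)
  if (anyNA(idx)) {
    stop("label(s) missing from taxonomy: ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  group <- taxonomy[[rank]][idx]
  agg <- tapply(as.numeric(proportions), group, sum)
  proportion_vector(names(agg), as.numeric(agg) / sum(agg))
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement of paired observations with the identity line,
#' penalizing both precision (scatter) and accuracy (location and scale
#' shifts):
#' rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2),
#' with population (divisor-n) moments. rho_c equals the Pearson
#' correlation only when means and variances agree; a pure location shift
#' gives |rho_c| < |r| even at r = 1.
#'
#' @param x,y numeric vectors of equal length >= 2; not both constant.
#' @return A list of class `concordance_result`: `rho_c`, `pearson_r`,
#'   `mean_x`, `mean_y`, `var_x`, `var_y`, `n`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) {
    stop("concordance undefined: both vectors constant", call. = FALSE)
  }
  cxy <- mean((x - mx) * (y - my))
  rho_c <- 2 * cxy / (vx + vy + (mx - my)^2)
  pearson <- if (vx > 0 && vy > 0) cxy / sqrt(vx * vy) else NA_real_
  structure(list(rho_c = rho_c, pearson_r = pearson, mean_x = mx,
                 mean_y = my, var_x = vx, var_y = vy, n = n),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Lin's CCC: rho_c = %.4f (Pearson r = %.4f, n = %d)\n",
              x$rho_c, x$pearson_r, x$n))
  invisible(x)
}
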