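#' Nanopore-like read error model
#'
#' Per-base i.i.d. substitution, insertion and deletion rates. Defaults
#' emulate older-pore long reads at ~96.5% accuracy (3.5% total errors,
#' indel-rich platforms would shift mass between the three rates).
#'
#' @param substitution_rate per-base substitution probability.
#' @param insertion_rate per-base probability of inserting a random base
#'   after the current one.
#' @param deletion_rate per-base deletion probability.
#' @param quality_char constant character used for FASTQ quality strings.
#' @param seed integer seed for the read simulation.
#' @return A list of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.025, insertion_rate = 0.005,
                        deletion_rate = 0.005, quality_char = "=",
                        seed = 1L) {
  for (r in c(substitution_rate, insertion_rate, deletion_rate)) {
    assert_fraction(r, "error rate")
  }
  if (substitution_rate + insertion_rate + deletion_rate >= 1) {
    stop("error rates must sum to < 1", call. = FALSE)
  }
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 quality_char = quality_char, seed = as.integer(seed)),
            class = "error_model")
}

## Build a library_molecules data.frame. End-state columns encode, per end:
## origin ("native" or "cas9_cut"), whether a sequencing adapter can ligate,
## and which probe's Cas9 blocks the end (empty if none).
new_molecules <- function(contig, start, end, sequence, left_origin,
                          left_ligatable, left_block, right_origin,
                          right_ligatable, right_block, source_species,
                          is_background, copy_weight = 1) {
  out <- data.frame(
    contig = contig, start = start, end = end, sequence = sequence,
    left_origin = left_origin, left_ligatable = left_ligatable,
    left_blocking_probe = left_block, right_origin = right_origin,
    right_ligatable = right_ligatable, right_blocking_probe = right_block,
    source_species = source_species, is_background = is_background,
    copy_weight = copy_weight, stringsAsFactors = FALSE
  )
  class(out) <- c("library_molecules", "data.frame")
  out
}

#' In-silico Cas9 digestion of a genome
#'
#' Cuts the genome at each cleavage site independently with probability
#' `cleavage_prob` and tracks the ligatability of every fragment end. The
#' genome's original termini are dephosphorylated (native, non-ligatable).
#' At each realized cut the Cas9 remains bound to the PAM-side fragment
#' (the one carrying the PAM and the PAM-proximal protospacer bases),
#' blocking adapter ligation there, while the PAM-distal side exposes a
#' ligatable 5' phosphate. With probes oriented so their PAMs face away
#' from the region of interest, the excised target fragment therefore gets
#' two ligatable ends. Set `pam_side_blocked = FALSE` to flip the
#' convention.
#'
#' @param sequence genome DNA string.
#' @param sites a `cleavage_sites` data.frame (possibly from several
#'   probes, rbind-ed).
#' @param cleavage_prob per-site cut probability in [0, 1].
#' @param seed integer seed.
#' @param contig contig name; sites must lie within the sequence.
#' @param source_species species label carried into the fragments.
#' @param pam_side_blocked single convention switch, see Description.
#' @return A `library_molecules` data.frame whose fragments partition the
#'   genome (ordered concatenation of `sequence` reproduces the input).
#' @export
digest <- function(sequence, sites, cleavage_prob = 0.9, seed = 1L,
                   contig = "seq", source_species = "",
                   pam_side_blocked = TRUE) {
  assert_fraction(cleavage_prob, "cleavage_prob")
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (!is.null(sites) && nrow(sites) > 0) {
    if (any(sites$cut_position < 0 | sites$cut_position > n)) {
      stop("site cut_position outside the contig", call. = FALSE)
    }
    realized <- with_seed(seed,
                          stats::runif(nrow(sites)) < cleavage_prob)
    sites <- sites[realized, , drop = FALSE]
    sites <- sites[!duplicated(sites$cut_position), , drop = FALSE]
    sites <- sites[order(sites$cut_position), , drop = FALSE]
  } else {
    sites <- empty_sites()
  }
  cuts <- sites$cut_position
  bounds <- c(0L, cuts, n)
  k <- length(bounds) - 1L
  # for a '+' site the PAM lies right of the cut; for '-' left of it
  pam_right <- sites$strand == "+"
  blocked_right_of_cut <- if (pam_side_blocked) pam_right else !pam_right
  left_origin <- c("native", rep("cas9_cut", length(cuts)))
  right_origin <- c(rep("cas9_cut", length(cuts)), "native")
  left_lig <- c(FALSE, !blocked_right_of_cut)
  right_lig <- c(blocked_right_of_cut, FALSE)
  left_block <- c("", ifelse(blocked_right_of_cut, sites$probe_name, ""))
  right_block <- c(ifelse(blocked_right_of_cut, "", sites$probe_name), "")
  new_molecules(
    contig = rep(contig, k),
    start = bounds[-length(bounds)], end = bounds[-1L],
    sequence = substring(sequence, bounds[-length(bounds)] + 1L,
                         bounds[-1L]),
    left_origin = left_origin, left_ligatable = left_lig,
    left_block = left_block,
    right_origin = right_origin, right_ligatable = right_lig,
    right_block = right_block,
    source_species = rep(source_species, k),
    is_background = rep(FALSE, k)
  )
}

#' Count ligatable ends per molecule
#' @param molecules a `library_molecules` data.frame.
#' @return integer vector.
#' @export
ligatable_ends <- function(molecules) {
  as.integer(molecules$left_ligatable) + as.integer(molecules$right_ligatable)
}

#' Sample a sequencing library from digested fragments
#'
#' With probability `1 - background_rate` a molecule is drawn (with
#' replacement) from the fragments that have at least one ligatable end,
#' weighted by `copy_weight x number of ligatable ends`; with probability
#' `background_rate` the molecule is a uniform random slice of the genome
#' (length log-normal, truncated to the contig) representing residual
#' un-dephosphorylated or fragmented DNA that escaped end protection.
#'
#' @param fragments a `library_molecules` data.frame from [digest()];
#'   digests of several genomes, and several replicate digestions of the
#'   same genome (independent template molecules), may be rbind-ed.
#' @param n_molecules number of library molecules to draw.
#' @param background_rate probability a molecule is background.
#' @param background_length c(mean, sd) of the background length
#'   distribution in bp (log-normal with that mean and sd).
#' @param seed integer seed.
#' @param genomes optional named character vector of the genome sequence
#'   per contig, used for background slices; if NULL the genomes are
#'   reconstructed from the fragments.
#' @return A `library_molecules` data.frame with `n_molecules` rows.
#' @export
sample_library <- function(fragments, n_molecules,
                           background_rate = 0,
                           background_length = c(3000, 2000),
                           seed = 1L, genomes = NULL) {
  assert_fraction(background_rate, "background_rate")
  stopifnot(n_molecules >= 1)
  lig <- ligatable_ends(fragments)
  weights <- fragments$copy_weight * lig
  if (sum(weights) == 0 && background_rate == 0) {
    stop("empty library: no ligatable fragments and background_rate is 0",
         call. = FALSE)
  }
  mu <- background_length[1]
  sdv <- background_length[2]
  sdlog <- sqrt(log(1 + (sdv / mu)^2))
  meanlog <- log(mu) - sdlog^2 / 2
  contigs <- unique(fragments$contig)
  if (is.null(genomes)) {
    # greedy tiling from any mixture of replicate digests: repeatedly take
    # a fragment starting exactly at the current end
    genomes <- vapply(contigs, function(ct) {
      fr <- fragments[fragments$contig == ct, , drop = FALSE]
      fr <- fr[order(fr$start, fr$end), , drop = FALSE]
      keep <- logical(nrow(fr))
      at <- 0L
      for (i in seq_len(nrow(fr))) {
        if (fr$start[i] == at) {
          keep[i] <- TRUE
          at <- fr$end[i]
        }
      }
      paste(fr$sequence[keep], collapse = "")
    }, character(1))
  } else {
    missing_ct <- setdiff(contigs, names(genomes))
    if (length(missing_ct) > 0) {
      stop("genomes missing for contig(s): ",
           paste(missing_ct, collapse = ", "), call. = FALSE)
    }
    genomes <- genomes[contigs]
  }
  contig_weight <- vapply(contigs, function(ct) {
    max(fragments$copy_weight[fragments$contig == ct])
  }, numeric(1)) * nchar(genomes)

  with_seed(seed, {
    is_bg <- stats::runif(n_molecules) < background_rate
    n_bg <- sum(is_bg)
    n_tg <- n_molecules - n_bg
    out <- list()
    if (n_tg > 0) {
      if (sum(weights) == 0) {
        stop("empty library: no ligatable fragments to draw from",
             call. = FALSE)
      }
      idx <- sample.int(nrow(fragments), n_tg, replace = TRUE,
                        prob = weights)
      tg <- fragments[idx, , drop = FALSE]
      tg$copy_weight <- 1
      out$target <- tg
    }
    if (n_bg > 0) {
      ct <- sample(seq_along(contigs), n_bg, replace = TRUE,
                   prob = contig_weight)
      glen <- nchar(genomes)[ct]
      len <- pmax(50L, as.integer(round(stats::rlnorm(n_bg, meanlog,
                                                      sdlog))))
      start <- vapply(seq_len(n_bg), function(i) {
        as.integer(floor(stats::runif(1, 0, max(1, glen[i] - len[i]))))
      }, integer(1))
      end <- pmin(start + len, glen)
      out$background <- new_molecules(
        contig = contigs[ct], start = start, end = end,
        sequence = substring(genomes[ct], start + 1L, end),
        left_origin = "native", left_ligatable = TRUE, left_block = "",
        right_origin = "native", right_ligatable = TRUE, right_block = "",
        source_species = vapply(ct, function(i) {
          fragments$source_species[fragments$contig == contigs[i]][1]
        }, character(1)),
        is_background = TRUE
      )
    }
    res <- do.call(rbind, out)
    # restore draw order so target/background are interleaved as drawn
    ord <- integer(n_molecules)
    ord[!is_bg] <- seq_len(n_tg)
    ord[is_bg] <- n_tg + seq_len(n_bg)
    res <- res[ord, , drop = FALSE]
    rownames(res) <- NULL
    class(res) <- c("library_molecules", "data.frame")
    res
  })
}

## Apply i.i.d. substitution/insertion/deletion errors to one sequence.
## Returns list(sequence, n_sub, n_ins, n_del). RNG state is the caller's.
apply_errors <- function(sequence, ps, pi, pd) {
  chars <- dna_chars(sequence)
  n <- length(chars)
  sub_idx <- which(stats::runif(n) < ps)
  if (length(sub_idx) > 0) {
    chars[sub_idx] <- vapply(chars[sub_idx], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  del <- stats::runif(n) < pd
  ins <- stats::runif(n) < pi
  n_ins <- sum(ins)
  ins_bases <- if (n_ins > 0) sample(DNA_BASES, n_ins, replace = TRUE)
               else character(0)
  pieces <- character(n)
  pieces[!del] <- chars[!del]
  j <- 0L
  for (i in which(ins)) {
    j <- j + 1L
    pieces[i] <- paste0(pieces[i], ins_bases[j])
  }
  list(sequence = paste(pieces, collapse = ""),
       n_sub = length(sub_idx), n_ins = n_ins, n_del = sum(del))
}

#' Simulate nanopore-like reads from library molecules
#'
#' Each molecule yields one read. Sequencing starts from a uniformly chosen
#' ligatable end (background molecules: either end): starting from the left
#' end reads the forward strand ('+'), from the right end the reverse
#' complement ('-'). Errors are applied per base i.i.d. at the model's
#' rates. Identical seeds give identical output.
#'
#' @param molecules a `library_molecules` data.frame.
#' @param model an [error_model()].
#' @return A list of class `simulated_reads`: `reads` (data.frame read_id,
#'   sequence, quality) and `truth` (data.frame read_id, species, contig,
#'   start, end, strand, is_background, n_sub, n_ins, n_del).
#' @export
simulate_reads <- function(molecules, model = error_model()) {
  stopifnot(inherits(model, "error_model"))
  if (nrow(molecules) == 0) stop("molecules must be non-empty",
                                 call. = FALSE)
  zero_len <- nchar(molecules$sequence) == 0
  if (any(zero_len)) {
    warning(sum(zero_len), " zero-length molecule(s) skipped",
            call. = FALSE)
    molecules <- molecules[!zero_len, , drop = FALSE]
  }
  ps <- model$substitution_rate
  pi <- model$insertion_rate
  pd <- model$deletion_rate
  n <- nrow(molecules)
  with_seed(model$seed, {
    strand <- character(n)
    for (i in seq_len(n)) {
      ends <- if (molecules$is_background[i]) {
        c(TRUE, TRUE)
      } else {
        c(molecules$left_ligatable[i], molecules$right_ligatable[i])
      }
      avail <- which(ends)
      if (length(avail) == 0) avail <- c(1L, 2L)  # defensive; not reachable
      pick <- if (length(avail) == 1) avail else sample(avail, 1L)
      strand[i] <- if (pick == 1L) "+" else "-"
    }
    seqs <- ifelse(strand == "+", molecules$sequence, NA)
    for (i in which(strand == "-")) seqs[i] <- revcomp(molecules$sequence[i])
    if (ps == 0 && pi == 0 && pd == 0) {
      err <- list(sequence = seqs, n_sub = integer(n), n_ins = integer(n),
                  n_del = integer(n))
    } else {
      res <- lapply(seqs, apply_errors, ps = ps, pi = pi, pd = pd)
      err <- list(sequence = vapply(res, `[[`, character(1), "sequence"),
                  n_sub = vapply(res, `[[`, integer(1), "n_sub"),
                  n_ins = vapply(res, `[[`, integer(1), "n_ins"),
                  n_del = vapply(res, `[[`, integer(1), "n_del"))
    }
    ids <- sprintf("read_%06d", seq_len(n))
    structure(list(
      reads = data.frame(read_id = ids, sequence = err$sequence,
                         quality = strrep(model$quality_char,
                                          nchar(err$sequence)),
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = ids, species = molecules$source_species,
                         contig = molecules$contig,
                         start = molecules$start, end = molecules$end,
                         strand = strand,
                         is_background = molecules$is_background,
                         n_sub = err$n_sub, n_ins = err$n_ins,
                         n_del = err$n_del, stringsAsFactors = FALSE)
    ), class = "simulated_reads")
  })
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("%d simulated reads (%d background)\n", nrow(x$reads),
              sum(x$truth$is_background)))
  invisible(x)
}

#' Build read-to-genome assignments from a simulation truth table
#'
#' For simulated data the true genomic interval of every read is known, so
#' the error-free assignment of reads to the genome can be constructed
#' directly; this is the idealized counterpart of mapping reads back with
#' an aligner and is used for enrichment accounting on simulations.
#'
#' @param truth a truth table from [simulate_reads()], or a
#'   `library_molecules` data.frame (one read per molecule, forward
#'   strand).
#' @return A `read_assignments` data.frame (see [assign_reads()]).
#' @export
assignments_from_truth <- function(truth) {
  if (inherits(truth, "simulated_reads")) truth <- truth$truth
  if (inherits(truth, "library_molecules")) {
    truth <- data.frame(read_id = sprintf("mol_%06d", seq_len(nrow(truth))),
                        contig = truth$contig, start = truth$start,
                        end = truth$end, strand = "+",
                        stringsAsFactors = FALSE)
  }
  out <- data.frame(read_id = truth$read_id, reference = truth$contig,
                    identity = 1, ref_start = truth$start,
                    ref_end = truth$end, strand = truth$strand,
                    aligned_bases = truth$end - truth$start,
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- 0L
  class(out) <- c("read_assignments", "data.frame")
  out
}
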