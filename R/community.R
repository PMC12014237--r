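#' Construct a mock-community specification
#'
#' A community is an ordered table of members, each with a genomic-DNA mass
#' fraction, a genome size and the number of copies of the marker (rDNA-like)
#' target region per genome. These three quantities are what convert a mass
#' composition into an expected marker-gene read composition.
#'
#' @param species character vector of unique species names.
#' @param taxon_group character vector, one of "nematode", "bacteria",
#'   "yeast" per member.
#' @param mass_fraction numeric, gDNA mass share per member; renormalized to
#'   sum to 1.
#' @param genome_size numeric, genome sizes in bp.
#' @param marker_copies integer, marker copies per genome (NA if unknown).
#' @param genus character vector for rank aggregation.
#' @param name community name.
#' @return A data.frame of class `community_spec`.
#' @export
community_spec <- function(species, taxon_group, mass_fraction, genome_size,
                           marker_copies, genus, name = "community") {
  if (anyDuplicated(species)) {
    stop("species names must be unique", call. = FALSE)
  }
  groups <- c("nematode", "bacteria", "yeast")
  if (!all(taxon_group %in% groups)) {
    stop("taxon_group must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  if (any(mass_fraction < 0) || any(genome_size <= 0)) {
    stop("mass fractions must be >= 0 and genome sizes > 0", call. = FALSE)
  }
  if (any(!is.na(marker_copies) & marker_copies < 1)) {
    stop("marker_copies must be >= 1 where known", call. = FALSE)
  }
  total <- sum(mass_fraction)
  if (total <= 0) stop("total mass must be positive", call. = FALSE)
  spec <- data.frame(
    species = as.character(species),
    taxon_group = as.character(taxon_group),
    mass_fraction = mass_fraction / total,
    genome_size = as.numeric(genome_size),
    marker_copies = as.integer(marker_copies),
    genus = as.character(genus),
    stringsAsFactors = FALSE
  )
  attr(spec, "name") <- name
  class(spec) <- c("community_spec", "data.frame")
  spec
}

#' Load a community table from TSV
#'
#' Expects a UTF-8 TSV with header columns `species`, `taxon_group`,
#' `mass_pct`, `genome_size_mbp`, `marker_copies`, `genus`. Mass percentages
#' are on the 0-100 scale and are renormalized to fractions summing to 1
#' (with a warning if they do not sum to 100); genome sizes are given in Mbp
#' as conventionally printed and converted to bp internally.
#'
#' @param path path to the TSV file.
#' @param name community name (defaults to the file stem).
#' @return A `community_spec`.
#' @export
load_community_table <- function(path,
                                 name = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "-"))
  required <- c("species", "taxon_group", "mass_pct", "genome_size_mbp",
                "marker_copies", "genus")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("community table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("mass_pct", "genome_size_mbp")) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("non-numeric or negative %s in row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  total <- sum(tab$mass_pct)
  if (abs(total - 100) > 0.1) {
    warning(sprintf("mass percentages sum to %.4g, not 100; renormalizing",
                    total), call. = FALSE)
  }
  community_spec(
    species = tab$species,
    taxon_group = tab$taxon_group,
    mass_fraction = tab$mass_pct / total,
    genome_size = tab$genome_size_mbp * 1e6,
    marker_copies = tab$marker_copies,
    genus = tab$genus,
    name = name
  )
}

#' Construct a proportion vector
#'
#' @param labels character labels.
#' @param proportions numeric proportions; must sum to 1 within 1e-9.
#' @return Named numeric vector of class `proportion_vector`.
#' @export
proportion_vector <- function(labels, proportions) {
  stopifnot(length(labels) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(proportions < 0 | proportions > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  structure(stats::setNames(as.numeric(proportions), labels),
            class = "proportion_vector")
}

#' Expected marker-gene composition of a community
#'
#' Converts a gDNA mass composition into the proportions of marker-gene
#' reads expected from it: a member contributing mass fraction m with genome
#' size G contributes m/G genome copies, each carrying c marker copies, so
#' its expected share of marker reads is w = (m/G) * c, normalized over the
#' community. This is the copy-number and genome-size correction that makes
#' marker-read counts comparable to organismal composition.
#'
#' @param spec a `community_spec`.
#' @return A `proportion_vector` over the member species, in table order.
#' @export
expected_composition <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  unknown <- is.na(spec$marker_copies)
  if (any(unknown)) {
    stop("marker copy number not known for: ",
         paste(spec$species[unknown], collapse = ", "), call. = FALSE)
  }
  w <- (spec$mass_fraction / spec$genome_size) * spec$marker_copies
  proportion_vector(spec$species, w / sum(w))
}

#' Synthesize a genome carrying a tandem-repeated target unit
#'
#' Emulates a genome with an rDNA-like tandem repeat: an i.i.d. random
#' background sequence with `copy_number` exact copies of `unit_sequence`
#' inserted head-to-tail at `insertion_locus`. Identical seeds give
#' byte-identical output.
#'
#' @param background_length background length in bp.
#' @param unit_sequence DNA string for one repeat unit (alphabet A/C/G/T).
#' @param copy_number number of tandem copies (>= 1).
#' @param insertion_locus 0-based offset of the first copy into the
#'   background; defaults to the middle.
#' @param gc_content GC content of the random background.
#' @param seed integer seed for the background sequence.
#' @param contig contig name used in annotations.
#' @return A list of class `synthetic_genome` with elements `sequence`
#'   (character), `contig`, and `units`, a data.frame of 0-based half-open
#'   intervals (`start`, `end`), one row per tandem copy.
#' @export
synthesize_genome <- function(background_length, unit_sequence, copy_number,
                              insertion_locus = background_length %/% 2,
                              gc_content = 0.5, seed = 1L,
                              contig = "synthetic") {
  unit_sequence <- as.character(unit_sequence)
  assert_dna(unit_sequence, "unit_sequence")
  if (nchar(unit_sequence) == 0) {
    stop("unit_sequence must be non-empty", call. = FALSE)
  }
  if (copy_number < 1) stop("copy_number must be >= 1", call. = FALSE)
  if (insertion_locus < 0 || insertion_locus > background_length) {
    stop("insertion_locus must lie within the background", call. = FALSE)
  }
  bg <- random_dna(background_length, gc_content, seed = seed)
  prefix <- substr(bg, 1, insertion_locus)
  suffix <- substr(bg, insertion_locus + 1, background_length)
  unit_len <- nchar(unit_sequence)
  sequence <- paste0(prefix,
                     paste(rep(unit_sequence, copy_number), collapse = ""),
                     suffix)
  starts <- insertion_locus + (seq_len(copy_number) - 1L) * unit_len
  structure(
    list(sequence = sequence,
         contig = contig,
         units = data.frame(start = starts, end = starts + unit_len)),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome '%s': %d bp, %d tandem unit copies\n",
              x$contig, nchar(x$sequence), nrow(x$units)))
  invisible(x)
}

#' Plant a protospacer + PAM site into a repeat unit
#'
#' Writes the probe's protospacer (optionally with a fixed number of seeded
#' random substitutions) followed by an NGG PAM into the unit at the given
#' offset and strand, enabling controlled mismatch scenarios. The 23 bp
#' written span is `[offset, offset + 23)` on the forward sequence; on the
#' minus strand the reverse complement of protospacer+PAM is written there.
#'
#' @param unit DNA string, or the result of a previous `plant_probe_site`
#'   call (sites accumulate and may not overlap).
#' @param probe a `crrna_probe`.
#' @param offset 0-based offset of the planted 23-mer.
#' @param strand "+" or "-".
#' @param n_mismatches number of substitutions (0-20) to place at seeded
#'   random protospacer positions.
#' @param seed integer seed for mismatch placement.
#' @return A list of class `planted_unit`: `sequence`, `sites` (data.frame
#'   of planted sites), and `mismatch_positions` (1-20 from the PAM-distal
#'   end, for the site just planted).
#' @export
plant_probe_site <- function(unit, probe, offset, strand = "+",
                             n_mismatches = 0L, seed = 1L) {
  stopifnot(inherits(probe, "crrna_probe"))
  if (inherits(unit, "planted_unit")) {
    sites <- unit$sites
    unit <- unit$sequence
  } else {
    sites <- data.frame(offset = integer(), strand = character(),
                        probe = character(), n_mismatches = integer(),
                        stringsAsFactors = FALSE)
  }
  assert_dna(unit, "unit")
  if (n_mismatches < 0 || n_mismatches > 20) {
    stop("n_mismatches must be in [0, 20]", call. = FALSE)
  }
  if (offset < 0 || offset + 23 > nchar(unit)) {
    stop("planted site must fit inside the unit (offset + 23 <= length)",
         call. = FALSE)
  }
  if (nrow(sites) > 0 &&
      any(offset < sites$offset + 23 & offset + 23 > sites$offset)) {
    stop("requested region overlaps an existing planted site", call. = FALSE)
  }
  proto <- dna_chars(probe$protospacer)
  mism <- integer(0)
  if (n_mismatches > 0) {
    mism <- with_seed(seed, sort(sample.int(20L, n_mismatches)))
    subs <- with_seed(seed + 1L, vapply(mism, function(i) {
      sample(setdiff(DNA_BASES, proto[i]), 1L)
    }, character(1)))
    proto[mism] <- subs
  }
  pam_n <- with_seed(seed + 2L, sample(DNA_BASES, 1L))
  site <- paste0(paste(proto, collapse = ""), pam_n, "GG")
  if (strand == "-") site <- revcomp(site)
  sequence <- paste0(substr(unit, 1, offset), site,
                     substr(unit, offset + 24, nchar(unit)))
  sites <- rbind(sites, data.frame(offset = offset, strand = strand,
                                   probe = probe$name,
                                   n_mismatches = n_mismatches,
                                   stringsAsFactors = FALSE))
  structure(list(sequence = sequence, sites = sites,
                 mismatch_positions = mism),
            class = "planted_unit")
}

#' @export
print.planted_unit <- function(x, ...) {
  cat(sprintf("unit of %d bp with %d planted probe site(s)\n",
              nchar(x$sequence), nrow(x$sites)))
  invisible(x)
}

#' @export
as.character.planted_unit <- function(x, ...) x$sequence
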