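#' Write sequences to FASTA
#'
#' @param sequences named character vector of DNA sequences.
#' @param path output path.
#' @param width line wrap width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  dna <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

#' Write simulated reads to FASTQ
#'
#' @param reads a `simulated_reads` object or a data.frame with `read_id`,
#'   `sequence`, `quality`.
#' @param path output path (".gz" suffix gzip-compresses).
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "simulated_reads")) reads <- reads$reads
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (plain or gzip).
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTQ: ", path, call. = FALSE)
  dna <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  q <- S4Vectors::mcols(dna)$qualities
  data.frame(read_id = sub("\\s.*", "", names(dna)),
             sequence = as.character(dna),
             quality = if (!is.null(q)) as.character(q) else
               strrep("I", nchar(as.character(dna))),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `start`, `end` (0-based half-open) and
#'   optionally `contig`, `name`, `strand`.
#' @param path output path.
#' @param contig default contig name if no `contig` column.
#' @export
write_bed <- function(intervals, path, contig = "seq") {
  chrom <- if ("contig" %in% names(intervals)) intervals$contig else contig
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  score <- rep(0L, nrow(intervals))
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  utils::write.table(
    data.frame(chrom, intervals$start, intervals$end, name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage array as bedGraph
#'
#' Consecutive equal values are collapsed into single intervals.
#'
#' @param coverage numeric vector, one value per base.
#' @param path output path.
#' @param contig contig name.
#' @export
write_bedgraph <- function(coverage, path, contig = "seq") {
  n <- length(coverage)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  change <- c(TRUE, coverage[-1] != coverage[-n])
  starts <- which(change) - 1L
  ends <- c(starts[-1], n)
  vals <- coverage[starts + 1L]
  keep <- vals != 0
  utils::write.table(
    data.frame(contig, starts[keep], ends[keep],
               format(vals[keep], scientific = TRUE, digits = 6)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render a cleavage-site table for reporting
#'
#' Converts internal 0-based half-open coordinates to 1-based inclusive
#' for the TSV report, keeping the conventional "contig:start-end" style.
#'
#' @param sites a `cleavage_sites` data.frame.
#' @return data.frame with 1-based inclusive coordinates and a
#'   comma-joined mismatch-offset column.
#' @export
format_site_report <- function(sites) {
  data.frame(
    contig = sites$contig,
    strand = sites$strand,
    protospacer_start = sites$proto_start + 1L,
    protospacer_end = sites$proto_end,
    pam_start = sites$pam_start + 1L,
    pam_end = sites$pam_end,
    pam = sites$pam_sequence,
    cut_after = sites$cut_position,
    mismatches = sites$mismatch_count,
    mismatch_offsets = vapply(sites$mismatch_offsets, paste,
                              character(1), collapse = ","),
    probe = sites$probe_name,
    stringsAsFactors = FALSE
  )
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
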