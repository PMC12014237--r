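#' Build and validate a run configuration
#'
#' Collects every knob of the end-to-end simulation-and-quantification
#' pipeline. All stochastic stages derive their seeds from the single
#' `seed` by stable per-stage derivation ([derive_seed()]), so any stage
#' can be rerun in isolation and reproduce its part of a full run.
#'
#' @param community a `community_spec` or path to a community TSV.
#' @param probes a list of two `crrna_probe`s (one `intended_flank`
#'   "forward", one "reverse") or path to a probe TSV.
#' @param seed integer global seed (mandatory).
#' @param output_dir where artifacts are written (NULL = nowhere).
#' @param genome_scale synthetic background bp emitted per real genome bp
#'   (keeps desk-scale genomes proportional to real genome sizes).
#' @param unit_length length of the synthetic marker repeat unit in bp.
#' @param n_molecules library size.
#' @param n_genome_copies independent template genome copies digested per
#'   member; each copy realizes its own per-site cuts, emulating the many
#'   template molecules of a real extract (with incomplete cleavage, a
#'   single copy would make whole ROI copies drop out of the library).
#' @param background_rate probability a library molecule is off-target
#'   background.
#' @param background_length c(mean, sd) in bp of the log-normal background
#'   fragment length distribution.
#' @param cleavage_prob per-site Cas9 cut probability.
#' @param substitution_rate,insertion_rate,deletion_rate read error rates.
#' @param min_identity assignment identity threshold.
#' @param min_overlap on-target aligned-span overlap threshold.
#' @param abundance_mode "read_count" or "mean_depth".
#' @param rank reporting rank, "species" or "genus".
#' @param max_mismatches probe-scan mismatch allowance.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(community, probes, seed,
                       output_dir = NULL,
                       genome_scale = 5e-4,
                       unit_length = 1200L,
                       n_molecules = 3000L,
                       n_genome_copies = 20L,
                       background_rate = 0.05,
                       background_length = c(3000, 2000),
                       cleavage_prob = 0.9,
                       substitution_rate = 0.025,
                       insertion_rate = 0.005,
                       deletion_rate = 0.005,
                       min_identity = 0.9,
                       min_overlap = 0.5,
                       abundance_mode = "read_count",
                       rank = "species",
                       max_mismatches = 2L) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory: every stochastic stage must be reproducible",
         call. = FALSE)
  }
  if (is.character(community)) community <- load_community_table(community)
  if (is.character(probes)) probes <- load_probe_table(probes)
  stopifnot(inherits(community, "community_spec"))
  flanks <- vapply(probes, `[[`, character(1), "intended_flank")
  if (!("forward" %in% flanks && "reverse" %in% flanks)) {
    stop("need at least one forward-flank and one reverse-flank probe",
         call. = FALSE)
  }
  for (r in c(background_rate, cleavage_prob, substitution_rate,
              insertion_rate, deletion_rate, min_identity, min_overlap)) {
    assert_fraction(r, "rate/fraction parameter")
  }
  stopifnot(n_molecules >= 1, n_genome_copies >= 1, unit_length >= 100,
            genome_scale > 0)
  structure(list(
    community = community, probes = probes, seed = as.integer(seed),
    output_dir = output_dir, genome_scale = genome_scale,
    unit_length = as.integer(unit_length),
    n_molecules = as.integer(n_molecules),
    n_genome_copies = as.integer(n_genome_copies),
    background_rate = background_rate,
    background_length = as.numeric(background_length),
    cleavage_prob = cleavage_prob,
    substitution_rate = substitution_rate,
    insertion_rate = insertion_rate, deletion_rate = deletion_rate,
    min_identity = min_identity, min_overlap = min_overlap,
    abundance_mode = abundance_mode, rank = rank,
    max_mismatches = as.integer(max_mismatches)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Paths inside the file are resolved relative to the file's directory.
#'
#' @param path YAML file with keys matching [run_config()] arguments
#'   (`community` and `probes` as file paths).
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("community", "probes")) {
    if (!is.null(y[[key]]) && is.character(y[[key]]) &&
        !file.exists(y[[key]])) {
      y[[key]] <- file.path(base, y[[key]])
    }
  }
  do.call(run_config, y)
}

## Build the per-species marker unit: species-specific random sequence with
## the forward-flank probe planted on '-' (PAM leftward, away from the ROI)
## near the left edge and the reverse-flank probe on '+' (PAM rightward)
## near the right edge. Returns the unit plus the ROI offsets within it.
build_marker_unit <- function(config, member_index) {
  cfg <- config
  probes <- cfg$probes
  flanks <- vapply(probes, `[[`, character(1), "intended_flank")
  fwd <- probes[[which(flanks == "forward")[1]]]
  rev <- probes[[which(flanks == "reverse")[1]]]
  useed <- derive_seed(cfg$seed, 1000L + member_index)
  unit <- random_dna(cfg$unit_length, 0.5, seed = useed)
  off_f <- 10L
  off_r <- cfg$unit_length - 33L
  planted <- plant_probe_site(unit, fwd, off_f, strand = "-",
                              seed = useed + 1L)
  planted <- plant_probe_site(planted, rev, off_r, strand = "+",
                              seed = useed + 2L)
  # cut coordinates within the unit: '-' site cuts at proto_start + 3 =
  # offset + 6; '+' site cuts at offset + 17
  roi_start <- off_f + 6L
  roi_end <- off_r + 17L
  list(sequence = planted$sequence, roi_start = roi_start,
       roi_end = roi_end)
}

#' Run the full enrichment-simulation pipeline
#'
#' Executes the stages of an in-silico Cas9 metabarcoding experiment in
#' order: probe-site scanning over synthetic genomes -> Cas9 digestion ->
#' library sampling with background -> read simulation -> read assignment
#' -> abundance quantification -> observed-vs-expected concordance. Each
#' member of the community gets a synthetic genome whose background length
#' is proportional to its real genome size and which carries its marker
#' unit in `marker_copies` tandem copies; genome copy numbers in the
#' library are proportional to mass fraction over genome size, as in a
#' gDNA pool.
#'
#' @param config a `run_config`, or a path to a YAML config file.
#' @return A list of class `run_report`: config echo, package version,
#'   per-stage summaries, per-member `enrichment_report`s (plus their mean
#'   E), observed and expected `proportion_vector`s at the configured
#'   rank, and the `concordance_result` between them.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  comm <- cfg$community
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(writer, x, name) {
    if (!is.null(out_dir)) writer(x, file.path(out_dir, name))
  }

  ## stage 1-2: genomes, probe scan, digestion -------------------------
  members <- seq_len(nrow(comm))
  genomes <- list()
  fragments <- list()
  rois <- list()
  refs <- character(0)
  site_tables <- list()
  for (i in members) {
    unit <- build_marker_unit(cfg, i)
    g <- synthesize_genome(
      background_length = max(2000L,
                              as.integer(round(comm$genome_size[i] *
                                               cfg$genome_scale))),
      unit_sequence = unit$sequence,
      copy_number = comm$marker_copies[i],
      seed = derive_seed(cfg$seed, 2000L + i),
      contig = comm$species[i])
    genomes[[comm$species[i]]] <- g
    sites <- do.call(rbind, lapply(cfg$probes, function(p) {
      find_cleavage_sites(g$sequence, p, cfg$max_mismatches,
                          contig = g$contig)
    }))
    site_tables[[i]] <- sites
    frag <- do.call(rbind, lapply(seq_len(cfg$n_genome_copies), function(r) {
      digest(g$sequence, sites, cfg$cleavage_prob,
             seed = derive_seed(cfg$seed, 3000L + i * 101L + r),
             contig = g$contig, source_species = comm$species[i])
    }))
    # genome copies in the pool are proportional to mass / genome size
    frag$copy_weight <- comm$mass_fraction[i] / comm$genome_size[i]
    fragments[[i]] <- frag
    rois[[comm$species[i]]] <- data.frame(
      start = g$units$start + unit$roi_start,
      end = g$units$start + unit$roi_end)
    refs[comm$species[i]] <- substr(unit$sequence, unit$roi_start + 1L,
                                    unit$roi_end)
  }
  pooled <- do.call(rbind, fragments)
  class(pooled) <- c("library_molecules", "data.frame")
  emit(function(x, p) write_fasta(x, p),
       stats::setNames(vapply(genomes, `[[`, character(1), "sequence"),
                       names(genomes)), "genomes.fasta")
  emit(write_tsv, format_site_report(do.call(rbind, site_tables)),
       "cleavage_sites.tsv")
  emit(function(x, p) write_fasta(x, p), refs, "marker_references.fasta")

  ## stage 3: library + reads ------------------------------------------
  library_mols <- sample_library(
    pooled, cfg$n_molecules, cfg$background_rate,
    background_length = cfg$background_length,
    seed = derive_seed(cfg$seed, 4000L),
    genomes = vapply(genomes, `[[`, character(1), "sequence"))
  model <- error_model(cfg$substitution_rate, cfg$insertion_rate,
                       cfg$deletion_rate,
                       seed = derive_seed(cfg$seed, 5000L))
  sim <- simulate_reads(library_mols, model)
  emit(function(x, p) write_fastq(x, p), sim, "reads.fastq")
  emit(write_tsv, sim$truth, "truth.tsv")

  ## stage 4: assignment ------------------------------------------------
  assignments <- assign_reads(sim, refs, min_identity = cfg$min_identity)
  emit(write_tsv, as.data.frame(assignments), "assignments.tsv")

  ## stage 5: quantification --------------------------------------------
  expected <- expected_composition(comm)
  if (nrow(assignments) > 0) {
    observed <- observed_proportions(assignments, refs,
                                     mode = cfg$abundance_mode)
    taxonomy <- data.frame(reference = comm$species,
                           species = comm$species, genus = comm$genus,
                           stringsAsFactors = FALSE)
    if (cfg$rank == "genus") {
      observed <- aggregate_rank(observed, taxonomy, "genus")
      expected <- aggregate_rank(expected, taxonomy, "genus")
    }
    expected <- proportion_vector(
      names(observed), as.numeric(expected[names(observed)]))
    concordance <- lin_ccc(as.numeric(observed), as.numeric(expected))
  } else {
    warning("no reads assigned to the marker references; ",
            "abundance and concordance not computed", call. = FALSE)
    observed <- NULL
    concordance <- NULL
  }

  ## per-member enrichment from the simulation truth --------------------
  enrichment <- list()
  for (i in members) {
    sp <- comm$species[i]
    tr <- sim$truth[sim$truth$contig == sp, , drop = FALSE]
    if (nrow(tr) == 0) next
    stats_i <- on_target_stats(assignments_from_truth(tr), rois[[sp]],
                               cfg$min_overlap)
    g <- genomes[[sp]]
    enrichment[[sp]] <- enrichment_score(
      stats_i$R_target, stats_i$R_total, nchar(g$sequence),
      rois[[sp]]$end[1] - rois[[sp]]$start[1], comm$marker_copies[i])
  }
  mean_E <- mean(vapply(enrichment, `[[`, numeric(1), "E"))

  report <- structure(list(
    config = cfg,
    version = as.character(utils::packageVersion("cas9enrich")),
    stages = list(
      n_members = nrow(comm),
      n_sites = sum(vapply(site_tables, nrow, integer(1))),
      n_fragments = nrow(pooled),
      n_molecules = nrow(library_mols),
      n_background = sum(library_mols$is_background),
      n_reads = nrow(sim$reads),
      n_assigned = nrow(assignments),
      n_unassigned = attr(assignments, "n_unassigned")
    ),
    enrichment = enrichment,
    mean_E = mean_E,
    observed = observed,
    expected = expected,
    concordance = concordance
  ), class = "run_report")
  if (!is.null(out_dir)) {
    write_run_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write a run report as JSON
#'
#' @param report a `run_report`.
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  x <- list(
    version = report$version,
    seed = report$config$seed,
    parameters = report$config[!(names(report$config) %in%
                                   c("community", "probes",
                                     "output_dir"))],
    stages = report$stages,
    enrichment = lapply(report$enrichment, unclass),
    mean_E = report$mean_E,
    observed = if (!is.null(report$observed))
      as.list(unclass(report$observed)),
    expected = as.list(unclass(report$expected)),
    concordance = if (!is.null(report$concordance))
      unclass(report$concordance)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %d reads, %d assigned\n",
              x$config$seed, x$stages$n_reads, x$stages$n_assigned))
  cat(sprintf("  mean enrichment E = %.1f across %d members\n", x$mean_E,
              length(x$enrichment)))
  if (!is.null(x$concordance)) {
    cat(sprintf("  observed-vs-expected CCC rho_c = %.4f (%s rank)\n",
                x$concordance$rho_c, x$config$rank))
  }
  invisible(x)
}
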