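# Orchestration: pcr -> simulate -> filter -> cluster -> classify -> report.
#
# Every stage reads only the previous stage's files in the output directory,
# so stages can be re-run individually and a run is reproducible from its
# manifest (parameters, seed, input hashes).

PIPELINE_STAGES <- c("pcr", "simulate", "filter", "cluster", "classify",
                     "report")

#' Assemble a pipeline configuration
#'
#' With no panel/ancestral/primers supplied, a synthetic mock-community
#' fixture is generated from the seed ([synthesize_reference_panel()]), so a
#' default config runs end-to-end without external data.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Global seed controlling every stochastic stage.
#' @param panel,ancestral,primers Reference panel tibble, `ancestral_ref`
#'   and primer set (`list(round1_pairs, round2_pair)`); all three default
#'   to the synthetic fixture.
#' @param n_aa2 AA2 members in the mock community.
#' @param weights Optional community weights.
#' @param sim [read_sim_params()] (its `seed` is overridden by `seed`).
#' @param pcr [pcr_params()] for the nested round 2.
#' @param pcr_round1 Optional [pcr_params()] for round 1.
#' @param filter [filter_params()].
#' @param clustering [clustering_params()].
#' @param classifier [classifier_params()].
#' @param sample_metadata Sample metadata tibble; defaults to two synthetic
#'   samples (surface and topsoil of one forest/season) to which reads are
#'   assigned alternately.
#' @param report_unit `"reads"` or `"otus"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, panel = NULL, ancestral = NULL,
                            primers = NULL, n_aa2 = 10, weights = NULL,
                            sim = read_sim_params(), pcr = pcr_params(),
                            pcr_round1 = NULL, filter = filter_params(),
                            clustering = clustering_params(),
                            classifier = classifier_params(),
                            sample_metadata = NULL,
                            report_unit = c("reads", "otus")) {
  report_unit <- match.arg(report_unit)
  if (is.null(panel) || is.null(ancestral) || is.null(primers)) {
    fix <- synthesize_reference_panel(seed = 20230227)
    panel <- panel %||% fix$panel
    ancestral <- ancestral %||% fix$ancestral
    primers <- primers %||% fix$primers
  }
  if (is.null(sample_metadata)) {
    sample_metadata <- tibble::tibble(
      sample_id = c("S1", "S2"),
      forest = "P", plot = c("1", "1"),
      depth_layer = c("a", "b,c"), season = "I"
    )
  }
  sim$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed), panel = panel,
                 ancestral = ancestral, primers = primers, n_aa2 = n_aa2,
                 weights = weights, sim = sim, pcr = pcr,
                 pcr_round1 = pcr_round1 %||% pcr, filter = filter,
                 clustering = clustering, classifier = classifier,
                 sample_metadata = validate_sample_metadata(sample_metadata),
                 report_unit = report_unit),
            class = "pipeline_config")
}

.stage_files <- function(outdir) {
  file.path(outdir, c(
    amplicons = "amplicons.fasta", reads = "reads.fastq",
    truth = "truth.tsv", samples = "samples.tsv",
    filtered = "filtered.fastq", filter_log = "filter_log.tsv",
    centroids = "otus.fasta", candidates = "otu_candidates.fasta",
    membership = "otu_membership.tsv",
    classifications = "classifications.tsv", report_prefix = "report",
    report_tsv = "report.tsv", report_json = "report.json",
    manifest = "manifest.json"
  )) |> stats::setNames(c("amplicons", "reads", "truth", "samples",
                          "filtered", "filter_log", "centroids",
                          "candidates", "membership", "classifications",
                          "report_prefix", "report_tsv", "report_json",
                          "manifest"))
}

.require_stage_file <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' requires output of stage '%s' (%s not found)",
                  needed_by, stage, basename(path)))
  }
  path
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order
#' (`pcr, simulate, filter, cluster, classify, report`); each stage consumes
#' the files written by its predecessor in `config$outdir`, so a later stage
#' without its prerequisite's output is an error naming both stages. The
#' manifest records parameters, seed and an MD5 hash of every produced file;
#' a rerun with the same config and seed is byte-identical.
#'
#' @param config [pipeline_config()].
#' @param stages Ordered subset of the stage names (default all).
#' @return An `aa2_pipeline` object: `manifest` tibble, `outdir`, `config`,
#'   and in-memory `results` for the stages that ran.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  f <- .stage_files(config$outdir)
  results <- list()
  log_line <- function(...) message("[peroxtyper] ", sprintf(...))

  if ("pcr" %in% stages) {
    templates <- tibble::tibble(id = config$panel$id,
                                sequence = config$panel$nt_sequence)
    amplicons <- nested_pcr(templates, config$primers$round1_pairs,
                            config$primers$round2_pair, config$pcr,
                            config$pcr_round1)
    write_amplicons(amplicons, f[["amplicons"]])
    results$amplicons <- amplicons
    log_line("pcr: %d templates -> %d nested products", nrow(templates),
             nrow(amplicons))
  }

  if ("simulate" %in% stages) {
    .require_stage_file(f[["amplicons"]], "pcr", "simulate")
    amplicons <- results$amplicons %||% read_amplicons(f[["amplicons"]])
    offtargets <- config$panel$id[config$panel$gene_type == "non-AA2"]
    community <- build_mock_community(config$panel, n_aa2 = config$n_aa2,
                                      offtarget_ids = offtargets,
                                      weights = config$weights)
    reads <- simulate_reads(community, amplicons, config$sim)
    write_fastq(reads, f[["reads"]])
    write_truth(reads, f[["truth"]])
    sample_ids <- config$sample_metadata$sample_id
    samples <- tibble::tibble(
      read_id = reads$read_id,
      sample_id = sample_ids[(seq_len(nrow(reads)) - 1L) %%
                               length(sample_ids) + 1L]
    )
    readr::write_tsv(samples, f[["samples"]], progress = FALSE)
    results$reads <- reads
    results$community <- community
    log_line("simulate: %d reads from %d members", nrow(reads),
             nrow(community))
  }

  if ("filter" %in% stages) {
    .require_stage_file(f[["reads"]], "simulate", "filter")
    reads <- read_fastq(f[["reads"]])
    trimmed <- quality_trim(reads, config$filter)
    fl <- filter_reads(trimmed, config$filter)
    write_fastq(fl$kept, f[["filtered"]])
    log_tbl <- dplyr::bind_rows(
      dplyr::mutate(fl$kept[, "read_id"], status = "kept",
                    reason = NA_character_),
      dplyr::mutate(fl$discarded[, c("read_id", "reason")], status = "discarded")
    )
    readr::write_tsv(log_tbl, f[["filter_log"]], progress = FALSE)
    results$filtered <- fl
    log_line("filter: %d in, %d kept, %d discarded", nrow(reads),
             nrow(fl$kept), nrow(fl$discarded))
  }

  if ("cluster" %in% stages) {
    .require_stage_file(f[["filtered"]], "filter", "cluster")
    kept <- read_fastq(f[["filtered"]])
    uniques <- dereplicate(kept)
    otus <- cluster_otus(uniques, config$clustering)
    pick_representatives(otus, f[["centroids"]])
    write_otu_candidates(otus, f[["candidates"]])
    readr::write_tsv(otu_membership(otus), f[["membership"]],
                     progress = FALSE)
    results$otus <- otus
    log_line("cluster: %d uniques -> %d OTUs", nrow(uniques), nrow(otus))
  }

  if ("classify" %in% stages) {
    .require_stage_file(f[["centroids"]], "cluster", "classify")
    .require_stage_file(f[["membership"]], "cluster", "classify")
    reps <- read_representatives(f[["centroids"]])
    otus <- tibble::tibble(otu_id = reps$otu_id,
                           centroid_sequence = reps$centroid_sequence,
                           size = reps$size)
    if (file.exists(f[["candidates"]])) {
      cands <- read_otu_candidates(f[["candidates"]])
      otus$candidate_seqs <- unname(cands[otus$otu_id])
    }
    cls <- classify_otus(otus, config$ancestral, config$panel,
                         config$classifier)
    readr::write_tsv(cls, f[["classifications"]], progress = FALSE)
    results$classifications <- cls
    tab <- table(cls$label)
    log_line("classify: %d OTUs (%s)", nrow(cls),
             paste(names(tab), tab, sep = "=", collapse = ", "))
  }

  if ("report" %in% stages) {
    .require_stage_file(f[["classifications"]], "classify", "report")
    .require_stage_file(f[["membership"]], "cluster", "report")
    .require_stage_file(f[["samples"]], "simulate", "report")
    cls <- readr::read_tsv(f[["classifications"]], show_col_types = FALSE,
                           progress = FALSE)
    membership <- readr::read_tsv(f[["membership"]], show_col_types = FALSE,
                                  progress = FALSE)
    samples <- readr::read_tsv(f[["samples"]], show_col_types = FALSE,
                               progress = FALSE)
    table <- tabulate_classes(cls, membership, samples,
                              config$sample_metadata,
                              unit = config$report_unit)
    class_counts <- membership |>
      dplyr::left_join(cls[, c("otu_id", "label")], by = "otu_id") |>
      dplyr::count(.data$label)
    shannon <- list(
      otu_shannon = shannon_index(cls$size),
      class_shannon = shannon_index(class_counts$n)
    )
    write_report(table, shannon, f[["report_prefix"]])
    results$report <- table
    results$shannon <- shannon
    log_line("report: %d groups", length(unique(table$group)))
  }

  produced <- f[file.exists(f)]
  produced <- produced[!names(produced) %in% c("manifest", "report_prefix")]
  manifest <- tibble::tibble(
    file = basename(unname(produced)),
    md5 = unname(tools::md5sum(unname(produced)))
  )
  manifest_payload <- list(
    seed = config$seed,
    stages = stages,
    files = manifest,
    params = list(
      pcr = unclass(config$pcr), pcr_round1 = unclass(config$pcr_round1),
      sim = unclass(config$sim), filter = unclass(config$filter),
      clustering = unclass(config$clustering),
      classifier = unclass(config$classifier),
      report_unit = config$report_unit
    )
  )
  jsonlite::write_json(manifest_payload, f[["manifest"]], digits = NA,
                       auto_unbox = TRUE)
  structure(list(outdir = config$outdir, manifest = manifest,
                 config = config, results = results, stages = stages),
            class = "aa2_pipeline")
}

#' Read amplicon products written by [write_amplicons()]
#' @param path FASTA path.
#' @return Product tibble (`template_id`, `start`, `end`, `pair_name`,
#'   `pcr_round`, `sequence`).
#' @export
read_amplicons <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_match(names(seqs),
                              "^(.*)\\|(\\d+)-(\\d+)\\|(.*)\\|(\\d)$")
  tibble::tibble(template_id = parts[, 2],
                 start = as.integer(parts[, 3]),
                 end = as.integer(parts[, 4]),
                 pair_name = parts[, 5],
                 pcr_round = as.integer(parts[, 6]),
                 sequence = unname(as.character(seqs)))
}

#' @export
print.aa2_pipeline <- function(x, ...) {
  cat("<aa2_pipeline> stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("outdir:", x$outdir, "\n")
  cat("files:", paste(x$manifest$file, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.aa2_pipeline <- function(x, ...) {
  x$results$classifications %||%
    abort("pipeline has no classification results (stage not run)")
}

#' @export
glance.aa2_pipeline <- function(x, ...) {
  r <- x$results
  cls <- r$classifications
  counts <- if (!is.null(cls)) {
    mem <- otu_membership_counts(cls)
    tibble::as_tibble(as.list(mem))
  } else {
    tibble::tibble()
  }
  base <- tibble::tibble(
    n_reads = if (!is.null(r$reads)) nrow(r$reads) else NA_integer_,
    n_kept = if (!is.null(r$filtered)) nrow(r$filtered$kept) else NA_integer_,
    n_otus = if (!is.null(r$otus)) nrow(r$otus) else NA_integer_
  )
  dplyr::bind_cols(base, counts)
}

# read-weighted class counts from an OTU classification table
otu_membership_counts <- function(cls) {
  agg <- stats::aggregate(cls$size, by = list(label = cls$label), FUN = sum)
  stats::setNames(as.integer(agg$x), paste0("reads_", gsub("-", "_", agg$label)))
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `outdir`, `seed`, reference paths (`panel_fasta` +
#' `panel_metadata`, `ancestral_fasta` + `ancestral_annotation`,
#' `sample_metadata`), `n_aa2`, `weights`, `report_unit`, and parameter
#' blocks `sim`, `pcr`, `pcr_round1`, `filter`, `clustering`, `classifier`
#' whose fields are passed to the corresponding `*_params()` constructor
#' (unknown fields are an error naming the block). Omitted references fall
#' back to the synthetic fixture, so a minimal config is just an output
#' directory and a seed.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  block <- function(name, ctor) {
    if (is.null(y[[name]])) return(NULL)
    bad <- setdiff(names(y[[name]]), names(formals(ctor)))
    if (length(bad) > 0) {
      abort(paste0("unknown field(s) in config block '", name, "': ",
                   paste(bad, collapse = ", ")))
    }
    do.call(ctor, y[[name]])
  }
  panel <- NULL
  if (!is.null(y$panel_fasta)) {
    panel <- read_reference_panel(y$panel_fasta, y$panel_metadata)
  }
  ancestral <- NULL
  if (!is.null(y$ancestral_fasta)) {
    ancestral <- read_ancestral_reference(y$ancestral_fasta,
                                          y$ancestral_annotation)
  }
  meta <- NULL
  if (!is.null(y$sample_metadata)) {
    meta <- read_sample_metadata(y$sample_metadata)
  }
  args <- list(outdir = y$outdir %||% "peroxtyper_out",
               seed = y$seed %||% 1L, panel = panel, ancestral = ancestral,
               primers = NULL, n_aa2 = y$n_aa2 %||% 10,
               weights = y$weights,
               sample_metadata = meta,
               report_unit = y$report_unit %||% "reads")
  for (nm in c("sim", "pcr", "pcr_round1", "filter", "clustering",
               "classifier")) {
    ctor <- switch(nm, sim = read_sim_params, pcr = pcr_params,
                   pcr_round1 = pcr_params, filter = filter_params,
                   clustering = clustering_params,
                   classifier = classifier_params)
    b <- block(nm, ctor)
    if (!is.null(b)) args[[nm]] <- b
  }
  do.call(pipeline_config, args)
}
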