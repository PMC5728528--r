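default_config <- function() {
  list(
    seed = 1L,
    inputs = list(r1 = NULL, r2 = NULL, mids = NULL, ref_fasta = NULL,
                  ref_tax = NULL, fallback_fasta = NULL, fallback_tax = NULL,
                  barcodes_fasta = NULL, specimens = NULL),
    out_dir = NULL,
    qc = list(bad_quality_max = 20, max_bad_run = 3, min_length = 100,
              max_mid_errors = 1),
    chimera = list(enabled = TRUE, skew = 2.0, n_chunks = 4,
                   top_parents_per_chunk = 4, min_gain = 1.0,
                   min_model_identity = 99.0, min_segment = 30),
    clustering = list(threshold_pct = 97, singleton_mode = "per_sample",
                      max_candidates = 20, min_overlap = 100),
    classifier = list(identity_window = 0.5, consensus_fraction = 0.5,
                      min_hit_identity = 80, lca_top_window = 10,
                      max_candidates = 100, min_hit_overlap = 100),
    evaluation = list(min_identity = 97, min_overlap = 100,
                      sanger_max_divergence = 3))
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key '", full, "'")
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration section '", full, "' must be a list")
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Build a pipeline configuration
#'
#' Nested sections `inputs`, `qc`, `chimera`, `clustering`, `classifier`,
#' `evaluation` plus `seed` and `out_dir`. Unknown keys are rejected before
#' any work. All defaults match the benchmark workflow's stated values
#' (bad iff Q <= 20, truncation at runs > 3, 100 nt minimum, 97% clustering,
#' 0.5-point identity window, 50% consensus, 97%/100 nt recovery, 3% Sanger
#' divergence).
#'
#' @param ... Overrides, e.g. `qc = list(min_length = 50)`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = "pipeline_config")
}

stage_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$counts <- list()
  env
}

note_stage <- function(ledger, stage, value) {
  ledger$counts[[stage]] <- value
  invisible(value)
}

#' Run the processing core on in-memory reads
#'
#' demultiplex -> quality truncate -> length filter -> dereplicate ->
#' chimera screen -> greedy cluster -> singleton filter -> dual-read
#' classify (LCA fallback for clusters without a COI match) -> categorize ->
#' MOTU table.
#'
#' @param pairs Pair data frame ([read_fastq_pair()]`$pairs`).
#' @param mids Named character vector sample_id -> MID.
#' @param ref_records Primary COI reference data frame (`record_id`,
#'   `taxonomy`, `sequence`).
#' @param fallback_records Secondary reference set for the LCA fallback, or
#'   NULL.
#' @param config A [pipeline_config()].
#' @return List with `motu_table`, `motus` (`motu_set`), `assignments`,
#'   `demux_report`, `chimera_calls`, `stage_counts`.
#' @export
run_core <- function(pairs, mids, ref_records, fallback_records = NULL,
                     config = pipeline_config()) {
  qc <- do.call(qc_params, config$qc)
  ledger <- stage_counter()
  note_stage(ledger, "input_pairs", nrow(pairs))

  dm <- demux_pairs(pairs, mids, qc)
  note_stage(ledger, "accepted_pairs", sum(dm$report$accepted))
  note_stage(ledger, "rejected_pairs", sum(dm$report$rejected))

  all_reads <- do.call(rbind, dm$samples)
  if (nrow(all_reads) == 0) stop("no read pairs survived demultiplexing/QC")
  sample_of_read <- setNames(rep(names(dm$samples),
                                 vapply(dm$samples, nrow, integer(1))),
                             all_reads$read_id)
  rev_of_read <- setNames(all_reads$r_bases, all_reads$read_id)

  uniq <- dereplicate(all_reads$f_bases, all_reads$read_id)
  note_stage(ledger, "unique_sequences", nrow(uniq))

  chimera_calls <- NULL
  if (isTRUE(config$chimera$enabled)) {
    ch <- config$chimera
    chimera_calls <- detect_chimeras(uniq, skew = ch$skew,
                                     n_chunks = ch$n_chunks,
                                     top_parents_per_chunk = ch$top_parents_per_chunk,
                                     min_gain = ch$min_gain,
                                     min_model_identity = ch$min_model_identity,
                                     min_segment = ch$min_segment)
    bad <- chimera_calls$query[chimera_calls$verdict == "chimeric"]
    note_stage(ledger, "chimeric_uniques", length(bad))
    note_stage(ledger, "chimeric_reads",
               sum(uniq$abundance[bad]))
    if (length(bad)) uniq <- uniq[-bad, , drop = FALSE]
  } else {
    note_stage(ledger, "chimeric_uniques", 0L)
    note_stage(ledger, "chimeric_reads", 0L)
  }

  motus <- greedy_cluster(uniq, threshold_pct = config$clustering$threshold_pct,
                          sample_of_read = sample_of_read,
                          rev_of_read = rev_of_read,
                          max_candidates = config$clustering$max_candidates,
                          min_overlap = config$clustering$min_overlap)
  note_stage(ledger, "clusters", nrow(motus$motus))
  motus <- remove_singletons(motus, mode = config$clustering$singleton_mode)
  note_stage(ledger, "clusters_after_singletons", nrow(motus$motus))
  note_stage(ledger, "reads_retained", sum(motus$counts))

  cp <- do.call(classifier_params, config$classifier)
  ref <- build_ref_index(ref_records)
  fb <- if (!is.null(fallback_records) && nrow(fallback_records) > 0)
    build_ref_index(fallback_records)
  assignments <- vector("list", nrow(motus$motus))
  for (i in seq_len(nrow(motus$motus))) {
    fwd <- motus$motus$centroid_fwd[i]
    rev <- motus$motus$centroid_rev[i]
    a <- dual_read_assign(fwd, rev, ref, cp)
    if (a$mode == "unassigned" && !is.null(fb)) a <- lca_assign(fwd, rev, fb, cp)
    assignments[[i]] <- a
  }
  categories <- vapply(assignments, categorize_motu, character(1))
  table <- motu_table(motus$motus$motu_id, motus$counts,
                      vapply(assignments, function(a)
                        format_lineage(a$lineage), character(1)),
                      categories)
  assign_df <- data.frame(
    motu_id = motus$motus$motu_id,
    mode = vapply(assignments, `[[`, character(1), "mode"),
    lineage = table$lineage,
    best_avg_identity_pct = vapply(assignments, function(a)
      a$best_avg_identity_pct, numeric(1)),
    n_retained_hits = vapply(assignments, function(a)
      a$n_retained_hits, numeric(1)),
    category = categories, stringsAsFactors = FALSE)

  list(motu_table = table, motus = motus, assignments = assign_df,
       assignment_objects = assignments, demux_report = dm$report,
       chimera_calls = chimera_calls, stage_counts = ledger$counts)
}

read_mids_tsv <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

#' Run the full pipeline from files on disk
#'
#' Reads the configured inputs, executes [run_core()], optionally evaluates
#' recovery against per-specimen barcodes, and writes the MOTU table,
#' assignment table, per-stage counters and reports under
#' `config$out_dir`. Every stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()] with `inputs` and `out_dir` set.
#' @return Invisibly, the [run_core()] result plus `recovery` when barcodes
#'   were supplied.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ins <- config$inputs
  need <- c("r1", "r2", "mids", "ref_fasta", "ref_tax")
  missing <- need[vapply(need, function(k) is.null(ins[[k]]), logical(1))]
  if (length(missing))
    stop("pipeline inputs missing: ", paste(missing, collapse = ", "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pairs <- stage("read_input", read_fastq_pair(ins$r1, ins$r2)$pairs)
  mids <- stage("read_mids", read_mids_tsv(ins$mids))
  ref_records <- stage("read_reference",
                       load_reference_records(ins$ref_fasta, ins$ref_tax))
  fallback_records <- if (!is.null(ins$fallback_fasta))
    stage("read_fallback",
          load_reference_records(ins$fallback_fasta, ins$fallback_tax))
  res <- run_core(pairs, mids, ref_records, fallback_records, config)

  if (!is.null(ins$barcodes_fasta)) {
    barcodes <- stage("read_barcodes", {
      seqs <- read_fasta(ins$barcodes_fasta)
      sp <- read.delim(ins$specimens, stringsAsFactors = FALSE)
      data.frame(specimen_id = names(seqs),
                 taxon_id = sp$taxon_id[match(names(seqs), sp$specimen_id)],
                 sequence = unname(seqs), stringsAsFactors = FALSE)
    })
    res$recovery <- stage("evaluate",
                          match_recovery(res$motus, barcodes,
                                         min_identity = config$evaluation$min_identity,
                                         min_overlap = config$evaluation$min_overlap))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$out_dir, f)
    write_motu_table(res$motu_table, o("motu_table.tsv"))
    write.table(res$assignments, o("assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts <- res$stage_counts
    write.table(data.frame(stage = names(counts),
                           value = unlist(counts)),
                o("stage_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(res$chimera_calls))
      write.table(res$chimera_calls, o("chimera_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    rep <- res$demux_report
    write.table(data.frame(key = c(paste0("accepted_", names(rep$accepted)),
                                   paste0("rejected_", names(rep$rejected))),
                           value = c(rep$accepted, rep$rejected)),
                o("demux_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(res$recovery)) {
      write.table(res$recovery$individuals, o("recovery_individuals.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$recovery$taxa, o("recovery_taxa.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(res)
}

load_reference_records <- function(fasta, tax) {
  seqs <- read_fasta(fasta)
  lineages <- read_taxonomy_table(tax)
  missing <- setdiff(names(seqs), names(lineages))
  if (length(missing))
    stop("reference records without taxonomy: ",
         paste(utils::head(missing, 3), collapse = ", "))
  data.frame(record_id = names(seqs),
             taxonomy = vapply(lineages[names(seqs)], format_lineage,
                               character(1)),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates a reference library, fallback library, mock design and paired
#' reads, and writes every file [run_pipeline()] needs: `refs.fasta`,
#' `refs_tax.tsv`, `fallback.fasta`, `fallback_tax.tsv`, `mids.tsv`,
#' `reads_R1.fastq`, `reads_R2.fastq`, `manifest.tsv`, `specimens.tsv`,
#' `barcodes.fasta`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed; identical seeds give identical files.
#' @param n_samples Samples (default 5).
#' @param reads_per_sample Pairs per sample (default 4000).
#' @param error_rate Per-base substitution rate (default 0.001).
#' @param chimera_rate Chimeric read fraction (default 0.02).
#' @param overwrite Refuse to clobber an existing dataset unless TRUE.
#' @param ... Passed to [build_mock_design()].
#' @return Invisibly, a list with the design, library, fallback and file
#'   paths.
#' @export
simulate_dataset <- function(out_dir, seed, n_samples = 5,
                             reads_per_sample = 4000, error_rate = 0.001,
                             chimera_rate = 0.02, overwrite = FALSE, ...) {
  if (n_samples < 1) stop("at least one sample required")
  paths <- file.path(out_dir, c("refs.fasta", "refs_tax.tsv",
                                "fallback.fasta", "fallback_tax.tsv",
                                "mids.tsv", "reads_R1.fastq",
                                "reads_R2.fastq", "manifest.tsv",
                                "specimens.tsv", "barcodes.fasta"))
  names(paths) <- c("ref_fasta", "ref_tax", "fallback_fasta", "fallback_tax",
                    "mids", "r1", "r2", "manifest", "specimens",
                    "barcodes_fasta")
  if (!overwrite && any(file.exists(paths)))
    stop("dataset files already exist in '", out_dir,
         "'; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  library <- generate_reference_library(6, 2, 2, seed = seed)
  fallback <- generate_fallback_library(seed = seed + 1)
  design <- build_mock_design(library, fallback, seed = seed + 2,
                              n_samples = n_samples, ...)
  sim <- simulate_paired_reads(design, reads_per_sample = reads_per_sample,
                               error_rate = error_rate,
                               chimera_rate = chimera_rate, seed = seed + 3)

  write_fasta(setNames(library$sequence, library$record_id), paths["ref_fasta"])
  write_taxonomy_table(setNames(lapply(library$taxonomy, parse_lineage),
                                library$record_id), paths["ref_tax"])
  write_fasta(setNames(fallback$sequence, fallback$record_id),
              paths["fallback_fasta"])
  write_taxonomy_table(setNames(lapply(fallback$taxonomy, parse_lineage),
                                fallback$record_id), paths["fallback_tax"])
  writeLines(paste0(design$samples$sample_id, "\t", design$samples$mid),
             paths["mids"])
  write_fastq(sim$fwd, paths["r1"])
  write_fastq(sim$rev, paths["r2"])
  write_manifest(sim$manifest, paths["manifest"])
  write.table(design$specimens, paths["specimens"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(design$barcodes, paths["barcodes_fasta"])
  invisible(list(design = design, library = library, fallback = fallback,
                 paths = paths))
}
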