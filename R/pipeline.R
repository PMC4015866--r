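#' Run the full small RNA pipeline
#'
#' Orchestrates the stages end to end: (optional) raw-read preprocessing,
#' collapsing, classification, per-miRNA expression and the exact count
#' test versus the baseline stage, the high-expression filter, trajectory
#' clustering, novel miRNA discovery from unannotated reads, and target
#' prediction. Every stage result is returned, together with a
#' machine-readable run manifest; re-running with identical inputs and
#' seed reproduces identical counts.
#'
#' @param collapsed a collapsed count table ([collapse_srna()] columns), or
#'   NULL when `read_files` is given.
#' @param read_files named character vector (stage label -> FASTA/FASTQ
#'   path) of raw reads to preprocess.
#' @param catalogs named list of reference catalogs (see
#'   [classify_srna()]); `transcript_est` doubles as the novel-miRNA and
#'   target search space.
#' @param totals named per-stage clean-read totals; default: column sums
#'   of the collapsed table.
#' @param baseline control stage for fold-changes (default first stage).
#' @param adapter,min_overlap 3' adapter trimming for raw input (NULL
#'   skips trimming).
#' @param alpha,tpm_min,pseudo expression-stage parameters.
#' @param k clusters for the trajectory stage (capped at the row count).
#' @param do_novel,do_targets toggle the discovery stages.
#' @param max_expectation target-penalty cutoff (default 3).
#' @param outdir optional directory for per-stage TSV outputs.
#' @param seed seed recorded in (and fixed for) the run.
#' @return a `srna_pipeline` list: `collapsed`, `classified`, `enrichment`,
#'   `mirna_counts`, `de`, `de_high`, `clusters`, `novel`, `targets`,
#'   `manifest`.
#' @export
run_pipeline <- function(collapsed = NULL, read_files = NULL, catalogs,
                         totals = NULL, baseline = NULL,
                         adapter = NULL, min_overlap = 8,
                         alpha = 0.05, tpm_min = 20, pseudo = 0.01,
                         k = 8, do_novel = TRUE, do_targets = TRUE,
                         max_expectation = 3, outdir = NULL, seed = 1) {
  set.seed(seed)
  manifest <- list(tool = "mirgrain",
                   version = as.character(utils::packageVersion("mirgrain")),
                   seed = seed)
  if (is.null(collapsed)) {
    if (is.null(read_files)) stop("need collapsed or read_files", call. = FALSE)
    manifest$input_md5 <- as.list(tools::md5sum(read_files))
    reads <- purrr::imap_dfr(read_files, function(path, stage) {
      r <- read_srna(path)
      r$stage <- stage
      r
    })
    manifest$reads_in <- as.list(table(reads$stage))
    if (!is.null(adapter)) {
      reads <- trim_adapter(reads, adapter, min_overlap = min_overlap)
    }
    reads <- filter_quality(reads)
    reads <- filter_by_length(reads)
    manifest$reads_clean <- as.list(table(reads$stage))
    collapsed <- collapse_srna(reads, stages = names(read_files))
  }
  stages <- stage_cols(collapsed)
  baseline <- baseline %||% stages[1]
  totals <- totals %||% library_totals(collapsed)
  manifest$unique_sequences <- nrow(collapsed)
  manifest$total_clean_reads <- as.list(totals)

  classified <- classify_srna(collapsed, catalogs)
  manifest$category_unique <- as.list(table(classified$category))
  enrichment <- summarize_enrichment(classified)

  mirna_counts <- classified |>
    filter(.data$category == "miRNA") |>
    group_by(mirna_id = .data$evidence) |>
    summarise(across(all_of(stages), sum), .groups = "drop")
  manifest$conserved_mirnas <- nrow(mirna_counts)
  manifest$conserved_families <- length(unique(
    mirna_family(mirna_counts$mirna_id)))

  de <- NULL; de_high <- NULL; clusters <- NULL
  if (nrow(mirna_counts) >= 2 && length(stages) >= 2) {
    de <- de_scan(mirna_counts, totals = totals, baseline = baseline,
                  alpha = alpha, pseudo = pseudo)
    manifest$de <- purrr::transpose(glance(de))
    names(manifest$de) <- glance(de)$comparison
    de_high <- filter_high_expression(de, tpm_min = tpm_min, de_only = TRUE)
    manifest$high_expression <- nrow(de_high$counts)
    if (nrow(de_high$counts) >= 2) {
      traj <- build_trajectories(de_high)
      kk <- min(k, nrow(traj))
      clusters <- cluster_trajectories(traj, k = kk)
      manifest$clusters <- as.list(table(clusters$assignment$cluster))
    }
  }

  novel <- NULL
  if (do_novel && !is.null(catalogs$transcript_est)) {
    novel <- discover_mirnas(classified, catalogs$transcript_est,
                             totals = totals)
    manifest$novel_accepted <- nrow(novel$mirnas)
  }

  targets <- NULL
  if (do_targets && !is.null(catalogs$transcript_est)) {
    query <- tibble(name = character(), seq = character())
    if (!is.null(de_high) && nrow(de_high$counts) > 0) {
      hiseq <- catalogs$miRNA_mature[
        match(de_high$counts$mirna_id, catalogs$miRNA_mature$name), ]
      query <- bind_rows(query, tibble(name = hiseq$name, seq = hiseq$seq))
    }
    if (!is.null(novel) && nrow(novel$mirnas) > 0) {
      query <- bind_rows(query, tibble(name = novel$mirnas$name,
                                       seq = novel$mirnas$seq))
    }
    query <- query[!duplicated(query$name) & !is.na(query$seq), ]
    if (nrow(query) > 0) {
      targets <- predict_targets(query, catalogs$transcript_est,
                                 max_expectation = max_expectation)
      manifest$target_hits <- nrow(targets)
    }
  }

  result <- structure(
    list(collapsed = collapsed, classified = classified,
         enrichment = enrichment, mirna_counts = mirna_counts,
         de = de, de_high = de_high, clusters = clusters,
         novel = novel, targets = targets, manifest = manifest,
         baseline = baseline, stages = stages),
    class = "srna_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  wt(result$classified, "classification.tsv")
  wt(result$enrichment, "enrichment.tsv")
  if (!is.null(result$de)) wt(tidy(result$de), "differential_expression.tsv")
  if (!is.null(result$clusters)) wt(tidy(result$clusters), "clusters.tsv")
  if (!is.null(result$novel) && nrow(result$novel$mirnas) > 0) {
    wt(result$novel$mirnas, "novel_mirnas.tsv")
    write_hairpins(result$novel, file.path(outdir, "precursors.str"))
  }
  if (!is.null(result$targets)) wt(result$targets, "targets.tsv")
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.srna_pipeline <- function(x, ...) {
  cat("sRNA pipeline run (baseline ", x$baseline, ")\n", sep = "")
  cat("  unique sequences: ", x$manifest$unique_sequences, "\n", sep = "")
  cat("  conserved miRNAs: ", x$manifest$conserved_mirnas, " (",
      x$manifest$conserved_families, " families)\n", sep = "")
  if (!is.null(x$manifest$novel_accepted)) {
    cat("  novel miRNAs accepted: ", x$manifest$novel_accepted, "\n", sep = "")
  }
  if (!is.null(x$manifest$target_hits)) {
    cat("  target hits: ", x$manifest$target_hits, "\n", sep = "")
  }
  invisible(x)
}

#' Human- and machine-readable run report
#'
#' Totals are recomputed from the stage tables, so the report is
#' consistent with them by construction.
#'
#' @param result a `srna_pipeline` run.
#' @return list: `text` (character vector of summary lines) and `json`
#'   (JSON string with stable keys).
#' @export
report_run <- function(result) {
  stopifnot(inherits(result, "srna_pipeline"))
  m <- result$manifest
  summary <- list(
    unique_sequences = nrow(result$collapsed),
    categories = as.list(table(result$classified$category)),
    conserved_mirnas = nrow(result$mirna_counts),
    conserved_families = length(unique(mirna_family(result$mirna_counts$mirna_id))),
    de_significant = if (!is.null(result$de)) {
      sum(tidy(result$de)$significant)
    } else 0L,
    novel_accepted = if (!is.null(result$novel)) {
      nrow(result$novel$mirnas)
    } else 0L,
    target_hits = if (!is.null(result$targets)) nrow(result$targets) else 0L,
    seed = m$seed
  )
  text <- c(
    sprintf("unique sequences: %d", summary$unique_sequences),
    sprintf("conserved miRNAs: %d (%d families)",
            summary$conserved_mirnas, summary$conserved_families),
    sprintf("significant DE records: %d", summary$de_significant),
    sprintf("novel miRNAs accepted: %d", summary$novel_accepted),
    sprintf("target hits: %d", summary$target_hits)
  )
  list(text = text,
       json = as.character(jsonlite::toJSON(summary, auto_unbox = TRUE)))
}
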