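#' Read small RNA reads from FASTA or FASTQ
#'
#' Parses a read file into a tibble, one row per read. Sequences are
#' canonicalized to the internal DNA alphabet (U stored as T). FASTQ
#' qualities are kept as Sanger-encoded strings in the `qual` column;
#' FASTA input yields `qual = NA`.
#'
#' @param path file path.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension, falling
#'   back to first-character sniffing).
#' @return tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_srna <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq"
      else if (grepl("\\.(fasta|fa|fna)$", path, ignore.case = TRUE)) "fasta"
      else {
        first <- substr(readLines(path, n = 1), 1, 1)
        if (identical(first, "@")) "fastq" else "fasta"
      }
  }
  if (format == "fastq") validate_fastq(path)
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(recs) == 0) {
    warning("no records in ", path)
    return(tibble(read_id = character(), seq = character(), qual = character()))
  }
  qual <- if (format == "fastq") {
    as.character(S4Vectors::mcols(recs)$qualities)
  } else {
    rep(NA_character_, length(recs))
  }
  seqs <- canonicalize_seq(as.character(recs))
  if (format == "fastq") {
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad) > 0) {
      stop("FASTQ parse error: quality length != sequence length at record ",
           bad[1], " (", names(recs)[bad[1]], ")", call. = FALSE)
    }
  }
  ids <- names(recs)
  ids <- sub("\\s.*$", "", ids)
  tibble(read_id = ids, seq = unname(seqs), qual = unname(qual))
}

# Structural FASTQ validation in chunks of whole records; the downstream
# parser trusts record geometry, so length mismatches must be caught here.
validate_fastq <- function(path, chunk_records = 1e5) {
  con <- file(path, "r")
  on.exit(close(con))
  rec <- 0L
  repeat {
    lines <- readLines(con, n = chunk_records * 4)
    if (length(lines) == 0) break
    if (length(lines) %% 4 != 0) {
      stop("FASTQ parse error: truncated record after line ",
           rec * 4 + length(lines), call. = FALSE)
    }
    idx <- seq(1, length(lines), by = 4)
    bad <- which(!startsWith(lines[idx], "@") |
                   !startsWith(lines[idx + 2], "+") |
                   nchar(lines[idx + 1]) != nchar(lines[idx + 3]))
    if (length(bad) > 0) {
      stop("FASTQ parse error at record ", rec + bad[1], " (line ",
           (rec + bad[1] - 1) * 4 + 1, ")", call. = FALSE)
    }
    rec <- rec + length(idx)
  }
  invisible(TRUE)
}

# Mean Phred score of a Sanger-encoded quality string.
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || nchar(q) == 0) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

discard_tally <- function(reason, n_in, n_out, tally = NULL) {
  add <- tibble(reason = reason, n = n_in - n_out)
  out <- bind_rows(tally, add)
  out[out$n > 0 | nrow(out) == 1, , drop = FALSE]
}

#' Trim a 3' adapter from reads
#'
#' Finds the leftmost exact occurrence of the first `min_overlap` bases of
#' the adapter and keeps the insert preceding it. Reads whose insert would
#' be empty are discarded; in `required = TRUE` mode reads with no adapter
#' match are discarded too (library prep guarantees an adapter, so a miss
#' means contamination). Discards are tallied by reason in the
#' `"discarded"` attribute of the result.
#'
#' @param reads tibble with at least `seq` (from [read_srna()]).
#' @param adapter3 adapter sequence ligated at the 3' end.
#' @param min_overlap number of adapter bases that must match exactly
#'   (default 8).
#' @param required discard reads without an adapter match (default FALSE:
#'   such reads pass through untrimmed).
#' @return tibble of surviving reads with trimmed `seq` (and `qual` when
#'   present), plus a `discarded` attribute tibble (`reason`, `n`).
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 8, required = FALSE) {
  stopifnot(is.data.frame(reads), "seq" %in% names(reads))
  adapter3 <- canonicalize_seq(adapter3)
  if (nchar(adapter3) == 0) stop("adapter3 must be non-empty", call. = FALSE)
  probe <- substr(adapter3, 1, min(min_overlap, nchar(adapter3)))
  pos <- regexpr(probe, reads$seq, fixed = TRUE)
  has_qual <- "qual" %in% names(reads) && any(!is.na(reads$qual))
  out <- reads
  hit <- pos > 0
  ins_len <- ifelse(hit, as.integer(pos) - 1L, nchar(reads$seq))
  out$seq <- substr(out$seq, 1L, ins_len)
  if (has_qual) out$qual <- substr(out$qual, 1L, ins_len)

  tally <- tibble(reason = character(), n = integer())
  empty <- hit & ins_len == 0L
  if (required) {
    miss <- !hit
    tally <- bind_rows(tally, tibble(reason = "no adapter", n = sum(miss)))
  } else {
    miss <- rep(FALSE, nrow(out))
  }
  tally <- bind_rows(tally, tibble(reason = "empty insert", n = sum(empty)))
  out <- out[!(empty | miss), , drop = FALSE]
  attr(out, "discarded") <- tally[tally$n > 0 | nrow(tally) == 0, , drop = FALSE]
  out
}

#' Drop low-quality and ambiguous reads
#'
#' Reads containing N are always discarded. When FASTQ qualities are
#' present, reads with mean Phred below `min_mean_quality` are discarded
#' too; FASTA input (no qualities) skips the quality rule.
#'
#' @param reads tibble with `seq` and optionally `qual`.
#' @param min_mean_quality mean Phred threshold (default 20).
#' @return surviving reads, with a `discarded` attribute tibble.
#' @export
filter_quality <- function(reads, min_mean_quality = 20) {
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  low_q <- rep(FALSE, nrow(reads))
  if ("qual" %in% names(reads)) {
    mq <- mean_phred(reads$qual)
    low_q <- !is.na(mq) & mq < min_mean_quality
  }
  out <- reads[!(has_n | low_q), , drop = FALSE]
  attr(out, "discarded") <- tibble(
    reason = c("contains N", "low quality"),
    n = c(sum(has_n), sum(low_q & !has_n))
  )
  out
}

#' Retain reads within a length window
#'
#' Small RNA analyses keep only inserts in the sequencing-informative size
#' range; both boundaries are inclusive.
#'
#' @param reads tibble with `seq`.
#' @param min_len,max_len inclusive bounds in nt (defaults 18 and 30).
#' @return surviving reads, with a `discarded` attribute tibble.
#' @export
filter_by_length <- function(reads, min_len = 18, max_len = 30) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  len <- nchar(reads$seq)
  short <- len < min_len
  long <- len > max_len
  out <- reads[!(short | long), , drop = FALSE]
  attr(out, "discarded") <- tibble(
    reason = c(paste0("< ", min_len, " nt"), paste0("> ", max_len, " nt")),
    n = c(sum(short), sum(long))
  )
  out
}

#' Collapse reads to unique sequences with per-library counts
#'
#' The unit of all downstream analysis is the unique ("collapsed") read:
#' one row per distinct sequence, one count column per stage library.
#' `total_clean_reads` per library (the TPM denominator) is the column sum,
#' recoverable with [library_totals()].
#'
#' @param reads tibble with columns `seq` and `stage` (one row per read),
#'   e.g. several [read_srna()] outputs bound with a `stage` label.
#' @param stages optional character vector fixing the stage/column order
#'   (default: order of first appearance).
#' @return tibble with `seq`, `length`, then one integer count column per
#'   stage, sorted by descending total count then sequence.
#' @export
collapse_srna <- function(reads, stages = NULL) {
  stopifnot(all(c("seq", "stage") %in% names(reads)))
  stages <- stages %||% unique(reads$stage)
  tab <- reads |>
    dplyr::count(.data$seq, .data$stage) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "n",
                       values_fill = 0L)
  missing_cols <- setdiff(stages, names(tab))
  for (m in missing_cols) tab[[m]] <- 0L
  tab <- tab[, c("seq", stages)]
  tab$length <- nchar(tab$seq)
  total <- rowSums(tab[, stages, drop = FALSE])
  tab <- tab[order(-total, tab$seq), c("seq", "length", stages)]
  as_tibble(tab)
}

#' Per-library clean-read totals of a collapsed table
#' @param collapsed output of [collapse_srna()].
#' @return named numeric vector, one total per stage column.
#' @export
library_totals <- function(collapsed) {
  cols <- stage_cols(collapsed)
  colSums(collapsed[, cols, drop = FALSE])
}

# Stage count columns of a collapsed table.
stage_cols <- function(collapsed) {
  setdiff(names(collapsed), c("seq", "length"))
}

#' Size distribution of a collapsed library set
#'
#' Redundant counts are read-weighted, unique counts sequence-weighted;
#' their ratio measures per-sequence sequencing depth by size class.
#'
#' @param collapsed output of [collapse_srna()].
#' @param lengths size classes to report (default 18:30).
#' @return long tibble: `stage`, `length`, `redundant`, `unique`, `ratio`
#'   (NA where unique = 0), `frac_redundant`, `frac_unique`.
#' @export
size_profile <- function(collapsed, lengths = 18:30) {
  cols <- stage_cols(collapsed)
  long <- collapsed |>
    tidyr::pivot_longer(all_of(cols), names_to = "stage", values_to = "count") |>
    filter(.data$count > 0) |>
    group_by(.data$stage, .data$length) |>
    summarise(redundant = sum(.data$count), unique = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(stage = cols, length = lengths)
  out <- grid |>
    left_join(long, by = c("stage", "length")) |>
    mutate(
      redundant = dplyr::coalesce(.data$redundant, 0),
      unique = dplyr::coalesce(.data$unique, 0L),
      ratio = ifelse(.data$unique > 0, .data$redundant / .data$unique, NA_real_)
    ) |>
    group_by(.data$stage) |>
    mutate(
      frac_redundant = ifelse(sum(.data$redundant) > 0,
                              .data$redundant / sum(.data$redundant), NA_real_),
      frac_unique = ifelse(sum(.data$unique) > 0,
                           .data$unique / sum(.data$unique), NA_real_)
    ) |>
    ungroup()
  out$stage <- factor(out$stage, levels = cols)
  arrange(out, .data$stage, .data$length)
}

#' Plot a size distribution
#' @param profile output of [size_profile()].
#' @param what one of `"redundant"`, `"unique"`, `"ratio"`.
#' @return a ggplot.
#' @export
plot_size_profile <- function(profile, what = c("redundant", "unique", "ratio")) {
  what <- match.arg(what)
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$length, y = .data[[what]],
                               fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read length (nt)", y = what) +
    ggplot2::theme_minimal()
}

#' Write / read a collapsed count table
#'
#' `format = "tsv"` is the lossless round-trip format (sequence, length,
#' per-stage counts). `format = "fasta"` writes one FASTA per call with
#' headers `sNNN_xCOUNT` using the summed count (export only).
#'
#' @param collapsed output of [collapse_srna()].
#' @param path output path.
#' @param format `"tsv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_collapsed <- function(collapsed, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  canonicalize_seq(collapsed$seq, allow_n = FALSE)
  if (format == "tsv") {
    write.table(collapsed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    total <- rowSums(collapsed[, stage_cols(collapsed), drop = FALSE])
    headers <- sprintf(">s%06d_x%d", seq_len(nrow(collapsed)), total)
    writeLines(as.vector(rbind(headers, collapsed$seq)), path)
  }
  invisible(path)
}

#' @rdname write_collapsed
#' @export
read_collapsed <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  tab$seq <- canonicalize_seq(tab$seq, allow_n = FALSE)
  as_tibble(tab)
}
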