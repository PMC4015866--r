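#' Read a reference catalog from FASTA
#'
#' A catalog is a named set of reference sequences of one category
#' (mature miRNAs, rRNA, tRNA, snRNA, snoRNA, or a transcript/EST set).
#'
#' @param path FASTA file.
#' @param category catalog category label.
#' @return tibble with `name`, `seq`, `category`.
#' @export
read_catalog <- function(path, category = c("miRNA_mature", "rRNA", "tRNA",
                                            "snRNA", "snoRNA",
                                            "transcript_est")) {
  category <- match.arg(category)
  recs <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(recs))) {
    stop("duplicate names in catalog ", path, call. = FALSE)
  }
  tibble(name = sub("\\s.*$", "", names(recs)),
         seq = unname(canonicalize_seq(as.character(recs))),
         category = category)
}

# Split a catalog into per-length character matrices for fast vectorized
# mismatch counting of end-to-end alignments.
catalog_by_length <- function(catalog) {
  split(catalog, nchar(catalog$seq))
}

#' Match a query against mature miRNA references
#'
#' Ungapped end-to-end comparison: the query is slid against each
#' reference at terminal offsets up to `end_offset` nt (unmatched
#' overhangs on either molecule at either end must not exceed the offset),
#' and mismatches are counted over the overlap. Ties break by fewest
#' mismatches, then reference name order.
#'
#' @param queries character vector of query sequences (DNA alphabet).
#' @param catalog mature catalog tibble (`name`, `seq`).
#' @param max_mismatch maximum mismatches (default 2).
#' @param end_offset maximum terminal offset in nt (default 2).
#' @return tibble, one row per query: `seq`, `ref` (NA if no hit),
#'   `mismatches`, `ambiguous` (equal-score hits in several references).
#' @export
match_mature <- function(queries, catalog, max_mismatch = 2, end_offset = 2) {
  stopifnot(max_mismatch >= 0, end_offset >= 0)
  groups <- split(seq_len(nrow(catalog)), nchar(catalog$seq))
  mats <- lapply(groups, function(idx) {
    do.call(cbind, strsplit(catalog$seq[idx], ""))
  })
  purrr::map_dfr(queries, function(q) {
    qc <- strsplit(q, "")[[1]]
    qlen <- length(qc)
    best_mm <- Inf
    best_refs <- character()
    for (g in names(groups)) {
      reflen <- as.integer(g)
      for (o in -end_offset:end_offset) {
        # query position i aligns to reference position i + o
        if (abs(reflen - qlen - o) > end_offset) next
        qi <- max(1, 1 - o):min(qlen, reflen - o)
        if (length(qi) == 0) next
        ri <- qi + o
        mm <- colSums(mats[[g]][ri, , drop = FALSE] != qc[qi])
        hit <- which(mm <= max_mismatch & mm <= best_mm)
        if (length(hit) > 0) {
          mmin <- min(mm[hit])
          if (mmin < best_mm) {
            best_mm <- mmin
            best_refs <- catalog$name[groups[[g]]][hit[mm[hit] == mmin]]
          } else {
            best_refs <- union(best_refs,
                               catalog$name[groups[[g]]][hit[mm[hit] == mmin]])
          }
        }
      }
    }
    if (is.infinite(best_mm)) {
      tibble(seq = q, ref = NA_character_, mismatches = NA_integer_,
             ambiguous = FALSE)
    } else {
      best_refs <- sort(best_refs)
      tibble(seq = q, ref = best_refs[1], mismatches = as.integer(best_mm),
             ambiguous = length(best_refs) > 1)
    }
  })
}

#' Match queries as exact substrings of reference sequences
#'
#' Used for housekeeping ncRNA catalogs (rRNA, tRNA, snRNA, snoRNA) and
#' transcript sets: a read matches if it occurs verbatim on either strand
#' of any reference.
#'
#' @param queries character vector.
#' @param catalog catalog tibble (`name`, `seq`).
#' @param strand `"both"` (default), `"plus"`, or `"minus"`.
#' @return tibble: `seq`, `ref` (first matching reference by name order,
#'   NA if none), `strand` of the match.
#' @export
match_substring <- function(queries, catalog, strand = c("both", "plus", "minus")) {
  strand <- match.arg(strand)
  cat_sorted <- catalog[order(catalog$name), , drop = FALSE]
  refs_plus <- cat_sorted$seq
  refs_minus <- revcomp(refs_plus)
  big_plus <- paste(refs_plus, collapse = "#")
  big_minus <- paste(refs_minus, collapse = "#")
  purrr::map_dfr(queries, function(q) {
    if (strand %in% c("both", "plus") && grepl(q, big_plus, fixed = TRUE)) {
      i <- which(stringr::str_detect(refs_plus, stringr::fixed(q)))[1]
      return(tibble(seq = q, ref = cat_sorted$name[i], strand = "+"))
    }
    if (strand %in% c("both", "minus") && grepl(q, big_minus, fixed = TRUE)) {
      i <- which(stringr::str_detect(refs_minus, stringr::fixed(q)))[1]
      return(tibble(seq = q, ref = cat_sorted$name[i], strand = "-"))
    }
    tibble(seq = q, ref = NA_character_, strand = NA_character_)
  })
}

#' Conserved miRNA family from a reference name
#'
#' Normalizes mature miRNA names to family labels by stripping the species
#' prefix and any lettered / variant suffix: `"tae-miR156a"`,
#' `"osa-miR156c-5p"` and `"miR156"` all map to family `"miR156"`.
#'
#' @param ref_names character vector of mature reference names.
#' @return character vector of family labels (NA propagates).
#' @export
mirna_family <- function(ref_names) {
  fam <- sub("^[A-Za-z]{2,5}[-_](?=(miR|MIR|let))", "", ref_names, perl = TRUE)
  core <- stringr::str_match(fam, "^((?:miR|MIR|let)-?[0-9]+)")[, 2]
  ifelse(is.na(ref_names), NA_character_,
         ifelse(is.na(core), fam, core))
}

#' Classify collapsed reads into the seven sRNA categories
#'
#' Each unique read receives exactly one of: miRNA, rRNA, tRNA, snRNA,
#' snoRNA, siRNA, unannotated. The first category in `precedence` whose
#' catalog yields a hit wins. miRNA calls use end-to-end mature matching
#' ([match_mature()]); housekeeping ncRNAs use exact substring matching on
#' either strand. The siRNA call is a heuristic: a still-unmatched 24-nt
#' read hitting the transcript catalog on the antisense strand.
#'
#' @param collapsed output of [collapse_srna()].
#' @param catalogs named list of catalog tibbles; recognized names:
#'   `miRNA_mature`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `transcript_est`.
#' @param precedence ordered category labels (default miRNA, rRNA, tRNA,
#'   snRNA, snoRNA, siRNA).
#' @param max_mismatch,end_offset mature-matching parameters
#'   (defaults 2, 2).
#' @param sirna_length read length for the antisense siRNA heuristic
#'   (default 24).
#' @return `collapsed` with added columns `category`, `evidence` (matched
#'   reference), `mismatches`, `family`.
#' @export
classify_srna <- function(collapsed, catalogs,
                          precedence = c("miRNA", "rRNA", "tRNA", "snRNA",
                                         "snoRNA", "siRNA"),
                          max_mismatch = 2, end_offset = 2,
                          sirna_length = 24) {
  seqs <- collapsed$seq
  n <- length(seqs)
  category <- rep("unannotated", n)
  evidence <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  family <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)

  for (cat_label in precedence) {
    idx <- which(unassigned)
    if (length(idx) == 0) break
    if (cat_label == "miRNA") {
      if (is.null(catalogs$miRNA_mature)) next
      hits <- match_mature(seqs[idx], catalogs$miRNA_mature,
                           max_mismatch = max_mismatch,
                           end_offset = end_offset)
      got <- !is.na(hits$ref)
      category[idx[got]] <- "miRNA"
      evidence[idx[got]] <- hits$ref[got]
      mismatches[idx[got]] <- hits$mismatches[got]
      family[idx[got]] <- mirna_family(hits$ref[got])
      unassigned[idx[got]] <- FALSE
    } else if (cat_label == "siRNA") {
      if (is.null(catalogs$transcript_est)) next
      cand <- idx[nchar(seqs[idx]) == sirna_length]
      if (length(cand) == 0) next
      hits <- match_substring(seqs[cand], catalogs$transcript_est,
                              strand = "minus")
      got <- !is.na(hits$ref)
      category[cand[got]] <- "siRNA"
      evidence[cand[got]] <- hits$ref[got]
      unassigned[cand[got]] <- FALSE
    } else {
      if (is.null(catalogs[[cat_label]])) next
      hits <- match_substring(seqs[idx], catalogs[[cat_label]])
      got <- !is.na(hits$ref)
      category[idx[got]] <- cat_label
      evidence[idx[got]] <- hits$ref[got]
      unassigned[idx[got]] <- FALSE
    }
  }
  out <- collapsed
  out$category <- category
  out$evidence <- evidence
  out$mismatches <- mismatches
  out$family <- family
  out
}

#' Per-library miRNA enrichment summary
#'
#' For each stage library: unique and redundant (count-weighted) tallies of
#' the chosen category, their ratio, and the library's total sRNA count —
#' the panels of a per-stage enrichment figure.
#'
#' @param classified output of [classify_srna()].
#' @param category category to profile (default `"miRNA"`).
#' @return tibble: `stage`, `unique`, `redundant`, `ratio` (NA when
#'   `unique` = 0), `total_srna`.
#' @export
summarize_enrichment <- function(classified, category = "miRNA") {
  cols <- setdiff(stage_cols(classified),
                  c("category", "evidence", "mismatches", "family"))
  sub <- classified[classified$category == category, , drop = FALSE]
  purrr::map_dfr(cols, function(s) {
    cnt <- sub[[s]]
    tibble(
      stage = s,
      unique = sum(cnt > 0),
      redundant = sum(cnt),
      ratio = ifelse(sum(cnt > 0) > 0, sum(cnt) / sum(cnt > 0), NA_real_),
      total_srna = sum(classified[[s]])
    )
  })
}
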