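#' Fold an RNA/DNA sequence by weighted base-pair maximization
#'
#' Nested (pseudoknot-free) secondary structure with a minimum hairpin
#' loop of 3 nt, maximizing the weighted pair sum (G:C 3, A:U 2, G:U 1).
#' The score is minus the weighted pair sum, so more negative means more
#' stable; it is on an arbitrary scale, not kcal/mol. Traceback is
#' deterministic. `force_unpaired` supports accessibility calculations.
#'
#' @param seq nucleotide sequence (ACGTU; N allowed, never paired).
#' @param force_unpaired integer positions (1-based) banned from pairing.
#' @return list with `structure` (dot-bracket) and `score`.
#' @export
fold_rna <- function(seq, force_unpaired = integer(0)) {
  seq <- canonicalize_seq(seq)
  .fold_cpp(seq, as.integer(force_unpaired))
}

#' Dot-bracket pair table
#' @param structure dot-bracket string.
#' @return integer vector: partner position per base, 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced structure", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced structure", call. = FALSE)
  pt
}

# Terminal (hairpin) loops: closing pairs (i, j) with nothing paired inside.
hairpin_loops <- function(pt) {
  out <- list()
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i && (j - i < 2 || all(pt[(i + 1):(j - 1)] == 0))) {
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}

# Maximal simple stem-loop extent around a hairpin loop closing pair:
# extend outward through stacked pairs, bulges and interior loops, stopping
# at a multiloop branch or the ends.
hairpin_extent <- function(pt, closing) {
  p <- closing[1]; q <- closing[2]
  n <- length(pt)
  repeat {
    a <- p - 1
    while (a >= 1 && pt[a] == 0) a <- a - 1
    if (a < 1) break
    b <- pt[a]
    if (b <= q) break                                  # branch on the 5' side
    if (b > q + 1 && any(pt[(q + 1):(b - 1)] > 0)) break  # branch on the 3' side
    p <- a; q <- b
  }
  c(p, q)
}

#' Map short sequences exactly onto a transcript set
#'
#' All exact, full-length occurrences on both strands; minus-strand hits
#' are reported in plus-strand coordinates with a strand flag.
#'
#' @param seqs character vector of sRNA sequences.
#' @param transcripts tibble with `name`, `seq`.
#' @return tibble: `seq`, `transcript`, `start`, `end` (1-based inclusive),
#'   `strand`.
#' @export
map_to_transcripts <- function(seqs, transcripts) {
  subj <- Biostrings::DNAStringSet(setNames(transcripts$seq, transcripts$name))
  purrr::map_dfr(unique(seqs), function(q) {
    hits <- list()
    for (str in c("+", "-")) {
      pat <- if (str == "+") q else revcomp(q)
      mi <- Biostrings::vmatchPattern(pat, subj)
      for (t in seq_along(mi)) {
        rg <- mi[[t]]
        if (length(rg) > 0) {
          hits[[length(hits) + 1]] <- tibble(
            seq = q, transcript = transcripts$name[t],
            start = BiocGenerics::start(rg), end = BiocGenerics::end(rg),
            strand = str)
        }
      }
    }
    bind_rows(hits)
  })
}

#' Candidate precursor windows around mapped loci
#'
#' For each flank size f in the ladder, two windows are cut so the sRNA can
#' sit on either arm of a hairpin: `[start - f, end + base_flank]` and
#' `[start - base_flank, end + f]`, clipped to the transcript. Minus-strand
#' loci yield reverse-complemented windows with the mature position
#' recomputed in window coordinates.
#'
#' @param loci output of [map_to_transcripts()].
#' @param transcripts tibble with `name`, `seq`.
#' @param flanks flank ladder in nt (default c(20, 40, 60, 100, 140)).
#' @param base_flank short-side flank (default 20).
#' @param max_window maximum window length (default 300); longer windows
#'   are skipped.
#' @return tibble: `seq`, `transcript`, `strand`, `w_start`, `w_end`
#'   (plus-strand transcript coordinates), `window` (oriented sequence),
#'   `m_start`, `m_end` (mature position within `window`), `clipped`.
#' @export
extract_windows <- function(loci, transcripts, flanks = c(20, 40, 60, 100, 140),
                            base_flank = 20, max_window = 300) {
  stopifnot(all(flanks > 0))
  tmap <- setNames(transcripts$seq, transcripts$name)
  rows <- purrr::pmap_dfr(loci, function(seq, transcript, start, end, strand, ...) {
    tlen <- nchar(tmap[[transcript]])
    purrr::map_dfr(flanks, function(f) {
      bind_rows(
        tibble(lo = start - f, hi = end + base_flank),
        tibble(lo = start - base_flank, hi = end + f)
      ) |>
        mutate(seq = seq, transcript = transcript, strand = strand,
               start = start, end = end, tlen = tlen)
    })
  })
  rows <- rows |>
    mutate(clipped = .data$lo < 1 | .data$hi > .data$tlen,
           w_start = pmax(1, .data$lo),
           w_end = pmin(.data$tlen, .data$hi)) |>
    filter(.data$w_end - .data$w_start + 1 <= max_window) |>
    dplyr::distinct(.data$seq, .data$transcript, .data$strand,
                    .data$w_start, .data$w_end, .keep_all = TRUE)
  rows |>
    mutate(
      window_plus = substr(tmap[.data$transcript], .data$w_start, .data$w_end),
      window = ifelse(.data$strand == "+", .data$window_plus,
                      revcomp(.data$window_plus)),
      m_start = ifelse(.data$strand == "+",
                       .data$start - .data$w_start + 1L,
                       .data$w_end - .data$end + 1L),
      m_end = .data$m_start + (.data$end - .data$start)
    ) |>
    select("seq", "transcript", "strand", "w_start", "w_end", "window",
           "m_start", "m_end", "clipped")
}

#' Evaluate stem-loop criteria for a precursor candidate
#'
#' Named structural criteria in the community tradition for plant miRNA
#' annotation, each an explicit configurable threshold:
#' c1 mature entirely on one arm of a single stem-loop; c2 at most
#' `max_unpaired` unpaired mature bases in the mature/star duplex; c3 no
#' asymmetric bulge wider than `max_bulge` nt within the duplex; c4 mature
#' does not span the terminal loop; c5 folding score at most `score_max`;
#' c6 paired fraction of the hairpin at least `min_paired_frac`. A
#' candidate is accepted iff all pass.
#'
#' @param window window sequence (oriented so the mature reads 5'->3').
#' @param m_start,m_end mature position within the window (1-based).
#' @param structure,score optional precomputed fold of `window`.
#' @param max_unpaired,max_bulge,score_max,min_paired_frac thresholds
#'   (defaults 4, 2, -15, 0.5).
#' @return one-row tibble: `structure`, `score`, flags `c1`..`c6`,
#'   `accept`, `arm` ("5p"/"3p"/NA), `star_start`, `star_end`, `star_seq`.
#' @export
evaluate_hairpin <- function(window, m_start, m_end,
                             structure = NULL, score = NULL,
                             max_unpaired = 4, max_bulge = 2,
                             score_max = -15, min_paired_frac = 0.5) {
  if (is.null(structure) || is.null(score)) {
    fd <- fold_rna(window)
    structure <- fd$structure
    score <- fd$score
  }
  pt <- pair_table(structure)
  n <- length(pt)
  mpos <- m_start:m_end

  loops <- hairpin_loops(pt)
  arm <- NA_character_
  extent <- c(1L, n)
  c1 <- FALSE
  for (cl in loops) {
    ext <- hairpin_extent(pt, cl)
    if (m_start >= ext[1] && m_end <= cl[1]) {
      c1 <- TRUE; arm <- "5p"; extent <- ext; break
    }
    if (m_start >= cl[2] && m_end <= ext[2]) {
      c1 <- TRUE; arm <- "3p"; extent <- ext; break
    }
  }
  # no mature base may pair with another mature base (self-folding mature)
  if (c1 && any(pt[mpos] %in% mpos & pt[mpos] != 0)) c1 <- FALSE

  c4 <- !any(vapply(loops, function(cl) {
    m_start <= cl[2] - 1 && m_end >= cl[1] + 1
  }, logical(1)))

  unpaired_mature <- sum(pt[mpos] == 0)
  c2 <- unpaired_mature <= max_unpaired

  paired_m <- mpos[pt[mpos] != 0]
  c3 <- TRUE
  if (length(paired_m) >= 2) {
    for (i in seq_len(length(paired_m) - 1)) {
      gap_m <- paired_m[i + 1] - paired_m[i] - 1
      gap_s <- abs(pt[paired_m[i]] - pt[paired_m[i + 1]]) - 1
      if (abs(gap_m - gap_s) > max_bulge) { c3 <- FALSE; break }
    }
  } else if (length(paired_m) == 0) {
    c3 <- FALSE
  }

  c5 <- score <= score_max
  reg <- extent[1]:extent[2]
  c6 <- mean(pt[reg] != 0) >= min_paired_frac

  star <- derive_star(window, structure, m_start, m_end, pt = pt)
  accept <- c1 && c2 && c3 && c4 && c5 && c6 && !is.na(star$star_start)
  tibble(structure = structure, score = score,
         c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
         accept = accept, arm = arm,
         hp_start = if (c1) extent[1] else NA_integer_,
         hp_end = if (c1) extent[2] else NA_integer_,
         star_start = star$star_start, star_end = star$star_end,
         star_seq = star$star_seq)
}

#' Derive the star (passenger) sequence of a mature within a hairpin
#'
#' Uses the Dicer duplex geometry: the star is the segment pairing with the
#' mature, offset so both strands carry 2-nt 3' overhangs. Unpaired mature
#' termini are projected through the nearest paired mature base.
#'
#' @inheritParams evaluate_hairpin
#' @param pt optional precomputed [pair_table()].
#' @return list with `star_start`, `star_end`, `star_seq` (all NA when the
#'   star would run off the window or the mature is entirely unpaired).
#' @export
derive_star <- function(window, structure, m_start, m_end, pt = NULL) {
  pt <- pt %||% pair_table(structure)
  n <- length(pt)
  none <- list(star_start = NA_integer_, star_end = NA_integer_,
               star_seq = NA_character_)
  # partner of m_end, projected if unpaired
  k2 <- m_end
  while (k2 >= m_start && pt[k2] == 0) k2 <- k2 - 1
  k1 <- m_start
  while (k1 <= m_end && pt[k1] == 0) k1 <- k1 + 1
  if (k2 < m_start || k1 > m_end) return(none)
  star_start <- pt[k2] - (m_end - k2) + 2L
  star_end <- pt[k1] + (k1 - m_start) + 2L
  if (star_start < 1 || star_end > n || star_end <= star_start) return(none)
  list(star_start = as.integer(star_start), star_end = as.integer(star_end),
       star_seq = substr(window, star_start, star_end))
}

# Reciprocal overlap of two intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Discover novel miRNA candidates from unannotated reads
#'
#' The full discovery path: exact mapping of candidate reads onto the
#' (non-coding) transcript set, precursor window extraction over a flank
#' ladder, folding, stem-loop criteria, per-mature deduplication (same
#' mature, >= 50% reciprocally overlapping precursors keep the
#' better-scoring window), sequential naming by descending total count,
#' and 5p/3p pairing of matures sharing one precursor.
#'
#' @param candidates collapsed (optionally classified) tibble; when a
#'   `category` column is present only `"unannotated"` rows are used.
#' @param transcripts tibble with `name`, `seq` (protein-coding entries
#'   already excluded).
#' @param totals named per-stage totals for TPM (default: column sums).
#' @param flanks,max_window see [extract_windows()].
#' @param name_prefix candidate name prefix (default `"Ta-miR"`).
#' @param ... criteria thresholds passed to [evaluate_hairpin()].
#' @return a `novel_mirna_set`: list with `mirnas` (accepted, named, with
#'   per-stage counts/TPM and partner links) and `candidates` (every
#'   evaluated window with flags).
#' @export
discover_mirnas <- function(candidates, transcripts, totals = NULL,
                            flanks = c(20, 40, 60, 100, 140), max_window = 300,
                            name_prefix = "Ta-miR", ...) {
  if ("category" %in% names(candidates)) {
    candidates <- candidates[candidates$category == "unannotated", , drop = FALSE]
  }
  stage_c <- setdiff(stage_cols(candidates),
                     c("category", "evidence", "mismatches", "family"))
  totals <- totals %||% colSums(candidates[, stage_c, drop = FALSE])

  empty <- structure(list(
    mirnas = tibble(), candidates = tibble(), stages = stage_c),
    class = "novel_mirna_set")
  if (nrow(candidates) == 0) return(empty)

  loci <- map_to_transcripts(candidates$seq, transcripts)
  if (nrow(loci) == 0) return(empty)
  wins <- extract_windows(loci, transcripts, flanks = flanks,
                          max_window = max_window)
  if (nrow(wins) == 0) return(empty)

  evals <- purrr::pmap_dfr(
    wins[, c("window", "m_start", "m_end")],
    function(window, m_start, m_end) {
      evaluate_hairpin(window, m_start, m_end, ...)
    })
  all_cand <- bind_rows(dplyr::bind_cols(wins, evals))

  acc <- all_cand[all_cand$accept, , drop = FALSE]
  if (nrow(acc) > 0) {
    # precursor = the folded hairpin extent in transcript coordinates
    # (dedup must be invariant to which ladder window held the hairpin)
    acc$prec_start <- ifelse(acc$strand == "+",
                             acc$w_start + acc$hp_start - 1L,
                             acc$w_end - acc$hp_end + 1L)
    acc$prec_end <- ifelse(acc$strand == "+",
                           acc$w_start + acc$hp_end - 1L,
                           acc$w_end - acc$hp_start + 1L)
    # dedup: same mature + >=50% reciprocal precursor overlap -> best score
    acc <- acc[order(acc$seq, acc$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(acc))
    for (i in seq_len(nrow(acc))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(acc))) {
        if (j <= i || !keep[j]) next
        # strand-agnostic: a stem-loop read in either orientation at one
        # locus is the same physical precursor
        if (acc$seq[j] == acc$seq[i] &&
            acc$transcript[j] == acc$transcript[i] &&
            reciprocal_overlap(acc$prec_start[i], acc$prec_end[i],
                               acc$prec_start[j], acc$prec_end[j]) >= 0.5) {
          keep[j] <- FALSE
        }
      }
    }
    acc <- acc[keep, , drop = FALSE]
  }
  if (nrow(acc) == 0) {
    empty$candidates <- all_cand
    return(empty)
  }

  acc <- left_join(acc, candidates[, c("seq", stage_c)], by = "seq")
  acc$total_count <- rowSums(acc[, stage_c, drop = FALSE])
  for (s in stage_c) {
    acc[[paste0("tpm_", s)]] <- compute_tpm(acc[[s]], totals[[s]])
  }

  # pair matures sharing a precursor (>=50% reciprocal window overlap,
  # opposite arms); then number precursors by descending total count
  acc$precursor_id <- NA_integer_
  pid <- 0L
  ord <- order(-acc$total_count, acc$seq)
  for (i in ord) {
    if (!is.na(acc$precursor_id[i])) next
    pid <- pid + 1L
    acc$precursor_id[i] <- pid
    for (j in ord) {
      if (i == j || !is.na(acc$precursor_id[j])) next
      if (acc$transcript[j] == acc$transcript[i] &&
          reciprocal_overlap(acc$prec_start[i], acc$prec_end[i],
                             acc$prec_start[j], acc$prec_end[j]) >= 0.5) {
        acc$precursor_id[j] <- pid
      }
    }
  }
  acc$name <- sprintf("%s%03d-%s", name_prefix, acc$precursor_id,
                      ifelse(is.na(acc$arm), "5p", acc$arm))
  # disambiguate several matures on one arm of one precursor
  dup <- duplicated(acc$name)
  if (any(dup)) {
    acc$name[dup] <- paste0(acc$name[dup], "-", seq_len(sum(dup)))
  }
  acc$partner <- NA_character_
  for (p in unique(acc$precursor_id)) {
    idx <- which(acc$precursor_id == p)
    arms <- acc$arm[idx]
    if (length(idx) >= 2 && all(c("5p", "3p") %in% arms)) {
      # best duplex pair: top-count mature on each arm
      i5 <- idx[arms == "5p"][which.max(acc$total_count[idx[arms == "5p"]])]
      i3 <- idx[arms == "3p"][which.max(acc$total_count[idx[arms == "3p"]])]
      acc$partner[i5] <- acc$name[i3]
      acc$partner[i3] <- acc$name[i5]
    }
  }
  acc <- acc[order(acc$precursor_id, acc$arm), , drop = FALSE]
  structure(list(mirnas = as_tibble(acc), candidates = all_cand,
                 stages = stage_c),
            class = "novel_mirna_set")
}

#' @export
print.novel_mirna_set <- function(x, ...) {
  cat("Novel miRNA discovery: ", nrow(x$mirnas), " accepted matures",
      if (nrow(x$mirnas) > 0)
        paste0(" on ", length(unique(x$mirnas$precursor_id)), " precursors"),
      "; ", nrow(x$candidates), " windows evaluated\n", sep = "")
  invisible(x)
}

#' Tidy a novel miRNA set
#' @param x a `novel_mirna_set`.
#' @param ... unused.
#' @return tibble of accepted matures.
#' @export
tidy.novel_mirna_set <- function(x, ...) x$mirnas

#' Write precursors as a Vienna-style structure file
#'
#' One record per accepted mature: header line, window sequence (RNA
#' alphabet), dot-bracket structure.
#'
#' @param x a `novel_mirna_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hairpins <- function(x, path) {
  stopifnot(inherits(x, "novel_mirna_set"))
  m <- x$mirnas
  lines <- character(0)
  for (i in seq_len(nrow(m))) {
    lines <- c(lines,
               sprintf(">%s %s:%d-%d(%s)", m$name[i], m$transcript[i],
                       m$w_start[i], m$w_end[i], m$strand[i]),
               to_rna(m$window[i]), m$structure[i])
  }
  writeLines(lines, path)
  invisible(path)
}
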