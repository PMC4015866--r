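target_weights <- function(wobble = 0.5, mismatch = 1, gap = 2,
                           core = c(2, 13), core_mult = 2) {
  list(wobble = wobble, mismatch = mismatch, gap = gap,
       core = core, core_mult = core_mult)
}

wc_pairs <- c(A = "T", C = "G", G = "C", T = "A")
is_wc <- function(a, b) !is.na(wc_pairs[a]) & wc_pairs[a] == b
is_gu <- function(a, b) (a == "G" & b == "T") | (a == "T" & b == "G")

#' Score a miRNA/target-site duplex
#'
#' Penalty-based complementarity score ("expectation"): per aligned
#' position a perfect pair costs 0, a G:U wobble 0.5, a mismatch 1, an
#' indel 2; penalties are doubled over the seed-proximal core (miRNA
#' positions 2-13). Up to `max_gaps` indels are allowed (default 1) and
#' the minimum-penalty alignment is returned. Lower is a better target;
#' 0 means perfect complementarity.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target site on the transcript, 5'->3' (the duplex is
#'   antiparallel; position 1 of the miRNA faces the 3' end of the site).
#' @param weights penalty scheme from `target_weights()`.
#' @param max_gaps maximum indels (default 1).
#' @return list: `expectation`, `alignment` (one char per duplex column:
#'   `|` pair, `o` G:U, `x` mismatch, `-` indel), `mirna_pos` (miRNA
#'   position per column), `n_col`.
#' @export
score_duplex <- function(mirna, site, weights = target_weights(),
                         max_gaps = 1) {
  mirna <- canonicalize_seq(mirna)
  site <- canonicalize_seq(site)
  if (nchar(mirna) == 0 || nchar(site) == 0) {
    stop("empty duplex operand", call. = FALSE)
  }
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])   # site read 3'->5' faces miRNA 5'->3'
  n <- length(m); L <- length(t)
  if (abs(L - n) > max_gaps) stop("site length incompatible with max_gaps",
                                  call. = FALSE)
  core_cost <- function(pos, c) {
    if (pos >= weights$core[1] && pos <= weights$core[2]) c * weights$core_mult
    else c
  }
  INF <- 1e18
  D <- array(INF, dim = c(max_gaps + 1, n + 1, L + 1))
  B <- array(0L, dim = c(max_gaps + 1, n + 1, L + 1))  # 1 diag 2 gap-t 3 gap-m
  D[1, 1, 1] <- 0
  for (g in 0:max_gaps) for (i in 0:n) for (j in 0:L) {
    cur <- D[g + 1, i + 1, j + 1]
    if (cur >= INF) next
    if (i < n && j < L) {
      cc <- if (is_wc(m[i + 1], t[j + 1])) 0
            else if (is_gu(m[i + 1], t[j + 1])) weights$wobble
            else weights$mismatch
      val <- cur + core_cost(i + 1, cc)
      if (val < D[g + 1, i + 2, j + 2]) {
        D[g + 1, i + 2, j + 2] <- val; B[g + 1, i + 2, j + 2] <- 1L
      }
    }
    if (g < max_gaps) {
      if (i < n) {
        val <- cur + core_cost(i + 1, weights$gap)
        if (val < D[g + 2, i + 2, j + 1]) {
          D[g + 2, i + 2, j + 1] <- val; B[g + 2, i + 2, j + 1] <- 2L
        }
      }
      if (j < L) {
        val <- cur + core_cost(min(i + 1, n), weights$gap)
        if (val < D[g + 2, i + 1, j + 2]) {
          D[g + 2, i + 1, j + 2] <- val; B[g + 2, i + 1, j + 2] <- 3L
        }
      }
    }
  }
  gbest <- which.min(D[, n + 1, L + 1]) - 1L
  expectation <- D[gbest + 1, n + 1, L + 1]
  # traceback
  cols <- character(0); pos <- integer(0)
  g <- gbest; i <- n; j <- L
  while (i > 0 || j > 0) {
    mv <- B[g + 1, i + 1, j + 1]
    if (mv == 1L) {
      sym <- if (is_wc(m[i], t[j])) "|" else if (is_gu(m[i], t[j])) "o" else "x"
      cols <- c(sym, cols); pos <- c(i, pos); i <- i - 1; j <- j - 1
    } else if (mv == 2L) {
      cols <- c("-", cols); pos <- c(i, pos); i <- i - 1; g <- g - 1
    } else {
      cols <- c("-", cols); pos <- c(min(i + 1, n), pos); j <- j - 1; g <- g - 1
    }
  }
  list(expectation = expectation, alignment = paste(cols, collapse = ""),
       mirna_pos = pos, n_col = length(cols))
}

#' Scan a transcript for target sites of one miRNA
#'
#' Every start position is evaluated by minimum-penalty duplex alignment
#' (site lengths within one indel of the miRNA length); windows at or
#' under `max_expectation` are kept and overlapping windows are merged to
#' the best-scoring site (ties to the leftmost).
#'
#' @inheritParams score_duplex
#' @param transcript transcript sequence, 5'->3'.
#' @param max_expectation penalty cutoff (default 3).
#' @return tibble: `start`, `end` (1-based inclusive), `expectation`,
#'   `site`, `alignment`, `mode` (see [classify_mode()]).
#' @export
scan_transcript <- function(mirna, transcript, max_expectation = 3,
                            weights = target_weights(), max_gaps = 1) {
  mirna <- canonicalize_seq(mirna)
  transcript <- canonicalize_seq(transcript)
  if (nchar(transcript) < nchar(mirna)) {
    stop("transcript shorter than miRNA", call. = FALSE)
  }
  raw <- .scan_transcript_cpp(mirna, transcript, max_expectation,
                              weights$wobble, weights$mismatch, weights$gap,
                              as.integer(weights$core[1]),
                              as.integer(weights$core[2]),
                              weights$core_mult, as.integer(max_gaps))
  raw <- as_tibble(raw)
  if (nrow(raw) == 0) {
    return(tibble(start = integer(), end = integer(),
                  expectation = numeric(), site = character(),
                  alignment = character(), mode = character()))
  }
  raw <- raw[order(raw$expectation, raw$start, raw$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(raw)) > i)
    if (length(later) > 0) {
      ov <- raw$start[later] <= raw$end[i] & raw$end[later] >= raw$start[i]
      keep[later[ov]] <- FALSE
    }
  }
  hits <- raw[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$site <- substr(rep(transcript, nrow(hits)), hits$start, hits$end)
  dups <- purrr::map(hits$site, ~score_duplex(mirna, .x, weights = weights,
                                              max_gaps = max_gaps))
  hits$alignment <- purrr::map_chr(dups, "alignment")
  hits$mode <- purrr::map_chr(dups, classify_mode)
  hits
}

#' Inhibition-mode call from duplex geometry
#'
#' Translational inhibition is called when a central mismatch or indel
#' falls on miRNA positions `central` (default 9-11, the cleavage-site
#' region); otherwise cleavage. G:U wobbles still pair and do not trigger
#' the call.
#'
#' @param duplex a [score_duplex()] result, or an alignment string (miRNA
#'   positions then inferred by walking the columns).
#' @param central miRNA positions checked (default 9:11).
#' @return `"cleavage"` or `"translational_inhibition"`.
#' @export
classify_mode <- function(duplex, central = 9:11) {
  if (is.character(duplex)) {
    cols <- strsplit(duplex, "")[[1]]
    pos <- seq_along(cols)  # best effort: column index stands in for position
    duplex <- list(alignment = duplex, mirna_pos = pos)
  }
  cols <- strsplit(duplex$alignment, "")[[1]]
  bad <- cols %in% c("x", "-")
  if (any(duplex$mirna_pos[bad] %in% central)) "translational_inhibition"
  else "cleavage"
}

#' Energy to unpair a target site
#'
#' Accessibility of a site: the region spanning the site plus flanks is
#' folded freely and again with the site bases forced unpaired; UPE is the
#' score difference (>= 0). With the built-in weighted-pair folding the
#' scale is arbitrary units, not kcal/mol, so the conventional UPE cutoff
#' is reported as a flag rather than used to drop hits.
#'
#' @param transcript transcript sequence.
#' @param start,end site coordinates (1-based inclusive).
#' @param flank_up,flank_down flank lengths upstream/downstream of the
#'   site (defaults 17 and 13).
#' @return list: `upe`, `clipped` (TRUE when a flank ran off the
#'   transcript).
#' @export
compute_upe <- function(transcript, start, end, flank_up = 17,
                        flank_down = 13) {
  tlen <- nchar(transcript)
  lo <- start - flank_up
  hi <- end + flank_down
  clipped <- lo < 1 || hi > tlen
  lo <- max(1, lo); hi <- min(tlen, hi)
  region <- substr(transcript, lo, hi)
  site_local <- (start - lo + 1):(end - lo + 1)
  free <- fold_rna(region)
  constrained <- fold_rna(region, force_unpaired = site_local)
  list(upe = abs(constrained$score - free$score), clipped = clipped)
}

#' Predict targets of a miRNA set on a transcript set
#'
#' @param mirnas tibble with `name`, `seq` (mature miRNAs).
#' @param transcripts tibble with `name`, `seq`.
#' @param max_expectation penalty cutoff (default 3).
#' @param with_upe also compute site accessibility (default FALSE; folding
#'   every site region is the slow step).
#' @param upe_max accessibility flag threshold (default 25; meaningful
#'   only for a thermodynamic backend, so hits above it are flagged, never
#'   dropped).
#' @inheritParams score_duplex
#' @return tibble of target hits: `mirna`, `transcript`, `start`, `end`,
#'   `expectation`, `alignment`, `mode`, and with `with_upe` also `upe`,
#'   `upe_flag`, `upe_clipped`.
#' @export
predict_targets <- function(mirnas, transcripts, max_expectation = 3,
                            with_upe = FALSE, upe_max = 25,
                            weights = target_weights(), max_gaps = 1) {
  out <- purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    purrr::map_dfr(seq_len(nrow(transcripts)), function(t) {
      hits <- scan_transcript(mirnas$seq[i], transcripts$seq[t],
                              max_expectation = max_expectation,
                              weights = weights, max_gaps = max_gaps)
      if (nrow(hits) == 0) return(tibble())
      dplyr::bind_cols(tibble(mirna = mirnas$name[i],
                              transcript = transcripts$name[t]), hits)
    })
  })
  if (nrow(out) > 0 && with_upe) {
    tmap <- setNames(transcripts$seq, transcripts$name)
    upes <- purrr::pmap(out[, c("transcript", "start", "end")],
                        function(transcript, start, end) {
                          compute_upe(tmap[[transcript]], start, end)
                        })
    out$upe <- purrr::map_dbl(upes, "upe")
    out$upe_clipped <- purrr::map_lgl(upes, "clipped")
    out$upe_flag <- out$upe > upe_max
  }
  out
}
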