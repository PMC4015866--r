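# Independent oracles and small fixture builders used across tests.

# Exact count test, recurrence route: log p(0|x) = -(x+1) log(1+r),
# log p(y+1|x) = log p(y|x) + log(r/(1+r)) + log(x+y+1) - log(y+1),
# iterated additively; a route independent of the package's log-gamma
# closed form.
ac_oracle <- function(x, y, n1, n2) {
  o <- ac_oracle_row(x, y, n1, n2)
  list(p_point = o$p_point[y + 1], C = o$C[y + 1], D = o$D[y + 1])
}

# Whole-row version for grid comparisons: matrices over y = 0..ymax.
ac_oracle_row <- function(x, ymax, n1, n2) {
  r <- n2 / n1
  upto <- max(ymax, stats::qnbinom(1e-17, size = x + 1, prob = 1 / (1 + r),
                                   lower.tail = FALSE)) + 50
  lp <- numeric(upto + 1)
  lp[1] <- -(x + 1) * log1p(r)
  lr <- log(r) - log1p(r)
  for (yy in seq_len(upto)) {
    lp[yy + 1] <- lp[yy] + lr + log(x + yy) - log(yy)
  }
  m <- max(lp)
  sc <- exp(lp - m)
  ys <- 0:ymax
  list(p_point = exp(lp[ys + 1]),
       C = pmin(1, exp(m) * cumsum(sc)[ys + 1]),
       D = pmin(1, exp(m) * rev(cumsum(rev(sc)))[ys + 1]))
}

# Exhaustive folding oracle: best weighted pair sum over every nested
# structure with hairpin loops >= 3 nt, by direct enumeration from the
# left end (no tabulation, no traceback).
enum_fold_score <- function(seq) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  rec <- function(i, j) {
    if (i > j) return(0)
    best <- rec(i + 1, j)              # i unpaired
    if (j >= i + 4) {
      for (k in (i + 4):j) {
        wk <- w(ch[i], ch[k])
        if (wk > 0) {
          cand <- wk + rec(i + 1, k - 1) + rec(k + 1, j)
          if (cand > best) best <- cand
        }
      }
    }
    best
  }
  -rec(1, length(ch))
}

# Weighted pair sum actually realized by a dot-bracket structure, with a
# validity check (balanced, loops >= 3, pairable letters only).
structure_score <- function(seq, db) {
  pt <- mirgrain::pair_table(db)
  ch <- strsplit(seq, "")[[1]]
  total <- 0
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i) {
      stopifnot(j - i > 3)  # min hairpin loop 3
      pair <- paste0(ch[i], ch[j])
      wk <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)[pair]
      stopifnot(!is.na(wk))
      total <- total + unname(wk)
    }
  }
  -total
}

# A perfect inverted-repeat hairpin around a given mature arm.
make_hairpin <- function(mature, loop = "AAAA", arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  star <- mirgrain::revcomp(mature)
  if (arm == "5p") paste0(mature, loop, star) else paste0(star, loop, mature)
}

# Altschul-Erikson dinucleotide shuffle: a random Eulerian walk over the
# dinucleotide graph, preserving length, GC and the full (overlapping)
# dinucleotide composition -- the standard decoy model for structure tests.
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  verts <- unique(ch)
  edges <- lapply(setNames(verts, verts), function(v) ch[which(ch[-n] == v) + 1])
  last <- ch[n]
  repeat {
    # pick a random last-exit edge per vertex; they must form a tree into
    # the terminal vertex for an Eulerian walk to exist
    last_exit <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_exit[[v]])) next
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_exit[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_exit[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  lists <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    le <- last_exit[[v]]
    if (!is.na(le)) {
      e <- e[-match(le, e)]
      c(sample(e), le)
    } else {
      sample(e)
    }
  })
  used <- setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    used[[cur]] <- used[[cur]] + 1L
    nxt <- lists[[cur]][used[[cur]]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# Small read tibble builder.
read_tbl <- function(seqs, stage = NULL, qual = NA_character_) {
  out <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                        seq = seqs, qual = qual)
  if (!is.null(stage)) out$stage <- stage
  out
}
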