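test_that("folding matches the exhaustive enumeration oracle up to 14 nt", {
  expect_equal(fold_rna("GGGGAAAACCCC")$structure, "((((....))))")
  expect_equal(fold_rna("GGGGAAAACCCC")$score, -12)
  expect_equal(fold_rna(strrep("A", 12))$score, 0)
  expect_equal(fold_rna(strrep("A", 12))$structure, strrep(".", 12))

  set.seed(314)
  for (i in 1:60) {
    n <- sample(4:14, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    f <- fold_rna(s)
    expect_equal(f$score, enum_fold_score(s), label = s)
    # the returned structure is valid and realizes the optimal score
    expect_equal(structure_score(s, f$structure), f$score, label = s)
  }
  expect_error(fold_rna("ACGTXX"), "invalid")
})

test_that("structures are balanced with hairpin loops >= 3 at any length", {
  set.seed(271)
  for (i in 1:15) {
    s <- random_dna(1, sample(30:120, 1))
    f <- fold_rna(s)
    pt <- pair_table(f$structure)  # errors if unbalanced
    paired <- which(pt > seq_along(pt))
    if (length(paired) > 0) {
      expect_true(all(pt[paired] - paired > 3))
    }
    # forced-unpaired mask is respected
    masked <- fold_rna(s, force_unpaired = 1:10)
    expect_true(all(pair_table(masked$structure)[1:10] == 0))
    expect_gte(masked$score, f$score)
  }
})

test_that("exact transcript mapping reports loci on both strands", {
  m <- "TGACAGAAGAGAGTGAGCACA"
  tr <- tibble::tibble(
    name = c("EST1", "EST2"),
    seq = c(paste0(strrep("C", 100), m, strrep("A", 100)),
            paste0(strrep("G", 50), revcomp(m), strrep("T", 50))))
  loci <- map_to_transcripts(m, tr)
  expect_equal(nrow(loci), 2)
  plus <- loci[loci$strand == "+", ]
  expect_equal(plus$transcript, "EST1")
  expect_equal(c(plus$start, plus$end), c(101, 121))
  expect_equal(loci$strand[loci$transcript == "EST2"], "-")
  expect_equal(nrow(map_to_transcripts("TTTTTTTTTTTTTTTTTTGG", tr)), 0)
})

test_that("window extraction clips to bounds and contains the transcript substring", {
  tr <- tibble::tibble(name = "EST1", seq = random_dna(1, 400))
  m <- substr(tr$seq, 101, 121)
  loci <- tibble::tibble(seq = m, transcript = "EST1", start = 101,
                         end = 121, strand = "+")
  wins <- extract_windows(loci, tr, flanks = c(20, 60))
  expect_true(all(vapply(wins$window, function(w) {
    grepl(w, tr$seq, fixed = TRUE)
  }, logical(1))))
  # interior locus, f = 60: window length = sRNA length + 80
  expect_true(any(wins$w_end - wins$w_start + 1 == nchar(m) + 80))
  # mature coordinates point at the mature inside the window
  expect_true(all(substr(wins$window, wins$m_start, wins$m_end) == m))
  # edge locus gets clipped and flagged
  edge <- tibble::tibble(seq = substr(tr$seq, 1, 21), transcript = "EST1",
                         start = 1, end = 21, strand = "+")
  we <- extract_windows(edge, tr, flanks = c(60))
  expect_true(all(we$clipped))
})

test_that("stem-loop criteria accept a clean hairpin and fail the right flags", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  # two trailing bases leave room for the star's 2-nt 3' overhang
  hp <- paste0(make_hairpin(mature, loop = "TTAA", arm = "5p"), "AC")
  ev <- evaluate_hairpin(hp, 1, nchar(mature))
  expect_true(ev$accept)
  expect_equal(ev$arm, "5p")
  expect_true(all(unlist(ev[, c("c1", "c2", "c3", "c4", "c5", "c6")])))

  # mature centered on the terminal loop fails c4 (and c1)
  loop_center <- nchar(mature) - 5
  ev_loop <- evaluate_hairpin(hp, loop_center, loop_center + 14)
  expect_false(ev_loop$c4)
  expect_false(ev_loop$accept)

  # five unpaired mature bases overflow the duplex budget (c2); the
  # structure is supplied explicitly so the check is on the criterion,
  # not on what the folder makes of the mutated sequence
  db <- paste0("((.((.((.((.((.((((((", "....",
               ")))))).)).)).)).)).))")
  hp_bare <- make_hairpin(mature, loop = "TTAA", arm = "5p")
  stopifnot(nchar(db) == nchar(hp_bare))
  ev_mm <- evaluate_hairpin(hp_bare, 1, nchar(mature), structure = db,
                            score = -40)
  expect_false(ev_mm$c2)
  expect_true(ev_mm$c1)

  # 3' arm mature is recognized as 3p
  hp3 <- make_hairpin(mature, loop = "TTAA", arm = "3p")
  m_start <- nchar(hp3) - nchar(mature) + 1
  ev3 <- evaluate_hairpin(hp3, m_start, nchar(hp3))
  expect_true(ev3$accept)
  expect_equal(ev3$arm, "3p")
})

test_that("star derivation follows Dicer 2-nt overhang geometry", {
  mature <- "TGACAGAAGAGAGTGAGCACA"
  L <- nchar(mature)
  # embed the mature inside a longer perfectly paired arm, so every
  # duplex position (including the 2-nt offsets) lies on the stem
  arm5 <- paste0("CAGTTC", mature, "GATCCA")
  hp <- paste0(arm5, "TTTAA", revcomp(arm5))
  m_start <- 7L
  m_end <- m_start + L - 1L
  f <- fold_rna(hp)
  st <- derive_star(hp, f$structure, m_start, m_end)
  pt <- pair_table(f$structure)
  # star pairs the mature with 2-nt 3' overhangs on both strands
  expect_equal(st$star_start, pt[m_end] + 2L)
  expect_equal(st$star_end, pt[m_start] + 2L)
  # involution: the star of the star recovers the mature coordinates
  back <- derive_star(hp, f$structure, st$star_start, st$star_end)
  expect_equal(c(back$star_start, back$star_end), c(m_start, m_end))
  # star running off the window is rejected: mature at the very 5' end
  # puts the star 2-nt overhang beyond the window
  tight <- make_hairpin(mature, loop = "TTTAA")
  ft <- fold_rna(tight)
  st2 <- derive_star(tight, ft$structure, 1, L)
  expect_true(is.na(st2$star_start))
})

test_that("discovery names, deduplicates and pairs arms across the flank ladder", {
  set.seed(5)
  mature <- "TGACAGAAGAGAGTGAGCACA"
  star_expr <- revcomp(mature)  # both arms expressed, perfect duplex
  hp <- paste0(mature, "GTTAAC", star_expr)
  tr <- tibble::tibble(
    name = "EST1",
    seq = paste0(random_dna(1, 150), hp, random_dna(1, 150)))
  cand <- tibble::tibble(seq = c(mature, star_expr),
                         length = nchar(c(mature, star_expr)),
                         `5DAP` = c(50L, 10L), `15DAP` = c(80L, 15L))
  nov <- discover_mirnas(cand, tr, totals = c(`5DAP` = 1e5, `15DAP` = 1e5))
  m <- tidy(nov)
  expect_equal(nrow(m), 2)
  # one precursor, both arms, symmetric partner links
  expect_equal(length(unique(m$precursor_id)), 1)
  expect_setequal(m$arm, c("5p", "3p"))
  expect_equal(m$partner[m$arm == "5p"], m$name[m$arm == "3p"])
  expect_equal(m$partner[m$arm == "3p"], m$name[m$arm == "5p"])
  expect_match(m$name, "^Ta-miR001-[53]p$")
  # TPM carried through from totals
  expect_equal(m$`tpm_5DAP`[m$arm == "5p"], 500)
  # acceptance is deduplicated: one window per mature despite the ladder
  expect_equal(sum(m$seq == mature), 1)

  # structure file round-trips through the Vienna-style layout
  path <- withr::local_tempfile(fileext = ".str")
  write_hairpins(nov, path)
  lines <- readLines(path)
  expect_equal(length(lines), 6)
  expect_match(lines[1], "^>Ta-miR001")
  expect_equal(nchar(lines[2]), nchar(lines[3]))
})
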