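test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 13, n_families = 6, n_novel = 3,
                    library_sizes = rep(2e4, 4))
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$collapsed, s2$collapsed)
  expect_identical(s1$catalogs$miRNA_mature, s2$catalogs$miRNA_mature)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth$targets, s2$truth$targets)
  # a different seed changes the world
  s3 <- simulate_experiment(sim_config(seed = 14, n_families = 6,
                                       n_novel = 3,
                                       library_sizes = rep(2e4, 4)))
  expect_false(identical(s1$collapsed, s3$collapsed))
})

test_that("catalog family structure respects the separation constraints", {
  cfg <- sim_config(seed = 3, n_families = 12)
  cats <- simulate_catalogs(cfg)
  mt <- cats$mirna_truth
  expect_equal(length(unique(mt$family)), 12)
  expect_true(all(nchar(mt$seq) %in% 20:24))
  # members of one family within 2 mismatches; families >= 5 apart
  fams <- split(mt$seq, mt$family)
  for (f in fams) {
    if (length(f) > 1) {
      for (i in 1:(length(f) - 1)) for (j in (i + 1):length(f)) {
        expect_lte(sum(strsplit(f[i], "")[[1]] != strsplit(f[j], "")[[1]]), 2)
      }
    }
  }
  seeds <- vapply(fams, function(f) f[1], character(1))
  for (i in 1:(length(seeds) - 1)) for (j in (i + 1):length(seeds)) {
    L <- min(nchar(seeds[i]), nchar(seeds[j]))
    d <- sum(strsplit(substr(seeds[i], 1, L), "")[[1]] !=
               strsplit(substr(seeds[j], 1, L), "")[[1]])
    expect_gte(d, 5)
  }
})

test_that("planted precursors satisfy the stem-loop criteria", {
  cfg <- sim_config(seed = 23, n_novel = 8)
  cats <- simulate_catalogs(cfg)
  prec <- simulate_precursors(cfg, cats$catalogs$miRNA_mature)
  pt <- prec$precursor_truth
  expect_equal(nrow(pt), 8)
  tmap <- setNames(prec$transcripts$seq, prec$transcripts$name)
  for (i in seq_len(nrow(pt))) {
    # truth coordinates point at the planted sequences
    expect_equal(substr(tmap[[pt$transcript[i]]], pt$m_start[i], pt$m_end[i]),
                 pt$mature[i])
    expect_equal(substr(tmap[[pt$transcript[i]]], pt$s_start[i], pt$s_end[i]),
                 pt$star[i])
    # the planted hairpin is accepted through the module's window ladder
    loci <- tibble::tibble(seq = pt$mature[i], transcript = pt$transcript[i],
                           start = pt$m_start[i], end = pt$m_end[i],
                           strand = "+")
    wins <- extract_windows(loci, prec$transcripts)
    evs <- purrr::pmap_dfr(wins[, c("window", "m_start", "m_end")],
                           evaluate_hairpin)
    expect_true(any(evs$accept), label = pt$precursor[i])
  }
})

test_that("planted target sites carry their designed penalty and mode", {
  cfg <- sim_config(seed = 31, n_novel = 2)
  cats <- simulate_catalogs(cfg)
  prec <- simulate_precursors(cfg, cats$catalogs$miRNA_mature)
  tg <- plant_targets(cfg, prec$transcripts, cats$mirna_truth,
                      prec$precursor_truth, n_targets = 10)
  tt <- tg$target_truth
  expect_equal(nrow(tt), 10)
  perfect <- is.na(tt$designed_mismatch_pos)
  expect_true(all(tt$expectation[perfect] == 0))
  central <- !perfect & tt$designed_mismatch_pos %in% 9:11
  expect_true(all(tt$mode[central] == "translational_inhibition"))
  expect_true(all(tt$mode[perfect] == "cleavage"))
  # sites are recoverable by the scanner at their coordinates
  tmap <- setNames(tg$transcripts$seq, tg$transcripts$name)
  for (i in which(perfect)[1:min(3, sum(perfect))]) {
    hits <- scan_transcript(tt$mirna_seq[i], tmap[[tt$transcript[i]]])
    expect_true(any(hits$start == tt$start[i] & hits$expectation == 0))
  }
})

test_that("library counts respect depth, composition and archetype truth", {
  cfg <- sim_config(seed = 5, n_families = 30, library_sizes = rep(1e6, 4))
  cats <- simulate_catalogs(cfg)
  libs <- simulate_libraries(cfg, cats)
  # depth conservation
  expect_equal(unname(colSums(libs$collapsed[, cfg$stages])),
               unname(cfg$library_sizes))
  # stage-wise empirical TPM converges to truth at depth 1e6: every
  # species within 5 binomial sd (which tightens to 5% relative as
  # abundance grows), and 5% relative for the typical species
  pool <- libs$pool
  hi <- pool$true_tpm_5DAP >= 100
  truth_tpm <- pool$true_tpm_5DAP[hi]
  emp <- compute_tpm(pool$`5DAP`[hi], 1e6)
  expect_true(all(abs(emp - truth_tpm) <=
                    pmax(0.05 * truth_tpm, 5 * sqrt(truth_tpm))))
  expect_lt(stats::median(abs(emp - truth_tpm) / truth_tpm), 0.05)
  # factor-2-per-stage archetype: empirical log2FC within 0.2 of truth for
  # adequately sampled species (counts >= 500 keep binomial noise well
  # inside the band)
  arch2 <- matrix(c(1, 2, 4, 8), 1, 4,
                  dimnames = list("X", cfg$stages))
  cfg2 <- sim_config(seed = 6, n_families = 30,
                     library_sizes = rep(1e6, 4), archetypes = arch2)
  libs2 <- simulate_libraries(cfg2, simulate_catalogs(cfg2))
  p2 <- libs2$pool
  hi2 <- p2$class == "miRNA" & p2$true_tpm_5DAP >= 500
  lfc <- log2_fold_change(compute_tpm(p2$`15DAP`[hi2], 1e6),
                          compute_tpm(p2$`5DAP`[hi2], 1e6))
  truth_lfc <- log2(p2$true_tpm_15DAP[hi2] / p2$true_tpm_5DAP[hi2])
  # truth lfc is the factor-2 step corrected for library renormalization
  expect_lt(max(abs(truth_lfc - 1)), 0.5)
  expect_lt(max(abs(lfc - truth_lfc)), 0.2)
})

test_that("emitted raw reads reproduce the collapsed counts after preprocessing", {
  cfg <- sim_config(seed = 17, n_families = 10, n_novel = 0,
                    library_sizes = rep(5e3, 4), jitter_prob = 0)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  files <- write_simulated_reads(sim, dir, format = "fasta", read_len = 45)
  expect_equal(length(files), 4)
  reads <- purrr::imap_dfr(files, function(path, stage) {
    r <- read_srna(path)
    r$stage <- stage
    r
  })
  expect_equal(nrow(reads), 4 * 5e3)
  trimmed <- trim_adapter(reads, cfg$adapter, required = FALSE)
  kept <- filter_by_length(trimmed)
  col <- collapse_srna(kept, stages = cfg$stages)
  # counts of sequences short enough to be fully adapter-resolved match
  ref <- sim$collapsed[sim$collapsed$length <= 37, ]
  merged <- dplyr::inner_join(col, ref, by = "seq",
                              suffix = c("_obs", "_true"))
  expect_equal(merged$`5DAP_obs`, merged$`5DAP_true`)
  expect_equal(merged$`30DAP_obs`, merged$`30DAP_true`)
})
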