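mature_cat <- tibble::tibble(
  name = c("tae-miR156a", "osa-miR164b", "ath-miR396a"),
  seq = c("TGACAGAAGAGAGTGAGCACA", "TGGAGAAGCAGGGCACGTGCA",
          "TTCCACAGCTTTCTTGAACTG"),
  category = "miRNA_mature")

test_that("mature matching is end-to-end with mismatch and offset limits", {
  q <- mature_cat$seq[1]
  hit <- match_mature(q, mature_cat)
  expect_equal(hit$ref, "tae-miR156a")
  expect_equal(hit$mismatches, 0L)

  # three mismatches exceed the default limit
  q3 <- q
  substr(q3, 1, 1) <- "C"; substr(q3, 5, 5) <- "T"; substr(q3, 9, 9) <- "C"
  expect_true(is.na(match_mature(q3, mature_cat)$ref))

  # 2-nt terminal offset: query trimmed by 2 at the 5' end still matches
  expect_equal(match_mature(substr(q, 3, 21), mature_cat)$ref, "tae-miR156a")
  # 3-nt offset is out of reach
  expect_true(is.na(match_mature(substr(q, 4, 21), mature_cat)$ref))

  # tie on equal mismatches resolves to first name, flagged ambiguous
  twin <- tibble::tibble(name = c("aaa-miR001", "zzz-miR002"),
                         seq = rep("ACGTACGTACGTACGTACGT", 2),
                         category = "miRNA_mature")
  h <- match_mature("ACGTACGTACGTACGTACGT", twin)
  expect_equal(h$ref, "aaa-miR001")
  expect_true(h$ambiguous)
})

test_that("substring matching covers both strands of long references", {
  ref <- tibble::tibble(name = "rRNA_1",
                        seq = paste0(strrep("AC", 200), "TTTGGGCCCAAATTT",
                                     strrep("GA", 200)))
  expect_equal(match_substring("TTTGGGCCCAAATTT", ref)$strand, "+")
  expect_equal(match_substring(revcomp("TTTGGGCCCAAATTT"), ref)$strand, "-")
  expect_true(is.na(match_substring(strrep("T", 21), ref)$ref))
})

test_that("family normalization strips species prefixes and member suffixes", {
  expect_equal(mirna_family("tae-miR156a"), "miR156")
  expect_equal(mirna_family("osa-miR156c-5p"), "miR156")
  expect_equal(mirna_family("miR396"), "miR396")
  expect_equal(mirna_family("ath-let7a"), "let7")
  expect_true(is.na(mirna_family(NA_character_)))
  # several members, one family: family count < miRNA count
  fams <- mirna_family(c("tae-miR156a", "tae-miR156b", "tae-miR164a"))
  expect_equal(length(unique(fams)), 2)
})

test_that("classification applies precedence and the antisense siRNA heuristic", {
  shared <- mature_cat$seq[1]
  catalogs <- list(
    miRNA_mature = mature_cat,
    rRNA = tibble::tibble(name = "rRNA_1",
                          seq = paste0(strrep("GT", 100), shared,
                                       strrep("CA", 100)),
                          category = "rRNA"),
    transcript_est = tibble::tibble(
      name = "EST1",
      seq = paste0(strrep("A", 50), revcomp(strrep("ACGGTT", 4)),
                   strrep("C", 50)),
      category = "transcript_est"))
  reads <- tibble::tibble(
    seq = c(shared,                      # hits miRNA and rRNA: precedence
            strrep("ACGGTT", 4),         # 24-nt antisense transcript hit
            strrep("TGCAGT", 4)),        # matches nothing
    length = nchar(c(shared, strrep("ACGGTT", 4), strrep("TGCAGT", 4))),
    `5DAP` = c(10L, 5L, 2L))
  cls <- classify_srna(reads, catalogs)
  expect_equal(cls$category, c("miRNA", "siRNA", "unannotated"))
  expect_equal(cls$family[1], "miR156")
  # partition: every read gets exactly one category
  expect_equal(sum(table(cls$category)), nrow(reads))

  # precedence monotonicity: dropping the miRNA catalog moves the shared
  # read to a later category, never an earlier one
  cls2 <- classify_srna(reads, catalogs[c("rRNA", "transcript_est")])
  expect_equal(cls2$category[1], "rRNA")
})

test_that("enrichment summary counts unique vs redundant miRNA reads", {
  reads <- tibble::tibble(
    seq = c(mature_cat$seq[1], mature_cat$seq[2], strrep("T", 20)),
    length = c(21L, 21L, 20L),
    `5DAP` = c(5L, 15L, 100L),
    `15DAP` = c(0L, 0L, 50L))
  cls <- classify_srna(reads, list(miRNA_mature = mature_cat))
  enr <- summarize_enrichment(cls)
  e5 <- enr[enr$stage == "5DAP", ]
  expect_equal(e5$unique, 2L)
  expect_equal(e5$redundant, 20)
  expect_equal(e5$ratio, 10)
  expect_equal(e5$total_srna, 120)
  expect_true(is.na(enr$ratio[enr$stage == "15DAP"]))
})

test_that("planted classes are recovered exactly on synthetic data", {
  cfg <- sim_config(seed = 11, n_families = 8, n_novel = 0,
                    library_sizes = rep(2e4, 4))
  cats <- simulate_catalogs(cfg)
  libs <- simulate_libraries(cfg, cats)
  cls <- classify_srna(libs$collapsed, cats$catalogs)
  truth <- libs$pool[match(cls$seq, libs$pool$seq), ]
  # decoy fragment classes recovered verbatim (truth "novel" absent here)
  for (cl in c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA")) {
    idx <- truth$class == cl
    expect_true(all(cls$category[idx] == cl),
                label = paste("all planted", cl, "recovered"))
  }
  # planted family assignments recovered
  mi <- truth$class == "miRNA"
  expect_equal(cls$family[mi],
               sub("syn-(miR[0-9]+).*", "\\1", truth$species[mi]))
})
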