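#' Default archetype trajectories
#'
#' Eight multiplicative expression trajectories over the four sampled
#' stages (5, 15, 25, 30 DAP; baseline factor 1 at 5 DAP), emulating the
#' recurring grain-filling profiles: early strong induction held high
#' (I, II), gradual induction (III), mild induction (IV), rapid
#' repression (V), repression with partial recovery (VI, VII), and
#' gradual repression (VIII).
#'
#' @return 8 x 4 numeric matrix, rows named I..VIII.
#' @export
default_archetypes <- function() {
  m <- rbind(
    I    = c(1, 8,    8,    8),
    II   = c(1, 4,    4,    8),
    III  = c(1, 2,    4,    8),
    IV   = c(1, 2,    2,    2),
    V    = c(1, 0.10, 0.02, 0.01),
    VI   = c(1, 0.30, 0.30, 0.60),
    VII  = c(1, 0.50, 0.12, 0.50),
    VIII = c(1, 0.50, 0.25, 0.12)
  )
  colnames(m) <- c("5DAP", "15DAP", "25DAP", "30DAP")
  m
}

#' Simulation configuration
#'
#' The stated world of the generator: four stage libraries of collapsed
#' 18-30 nt reads with planted conserved miRNA families following eight
#' archetype trajectories, decoy housekeeping ncRNA fragments, hairpin
#' precursors embedded in a transcript set, and transcripts carrying
#' target sites of known penalty. Counts are multinomial at the configured
#' depth (single library per stage, no replicates), with an optional
#' Dirichlet overdispersion switch for power studies.
#'
#' @param seed integer seed; fully determines the output.
#' @param n_families number of conserved miRNA families (default 40).
#' @param n_novel number of planted hairpin precursors (default 10).
#' @param both_arm_fraction fraction of precursors with both arms
#'   expressed (default 0.3).
#' @param stages stage labels.
#' @param library_sizes reads per stage library (default 1e6 each, the
#'   depth at which the calibration properties are stated).
#' @param archetypes trajectory factor matrix (default
#'   [default_archetypes()]).
#' @param class_proportions expected read-mass proportions at baseline.
#' @param abundance_log10_range per-species base abundance is
#'   10^U(range) (log-uniform).
#' @param n_transcripts,transcript_len transcript (EST stand-in) set.
#' @param adapter 3' adapter appended to emitted raw reads.
#' @param jitter_prob probability an emitted read loses its final insert
#'   base (length jitter; default 0.05).
#' @param overdispersion Dirichlet concentration scale; `Inf` (default)
#'   means plain multinomial.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_families = 40,
                       n_novel = 10,
                       both_arm_fraction = 0.3,
                       stages = c("5DAP", "15DAP", "25DAP", "30DAP"),
                       library_sizes = rep(1e6, 4),
                       archetypes = default_archetypes(),
                       class_proportions = c(miRNA = 0.30, rRNA = 0.20,
                                             tRNA = 0.12, snRNA = 0.05,
                                             snoRNA = 0.05, novel = 0.05,
                                             unannotated = 0.23),
                       abundance_log10_range = c(0, 3),
                       n_transcripts = 30,
                       transcript_len = 600,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       jitter_prob = 0.05,
                       overdispersion = Inf) {
  stopifnot(length(stages) == ncol(archetypes),
            length(library_sizes) == length(stages),
            all(class_proportions >= 0), sum(class_proportions) <= 1 + 1e-9)
  structure(list(seed = seed, n_families = n_families, n_novel = n_novel,
                 both_arm_fraction = both_arm_fraction, stages = stages,
                 library_sizes = setNames(library_sizes, stages),
                 archetypes = archetypes,
                 class_proportions = class_proportions,
                 abundance_log10_range = abundance_log10_range,
                 n_transcripts = n_transcripts,
                 transcript_len = transcript_len,
                 adapter = adapter, jitter_prob = jitter_prob,
                 overdispersion = overdispersion),
            class = "sim_config")
}

# Substitute k non-pairing bases at interior positions of the star arm.
plant_mismatches <- function(star, mature, k) {
  L <- nchar(star)
  if (k == 0) return(star)
  cand <- 4:(L - 3)
  pos <- sample(cand, k)
  sc <- strsplit(star, "")[[1]]
  mc <- rev(strsplit(mature, "")[[1]])  # star position j faces mature L-j+1
  for (p in pos) {
    m_base <- mc[p]
    opts <- setdiff(c("A", "C", "G", "T"), c(sc[p], wc_pairs[m_base]))
    opts <- opts[!((opts == "G" & m_base == "T") |
                     (opts == "T" & m_base == "G"))]
    sc[p] <- sample(opts, 1)
  }
  paste(sc, collapse = "")
}

#' Generate reference catalogs with planted family structure
#'
#' Mature miRNAs of 20-24 nt grouped into families (members within 1
#' substitution of a family seed, so pairwise at most 2 apart; distinct
#' families at Hamming distance of at least 5 over their common prefix),
#' plus decoy housekeeping ncRNA reference sequences.
#'
#' @param config a [sim_config()].
#' @return list: `catalogs` (named list of catalog tibbles) and
#'   `mirna_truth` (name, seq, family).
#' @export
simulate_catalogs <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  fam_seeds <- character(0)
  rows <- list()
  for (f in seq_len(config$n_families)) {
    ok <- FALSE
    for (try in 1:100) {
      len <- sample(20:24, 1)
      s <- random_dna(1, len)
      far <- all(vapply(fam_seeds, function(o) {
        L <- min(nchar(o), nchar(s))
        hamming(substr(o, 1, L), substr(s, 1, L)) >= 5
      }, logical(1)))
      if (far) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place family ", f, " at Hamming >= 5",
                  call. = FALSE)
    fam_seeds <- c(fam_seeds, s)
    fam_label <- sprintf("miR%03d", f + 100)
    n_members <- 1 + stats::rpois(1, 0.5)
    for (m in seq_len(n_members)) {
      seq_m <- s
      if (m > 1) {
        p <- sample(nchar(s), 1)
        sc <- strsplit(s, "")[[1]]
        sc[p] <- sample(setdiff(c("A", "C", "G", "T"), sc[p]), 1)
        seq_m <- paste(sc, collapse = "")
      }
      rows[[length(rows) + 1]] <- tibble(
        name = sprintf("syn-%s%s", fam_label, letters[m]),
        seq = seq_m, family = fam_label)
    }
  }
  mirna_truth <- bind_rows(rows)
  mature <- tibble(name = mirna_truth$name, seq = mirna_truth$seq,
                   category = "miRNA_mature")
  decoy <- function(prefix, n, len, category) {
    tibble(name = sprintf("%s_%02d", prefix, seq_len(n)),
           seq = random_dna(n, len), category = category)
  }
  catalogs <- list(
    miRNA_mature = mature,
    rRNA = decoy("rRNA", 2, 1200, "rRNA"),
    tRNA = decoy("tRNA", 6, 75, "tRNA"),
    snRNA = decoy("snRNA", 4, 140, "snRNA"),
    snoRNA = decoy("snoRNA", 4, 110, "snoRNA")
  )
  list(catalogs = catalogs, mirna_truth = mirna_truth)
}

#' Generate a transcript set with embedded hairpin precursors
#'
#' Random transcripts (the non-coding EST stand-in) into which one hairpin
#' per planted novel miRNA is spliced: mature arm, 4-8 nt loop, and a
#' near-reverse-complement star arm with up to 2 planted mismatches. A
#' configured fraction of precursors expresses both arms.
#'
#' @param config a [sim_config()].
#' @param mature_catalog mature catalog to avoid colliding with.
#' @return list: `transcripts` tibble and `precursor_truth` (transcript,
#'   hairpin coordinates, mature/star sequences and global coordinates,
#'   arm, `both_arms`).
#' @export
simulate_precursors <- function(config, mature_catalog = NULL) {
  set.seed(derive_seed(config$seed, 2))
  transcripts <- tibble(
    name = sprintf("EST%04d", seq_len(config$n_transcripts)),
    seq = random_dna(config$n_transcripts, config$transcript_len))
  occupied <- list()
  truth <- list()
  for (i in seq_len(config$n_novel)) {
    planted <- FALSE
    for (attempt in 1:40) {
      repeat {
        mlen <- sample(20:22, 1)
        mature <- random_dna(1, mlen, gc = 0.55)
        if (is.null(mature_catalog)) break
        hit <- match_mature(mature, mature_catalog)
        if (is.na(hit$ref[1])) break
      }
      loop <- random_dna(1, sample(4:8, 1), gc = 0.2)
      n_mm <- sample(0:2, 1)
      star <- plant_mismatches(revcomp(mature), mature, n_mm)
      arm <- sample(c("5p", "3p"), 1)
      hairpin <- if (arm == "5p") paste0(mature, loop, star)
                 else paste0(star, loop, mature)
      hlen <- nchar(hairpin)
      repeat {
        tr <- sample(config$n_transcripts, 1)
        pos <- sample(40:(config$transcript_len - hlen - 40), 1)
        clash <- any(vapply(occupied, function(o) {
          o$tr == tr && pos <= o$hi + 10 && pos + hlen - 1 >= o$lo - 10
        }, logical(1)))
        if (!clash) break
      }
      tseq <- transcripts$seq[tr]
      new_seq <- paste0(substr(tseq, 1, pos - 1), hairpin,
                        substr(tseq, pos + hlen, nchar(tseq)))
      m_off <- if (arm == "5p") 0L else nchar(star) + nchar(loop)
      # build-time oracle: the planted hairpin must be discoverable
      # through the module's own window ladder, in its real context
      cand <- tibble(name = transcripts$name[tr], seq = new_seq)
      loci <- tibble(seq = mature, transcript = transcripts$name[tr],
                     start = pos + m_off, end = pos + m_off + mlen - 1,
                     strand = "+")
      wins <- extract_windows(loci, cand)
      ok <- FALSE
      for (w in seq_len(nrow(wins))) {
        ev <- evaluate_hairpin(wins$window[w], wins$m_start[w], wins$m_end[w])
        if (ev$accept) { ok <- TRUE; break }
      }
      if (!ok) next
      transcripts$seq[tr] <- new_seq
      occupied[[length(occupied) + 1]] <- list(tr = tr, lo = pos,
                                               hi = pos + hlen - 1)
      s_off <- if (arm == "5p") mlen + nchar(loop) else 0L
      truth[[i]] <- tibble(
        precursor = sprintf("prec%03d", i),
        transcript = transcripts$name[tr],
        hp_start = pos, hp_end = pos + hlen - 1,
        mature = mature, m_start = pos + m_off,
        m_end = pos + m_off + mlen - 1,
        star = star, s_start = pos + s_off,
        s_end = pos + s_off + nchar(star) - 1,
        arm = arm, n_mismatch = n_mm,
        both_arms = stats::runif(1) < config$both_arm_fraction)
      planted <- TRUE
      break
    }
    if (!planted) {
      stop("could not plant a criteria-passing precursor after 40 attempts",
           call. = FALSE)
    }
  }
  list(transcripts = transcripts, precursor_truth = bind_rows(truth))
}

#' Plant miRNA target sites into transcripts
#'
#' Reverse-complement sites (optionally with a designed mismatch at a
#' designed miRNA position) inserted at recorded coordinates away from any
#' planted precursor; the designed expectation under the package's penalty
#' scheme is stored in the truth table.
#'
#' @param config a [sim_config()].
#' @param transcripts transcript tibble (after [simulate_precursors()]).
#' @param matures tibble with `name`, `seq` of miRNAs to target with.
#' @param precursor_truth precursor coordinates to avoid.
#' @param n_targets number of sites (default 8).
#' @param mismatch_positions pool of designed mismatch miRNA positions;
#'   each site draws 0 or 1 of them (default c(5, 10, 14)).
#' @return list: updated `transcripts`, `target_truth` (mirna, transcript,
#'   start, end, designed expectation and mode).
#' @export
plant_targets <- function(config, transcripts, matures, precursor_truth = NULL,
                          n_targets = 8, mismatch_positions = c(5, 10, 14)) {
  set.seed(derive_seed(config$seed, 3))
  truth <- list()
  occupied <- if (is.null(precursor_truth) || nrow(precursor_truth) == 0) {
    list()
  } else {
    purrr::pmap(precursor_truth[, c("transcript", "hp_start", "hp_end")],
                function(transcript, hp_start, hp_end) {
                  list(tr = transcript, lo = hp_start, hi = hp_end)
                })
  }
  for (i in seq_len(n_targets)) {
    mi <- sample(nrow(matures), 1)
    mature <- matures$seq[mi]
    site <- revcomp(mature)
    L <- nchar(site)
    mm_at <- if (stats::runif(1) < 0.5) integer(0)
             else sample(mismatch_positions, 1)
    if (length(mm_at) == 1) {
      j <- L - mm_at + 1  # site position facing miRNA position mm_at
      sc <- strsplit(site, "")[[1]]
      m_base <- strsplit(mature, "")[[1]][mm_at]
      opts <- setdiff(c("A", "C", "G", "T"), c(sc[j], wc_pairs[m_base]))
      opts <- opts[!((opts == "G" & m_base == "T") |
                       (opts == "T" & m_base == "G"))]
      sc[j] <- sample(opts, 1)
      site <- paste(sc, collapse = "")
    }
    repeat {
      tr <- sample(nrow(transcripts), 1)
      tlen <- nchar(transcripts$seq[tr])
      pos <- sample(30:(tlen - L - 30), 1)
      clash <- any(vapply(occupied, function(o) {
        o$tr == transcripts$name[tr] && pos <= o$hi + 5 && pos + L - 1 >= o$lo - 5
      }, logical(1)))
      if (!clash) break
    }
    occupied[[length(occupied) + 1]] <- list(tr = transcripts$name[tr],
                                             lo = pos, hi = pos + L - 1)
    tseq <- transcripts$seq[tr]
    transcripts$seq[tr] <- paste0(substr(tseq, 1, pos - 1), site,
                                  substr(tseq, pos + L, nchar(tseq)))
    dup <- score_duplex(mature, site)
    truth[[i]] <- tibble(
      mirna = matures$name[mi], mirna_seq = mature,
      transcript = transcripts$name[tr],
      start = pos, end = pos + L - 1,
      designed_mismatch_pos = if (length(mm_at) == 1) mm_at else NA_integer_,
      expectation = dup$expectation,
      mode = classify_mode(dup))
  }
  list(transcripts = transcripts, target_truth = bind_rows(truth))
}

#' Simulate the four stage libraries
#'
#' Builds the emission pool (conserved matures, novel matures/stars, decoy
#' ncRNA fragments, unannotated sequences), assigns each miRNA species an
#' archetype and a log-uniform base abundance, scales class masses to the
#' configured baseline proportions, and draws per-stage counts
#' multinomially at the configured depths. Truth TPMs are the expected
#' per-stage proportions times 1e6.
#'
#' @param config a [sim_config()].
#' @param catalogs output of [simulate_catalogs()].
#' @param precursors output of [simulate_precursors()] (or NULL for none).
#' @return list: `collapsed` (counts tibble as from [collapse_srna()]),
#'   `pool` (full truth: class, family, archetype, per-stage expected TPM
#'   and counts), `totals`.
#' @export
simulate_libraries <- function(config, catalogs, precursors = NULL) {
  set.seed(derive_seed(config$seed, 4))
  stages <- config$stages
  arch <- config$archetypes
  cat_list <- catalogs$catalogs

  draw_abund <- function(n) {
    10^stats::runif(n, config$abundance_log10_range[1],
                    config$abundance_log10_range[2])
  }
  frag_from <- function(refs, n, class) {
    idx <- sample(nrow(refs), n, replace = TRUE)
    lens <- sample(18:30, n, replace = TRUE)
    starts <- vapply(seq_len(n), function(i) {
      sample(nchar(refs$seq[idx[i]]) - lens[i] + 1, 1)
    }, integer(1))
    tibble(species = sprintf("%s_frag%03d", class, seq_len(n)),
           seq = substr(refs$seq[idx], starts, starts + lens - 1),
           class = class, family = NA_character_,
           archetype = NA_character_)
  }

  mt <- catalogs$mirna_truth
  arch_ids <- rownames(arch)
  assign_arch <- function(n) {
    sample(rep(arch_ids, length.out = max(n, length(arch_ids))))[seq_len(n)]
  }
  pool <- tibble(species = mt$name, seq = mt$seq, class = "miRNA",
                 family = mt$family, archetype = assign_arch(nrow(mt)))
  if (!is.null(precursors) && nrow(precursors$precursor_truth) > 0) {
    pt <- precursors$precursor_truth
    nov <- tibble(species = paste0(pt$precursor, "_mature"), seq = pt$mature,
                  class = "novel", family = NA_character_,
                  archetype = assign_arch(nrow(pt)))
    stars <- pt[pt$both_arms, , drop = FALSE]
    if (nrow(stars) > 0) {
      nov <- bind_rows(nov, tibble(
        species = paste0(stars$precursor, "_star"), seq = stars$star,
        class = "novel", family = NA_character_,
        archetype = assign_arch(nrow(stars))))
    }
    pool <- bind_rows(pool, nov)
  }
  pool <- bind_rows(
    pool,
    frag_from(cat_list$rRNA, 40, "rRNA"),
    frag_from(cat_list$tRNA, 30, "tRNA"),
    frag_from(cat_list$snRNA, 10, "snRNA"),
    frag_from(cat_list$snoRNA, 10, "snoRNA"),
    tibble(species = sprintf("unann_%03d", 1:60),
           seq = random_dna(60, sample(18:30, 60, replace = TRUE)),
           class = "unannotated", family = NA_character_,
           archetype = NA_character_)
  )
  pool <- pool[!duplicated(pool$seq), , drop = FALSE]
  # unannotated decoys must not collide with any catalog
  if (!is.null(cat_list$miRNA_mature)) {
    una <- which(pool$class == "unannotated")
    bad <- una[!is.na(match_mature(pool$seq[una],
                                   cat_list$miRNA_mature)$ref)]
    if (length(bad) > 0) pool <- pool[-bad, , drop = FALSE]
  }

  pool$base <- draw_abund(nrow(pool))
  # scale class masses to configured baseline proportions
  prop <- config$class_proportions
  cls_mass <- tapply(pool$base, pool$class, sum)
  for (cl in names(cls_mass)) {
    target <- if (cl %in% names(prop)) prop[[cl]] else 0.01
    pool$base[pool$class == cl] <-
      pool$base[pool$class == cl] * target / cls_mass[[cl]]
  }

  fac <- matrix(1, nrow(pool), length(stages),
                dimnames = list(NULL, stages))
  has_arch <- !is.na(pool$archetype)
  fac[has_arch, ] <- arch[pool$archetype[has_arch], , drop = FALSE]
  weights <- pool$base * fac
  props <- sweep(weights, 2, colSums(weights), "/")
  for (s in stages) {
    pool[[paste0("true_tpm_", s)]] <- props[, s] * 1e6
    pr <- props[, s]
    if (is.finite(config$overdispersion)) {
      g <- stats::rgamma(length(pr), shape = pr * config$overdispersion)
      pr <- g / sum(g)
    }
    pool[[s]] <- as.integer(rmultinom(1, config$library_sizes[[s]], pr))
  }
  collapsed <- pool[, c("seq", stages)]
  collapsed$length <- nchar(collapsed$seq)
  total <- rowSums(collapsed[, stages, drop = FALSE])
  keep <- total > 0
  collapsed <- collapsed[keep, c("seq", "length", stages)]
  collapsed <- collapsed[order(-total[keep], collapsed$seq), , drop = FALSE]
  list(collapsed = as_tibble(collapsed), pool = as_tibble(pool),
       totals = setNames(as.numeric(config$library_sizes), stages))
}

#' Run the whole generator
#'
#' Catalogs, transcripts with precursors and planted target sites, and the
#' four stage libraries, with every ground-truth table.
#'
#' @param config a [sim_config()].
#' @param n_targets planted target sites (default 8).
#' @return list: `config`, `catalogs`, `transcripts`, `collapsed`,
#'   `totals`, `truth` (list `mirna`, `pool`, `precursors`, `targets`).
#' @export
simulate_experiment <- function(config = sim_config(), n_targets = 8) {
  cats <- simulate_catalogs(config)
  prec <- simulate_precursors(config, cats$catalogs$miRNA_mature)
  tg <- plant_targets(config, prec$transcripts, cats$mirna_truth,
                      prec$precursor_truth, n_targets = n_targets)
  libs <- simulate_libraries(config, cats, prec)
  cats$catalogs$transcript_est <- tibble(name = tg$transcripts$name,
                                         seq = tg$transcripts$seq,
                                         category = "transcript_est")
  list(config = config,
       catalogs = cats$catalogs,
       transcripts = tg$transcripts,
       collapsed = libs$collapsed,
       totals = libs$totals,
       truth = list(mirna = cats$mirna_truth, pool = libs$pool,
                    precursors = prec$precursor_truth,
                    targets = tg$target_truth))
}

#' Emit raw read files for a simulated experiment
#'
#' Expands the per-stage counts into raw reads (insert plus 3' adapter,
#' truncated to `read_len`), applies length jitter (loss of the final
#' insert base with the configured probability), shuffles, and writes one
#' FASTA or FASTQ per stage. FASTQ qualities are constant high-quality
#' placeholders (error-model realism is out of the generator's scope).
#'
#' @param sim output of [simulate_experiment()].
#' @param dir output directory (created).
#' @param format `"fasta"` or `"fastq"`.
#' @param read_len emitted read length (default 36).
#' @param max_reads optional cap per stage (proportional thinning) to keep
#'   files desk-sized.
#' @return named vector of file paths.
#' @export
write_simulated_reads <- function(sim, dir, format = c("fasta", "fastq"),
                                  read_len = 36, max_reads = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(sim$config$seed, 5))
  cfg <- sim$config
  out <- character(0)
  for (s in cfg$stages) {
    counts <- sim$collapsed[[s]]
    if (!is.null(max_reads) && sum(counts) > max_reads) {
      counts <- as.integer(rmultinom(1, max_reads, counts / sum(counts)))
    }
    inserts <- rep(sim$collapsed$seq, counts)
    jit <- runif(length(inserts)) < cfg$jitter_prob
    inserts[jit] <- substr(inserts[jit], 1, nchar(inserts[jit]) - 1L)
    reads <- substr(paste0(inserts, cfg$adapter), 1, read_len)
    reads <- sample(reads)
    ids <- sprintf("%s_read%07d", s, seq_along(reads))
    path <- file.path(dir, paste0(s, ".", format))
    if (format == "fasta") {
      writeLines(as.vector(rbind(paste0(">", ids), reads)), path)
    } else {
      quals <- strrep("I", nchar(reads))
      writeLines(as.vector(rbind(paste0("@", ids), reads, "+", quals)), path)
    }
    out[s] <- path
  }
  out
}
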