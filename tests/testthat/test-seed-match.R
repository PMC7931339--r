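mir99a <- "AACCCGUAGAUCCGAUCUUGUG"  # mature miR-99a, seed ACCCGUA

test_that("seed extraction returns nucleotides 2-8 and checks bounds", {
  m <- mature_mirna("hsa-miR-99a", mir99a)
  expect_equal(extract_seed(m), "ACCCGUA")
  expect_equal(extract_seed(m, first = 1, last = 7), "AACCCGU")
  expect_error(extract_seed("ACGUACG", first = 2, last = 8), "length")
  expect_error(mature_mirna("short", "ACGUACGUACG"), ">= 16")
  expect_warning(mature_mirna("dna", "AACCCGTAGATCCGATCTTGTG"),
                 "auto-converted")
})

test_that("transcript region annotations are validated", {
  reg <- data.frame(label = c("5UTR", "CDS", "3UTR"),
                    start = c(1, 21, 61), end = c(20, 60, 100))
  tr <- transcript_regions("g1", paste(rep("ACGU", 25), collapse = ""), reg)
  expect_s3_class(tr, "transcript_regions")
  bad <- reg; bad$end[3] <- 200
  expect_error(transcript_regions("g1",
                                  paste(rep("ACGU", 25), collapse = ""),
                                  bad), "out of bounds")
  overlap <- reg; overlap$start[2] <- 15
  expect_error(transcript_regions("g1",
                                  paste(rep("ACGU", 25), collapse = ""),
                                  overlap), "overlapping")
})

make_tr <- function(seq) {
  L <- nchar(seq)
  transcript_regions("gX", seq, data.frame(
    label = c("5UTR", "CDS", "3UTR"),
    start = c(1, floor(L * 0.2) + 1, floor(L * 0.7) + 1),
    end = c(floor(L * 0.2), floor(L * 0.7), L)))
}

test_that("a planted exact site and its mutations are recovered", {
  set.seed(301)
  m <- mature_mirna("hsa-miR-99a", mir99a)
  # the reverse complement of seed ACCCGUA read 5'->3' is UACGGGU
  bg <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
              collapse = "")
  seq0 <- paste0(substr(bg, 1, 10), "UACGGGU", substr(bg, 18, 60))
  hits <- find_seed_sites(m, make_tr(seq0), max_mismatch = 0)
  planted <- hits[hits$start == 11, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$mismatches, 0)
  expect_equal(planted$end, 17)
  expect_equal(planted$site_seq, "UACGGGU")
  # one substitution in the window -> one mismatch
  seq1 <- paste0(substr(bg, 1, 10), "UACGAGU", substr(bg, 18, 60))
  hits1 <- find_seed_sites(m, make_tr(seq1), max_mismatch = 2)
  expect_equal(hits1$mismatches[hits1$start == 11], 1)
})

test_that("site lists equal the exhaustive window-scan oracle", {
  set.seed(302)
  m <- mature_mirna("hsa-miR-99a", mir99a)
  for (rep_i in 1:25) {
    L <- sample(60:400, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                 collapse = "")
    tr <- make_tr(seq)
    for (mm in 0:2) {
      for (wob in c(FALSE, TRUE)) {
        got <- find_seed_sites(m, tr, max_mismatch = mm,
                               allow_wobble = wob)
        want <- oracle_seed_scan(mir99a, seq, mm, allow_wobble = wob)
        expect_identical(got$start, as.integer(want$start))
        expect_identical(got$mismatches, as.integer(want$mm))
      }
    }
  }
})

test_that("mismatch-k sites are a subset of mismatch-(k+1) sites", {
  set.seed(303)
  m <- mature_mirna("hsa-miR-99a", mir99a)
  seq <- paste(sample(c("A", "C", "G", "U"), 500, replace = TRUE),
               collapse = "")
  tr <- make_tr(seq)
  s0 <- find_seed_sites(m, tr, max_mismatch = 0)$start
  s1 <- find_seed_sites(m, tr, max_mismatch = 1)$start
  s2 <- find_seed_sites(m, tr, max_mismatch = 2)$start
  expect_true(all(s0 %in% s1))
  expect_true(all(s1 %in% s2))
})

test_that("duplex symmetry: revcomp of both strands preserves mismatches", {
  set.seed(304)
  revcomp <- function(s) {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  for (i in 1:10) {
    mseq <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                  collapse = "")
    tseq <- paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE),
                  collapse = "")
    m <- mature_mirna("m", mseq)
    a <- find_seed_sites(m, make_tr(tseq), max_mismatch = 2)
    # in the flipped duplex the seed (mirna nt 2-8) occupies positions
    # L-7..L-1 of the revcomped mirna; scan with an equivalent query whose
    # nt 2-8 equal revcomp of the original window positions
    L <- nchar(tseq)
    tflip <- revcomp(tseq)
    sflip <- revcomp(extract_seed(m))
    query <- mature_mirna("q", paste0("A", sflip, "AAAAAAAAAAAAAA"))
    b <- find_seed_sites(query, make_tr(tflip), max_mismatch = 2)
    # window [s, s+6] on the original maps to [L-s-5, L-s+1] on the flip
    expect_setequal(paste(L - a$start - 5, a$mismatches),
                    paste(b$start, b$mismatches))
  }
})

test_that("3'-supplementary score counts pairs at the anchored offset", {
  m <- mature_mirna("hsa-miR-99a", mir99a)  # nt 13-16 = C,G,A,U
  # build a transcript where the 4 bases opposing nt 13-16 are their
  # complements: opposing position for mirna nt p is end + 2 - p
  site_start <- 31; site_end <- 37
  base <- rep("A", 80)
  base[site_start:site_end] <- strsplit("UACGGGU", "")[[1]]
  # p = 13..16 -> tpos = 26..23; complements of C,G,A,U are G,C,U,A
  base[26] <- "G"; base[25] <- "C"; base[24] <- "U"; base[23] <- "A"
  tr <- make_tr(paste(base, collapse = ""))
  site <- find_seed_sites(m, tr, max_mismatch = 0)
  site <- site[site$start == site_start, ]
  expect_equal(site$supplementary_score, 4L)
  # all-A target opposite an all-A window scores 0
  m2 <- mature_mirna("allA", "GGGGGGGGGGGGAAAAGGGG")
  tr2 <- make_tr(paste(rep("A", 80), collapse = ""))
  expect_equal(score_3prime_supplementary(m2, tr2, list(end = 40)), 0L)
  # brute-force equality on random cases
  set.seed(305)
  for (i in 1:20) {
    mseq <- paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
                  collapse = "")
    tseq <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
                  collapse = "")
    mm <- mature_mirna("m", mseq)
    trr <- make_tr(tseq)
    end <- sample(20:50, 1)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    manual <- sum(vapply(13:16, function(p) {
      tpos <- end + 2 - p
      comp[[substr(mseq, p, p)]] == substr(tseq, tpos, tpos)
    }, logical(1)))
    expect_equal(score_3prime_supplementary(mm, trr, list(end = end)),
                 as.integer(manual))
  }
  expect_error(
    score_3prime_supplementary(m, tr, list(end = 40), window = 13:30),
    "beyond miRNA length")
})

test_that("alignments are deterministic with asterisks at paired bases", {
  m <- mature_mirna("hsa-miR-99a", mir99a)
  set.seed(306)
  bg <- paste(sample(c("A", "C", "G", "U"), 80, replace = TRUE),
              collapse = "")
  seq0 <- paste0(substr(bg, 1, 30), "UACGGGU", substr(bg, 38, 80))
  tr <- make_tr(seq0)
  site <- find_seed_sites(m, tr, max_mismatch = 0)
  site <- site[site$start == 31, ]
  a1 <- render_alignment(m, tr, site)
  expect_identical(a1, render_alignment(m, tr, site))
  lines <- strsplit(a1, "\n")[[1]]
  # the seed columns (carets in line 4) all carry asterisks for a
  # 0-mismatch site
  stars <- strsplit(lines[2], "")[[1]]
  carets <- strsplit(lines[4], "")[[1]]
  expect_equal(sum(carets == "^"), 7)
  expect_true(all(stars[carets == "^"] == "*"))
  # a 2-mismatch site shows exactly 5 asterisks over the seed span
  seq2 <- paste0(substr(bg, 1, 30), "UAAGGGA", substr(bg, 38, 80))
  tr2 <- make_tr(seq2)
  site2 <- find_seed_sites(m, tr2, max_mismatch = 2)
  site2 <- site2[site2$start == 31, ]
  expect_equal(site2$mismatches, 2L)
  l2 <- strsplit(render_alignment(m, tr2, site2), "\n")[[1]]
  stars2 <- strsplit(l2[2], "")[[1]]
  expect_equal(sum(stars2[carets == "^"] == "*"), 5)
})

test_that("site position relative to the 3'UTR matches direct arithmetic", {
  seq <- paste(rep("ACGU", 75), collapse = "")  # 300 nt
  tr <- transcript_regions("g", seq, data.frame(
    label = c("5UTR", "CDS", "3UTR"), start = c(1, 51, 199),
    end = c(50, 198, 300)))
  # site ending at 100, 3'UTR starting at 199: 98 nt upstream gap
  expect_equal(annotate_site_position(list(start = 94, end = 100), tr),
               list(region = "CDS", distance_to_3utr = 98))
  expect_equal(
    annotate_site_position(list(start = 210, end = 216), tr)$distance_to_3utr,
    0)
  # no 3'UTR annotated: distance undefined, not an error
  tr2 <- transcript_regions("g2", seq, data.frame(
    label = c("5UTR", "CDS"), start = c(1, 51), end = c(50, 300)))
  res <- annotate_site_position(list(start = 94, end = 100), tr2)
  expect_true(is.na(res$distance_to_3utr))
  # randomized agreement with coordinate arithmetic
  set.seed(307)
  for (i in 1:20) {
    s <- sample(1:280, 1)
    got <- annotate_site_position(list(start = s, end = s + 6), tr)
    want <- if (s + 6 < 199) 199 - 1 - (s + 6) else 0
    expect_equal(got$distance_to_3utr, want)
  }
})

test_that("FASTA and region-table IO round-trips through Biostrings", {
  set.seed(308)
  m <- mature_mirna("hsa-miR-99a", mir99a)
  sim <- simulate_transcripts(n_genes = 3, length_range = c(100, 200),
                              mirnas = list(`hsa-miR-99a` = m),
                              plant_spec = data.frame(
                                gene = 1, mirna_id = "hsa-miR-99a",
                                mismatches = 0), seed = 5)
  fa <- tempfile(fileext = ".fa"); rg <- tempfile(fileext = ".tsv")
  write_transcripts(sim$transcripts, fa, rg)
  back <- read_transcripts(fa, rg)
  expect_equal(names(back), names(sim$transcripts))
  expect_equal(back$gene_001$sequence, sim$transcripts$gene_001$sequence)
  expect_equal(back$gene_002$regions, sim$transcripts$gene_002$regions,
               ignore_attr = TRUE)
  # miRNA FASTA reader transcribes DNA with a warning
  mf <- tempfile(fileext = ".fa")
  writeLines(c(">hsa-miR-99a", "AACCCGTAGATCCGATCTTGTG"), mf)
  expect_warning(mir <- read_mirna_fasta(mf), "auto-converted")
  expect_equal(mir$`hsa-miR-99a`$sequence, mir99a)
})
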