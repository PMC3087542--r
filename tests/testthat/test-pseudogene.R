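test_that("a sequence screened against itself is a perfect match", {
  s <- gen_codon_seq(100, bias = 0.3, seed = 8)
  rep <- pairwise_screen(s, s)
  expect_equal(rep$identity, 100)
  expect_identical(rep$indel_events, 0L)
  expect_identical(rep$internal_stops, 0L)
  expect_true(rep$start_present)
  expect_true(rep$stop_present)
})

test_that("an internal stop codon mutation is counted in the projected frame", {
  s <- gen_codon_seq(100, bias = 0.3, seed = 9)
  q <- paste0(substr(s, 1, 150), "TAA", substr(s, 154, nchar(s)))
  rep <- pairwise_screen(q, s)
  expect_identical(rep$internal_stops, 1L)
  # degrading the start codon flips the start flag
  q2 <- paste0("ACG", substr(s, 4, nchar(s)))
  expect_false(pairwise_screen(q2, s)$start_present)
})

test_that("indel events equal the brute-force count of maximal gap runs", {
  # statistics on fixed alignments: no re-alignment happens
  set.seed(12)
  for (case in 1:20) {
    n <- 60
    q <- strsplit(random_dna_str(n), "")[[1]]
    r <- strsplit(random_dna_str(n), "")[[1]]
    # punch non-overlapping gap runs into either row (never both at one column)
    for (g in seq_len(sample(0:4, 1))) {
      w <- sample(1:5, 1)
      st <- sample(n - w, 1)
      row <- sample(2, 1)
      if (row == 1) q[st:(st + w - 1)] <- "-" else r[st:(st + w - 1)] <- "-"
    }
    both <- which(q == "-" & r == "-")
    if (length(both)) r[both] <- "A"
    qs <- paste(q, collapse = ""); rs <- paste(r, collapse = "")
    rpad <- (3 - sum(r != "-") %% 3) %% 3  # keep the reference frame intact
    qs <- paste0(qs, strrep("A", rpad)); rs <- paste0(rs, strrep("A", rpad))
    rep <- pairwise_screen(NULL, NULL, alignment = c(qs, rs))
    expect_identical(rep$indel_events, bf_gap_runs(qs, rs))
    expect_identical(rep$alignment_length, nchar(qs))
  }
})

test_that("pairwise alignment files in aligned FASTA and CLUSTAL dialects read back", {
  qa <- "ATG--AAACCC"
  ra <- "ATGGGAAACCC"
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">query", qa, ">ref", ra), fa)
  rows <- read_pairwise_alignment(fa)
  expect_identical(unname(rows), c(qa, ra))
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               sprintf("query           %s", substr(qa, 1, 6)),
               sprintf("ref             %s", substr(ra, 1, 6)),
               "                ***   ", "",
               sprintf("query           %s", substr(qa, 7, 11)),
               sprintf("ref             %s", substr(ra, 7, 11))), cl)
  rows2 <- read_pairwise_alignment(cl)
  expect_identical(unname(rows2), c(qa, ra))
  expect_error(read_pairwise_alignment(write_lines_tmp(c(">a", "ACGT"))), "expected 2")
})

test_that("edit hints flag undetermined starts/stops and internal stops", {
  mk <- function(cds) {
    plastome_record("x", paste0(cds, "ACGTACGT"),
                    features = list(gene_feature("rps11", 1L, c(0, nchar(cds)), kind = "CDS")))
  }
  h1 <- edit_hint_scan(mk("ACGAAATAA"))$hints
  expect_identical(h1$kind, "undetermined-start")
  expect_identical(h1$position, 1L)
  expect_identical(nrow(edit_hint_scan(mk("ATGAAATAA"))$hints), 0L)
  h3 <- edit_hint_scan(mk("ATGTAAAAACAC"))$hints
  expect_setequal(h3$kind, c("internal-stop", "undetermined-stop"))
  # pseudogenes are not scanned, and GTG passes when accepted
  rec <- mk("GTGAAATAA")
  expect_identical(nrow(edit_hint_scan(rec, starts = c("ATG", "GTG"))$hints), 0L)
  rec$features[[1]]$pseudo <- TRUE
  expect_identical(edit_hint_scan(rec)$summary$genes_scanned, 0L)
})

test_that("planted non-canonical starts are recovered exactly from a generated genome", {
  set.seed(31)
  genes <- lapply(1:6, function(i) gen_codon_seq(60, bias = 0.2, seed = 40 + i))
  edited <- c(2, 5)
  for (i in edited) genes[[i]] <- paste0("ACG", substr(genes[[i]], 4, nchar(genes[[i]])))
  spacer <- random_dna_str(40)
  seqn <- paste0(spacer, paste(unlist(genes), collapse = spacer), spacer)
  feats <- list(); pos <- nchar(spacer)
  for (i in seq_along(genes)) {
    feats[[i]] <- gene_feature(paste0("orf", i), 1L, c(pos, pos + nchar(genes[[i]])), kind = "CDS")
    pos <- pos + nchar(genes[[i]]) + nchar(spacer)
  }
  rec <- plastome_record("p", seqn, features = feats)
  hints <- edit_hint_scan(rec)$hints
  expect_setequal(hints$gene[hints$kind == "undetermined-start"],
                  paste0("orf", edited))
  expect_identical(nrow(hints[hints$kind != "undetermined-start", ]), 0L)
})

test_that("ORF finding recovers planted frames and respects strand flags", {
  set.seed(33)
  orf <- gen_codon_seq(150, bias = 0, seed = 12)      # 450 nt ATG...TAA
  flank <- paste(rep("TAA", 12), collapse = "")
  region <- paste0(flank, orf, flank)
  hits <- find_orfs(region, min_length = 300, both_strands = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, nchar(flank))
  expect_identical(hits$end, nchar(flank) + nchar(orf))
  expect_identical(hits$length, nchar(orf))

  expect_identical(nrow(find_orfs(strrep("TAA", 40), min_length = 30)), 0L)

  rev_region <- revcomp(region)
  expect_identical(nrow(find_orfs(rev_region, min_length = 300, both_strands = FALSE)), 0L)
  rhits <- find_orfs(rev_region, min_length = 300, both_strands = TRUE)
  expect_identical(nrow(rhits), 1L)
  expect_identical(rhits$strand, -1L)
  expect_identical(rhits$end - rhits$start, nchar(orf))
})
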