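test_that("GenBank features parse with 1-based inclusive -> 0-based half-open conversion", {
  set.seed(42)
  seqn <- random_dna_str(200)
  path <- write_lines_tmp(make_genbank_text("FIX1", seqn,
    gb_feature_lines("gene", "10..60", "psbA")), ext = ".gb")
  rec <- read_plastome_flatfile(path)
  expect_s3_class(rec, "plastome_record")
  expect_identical(rec$identifier, "FIX1")
  expect_identical(rec$sequence, seqn)
  expect_true(rec$circular)
  expect_length(rec$features, 1L)
  f <- rec$features[[1]]
  expect_identical(f$name, "psbA")
  expect_identical(f$strand, 1L)
  expect_identical(f$intervals, matrix(c(9L, 60L), ncol = 2))
})

test_that("origin-spanning complement(join()) becomes a wrapping minus-strand feature", {
  set.seed(43)
  seqn <- random_dna_str(200)
  path <- write_lines_tmp(make_genbank_text("FIX2", seqn,
    gb_feature_lines("CDS", "complement(join(181..200,1..20))", "ycf2")), ext = ".gb")
  rec <- read_plastome_flatfile(path)
  f <- rec$features[[1]]
  expect_identical(f$strand, -1L)
  expect_identical(nrow(f$intervals), 2L)
  expect_identical(sum(f$intervals[, 2] - f$intervals[, 1]), 40L)
  # spliced sequence equals the reverse complement of the circular span
  span <- paste0(substr(seqn, 181, 200), substr(seqn, 1, 20))
  expect_identical(feature_seq(rec, 1), revcomp(span))
})

test_that("GenBank parse and integrity errors are reported", {
  set.seed(44)
  seqn <- random_dna_str(100)
  out_of_range <- write_lines_tmp(make_genbank_text("BAD1", seqn,
    gb_feature_lines("gene", "50..150", "psbA")), ext = ".gb")
  expect_error(read_plastome_flatfile(out_of_range), "outside sequence")
  no_origin <- write_lines_tmp(c("LOCUS       X 10 bp DNA circular", "//"), ext = ".gb")
  expect_error(read_plastome_flatfile(no_origin), "ORIGIN")
  bad_loc <- write_lines_tmp(make_genbank_text("BAD2", seqn,
    gb_feature_lines("gene", "10..x", "psbA")), ext = ".gb")
  expect_error(read_plastome_flatfile(bad_loc), "parse failure")
})

test_that("pseudo qualifier and /gene merging behave", {
  set.seed(45)
  seqn <- random_dna_str(300)
  lines <- c(gb_feature_lines("gene", "10..90", "rps16", pseudo = TRUE),
             gb_feature_lines("gene", "101..200", "matK"),
             gb_feature_lines("CDS", "101..200", "matK"))
  rec <- read_plastome_flatfile(write_lines_tmp(make_genbank_text("FIX3", seqn, lines), ".gb"))
  nms <- vapply(rec$features, function(f) f$name, character(1))
  expect_setequal(nms, c("rps16", "matK"))
  expect_true(rec$features[[which(nms == "rps16")]]$pseudo)
  expect_identical(rec$features[[which(nms == "matK")]]$kind, "CDS")
})

test_that("interleaved NEXUS blocks concatenate and EXSET converts to 0-based columns", {
  lines <- c("#NEXUS",
             "BEGIN DATA;",
             "  DIMENSIONS NTAX=3 NCHAR=12;",
             "  FORMAT DATATYPE=DNA MISSING=? GAP=- INTERLEAVE;",
             "  MATRIX",
             "  A  ACGTAC",
             "  B  ACGTAC",
             "  C  ACCTAC",
             "",
             "  A  GGGTTT",
             "  B  GGCTTT",
             "  C  GGGTTT",
             "  ;",
             "END;",
             "BEGIN ASSUMPTIONS;",
             "  EXSET * untrustworthy = 4-6;",
             "END;")
  aln <- read_alignment_nexus(write_lines_tmp(lines, ".nex"))
  expect_identical(aln$ncol, 12L)
  expect_identical(aln$taxa, c("A", "B", "C"))
  expect_identical(unname(aln$rows["A"]), "ACGTACGGGTTT")
  expect_identical(aln$excluded, c(3L, 4L, 5L))
})

test_that("CHARSET partitions are recorded and malformed matrices error", {
  lines <- c("#NEXUS", "BEGIN DATA;",
             "  DIMENSIONS NTAX=2 NCHAR=6;",
             "  FORMAT DATATYPE=DNA;",
             "  MATRIX",
             "  A  ACGTAA", "  B  ACGTTT", "  ;", "END;",
             "BEGIN SETS;",
             "  CHARSET psbA = 1-3;",
             "  CHARSET rbcL = 4-6;",
             "END;")
  aln <- read_alignment_nexus(write_lines_tmp(lines, ".nex"))
  expect_named(aln$partitions, c("psbA", "rbcL"))
  expect_identical(aln$partitions$psbA, 0:2)

  dup <- c("#NEXUS", "BEGIN DATA;", "  DIMENSIONS NTAX=2 NCHAR=3;",
           "  FORMAT DATATYPE=DNA;", "  MATRIX",
           "  A  ACG", "  A  ACG", "  ;", "END;")
  expect_error(read_alignment_nexus(write_lines_tmp(dup, ".nex")), "duplicate taxon")

  ragged <- c("#NEXUS", "BEGIN DATA;", "  DIMENSIONS NTAX=2 NCHAR=4;",
              "  FORMAT DATATYPE=DNA;", "  MATRIX",
              "  A  ACGT", "  B  ACG", "  ;", "END;")
  expect_error(read_alignment_nexus(write_lines_tmp(ragged, ".nex")), "NCHAR|ragged")
})

test_that("Newick reading preserves topology, polytomies, and rejects malformed input", {
  tr <- read_tree_newick("((A,B),(C,D));")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  parts <- ape::prop.part(tr)
  sets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(sets, function(s) identical(s, c("A", "B")), logical(1))) ||
                any(vapply(sets, function(s) identical(s, c("C", "D")), logical(1))))
  star <- read_tree_newick("(A,B,C);")
  expect_identical(star$Nnode, 1L)
  expect_error(read_tree_newick("((A,B),(C,D)"), "parse error")
  expect_error(read_tree_newick("((A,B),(A,D));"), "duplicate")
})

test_that("binary matrix NEXUS round-trip is the identity", {
  m <- binary_matrix(matrix(c("1", "0", "0", "1"), nrow = 2,
                            dimnames = list(c("tA", "tB"), c("rbcL_12", "psbA_3"))))
  path <- tempfile(fileext = ".nex")
  write_binary_matrix_nexus(m, path)
  txt <- readLines(path)
  expect_true(any(grepl("CHARSTATELABELS", txt)))
  expect_true(any(grepl("SYMBOLS=\"01\"", txt)))
  m2 <- read_binary_matrix_nexus(path)
  expect_identical(m2$taxa, m$taxa)
  expect_identical(m2$characters, m$characters)
  expect_identical(m2$cells, m$cells)

  # degenerate: zero characters
  empty <- binary_matrix(matrix(character(0), nrow = 2, ncol = 0,
                                dimnames = list(c("tA", "tB"), NULL)))
  p2 <- tempfile(fileext = ".nex")
  write_binary_matrix_nexus(empty, p2)
  e2 <- read_binary_matrix_nexus(p2)
  expect_identical(length(e2$characters), 0L)
  expect_identical(e2$taxa, c("tA", "tB"))

  # a matrix the size of a real indel data set, with missing data
  big <- random_binary_matrix(43, 152, seed = 7)
  p3 <- tempfile(fileext = ".nex")
  write_binary_matrix_nexus(big, p3)
  b2 <- read_binary_matrix_nexus(p3)
  expect_identical(b2$cells, big$cells)
  expect_length(b2$characters, 152L)
})

test_that("spliced feature length equals the sum of interval lengths", {
  g <- gen_plastome(900, 400, 250, n_genes = 8, seed = 21)
  for (i in seq_along(g$record$features)) {
    f <- g$record$features[[i]]
    expect_identical(nchar(feature_seq(g$record, f)),
                     as.integer(sum(f$intervals[, 2] - f$intervals[, 1])))
  }
})

test_that("rotating a circular record maps features consistently", {
  g <- gen_plastome(900, 400, 250, n_genes = 6, seed = 22)
  rec <- g$record
  n <- nchar(rec$sequence)
  for (k in c(1L, 137L, n - 5L)) {
    rot <- rotate_record(rec, k)
    expect_identical(nchar(rot$sequence), n)
    # spliced gene sequences are invariant under rotation
    s1 <- sort(vapply(seq_along(rec$features), function(i) feature_seq(rec, i), character(1)))
    s2 <- sort(vapply(seq_along(rot$features), function(i) feature_seq(rot, i), character(1)))
    expect_identical(s1, s2)
    # and starts shift by -k modulo n
    st1 <- sort((vapply(rec$features, function(f) f$intervals[1, 1], integer(1)) - k) %% n)
    st2 <- sort(vapply(rot$features, function(f) f$intervals[1, 1], integer(1)))
    expect_identical(st1, st2)
  }
})

test_that("gene symbols normalize into one symbol space", {
  expect_identical(normalize_gene_name(c("PSBA", "psba", "psbA")), rep("psbA", 3))
  expect_identical(normalize_gene_name("RPOC1"), "rpoC1")
  expect_identical(normalize_gene_name("trni-cau"), "trnI-CAU")
  expect_identical(normalize_gene_name("TRNFM-CAT"), "trnfM-CAU")
  expect_identical(normalize_gene_name("trnS-CGA"), "trnS-CGA")
  expect_identical(normalize_gene_name("rrn16S"), "rrn16")
  expect_identical(normalize_gene_name(c("ycf2", "MATK", "rps7")),
                   c("ycf2", "matK", "rps7"))
})

test_that("ambiguity codes other than N are mapped to N with a warning", {
  expect_warning(rec <- plastome_record("amb", "ACGTRYACGT"), "ambiguity")
  expect_identical(rec$sequence, "ACGTNNACGT")
  expect_error(plastome_record("bad", "ACGT!!"), "non-nucleotide")
})
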