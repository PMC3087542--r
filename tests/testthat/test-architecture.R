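test_that("a constructed circle X + R + Y + revcomp(R) is partitioned correctly", {
  set.seed(101)
  repeat {
    X <- random_dna_str(100); R <- random_dna_str(30); Y <- random_dna_str(40)
    circ <- paste0(X, R, Y, revcomp(R))
    if (bf_max_ir_length(circ, 10) == 30L) break  # R must be the unique maximal IR
  }
  st <- detect_inverted_repeat(plastome_record("toy", circ), min_length = 10)
  expect_identical(st$ir_length, 30L)
  expect_identical(st$lsc_length, 100L)
  expect_identical(st$ssc_length, 40L)
  expect_identical(st$ira$start, 100L)
  expect_identical(st$irb$start, 170L)
  expect_true(valid_ir_pair(circ, st))
})

test_that("repeat-free circles yield no structure and linear records error", {
  set.seed(102)
  # an exact 50 bp inverted repeat arising by chance in 1 kb is vanishingly rare
  s <- random_dna_str(1000)
  expect_null(detect_inverted_repeat(plastome_record("r", s), min_length = 50))
  lin <- plastome_record("lin", "ACGTACGTACGT", circular = FALSE)
  expect_error(detect_inverted_repeat(lin, 2), "circular")
})

test_that("detection agrees with the exhaustive all-pairs oracle on small circles", {
  set.seed(103)
  for (case in 1:6) {
    n <- sample(140:200, 1)
    s <- if (case %% 2 == 0) {
      # plant a small IR
      irl <- sample(12:25, 1)
      core <- random_dna_str(n - 2L * irl - 20L)
      ir <- random_dna_str(irl)
      paste0(core, ir, random_dna_str(20), revcomp(ir))
    } else random_dna_str(n)
    minl <- 8L
    oracle <- bf_max_ir_length(s, minl)
    st <- detect_inverted_repeat(plastome_record("c", s), min_length = minl)
    if (oracle == 0L) {
      expect_null(st)
    } else {
      expect_identical(st$ir_length, as.integer(oracle))
      expect_true(valid_ir_pair(s, st))
    }
  }
})

test_that("detected structures tile the circle and are rotation invariant", {
  for (s in 1:15) {
    g <- gen_plastome(800, 300, 200, n_genes = 0, seed = 300 + s)
    st <- detect_inverted_repeat(g$record, min_length = 50)
    expect_identical(st$lsc_length + st$ssc_length + 2L * st$ir_length,
                     st$total_length)
    expect_identical(st$ira$start, g$truth$regions$ira$start)
    expect_identical(st$irb$start, g$truth$regions$irb$start)
    expect_identical(st$ir_length, g$truth$regions$ira$length)
  }
  # rotation invariance: structure on the rotated circle maps back
  g <- gen_plastome(800, 300, 200, n_genes = 0, seed = 400)
  n <- nchar(g$record$sequence)
  st0 <- detect_inverted_repeat(g$record, min_length = 50)
  for (k in c(37L, 800L, 1499L)) {
    rot <- rotate_record(g$record, k)
    st <- detect_inverted_repeat(rot, min_length = 50)
    expect_identical(st$ir_length, st0$ir_length)
    expect_identical((st$ira$start + k) %% n, st0$ira$start)
    expect_identical((st$lsc$start + k) %% n, st0$lsc$start)
  }
})

test_that("region stats satisfy the length identity and composition bounds", {
  g <- gen_plastome(900, 400, 250, n_genes = 0, seed = 77, gc_target = 0.4)
  st <- detect_inverted_repeat(g$record, min_length = 50)
  rs <- region_stats(g$record, st)
  expect_identical(rs$length[rs$region == "total"],
                   sum(rs$length[rs$region %in% c("LSC", "SSC")]) +
                     2L * rs$length[rs$region == "IR"])
  expect_true(all(rs$gc >= 0 & rs$gc <= 1))
  expect_equal(rs$gc[rs$region == "total"], 0.4, tolerance = 0.025)

  # all-G circle: G/C is exactly 1 in every region (any split tiles it)
  allg <- plastome_record("g", strrep("G", 400))
  stg <- quadripartite_structure(lsc = list(start = 0L, length = 200L),
                                 ira = list(start = 200L, length = 50L),
                                 ssc = list(start = 250L, length = 100L),
                                 irb = list(start = 350L, length = 50L),
                                 total_length = 400L)
  rsg <- region_stats(allg, stg)
  expect_true(all(rsg$gc == 1))
})

test_that("genes classify by region, IR duplicates get copy count 2, straddlers are IR-partial", {
  g <- gen_plastome(1000, 400, 300, n_genes = 10, seed = 55)
  st <- detect_inverted_repeat(g$record, min_length = 50)
  rec <- g$record
  # add a gene straddling the SSC/IRB junction (IRB starts at 1700)
  rec$features <- c(rec$features,
                    list(gene_feature("ndhF", 1L, c(st$irb$start - 40L, st$irb$start + 40L),
                                      kind = "CDS")))
  cls <- classify_gene_regions(rec, st)
  asg <- cls$assignments
  expect_identical(nrow(asg), length(rec$features))
  expect_identical(asg$region[asg$gene == "ndhF"], "IR-partial(SSC)")
  ir_genes <- asg[asg$region == "IR", ]
  if (nrow(ir_genes)) {
    dup <- table(ir_genes$gene)
    expect_true(all(asg$copies[asg$gene %in% names(dup[dup == 2])] == 2L))
  }
  # the straddler appears as spanning in the SSC-IRB junction table
  j <- cls$junctions
  expect_true(any(j$junction == "SSC-IRB" & j$gene == "ndhF" & j$side == "spanning" & j$partial))
  expect_setequal(unique(j$junction), c("LSC-IRA", "IRA-SSC", "SSC-IRB", "IRB-LSC"))
})

test_that("gene content diff finds unique genes, pseudo, intron and copy differences", {
  set.seed(66)
  s <- random_dna_str(2000)
  mk <- function(id, feats) plastome_record(id, s, features = feats)
  a <- mk("A", list(
    gene_feature("trnS-CGA", 1L, c(10, 90), kind = "tRNA"),
    gene_feature("clpP", 1L, matrix(c(100, 200, 300, 400), ncol = 2, byrow = TRUE), kind = "CDS"),
    gene_feature("rps7", 1L, c(500, 650), kind = "CDS"),
    gene_feature("ycf66", 1L, c(700, 850), kind = "CDS", pseudo = TRUE)))
  b <- mk("B", list(
    gene_feature("clpP", 1L, matrix(c(100, 200, 250, 300, 350, 400), ncol = 2, byrow = TRUE),
                 kind = "CDS"),
    gene_feature("rps7", 1L, c(500, 650), kind = "CDS"),
    gene_feature("rps7", -1L, c(900, 1050), kind = "CDS"),
    gene_feature("ycf66", 1L, c(700, 850), kind = "CDS"),
    gene_feature("tufA", 1L, c(1100, 1250), kind = "CDS", pseudo = TRUE)))
  d <- gene_content_diff(a, b)
  expect_identical(d$only_in_a, "trnS-CGA")
  expect_identical(d$only_in_b, "tufA")
  expect_identical(d$intron_diff$gene, "clpP")
  expect_identical(d$intron_diff$introns_a, 1L)
  expect_identical(d$intron_diff$introns_b, 2L)
  expect_identical(d$copy_diff$gene, "rps7")
  expect_identical(d$copy_diff$copies_b, 2L)
  expect_identical(d$pseudo_diff$gene, "ycf66")
  expect_identical(d$pseudo_diff$pseudo_in, "A")

  # identical records diff to nothing
  d0 <- gene_content_diff(a, a)
  expect_length(d0$only_in_a, 0L)
  expect_length(d0$only_in_b, 0L)
  expect_identical(nrow(d0$pseudo_diff) + nrow(d0$intron_diff) + nrow(d0$copy_diff), 0L)
})
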