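test_that("a single shared gap codes one character with 1/0 states", {
  aln <- plastome_alignment(c(A = "ATGACG", B = "ATG---", C = "ATGACG"))
  # B's gap is terminal (trailing), so it is missing data, not an indel
  coded <- code_indels(aln)
  expect_identical(length(coded$matrix$characters), 0L)

  aln2 <- plastome_alignment(c(A = "ATGACGT", B = "ATG---T", C = "ATGACGT"))
  coded2 <- code_indels(aln2)
  expect_identical(length(coded2$matrix$characters), 1L)
  expect_identical(coded2$characters$start, 3L)
  expect_identical(coded2$characters$end, 6L)
  expect_identical(unname(coded2$matrix$cells[, 1]), c("1", "0", "1"))
})

test_that("nested gaps follow simple indel coding: containment scores ?", {
  aln <- plastome_alignment(c(A = "ATGACGTT", B = "ATG---TT", C = "A------T"))
  coded <- code_indels(aln)
  chars <- coded$characters
  expect_identical(nrow(chars), 2L)
  # span [1,7): A=1, B=? (B has bases at 1,2,6 but gaps inside), C=0
  wide <- which(chars$start == 1L & chars$end == 7L)
  expect_identical(unname(coded$matrix$cells[, wide]), c("1", "?", "0"))
  # span [3,6): A=1, B=0, C=? (C's gap strictly contains it)
  narrow <- which(chars$start == 3L & chars$end == 6L)
  expect_identical(unname(coded$matrix$cells[, narrow]), c("1", "0", "?"))
})

test_that("excluded columns yield no characters and gap-free alignments code empty", {
  aln <- plastome_alignment(c(A = "ATGACGTT", B = "ATG---TT"), excluded = 3:5)
  expect_identical(length(code_indels(aln)$matrix$characters), 0L)
  expect_identical(length(code_indels(aln, use_exclusions = FALSE)$matrix$characters), 1L)
  nogap <- plastome_alignment(c(A = "ACGT", B = "ACGT"))
  expect_identical(length(code_indels(nogap)$matrix$characters), 0L)
})

test_that("leading and trailing terminal gaps are missing data", {
  aln <- plastome_alignment(c(A = "--GACGTA", B = "ATG---TA", C = "ATGACGTA"))
  coded <- code_indels(aln)
  # only B's internal gap is a character; A's leading gap is not scored
  expect_identical(nrow(coded$characters), 1L)
  expect_identical(coded$characters$start, 3L)
})

test_that("coding is insensitive to taxon order and to appended invariant columns", {
  rows <- c(A = "ATGACGTT", B = "ATG---TT", C = "A------T")
  c1 <- code_indels(plastome_alignment(rows))
  c2 <- code_indels(plastome_alignment(rows[c(3, 1, 2)]))
  expect_identical(c1$matrix$cells[sort(names(rows)), ],
                   c2$matrix$cells[sort(names(rows)), ])
  c3 <- code_indels(plastome_alignment(paste0(rows, "ACGT") |> stats::setNames(names(rows))))
  expect_identical(unname(c1$matrix$cells), unname(c3$matrix$cells))
  expect_identical(c1$characters$start, c3$characters$start)
})

test_that("character labels carry the gene partition and 1-based in-gene position", {
  rows <- c(A = "AAATTTGGGCCC", B = "AAA---GGGCCC")
  aln <- plastome_alignment(rows, partitions = list(atpA = 0:5, atpB = 6:11))
  coded <- code_indels(aln)
  expect_identical(coded$characters$label, "atpA_4")
  expect_identical(coded$characters$gene, "atpA")
})

test_that("small-parsimony classification matches hand-worked cases", {
  tr <- read_tree_newick("((A,B),(C,D));")
  syn <- classify_character(c(A = "1", B = "1", C = "0", D = "0"), tr)
  expect_identical(syn$steps, 1L)
  expect_identical(syn$category, "synapomorphic")
  expect_identical(syn$clade, c("A", "B"))
  aut <- classify_character(c(A = "1", B = "0", C = "0", D = "0"), tr)
  expect_identical(aut$steps, 1L)
  expect_identical(aut$category, "autapomorphic")
  expect_identical(aut$clade, "A")
  hom <- classify_character(c(A = "1", B = "0", C = "1", D = "0"), tr)
  expect_identical(hom$steps, 2L)
  expect_identical(hom$category, "homoplastic")
  inv <- classify_character(c(A = "1", B = "1", C = "1", D = "?"), tr)
  expect_identical(inv$steps, 0L)
  expect_identical(inv$category, "invariant")
})

test_that("Fitch steps equal exhaustive minimization on random trees with missing data", {
  set.seed(1234)
  for (case in 1:40) {
    n <- sample(5:8, 1)
    tr <- ape::rtopology(n, rooted = FALSE)
    tr$tip.label <- paste0("t", seq_len(n))
    st <- stats::setNames(sample(c("0", "1", "?"), n, replace = TRUE,
                                 prob = c(0.4, 0.4, 0.2)), tr$tip.label)
    if (length(unique(st[st != "?"])) < 2) next
    got <- classify_character(st, tr)$steps
    expect_identical(got, bf_fitch(tr, st),
                     label = sprintf("case %d (n=%d, states=%s)", case, n,
                                     paste(st, collapse = "")))
  }
})

test_that("Fitch steps agree with phangorn's parsimony on complete data", {
  skip_if_not_installed("phangorn")
  set.seed(4321)
  for (case in 1:20) {
    n <- sample(5:10, 1)
    tr <- ape::rtopology(n, rooted = FALSE)
    tr$tip.label <- paste0("t", seq_len(n))
    st <- stats::setNames(sample(c("0", "1"), n, replace = TRUE), tr$tip.label)
    if (length(unique(st)) < 2) next
    dat <- phangorn::phyDat(matrix(st, ncol = 1, dimnames = list(names(st), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_identical(classify_character(st, tr)$steps,
                     as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("matrix classification aggregates counts and conserves the category partition", {
  tr <- read_tree_newick("((A,B),(C,D));")
  cells <- cbind(c("1", "1", "0", "0"), c("1", "0", "0", "0"), c("1", "0", "1", "0"))
  dimnames(cells) <- list(c("A", "B", "C", "D"), c("g_1", "g_2", "g_3"))
  cls <- classify_matrix(binary_matrix(cells), tr)
  expect_identical(unname(cls$counts["synapomorphic"]), 1L)
  expect_identical(unname(cls$counts["autapomorphic"]), 1L)
  expect_identical(unname(cls$counts["homoplastic"]), 1L)
  expect_identical(sum(cls$counts), cls$n_characters)
  expect_identical(cls$autapomorphic_tree_free, 1L)
})

test_that("tree-free autapomorphy equals tree-based autapomorphy for complete characters", {
  set.seed(77)
  for (case in 1:10) {
    n <- 8
    tr <- ape::rtopology(n, rooted = FALSE)
    tr$tip.label <- paste0("t", seq_len(n))
    nch <- 12
    cells <- matrix(sample(c("0", "1"), n * nch, replace = TRUE), nrow = n,
                    dimnames = list(tr$tip.label, paste0("c_", seq_len(nch))))
    # drop invariant columns (no minority state)
    keep <- apply(cells, 2, function(x) length(unique(x)) == 2)
    cells <- cells[, keep, drop = FALSE]
    if (!ncol(cells)) next
    cls <- classify_matrix(binary_matrix(cells), tr)
    expect_identical(unname(cls$counts["autapomorphic"]), cls$autapomorphic_tree_free)
  }
})

test_that("label reconciliation errors list the offending taxa", {
  tr <- read_tree_newick("((A,B),(C,D));")
  cells <- matrix(c("1", "0", "0", "0"), ncol = 1,
                  dimnames = list(c("A", "B", "C", "Dx"), "g_1"))
  expect_error(classify_matrix(binary_matrix(cells), tr), "Dx")
  # a label map repairs the mismatch
  cls <- classify_matrix(binary_matrix(cells), tr, label_map = c(Dx = "D"))
  expect_identical(cls$n_characters, 1L)
})
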