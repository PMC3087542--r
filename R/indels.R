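# Simple indel coding and tree-based character classification.
#
# Coding follows the simple-indel-coding convention: every distinct gap with
# identical start and end columns observed in at least one taxon defines one
# binary character; taxa with that exact gap score 0 (stretch absent), taxa
# with nucleotides across the whole span score 1 (stretch present), and taxa
# whose own gap strictly contains the span — or that are missing anywhere in
# it — score ?. Leading and trailing terminal gaps are treated as missing
# data, not indels. Columns in the alignment's exclusion set yield no
# characters.
#
# Classification computes the minimum number of state changes of each
# character on a supplied tree (unit-cost Sankoff dynamic programming, which
# is exact for multifurcations and root-invariant; ? is a free state) and
# categorizes: 0 steps = invariant, 1 step on a pendant edge = autapomorphic,
# 1 step on an internal edge = synapomorphic, >= 2 steps = homoplastic.

#' Code alignment gaps as binary indel characters
#'
#' @param alignment A [plastome_alignment()].
#' @param use_exclusions Honor the alignment's excluded columns (default
#'   `TRUE`); characters whose span touches an excluded column are not
#'   produced.
#' @return A list with `matrix` (a [binary_matrix()], one column per indel
#'   character, labeled `<gene>_<1-based start>`) and `characters` (data
#'   frame: `label`, `gene`, `start`, `end` — alignment columns, 0-based
#'   half-open).
#' @export
code_indels <- function(alignment, use_exclusions = TRUE) {
  stopifnot(inherits(alignment, "plastome_alignment"))
  taxa <- alignment$taxa
  m <- do.call(rbind, strsplit(unname(alignment$rows), "", fixed = TRUE))
  rownames(m) <- taxa
  nc <- ncol(m)
  # terminal gaps are missing data
  for (t in seq_along(taxa)) {
    row <- m[t, ]
    ng <- which(row != "-")
    if (!length(ng)) { m[t, ] <- "?"; next }
    if (ng[1] > 1L) m[t, seq_len(ng[1] - 1L)] <- "?"
    if (ng[length(ng)] < nc) m[t, seq.int(ng[length(ng)] + 1L, nc)] <- "?"
  }
  excluded1 <- if (use_exclusions) alignment$excluded + 1L else integer(0)

  # collect distinct internal gap spans (0-based half-open)
  spans <- list()
  gap_runs <- vector("list", length(taxa))
  for (t in seq_along(taxa)) {
    r <- rle(m[t, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    gap_runs[[t]] <- runs
    for (i in seq_len(nrow(runs))) {
      key <- paste0(runs[i, 1L], ":", runs[i, 2L])
      spans[[key]] <- c(runs[i, 1L], runs[i, 2L])
    }
  }
  if (!length(spans)) {
    cells <- matrix(character(0), nrow = length(taxa), ncol = 0L,
                    dimnames = list(taxa, NULL))
    return(list(matrix = binary_matrix(cells),
                characters = data.frame(label = character(0), gene = character(0),
                                        start = integer(0), end = integer(0))))
  }
  sp <- do.call(rbind, spans)
  sp <- sp[order(sp[, 1L], sp[, 2L]), , drop = FALSE]
  keep <- !vapply(seq_len(nrow(sp)), function(i)
    any(seq.int(sp[i, 1L], sp[i, 2L]) %in% excluded1), logical(1))
  sp <- sp[keep, , drop = FALSE]

  label_of <- function(s1) {
    # s1: 1-based start column; map into a gene partition when available
    for (nm in names(alignment$partitions)) {
      cols1 <- alignment$partitions[[nm]] + 1L
      if ((s1) %in% cols1) return(c(nm, as.character(match(s1, sort(cols1)))))
    }
    c("aln", as.character(s1))
  }

  states <- list(); labels <- character(0)
  chars <- list()
  for (i in seq_len(nrow(sp))) {
    s1 <- sp[i, 1L]; e1 <- sp[i, 2L]
    st <- vapply(seq_along(taxa), function(t) {
      seg <- m[t, s1:e1]
      if (all(seg %in% c("A", "C", "G", "T", "N"))) return("1")
      runs <- gap_runs[[t]]
      if (nrow(runs) && any(runs[, 1L] == s1 & runs[, 2L] == e1)) return("0")
      "?"
    }, character(1))
    if (!any(st == "0") || !any(st == "1")) next
    lg <- label_of(s1)
    lab <- paste0(lg[1], "_", lg[2])
    k <- 2L
    while (lab %in% labels) { lab <- paste0(lg[1], "_", lg[2], ".", k); k <- k + 1L }
    labels <- c(labels, lab)
    states[[length(states) + 1L]] <- st
    chars[[length(chars) + 1L]] <- data.frame(label = lab, gene = lg[1],
                                              start = s1 - 1L, end = e1,
                                              stringsAsFactors = FALSE)
  }
  cells <- if (length(states)) {
    matrix(unlist(states), nrow = length(taxa), dimnames = list(taxa, labels))
  } else matrix(character(0), nrow = length(taxa), ncol = 0L, dimnames = list(taxa, NULL))
  list(matrix = binary_matrix(cells),
       characters = do.call(rbind, chars) %||%
         data.frame(label = character(0), gene = character(0),
                    start = integer(0), end = integer(0)))
}

# ---- small parsimony --------------------------------------------------------

# minimum number of binary-state changes on tree for states in {"0","1","?"};
# unit-cost Sankoff over the (possibly multifurcating) tree
fitch_steps <- function(tree, states) {
  tips <- tree$tip.label
  miss <- setdiff(names(states)[states != "?"], tips)
  if (length(miss))
    stop(sprintf("taxa not on tree: %s", paste(miss, collapse = ", ")), call. = FALSE)
  nt <- length(tips)
  nn <- nt + tree$Nnode
  cost <- matrix(Inf, nrow = nn, ncol = 2L)
  for (i in seq_len(nt)) {
    s <- states[tips[i]]
    if (is.na(s) || s == "?") cost[i, ] <- c(0, 0)
    else if (s == "0") cost[i, 1L] <- 0
    else cost[i, 2L] <- 0
  }
  edge <- tree$edge
  ord <- rev(seq_len(nrow(edge)))  # ape cladewise: reverse order visits children first
  # safer: process edges in postorder
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1L]; ch <- po[i, 2L]
    if (all(!is.finite(cost[par, ]))) cost[par, ] <- c(0, 0)
    add0 <- min(cost[ch, 1L], cost[ch, 2L] + 1)
    add1 <- min(cost[ch, 2L], cost[ch, 1L] + 1)
    cost[par, 1L] <- cost[par, 1L] + add0
    cost[par, 2L] <- cost[par, 2L] + add1
  }
  root <- setdiff(po[, 1L], po[, 2L])[1L]
  as.integer(min(cost[root, ]))
}

# edges whose bipartition cleanly separates the observed 0s from the 1s
consistent_edges <- function(tree, states) {
  tips <- tree$tip.label
  obs <- states[tips]
  ones <- tips[!is.na(obs) & obs == "1"]
  zeros <- tips[!is.na(obs) & obs == "0"]
  edge <- tree$edge
  below <- clade_tips(tree)
  out <- list()
  for (i in seq_len(nrow(edge))) {
    side <- below[[edge[i, 2L]]]
    other <- setdiff(tips, side)
    if ((all(ones %in% side) && all(zeros %in% other)) ||
        (all(zeros %in% side) && all(ones %in% other))) {
      out[[length(out) + 1L]] <- list(edge = i, side = side, other = other)
    }
  }
  out
}

# tips below every node (index = node id)
clade_tips <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    below[[po[i, 1L]]] <- c(below[[po[i, 1L]]], below[[po[i, 2L]]])
  }
  below
}

#' Classify one binary character against a tree
#'
#' Computes the minimum parsimony length (missing states free) and the
#' category: `invariant` (0 steps), `autapomorphic` (1 step on a pendant
#' edge), `synapomorphic` (1 step on an internal edge) or `homoplastic`
#' (2+ steps). For single-step characters the change edge's smaller leaf
#' set is reported as the supporting clade; when several edges can carry
#' the single step (possible with missing data) the one with the smallest
#' clade is chosen, so a state confined to one terminal is always scored
#' autapomorphic.
#'
#' @param states Named character vector of `"0"`/`"1"`/`"?"` keyed by taxon.
#' @param tree An `ape::phylo` tree whose leaves cover all non-missing taxa.
#' @return A list with `steps`, `category` and `clade` (character vector of
#'   leaf labels; `NULL` unless steps is 1).
#' @export
classify_character <- function(states, tree) {
  obs <- states[states != "?" & !is.na(states)]
  if (!length(obs)) return(list(steps = 0L, category = "invariant", clade = NULL))
  if (length(unique(obs)) == 1L)
    return(list(steps = 0L, category = "invariant", clade = NULL))
  steps <- fitch_steps(tree, states)
  if (steps == 0L) return(list(steps = 0L, category = "invariant", clade = NULL))
  if (steps >= 2L) return(list(steps = steps, category = "homoplastic", clade = NULL))
  ce <- consistent_edges(tree, states)
  sizes <- vapply(ce, function(e) min(length(e$side), length(e$other)), integer(1))
  pick <- ce[[which.min(sizes)]]
  clade <- if (length(pick$side) <= length(pick$other)) pick$side else pick$other
  category <- if (length(clade) == 1L) "autapomorphic" else "synapomorphic"
  list(steps = 1L, category = category, clade = sort(clade))
}

#' Classify a whole indel matrix against a tree
#'
#' @param matrix A [binary_matrix()].
#' @param tree An `ape::phylo` tree.
#' @param label_map Optional named character vector mapping matrix taxon
#'   labels to tree leaf labels (the spelling of taxon names often differs
#'   between data matrices and trees; no guessing is attempted).
#' @return An object of class `indel_classification`: list with `table`
#'   (data frame: `label`, `steps`, `category`, `clade`), `counts` (named
#'   integer vector over the four categories), `n_characters`, and
#'   `autapomorphic_tree_free` (number of characters whose minority state
#'   occurs in exactly one taxon, computable without any tree).
#' @export
classify_matrix <- function(matrix, tree, label_map = NULL) {
  stopifnot(inherits(matrix, "indel_binary_matrix"))
  taxa <- matrix$taxa
  if (!is.null(label_map)) {
    mapped <- label_map[taxa]
    taxa <- ifelse(is.na(mapped), taxa, mapped)
  }
  unmatched <- setdiff(taxa, tree$tip.label)
  if (length(unmatched))
    stop(sprintf("taxon labels not on tree (supply label_map): %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  cats <- c("synapomorphic", "autapomorphic", "homoplastic", "invariant")
  n <- length(matrix$characters)
  rows <- vector("list", n)
  tree_free <- 0L
  for (i in seq_len(n)) {
    st <- stats::setNames(matrix$cells[, i], taxa)
    cl <- classify_character(st, tree)
    rows[[i]] <- data.frame(label = matrix$characters[i], steps = cl$steps,
                            category = cl$category,
                            clade = paste(cl$clade %||% character(0), collapse = ";"),
                            stringsAsFactors = FALSE)
    n0 <- sum(st == "0"); n1 <- sum(st == "1")
    if (min(n0, n1) == 1L) tree_free <- tree_free + 1L
  }
  tab <- do.call(rbind, rows) %||%
    data.frame(label = character(0), steps = integer(0), category = character(0),
               clade = character(0))
  counts <- stats::setNames(vapply(cats, function(cc) sum(tab$category == cc), integer(1)), cats)
  base::structure(list(table = tab, counts = counts, n_characters = n,
                       autapomorphic_tree_free = tree_free),
                  class = "indel_classification")
}

#' @export
print.indel_classification <- function(x, ...) {
  cat(sprintf("<indel_classification> %d characters: %s\n", x$n_characters,
              paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", ")))
  cat(sprintf("  tree-free autapomorphies (minority state in exactly one taxon): %d\n",
              x$autapomorphic_tree_free))
  invisible(x)
}
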