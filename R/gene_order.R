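# Signed circular gene orders and their comparison: breakpoint distances,
# oriented synteny blocks (inversion candidates) and region translocations.
#
# Rearrangements are reported descriptively, as maximal inverted blocks
# between two genomes; minimal reversal scenarios (sorting by reversals) are
# deliberately not computed, since shared individual inversions — not
# distances — are what comparative plastome work interprets.

#' Construct a signed gene order
#'
#' @param id Genome identifier.
#' @param genes Character vector of gene symbols, in circular positional
#'   order.
#' @param strands Integer vector of `+1`/`-1` orientations.
#' @param regions Optional named character vector mapping gene symbols to
#'   region labels (`LSC`, `SSC`, `IR`, `IR-partial(LSC)`, `IR-partial(SSC)`).
#' @param ir_collapsed Logical; `TRUE` when IR duplicates were reduced to
#'   the IRA copy.
#' @return An object of class `signed_gene_order`.
#' @export
signed_gene_order <- function(id, genes, strands, regions = NULL, ir_collapsed = FALSE) {
  stopifnot(length(genes) == length(strands), all(strands %in% c(1L, -1L)))
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene symbols in order: %s",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")), call. = FALSE)
  structure(list(id = id, genes = as.character(genes), strands = as.integer(strands),
                 regions = regions, ir_collapsed = isTRUE(ir_collapsed)),
            class = "signed_gene_order")
}

#' @export
print.signed_gene_order <- function(x, ...) {
  cat(sprintf("<signed_gene_order> %s: %d genes%s\n", x$id, length(x$genes),
              if (x$ir_collapsed) " (IR collapsed)" else ""))
  shown <- paste0(ifelse(x$strands == 1L, "", "-"), x$genes)
  cat(" ", paste(utils::head(shown, 12), collapse = " "),
      if (length(shown) > 12) "..." else "", "\n")
  invisible(x)
}

#' Extract the signed gene order of a plastome
#'
#' Features in circular positional order with strand orientation. With
#' `collapse_ir = TRUE` exactly one copy of each IR-duplicated gene is kept
#' (the IRA copy), so symbols are unique; duplicated symbols outside the IR
#' raise an error listing the offenders. tRNAs are included by default
#' because several diagnostic inversion endpoints are tRNAs.
#'
#' @param record A [plastome_record()].
#' @param structure A [quadripartite_structure()]; required when
#'   `collapse_ir = TRUE` or when region labels are wanted.
#' @param collapse_ir Drop the IRB copy of fully-IR duplicated genes.
#' @param include_trnas Include tRNA features.
#' @return A [signed_gene_order()].
#' @export
extract_signed_order <- function(record, structure = NULL, collapse_ir = !is.null(structure),
                                 include_trnas = TRUE) {
  feats <- record$features
  if (!include_trnas) feats <- Filter(function(f) f$kind != "tRNA", feats)
  regions <- NULL
  drop <- rep(FALSE, length(feats))
  if (!is.null(structure)) {
    sub <- record; sub$features <- feats
    cls <- classify_gene_regions(sub, structure)$assignments
    if (collapse_ir) drop <- cls$region == "IR" & cls$copies == 2L & cls$ir_copy == "IRB"
    regions <- cls$region
  } else if (collapse_ir) {
    stop("collapse_ir requires a quadripartite structure", call. = FALSE)
  }
  feats <- feats[!drop]
  if (!is.null(regions)) regions <- regions[!drop]
  starts <- vapply(feats, function(f) f$intervals[1L, 1L], integer(1))
  ord <- order(starts)
  genes <- vapply(feats, function(f) f$name, character(1))[ord]
  strands <- vapply(feats, function(f) f$strand, integer(1))[ord]
  rg <- if (!is.null(regions)) stats::setNames(regions[ord], genes) else NULL
  signed_gene_order(record$identifier, genes, strands, regions = rg,
                    ir_collapsed = collapse_ir)
}

# restrict two orders to their shared gene set, preserving order
restrict_shared <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  dropped_a <- setdiff(a$genes, shared); dropped_b <- setdiff(b$genes, shared)
  if (length(dropped_a) || length(dropped_b)) {
    message(sprintf("restricting to %d shared genes (dropping %d from %s, %d from %s)",
                    length(shared), length(dropped_a), a$id, length(dropped_b), b$id))
  }
  keep <- function(x) {
    ix <- x$genes %in% shared
    signed_gene_order(x$id, x$genes[ix], x$strands[ix],
                      regions = if (!is.null(x$regions)) x$regions[x$genes[ix]] else NULL,
                      ir_collapsed = x$ir_collapsed)
  }
  list(a = keep(a), b = keep(b), shared = shared)
}

# canonical string form of a signed adjacency (x -> y) == (-y -> -x)
canon_adjacency <- function(x, y) {
  a1 <- paste0(x, ">", y); a2 <- paste0(-y, ">", -x)
  if (a1 <= a2) a1 else a2
}

signed_elements <- function(order, symtab) {
  match(order$genes, symtab) * order$strands
}

#' Breakpoint distance between two signed circular gene orders
#'
#' Number of signed adjacencies of one circular order absent from the other,
#' where adjacency `(x -> y)` matches `(x -> y)` or `(-y -> -x)`. The
#' distance is symmetric and zero exactly when the orders are equivalent up
#' to rotation and whole-circle flip. Orders are restricted to their shared
#' gene set first.
#'
#' @param a,b [signed_gene_order()] objects.
#' @return Integer breakpoint count.
#' @export
breakpoint_distance <- function(a, b) {
  r <- restrict_shared(a, b)
  if (length(r$shared) < 2L)
    stop("breakpoint distance undefined: fewer than 2 shared genes", call. = FALSE)
  sym <- r$shared
  ea <- signed_elements(r$a, sym); eb <- signed_elements(r$b, sym)
  adj <- function(e) {
    nxt <- c(e[-1L], e[1L])
    vapply(seq_along(e), function(i) canon_adjacency(e[i], nxt[i]), character(1))
  }
  sum(!(adj(ea) %in% adj(eb)))
}

#' Oriented synteny blocks between two gene orders
#'
#' Maximal runs of shared genes that are consecutive and co-linear in both
#' circular genomes, labeled `same` or `inverted`. Every inverted block that
#' does not cover the whole shared circle is reported as an inversion
#' candidate with its endpoint genes ("inversion involving X to Y"). Blocks
#' partition the shared-gene circle.
#'
#' @param a,b [signed_gene_order()] objects.
#' @return A data frame with one row per block: `genes` (comma-collapsed, in
#'   `a`'s order), `n_genes`, `orientation`, `start_gene`, `end_gene`. The
#'   inversion candidates are attached as attribute `"candidates"` (data
#'   frame with `start_gene`, `end_gene`, `n_genes`).
#' @export
synteny_blocks <- function(a, b) {
  r <- restrict_shared(a, b)
  if (length(r$shared) < 2L)
    stop("synteny blocks undefined: fewer than 2 shared genes", call. = FALSE)
  ga <- r$a$genes; n <- length(ga)
  posb <- match(ga, r$b$genes)                       # position of each a-gene in b
  rel <- r$a$strands * r$b$strands[posb]             # +1 same, -1 flipped
  nxt <- c(2:n, 1L)
  # is the circular adjacency (i, nxt[i]) of a preserved in b?
  preserved <- vapply(seq_len(n), function(i) {
    j <- nxt[i]
    (rel[i] == 1L && rel[j] == 1L && posb[j] == (posb[i] %% n) + 1L) ||
      (rel[i] == -1L && rel[j] == -1L && posb[j] == ((posb[i] - 2L) %% n) + 1L)
  }, logical(1))
  if (all(preserved)) {
    blocks <- data.frame(genes = paste(ga, collapse = ","), n_genes = n,
                         orientation = if (all(rel == 1L)) "same" else "inverted",
                         start_gene = ga[1L], end_gene = ga[n], stringsAsFactors = FALSE)
    attr(blocks, "candidates") <- data.frame(start_gene = character(0),
                                             end_gene = character(0), n_genes = integer(0))
    return(blocks)
  }
  breaks <- which(!preserved)                         # block ends at i, next starts at i+1
  starts <- (breaks %% n) + 1L
  starts <- sort(starts)
  rows <- list()
  for (bi in seq_along(starts)) {
    s <- starts[bi]
    e_excl <- if (bi < length(starts)) starts[bi + 1L] else starts[1L]
    len <- ((e_excl - s - 1L) %% n) + 1L
    ix <- ((s - 1L + seq_len(len) - 1L) %% n) + 1L
    rows[[bi]] <- data.frame(
      genes = paste(ga[ix], collapse = ","), n_genes = len,
      orientation = if (all(rel[ix] == 1L)) "same" else "inverted",
      start_gene = ga[ix[1L]], end_gene = ga[ix[len]], stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  cand <- blocks[blocks$orientation == "inverted" & blocks$n_genes < n,
                 c("start_gene", "end_gene", "n_genes")]
  rownames(cand) <- NULL
  attr(blocks, "candidates") <- cand
  blocks
}

#' Genes whose quadripartite region differs between two genomes
#'
#' @param a,b [signed_gene_order()] objects carrying region maps.
#' @return Data frame with `gene`, `region_a`, `region_b` for every shared
#'   gene whose labels differ (IR-partial labels count as distinct labels).
#' @export
region_translocations <- function(a, b) {
  if (is.null(a$regions) || is.null(b$regions))
    stop("region_translocations: both orders need region maps", call. = FALSE)
  shared <- intersect(a$genes, b$genes)
  ra <- unname(a$regions[shared]); rb <- unname(b$regions[shared])
  ix <- which(ra != rb)
  data.frame(gene = shared[ix], region_a = ra[ix], region_b = rb[ix],
             stringsAsFactors = FALSE)
}
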