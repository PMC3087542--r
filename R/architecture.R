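# Quadripartite architecture: inverted-repeat detection, LSC/SSC/IRA/IRB
# partition, per-region statistics, gene-region classification and gene
# content comparison.
#
# The detector finds the maximal pair of disjoint circular intervals whose
# sequences are exact reverse complements (no mismatch tolerance). Exactness
# keeps the maximal pair well defined and lets generator-based tests demand
# exact recovery. Seeds of length k = min(min_length, 24) are hashed and
# extended along complement anti-diagonals; each maximal run is examined
# once.

#' Quadripartite structure of a circular plastome
#'
#' Constructed by [detect_inverted_repeat()]. Regions are stored as
#' `list(start, length)` in native 0-based coordinates (`start` may be
#' anywhere on the circle; intervals wrap implicitly). Traversing the circle
#' from `lsc$start` visits LSC, IRA, SSC, IRB in that canonical order, and
#' the IRB sequence is the exact reverse complement of the IRA sequence.
#'
#' @param lsc,ira,ssc,irb `list(start, length)` region descriptors.
#' @param total_length Circle size in bp.
#' @return An object of class `quadripartite_structure` with the four
#'   regions plus `ir_length`, `lsc_length`, `ssc_length`, `total_length`.
#' @export
quadripartite_structure <- function(lsc, ira, ssc, irb, total_length) {
  stopifnot(ira$length == irb$length, lsc$length >= ssc$length)
  if (lsc$length + ssc$length + 2L * ira$length != total_length)
    stop("quadripartite regions do not tile the circle", call. = FALSE)
  structure(list(lsc = lsc, ira = ira, ssc = ssc, irb = irb,
                 ir_length = ira$length, lsc_length = lsc$length,
                 ssc_length = ssc$length, total_length = total_length),
            class = "quadripartite_structure")
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  cat(sprintf("<quadripartite_structure> total %s bp = LSC %s + IRA %s + SSC %s + IRB %s\n",
              format(x$total_length, big.mark = ","),
              format(x$lsc_length, big.mark = ","), format(x$ir_length, big.mark = ","),
              format(x$ssc_length, big.mark = ","), format(x$ir_length, big.mark = ",")))
  cat(sprintf("  LSC [%d,+%d)  IRA [%d,+%d)  SSC [%d,+%d)  IRB [%d,+%d)\n",
              x$lsc$start, x$lsc$length, x$ira$start, x$ira$length,
              x$ssc$start, x$ssc$length, x$irb$start, x$irb$length))
  invisible(x)
}

#' Sequence of one region of a quadripartite structure
#'
#' @param record A [plastome_record()].
#' @param structure A [quadripartite_structure()].
#' @param region One of `"lsc"`, `"ira"`, `"ssc"`, `"irb"`.
#' @return DNA string of the region (forward strand).
#' @export
region_sequence <- function(record, structure, region = c("lsc", "ira", "ssc", "irb")) {
  region <- match.arg(region)
  r <- structure[[region]]
  circ_substr(record$sequence, r$start, r$length)
}

# maximal complement-match run through seed pair (i0, j0) of length k,
# 0-based, on circular char vector sv with complement cv. Returns
# c(a_start, b_start, len) or NULL.
extend_ir_run <- function(sv, cv, n, i0, j0, k) {
  C <- (i0 + j0 + k - 1L) %% n
  ts <- seq.int(i0 - n + 1L, i0 + k - 1L + n - 1L)
  p <- ((ts %% n) + n) %% n
  q <- (((C - ts) %% n) + n) %% n
  ok <- sv[p + 1L] == cv[q + 1L]
  # indices of the seed inside ts
  s1 <- n; s2 <- n + k - 1L          # positions of t = i0 .. i0+k-1 in ts
  bad <- which(!ok)
  left <- bad[bad < s1]
  right <- bad[bad > s2]
  lo <- if (length(left)) max(left) + 1L else 1L
  hi <- if (length(right)) min(right) - 1L else length(ts)
  len <- hi - lo + 1L
  if (len >= n) { lo <- s1; len <- n }   # cap at circle size
  a_start <- ((ts[lo] %% n) + n) %% n
  b_start <- (((C - ts[lo] - len + 1L) %% n) + n) %% n
  c(a_start, b_start, len)
}

ir_disjoint <- function(a, b, L, n) {
  ((b - a) %% n) >= L && ((a - b) %% n) >= L
}

#' Detect the inverted repeat and quadripartite partition
#'
#' Finds the maximal-length pair of disjoint intervals on the circle whose
#' sequences are exact reverse complements of each other, with length at
#' least `min_length`, and derives the induced LSC/SSC partition (the longer
#' single-copy arc is the LSC). When several maximal pairs exist, the pair
#' whose smaller start coordinate is smallest is chosen, so the result is
#' deterministic. Genomes with no qualifying pair are reported as having no
#' IR (`NULL`) rather than forced into a quadripartite model.
#'
#' @param record A circular [plastome_record()].
#' @param min_length Minimum acceptable IR length in bp (default 1000,
#'   which avoids spurious short repeats in real plastomes).
#' @return A [quadripartite_structure()], or `NULL` if no inverted repeat of
#'   the required length exists.
#' @export
detect_inverted_repeat <- function(record, min_length = 1000L) {
  if (!inherits(record, "plastome_record")) record <- plastome_record("seq", record)
  if (!record$circular)
    stop("detect_inverted_repeat: record must be circular", call. = FALSE)
  min_length <- as.integer(min_length)
  stopifnot(min_length >= 1L)
  s <- record$sequence
  n <- nchar(s)
  if (n < 2L * min_length) return(NULL)
  k <- min(min_length, 24L, n %/% 2L)
  sv <- dna_chars(s)
  cv <- comp_chars(sv)

  d <- paste0(s, s)
  kmers <- substring(d, seq_len(n), seq_len(n) + k - 1L)
  rc <- revcomp(s)
  rc2 <- paste0(rc, rc)
  starts0 <- ((n - seq_len(n) + 1L - k) %% n)          # 0-based start in rc
  rckmers <- substring(rc2, starts0 + 1L, starts0 + k)
  idx <- split(seq_len(n) - 1L, kmers)                 # kmer -> 0-based starts

  visited <- new.env(hash = TRUE, parent = emptyenv())
  cands <- list()
  for (i1 in seq_len(n)) {
    hits <- idx[[rckmers[i1]]]
    if (is.null(hits)) next
    i0 <- i1 - 1L
    for (j0 in hits) {
      key <- paste0(i0, "_", j0)
      if (!is.null(visited[[key]])) next
      run <- extend_ir_run(sv, cv, n, i0, j0, k)
      a <- run[1L]; b <- run[2L]; L <- run[3L]
      # mark all seed pairs along this run as visited
      if (L >= k) {
        offs <- 0L:(L - k)
        ps <- (a + offs) %% n
        qs <- (b + (L - k) - offs) %% n
        for (m in seq_along(offs)) visited[[paste0(ps[m], "_", qs[m])]] <- TRUE
        # the symmetric orientation too
        for (m in seq_along(offs)) visited[[paste0(qs[m], "_", ps[m])]] <- TRUE
      }
      if (L < min_length) next
      if (ir_disjoint(a, b, L, n)) {
        cands[[length(cands) + 1L]] <- c(a, b, L)
      } else {
        # trim the run to the longest disjoint sub-pair on the same diagonal
        C <- (a + b + L - 1L) %% n
        found <- FALSE
        top <- min(L, n %/% 2L)
        if (top < min_length) next
        for (Lp in seq.int(top, min_length)) {
          for (off in 0L:(L - Lp)) {
            ap <- (a + off) %% n
            bp <- ((C - ap - Lp + 1L) %% n + n) %% n
            if (ir_disjoint(ap, bp, Lp, n)) {
              cands[[length(cands) + 1L]] <- c(ap, bp, Lp)
              found <- TRUE; break
            }
          }
          if (found) break
        }
      }
    }
  }
  if (!length(cands)) return(NULL)
  cm <- do.call(rbind, cands)
  # canonicalize pair orientation: first = smaller start
  flip <- cm[, 1L] > cm[, 2L]
  cm[flip, 1:2] <- cm[flip, 2:1]
  cm <- unique(cm)
  best_len <- max(cm[, 3L])
  cm <- cm[cm[, 3L] == best_len, , drop = FALSE]
  cm <- cm[order(cm[, 1L], cm[, 2L]), , drop = FALSE]
  a <- cm[1L, 1L]; b <- cm[1L, 2L]; L <- cm[1L, 3L]

  # arcs between the two copies: arc1 follows copy A, arc2 follows copy B
  arc1_start <- (a + L) %% n; arc1_len <- (b - a - L) %% n
  arc2_start <- (b + L) %% n; arc2_len <- (a - b - L) %% n
  if (arc2_len >= arc1_len) {
    lsc <- list(start = arc2_start, length = arc2_len)
    ssc <- list(start = arc1_start, length = arc1_len)
    ira <- list(start = a, length = L); irb <- list(start = b, length = L)
  } else {
    lsc <- list(start = arc1_start, length = arc1_len)
    ssc <- list(start = arc2_start, length = arc2_len)
    ira <- list(start = b, length = L); irb <- list(start = a, length = L)
  }
  st <- quadripartite_structure(lsc, ira, ssc, irb, n)
  # integrity: IRB must be the exact reverse complement of IRA
  stopifnot(identical(revcomp(region_sequence(record, st, "ira")),
                      region_sequence(record, st, "irb")))
  st
}

#' Per-region lengths and G/C content
#'
#' @param record A [plastome_record()].
#' @param structure A [quadripartite_structure()] tiling the record.
#' @return A data frame with one row per region (LSC, SSC, IR, total):
#'   length in bp and G/C fraction. The total counts both IR copies and the
#'   G/C denominators exclude N.
#' @export
region_stats <- function(record, structure) {
  if (structure$total_length != nchar(record$sequence))
    stop("structure and record lengths disagree", call. = FALSE)
  gc_ir <- gc_content(region_sequence(record, structure, "ira"))
  data.frame(
    region = c("LSC", "SSC", "IR", "total"),
    length = c(structure$lsc_length, structure$ssc_length, structure$ir_length,
               structure$total_length),
    gc = c(gc_content(region_sequence(record, structure, "lsc")),
           gc_content(region_sequence(record, structure, "ssc")),
           gc_ir,
           gc_content(record$sequence)),
    stringsAsFactors = FALSE
  )
}

# region label ("LSC","IRA","SSC","IRB") of every 0-based position
region_label_vector <- function(structure) {
  n <- structure$total_length
  lab <- character(n)
  for (nm in c("lsc", "ira", "ssc", "irb")) {
    r <- structure[[nm]]
    if (r$length > 0L) {
      pos <- (seq.int(r$start, r$start + r$length - 1L) %% n) + 1L
      lab[pos] <- toupper(nm)
    }
  }
  lab
}

#' Classify genes by quadripartite region
#'
#' Assigns every feature a region label: `LSC`, `SSC`, `IR`, or — for
#' features overlapping an IR/single-copy junction — `IR-partial(LSC)` /
#' `IR-partial(SSC)` naming the single-copy side. Fully-IR features with a
#' same-named duplicate in the other IR copy get copy count 2. The four
#' junction gene tables (the gene nearest each side of every junction, plus
#' any genes spanning it) are returned alongside.
#'
#' @param record A [plastome_record()].
#' @param structure A [quadripartite_structure()].
#' @return An object of class `gene_region_assignment`: list with
#'   `assignments` (data frame: gene, kind, strand, pseudo, region, ir_copy,
#'   copies) and `junctions` (data frame: junction, gene, side, partial).
#' @export
classify_gene_regions <- function(record, structure) {
  n <- nchar(record$sequence)
  if (structure$total_length != n)
    stop("structure and record lengths disagree", call. = FALSE)
  lab <- region_label_vector(structure)
  feats <- record$features
  rows <- lapply(feats, function(f) {
    pos <- interval_positions(f$intervals, n)
    regs <- unique(lab[pos + 1L])
    in_ir <- any(regs %in% c("IRA", "IRB"))
    ir_copy <- NA_character_
    region <- if (in_ir && length(setdiff(regs, c("IRA", "IRB"))) == 0L) {
      ir_copy <- if (all(regs == "IRA")) "IRA" else if (all(regs == "IRB")) "IRB" else "both"
      "IR"
    } else if (in_ir && "LSC" %in% regs && !("SSC" %in% regs)) {
      "IR-partial(LSC)"
    } else if (in_ir && "SSC" %in% regs && !("LSC" %in% regs)) {
      "IR-partial(SSC)"
    } else if (in_ir) {
      # spans both single-copy sides; name the side with the larger overlap
      if (sum(lab[pos + 1L] == "LSC") >= sum(lab[pos + 1L] == "SSC"))
        "IR-partial(LSC)" else "IR-partial(SSC)"
    } else if (all(regs == "LSC")) "LSC" else "SSC"
    data.frame(gene = f$name, kind = f$kind, strand = f$strand,
               pseudo = f$pseudo, region = region, ir_copy = ir_copy,
               start = f$intervals[1L, 1L], stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, rows) %||%
    data.frame(gene = character(0), kind = character(0), strand = integer(0),
               pseudo = logical(0), region = character(0), ir_copy = character(0),
               start = integer(0))
  asg$copies <- 1L
  full_ir <- which(asg$region == "IR")
  if (length(full_ir)) {
    for (i in full_ir) {
      mate <- full_ir[asg$gene[full_ir] == asg$gene[i] &
                        asg$ir_copy[full_ir] != asg$ir_copy[i]]
      if (length(mate)) asg$copies[i] <- 2L
    }
  }

  # junction tables: canonical order LSC-IRA, IRA-SSC, SSC-IRB, IRB-LSC
  jpos <- c("LSC-IRA" = structure$ira$start, "IRA-SSC" = structure$ssc$start,
            "SSC-IRB" = structure$irb$start, "IRB-LSC" = structure$lsc$start)
  jrows <- list()
  if (nrow(asg)) {
    covers <- lapply(feats, function(f) interval_positions(f$intervals, n))
    for (jn in names(jpos)) {
      jp <- jpos[[jn]]                      # junction sits before position jp
      spanning <- which(vapply(covers, function(pos) {
        (((jp - 1L) %% n) %in% pos) && (jp %in% pos)
      }, logical(1)))
      # nearest feature end before the junction / start after it
      dist_before <- vapply(covers, function(pos) min((jp - 1L - pos) %% n), integer(1))
      dist_after <- vapply(covers, function(pos) min((pos - jp) %% n), integer(1))
      before <- setdiff(order(dist_before)[1L], spanning)
      after <- setdiff(order(dist_after)[1L], spanning)
      add <- function(i, side) {
        jrows[[length(jrows) + 1L]] <<- data.frame(
          junction = jn, gene = feats[[i]]$name, side = side,
          partial = grepl("^IR-partial", asg$region[i]), stringsAsFactors = FALSE)
      }
      for (i in before) add(i, "before")
      for (i in spanning) add(i, "spanning")
      for (i in after) add(i, "after")
    }
  }
  junctions <- do.call(rbind, jrows) %||%
    data.frame(junction = character(0), gene = character(0), side = character(0),
               partial = logical(0))
  base::structure(list(assignments = asg, junctions = junctions),
                  class = "gene_region_assignment")
}

#' @export
print.gene_region_assignment <- function(x, ...) {
  cat(sprintf("<gene_region_assignment> %d features\n", nrow(x$assignments)))
  print(table(x$assignments$region))
  invisible(x)
}

# per-record gene inventory used by gene_content_diff
gene_inventory <- function(record) {
  if (!length(record$features)) return(data.frame(gene = character(0), copies = integer(0),
                                                  pseudo = logical(0), introns = integer(0)))
  nm <- vapply(record$features, function(f) f$name, character(1))
  introns <- vapply(record$features, function(f) nrow(f$intervals) - 1L, integer(1))
  pseudo <- vapply(record$features, function(f) f$pseudo, logical(1))
  out <- lapply(split(seq_along(nm), nm), function(ix) {
    data.frame(gene = nm[ix[1]], copies = length(ix), pseudo = any(pseudo[ix]),
               introns = max(introns[ix]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare gene content of two plastomes
#'
#' Set differences of the normalized gene inventories, pseudogene-status
#' differences among shared genes, and per-gene intron-count (multi-interval
#' features: intervals minus one) and copy-number differences.
#'
#' @param a,b [plastome_record()] objects with normalized feature names.
#' @return An object of class `content_diff`: list with `only_in_a`,
#'   `only_in_b` (character vectors), `pseudo_diff`, `intron_diff`,
#'   `copy_diff` (data frames).
#' @export
gene_content_diff <- function(a, b) {
  ia <- gene_inventory(a); ib <- gene_inventory(b)
  if (!nrow(ia) || !nrow(ib)) warning("empty feature table; diff is empty")
  shared <- intersect(ia$gene, ib$gene)
  sa <- ia[match(shared, ia$gene), ]; sb <- ib[match(shared, ib$gene), ]
  pd <- shared[sa$pseudo != sb$pseudo]
  pseudo_diff <- data.frame(gene = pd,
                            pseudo_in = ifelse(sa$pseudo[match(pd, shared)],
                                               a$identifier, b$identifier),
                            stringsAsFactors = FALSE)
  idx <- sa$introns != sb$introns
  intron_diff <- data.frame(gene = shared[idx], introns_a = sa$introns[idx],
                            introns_b = sb$introns[idx], stringsAsFactors = FALSE)
  cdx <- sa$copies != sb$copies
  copy_diff <- data.frame(gene = shared[cdx], copies_a = sa$copies[cdx],
                          copies_b = sb$copies[cdx], stringsAsFactors = FALSE)
  structure(list(a = a$identifier, b = b$identifier,
                 only_in_a = setdiff(ia$gene, ib$gene),
                 only_in_b = setdiff(ib$gene, ia$gene),
                 pseudo_diff = pseudo_diff, intron_diff = intron_diff,
                 copy_diff = copy_diff),
            class = "content_diff")
}

#' @export
print.content_diff <- function(x, ...) {
  cat(sprintf("<content_diff> %s vs %s\n", x$a, x$b))
  cat(sprintf("  only in %s: %s\n", x$a,
              if (length(x$only_in_a)) paste(x$only_in_a, collapse = ", ") else "(none)"))
  cat(sprintf("  only in %s: %s\n", x$b,
              if (length(x$only_in_b)) paste(x$only_in_b, collapse = ", ") else "(none)"))
  cat(sprintf("  pseudo status differs: %d, intron counts differ: %d, copy numbers differ: %d\n",
              nrow(x$pseudo_diff), nrow(x$intron_diff), nrow(x$copy_diff)))
  invisible(x)
}
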