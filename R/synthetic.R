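# Ground-truthed synthetic data generators.
#
# Each generator takes an explicit seed (never global RNG state), returns
# its output together with a truth log sufficient to score the
# corresponding analysis exactly, and is byte-reproducible: the same
# parameters and seed give identical output. The generators emulate the
# statistical structure the analyses assume — a quadripartite circle with a
# planted inverted repeat and repeat-free flanks, signed gene orders
# differing by known reversals and region relabelings, alignments whose
# gaps arise from indel events placed on known branches, and coding
# sequences with tunable codon bias — not realistic substitution processes.

random_dna <- function(n, gc = 0.35) {
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  dna_collapse(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p))
}

#' Generate a quadripartite plastome with a planted inverted repeat
#'
#' Builds a circular record LSC + IRA + SSC + revcomp(IRA). Rejection
#' sampling guarantees the planted pair is the unique maximal inverted
#' repeat: candidate sequences harboring any incidental inverted repeat of
#' 50 bp or more outside the planted pair are discarded, which makes
#' detector tests exact. Genes (`orf1`, `orf2`, ...) are placed without
#' overlap; genes falling in IRA are mirrored into IRB as a second copy.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp (`lsc_len >=
#'   ssc_len`; `ir_len = 0` plants no repeat).
#' @param n_genes Number of genes to place.
#' @param gc_target Genome G/C fraction (achieved within one point).
#' @param seed Integer seed.
#' @param straddle Number of genes forced to straddle region junctions.
#' @return A list with `record` ([plastome_record()]) and `truth` (list:
#'   parameters, planted region intervals as `list(start, length)`, gene
#'   placements).
#' @export
gen_plastome <- function(lsc_len, ssc_len, ir_len, n_genes = 12L, gc_target = 0.35,
                         seed = 1L, straddle = 0L) {
  lsc_len <- as.integer(lsc_len); ssc_len <- as.integer(ssc_len)
  ir_len <- as.integer(ir_len); n_genes <- as.integer(n_genes)
  stopifnot(lsc_len > 0L, ssc_len > 0L, ir_len >= 0L, lsc_len >= ssc_len)
  with_seed(seed, {
    total <- lsc_len + ssc_len + 2L * ir_len
    accepted <- FALSE
    for (try in 1:50) {
      lsc <- random_dna(lsc_len, gc_target)
      ssc <- random_dna(ssc_len, gc_target)
      ira <- if (ir_len > 0L) random_dna(ir_len, gc_target) else ""
      seqn <- paste0(lsc, ira, ssc, if (ir_len > 0L) revcomp(ira) else "")
      gc <- gc_content(seqn)
      if (abs(gc - gc_target) > 0.01) next
      det <- detect_inverted_repeat(plastome_record("tmp", seqn), min_length = 50L)
      accepted <- if (ir_len >= 50L) {
        !is.null(det) && det$ir_length == ir_len &&
          det$ira$start == lsc_len && det$irb$start == lsc_len + ir_len + ssc_len
      } else is.null(det)
      if (accepted) break
    }
    if (!accepted) stop("gen_plastome: could not build a repeat-free circle", call. = FALSE)

    regions <- list(lsc = list(start = 0L, length = lsc_len),
                    ira = list(start = lsc_len, length = ir_len),
                    ssc = list(start = lsc_len + ir_len, length = ssc_len),
                    irb = list(start = lsc_len + ir_len + ssc_len, length = ir_len))

    # gene placement: non-overlapping intervals inside LSC, SSC and IRA
    feats <- list()
    occupied <- matrix(integer(0), ncol = 2L)
    overlaps <- function(s, e) {
      nrow(occupied) > 0L && any(pmax(occupied[, 1L], s) < pmin(occupied[, 2L], e))
    }
    place <- function(s, e, name, mirror = TRUE) {
      strand <- sample(c(1L, -1L), 1L)
      feats[[length(feats) + 1L]] <<- gene_feature(name, strand, c(s, e), kind = "CDS")
      occupied <<- rbind(occupied, c(s, e))
      # a gene fully inside IRA has an exact mirrored copy in IRB
      if (mirror && ir_len > 0L && s >= lsc_len && e <= lsc_len + ir_len) {
        b_start <- regions$irb$start + (regions$ira$start + ir_len - e)
        feats[[length(feats) + 1L]] <<- gene_feature(name, -strand,
                                                     c(b_start, b_start + (e - s)),
                                                     kind = "CDS")
        occupied <<- rbind(occupied, c(b_start, b_start + (e - s)))
      }
    }
    gi <- 0L
    if (straddle > 0L) {
      junctions <- c(regions$ira$start, regions$ssc$start,
                     regions$irb$start, 0L)[seq_len(min(straddle, 4L))]
      for (jp in junctions) {
        gi <- gi + 1L
        len <- 90L
        s <- (jp - len %/% 2L) %% total
        e <- s + len
        if (e <= total && !overlaps(s, e)) place(s, e, paste0("orf", gi), mirror = FALSE)
      }
    }
    zones <- rbind(c(0L, lsc_len), c(lsc_len + ir_len, lsc_len + ir_len + ssc_len))
    if (ir_len >= 200L) zones <- rbind(zones, c(lsc_len, lsc_len + ir_len))
    while (gi < n_genes) {
      gi <- gi + 1L
      placed <- FALSE
      for (attempt in 1:200) {
        z <- zones[sample(nrow(zones), 1L, prob = zones[, 2L] - zones[, 1L]), ]
        len <- 3L * sample(20:50, 1L)
        if (z[2L] - z[1L] < len + 2L) next
        s <- z[1L] + sample.int(z[2L] - z[1L] - len, 1L) - 1L
        e <- s + len
        if (!overlaps(s, e)) { place(s, e, paste0("orf", gi)); placed <- TRUE; break }
      }
      if (!placed) stop(sprintf("gen_plastome: cannot place %d genes", n_genes), call. = FALSE)
    }
    rec <- plastome_record(sprintf("synth_%d", seed), seqn, circular = TRUE,
                           features = feats, source = "synthetic")
    truth <- list(seed = seed,
                  params = list(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
                                n_genes = n_genes, gc_target = gc_target),
                  regions = regions,
                  genes = data.frame(
                    gene = vapply(feats, function(f) f$name, character(1)),
                    start = vapply(feats, function(f) f$intervals[1L, 1L], integer(1)),
                    end = vapply(feats, function(f) f$intervals[nrow(f$intervals), 2L], integer(1)),
                    strand = vapply(feats, function(f) f$strand, integer(1)),
                    stringsAsFactors = FALSE))
    list(record = rec, truth = truth)
  })
}

#' Generate a pair of signed gene orders differing by known events
#'
#' The first order is `orf1..orfN` with random strands and contiguous
#' region labels (LSC, IR, SSC). The second applies `k_reversals`
#' non-overlapping signed block reversals (recorded with their endpoint
#' genes) and `n_translocations` single-gene region relabelings
#' (LSC <-> SSC).
#'
#' @param n_genes Number of genes.
#' @param k_reversals Number of non-overlapping reversals.
#' @param n_translocations Number of region relabelings.
#' @param seed Integer seed.
#' @return List with `a`, `b` ([signed_gene_order()]) and `truth` (list
#'   with an `operations` data frame).
#' @export
gen_rearranged_pair <- function(n_genes = 30L, k_reversals = 1L,
                                n_translocations = 0L, seed = 1L) {
  stopifnot(n_genes >= 4L)
  with_seed(seed, {
    genes <- paste0("orf", seq_len(n_genes))
    strands <- sample(c(1L, -1L), n_genes, replace = TRUE)
    n_lsc <- max(1L, round(0.6 * n_genes)); n_ir <- max(1L, round(0.15 * n_genes))
    n_ssc <- n_genes - n_lsc - n_ir
    regions <- stats::setNames(rep(c("LSC", "IR", "SSC"), c(n_lsc, n_ir, n_ssc)), genes)

    # choose non-overlapping reversal windows (never position 1, so the
    # circular anchor gene stays put and endpoints are unambiguous)
    used <- rep(FALSE, n_genes)
    used[1L] <- TRUE
    ops <- list()
    bg <- genes; bs <- strands
    for (r in seq_len(k_reversals)) {
      placed <- FALSE
      for (attempt in 1:200) {
        w <- sample(2:min(8L, n_genes - 2L), 1L)
        i <- sample.int(n_genes - w - 1L, 1L) + 1L
        j <- i + w - 1L
        if (any(used[i:j])) next
        used[i:j] <- TRUE
        ops[[length(ops) + 1L]] <- data.frame(type = "reversal",
                                              start_index = i, end_index = j,
                                              start_gene = genes[i], end_gene = genes[j],
                                              stringsAsFactors = FALSE)
        bg[i:j] <- rev(bg[i:j]); bs[i:j] <- -rev(bs[i:j])
        placed <- TRUE; break
      }
      if (!placed) stop("gen_rearranged_pair: cannot place non-overlapping reversals",
                        call. = FALSE)
    }
    regions_b <- regions
    free <- which(!used)
    if (n_translocations > length(free))
      stop("gen_rearranged_pair: too many translocations requested", call. = FALSE)
    for (tr in seq_len(n_translocations)) {
      g <- genes[free[tr]]
      from <- regions[[g]]
      to <- if (from == "LSC") "SSC" else "LSC"
      regions_b[g] <- to
      ops[[length(ops) + 1L]] <- data.frame(type = "translocation", start_index = free[tr],
                                            end_index = free[tr], start_gene = g,
                                            end_gene = g, stringsAsFactors = FALSE)
    }
    a <- signed_gene_order("synthA", genes, strands, regions = regions)
    b <- signed_gene_order("synthB", bg, bs, regions = regions_b[bg])
    list(a = a, b = b,
         truth = list(seed = seed, operations = do.call(rbind, ops) %||%
                        data.frame(type = character(0), start_index = integer(0),
                                   end_index = integer(0), start_gene = character(0),
                                   end_gene = character(0))))
  })
}

#' Generate a gene alignment with indel events planted on tree branches
#'
#' Starts from identical (substitution-free) sequences for all taxa and
#' plants indel events on branches: each branch receives a Poisson number
#' of events; a deletion gaps the span in all leaves below the branch, an
#' insertion gaps it in all other leaves (the stretch is present only below
#' the branch). Spans never share boundaries, never overlap, start at codon
#' boundaries, and in frame-preserving mode have lengths that are multiples
#' of 3. Events on pendant branches are autapomorphic, on internal branches
#' synapomorphic; `homoplasy_pairs` additionally plants identical spans on
#' two incompatible pendant branches, giving homoplastic characters.
#'
#' @param tree An `ape::phylo` tree.
#' @param n_genes Number of gene partitions.
#' @param events_per_branch Poisson rate of events per branch.
#' @param frame_preserving Plant only codon-multiple spans.
#' @param homoplasy_pairs Number of deliberately homoplastic characters.
#' @param seed Integer seed.
#' @return List with `alignment` ([plastome_alignment()]) and `truth`
#'   (data frame `events`: gene, 0-based span, type, branch child node,
#'   affected taxa, true category).
#' @export
gen_indel_alignment <- function(tree, n_genes = 3L, events_per_branch = 0.5,
                                frame_preserving = TRUE, homoplasy_pairs = 0L,
                                seed = 1L) {
  stopifnot(inherits(tree, "phylo"), events_per_branch >= 0)
  with_seed(seed, {
    taxa <- tree$tip.label
    gene_codons <- sample(40:80, n_genes, replace = TRUE)
    gene_len <- 3L * gene_codons
    offsets <- cumsum(c(0L, gene_len[-n_genes]))
    total <- sum(gene_len)
    base <- random_dna(total, gc = 0.4)
    rows <- matrix(rep(dna_chars(base), length(taxa)), nrow = length(taxa), byrow = TRUE)
    rownames(rows) <- taxa

    below <- clade_tips(tree)
    edge <- tree$edge
    is_pendant <- edge[, 2L] <= length(taxa)

    spans <- matrix(integer(0), ncol = 2L)
    events <- list()
    margin <- 3L
    pick_span <- function() {
      for (attempt in 1:200) {
        g <- sample.int(n_genes, 1L)
        len <- if (frame_preserving) 3L * sample(1:3, 1L) else sample(2:9, 1L)
        lo <- offsets[g] + margin
        hi <- offsets[g] + gene_len[g] - margin - len
        if (hi <= lo) next
        s <- if (frame_preserving) {
          cands <- seq.int(lo, hi, by = 3L)
          cands[sample.int(length(cands), 1L)]
        } else lo + sample.int(hi - lo, 1L) - 1L
        e <- s + len
        # keep a buffer column between spans: touching gaps would merge into
        # one run and change character boundaries
        if (nrow(spans) && any(pmax(spans[, 1L], s - 1L) < pmin(spans[, 2L], e + 1L))) next
        spans <<- rbind(spans, c(s, e))
        return(list(gene = g, start = s, end = e))
      }
      stop("gen_indel_alignment: event rate too high, spans collide", call. = FALSE)
    }
    apply_gap <- function(who, s, e) rows[who, (s + 1L):e] <<- "-"

    for (ei in seq_len(nrow(edge))) {
      k <- stats::rpois(1L, events_per_branch)
      if (k == 0L) next
      clade <- below[[edge[ei, 2L]]]
      if (length(clade) == length(taxa)) next
      for (ev in seq_len(k)) {
        sp <- pick_span()
        type <- sample(c("deletion", "insertion"), 1L)
        affected <- if (type == "deletion") clade else setdiff(taxa, clade)
        gapped <- if (type == "deletion") clade else setdiff(taxa, clade)
        apply_gap(gapped, sp$start, sp$end)
        events[[length(events) + 1L]] <- data.frame(
          gene = paste0("gene", sp$gene), start = sp$start, end = sp$end,
          type = type, node = edge[ei, 2L],
          taxa = paste(sort(gapped), collapse = ";"),
          category = if (is_pendant[ei]) "autapomorphic" else "synapomorphic",
          stringsAsFactors = FALSE)
      }
    }
    if (homoplasy_pairs > 0L) {
      pend <- which(is_pendant)
      for (hp in seq_len(homoplasy_pairs)) {
        # two tips that are not sisters: their union is not a clade
        pair <- NULL
        for (attempt in 1:200) {
          cand <- sample(pend, 2L)
          t2 <- c(below[[edge[cand[1L], 2L]]], below[[edge[cand[2L], 2L]]])
          is_clade <- any(vapply(below, function(x) setequal(x, t2), logical(1)))
          anti <- setdiff(taxa, t2)
          anti_clade <- any(vapply(below, function(x) setequal(x, anti), logical(1)))
          if (!is_clade && !anti_clade) { pair <- t2; break }
        }
        if (is.null(pair)) stop("gen_indel_alignment: cannot place homoplastic pair",
                                call. = FALSE)
        sp <- pick_span()
        apply_gap(pair, sp$start, sp$end)
        events[[length(events) + 1L]] <- data.frame(
          gene = paste0("gene", sp$gene), start = sp$start, end = sp$end,
          type = "deletion", node = NA_integer_,
          taxa = paste(sort(pair), collapse = ";"),
          category = "homoplastic", stringsAsFactors = FALSE)
      }
    }
    parts <- lapply(seq_len(n_genes), function(g) seq.int(offsets[g], offsets[g] + gene_len[g] - 1L))
    names(parts) <- paste0("gene", seq_len(n_genes))
    aln <- plastome_alignment(
      stats::setNames(apply(rows, 1L, paste, collapse = ""), taxa),
      partitions = parts)
    list(alignment = aln,
         truth = list(seed = seed,
                      events = do.call(rbind, events) %||%
                        data.frame(gene = character(0), start = integer(0),
                                   end = integer(0), type = character(0),
                                   node = integer(0), taxa = character(0),
                                   category = character(0))))
  })
}

#' Generate an in-frame coding sequence with tunable codon bias
#'
#' Samples amino acids uniformly, then codons within each synonymous family
#' from a mixture: with probability `bias` the family's canonical (first)
#' codon, otherwise uniformly within the family. `bias = 1` therefore uses
#' exactly one codon per amino acid (ENc 20); `bias = 0` is uniform within
#' families (ENc at the unbiased maximum). The sequence starts with ATG,
#' ends with a single TAA and contains no internal stops.
#'
#' @param n_codons Total codons including start and stop (>= 3).
#' @param bias Bias parameter in `[0, 1]`.
#' @param code Genetic code id (see [codon_usage()]).
#' @param seed Integer seed.
#' @return DNA string of length `3 * n_codons`.
#' @export
gen_codon_seq <- function(n_codons, bias = 0, code = "universal", seed = 1L) {
  stopifnot(bias >= 0, bias <= 1)
  if (n_codons < 3L) stop("gen_codon_seq: need at least 3 codons", call. = FALSE)
  with_seed(seed, {
    tab <- get_code_table(code)
    aas <- setdiff(unique(tab), "*")
    fams <- lapply(aas, function(aa) sort(names(tab)[tab == aa]))
    names(fams) <- aas
    k <- n_codons - 2L
    aa_draw <- sample(aas, k, replace = TRUE)
    # common random numbers: u decides canonical-vs-uniform, v picks within
    # the family, so raising `bias` only switches positions to the canonical
    # codon and the response is monotone
    u <- stats::runif(k)
    v <- stats::runif(k)
    codons <- vapply(seq_len(k), function(i) {
      fam <- fams[[aa_draw[i]]]
      if (u[i] < bias) fam[1L]
      else fam[min(length(fam), 1L + floor(v[i] * length(fam)))]
    }, character(1))
    paste0("ATG", paste(codons, collapse = ""), "TAA")
  })
}

#' Write a generated plastome as a GenBank-style flat file
#'
#' Minimal flat-file writer (LOCUS, ACCESSION, FEATURES with gene/CDS/tRNA/
#' rRNA keys and join/complement locations, ORIGIN) so that synthetic
#' fixtures exercise the real parser. Not a general-purpose GenBank writer.
#'
#' @param record A [plastome_record()].
#' @param path Output path.
#' @export
write_plastome_flatfile <- function(record, path) {
  con <- file(path, "w"); on.exit(close(con))
  n <- nchar(record$sequence)
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2000",
    record$identifier, n, if (record$circular) "circular" else "linear")
  w("DEFINITION  synthetic plastome %s.", record$identifier)
  w("ACCESSION   %s", record$identifier)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", n)
  loc_str <- function(f) {
    iv <- f$intervals
    if (f$strand == -1L) iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
    spans <- sprintf("%d..%d", iv[, 1L] + 1L, iv[, 2L])
    body <- if (length(spans) > 1L) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
    if (f$strand == -1L) sprintf("complement(%s)", body) else body
  }
  for (f in record$features) {
    key <- if (f$kind == "other") "gene" else f$kind
    w("     %s%s", formatC(key, width = -16), loc_str(f))
    w("                     /gene=\"%s\"", f$name)
    if (f$pseudo) w("                     /pseudo")
  }
  w("ORIGIN")
  pos <- seq.int(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", p, tolower(paste(groups, collapse = " ")))
  }
  w("//")
  invisible(path)
}
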