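# Independent oracles used to check the package's algorithms on small
# inputs: exhaustive scans that are too slow for real data but exact.

# maximal length of a pair of disjoint circular intervals whose sequences
# are exact reverse complements, by scanning all (start, end) anchor pairs
bf_max_ir_length <- function(seq, min_length) {
  sv <- strsplit(seq, "", fixed = TRUE)[[1]]
  cv <- chartr("ACGTN", "TGCAN", sv)
  n <- length(sv)
  disjoint <- function(a, b, L) ((b - a) %% n) >= L && ((a - b) %% n) >= L
  best <- 0L
  for (i0 in 0:(n - 1L)) {
    for (e0 in 0:(n - 1L)) {
      L <- 0L
      repeat {
        if (L >= n) break
        p <- (i0 + L) %% n
        q <- ((e0 - L) %% n + n) %% n
        if (sv[p + 1L] != cv[q + 1L]) break
        L <- L + 1L
        bs <- ((e0 - L + 1L) %% n + n) %% n
        if (L >= min_length && disjoint(i0, bs, L) && L > best) best <- L
      }
    }
  }
  best
}

# is (structure) a valid IR pair of the claimed length on seq?
valid_ir_pair <- function(seq, st) {
  ira <- plastarch:::circ_substr(seq, st$ira$start, st$ira$length)
  irb <- plastarch:::circ_substr(seq, st$irb$start, st$irb$length)
  identical(revcomp(ira), irb)
}

# minimum number of binary state changes on a tree by exhaustive enumeration
# over all internal-node assignments and all assignments of '?' leaves
bf_fitch <- function(tree, states) {
  tips <- tree$tip.label
  nt <- length(tips)
  nn <- nt + tree$Nnode
  edge <- tree$edge
  leaf_state <- states[tips]
  free_leaves <- which(is.na(leaf_state) | leaf_state == "?")
  fixed <- ifelse(is.na(leaf_state) | leaf_state == "?", NA, as.integer(leaf_state == "1"))
  internal <- (nt + 1L):nn
  best <- Inf
  n_free <- length(free_leaves)
  n_int <- length(internal)
  for (mask in 0:(2^(n_int + n_free) - 1L)) {
    assign <- fixed
    bits <- mask
    full <- integer(nn)
    full[seq_len(nt)] <- assign
    for (j in seq_len(n_int)) {
      full[internal[j]] <- bits %% 2L
      bits <- bits %/% 2L
    }
    for (j in seq_len(n_free)) {
      full[free_leaves[j]] <- bits %% 2L
      bits <- bits %/% 2L
    }
    steps <- sum(full[edge[, 1L]] != full[edge[, 2L]])
    if (steps < best) best <- steps
  }
  as.integer(best)
}

# count maximal '-' runs across both rows of a pairwise alignment
bf_gap_runs <- function(q, r) {
  count <- function(x) {
    v <- strsplit(x, "", fixed = TRUE)[[1]] == "-"
    sum(rle(v)$values)
  }
  count(q) + count(r)
}

random_dna_str <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
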