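#' Gene feature on a plastome
#'
#' A single annotated feature: a normalized gene symbol, a strand, and one
#' or more genomic intervals in 0-based half-open coordinates, listed in
#' transcription order. Intervals may wrap the origin of a circular record;
#' such intervals are split at the origin on construction so that every
#' stored interval satisfies `0 <= start < end <= length`.
#'
#' @param name Gene name (normalized with [normalize_gene_name()]).
#' @param strand `+1` or `-1`.
#' @param intervals Two-column integer matrix of `[start, end)` pairs, or a
#'   single `c(start, end)` vector.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"other"`.
#' @param pseudo Logical; `TRUE` for pseudogenes (coding constraints such as
#'   start/stop codons are not expected to hold).
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(name, strand, intervals, kind = "other", pseudo = FALSE) {
  if (is.vector(intervals)) intervals <- matrix(as.integer(intervals), ncol = 2L, byrow = TRUE)
  storage.mode(intervals) <- "integer"
  stopifnot(ncol(intervals) == 2L, nrow(intervals) >= 1L,
            strand %in% c(1L, -1L),
            kind %in% c("CDS", "tRNA", "rRNA", "other"))
  if (any(intervals[, 2L] <= intervals[, 1L]))
    stop("gene_feature: empty or inverted interval", call. = FALSE)
  structure(list(name = normalize_gene_name(name), strand = as.integer(strand),
                 intervals = intervals, kind = kind, pseudo = isTRUE(pseudo)),
            class = "gene_feature")
}

# split intervals with end > n at the origin; validate bounds
normalize_feature_intervals <- function(feature, n) {
  iv <- feature$intervals
  out <- list()
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    if (s < 0L || s >= n || e - s > n)
      stop(sprintf("feature '%s': interval [%d,%d) outside sequence of length %d",
                   feature$name, s, e, n), call. = FALSE)
    if (e <= n) {
      out[[length(out) + 1L]] <- c(s, e)
    } else {
      out[[length(out) + 1L]] <- c(s, n)
      out[[length(out) + 1L]] <- c(0L, e - n)
    }
  }
  feature$intervals <- matrix(as.integer(unlist(out)), ncol = 2L, byrow = TRUE)
  feature
}

feature_length <- function(feature) sum(feature$intervals[, 2L] - feature$intervals[, 1L])

#' Construct a plastome record
#'
#' The shared in-memory model for an annotated (usually circular) plastid
#' genome: an uppercase DNA sequence over A/C/G/T/N plus an ordered list of
#' [gene_feature()] annotations in 0-based half-open coordinates.
#'
#' @param identifier Accession or name.
#' @param sequence DNA string; ambiguity codes other than N are mapped to N
#'   with a warning.
#' @param circular Logical.
#' @param features List of [gene_feature()] objects.
#' @param source File path of origin, or `"synthetic"`.
#' @return An object of class `plastome_record`.
#' @export
plastome_record <- function(identifier, sequence, circular = TRUE,
                            features = list(), source = "synthetic") {
  sequence <- clean_dna(sequence, identifier)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  features <- lapply(features, function(f) {
    stopifnot(inherits(f, "gene_feature"))
    if (!circular && any(f$intervals[, 2L] > n))
      stop(sprintf("feature '%s' wraps the origin of a linear record", f$name),
           call. = FALSE)
    normalize_feature_intervals(f, n)
  })
  structure(list(identifier = identifier, sequence = sequence,
                 circular = isTRUE(circular), features = features,
                 source = source),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features (source: %s)\n",
              x$identifier, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              length(x$features), x$source))
  invisible(x)
}

#' Spliced sequence of a feature
#'
#' Extracts and concatenates the feature's intervals in transcription order,
#' reverse-complementing minus-strand segments.
#'
#' @param record A [plastome_record()].
#' @param feature A [gene_feature()] (or index into `record$features`).
#' @return DNA string of the spliced feature.
#' @export
feature_seq <- function(record, feature) {
  if (is.numeric(feature)) feature <- record$features[[feature]]
  parts <- vapply(seq_len(nrow(feature$intervals)), function(i) {
    s <- feature$intervals[i, 1L]; e <- feature$intervals[i, 2L]
    seg <- substr(record$sequence, s + 1L, e)
    if (feature$strand == -1L) revcomp(seg) else seg
  }, character(1))
  paste(parts, collapse = "")
}

#' Rotate the origin of a circular record
#'
#' Moves the origin forward by `k` bases; feature coordinates are remapped
#' accordingly. Useful for testing rotation invariance of downstream
#' analyses.
#'
#' @param record A circular [plastome_record()].
#' @param k Integer shift in bp.
#' @return A rotated `plastome_record`.
#' @export
rotate_record <- function(record, k) {
  if (!record$circular) stop("rotate_record: record is not circular", call. = FALSE)
  n <- nchar(record$sequence)
  k <- ((as.integer(k)) %% n + n) %% n
  seq2 <- circ_substr(record$sequence, k, n)
  feats <- lapply(record$features, function(f) {
    iv <- f$intervals
    iv2 <- matrix(0L, nrow = nrow(iv), ncol = 2L)
    for (i in seq_len(nrow(iv))) {
      s <- (iv[i, 1L] - k) %% n
      iv2[i, ] <- c(s, s + (iv[i, 2L] - iv[i, 1L]))
    }
    f$intervals <- iv2
    f
  })
  # re-merge intervals that were split at the old origin and are now contiguous
  feats <- lapply(feats, function(f) {
    iv <- f$intervals
    if (nrow(iv) >= 2L) {
      keep <- list(iv[1L, ])
      for (i in 2L:nrow(iv)) {
        last <- keep[[length(keep)]]
        if (iv[i, 1L] == last[2L] %% n && last[2L] <= n) {
          keep[[length(keep)]] <- c(last[1L], last[2L] + (iv[i, 2L] - iv[i, 1L]))
        } else keep[[length(keep) + 1L]] <- iv[i, ]
      }
      f$intervals <- matrix(as.integer(unlist(keep)), ncol = 2L, byrow = TRUE)
    }
    f
  })
  plastome_record(record$identifier, seq2, circular = TRUE, features = feats,
                  source = record$source)
}
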