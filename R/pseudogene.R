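# Pseudogene and RNA-editing screens.
#
# pairwise_screen compares a candidate region with a reference CDS: global
# affine-gap alignment (Biostrings), percent identity over all alignment
# columns (gap columns included in the denominator — the convention is
# configurable via `identity_denominator`), indel events as maximal gap runs
# in either row, and stop/start codon accounting in the reading frame
# projected from the reference through the alignment (a decayed region has
# no intact frame of its own). A precomputed alignment can be supplied
# verbatim, in which case no re-alignment happens.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# statistics on a fixed pair of aligned rows (query first)
screen_from_alignment <- function(qrow, rrow, starts = "ATG",
                                  identity_denominator = c("all", "ungapped")) {
  identity_denominator <- match.arg(identity_denominator)
  qv <- dna_chars(toupper(qrow)); rv <- dna_chars(toupper(rrow))
  if (length(qv) != length(rv)) stop("aligned rows differ in length", call. = FALSE)
  ncol <- length(qv)
  ident <- sum(qv == rv & qv != "-")
  denom <- if (identity_denominator == "all") ncol else sum(qv != "-" & rv != "-")
  gap_runs <- function(v) { r <- rle(v == "-"); sum(r$values) }
  indels <- gap_runs(qv) + gap_runs(rv)

  # project the reference frame onto the query
  ref_pos <- cumsum(rv != "-")           # 1-based ref coordinate at each column
  ref_len <- ref_pos[ncol]
  if (ref_len %% 3L != 0L)
    stop(sprintf("reference frame violation: ungapped length %d", ref_len), call. = FALSE)
  n_codons <- ref_len %/% 3L
  codons <- rep(NA_character_, n_codons)
  complete <- rep(TRUE, n_codons)
  buf <- character(3)
  for (i in seq_len(ncol)) {
    if (rv[i] == "-") next                # query insertion: outside ref frame
    p <- ref_pos[i]
    ci <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    if (qv[i] %in% c("A", "C", "G", "T")) buf[off] <- qv[i]
    else complete[ci] <- FALSE
    if (off == 3L) {
      codons[ci] <- paste(buf, collapse = "")
      buf <- character(3)
    }
  }
  ok <- complete & !is.na(codons) & grepl("^[ACGT]{3}$", codons)
  internal <- if (n_codons > 2L) {
    ix <- 2:(n_codons - 1L)
    sum(ok[ix] & codons[ix] %in% STOP_CODONS)
  } else 0L
  list(identity = 100 * ident / denom,
       indel_events = indels,
       internal_stops = as.integer(internal),
       start_present = isTRUE(ok[1L]) && codons[1L] %in% starts,
       stop_present = isTRUE(ok[n_codons]) && codons[n_codons] %in% STOP_CODONS,
       alignment_length = ncol)
}

#' Screen a candidate region against a reference CDS
#'
#' @param query Candidate DNA string (e.g. a suspected pseudogene region).
#' @param reference Reference CDS (length divisible by 3).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1/-1/-5/-1) used when no precomputed alignment is given.
#' @param alignment Optional character vector of two aligned rows (query,
#'   reference) — e.g. from [read_pairwise_alignment()] — used verbatim.
#' @param starts Accepted start codons (default strict `ATG`).
#' @param identity_denominator `"all"` divides identical columns by the full
#'   alignment length (gap columns included); `"ungapped"` by columns where
#'   neither row gaps.
#' @return An object of class `pairwise_screen_report`: percent identity,
#'   indel event count (maximal gap runs in either row), internal stop
#'   count in the reference-projected frame, start/stop presence flags and
#'   alignment length.
#' @export
pairwise_screen <- function(query, reference, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 1, alignment = NULL,
                            starts = "ATG",
                            identity_denominator = c("all", "ungapped")) {
  if (is.null(alignment)) {
    stopifnot(nzchar(query), nzchar(reference))
    if (nchar(gsub("-", "", reference)) %% 3L != 0L)
      stop("reference length not divisible by 3", call. = FALSE)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                    baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(query)),
                                        Biostrings::DNAString(toupper(reference)),
                                        type = "global", substitutionMatrix = mat,
                                        gapOpening = gap_open, gapExtension = gap_extend)
    qrow <- as.character(Biostrings::alignedPattern(pa))
    rrow <- as.character(Biostrings::alignedSubject(pa))
  } else {
    stopifnot(length(alignment) == 2L)
    qrow <- alignment[[1]]; rrow <- alignment[[2]]
  }
  res <- screen_from_alignment(qrow, rrow, starts = starts,
                               identity_denominator = identity_denominator)
  base::structure(res, class = "pairwise_screen_report")
}

#' @export
print.pairwise_screen_report <- function(x, ...) {
  cat(sprintf("<pairwise_screen_report> identity %.1f%%, %d indel events, %d internal stops, start %s, stop %s (%d columns)\n",
              x$identity, x$indel_events, x$internal_stops,
              if (x$start_present) "present" else "absent",
              if (x$stop_present) "present" else "absent", x$alignment_length))
  invisible(x)
}

#' Read a pairwise alignment (aligned FASTA or ClustalW .aln)
#'
#' @param path Path to an aligned-FASTA or CLUSTAL-format file with exactly
#'   two sequences.
#' @return Character vector of the two aligned rows, named by sequence.
#' @export
read_pairwise_alignment <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  rows <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)[-1]
    acc <- list()
    for (ln in lines) {
      if (!nzchar(trimws(ln)) || grepl("^[[:space:]]*[*:. ]+$", ln)) next
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(parts) < 2L) next
      nm <- parts[1]
      acc[[nm]] <- paste0(acc[[nm]] %||% "", parts[2])
    }
    unlist(acc)
  } else {
    x <- Biostrings::readBStringSet(path)
    stats::setNames(toupper(as.character(x)), names(x))
  }
  if (length(rows) != 2L)
    stop(sprintf("%s: expected 2 aligned sequences, found %d", path, length(rows)),
         call. = FALSE)
  rows
}

#' Scan annotated coding genes for RNA-editing hints
#'
#' For every non-pseudo CDS: flags an undetermined start when the first
#' codon is outside the accepted start set, an undetermined stop when the
#' final codon is not TAA/TAG/TGA, and an internal stop for every in-frame
#' stop codon before the final one. Such genomic anomalies hint at RNA
#' editing (or annotation problems); confirming editing requires cDNA and
#' is out of scope.
#'
#' @param record A [plastome_record()].
#' @param starts Accepted start codons (default strict `ATG`; add `"GTG"`
#'   or `"ACG"` to relax).
#' @return A list with `hints` (data frame: `gene`, `kind`, `position` —
#'   1-based codon index) and `summary` (data frame of per-kind locus
#'   counts plus the number of genes with at least one hint).
#' @export
edit_hint_scan <- function(record, starts = "ATG") {
  rows <- list()
  genes_scanned <- 0L
  for (f in record$features) {
    if (f$kind != "CDS" || f$pseudo) next
    s <- feature_seq(record, f)
    if (nchar(s) < 6L) {
      warning(sprintf("CDS '%s' shorter than 6 nt; skipped", f$name))
      next
    }
    if (nchar(s) %% 3L != 0L) {
      warning(sprintf("CDS '%s' length %d not divisible by 3; trailing bases ignored",
                      f$name, nchar(s)))
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
    genes_scanned <- genes_scanned + 1L
    st <- seq.int(1L, nchar(s), by = 3L)
    codons <- substring(s, st, st + 2L)
    nc <- length(codons)
    if (!(codons[1L] %in% starts))
      rows[[length(rows) + 1L]] <- data.frame(gene = f$name, kind = "undetermined-start",
                                              position = 1L, stringsAsFactors = FALSE)
    if (!(codons[nc] %in% STOP_CODONS))
      rows[[length(rows) + 1L]] <- data.frame(gene = f$name, kind = "undetermined-stop",
                                              position = nc, stringsAsFactors = FALSE)
    if (nc > 2L) {
      for (i in which(codons[2:(nc - 1L)] %in% STOP_CODONS)) {
        rows[[length(rows) + 1L]] <- data.frame(gene = f$name, kind = "internal-stop",
                                                position = i + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  hints <- do.call(rbind, rows) %||%
    data.frame(gene = character(0), kind = character(0), position = integer(0))
  summary <- data.frame(
    genes_scanned = genes_scanned,
    genes_with_hints = length(unique(hints$gene)),
    undetermined_start = sum(hints$kind == "undetermined-start"),
    undetermined_stop = sum(hints$kind == "undetermined-stop"),
    internal_stop = sum(hints$kind == "internal-stop"))
  list(hints = hints, summary = summary)
}

#' Find open reading frames in a region
#'
#' Maximal ATG-to-stop spans (stop codon included) of at least `min_length`
#' nucleotides, in all three forward frames and, optionally, the three
#' reverse frames. Coordinates are 0-based half-open in the forward
#' orientation of the region.
#'
#' @param region DNA string.
#' @param min_length Minimum ORF length in nt (including the stop codon).
#' @param both_strands Also scan the reverse complement.
#' @return Data frame: `start`, `end`, `strand`, `frame`, `length`.
#' @export
find_orfs <- function(region, min_length = 300L, both_strands = TRUE) {
  region <- toupper(region)
  n <- nchar(region)
  scan_fwd <- function(s, strand) {
    out <- list()
    for (fr in 0:2) {
      if (nchar(s) < fr + 3L) next
      st <- seq.int(fr + 1L, nchar(s) - 2L, by = 3L)
      st <- st[st + 2L <= nchar(s)]
      if (!length(st)) next
      codons <- substring(s, st, st + 2L)
      seg_start <- 1L                     # index into codons of current open segment
      for (i in seq_along(codons)) {
        if (codons[i] %in% STOP_CODONS) {
          seg <- seg_start:i
          atg <- seg[codons[seg] == "ATG"]
          if (length(atg)) {
            a <- atg[1L]
            len <- (i - a + 1L) * 3L
            if (len >= min_length) {
              s0 <- st[a] - 1L; e0 <- st[i] + 2L
              out[[length(out) + 1L]] <- data.frame(start = s0, end = e0,
                                                    strand = strand, frame = fr,
                                                    length = len)
            }
          }
          seg_start <- i + 1L
        }
      }
    }
    out
  }
  res <- scan_fwd(region, 1L)
  if (both_strands) {
    rres <- scan_fwd(revcomp(region), -1L)
    rres <- lapply(rres, function(d) {
      data.frame(start = n - d$end, end = n - d$start, strand = -1L,
                 frame = d$frame, length = d$length)
    })
    res <- c(res, rres)
  }
  out <- do.call(rbind, res) %||%
    data.frame(start = integer(0), end = integer(0), strand = integer(0),
               frame = integer(0), length = integer(0))
  out[order(out$start), , drop = FALSE]
}
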