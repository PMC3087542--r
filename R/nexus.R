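# NEXUS matrix reading and writing.
#
# Two dialects are supported: DNA alignments (DATA/CHARACTERS block, optional
# interleave, optional ASSUMPTIONS/SETS block with EXSET and CHARSET
# statements) and standard binary 0/1 matrices with CHARSTATELABELS (the
# indel-matrix dialect). ape's NEXUS reader covers neither exclusion sets nor
# character state labels, so the parsing lives here; trees still go through
# ape.

# strip [...] comments (non-nested) and split a NEXUS file into commands
nexus_commands <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))
    stop(sprintf("%s: not a NEXUS file (missing #NEXUS header)", path), call. = FALSE)
  txt <- gsub("\\[[^][]*\\]", "", txt)
  txt <- sub("^\\s*#NEXUS", "", txt, ignore.case = TRUE)
  cmds <- strsplit(txt, ";", fixed = TRUE)[[1]]
  cmds <- cmds[nzchar(trimws(cmds))]
  cmds
}

nexus_keyval <- function(cmd) {
  # parse KEY=VALUE tokens of a command line (values may be quoted)
  m <- gregexpr('([A-Za-z_]+)\\s*=\\s*("[^"]*"|\\S+)', cmd)[[1]]
  out <- character(0)
  if (m[1] != -1) {
    toks <- regmatches(cmd, gregexpr('([A-Za-z_]+)\\s*=\\s*("[^"]*"|\\S+)', cmd))[[1]]
    for (t in toks) {
      kv <- strsplit(t, "=", fixed = TRUE)[[1]]
      out[tolower(trimws(kv[1]))] <- gsub('^"|"$', "", trimws(paste(kv[-1], collapse = "=")))
    }
  }
  out
}

# expand a NEXUS position list like "4-6 9 12-." into 1-based integers
nexus_positions <- function(spec, nchar_total) {
  toks <- strsplit(trimws(spec), "[[:space:]]+")[[1]]
  out <- integer(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) out <- c(out, as.integer(t))
    else if (grepl("^[0-9]+-([0-9]+|\\.)$", t)) {
      ab <- strsplit(t, "-", fixed = TRUE)[[1]]
      a <- as.integer(ab[1])
      b <- if (ab[2] == ".") nchar_total else as.integer(ab[2])
      out <- c(out, seq.int(a, b))
    } else stop(sprintf("cannot parse NEXUS position token '%s'", t), call. = FALSE)
  }
  out
}

parse_nexus_matrix_rows <- function(body, interleaved) {
  # body: the text after MATRIX; returns named list of concatenated row strings
  rows <- list(); order <- character(0)
  seen_in_block <- character(0)
  for (ln in strsplit(body, "\n", fixed = TRUE)[[1]]) {
    if (!nzchar(trimws(ln))) { seen_in_block <- character(0); next }
    ln <- trimws(ln)
    parts <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", ln))[[1]]
    if (!length(parts)) {
      if (grepl("^\\S+$", ln)) parts <- c(ln, ln, "")   # zero-column row
      else stop(sprintf("cannot parse matrix row '%s'", ln), call. = FALSE)
    }
    label <- gsub("^['\"]|['\"]$", "", parts[2])
    states <- gsub("[[:space:]]", "", parts[3])
    if (label %in% names(rows)) {
      if (!interleaved)
        stop(sprintf("duplicate taxon label '%s' in non-interleaved matrix", label),
             call. = FALSE)
      if (label %in% seen_in_block) seen_in_block <- character(0)  # new block
      rows[[label]] <- paste0(rows[[label]], states)
    } else {
      rows[[label]] <- states
      order <- c(order, label)
    }
    seen_in_block <- c(seen_in_block, label)
  }
  rows[order]
}

#' Construct an alignment object
#'
#' @param rows Named character vector (or list) of equal-length aligned
#'   sequences over `A,C,G,T,N,-,?`.
#' @param partitions Named list mapping gene symbols to 0-based column index
#'   vectors (disjoint).
#' @param excluded Integer vector of 0-based excluded column indices.
#' @return An object of class `plastome_alignment` with elements `taxa`,
#'   `rows`, `partitions`, `excluded`, `ncol`.
#' @export
plastome_alignment <- function(rows, partitions = list(), excluded = integer(0)) {
  rows <- vapply(rows, toupper, character(1))
  taxa <- names(rows)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("alignment rows must be named", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L)
    stop(sprintf("ragged alignment: row lengths %s", paste(unique(widths), collapse = ", ")),
         call. = FALSE)
  nc <- widths[1]
  excluded <- sort(unique(as.integer(excluded)))
  if (length(excluded) && (min(excluded) < 0L || max(excluded) >= nc))
    stop("excluded columns outside [0, ncol)", call. = FALSE)
  if (length(partitions)) {
    all_cols <- unlist(partitions)
    if (anyDuplicated(all_cols)) stop("partitions overlap", call. = FALSE)
    if (length(all_cols) && (min(all_cols) < 0L || max(all_cols) >= nc))
      stop("partition columns outside [0, ncol)", call. = FALSE)
  }
  structure(list(taxa = taxa, rows = rows, partitions = partitions,
                 excluded = excluded, ncol = as.integer(nc)),
            class = "plastome_alignment")
}

#' @export
print.plastome_alignment <- function(x, ...) {
  cat(sprintf("<plastome_alignment> %d taxa x %d columns, %d partitions, %d excluded columns\n",
              length(x$taxa), x$ncol, length(x$partitions), length(x$excluded)))
  invisible(x)
}

#' Read a NEXUS DNA alignment with exclusion sets
#'
#' Reads a DATA or CHARACTERS block (interleaved or not) into a
#' [plastome_alignment()]. `EXSET` statements (ASSUMPTIONS or SETS block)
#' are recorded as 0-based excluded column indices, and `CHARSET` statements
#' as per-gene partitions.
#'
#' @param path Path to a NEXUS file.
#' @return A [plastome_alignment()].
#' @export
read_alignment_nexus <- function(path) {
  cmds <- nexus_commands(path)
  nchar_total <- NA_integer_; interleaved <- FALSE
  rows <- NULL; excluded <- integer(0); partitions <- list()
  for (cmd in cmds) {
    first <- tolower(sub("^\\s*(\\S+).*$", "\\1", cmd))
    if (first == "dimensions") {
      kv <- nexus_keyval(cmd)
      if (!is.na(kv["nchar"])) nchar_total <- as.integer(kv["nchar"])
    } else if (first == "format") {
      interleaved <- grepl("interleave", cmd, ignore.case = TRUE) &&
        !grepl("interleave\\s*=\\s*no", cmd, ignore.case = TRUE)
    } else if (first == "matrix") {
      body <- sub("^\\s*matrix", "", cmd, ignore.case = TRUE)
      rows <- parse_nexus_matrix_rows(body, interleaved)
    } else if (first == "exset") {
      spec <- sub("^[^=]*=", "", cmd)
      nc <- if (!is.na(nchar_total)) nchar_total else max(nchar(unlist(rows)))
      excluded <- c(excluded, nexus_positions(spec, nc) - 1L)
    } else if (first == "charset") {
      nm <- sub("^\\s*charset\\s+(\\*\\s*)?('[^']+'|\\S+)\\s*=.*$", "\\2", cmd,
                ignore.case = TRUE)
      nm <- gsub("^'|'$", "", nm)
      spec <- sub("^[^=]*=", "", cmd)
      nc <- if (!is.na(nchar_total)) nchar_total else max(nchar(unlist(rows)))
      partitions[[nm]] <- nexus_positions(spec, nc) - 1L
    }
  }
  if (is.null(rows)) stop(sprintf("%s: no MATRIX command found", path), call. = FALSE)
  rows <- unlist(rows)
  if (!is.na(nchar_total) && any(nchar(rows) != nchar_total))
    stop(sprintf("%s: row lengths disagree with NCHAR=%d", path, nchar_total),
         call. = FALSE)
  plastome_alignment(rows, partitions = partitions, excluded = excluded)
}

#' Write a NEXUS DNA alignment
#'
#' Inverse of [read_alignment_nexus()]: writes the matrix plus CHARSET
#' statements for partitions and an EXSET for excluded columns.
#'
#' @param aln A [plastome_alignment()].
#' @param path Output path.
#' @export
write_alignment_nexus <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("  DIMENSIONS NTAX=%d NCHAR=%d;", length(aln$taxa), aln$ncol)
  w("  FORMAT DATATYPE=DNA MISSING=? GAP=-;")
  w("  MATRIX")
  pad <- max(nchar(aln$taxa)) + 2L
  for (t in aln$taxa) w("  %s%s", formatC(t, width = -pad), aln$rows[[t]])
  w("  ;")
  w("END;")
  if (length(aln$partitions) || length(aln$excluded)) {
    w("BEGIN SETS;")
    for (nm in names(aln$partitions)) {
      cols <- sort(aln$partitions[[nm]]) + 1L
      w("  CHARSET %s = %s;", nm, compress_positions(cols))
    }
    if (length(aln$excluded))
      w("  EXSET * excluded = %s;", compress_positions(aln$excluded + 1L))
    w("END;")
  }
  invisible(path)
}

# compress sorted 1-based positions into "a-b c d-e" runs
compress_positions <- function(pos) {
  pos <- sort(unique(pos))
  breaks <- c(0L, which(diff(pos) != 1L), length(pos))
  parts <- vapply(seq_len(length(breaks) - 1L), function(i) {
    seg <- pos[(breaks[i] + 1L):breaks[i + 1L]]
    if (length(seg) == 1L) as.character(seg) else sprintf("%d-%d", seg[1], seg[length(seg)])
  }, character(1))
  paste(parts, collapse = " ")
}

# ---- binary matrices --------------------------------------------------------

#' Construct a binary indel matrix
#'
#' @param cells Character matrix with values in `0`, `1`, `?`; rownames are
#'   taxon labels, colnames are character labels (`<gene>_<position>`).
#' @return An object of class `indel_binary_matrix` with elements `taxa`,
#'   `characters` and `cells`.
#' @export
binary_matrix <- function(cells) {
  stopifnot(is.matrix(cells))
  if (length(cells) && !all(cells %in% c("0", "1", "?")))
    stop("binary matrix cells must be 0, 1 or ?", call. = FALSE)
  taxa <- rownames(cells); chars <- colnames(cells)
  if (is.null(taxa) || anyDuplicated(taxa)) stop("taxa labels missing or duplicated", call. = FALSE)
  if (ncol(cells) > 0L && (is.null(chars) || anyDuplicated(chars)))
    stop("character labels missing or duplicated", call. = FALSE)
  structure(list(taxa = taxa, characters = chars %||% character(0), cells = cells),
            class = "indel_binary_matrix")
}

#' @export
print.indel_binary_matrix <- function(x, ...) {
  cat(sprintf("<indel_binary_matrix> %d taxa x %d characters\n",
              length(x$taxa), length(x$characters)))
  invisible(x)
}

#' Write a binary matrix as NEXUS with CHARSTATELABELS
#'
#' Writes `FORMAT SYMBOLS="01" MISSING=?` and a CHARSTATELABELS list naming
#' every character; [read_binary_matrix_nexus()] round-trips the file back
#' to an identical matrix.
#'
#' @param matrix A [binary_matrix()].
#' @param path Output path.
#' @export
write_binary_matrix_nexus <- function(matrix, path) {
  stopifnot(inherits(matrix, "indel_binary_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  nch <- length(matrix$characters)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("  DIMENSIONS NTAX=%d NCHAR=%d;", length(matrix$taxa), nch)
  w("  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;")
  if (nch > 0L) {
    labs <- vapply(seq_len(nch), function(i) {
      sprintf("    %d %s%s", i, matrix$characters[i], if (i < nch) "," else "")
    }, character(1))
    w("  CHARSTATELABELS")
    writeLines(labs, con)
    w("  ;")
  }
  w("  MATRIX")
  pad <- max(nchar(matrix$taxa)) + 2L
  for (t in matrix$taxa) {
    row <- if (nch > 0L) paste(matrix$cells[t, ], collapse = "") else ""
    w("  %s%s", formatC(t, width = -pad), row)
  }
  w("  ;")
  w("END;")
  invisible(path)
}

#' Read a NEXUS binary matrix with CHARSTATELABELS
#'
#' @param path Path to a NEXUS file written in the 0/1 standard-data dialect.
#' @return A [binary_matrix()].
#' @export
read_binary_matrix_nexus <- function(path) {
  cmds <- nexus_commands(path)
  nchar_total <- NA_integer_; interleaved <- FALSE
  rows <- NULL; labels <- NULL
  for (cmd in cmds) {
    first <- tolower(sub("^\\s*(\\S+).*$", "\\1", cmd))
    if (first == "dimensions") {
      kv <- nexus_keyval(cmd)
      if (!is.na(kv["nchar"])) nchar_total <- as.integer(kv["nchar"])
    } else if (first == "format") {
      interleaved <- grepl("interleave", cmd, ignore.case = TRUE)
    } else if (first == "charstatelabels") {
      body <- sub("^\\s*charstatelabels", "", cmd, ignore.case = TRUE)
      items <- strsplit(body, ",", fixed = TRUE)[[1]]
      labels <- character(length(items))
      for (it in items) {
        toks <- strsplit(trimws(it), "[[:space:]]+")[[1]]
        labels[as.integer(toks[1])] <- toks[2]
      }
    } else if (first == "matrix") {
      body <- sub("^\\s*matrix", "", cmd, ignore.case = TRUE)
      rows <- parse_nexus_matrix_rows(body, interleaved)
    }
  }
  if (is.null(rows)) stop(sprintf("%s: no MATRIX command found", path), call. = FALSE)
  nch <- if (!is.na(nchar_total)) nchar_total else max(c(0L, nchar(unlist(rows))))
  if (any(nchar(unlist(rows)) != nch))
    stop(sprintf("%s: ragged binary matrix", path), call. = FALSE)
  taxa <- names(rows)
  cells <- matrix("?", nrow = length(taxa), ncol = nch,
                  dimnames = list(taxa, labels %||% (if (nch) paste0("char_", seq_len(nch)) else NULL)))
  for (t in taxa) if (nch > 0L) cells[t, ] <- strsplit(rows[[t]], "", fixed = TRUE)[[1]]
  binary_matrix(cells)
}

# ---- trees and FASTA --------------------------------------------------------

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with up-front validation: balanced parentheses,
#' at least two leaves, unique leaf labels. Polytomies are preserved.
#'
#' @param path Path to a Newick file (or a literal Newick string).
#' @return An `ape::phylo` tree.
#' @export
read_tree_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "") else path
  opens <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  closes <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (opens != closes)
    stop(sprintf("Newick parse error: %d '(' vs %d ')'", opens, closes), call. = FALSE)
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tree)) stop("Newick parse error", call. = FALSE)
  if (length(tree$tip.label) < 2L) stop("tree has fewer than 2 leaves", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate leaf labels: %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")),
         call. = FALSE)
  tree
}

#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings returning/accepting named character vectors.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
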