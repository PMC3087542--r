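#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

dna_collapse <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character strings over the alphabet A, C, G, T, N.
#'
#' @param x A DNA string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# complement of a character vector of bases (no reversal)
comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

# Clean a raw sequence string: uppercase, map ambiguity codes other than N
# to N (with a warning), reject anything non-nucleotide.
clean_dna <- function(x, what = "sequence") {
  x <- toupper(gsub("[[:space:][:digit:]]", "", x))
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    amb <- unique(dna_chars(bad))
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
    if (!all(amb %in% iupac)) {
      stop(sprintf("%s contains non-nucleotide characters: %s", what,
                   paste(setdiff(amb, iupac), collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("%s: ambiguity codes mapped to N (%s)", what,
                    paste(amb, collapse = ", ")), call. = FALSE)
    x <- chartr("UuRYSWKMBDHV", "TTNNNNNNNNNN", x)
  }
  x
}

# Evaluate `code` with the RNG seeded to `seed`, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Alias table for gene symbol spellings seen across GenBank records.
GENE_ALIASES <- c(
  "rrn16s"  = "rrn16",
  "rrn23s"  = "rrn23",
  "rrn5s"   = "rrn5",
  "rrn4.5s" = "rrn4.5",
  "16s"     = "rrn16",
  "23s"     = "rrn23",
  "4.5s"    = "rrn4.5",
  "5s"      = "rrn5",
  "psbzc"   = "psbZ",
  "ycf15orf" = "ycf15"
)

upper_letters <- function(x) {
  chartr("abcdefghijklmnopqrstuvwxyz", "ABCDEFGHIJKLMNOPQRSTUVWXYZ", x)
}

#' Normalize plastid gene symbols
#'
#' Maps gene names from heterogeneous annotations into one symbol space:
#' three-letter lowercase stem with uppercased suffix (`psbA`, `rpoC1`,
#' `ycf2`, `rrn16`), and tRNAs as `trnX-ANT` with an RNA-alphabet anticodon
#' (`trnI-CAU`, `trnfM-CAU`). A small alias table resolves known spelling
#' variants.
#'
#' @param names Character vector of raw gene names.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_gene_name(c("PSBA", "trni-cau", "RPOC1", "rrn16S"))
normalize_gene_name <- function(names) {
  vapply(names, function(nm) {
    nm <- gsub("[[:space:]]+", "", nm)
    low <- tolower(nm)
    if (!is.na(GENE_ALIASES[low])) return(unname(GENE_ALIASES[low]))
    if (grepl("^trn", low)) {
      m <- regmatches(low, regexec("^trn(f?)([a-z])(?:[-_]?([acgtu]{3}))?", low))[[1]]
      if (length(m) == 4L && nzchar(m[3])) {
        out <- paste0("trn", m[2], toupper(m[3]))
        if (nzchar(m[4])) {
          out <- paste0(out, "-", toupper(chartr("t", "u", m[4])))
        }
        return(out)
      }
    }
    if (nchar(low) <= 3L) return(low)
    paste0(substr(low, 1L, 3L), upper_letters(substr(low, 4L, nchar(low))))
  }, character(1), USE.NAMES = FALSE)
}

# positions (0-based) covered by a feature's intervals, on a circle of size n
interval_positions <- function(intervals, n) {
  unlist(lapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals[i, 1L]; e <- intervals[i, 2L]
    if (e <= n) seq.int(s, e - 1L) else c(seq.int(s, n - 1L), seq.int(0L, e - n - 1L))
  }), use.names = FALSE)
}

# substring of a circular sequence, 0-based start, given length
circ_substr <- function(seq, start, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  start <- start %% n
  if (start + len <= n) {
    substr(seq, start + 1L, start + len)
  } else {
    paste0(substr(seq, start + 1L, n), substr(seq, 1L, start + len - n))
  }
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
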