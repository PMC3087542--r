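# Fixtures are built in code at test time; nothing binary is stored.

# raw GenBank flat-file text (exercises the parser independently of the
# package's own writer)
make_genbank_text <- function(identifier, sequence, feature_lines, circular = TRUE) {
  n <- nchar(sequence)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2000",
            identifier, n, if (circular) "circular" else "linear"),
    sprintf("DEFINITION  test fixture %s.", identifier),
    sprintf("ACCESSION   %s", identifier),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    feature_lines,
    "ORIGIN")
  pos <- seq.int(1L, n, by = 60L)
  for (p in pos) {
    chunk <- tolower(substr(sequence, p, min(p + 59L, n)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  c(out, "//")
}

gb_feature_lines <- function(key, location, gene, pseudo = FALSE) {
  out <- c(sprintf("     %s%s", formatC(key, width = -16), location),
           sprintf("                     /gene=\"%s\"", gene))
  if (pseudo) out <- c(out, "                     /pseudo")
  out
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# codon usage profiles at the two ENc extremes
uniform_profile <- function(per_codon = 10) {
  tab <- Biostrings::GENETIC_CODE
  codon_usage(paste(rep(names(tab)[tab != "*"], each = per_codon), collapse = ""))
}

degenerate_profile <- function(per_aa = 10) {
  tab <- Biostrings::GENETIC_CODE
  fams <- split(names(tab)[tab != "*"], tab[tab != "*"])
  one <- vapply(fams, function(f) sort(f)[1], character(1))
  codon_usage(paste(rep(one, each = per_aa), collapse = ""))
}

# small random binary matrix with missing data
random_binary_matrix <- function(ntax, nchar_, seed = 1) {
  set.seed(seed)
  cells <- matrix(sample(c("0", "1", "?"), ntax * nchar_, replace = TRUE,
                         prob = c(0.4, 0.5, 0.1)),
                  nrow = ntax,
                  dimnames = list(paste0("tax", seq_len(ntax)),
                                  if (nchar_) paste0("gene", seq_len(nchar_), "_", seq_len(nchar_)) else NULL))
  binary_matrix(cells)
}
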