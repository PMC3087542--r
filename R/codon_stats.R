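# Nucleotide composition and codon-usage bias.
#
# ENc is Wright's effective number of codons: for each amino acid with
# synonymy degree k and n observed codons with frequencies p_i, the codon
# homozygosity is F = (n * sum(p_i^2) - 1) / (n - 1); F-hat_k averages F
# over the amino acids of degree k, and
#   ENc = n1 + N2/F2 + N3/F3 + N4/F4 + N6/F6
# where n1 counts single-codon amino acids and Nk the degree-k families
# (universal code: 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6), capped at the code's
# maximum (61 for the universal code). Families observed fewer than twice
# are dropped from their average; a missing threefold average falls back to
# (F2 + F4)/2 (the CodonW convention); any other missing or non-positive
# family average makes ENc undefined.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

get_code_table <- function(code = "universal") {
  if (identical(code, "universal") || identical(code, "1")) {
    Biostrings::GENETIC_CODE
  } else {
    Biostrings::getGeneticCode(as.character(code))
  }
}

#' G/C content of a DNA string
#'
#' `(G + C) / (A + C + G + T)`; N, gaps and missing characters are excluded
#' from numerator and denominator, so undefined composition does not dilute
#' the statistic.
#'
#' @param sequence DNA string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  v <- dna_chars(toupper(sequence))
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  if (acgt == 0L) stop("gc_content undefined: no A/C/G/T characters", call. = FALSE)
  sum(v %in% c("G", "C")) / acgt
}

#' Codon usage profile of an in-frame coding sequence
#'
#' Counts the 64 codons; codons containing characters other than A/C/G/T
#' (e.g. N) are skipped.
#'
#' @param sequence In-frame DNA string (length divisible by 3).
#' @param code Genetic code: `"universal"` (default) or an NCBI code id such
#'   as `"11"` (plastid/bacterial).
#' @return An object of class `codon_usage_profile`: list with `counts`
#'   (named integer vector over the 64 codons), `code_id`, `code` (codon to
#'   amino acid map) and `total`.
#' @export
codon_usage <- function(sequence, code = "universal") {
  sequence <- toupper(sequence)
  if (nchar(sequence) %% 3L != 0L)
    stop(sprintf("sequence length %d not divisible by 3", nchar(sequence)), call. = FALSE)
  starts <- seq.int(1L, nchar(sequence), by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  counts <- stats::setNames(integer(64), ALL_CODONS)
  tb <- table(codons)
  counts[names(tb)] <- as.integer(tb)
  base::structure(list(counts = counts, code_id = as.character(code),
                       code = get_code_table(code), total = sum(counts)),
                  class = "codon_usage_profile")
}

#' @export
print.codon_usage_profile <- function(x, ...) {
  cat(sprintf("<codon_usage_profile> %d codons, genetic code %s\n", x$total, x$code_id))
  invisible(x)
}

# merge two profiles (same code)
pool_profiles <- function(a, b) {
  stopifnot(identical(a$code_id, b$code_id))
  a$counts <- a$counts + b$counts
  a$total <- a$total + b$total
  a
}

#' Codon homozygosity of one synonymous family
#'
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` for a family with counts `counts`
#' and `n = sum(counts)`; `NA` when `n < 2`.
#'
#' @param counts Integer vector of synonymous codon counts.
#' @return Homozygosity F, or `NA_real_`.
#' @export
family_homozygosity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (ENc)
#'
#' Wright's codon-bias statistic, from 20 (one codon per amino acid) to 61
#' (uniform synonymous usage under the universal code).
#'
#' @param profile A [codon_usage_profile()].
#' @param detail Return the per-family table and per-degree averages
#'   alongside the statistic.
#' @return The ENc value (possibly `NA` with a warning when undefined), or
#'   with `detail = TRUE` a list with `enc`, `fhat` (named by degree) and
#'   `families` (data frame: amino acid, degree, n, F).
#' @export
enc <- function(profile, detail = FALSE) {
  stopifnot(inherits(profile, "codon_usage_profile"))
  if (profile$total < 1L) stop("enc undefined: empty profile", call. = FALSE)
  code <- profile$code
  aas <- setdiff(unique(code), "*")
  fam <- lapply(aas, function(aa) names(code)[code == aa])
  deg <- vapply(fam, length, integer(1))
  Fv <- vapply(fam, function(cods) family_homozygosity(profile$counts[cods]), numeric(1))
  nv <- vapply(fam, function(cods) sum(profile$counts[cods]), numeric(1))
  families <- data.frame(aa = aas, degree = deg, n = nv, F = Fv,
                         stringsAsFactors = FALSE)
  n1 <- sum(deg == 1L)
  degrees <- sort(unique(deg[deg > 1L]))
  fhat <- stats::setNames(rep(NA_real_, length(degrees)), degrees)
  for (k in degrees) {
    vals <- Fv[deg == k & !is.na(Fv)]
    if (length(vals)) fhat[as.character(k)] <- mean(vals)
  }
  if (is.na(fhat["3"]) && "3" %in% names(fhat) &&
      !is.na(fhat["2"]) && !is.na(fhat["4"])) {
    fhat["3"] <- (fhat["2"] + fhat["4"]) / 2
  }
  if (all(is.na(fhat))) stop("enc undefined: no synonymous family estimable", call. = FALSE)
  value <- if (any(is.na(fhat) | fhat <= 0)) {
    warning("ENc undefined: some family average unestimable or non-positive")
    NA_real_
  } else {
    nk <- vapply(degrees, function(k) sum(deg == k), integer(1))
    v <- n1 + sum(nk / fhat[as.character(degrees)])
    cap <- n1 + sum(nk * degrees)
    min(v, cap)
  }
  if (detail) list(enc = unname(value), fhat = fhat, families = families)
  else unname(value)
}

#' Per-taxon G/C and ENc from a gene alignment
#'
#' For every taxon, the coding sequence of each gene partition is recovered
#' by dropping excluded columns and that taxon's gap/missing characters; the
#' per-gene codon counts are pooled into a single profile per taxon (one
#' value per taxon, not an average over genes), from which G/C percent and
#' ENc are computed. Values are rounded to 2 decimals.
#'
#' @param alignment A [plastome_alignment()]; when it has no partitions the
#'   whole matrix is treated as one in-frame gene.
#' @param taxa Taxa to report (default: all).
#' @param code Genetic code id passed to [codon_usage()].
#' @param use_exclusions Honor the alignment's excluded columns.
#' @param frame `"strict"` raises an error when a taxon/gene sequence length
#'   is not divisible by 3 after gap removal; `"trim"` drops the remainder.
#' @return Data frame: `taxon`, `n_codons`, `gc_percent`, `enc`.
#' @export
taxon_codon_report <- function(alignment, taxa = alignment$taxa, code = "universal",
                               use_exclusions = TRUE, frame = c("strict", "trim")) {
  stopifnot(inherits(alignment, "plastome_alignment"))
  frame <- match.arg(frame)
  parts <- alignment$partitions
  if (!length(parts)) parts <- list(aln = seq_len(alignment$ncol) - 1L)
  excl <- if (use_exclusions) alignment$excluded else integer(0)
  rows <- lapply(taxa, function(t) {
    chars <- dna_chars(alignment$rows[[t]])
    prof <- NULL; nt_all <- character(0)
    for (g in names(parts)) {
      cols <- sort(parts[[g]])
      cols <- setdiff(cols, excl)
      seg <- chars[cols + 1L]
      seg <- seg[seg %in% c("A", "C", "G", "T", "N")]
      if (length(seg) %% 3L != 0L) {
        if (frame == "strict")
          stop(sprintf("frame violation: taxon '%s', gene '%s' has %d aligned bases",
                       t, g, length(seg)), call. = FALSE)
        seg <- seg[seq_len(length(seg) - length(seg) %% 3L)]
      }
      if (!length(seg)) next
      p <- codon_usage(dna_collapse(seg), code = code)
      prof <- if (is.null(prof)) p else pool_profiles(prof, p)
      nt_all <- c(nt_all, seg)
    }
    if (is.null(prof) || prof$total == 0L)
      return(data.frame(taxon = t, n_codons = 0L, gc_percent = NA_real_,
                        enc = NA_real_, stringsAsFactors = FALSE))
    e <- tryCatch(enc(prof), error = function(err) {
      warning(sprintf("taxon '%s': %s", t, conditionMessage(err)))
      NA_real_
    })
    data.frame(taxon = t, n_codons = prof$total,
               gc_percent = round(100 * gc_content(dna_collapse(nt_all)), 2),
               enc = round(e, 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
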