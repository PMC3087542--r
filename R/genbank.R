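# GenBank flat-file reading.
#
# Only what plastome work needs: LOCUS (length, circular/linear), ACCESSION,
# the FEATURES table restricted to gene/CDS/tRNA/rRNA keys (with compound
# join/complement locations, including origin-spanning joins on circular
# molecules), /gene, /product, /pseudo qualifiers, and the ORIGIN block.
# Coordinates are converted from GenBank 1-based inclusive to the package's
# 0-based half-open convention at this boundary and nowhere else.

# ---- location grammar -------------------------------------------------------
# location := span | "complement(" location ")" | "join(" location, ... ")"
#           | "order(" location, ... ")"
# span     := n | n..m   (with optional < > partial markers)
parse_gb_location <- function(loc, line = NA) {
  loc <- gsub("[[:space:]<>]", "", loc)
  fail <- function(msg) {
    stop(sprintf("GenBank location parse failure%s: %s in '%s'",
                 if (is.na(line)) "" else sprintf(" at line %d", line), msg, loc),
         call. = FALSE)
  }
  # split a comma-separated argument list at depth 0
  split_args <- function(x) {
    depth <- 0L; cuts <- integer(0)
    cs <- strsplit(x, "", fixed = TRUE)[[1]]
    for (i in seq_along(cs)) {
      if (cs[i] == "(") depth <- depth + 1L
      else if (cs[i] == ")") depth <- depth - 1L
      else if (cs[i] == "," && depth == 0L) cuts <- c(cuts, i)
    }
    starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, nchar(x))
    mapply(function(s, e) substr(x, s, e), starts, ends, USE.NAMES = FALSE)
  }
  rec <- function(x) {
    if (grepl("^complement\\(", x)) {
      if (substr(x, nchar(x), nchar(x)) != ")") fail("unbalanced parentheses")
      inner <- rec(substr(x, 12L, nchar(x) - 1L))
      # complement: flip strand, reverse segment order (transcription order)
      list(strand = -inner$strand, spans = inner$spans[rev(seq_along(inner$spans))])
    } else if (grepl("^(join|order)\\(", x)) {
      open <- regexpr("(", x, fixed = TRUE)
      if (substr(x, nchar(x), nchar(x)) != ")") fail("unbalanced parentheses")
      parts <- lapply(split_args(substr(x, open + 1L, nchar(x) - 1L)), rec)
      strands <- vapply(parts, function(p) p$strand, integer(1))
      strand <- if (all(strands == -1L)) -1L else 1L
      spans <- do.call(c, lapply(parts, function(p) p$spans))
      if (strand == -1L && all(strands == -1L) && length(parts) > 1L) {
        # join(complement(a),complement(b)): transcription order is reversed
        spans <- do.call(c, lapply(rev(parts), function(p) p$spans))
      }
      list(strand = strand, spans = spans)
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", x)) {
      ab <- as.integer(strsplit(x, "..", fixed = TRUE)[[1]])
      list(strand = 1L, spans = list(ab))
    } else if (grepl("^[0-9]+$", x)) {
      list(strand = 1L, spans = list(c(as.integer(x), as.integer(x))))
    } else fail("unrecognized location syntax")
  }
  rec(loc)
}

# 1-based inclusive span list -> 0-based half-open interval matrix,
# in transcription order for the given strand
gb_spans_to_intervals <- function(parsed) {
  spans <- parsed$spans
  iv <- matrix(0L, nrow = length(spans), ncol = 2L)
  for (i in seq_along(spans)) {
    ab <- spans[[i]]
    if (ab[2L] < ab[1L])
      stop(sprintf("GenBank span %d..%d runs backwards", ab[1L], ab[2L]),
           call. = FALSE)
    iv[i, ] <- c(ab[1L] - 1L, ab[2L])
  }
  iv
}

#' Read an annotated plastome from a GenBank flat file
#'
#' Parses the LOCUS line (length, circular/linear topology), the FEATURES
#' table (gene, CDS, tRNA and rRNA keys, with compound `join`/`complement`
#' locations, including origin-spanning joins on circular records) and the
#' ORIGIN sequence block. Gene names are normalized with
#' [normalize_gene_name()]; `/pseudo` qualifiers set the pseudogene flag;
#' GenBank 1-based inclusive coordinates become 0-based half-open. A `gene`
#' feature is retained only when no CDS/tRNA/rRNA feature shares its name;
#' otherwise it only contributes its `/pseudo` flag to the matching feature.
#'
#' @param path Path to a GenBank flat file.
#' @return A [plastome_record()].
#' @export
read_plastome_flatfile <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)[1]
  if (is.na(locus_i))
    stop(sprintf("%s: no LOCUS line (line 1)", path), call. = FALSE)
  locus <- lines[locus_i]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "[[:space:]]+")[[1]][1]
  acc_i <- grep("^ACCESSION", lines)
  identifier <- if (length(acc_i)) {
    strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "[[:space:]]+")[[1]][1]
  } else name
  if (is.na(identifier) || !nzchar(identifier)) identifier <- name

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i))
    stop(sprintf("%s: no ORIGIN block (searched %d lines)", path, length(lines)),
         call. = FALSE)
  orig_i <- orig_i[1]

  # ---- sequence ----
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > orig_i][1] else length(lines) + 1L
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[seq.int(orig_i + 1L, end_i - 1L)]
  sequence <- clean_dna(paste(seq_lines, collapse = ""), identifier)
  n <- nchar(sequence)

  # ---- features ----
  entries <- list()
  if (length(feat_i)) {
    i <- feat_i[1] + 1L
    cur <- NULL
    flush <- function(cur) if (!is.null(cur)) entries[[length(entries) + 1L]] <<- cur
    while (i < orig_i) {
      ln <- lines[i]
      if (grepl("^ {1,10}[A-Za-z0-9_'-]+ +\\S", ln) && !grepl("^ {12,}", ln)) {
        flush(cur)
        key <- sub("^ +([A-Za-z0-9_'-]+).*$", "\\1", ln)
        loc <- trimws(sub("^ +[A-Za-z0-9_'-]+ +", "", ln))
        cur <- list(key = key, loc = loc, quals = character(0), line = i)
        # location continuation lines (no leading slash)
        while (i + 1L < orig_i && grepl("^ {12,}[^/ ]", lines[i + 1L])) {
          cur$loc <- paste0(cur$loc, trimws(lines[i + 1L]))
          i <- i + 1L
        }
      } else if (grepl("^ {12,}/", ln)) {
        q <- trimws(ln)
        # continuation lines of a long qualifier value: indented, first
        # non-space character is not a slash
        while (i + 1L < orig_i && grepl("^ {12,}[^/ ]", lines[i + 1L])) {
          q <- paste(q, trimws(lines[i + 1L]))
          i <- i + 1L
        }
        if (!is.null(cur)) cur$quals <- c(cur$quals, q)
      }
      i <- i + 1L
    }
    flush(cur)
  }

  get_qual <- function(e, qname) {
    hit <- grep(sprintf("^/%s=", qname), e$quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub('^/[^=]+="?|"$', "", hit[1])
  }
  has_flag <- function(e, qname) any(grepl(sprintf("^/%s(=|$)", qname), e$quals))

  keep_keys <- c("gene", "CDS", "tRNA", "rRNA")
  entries <- Filter(function(e) e$key %in% keep_keys, entries)
  feats <- list(); genes_only <- list()
  for (e in entries) {
    nm <- get_qual(e, "gene")
    if (is.na(nm)) nm <- get_qual(e, "product")
    if (is.na(nm)) nm <- get_qual(e, "locus_tag")
    if (is.na(nm)) next
    parsed <- parse_gb_location(e$loc, line = e$line)
    iv <- gb_spans_to_intervals(parsed)
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > n)) {
      # allow origin-wrapping represented as join(a..n, 1..b)
      stop(sprintf("%s: feature '%s' coordinates outside sequence [1,%d]",
                   path, nm, n), call. = FALSE)
    }
    kind <- if (e$key %in% c("CDS", "tRNA", "rRNA")) e$key else "other"
    f <- gene_feature(nm, parsed$strand, iv, kind = kind,
                      pseudo = has_flag(e, "pseudo") || has_flag(e, "pseudogene"))
    if (e$key == "gene") genes_only[[length(genes_only) + 1L]] <- f
    else feats[[length(feats) + 1L]] <- f
  }
  feat_names <- vapply(feats, function(f) f$name, character(1))
  for (g in genes_only) {
    hit <- which(feat_names == g$name)
    if (length(hit)) {
      if (g$pseudo) for (h in hit) feats[[h]]$pseudo <- TRUE
    } else {
      feats[[length(feats) + 1L]] <- g
      feat_names <- c(feat_names, g$name)
    }
  }
  # order features by first genomic position
  ord <- order(vapply(feats, function(f) f$intervals[1L, 1L], integer(1)))
  plastome_record(identifier, sequence, circular = circular,
                  features = feats[ord], source = path)
}
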