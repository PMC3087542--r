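# Pipeline orchestration: run the full comparative analysis over a set of
# genomes (+ optional alignment, indel matrix and tree) and write the report
# tables as TSV plus a machine-readable JSON run log. Stages are isolated:
# a failure in one stage is recorded and does not corrupt the outputs of
# completed stages. Report content is deterministic for fixed inputs and
# seed (timings live only in the run log).

PIPELINE_KEYS <- c("genomes", "alignment", "indel_matrix", "tree", "out_dir",
                   "collapse_ir", "include_trnas", "genetic_code",
                   "min_ir_length", "start_codons", "label_map", "seed")

#' Validate a pipeline configuration
#'
#' @param config Named list (or path to a YAML file) with keys: `genomes`
#'   (character vector of GenBank flat-file paths), optional `alignment`
#'   (NEXUS), `indel_matrix` (NEXUS), `tree` (Newick), `out_dir`, and flags
#'   `collapse_ir`, `include_trnas`, `genetic_code`, `min_ir_length`,
#'   `start_codons`, `label_map`, `seed`. Unknown keys are rejected and all
#'   referenced paths must exist.
#' @return The validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(config$genomes) || !length(config$genomes))
    stop("config needs at least one genome", call. = FALSE)
  for (p in c(config$genomes, config$alignment, config$indel_matrix, config$tree)) {
    if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p), call. = FALSE)
  }
  config$out_dir <- config$out_dir %||% "plastarch_report"
  config$collapse_ir <- config$collapse_ir %||% TRUE
  config$include_trnas <- config$include_trnas %||% TRUE
  config$genetic_code <- config$genetic_code %||% "universal"
  config$min_ir_length <- as.integer(config$min_ir_length %||% 1000L)
  config$start_codons <- config$start_codons %||% "ATG"
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full comparative report
#'
#' Executes all stages over the configured inputs and writes, under
#' `out_dir`: `architecture.tsv` (per genome: total/LSC/SSC/IR lengths and
#' G/C), `junctions.tsv` (IR junction gene tables), `gene_order.tsv`,
#' `synteny_blocks.tsv` and `translocations.tsv` (pairwise comparisons),
#' `indel_matrix.nex` + `indel_classification.tsv` + `indel_summary.tsv`
#' (when an alignment or matrix and tree are given), `codon_usage.tsv`
#' (per-taxon G/C% and ENc) and `edit_hints.tsv`, plus `run_log.json` with
#' package version, parameters, per-stage status and timings.
#'
#' @param config A config list or YAML path (see [pipeline_config()]).
#' @return Invisibly, a list with per-stage results and the run log; the
#'   element `status` is `"ok"` only when every stage succeeded.
#' @export
run_report <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package = "plastarch",
              version = as.character(utils::packageVersion("plastarch")),
              parameters = cfg[setdiff(names(cfg), "label_map")],
              stages = list())
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(value = fun(), error = NULL),
                    error = function(e) list(value = NULL, error = conditionMessage(e)))
    log$stages[[name]] <<- list(
      status = if (is.null(res$error)) "ok" else paste("failed:", res$error),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    results[[name]] <<- res$value
    is.null(res$error)
  }

  records <- NULL; structures <- NULL
  stage("read_genomes", function() {
    recs <- lapply(cfg$genomes, read_plastome_flatfile)
    records <<- recs
    recs
  })
  stage("architecture", function() {
    stopifnot(!is.null(records))
    structures <<- lapply(records, detect_inverted_repeat, min_length = cfg$min_ir_length)
    rows <- list(); jrows <- list()
    for (i in seq_along(records)) {
      rec <- records[[i]]; st <- structures[[i]]
      if (is.null(st)) {
        rows[[i]] <- data.frame(genome = rec$identifier, total = nchar(rec$sequence),
                                lsc = NA_integer_, ssc = NA_integer_, ir = NA_integer_,
                                gc_total = round(100 * gc_content(rec$sequence), 2),
                                gc_lsc = NA_real_, gc_ssc = NA_real_, gc_ir = NA_real_,
                                ir_detected = FALSE)
        next
      }
      rs <- region_stats(rec, st)
      g <- function(r, col) rs[[col]][rs$region == r]
      rows[[i]] <- data.frame(genome = rec$identifier, total = st$total_length,
                              lsc = st$lsc_length, ssc = st$ssc_length, ir = st$ir_length,
                              gc_total = round(100 * g("total", "gc"), 2),
                              gc_lsc = round(100 * g("LSC", "gc"), 2),
                              gc_ssc = round(100 * g("SSC", "gc"), 2),
                              gc_ir = round(100 * g("IR", "gc"), 2),
                              ir_detected = TRUE)
      cls <- classify_gene_regions(rec, st)
      if (nrow(cls$junctions)) {
        jr <- cls$junctions; jr$genome <- rec$identifier
        jrows[[length(jrows) + 1L]] <- jr[, c("genome", "junction", "gene", "side", "partial")]
      }
    }
    write_tsv(do.call(rbind, rows), file.path(cfg$out_dir, "architecture.tsv"),
              comment = "lengths in bp; G/C in percent (N excluded); IR length per copy")
    write_tsv(do.call(rbind, jrows) %||%
                data.frame(genome = character(0), junction = character(0),
                           gene = character(0), side = character(0), partial = logical(0)),
              file.path(cfg$out_dir, "junctions.tsv"),
              comment = "genes at the four IR junctions; partial = straddles the junction")
    TRUE
  })
  stage("gene_order", function() {
    stopifnot(!is.null(records))
    orders <- lapply(seq_along(records), function(i) {
      if (is.null(structures[[i]])) {
        extract_signed_order(records[[i]], NULL, collapse_ir = FALSE,
                             include_trnas = cfg$include_trnas)
      } else {
        extract_signed_order(records[[i]], structures[[i]], collapse_ir = cfg$collapse_ir,
                             include_trnas = cfg$include_trnas)
      }
    })
    prows <- list(); brows <- list(); trows <- list()
    if (length(orders) >= 2L) {
      for (i in seq_along(orders)) for (j in seq_along(orders)) {
        if (i >= j) next
        d <- tryCatch(breakpoint_distance(orders[[i]], orders[[j]]), error = function(e) NA)
        prows[[length(prows) + 1L]] <- data.frame(a = orders[[i]]$id, b = orders[[j]]$id,
                                                  breakpoints = d)
        bl <- tryCatch(synteny_blocks(orders[[i]], orders[[j]]), error = function(e) NULL)
        if (!is.null(bl)) {
          bl$a <- orders[[i]]$id; bl$b <- orders[[j]]$id
          brows[[length(brows) + 1L]] <- bl[, c("a", "b", "orientation", "n_genes",
                                                "start_gene", "end_gene", "genes")]
        }
        if (!is.null(orders[[i]]$regions) && !is.null(orders[[j]]$regions)) {
          tr <- region_translocations(orders[[i]], orders[[j]])
          if (nrow(tr)) {
            tr$a <- orders[[i]]$id; tr$b <- orders[[j]]$id
            trows[[length(trows) + 1L]] <- tr[, c("a", "b", "gene", "region_a", "region_b")]
          }
        }
      }
    }
    write_tsv(do.call(rbind, prows) %||% data.frame(a = character(0), b = character(0),
                                                    breakpoints = integer(0)),
              file.path(cfg$out_dir, "gene_order.tsv"),
              comment = "signed circular breakpoint distances over shared genes")
    write_tsv(do.call(rbind, brows) %||%
                data.frame(a = character(0), b = character(0), orientation = character(0),
                           n_genes = integer(0), start_gene = character(0),
                           end_gene = character(0), genes = character(0)),
              file.path(cfg$out_dir, "synteny_blocks.tsv"),
              comment = "maximal co-linear blocks; inverted blocks are inversion candidates")
    write_tsv(do.call(rbind, trows) %||%
                data.frame(a = character(0), b = character(0), gene = character(0),
                           region_a = character(0), region_b = character(0)),
              file.path(cfg$out_dir, "translocations.tsv"),
              comment = "shared genes whose quadripartite region differs")
    TRUE
  })
  stage("indels", function() {
    if (is.null(cfg$alignment) && is.null(cfg$indel_matrix)) return("skipped: no alignment")
    mat <- if (!is.null(cfg$indel_matrix)) {
      read_binary_matrix_nexus(cfg$indel_matrix)
    } else {
      aln <- read_alignment_nexus(cfg$alignment)
      coded <- code_indels(aln)
      write_binary_matrix_nexus(coded$matrix, file.path(cfg$out_dir, "indel_matrix.nex"))
      coded$matrix
    }
    if (is.null(cfg$tree)) return("skipped classification: no tree")
    tree <- read_tree_newick(cfg$tree)
    lm <- if (!is.null(cfg$label_map)) unlist(cfg$label_map) else NULL
    cls <- classify_matrix(mat, tree, label_map = lm)
    write_tsv(cls$table, file.path(cfg$out_dir, "indel_classification.tsv"),
              comment = "Fitch minimum steps per binary indel character; clade for 1-step characters")
    write_tsv(data.frame(category = names(cls$counts), count = as.integer(cls$counts)),
              file.path(cfg$out_dir, "indel_summary.tsv"),
              comment = sprintf("%d characters; tree-free autapomorphies: %d",
                                cls$n_characters, cls$autapomorphic_tree_free))
    cls
  })
  stage("codon_usage", function() {
    if (is.null(cfg$alignment)) return("skipped: no alignment")
    aln <- read_alignment_nexus(cfg$alignment)
    rep <- taxon_codon_report(aln, code = cfg$genetic_code, frame = "trim")
    write_tsv(rep, file.path(cfg$out_dir, "codon_usage.tsv"),
              comment = "G/C in percent and ENc from pooled codon counts; excluded columns removed")
    rep
  })
  stage("screen", function() {
    stopifnot(!is.null(records))
    rows <- list()
    for (rec in records) {
      sc <- edit_hint_scan(rec, starts = cfg$start_codons)
      if (nrow(sc$hints)) {
        h <- sc$hints; h$genome <- rec$identifier
        rows[[length(rows) + 1L]] <- h[, c("genome", "gene", "kind", "position")]
      }
    }
    write_tsv(do.call(rbind, rows) %||%
                data.frame(genome = character(0), gene = character(0),
                           kind = character(0), position = integer(0)),
              file.path(cfg$out_dir, "edit_hints.tsv"),
              comment = "RNA-editing hints: undetermined start/stop and internal stop codons (1-based codon index)")
    TRUE
  })

  failed <- vapply(log$stages, function(s) startsWith(s$status, "failed"), logical(1))
  log$status <- if (any(failed)) "failed" else "ok"
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(status = log$status, results = results, log = log))
}
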