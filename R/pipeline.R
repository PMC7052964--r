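# Orchestration: run the configured stages in dependency order, write one
# TSV per stage plus a machine-readable manifest. Orchestration adds no
# computation — every stage output equals the corresponding direct call.

pipeline_stage_names <- c("synteny", "ani", "stats", "expand", "enrich",
                          "hgt", "loh")

#' Read a pipeline configuration from JSON
#'
#' The configuration is a plain mapping with one section per stage (only
#' configured stages run) plus optional `seed` and `out_dir` keys. Unknown
#' top-level keys are rejected.
#'
#' @param path Path to a JSON config file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), c(pipeline_stage_names, "seed", "out_dir"))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg
}

stage_abort <- function(stage, parent) {
  rlang::abort(paste0("stage '", stage, "' failed: ",
                      conditionMessage(parent)))
}

run_stage <- function(stage, code) {
  message("[", stage, "] running")
  tryCatch(code, error = function(e) stage_abort(stage, e))
}

cfg_get <- function(section, key, default) {
  if (!is.null(section[[key]])) section[[key]] else default
}

require_input <- function(stage, section, keys) {
  for (key in keys) {
    path <- section[[key]]
    if (is.null(path)) {
      rlang::abort(paste0("missing config key '", key, "'"))
    }
    if (!file.exists(path)) {
      rlang::abort(paste0("input file not found: ", path))
    }
  }
  invisible(TRUE)
}

#' Run the configured pipeline stages
#'
#' Executes every stage present in the configuration, writes one TSV per
#' stage into `out_dir`, and records a manifest (package version,
#' parameters, input checksums, stage status). Identical configuration and
#' inputs give byte-identical outputs. A stage error aborts the run naming
#' the stage; the manifest then flags the partial output set.
#'
#' Stage sections and their keys (paths unless noted):
#' \describe{
#'   \item{synteny}{`ref_index`, `qry_index`, `coords`; optional `dialect`,
#'     `window`, `step`, `min_support`.}
#'   \item{ani}{`msa` (aligned FASTA).}
#'   \item{stats}{`genes` (BED-like TSV: contig, start, end), `index`,
#'     optional `counts` + `species` for the multi-copy fraction.}
#'   \item{expand}{`counts`; optional `focal`, `threshold` (number).}
#'   \item{enrich}{`study`, `population` (one gene per line), `gene2go`;
#'     optional `alpha` (number).}
#'   \item{hgt}{`blast`, `lineage_map`; optional `exclude` (vector),
#'     `threshold` (number).}
#'   \item{loh}{`vcf`, `index`; optional `threshold` (number).}
#' }
#'
#' @param config A named list (see [read_pipeline_config()]) or a path to
#'   a JSON config file.
#' @param out_dir Output directory (created if absent); overrides the
#'   config's `out_dir`.
#' @return Invisibly, a named list of stage results plus the manifest.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% rlang::abort("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- intersect(pipeline_stage_names, names(config))
  results <- list()
  manifest <- list(
    package = "genomescreens",
    version = as.character(utils::packageVersion("genomescreens")),
    stages = stages,
    parameters = config[stages],
    inputs = list(),
    completed = character())
  checksum <- function(paths) {
    paths <- unlist(paths, use.names = FALSE)
    paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p), logical(1))]
    as.list(tools::md5sum(paths))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(write_manifest())

  for (stage in stages) {
    sec <- config[[stage]]
    manifest$inputs[[stage]] <- checksum(sec)
    res <- switch(stage,
      synteny = run_stage("synteny", {
        require_input("synteny", sec, c("ref_index", "qry_index", "coords"))
        cfg <- synteny_config(
          window_size = cfg_get(sec, "window", 20000),
          step_size = cfg_get(sec, "step", 10000),
          min_support_bp = cfg_get(sec, "min_support", 2000))
        ref_index <- read_genome_index(sec$ref_index)
        qry_index <- read_genome_index(sec$qry_index)
        aln <- read_coords(sec$coords,
                           dialect = cfg_get(sec, "dialect", "show_coords_tab"),
                           ref_index = ref_index, qry_index = qry_index)
        blocks <- call_synteny_blocks(aln, ref_index, qry_index, cfg)
        write_blocks(blocks, file.path(out_dir, "synteny_blocks.tsv"),
                     file.path(out_dir, "synteny_links.txt"))
        blocks
      }),
      ani = run_stage("ani", {
        require_input("ani", sec, "msa")
        m <- ani_matrix(sec$msa)
        write_ani(m, file.path(out_dir, "ani.tsv"))
        m
      }),
      stats = run_stage("stats", {
        require_input("stats", sec, c("genes", "index"))
        idx <- read_genome_index(sec$index)
        genes <- readr::read_tsv(sec$genes, col_names = c("contig", "start", "end"),
                                 show_col_types = FALSE, progress = FALSE,
                                 comment = "#")
        res <- genic_fraction(genes, idx)
        if (!is.null(sec$counts) && !is.null(sec$species)) {
          res$multicopy_pct <- multicopy_fraction(read_genecounts(sec$counts),
                                                  sec$species)
        }
        readr::write_tsv(res, file.path(out_dir, "genome_stats.tsv"),
                         progress = FALSE)
        res
      }),
      expand = run_stage("expand", {
        require_input("expand", sec, "counts")
        ratios <- expansion_ratios(read_genecounts(sec$counts),
                                   focal_species = sec$focal,
                                   threshold = cfg_get(sec, "threshold", 2))
        readr::write_tsv(ratios, file.path(out_dir, "expansions.tsv"),
                         progress = FALSE)
        ratios
      }),
      enrich = run_stage("enrich", {
        require_input("enrich", sec, c("study", "population", "gene2go"))
        enr <- go_enrichment(readr::read_lines(sec$study),
                             readr::read_lines(sec$population),
                             read_gene2go(sec$gene2go),
                             alpha = cfg_get(sec, "alpha", 0.05))
        readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"),
                         progress = FALSE)
        enr
      }),
      hgt = run_stage("hgt", {
        require_input("hgt", sec, c("blast", "lineage_map"))
        ai <- alien_index_screen(
          read_blast_hits(sec$blast),
          read_lineage_map(sec$lineage_map),
          exclude_taxa = cfg_get(sec, "exclude", character()),
          threshold = cfg_get(sec, "threshold", 20))
        readr::write_tsv(tibble::as_tibble(ai), file.path(out_dir, "alien_index.tsv"),
                         progress = FALSE)
        ai
      }),
      loh = run_stage("loh", {
        require_input("loh", sec, c("vcf", "index"))
        idx <- read_genome_index(sec$index)
        snps <- read_vcf_snps(sec$vcf)
        loh <- classify_loh(snps, idx,
                            threshold = cfg_get(sec, "threshold", 0.5))
        readr::write_tsv(tidy(loh), file.path(out_dir, "loh_calls.tsv"),
                        progress = FALSE)
        readr::write_tsv(glance(loh), file.path(out_dir, "loh_summary.tsv"),
                        progress = FALSE)
        loh
      }))
    results[[stage]] <- res
    manifest$completed <- c(manifest$completed, stage)
  }
  write_manifest()
  on.exit()
  invisible(c(results, list(manifest = manifest)))
}
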