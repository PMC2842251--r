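#' Read (or construct) a run configuration
#'
#' A run configuration is a YAML file (or list) with the input paths,
#' search parameters, null-model settings and output directory used by the
#' \code{cmd_*} pipeline stages.  Missing keys take the documented
#' defaults; the configuration round-trips unchanged through
#' serialization.
#'
#' @param path YAML file path, or \code{NULL} to build from \code{...}.
#' @param ... named overrides applied on top of the file/defaults.
#' @return list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL, ...) {
  defaults <- list(alignments = NULL, mirnas = NULL, expression = NULL,
                   windows = NULL, mutants = NULL, annotations = NULL,
                   out_dir = ".", focal_species = "hsa", cell_line = NA,
                   dg_cutoff = -14, min_stretch = 7, wobbles = c(0L, 1L),
                   max_gu_5p = 0L, max_gu_3p = 1L,
                   iterations = 1000L, seed = 1L,
                   generator = list())
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(defaults, cfg)
  cfg <- utils::modifyList(cfg, list(...))
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Serialize a run configuration to YAML
#'
#' @param config a \code{run_config}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]  # YAML nulls would be dropped
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @noRd
log_stage <- function(stage, config, energy = NULL) {
  message(sprintf("[uaugscan %s] stage=%s config=%s energy=%s",
                  as.character(utils::packageVersion("uaugscan")), stage,
                  config_hash(config),
                  if (is.null(energy)) "-" else energy$parameter_set_id))
}

#' @noRd
out_path <- function(config, file) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$out_dir, file)
}

#' Pipeline stage: extract uAUG motifs and summaries
#'
#' Thin orchestration over \code{\link{read_alignment_pairs}} and
#' \code{\link{extract_all}}; writes \code{motifs.tsv} and
#' \code{summary.tsv} under the configured output directory.
#'
#' @param config a \code{run_config} with \code{alignments} set.
#' @return invisibly, the written paths.
#' @export
cmd_extract <- function(config) {
  log_stage("extract", config)
  pairs <- read_alignment_pairs(config$alignments)
  ex <- extract_all(pairs)
  invisible(write_motif_tables(ex, out_path(config, "motifs.tsv"),
                               out_path(config, "summary.tsv")))
}

#' @noRd
load_partition <- function(config) {
  records <- read_mirna_fasta(config$mirnas)
  focal <- records[records$species_prefix == config$focal_species, ,
                   drop = FALSE]
  classify_mirna_conservation(focal, records)
}

#' Pipeline stage: scan motifs against the miRNA catalog
#'
#' Runs the two-step screen once per configured wobble allowance and
#' writes \code{hits_gu<w>.tsv} per configuration.
#'
#' @param config a \code{run_config} with \code{alignments} and
#'   \code{mirnas} set.
#' @return invisibly, the written paths.
#' @export
cmd_scan <- function(config) {
  energy <- default_energy_params()
  log_stage("scan", config, energy)
  pairs <- read_alignment_pairs(config$alignments)
  motifs <- extract_all(pairs)$motifs
  partition <- load_partition(config)
  paths <- vapply(config$wobbles, function(w) {
    params <- search_params(dg_cutoff = config$dg_cutoff,
                            min_stretch = config$min_stretch,
                            max_gu_5p = w, max_gu_3p = w)
    hits <- scan_hits(motifs, partition, params, energy)
    write_hits_table(hits, out_path(config, sprintf("hits_gu%d.tsv", w)))
  }, character(1))
  invisible(paths)
}

#' Pipeline stage: shuffle-null significance report
#'
#' Writes \code{significance.tsv} with one row per (wobble, stratum).
#'
#' @param config a \code{run_config}.
#' @return invisibly, the written path.
#' @export
cmd_significance <- function(config) {
  energy <- default_energy_params()
  log_stage("significance", config, energy)
  pairs <- read_alignment_pairs(config$alignments)
  motifs <- extract_all(pairs)$motifs
  partition <- load_partition(config)
  res <- run_interaction_analysis(motifs, partition, energy,
                                  iterations = config$iterations,
                                  seed = config$seed,
                                  wobbles = config$wobbles,
                                  dg_cutoff = config$dg_cutoff,
                                  min_stretch = config$min_stretch)
  path <- out_path(config, "significance.tsv")
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: per-gene report
#'
#' Scans explicit uAUG windows (TSV with columns \code{label},
#' \code{sequence}, optionally \code{fold}; plus an optional mutant TSV
#' with \code{label}, \code{sequence}) against conserved miRNAs under the
#' gene-level wobble policy and writes \code{gene_report.tsv}.
#'
#' @param config a \code{run_config} with \code{windows} and
#'   \code{mirnas} set (optionally \code{mutants}, \code{expression},
#'   \code{cell_line}).
#' @return invisibly, the written path.
#' @export
cmd_gene_report <- function(config) {
  energy <- default_energy_params()
  log_stage("gene-report", config, energy)
  wtab <- read.delim(config$windows, stringsAsFactors = FALSE)
  windows <- uaug_windows(wtab$label, wtab$sequence,
                          gene_id = if (is.null(wtab$gene)) "gene" else
                            wtab$gene[1])
  mutants <- if (!is.null(config$mutants)) {
    read.delim(config$mutants, stringsAsFactors = FALSE)
  }
  partition <- load_partition(config)
  params <- search_params(dg_cutoff = config$dg_cutoff,
                          min_stretch = config$min_stretch,
                          max_gu_5p = config$max_gu_5p,
                          max_gu_3p = config$max_gu_3p)
  hits <- scan_gene(windows = windows, mutants = mutants,
                    partition = partition, params = params, energy = energy,
                    gene_id = windows$gene_id[1])
  allw <- windows
  if (!is.null(mutants)) {
    allw <- rbind(windows, uaug_windows(mutants$label, mutants$sequence,
                                        mutant = TRUE,
                                        gene_id = windows$gene_id[1]))
  }
  annotations <- if (!is.null(wtab$fold)) {
    data.frame(label = wtab$label, fold = wtab$fold)
  }
  expression <- if (!is.null(config$expression)) {
    read_expression_table(config$expression)
  }
  report <- gene_report(hits, allw, annotations, expression,
                        config$cell_line)
  path <- out_path(config, "gene_report.tsv")
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' Builds a \code{\link{generator_config}} from the \code{generator} block
#' of the run configuration (its \code{seed} defaults to the run seed) and
#' writes the dataset plus ground truth under the output directory.
#'
#' @param config a \code{run_config}.
#' @return invisibly, the written paths.
#' @export
cmd_simulate <- function(config) {
  log_stage("simulate", config)
  gen_args <- config$generator
  if (is.null(gen_args$seed)) gen_args$seed <- config$seed
  gcfg <- do.call(generator_config, gen_args)
  params <- search_params(dg_cutoff = config$dg_cutoff,
                          min_stretch = config$min_stretch)
  dataset <- simulate_dataset(gcfg, params)
  invisible(write_dataset(dataset, config$out_dir))
}
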