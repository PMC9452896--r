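#' Run the full analysis pipeline from a config file
#'
#' Config-driven orchestration: quantify (or load) counts, filter and
#' normalize, run every differential-expression contrast under the
#' dual-normalization design, compute myobundle-EV correlations for the
#' significant miRs, detect preferentially expressed miRs, run
#' over-representation analysis (when pathway sets are supplied) and the
#' normalization-method comparison. All tables are written to `out_dir`
#' with stable names plus a JSON run manifest; reruns with the same config
#' and inputs are bit-identical for all tables.
#'
#' The config (YAML file or equivalent named list) has blocks:
#' \preformatted{
#' seed: 1
#' inputs:
#'   counts: counts.tsv          # either a count matrix ...
#'   sample_sheet: samples.tsv
#'   sam_dir: aligned/           # ... or per-sample <sample_id>.sam + gff
#'   gff: mature.gff3
#'   gmt: pathways.gmt           # optional
#' parameters:                   # all optional, defaults shown
#'   max_hits: 13
#'   max_3p_var: 2
#'   seed_mode: anchor
#'   umi_pattern: "_([^_]+)$"
#'   cpm_threshold: 0.5
#'   min_samples: 2
#'   prior_df: 10
#'   alpha: 0.05
#'   compare_compartment: MB
#'   compare_treatments: [CTL, CLFS]
#' }
#'
#' @param config path to a YAML file, or a named list of the same shape.
#' @param out_dir output directory (created; inputs are never modified).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    cfg <- config
  } else {
    stop("`config` must be a YAML path or a named list")
  }
  inputs <- cfg$inputs
  if (is.null(inputs)) stop("config lacks an 'inputs' block")
  par <- pipeline_params(cfg$parameters)

  # pre-flight: every named input must exist before any stage runs
  if (is.null(inputs$sample_sheet)) stop("config lacks inputs$sample_sheet")
  from_sam <- !is.null(inputs$sam_dir)
  need <- c(inputs$sample_sheet,
            if (from_sam) c(inputs$sam_dir, inputs$gff) else inputs$counts,
            inputs$gmt)
  missing <- need[!file.exists(unlist(need))]
  if (length(missing)) {
    stop("missing input(s): ", paste(unlist(missing), collapse = ", "))
  }
  if (!from_sam && is.null(inputs$counts)) {
    stop("config must name either inputs$counts or inputs$sam_dir + gff")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  samples <- read_sample_sheet(inputs$sample_sheet)
  stages <- list()
  if (from_sam) {
    annot <- read_mirbase_gff(inputs$gff)
    sams <- stats::setNames(
      file.path(inputs$sam_dir, paste0(samples$sample_id, ".sam")),
      samples$sample_id)
    x <- quantify_dataset(sams, annot, samples,
                          max_hits = par$max_hits,
                          max_3p_var = par$max_3p_var,
                          seed_mode = par$seed_mode,
                          umi_pattern = par$umi_pattern)
    stages$quantify <- list(n_mirs = nrow(x$counts),
                            n_samples = ncol(x$counts))
  } else {
    m <- read_count_matrix(inputs$counts)
    x <- mir_counts(m, samples)
    stages$load_counts <- list(n_mirs = nrow(x$counts),
                               n_samples = ncol(x$counts))
  }
  write_count_matrix(x, file.path(out_dir, "counts.tsv"))

  res <- run_all_contrasts(x, cpm_threshold = par$cpm_threshold,
                           min_samples = par$min_samples,
                           prior_df = par$prior_df)
  de_hits <- list()
  for (trt in names(res$within_treatment)) {
    tab <- res$within_treatment[[trt]]
    write_results_table(tab, file.path(out_dir,
                                       paste0("de_MBvsEV_", trt, ".tsv")))
    de_hits[[trt]] <- tab$mir_id[!is.na(tab$p_value) &
                                   tab$p_value < par$alpha]
  }
  for (comp in names(res$between_treatment)) {
    for (nm in names(res$between_treatment[[comp]])) {
      write_results_table(
        res$between_treatment[[comp]][[nm]],
        file.path(out_dir, paste0("de_", comp, "_", nm, ".tsv")))
    }
  }
  stages$contrasts <- list(
    n_within = length(res$within_treatment),
    n_between = sum(lengths(res$between_treatment)),
    n_filtered_joint = length(res$filtered_ids$joint),
    de_hits_within = vapply(de_hits, length, integer(1)))

  # correlations on TMM-normalized counts, significant miRs per treatment
  joint_cpm <- cpm(
    subset_mir_counts(x, mirs = res$filtered_ids$joint), res$norm$joint)
  cor_tabs <- lapply(names(de_hits), function(trt) {
    if (length(de_hits[[trt]]) == 0) return(NULL)
    compartment_correlation(joint_cpm, samples, trt,
                            mir_subset = de_hits[[trt]])
  })
  cor_tab <- do.call(rbind, cor_tabs)
  if (is.null(cor_tab)) {
    cor_tab <- data.frame(mir_id = character(), treatment = character(),
                          r = numeric(), r_squared = numeric(),
                          p_value = numeric(), n_pairs = integer(),
                          flag = character(), stringsAsFactors = FALSE)
  }
  write_results_table(cor_tab, file.path(out_dir, "correlations.tsv"))
  stages$correlations <- list(n_rows = nrow(cor_tab),
                              n_significant = sum(!is.na(cor_tab$p_value) &
                                                    cor_tab$p_value < par$alpha))

  pref <- preferential_expression(res$filtered_ids$joint,
                                  res$filtered_ids$MB,
                                  res$filtered_ids$EV, x,
                                  alpha = par$alpha)
  for (comp in names(pref)) {
    write_results_table(pref[[comp]]$table,
                        file.path(out_dir,
                                  paste0("preferential_", comp, ".tsv")))
  }
  stages$preferential <- list(n_MB = length(pref$MB$mir_ids),
                              n_EV = length(pref$EV$mir_ids))

  if (!is.null(inputs$gmt)) {
    pathways <- read_gmt(inputs$gmt)
    hits <- sort(unique(unlist(de_hits)))
    universe <- rownames(x$counts)
    ora <- ora_hypergeometric(hits, universe, pathways)
    write_results_table(ora, file.path(out_dir, "ora.tsv"))
    stages$ora <- list(n_pathways = nrow(ora), n_hits = length(hits),
                       n_universe = length(universe))
  }

  cmp_trts <- intersect(par$compare_treatments,
                        unique(samples$treatment))
  if (length(cmp_trts) == 2 &&
      par$compare_compartment %in% samples$compartment) {
    cmp <- compare_normalizations(x, compartment = par$compare_compartment,
                                  treatments = cmp_trts,
                                  prior_df = par$prior_df)
    size_tab <- do.call(rbind, lapply(names(cmp$sizes), function(k) {
      data.frame(threshold = k, method = names(cmp$sizes[[k]]),
                 n_de = unname(cmp$sizes[[k]]), stringsAsFactors = FALSE)
    }))
    write_results_table(size_tab,
                        file.path(out_dir, "norm_comparison_sizes.tsv"))
    ov_tab <- do.call(rbind, lapply(names(cmp$overlaps), function(k) {
      data.frame(threshold = k, region = names(cmp$overlaps[[k]]),
                 n = lengths(cmp$overlaps[[k]]),
                 ids = vapply(cmp$overlaps[[k]], paste, character(1),
                              collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    write_results_table(ov_tab,
                        file.path(out_dir, "norm_comparison_overlaps.tsv"))
    stages$compare_norm <- list(sizes = cmp$sizes)
  }

  manifest <- list(
    config_hash = unname(tools::md5sum(
      textConnection_write(jsonlite::toJSON(cfg, auto_unbox = TRUE)))),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("mirbundle")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = par,
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of a string via a temp file (tools::md5sum is file-based).
textConnection_write <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  f
}

# Merge user parameters over pipeline defaults.
pipeline_params <- function(p) {
  def <- list(max_hits = 13, max_3p_var = 2, seed_mode = "anchor",
              umi_pattern = "_([^_]+)$", cpm_threshold = 0.5,
              min_samples = 2, prior_df = 10, alpha = 0.05,
              compare_compartment = "MB",
              compare_treatments = c("CTL", "CLFS"))
  if (!is.null(p)) {
    for (nm in names(p)) def[[nm]] <- p[[nm]]
  }
  def
}
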