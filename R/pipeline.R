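# End-to-end orchestration: load statistics -> differentiation ->
# prioritization -> (optional) association, with a parameter-echoing run
# log so every emitted number is traceable to config, seed and inputs.

#' Run the full analysis pipeline
#'
#' Reads genotypes, polarizes against the outgroup, attaches annotations,
#' computes the all-pairs load table for the requested site classes, scans
#' differentiation and extracts stage-1 candidates for the focal breed,
#' optionally prioritizes against gene lists, merges selection windows when
#' scan scores are supplied, and runs the cohort association battery when a
#' cohort is supplied.  TSV reports and a JSON run log (parameter echo,
#' seed, input checksums) are written to `out_dir`.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   `vcf`, `outgroup`, `breed_map`, `annotations` (paths; required);
#'   optional `mask` (BED), `clr` (window-score TSV with chrom/start/clr),
#'   `genes` (BED with name column), `gene_list` (text file, one gene per
#'   line), `gene_mode` ("coding" or "regulatory"), `cohort` (TSV),
#'   `markers` (character vector for the association battery);
#'   parameters `site_classes` (default c("synonymous","high")),
#'   `convention`, `blocks` (50), `fst_min` (0.7), `freq_min` (0.7),
#'   `top_frac` (0.05), `window_size` (10000), `join_dist` (100000),
#'   `family_size`, `focal_breed` (default: first breed), `statistic`
#'   ("R"), `seed` (default 1), `out_dir` (required).
#' @return invisibly, a list with the computed tables (`load`,
#'   `candidates`, `regions`, `association`) and the run-log list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(site_classes = c("synonymous", "high"),
                   convention = "methods", blocks = 50, fst_min = 0.7,
                   freq_min = 0.7, top_frac = 0.05, window_size = 10000,
                   join_dist = 100000, statistic = "R", seed = 1,
                   gene_mode = "coding")
  config <- utils::modifyList(defaults, config)
  for (key in c("vcf", "outgroup", "breed_map", "annotations", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  for (key in c("vcf", "outgroup", "breed_map", "annotations", "mask",
                "clr", "genes", "gene_list", "cohort")) {
    p <- config[[key]]
    if (!is.null(p) && is.character(p) && !file.exists(p))
      stop("input file for '", key, "' not found: ", p)
  }
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("breedload")),
              r_version = R.version.string,
              parameters = config[setdiff(names(config),
                                          "out_dir")],
              input_md5 = vapply(
                Filter(function(p) is.character(p) && file.exists(p),
                       config[c("vcf", "outgroup", "breed_map",
                                "annotations", "mask", "clr", "genes",
                                "gene_list", "cohort")]),
                function(p) unname(tools::md5sum(p)), ""))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- stage("io", {
    d <- read_genotypes(config$vcf, config$breed_map)
    d <- polarize(d, config$outgroup)
    attach_annotations(d, config$annotations)
  })
  mask <- if (!is.null(config$mask)) normalize_mask(read_bed(config$mask))

  load_tab <- stage("load-stats",
                    load_table(ds, config$site_classes, config$statistic,
                               n_blocks = config$blocks, mask = mask))

  focal <- if (!is.null(config$focal_breed)) config$focal_breed else
    breeds(ds)[1]
  records <- stage("differentiation", fst_scan(ds))
  cand <- stage("prioritization",
                stage1_candidates(ds, records, focal,
                                  fst_min = config$fst_min,
                                  freq_min = config$freq_min))
  if (!is.null(config$genes) && !is.null(config$gene_list)) {
    gl <- readLines(config$gene_list)
    cand <- stage("prioritization",
                  prioritize_by_gene(cand, config$genes, config$gene_mode,
                                     gene_list = gl))
  }
  regions <- NULL
  if (!is.null(config$clr)) {
    clr <- utils::read.table(config$clr, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    regions <- stage("sweep-merge",
                     merge_selection_windows(clr, config$top_frac,
                                             config$window_size,
                                             config$join_dist))
  }
  assoc <- NULL
  if (!is.null(config$cohort)) {
    assoc <- stage("association", {
      cohort <- read_cohort(config$cohort)
      markers <- if (!is.null(config$markers)) config$markers else
        attr(cohort, "markers")
      seg <- vapply(markers, function(m)
        length(unique(stats::na.omit(cohort[[m]]))) > 1L, TRUE)
      do.call(rbind, lapply(markers[seg], function(m)
        summary(interaction_models(cohort, m))))
    })
  }

  emit <- function(obj, name) {
    if (is.null(obj)) return(NULL)
    path <- file.path(config$out_dir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  emit(load_tab, "load_statistics.tsv")
  emit(cand, "candidates.tsv")
  emit(regions, "selection_regions.tsv")
  emit(assoc, "association.tsv")
  log_path <- file.path(config$out_dir, "run_log.json")
  writeLines(.to_json(log), log_path)
  invisible(list(load = load_tab, candidates = cand, regions = regions,
                 association = assoc, log = log))
}

# tiny JSON serializer for the run log (atomic vectors and lists only)
.to_json <- function(x, indent = "") {
  esc <- function(s) gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", s))
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (is.null(names(x)))
      return(paste0("[", paste(vapply(x, .to_json, "", indent),
                               collapse = ", "), "]"))
    items <- vapply(seq_along(x), function(i)
      paste0("\"", esc(names(x)[i]), "\": ", .to_json(x[[i]], indent)), "")
    return(paste0("{", paste(items, collapse = ", "), "}"))
  }
  if (length(x) != 1 || !is.null(names(x))) {
    if (!is.null(names(x)))
      return(.to_json(as.list(x), indent))
    return(paste0("[", paste(vapply(x, .to_json, "", indent),
                             collapse = ", "), "]"))
  }
  if (is.character(x)) return(paste0("\"", esc(x), "\""))
  if (is.logical(x)) return(if (is.na(x)) "null" else tolower(as.character(x)))
  if (is.na(x)) return("null")
  format(x, digits = 15, scientific = FALSE)
}
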