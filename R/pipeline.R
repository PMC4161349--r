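#' Assemble or read a pipeline configuration
#'
#' A config drives [run_profile()]: where the proteome and identification
#' files live, reconstruction and profiling options, the output
#' directory and the seed. `pipeline_config()` builds one in code;
#' `read_pipeline_config()` loads the same keys from a YAML file (paths
#' in the file are resolved relative to the file's directory). Keys and
#' defaults:
#'
#' * `proteome`: FASTA path (required).
#' * `identifications`: character vector of TSV paths (required; see
#'   [read_identifications_tsv()]).
#' * `dedupe` (`TRUE`), `require_p1` (`TRUE`), `same_group_only`
#'   (`FALSE`), `min_peptide_length` (4): reconstruction options.
#' * `alpha` (0.01), `pseudocount` (0.5), `background_source`
#'   (`"proteome"` or a composition TSV path): profiling options.
#' * `output_dir`: where result files are written (required).
#' * `seed` (1): recorded in outputs for provenance.
#'
#' @param proteome,identifications,output_dir See above.
#' @param dedupe,require_p1,same_group_only,min_peptide_length
#'   Reconstruction options.
#' @param alpha,pseudocount,background_source Profiling options.
#' @param seed Integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome, identifications, output_dir,
                            dedupe = TRUE, require_p1 = TRUE,
                            same_group_only = FALSE, min_peptide_length = 4L,
                            alpha = 0.01, pseudocount = 0.5,
                            background_source = "proteome", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, pseudocount > 0, min_peptide_length >= 1L)
  structure(
    list(proteome = proteome,
         identifications = identifications,
         output_dir = output_dir,
         dedupe = isTRUE(dedupe), require_p1 = isTRUE(require_p1),
         same_group_only = isTRUE(same_group_only),
         min_peptide_length = as.integer(min_peptide_length),
         alpha = alpha, pseudocount = pseudocount,
         background_source = background_source,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML config file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  need <- c("proteome", "identifications", "output_dir")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  args <- raw
  args$proteome <- rel(raw$proteome)
  args$identifications <- rel(unlist(raw$identifications))
  args$output_dir <- rel(raw$output_dir)
  if (!is.null(args$background_source) &&
      !identical(args$background_source, "proteome")) {
    args$background_source <- rel(args$background_source)
  }
  do.call(pipeline_config, args)
}

#' Run the full specificity-profiling pipeline
#'
#' Reads the proteome and the identified prime-side peptides, builds the
#' substring index, reconstructs P6-P6' cleavage windows, and profiles
#' each (protease, library) pair: positional counts, occurrence
#' percentages, background-normalised enrichment with significance
#' calls, and a subsite PWM. Per pair it writes
#' `<protease>_<library>_windows.tsv`, `..._heatmap.tsv`,
#' `..._enrichment.tsv` and `..._pwm.tsv`; globally it writes
#' `summary.json` (mapping counts, top residues per subsite, significant
#' calls, config fingerprint and seed) and `run.log`. A failure for one
#' protease is caught, logged, and does not abort the others.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @return The summary list, invisibly.
#' @export
run_profile <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # validate inputs before any computation
  inputs <- c(config$proteome, config$identifications)
  if (!identical(config$background_source, "proteome")) {
    inputs <- c(inputs, config$background_source)
  }
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) {
    stop("config error: missing input file(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  cfg_hash <- fnv1a32(as.character(cfg_json))
  logf("picsr %s | config %s | seed %d",
       as.character(utils::packageVersion("picsr")), cfg_hash, config$seed)

  prot <- read_proteome_fasta(config$proteome)
  logf("proteome: %d records, %d isoform groups", nrow(prot),
       length(unique(prot$isoform_group)))
  idx <- proteome_index(prot)
  background <- if (identical(config$background_source, "proteome")) {
    background_composition(prot)
  } else {
    read_composition_tsv(config$background_source)
  }

  ids <- do.call(rbind, lapply(config$identifications,
                               read_identifications_tsv))
  logf("identifications: %d rows from %d file(s)", nrow(ids),
       length(config$identifications))

  groups <- split(ids, paste(ids$protease, ids$library, sep = "_"))
  summaries <- list()
  for (gname in names(groups)) {
    res <- tryCatch({
      g <- groups[[gname]]
      rec <- reconstruct_all(g, idx, dedupe = config$dedupe,
                             require_p1 = config$require_p1,
                             min_peptide_length = config$min_peptide_length,
                             same_group_only = config$same_group_only)
      stub <- file.path(config$output_dir, gsub("[^A-Za-z0-9_.-]", "_", gname))
      write_windows_tsv(rec$windows, paste0(stub, "_windows.tsv"))
      pcm <- count_matrix(rec$windows)
      write_matrix_tsv(occurrence_percent(pcm), paste0(stub, "_heatmap.tsv"))
      prof <- enrichment_profile(pcm, background, alpha = config$alpha)
      write_profile_tsv(prof, paste0(stub, "_enrichment.tsv"))
      pwm <- pwm_from_profile(prof, pseudocount = config$pseudocount)
      write_matrix_tsv(pwm, paste0(stub, "_pwm.tsv"))
      s <- summary(prof)
      logf("%s: %d/%d mapped, %d windows, %d significant calls", gname,
           rec$report$n_mapped, rec$report$n_input, rec$report$n_windows,
           nrow(s$significant))
      list(report = rec$report,
           n_sites = s$n_sites,
           top_residues = lapply(s$top_residues, `[`, 1L),
           significant = s$significant)
    }, error = function(e) {
      logf("%s: FAILED (%s)", gname, conditionMessage(e))
      list(error = conditionMessage(e))
    })
    summaries[[gname]] <- res
  }
  out <- list(config_hash = cfg_hash, seed = config$seed,
              alpha = config$alpha, groups = summaries)
  jsonlite::write_json(out, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE, pretty = TRUE)
  logf("done: %d group(s)", length(summaries))
  invisible(out)
}
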