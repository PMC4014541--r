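#' Read a raw-sample CSV
#'
#' One row per blood sample. Required columns: `subject_id`, `time_min`
#' and either `ratio_tracer` (labeled/unlabeled ion-intensity ratio) or
#' `ape_percent` (pre-computed APE). Optional: `visit`, `ratio_is`
#' (analyte/internal-standard ratio for concentration). Header required;
#' decimal point, UTF-8.
#'
#' @param path CSV file path.
#' @return Data frame of samples.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "time_min") %in% names(d))) {
    abort_input("samples CSV needs columns `subject_id` and `time_min`")
  }
  if (!("ratio_tracer" %in% names(d)) && !("ape_percent" %in% names(d))) {
    abort_input("samples CSV needs `ratio_tracer` or `ape_percent`")
  }
  d
}

#' Build enrichment curves from a sample table
#'
#' Splits a raw-sample table by subject (and visit, when present) and
#' converts each group into an [enrichment_curve()]: via [compute_ape()]
#' when ratios are given, or directly from pre-computed `ape_percent`
#' values (rows with `time_min < 0` are dropped in that case).
#'
#' @param samples Data frame as returned by [read_samples()].
#' @param ape_method APE convention for the ratio conversion.
#' @return Named list of [enrichment_curve()]s.
#' @export
curves_from_samples <- function(samples,
                                ape_method = c("ratio", "mole_fraction")) {
  ape_method <- match.arg(ape_method)
  has_visit <- "visit" %in% names(samples)
  key <- if (has_visit) {
    paste(samples$subject_id, samples$visit, sep = "/")
  } else as.character(samples$subject_id)
  groups <- split(samples, factor(key, levels = unique(key)))
  lapply(groups, function(g) {
    sid <- if (has_visit) paste(g$subject_id[[1L]], g$visit[[1L]], sep = "/")
           else as.character(g$subject_id[[1L]])
    if ("ratio_tracer" %in% names(g)) {
      compute_ape(g, ape_method = ape_method, subject_id = sid)
    } else {
      post <- g[g$time_min >= 0, , drop = FALSE]
      enrichment_curve(post$time_min, post$ape_percent, subject_id = sid,
                       ape_method = ape_method)
    }
  })
}

#' Write a results table as CSV
#'
#' Plain CSV with a stable column order, no row names and no quoting,
#' so re-running an analysis on identical inputs reproduces the file
#' byte for byte.
#'
#' @param results Data frame (e.g. from [analyze_cohort()]).
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' A flat YAML file with dotted keys mirroring the design defaults:
#' `dose.amount_mg_per_kg`, `dose.molar_mass`, `dose.purity`,
#' `infusion.compound`, `infusion.rate_mg_per_kg_per_h`,
#' `infusion.molar_mass`, `infusion.stoichiometry`, `auc.method`,
#' `auc.extrapolate`, `auc.n_tail`, `auc.add_head`, `loq_ape`,
#' `ape_method`. Missing keys take the package defaults.
#'
#' @param path YAML file path, or `NULL` for an all-default setup.
#' @return List with elements `dose` ([tracer_dose()]), `infusion`
#'   ([infusion_regimen()]) and `config` ([kinetics_config()]).
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  get_or <- function(key, default) {
    if (is.null(raw[[key]])) default else raw[[key]]
  }
  dose <- tracer_dose(
    amount_mg_per_kg = get_or("dose.amount_mg_per_kg", 3),
    molar_mass_g_per_mol = get_or("dose.molar_mass", .molar_mass[["gln_1_13c"]]),
    isotopic_purity = get_or("dose.purity", 1)
  )
  rate <- get_or("infusion.rate_mg_per_kg_per_h", 0)
  infusion <- infusion_regimen(
    compound = get_or("infusion.compound", "saline"),
    rate_mg_per_kg_per_h = rate,
    compound_molar_mass_g_per_mol = get_or("infusion.molar_mass",
                                           .molar_mass[["ala_gln"]]),
    moles_glutamine_per_mole_compound = get_or("infusion.stoichiometry",
                                               if (rate > 0) 1 else 0)
  )
  config <- kinetics_config(
    auc_method = get_or("auc.method", "linear"),
    extrapolate = get_or("auc.extrapolate", TRUE),
    n_tail = get_or("auc.n_tail", 10),
    loq_ape = get_or("loq_ape", 0.01),
    ape_method = get_or("ape_method", "ratio"),
    add_head = get_or("auc.add_head", FALSE)
  )
  list(dose = dose, infusion = infusion, config = config)
}

#' Write a run manifest
#'
#' Records what produced an output directory: package version, seed,
#' configuration snapshot, and MD5 digests of the input files. Re-running
#' with inputs matching the manifest reproduces the numerical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param inputs Character vector of input file paths to digest.
#' @param config Arbitrary configuration list to snapshot.
#' @param seed Integer seed used for the run, or `NULL`.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(out_dir, inputs = character(), config = list(),
                           seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    tool = "glnbolus",
    version = as.character(utils::packageVersion("glnbolus")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = digests
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
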