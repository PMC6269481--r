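# Stage seeds are split deterministically from the single run seed so a
# stage re-run in isolation reproduces its full-run output.
.stage_seed <- function(seed, stage) {
  offsets <- c(score = 101L, survive = 211L, derive = 307L, enrich = 401L)
  as.integer(seed) + offsets[[stage]]
}

.pipeline_stages <- c("score", "survive", "derive", "enrich")

#' Run the end-to-end signature analysis pipeline
#'
#' Executes the selected stages in dependency order on the inputs named in
#' a config (YAML file or equivalent list):
#' \describe{
#'   \item{score}{rank-sum signature scoring of the miRNA matrix, with
#'     median dichotomization; writes `scores.tsv`.}
#'   \item{survive}{KM curves per score group, log-rank test, landmark
#'     survival with CI, and (with covariates configured) the
#'     outcome-restricted logistic fit; writes `survival_report.json`.}
#'   \item{derive}{Pearson correlation ranking of the mRNA matrix against
#'     the scores and the top-N derived signature; writes
#'     `ranked_genes.tsv` and `derived_signature.tsv`.}
#'   \item{enrich}{pre-ranked enrichment of a GMT collection against the
#'     ranked list from the derive stage; writes `enrichment.tsv`.}
#' }
#' Identical config + inputs + seed reproduce numerically identical
#' outputs.  Any stage failure aborts with the stage name, leaves partial
#' outputs alongside a `FAILED` marker, and writes no manifest; on success
#' a `manifest.json` (config echo, input MD5 digests, seed, output paths,
#' package version) is written last.
#'
#' Config keys: `seed`; `stages` (subset of score, survive, derive,
#' enrich); `inputs` (paths: `mirna_matrix`, `signature`, `mrna_matrix`,
#' `clinical`, `gene_sets`); optional `params` (`min_coverage`, `top_n`,
#' `landmark_time`, `covariates`, `score_form`, `min_followup`, `n_perm`,
#' `weight_exponent`).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest, invisibly (list, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = "stemscore_run") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- unlist(config$stages)
  if (is.null(stages)) stages <- .pipeline_stages
  unknown <- setdiff(stages, .pipeline_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  inputs <- config$inputs
  params <- if (is.null(config$params)) list() else config$params
  par <- function(nm, default) if (is.null(params[[nm]])) default else params[[nm]]

  needed <- c("mirna_matrix", "signature")
  if ("survive" %in% stages) needed <- c(needed, "clinical")
  if ("derive" %in% stages || "enrich" %in% stages)
    needed <- c(needed, "mrna_matrix")
  if ("enrich" %in% stages) needed <- c(needed, "gene_sets")
  needed <- unique(needed)
  missing_in <- needed[vapply(needed, function(nm) {
    is.null(inputs[[nm]]) || !file.exists(inputs[[nm]])
  }, TRUE)]
  if (length(missing_in))
    stop("missing or unreadable input file(s): ",
         paste(vapply(missing_in, function(nm)
           sprintf("%s (%s)", nm, if (is.null(inputs[[nm]])) "not configured"
                   else inputs[[nm]]), ""), collapse = ", "))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  outputs <- character()
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    log_line("stage ", stage, ": start")
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(c(stage, conditionMessage(e)), file.path(out_dir, "FAILED"))
      log_line("stage ", stage, ": FAILED (", conditionMessage(e), ")")
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_line("stage ", stage, ": done")
    ok
  }

  if ("score" %in% stages || length(intersect(stages, c("survive", "derive"))))
    run_stage("score", function() {
      mat <- read_expression_matrix(inputs$mirna_matrix)
      sig <- read_signature(inputs$signature)
      state$scores <- signature_score(mat, sig,
                                      min_coverage = par("min_coverage", 0.5))
      state$groups <- dichotomize_by_median(state$scores)
      path <- file.path(out_dir, "scores.tsv")
      utils::write.table(
        data.frame(sample_id = state$scores$sample_ids,
                   score = unname(state$scores$score),
                   group = as.character(state$groups$label)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[["scores"]] <<- path
    })

  if ("survive" %in% stages)
    run_stage("survive", function() {
      clinical <- read_clinical_table(inputs$clinical)
      covariates <- par("covariates", NULL)
      report <- survival_report(
        state$scores, clinical,
        landmark_time = par("landmark_time", 5),
        covariates = if (length(covariates)) unlist(covariates) else NULL,
        score_form = par("score_form", "dichotomized"),
        min_followup = par("min_followup", 3))
      path <- file.path(out_dir, "survival_report.json")
      jsonlite::write_json(.survival_report_json(report), path,
                           auto_unbox = TRUE, digits = NA)
      outputs[["survival_report"]] <<- path
    })

  if ("derive" %in% stages || "enrich" %in% stages)
    run_stage("derive", function() {
      mrna <- read_expression_matrix(inputs$mrna_matrix)
      state$ranked <- correlate_genes_with_score(mrna, state$scores)
      rpath <- file.path(out_dir, "ranked_genes.tsv")
      utils::write.table(as.data.frame(state$ranked), rpath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs[["ranked_genes"]] <<- rpath
      if ("derive" %in% stages) {
        sig <- derive_top_signature(state$ranked, n = par("top_n", 500L),
                                    name = "derived_mrna_signature")
        spath <- file.path(out_dir, "derived_signature.tsv")
        write_signature(sig, spath)
        outputs[["derived_signature"]] <<- spath
      }
    })

  if ("enrich" %in% stages)
    run_stage("enrich", function() {
      sets <- read_gmt(inputs$gene_sets)
      enr <- preranked_enrichment(
        state$ranked, sets,
        weight_exponent = par("weight_exponent", 1),
        n_perm = par("n_perm", 1000L),
        seed = .stage_seed(seed, "enrich"))
      path <- file.path(out_dir, "enrichment.tsv")
      flat <- enr
      flat$leading_edge <- vapply(enr$leading_edge, paste, "", collapse = ",")
      utils::write.table(flat, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs[["enrichment"]] <<- path
    })

  manifest <- list(
    package_version = as.character(utils::packageVersion("stemscore")),
    seed = seed,
    stages = stages,
    config = config,
    input_digests = as.list(tools::md5sum(unlist(inputs[needed]))),
    outputs = as.list(outputs))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_line("manifest written: ", manifest_path)
  invisible(manifest)
}

.survival_report_json <- function(report) {
  list(
    cutoff = report$groups$cutoff_value,
    n_low = sum(report$groups$label == "low"),
    n_high = sum(report$groups$label == "high"),
    logrank = list(chi2 = report$logrank$chi2, df = report$logrank$df,
                   p = report$logrank$p,
                   observed = as.list(report$logrank$observed),
                   expected = as.list(report$logrank$expected)),
    landmark = lapply(report$landmark, function(l)
      l[c("estimate", "lower", "upper", "extrapolated")]),
    km = lapply(report$km, function(k)
      k[c("event_times", "at_risk", "events", "survival", "greenwood_var")]),
    logistic = if (is.null(report$logistic)) NULL else list(
      coefficients = as.list(report$logistic$coefficients),
      odds_ratio = as.list(report$logistic$odds_ratio),
      p = as.list(report$logistic$p),
      n_used = report$logistic$n_used,
      n_excluded = report$logistic$n_excluded,
      converged = report$logistic$converged))
}

#' Simulate, analyze and report on a default synthetic cohort
#'
#' One-command demonstration: generates the default synthetic cohort,
#' writes its artifacts, and runs the full pipeline
#' (score, survive, derive, enrich) against the packaged ESC miRNA
#' signature, with the planted driver set as the gene-set collection for
#' the enrichment stage.
#'
#' @param out_dir Output directory.
#' @param seed Seed for the cohort and the enrichment null.
#' @param config Optional [simulation_config()] overriding the defaults.
#' @return The run manifest, invisibly.
#' @export
stemscore_demo <- function(out_dir = "stemscore_demo", seed = 1L,
                           config = NULL) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  cohort <- simulate_cohort(config)
  data_dir <- file.path(out_dir, "data")
  paths <- write_synthetic_cohort(cohort, data_dir)
  sig_path <- file.path(data_dir, "signature.tsv")
  write_signature(truth_signature(cohort), sig_path)
  gmt_path <- file.path(data_dir, "sets.gmt")
  write_gmt(list(planted_drivers = cohort$truth$drivers), gmt_path)
  run_pipeline(list(
    seed = seed,
    stages = as.list(.pipeline_stages),
    inputs = list(mirna_matrix = unname(paths[["mirna"]]),
                  mrna_matrix = unname(paths[["mrna"]]),
                  clinical = unname(paths[["clinical"]]),
                  signature = sig_path,
                  gene_sets = gmt_path),
    params = list(covariates = list("mycn_amplified", "stage4", "age_ge_1y"),
                  top_n = config$n_driver_genes,
                  n_perm = 200L)),
    out_dir = file.path(out_dir, "results"))
}
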