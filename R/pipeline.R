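#' Run the simulate / preprocess / fit / summarize pipeline from a config
#'
#' Executes the requested stages in order and writes every stage's outputs
#' plus a JSON run manifest (config snapshot, seeds, input file hashes, stage
#' versions, output paths) under `output_dir`.  A stage failure aborts with
#' the stage name; outputs of earlier stages are left intact.  Reruns with the
#' same config and seeds reproduce identical categorical data and identical
#' retained draws.
#'
#' Config schema (YAML file or an equivalent named list):
#' \preformatted{
#' output_dir: path            # required
#' seed: 1                     # required, drives every stage
#' stages: [simulate, fit, summarize]   # required, executed in this order
#' simulate:                   # required when 'simulate' is listed
#'   preset: tiny              # see nhanes_like_spec()
#'   size_factor: 1.0          # optional
#' preprocess:                 # alternative to simulate: categorize a CSV
#'   amounts: path.csv         # person x food amounts, plus columns id, subgroup
#' fit:                        # required when 'fit' is listed
#'   k0: 30
#'   ks: 30
#'   n_iter: 2000
#'   burn_in: 1000             # optional, default n_iter/2
#'   thin: 2
#' summarize:
#'   threshold: 0.05
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @return The run manifest (class `rpc_manifest`), invisibly.  Stage outputs
#'   land in `output_dir`: `data.csv` + `truth.json` (simulate),
#'   `categorized.csv` + `rule.csv` (preprocess), `draws.rds` (fit),
#'   `modal_patterns.csv`, `allocation_heatmap.csv`, `summary.rds`
#'   (summarize), and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  manifest <- list(config = config, config_file = cfg_path,
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("rpclust")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list(), input_hashes = list(), outputs = list())

  run_stage <- function(name, fun) {
    message("stage: ", name)
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(completed = TRUE)
    res
  }

  for (stage in config$stages) {
    if (stage == "simulate") {
      run_stage("simulate", function() {
        sim_cfg <- config$simulate
        spec <- nhanes_like_spec(sim_cfg$preset,
                                 size_factor = sim_cfg$size_factor,
                                 seed = config$seed)
        sim <- generate_dataset(spec)
        write_consumption(sim$data, out("data.csv"))
        write_truth(sim$truth, out("truth.json"))
        manifest$outputs$data <<- out("data.csv")
        manifest$outputs$truth <<- out("truth.json")
      })
    } else if (stage == "preprocess") {
      run_stage("preprocess", function() {
        amounts_file <- config$preprocess$amounts
        manifest$input_hashes[[amounts_file]] <<-
          unname(tools::md5sum(amounts_file))
        df <- read.csv(amounts_file, check.names = FALSE)
        amounts <- as.matrix(df[setdiff(names(df), c("id", "subgroup"))])
        rule <- fit_categorization(amounts)
        cm <- categorize(amounts, rule,
                         subgroup = factor(df$subgroup,
                                           levels = unique(df$subgroup)))
        write_consumption(cm, out("data.csv"))
        write_rule(rule, out("rule.csv"))
        manifest$outputs$data <<- out("data.csv")
        manifest$outputs$rule <<- out("rule.csv")
      })
    } else if (stage == "fit") {
      run_stage("fit", function() {
        if (is.null(manifest$outputs$data))
          stop("no data available: run the simulate or preprocess stage first")
        cm <- read_consumption(manifest$outputs$data)
        fit_cfg <- config$fit
        cfg <- mcmc_config(
          K0_max = fit_cfg$k0 %||% 30L, Ks_max = fit_cfg$ks %||% 30L,
          n_iter = fit_cfg$n_iter %||% 2000L,
          burn_in = fit_cfg$burn_in %||% ((fit_cfg$n_iter %||% 2000L) %/% 2L),
          thin = fit_cfg$thin %||% 2L, seed = config$seed)
        samples <- run_mcmc(cm, rpc_priors(), cfg)
        saveRDS(samples, out("draws.rds"))
        manifest$outputs$draws <<- out("draws.rds")
      })
    } else if (stage == "summarize") {
      run_stage("summarize", function() {
        if (is.null(manifest$outputs$draws))
          stop("missing dependency: the fit stage must run before summarize")
        samples <- readRDS(manifest$outputs$draws)
        thr <- config$summarize$threshold %||% 0.05
        summ <- summarize_rpc(samples, occupancy_threshold = thr)
        write_modal_csv(summ, out("modal_patterns.csv"))
        if (!is.null(summ$allocation)) {
          heat <- data.frame(item = rownames(summ$allocation$G),
                             summ$allocation$G, check.names = FALSE)
          write.csv(heat, out("allocation_heatmap.csv"), row.names = FALSE)
          manifest$outputs$heatmap <<- out("allocation_heatmap.csv")
        }
        saveRDS(summ, out("summary.rds"))
        manifest$outputs$modal <<- out("modal_patterns.csv")
        manifest$outputs$summary <<- out("summary.rds")
      })
    } else {
      stop("unknown pipeline stage '", stage, "'", call. = FALSE)
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  class(manifest) <- "rpc_manifest"
  write_manifest(manifest, out("manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  for (key in c("output_dir", "seed", "stages"))
    if (is.null(config[[key]]))
      stop("config error: required key '", key, "' is missing", call. = FALSE)
  known <- c("simulate", "preprocess", "fit", "summarize")
  bad <- setdiff(unlist(config$stages), known)
  if (length(bad))
    stop("config error: unknown stage(s) ", paste(bad, collapse = ", "),
         "; known stages: ", paste(known, collapse = ", "), call. = FALSE)
  if ("simulate" %in% config$stages && is.null(config$simulate$preset))
    stop("config error: simulate stage requires 'simulate: preset:'",
         call. = FALSE)
  if ("preprocess" %in% config$stages && is.null(config$preprocess$amounts))
    stop("config error: preprocess stage requires 'preprocess: amounts:'",
         call. = FALSE)
  invisible(config)
}

#' Write a modal-pattern table as CSV
#'
#' One row per (scope, pattern, item): modal consumption level, its
#' posterior probability, and the tie flag.  Scope is `"global"` or the
#' subgroup name.
#'
#' @param summ An `rpc_pattern_summary` (from [summarize_rpc()], or
#'   [prune_and_relabel()] — modal patterns are computed if absent).
#' @param path File path.
#' @export
write_modal_csv <- function(summ, path) {
  modal <- summ$modal %||% modal_patterns(summ)
  rows <- list()
  add <- function(scope, set) {
    for (k in seq_len(nrow(set$levels)))
      rows[[length(rows) + 1L]] <<- data.frame(
        scope = scope, pattern = k, item = colnames(set$levels),
        modal_level = set$levels[k, ], modal_prob = set$prob[k, ],
        tie = set$tie[k, ], row.names = NULL)
  }
  add("global", modal$global)
  for (s in seq_along(modal$local))
    add(names(modal$local)[s] %||% paste0("subgroup", s), modal$local[[s]])
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a pipeline run manifest (lossless JSON round-trip)
#' @param manifest An `rpc_manifest`.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  class(m) <- "rpc_manifest"
  m
}
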