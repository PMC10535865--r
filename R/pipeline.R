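# End-to-end orchestration: one structured config drives a reproducible
# run over the requested stages. Outputs are TSVs with a one-line `#`
# provenance header (config hash, seed, package version) plus JSON
# mirrors; reruns with the same config are byte-identical.

config_hash <- function(config) {
  # identify the analysis, not where its outputs land
  config$out_dir <- NULL
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

write_stage_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pgptools %s config_hash=%s seed=%s",
                     as.character(utils::packageVersion("pgptools")),
                     hash, seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order -- `kinetics` (uptake-trace
#' inversion and inhibition ratio), `doseresponse` (Hill fit),
#' `qpcr` (2^-ddCt), `mmgbsa` (replica aggregation) and `hbonds`
#' (occupancy report) -- from a single structured configuration, either
#' an R list or the path of a YAML file with the same shape. All input
#' paths are validated before any stage runs; a failing stage is
#' recorded and does not abort independent stages.
#'
#' Config shape (all stages optional):
#' \preformatted{
#' seed: 1
#' out_dir: results/          # omit to skip writing files
#' kinetics:
#'   trace: path.csv          # `time_s,intensity`
#'   events: events.csv       # `event,time_s`
#'   control_trace: ctrl.csv  # optional; enables the inhibition ratio
#'   control_events: ev.csv
#'   total_drug: 1000         # assay conditions (defaults shown in
#'   n_cells: 2e6             #  assay_conditions())
#'   solution_volume: 0.002
#'   background: 5
#' doseresponse:
#'   file: doses.csv          # `dose,unit,replicate,viability_pct`
#'   fix_top_bottom: false
#' qpcr:
#'   file: ct.csv             # `sample,gene,ct`
#'   target: ABCB1
#'   reference: GAPDH
#'   treated: treated         # sample labels
#'   control: control
#' mmgbsa:
#'   energies: frames.csv     # `replica,frame,e_vdw,...`
#'   temperature: 310
#'   decomposition: decomp.csv  # optional `residue,energy`
#' hbonds:
#'   trajectory: traj.csv     # `frame,serial,name,resname,resid,x,y,z`
#'   annotations: ann.csv     # `serial,role`
#'   grouping: residue
#' }
#'
#' @param config list or YAML file path.
#' @return (invisibly) a list with one element per executed stage, plus
#'   `provenance` (config hash, seed, package version) and `errors`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # pre-flight: every referenced path must exist before any stage runs
  path_keys <- c("trace", "events", "control_trace", "control_events",
                 "file", "energies", "decomposition", "trajectory",
                 "annotations")
  for (stage in intersect(names(config),
                          c("kinetics", "doseresponse", "qpcr", "mmgbsa",
                            "hbonds"))) {
    for (k in intersect(names(config[[stage]]), path_keys)) {
      p <- config[[stage]][[k]]
      if (!is.null(p) && !file.exists(p)) {
        stop(sprintf("config validation: %s$%s file not found: %s",
                     stage, k, p))
      }
    }
  }

  hash <- config_hash(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list(provenance = list(config_hash = hash, seed = seed,
                                    package = "pgptools",
                                    version = as.character(
                                      utils::packageVersion("pgptools"))))
  errors <- list()
  emit <- function(name, df) {
    if (!is.null(out_dir)) {
      write_stage_tsv(df, file.path(out_dir, paste0(name, ".tsv")),
                      hash, seed)
      jsonlite::write_json(df, file.path(out_dir, paste0(name, ".json")),
                           dataframe = "rows", digits = NA)
    }
  }
  run_stage <- function(name, fun) {
    if (is.null(config[[name]])) return()
    res <- tryCatch(fun(config[[name]]),
                    error = function(e) {
                      errors[[name]] <<- conditionMessage(e)
                      NULL
                    })
    if (!is.null(res)) results[[name]] <<- res
  }

  run_stage("kinetics", function(cfg) {
    cond <- assay_conditions(
      total_drug = cfg$total_drug %||% 1000,
      n_cells = cfg$n_cells %||% 2e6,
      solution_volume = cfg$solution_volume %||% 2e-3,
      background = cfg$background %||% 5)
    tr <- read_trace_csv(cfg$trace, cfg$events)
    est <- fit_efflux_kinetics(tr, cond)
    row <- as.data.frame(est[c("F0", "Fn", "FN", "C_n", "C_N", "C_i",
                               "C_e_ss", "V_plus", "k_plus", "V_a",
                               "k_a")])
    row <- cbind(assay = "treated", row)
    if (!is.null(cfg$control_trace)) {
      tc <- read_trace_csv(cfg$control_trace, cfg$control_events)
      ec <- fit_efflux_kinetics(tc, cond)
      rowc <- cbind(assay = "control",
                    as.data.frame(ec[c("F0", "Fn", "FN", "C_n", "C_N",
                                       "C_i", "C_e_ss", "V_plus",
                                       "k_plus", "V_a", "k_a")]))
      row <- rbind(row, rowc)
      r <- inhibition_ratio(est$k_a, ec$k_a)$ratio
      row$inhibition_ratio <- r
    }
    emit("kinetics", row)
    row
  })

  run_stage("doseresponse", function(cfg) {
    dd <- read_dose_response_csv(cfg$file)
    fit <- fit_dose_response(dd, fix_top_bottom =
                               isTRUE(cfg$fix_top_bottom))
    df <- data.frame(ic50 = fit$ic50, hill = fit$hill, top = fit$top,
                     bottom = fit$bottom, rss = fit$rss,
                     converged = fit$converged,
                     ic50_is_bound = fit$ic50_is_bound,
                     unit = dd$unit[1])
    emit("doseresponse", df)
    fit
  })

  run_stage("qpcr", function(cfg) {
    ct <- read_qpcr_csv(cfg$file)
    pick <- function(sample, gene) {
      v <- ct$ct[ct$sample == sample & ct$gene == gene]
      if (!length(v)) stop("no Ct for sample ", sample, " gene ", gene)
      mean(v)
    }
    fold <- ddct_expression(pick(cfg$treated, cfg$target),
                            pick(cfg$treated, cfg$reference),
                            pick(cfg$control, cfg$target),
                            pick(cfg$control, cfg$reference))
    df <- data.frame(target = cfg$target, reference = cfg$reference,
                     treated = cfg$treated, control = cfg$control,
                     fold_change = fold)
    emit("qpcr", df)
    df
  })

  run_stage("mmgbsa", function(cfg) {
    frames <- read_energy_csv(cfg$energies)
    summ <- mmgbsa_summarize(frames,
                             temperature = cfg$temperature %||% 310)
    emit("mmgbsa", summ$summary)
    if (!is.null(cfg$decomposition)) {
      dec <- decompose_filter(read_decomposition_csv(cfg$decomposition),
                              threshold = cfg$threshold %||% -0.5)
      emit("mmgbsa_decomposition", dec)
      summ$decomposition <- dec
    }
    summ
  })

  run_stage("hbonds", function(cfg) {
    traj <- read_trajectory_csv(cfg$trajectory, cfg$annotations)
    occ <- hbond_occupancy(traj,
                           grouping = cfg$grouping %||% "residue",
                           min_occupancy = cfg$min_occupancy %||% 30)
    emit("hbonds", occ)
    cnt <- hbond_count_series(traj)
    list(occupancy = occ, count_mean = cnt$mean, count_sd = cnt$sd)
  })

  results$errors <- errors
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
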