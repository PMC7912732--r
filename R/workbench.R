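#' Run the end-to-end e-MIP design pipeline from a single configuration
#'
#' Executes an ordered subset of stages, each writing its outputs to its
#' own subdirectory of `output_dir`, and aggregates a consolidated
#' report. One global seed fans out deterministically to per-stage seeds,
#' so re-running an identical configuration reproduces every numeric
#' output exactly. A stage whose parameter block and inputs are unchanged
#' (tracked by checksum) is resumed from its stored result instead of
#' recomputed.
#'
#' Stages and their parameter blocks:
#' \describe{
#'   \item{simulate}{Build the layered toy box ([build_layered_initial()])
#'     and sample it ([run_simulation()]). Keys: `n_monomer`, `n_solvent`,
#'     `target_density`, plus any [simulation_spec()] field. Writes
#'     `trajectory.xyz` and the move log.}
#'   \item{cavities}{Extract first-shell cavities from the trajectory
#'     (own `trajectory` key, or the simulate stage's output), run the
#'     funnel and the population report. Keys: `shell_cutoff` (number or
#'     `"auto"`), `stage1_cutoff`, `stage2_cutoff`, `group_range`,
#'     `relax`.}
#'   \item{aim}{Classify a BCP table ([read_bcp_table()] /
#'     [cavity_interaction_summary()]). Keys: `input` (CSV path) or
#'     `synthetic` (arguments of [gen_bcp_table()]), `h_tol`.}
#'   \item{calibrate}{Fit a calibration line ([fit_calibration()]).
#'     Keys: `input` (CSV `concentration,current`) or `synthetic`
#'     (arguments of [gen_calibration()]), `lod_rule`, `s_blank`.}
#'   \item{eis}{Fit a Randles circuit ([fit_randles()]). Keys: `input`
#'     (CSV `frequency,z_real,z_imag`) or `synthetic` (arguments of
#'     [gen_eis()]).}
#'   \item{thickness}{[film_thickness()]. Keys: `q`, `M`, `rho`, `A`,
#'     `n_electrons`.}
#' }
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure: top-level keys `stages` (ordered character vector),
#'   `output_dir`, `seed`, plus one block per stage.
#' @param output_dir Overrides `config$output_dir`.
#' @return An `emip_report` (named list of per-stage results), invisibly;
#'   a plain-text `report.txt` and per-stage CSVs are written under
#'   `output_dir`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) stop("config parse error: ",
                                                conditionMessage(e)))
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  stages <- unlist(config$stages)
  known <- c("simulate", "cavities", "aim", "calibrate", "eis", "thickness")
  if (is.null(stages) || !length(stages))
    stop("config must name at least one stage in 'stages'")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; known: ", paste(known, collapse = ", "))
  if ("cavities" %in% stages && is.null(config$cavities$trajectory) &&
      !"simulate" %in% stages[seq_len(match("cavities", stages) - 1L)])
    stop("stage 'cavities' needs a 'trajectory' input or a preceding ",
         "'simulate' stage")
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (is.null(out_dir)) stop("config must set 'output_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list()
  state <- new.env(parent = emptyenv())
  for (k in seq_along(stages)) {
    stage <- stages[k]
    stage_dir <- file.path(out_dir, stage)
    dir.create(stage_dir, showWarnings = FALSE)
    stage_seed <- (seed * 1009L + k * 9973L) %% .Machine$integer.max
    block <- config[[stage]]
    result <- tryCatch(
      run_stage(stage, block, stage_dir, stage_seed, state),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    report[[stage]] <- result
  }
  class(report) <- "emip_report"
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(report)
}

# checksum of the stage parameter block plus any referenced input files
stage_checksum <- function(block, files = character()) {
  blob <- paste(utils::capture.output(utils::str(block)), collapse = "\n")
  files <- files[file.exists(files)]
  if (length(files))
    blob <- paste(blob, paste(tools::md5sum(files), collapse = ""), sep = "|")
  paste0(nchar(blob), "-", sum(utf8ToInt(gsub("[^ -~]", "", blob))))
}

stage_resume <- function(stage_dir, checksum) {
  cs_file <- file.path(stage_dir, ".inputs.checksum")
  rds <- file.path(stage_dir, "result.rds")
  if (file.exists(cs_file) && file.exists(rds) &&
      identical(readLines(cs_file, warn = FALSE)[1], checksum)) {
    return(readRDS(rds))
  }
  NULL
}

stage_store <- function(result, stage_dir, checksum) {
  saveRDS(result, file.path(stage_dir, "result.rds"))
  writeLines(checksum, file.path(stage_dir, ".inputs.checksum"))
  result
}

run_stage <- function(stage, block, stage_dir, stage_seed, state) {
  if (is.null(block)) block <- list()
  infiles <- unlist(block[c("input", "trajectory")], use.names = FALSE)
  checksum <- paste0(stage_checksum(block, infiles %||% character()),
                     "-s", stage_seed)
  cached <- stage_resume(stage_dir, checksum)
  if (!is.null(cached)) {
    if (stage == "simulate")
      state$trajectory <- file.path(stage_dir, "trajectory.xyz")
    return(cached)
  }
  result <- switch(
    stage,
    simulate = stage_simulate(block, stage_dir, stage_seed, state),
    cavities = stage_cavities(block, stage_dir, stage_seed, state),
    aim = stage_aim(block, stage_dir, stage_seed),
    calibrate = stage_calibrate(block, stage_dir, stage_seed),
    eis = stage_eis(block, stage_dir, stage_seed),
    thickness = stage_thickness(block, stage_dir)
  )
  stage_store(result, stage_dir, checksum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_simulate <- function(block, stage_dir, stage_seed, state) {
  sys <- make_toy_system()
  set.seed(stage_seed)
  initial <- build_layered_initial(
    sys$template, sys$monomer, sys$solvent,
    n_monomer = block$n_monomer %||% 20L,
    n_solvent = block$n_solvent %||% 60L,
    target_density = block$target_density %||% 0.35,
    temperature = block$temperature %||% 298,
    pressure = block$pressure %||% 1)
  spec_args <- block[intersect(names(block), names(formals(simulation_spec)))]
  spec_args$rng_seed <- stage_seed
  spec <- do.call(simulation_spec, spec_args)
  sim <- run_simulation(initial, spec)
  traj_path <- file.path(stage_dir, "trajectory.xyz")
  write_trajectory(sim$frames, traj_path)
  utils::write.csv(sim$moves, file.path(stage_dir, "moves.csv"),
                   row.names = FALSE)
  state$trajectory <- traj_path
  state$topologies <- initial$topologies
  acc <- tapply(sim$moves$accepted, sim$moves$move_kind, mean)
  list(n_frames = length(sim$frames), trajectory = traj_path,
       acceptance = acc,
       final_energy = sim$frames[[length(sim$frames)]]$potential_energy)
}

stage_cavities <- function(block, stage_dir, stage_seed, state) {
  traj_path <- block$trajectory %||% state$trajectory
  if (is.null(traj_path)) stop("no trajectory available")
  topos <- state$topologies %||% {
    s <- make_toy_system()
    stats::setNames(list(s$template, s$monomer, s$solvent),
                    c(s$template$name, s$monomer$name, s$solvent$name))
  }
  frames <- read_trajectory(traj_path, topos)
  cutoff <- block$shell_cutoff %||% 4.0
  if (identical(cutoff, "auto")) cutoff <- shell_cutoff_from_rdf(frames)
  cavities <- lapply(frames, extract_first_shell, shell_cutoff = cutoff)
  pop <- population_report(cavities)
  utils::write.csv(pop, file.path(stage_dir, "population.csv"),
                   row.names = FALSE)
  sizes <- vapply(cavities, function(cv) cv$n_monomers, 0L)
  fspec <- funnel_spec(
    stage1_cutoff = block$stage1_cutoff %||% 10,
    stage2_cutoff = block$stage2_cutoff %||% 5,
    group_range = unlist(block$group_range) %||% range(sizes))
  funnel <- funnel_select(cavities, fspec,
                          relax = block$relax %||% TRUE,
                          max_iterations = block$max_iterations %||% 50)
  utils::write.csv(funnel$groups, file.path(stage_dir, "funnel_groups.csv"),
                   row.names = FALSE)
  ctab <- data.frame(
    run_id = vapply(cavities, function(cv) as.integer(cv$run_id), 0L),
    step = vapply(cavities, function(cv) as.integer(cv$step), 0L),
    n_monomers = sizes)
  utils::write.csv(ctab, file.path(stage_dir, "cavities.csv"),
                   row.names = FALSE)
  for (i in seq_along(funnel$selected)) {
    cv <- funnel$selected[[i]]
    poses <- c(list(cv$template_pose), cv$monomer_poses)
    # recentre so the complex sits well inside the dummy export box and
    # wrapping cannot split it
    minpos <- apply(do.call(rbind, lapply(poses, function(p) p$position)),
                    2, min)
    poses <- lapply(poses, function(p) {
      p$position <- p$position - minpos + 100
      p
    })
    cfg <- configuration(rep(1000, 3), poses, cv$topologies)
    write_trajectory(list(trajectory_frame(cv$run_id, max(cv$step, 0L), cfg,
                                           cv$binding_energy)),
                     file.path(stage_dir, sprintf("cavity_%03d.xyz", i)))
  }
  list(shell_cutoff = cutoff, population = pop, funnel_groups = funnel$groups,
       n_selected = length(funnel$selected))
}

stage_aim <- function(block, stage_dir, stage_seed) {
  tab <- if (!is.null(block$input)) read_bcp_table(block$input)
  else {
    args <- block$synthetic %||% list()
    args$seed <- args$seed %||% stage_seed
    do.call(gen_bcp_table, args)
  }
  h_tol <- block$h_tol %||% 0.005
  ann <- annotate_bcp_table(tab, h_tol)
  utils::write.csv(ann, file.path(stage_dir, "bcp_annotated.csv"),
                   row.names = FALSE)
  summ <- cavity_interaction_summary(tab, h_tol)
  utils::write.csv(summ, file.path(stage_dir, "interaction_summary.csv"),
                   row.names = FALSE)
  summ
}

stage_calibrate <- function(block, stage_dir, stage_seed) {
  dat <- if (!is.null(block$input)) {
    utils::read.csv(block$input)
  } else {
    args <- block$synthetic %||% list()
    args$seed <- args$seed %||% stage_seed
    do.call(gen_calibration, args)
  }
  if (!all(c("concentration", "current") %in% names(dat)))
    stop("calibration data needs 'concentration' and 'current' columns")
  fit <- fit_calibration(dat$concentration, dat$current,
                         lod_rule = block$lod_rule %||% "intercept_se",
                         s_blank = block$s_blank)
  utils::write.csv(
    data.frame(quantity = c("slope", "intercept", "slope_se", "intercept_se",
                            "r_squared", "n", "lod", "loq"),
               value = c(fit$slope, fit$intercept, fit$slope_se,
                         fit$intercept_se, fit$r_squared, fit$n, fit$lod,
                         fit$loq)),
    file.path(stage_dir, "calibration.csv"), row.names = FALSE)
  fit
}

stage_eis <- function(block, stage_dir, stage_seed) {
  spec <- if (!is.null(block$input)) {
    d <- utils::read.csv(block$input)
    if (!all(c("frequency", "z_real", "z_imag") %in% names(d)))
      stop("EIS data needs 'frequency', 'z_real', 'z_imag' columns")
    eis_spectrum(d$frequency, d$z_real, d$z_imag)
  } else {
    args <- block$synthetic %||% list()
    model_keys <- intersect(names(args), names(formals(randles_model)))
    if (length(model_keys))
      args <- c(list(model = do.call(randles_model, args[model_keys])),
                args[setdiff(names(args), model_keys)])
    args$seed <- args$seed %||% stage_seed
    do.call(gen_eis, args)
  }
  fit <- fit_randles(spec)
  utils::write.csv(
    data.frame(parameter = c("r_s", "r_ct", "cpe_q", "cpe_n"),
               value = c(fit$model$r_s, fit$model$r_ct, fit$model$cpe_q,
                         fit$model$cpe_n),
               se = unname(fit$se)),
    file.path(stage_dir, "randles_fit.csv"), row.names = FALSE)
  fit
}

stage_thickness <- function(block, stage_dir) {
  h <- film_thickness(q = block$q, M = block$M %||% 108.14,
                      rho = block$rho %||% 1.2, A = block$A,
                      n_electrons = block$n_electrons)
  utils::write.csv(data.frame(quantity = "film_thickness_nm", value = h),
                   file.path(stage_dir, "thickness.csv"), row.names = FALSE)
  list(thickness_nm = h)
}

#' @export
print.emip_report <- function(x, ...) {
  cat("<emip_report> stages:", paste(names(x), collapse = ", "), "\n")
  for (nm in names(x)) {
    cat("\n==", nm, "==\n")
    r <- x[[nm]]
    if (nm == "cavities") {
      cat("shell cutoff:", format(r$shell_cutoff), "A\n")
      cat("population (fraction by monomer count):\n")
      print(as.data.frame(r$population), row.names = FALSE)
      cat("funnel groups:\n")
      print(r$funnel_groups, row.names = FALSE)
    } else if (nm == "simulate") {
      cat(r$n_frames, "frames;",
          sprintf("final energy %.3f kcal/mol\n", r$final_energy))
      cat("acceptance:", paste(sprintf("%s %.1f%%", names(r$acceptance),
                                       100 * r$acceptance),
                               collapse = ", "), "\n")
    } else if (inherits(r, "calibration_result")) {
      print(r)
    } else if (nm == "eis") {
      cat(sprintf(
        "Randles fit: r_s = %.4g, r_ct = %.4g ohm, Q = %.4g S s^n, n = %.3f%s\n",
        r$model$r_s, r$model$r_ct, r$model$cpe_q, r$model$cpe_n,
        if (length(r$pinned)) paste0(" [pinned: ",
                                     paste(r$pinned, collapse = ","), "]")
        else ""))
    } else if (nm == "thickness") {
      cat(sprintf("film thickness: %.3g nm\n", r$thickness_nm))
    } else {
      print(r)
    }
  }
  invisible(x)
}
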