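# Persistence: trial records as directories of delimited text plus a YAML
# manifest, and YAML run configurations.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a trial record to a directory
#'
#' Persists an `oc_trial` as plain delimited text: `spikes.tsv` (time in
#' seconds, 0-based unit id), `rate.tsv` (time, rate estimate, target),
#' `control.tsv`, `optical.tsv` (per-step blue/yellow power), optionally
#' `whisker.tsv`, and a `manifest.yaml` holding the seed, annotations, and
#' the configuration snapshot.
#'
#' @param trial An `oc_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_record <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- trial$spikes
  write_tsv(data.frame(time_s = fmt_num(sp$time), unit_id = sp$unit - 1L),
            file.path(dir, "spikes.tsv"))
  write_tsv(data.frame(t_s = fmt_num(trial$t), f_hz_per_unit = fmt_num(trial$f),
                       target_hz_per_unit = fmt_num(trial$target)),
            file.path(dir, "rate.tsv"))
  ct <- trial$control
  write_tsv(data.frame(t_s = fmt_num(ct$t), u = fmt_num(ct$u),
                       U_C = fmt_num(ct$U_C), U_H = fmt_num(ct$U_H)),
            file.path(dir, "control.tsv"))
  write_tsv(data.frame(t_s = fmt_num(trial$t),
                       blue_mw_mm2 = fmt_num(trial$blue),
                       yellow_mw_mm2 = fmt_num(trial$yellow)),
            file.path(dir, "optical.tsv"))
  if (!is.null(trial$whisker))
    write_tsv(data.frame(t_s = fmt_num(trial$t),
                         position_deg = fmt_num(trial$whisker)),
              file.path(dir, "whisker.tsv"))
  manifest <- list(
    seed = trial$seed,
    dt_sim = trial$dt_sim,
    n_steps = trial$n_steps,
    annotations = trial$annotations,
    config = serialize_config(trial$config))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

# flatten the configuration snapshot into plain lists for YAML
serialize_config <- function(cfg) {
  plant <- cfg$plant
  ctl <- cfg$controller
  list(
    plant = c(list(type = plant$type),
              lapply(unclass(plant$params), function(x)
                if (inherits(x, "oc_drug_condition")) unclass(x) else x)),
    controller = lapply(unclass(ctl), function(x)
      if (is.list(x)) lapply(unclass(x), identity) else x),
    schedule = list(times = cfg$schedule$times, rates = cfg$schedule$rates),
    timing = unclass(cfg$timing),
    duration = cfg$duration,
    pre_pulse = cfg$pre_pulse,
    whisker = cfg$whisker,
    lock_at = cfg$lock_at,
    lock_mode = cfg$lock_mode)
}

#' Read a trial record from a directory
#'
#' Reconstructs the traces and manifest written by [write_trial_record()].
#' The configuration snapshot is returned as plain lists (sufficient to
#' re-run via [config_to_objects()] and [run_closed_loop()]).
#'
#' @param dir Record directory.
#' @return An object of class `oc_trial`.
#' @export
read_trial_record <- function(dir) {
  need <- c("spikes.tsv", "rate.tsv", "control.tsv", "optical.tsv",
            "manifest.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("record at ", dir, " lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t")
  sp <- rd("spikes.tsv")
  rate <- rd("rate.tsv")
  ctl <- rd("control.tsv")
  opt <- rd("optical.tsv")
  whisker <- NULL
  if (file.exists(file.path(dir, "whisker.tsv")))
    whisker <- rd("whisker.tsv")$position_deg
  cfgl <- man$config
  cfg <- config_to_objects(cfgl)
  cfg$duration <- cfgl$duration
  cfg$pre_pulse <- cfgl$pre_pulse
  cfg$whisker <- cfgl$whisker
  cfg$lock_at <- cfgl$lock_at
  cfg$lock_mode <- cfgl$lock_mode
  structure(list(
    dt_sim = man$dt_sim, n_steps = man$n_steps, t = rate$t_s,
    spikes = data.frame(time = sp$time_s, unit = sp$unit_id + 1L),
    f = rate$f_hz_per_unit,
    target = rate$target_hz_per_unit,
    blue = opt$blue_mw_mm2, yellow = opt$yellow_mw_mm2,
    counts = NULL,
    control = data.frame(t = ctl$t_s, u = ctl$u, U_C = ctl$U_C,
                         U_H = ctl$U_H),
    whisker = whisker,
    seed = man$seed,
    config = cfg,
    annotations = man$annotations),
    class = "oc_trial")
}

#' Build plant/controller/schedule objects from a plain configuration list
#'
#' Accepts the nested list produced by reading a YAML run configuration
#' (blocks `plant`, `controller`, `schedule`, `timing`, plus scalar
#' options) and instantiates the corresponding package objects. Unknown
#' keys are rejected.
#'
#' @param cfg A named list.
#' @return A list with `plant`, `controller`, `schedule`, `timing`.
#' @export
config_to_objects <- function(cfg) {
  pl <- cfg$plant
  ptype <- pl$type %||% "network"
  pargs <- pl[setdiff(names(pl), "type")]
  plant <- switch(ptype,
    network = {
      if (!is.null(pargs$drug) && is.list(pargs$drug))
        pargs$drug <- do.call(drug_condition, pargs$drug)
      network_plant(do.call(network_plant_params, pargs))
    },
    tcu = tcu_plant(do.call(tcu_plant_params, pargs)),
    static = do.call(static_gain_plant, pargs),
    stop("unknown plant type: ", ptype, call. = FALSE))
  cl <- cfg$controller
  ctype <- cl$type %||% "pi"
  cargs <- cl[setdiff(names(cl), c("type", "cfg", "waveform"))]
  if (!is.null(cl$cfg)) cargs <- c(cargs, cl$cfg[setdiff(names(cl$cfg),
                                                         c("u_min", "u_max"))])
  if (!is.null(cl$waveform) && is.list(cl$waveform))
    cargs$waveform <- cl$waveform$kind
  else if (!is.null(cl$waveform)) cargs$waveform <- cl$waveform
  controller <- switch(ctype,
    pi = do.call(pi_controller, cargs),
    integral = do.call(integral_controller, cargs),
    onoff = do.call(onoff_controller, cargs),
    stop("unknown controller type: ", ctype, call. = FALSE))
  sc <- cfg$schedule
  schedule <- if (is.null(sc)) target_schedule(0, 1) else
    target_schedule(unlist(sc$times) %||% 0, unlist(sc$rates))
  timing <- if (is.null(cfg$timing)) loop_timing() else
    do.call(loop_timing, cfg$timing)
  list(plant = plant, controller = controller, schedule = schedule,
       timing = timing)
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file with blocks `plant`, `controller`,
#'   `schedule`, `timing` and scalars `duration`, `seed`, `pre_pulse`.
#' @return The raw configuration list (validated keys).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("plant", "controller", "schedule", "timing", "duration",
             "seed", "pre_pulse", "whisker", "lock_at", "lock_mode",
             "output")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}
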