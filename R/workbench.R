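#' Generate synthetic fixtures with known ground truth
#'
#' Three fixture kinds support oracle-style testing:
#' \describe{
#'   \item{`toy_trace`}{A trapezoidal AP train: rest at -85 mV, instantaneous
#'     rise to +20 mV at each stimulus, plateau of `apd_ms`, instantaneous
#'     fall.  `measure_apd()` must recover `apd_ms` exactly.}
#'   \item{`toy_restitution`}{A sigmoid-plus-plateau (DI, APD) point set
#'     mimicking an EAD-steepened restitution curve:
#'     `APD = base + amp / (1 + exp(-(DI - di_mid)/width))`.}
#'   \item{`reverse_engineered_map`}{A knot set whose interpolating spline
#'     carries an exactly planted period-2 orbit `{di_a, di_b}` at period
#'     `T`: the knots include `(di_a, T - di_b)` and `(di_b, T - di_a)`.}
#' }
#' Generation is deterministic given `seed` (only `toy_restitution` with
#' `noise_sd > 0` draws random numbers).
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param ... shape parameters, see Details of each kind in the source.
#' @return a list whose content depends on `kind`; always contains the
#'   ground-truth values needed by a test.
#' @export
generate_fixture <- function(kind = c("toy_trace", "toy_restitution",
                                      "reverse_engineered_map"),
                             seed = 1, ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  g <- function(nm, def) opts[[nm]] %||% def
  switch(kind,
    toy_trace = {
      n_beats <- g("n_beats", 3)
      CL <- g("CL", 500)
      apd_ms <- g("apd_ms", 200)
      dt <- g("dt", 0.5)
      t <- seq(0, n_beats * CL, by = dt)
      v <- rep(-85, length(t))
      stim <- (seq_len(n_beats) - 1) * CL
      for (s in stim) v[t > s & t <= s + apd_ms] <- 20
      list(trace = data.frame(t = t, v = v), stim_times = stim,
           apd_true = apd_ms, CL = CL)
    },
    toy_restitution = {
      di <- g("di", seq(20, 500, by = 20))
      base <- g("base", 200)
      amp <- g("amp", 250)
      di_mid <- g("di_mid", 350)
      width <- g("width", 15)
      noise_sd <- g("noise_sd", 0)
      apd <- base + amp / (1 + exp(-(di - di_mid) / width))
      if (noise_sd > 0) {
        rng <- cpp_binom_stream(length(di), 1000000L, 0.5, seed)
        apd <- apd + noise_sd * (rng - 5e5) / sqrt(25e10)
      }
      list(points = data.frame(di = di, apd = apd), base = base, amp = amp,
           di_mid = di_mid, width = width)
    },
    reverse_engineered_map = {
      T <- g("T", 650)
      di_a <- g("di_a", 250)
      di_b <- g("di_b", 420)
      stopifnot(di_a < di_b)
      lo <- di_a - 100
      hi <- di_b + 100
      mid <- (di_a + di_b) / 2
      kd <- c(lo, di_a, mid, di_b, hi)
      ka <- c(T - di_b - 40, T - di_b, T - mid, T - di_a, T - di_a + 40)
      list(points = data.frame(di = kd, apd = ka), T = T,
           orbit = c(di_a, di_b))
    })
}

#' Figure-style experiment presets
#'
#' Named, reduced-scale experiment configurations mirroring the package's
#' reference protocols: `fig3a` (single-cell dynamic CL sweep, normal vs
#' reduced inactivation), `fig5b` (deterministic hysteresis sweep plus
#' stochastic overlay), `fig8` (S1S2 restitution, spline map, bifurcation
#' diagram and second-iterate analysis) and `fig9b` (tissue-derived map phase
#' diagram).  Pass `full = TRUE` for publication-scale beat counts.
#'
#' @param name preset name.
#' @param full use full-scale beat counts.
#' @param seed integer seed.
#' @return an experiment config list for [run_experiment()].
#' @export
preset_config <- function(name = c("fig3a", "fig5b", "fig8", "fig9b"),
                          full = FALSE, seed = 1) {
  name <- match.arg(name)
  bpc <- if (full) 200 else 30
  rec <- if (full) 50 else 10
  base <- list(name = name, seed = seed, preset = "ead")
  proto <- switch(name,
    fig3a = list(kind = "dynamic_sweep", CLs = seq(440, 552, by = 16),
                 beats_per_CL = bpc, record_last = rec, direction = "up",
                 compare_normal = TRUE),
    fig5b = list(kind = "dynamic_sweep", CLs = seq(475, 550, by = 15),
                 beats_per_CL = bpc, record_last = rec,
                 direction = "up_then_down"),
    fig8 = list(kind = "map_analysis", S1 = 500,
                s2_list = seq(320, 1000, by = if (full) 20 else 40),
                beats_S1 = if (full) 50 else 20,
                T_range = seq(560, 720, by = if (full) 2 else 8)),
    fig9b = list(kind = "phase_diagram", S1 = 500,
                 s2_list = seq(320, 1000, by = if (full) 20 else 40),
                 dimin_block = 25,
                 T_grid = seq(560, 760, by = if (full) 5 else 20),
                 DI0_grid = seq(60, 500, by = if (full) 10 else 40)))
  c(base, list(protocol = proto))
}

#' Run a configured experiment and write its outputs
#'
#' Executes one experiment described by a config list (or YAML file path):
#' model preset plus overrides, simulation mode, protocol, and output
#' directory.  All tabular outputs are CSV; a `manifest.json` records the
#' config hash, package version, seeds, per-stage wall time and the file
#' list, so a rerun with the same config reproduces the outputs bit for bit
#' (stochastic ones per seed).
#'
#' @param config config list (see [preset_config()]) or path to a YAML file.
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_experiment <- function(config, outdir = tempfile("eadsim_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  params <- do.call(ead_params, c(list(config$preset %||% "default"),
                                  config$overrides %||% list()))
  seed <- config$seed %||% 1
  proto <- config$protocol
  files <- character(0)
  stages <- list()
  emit <- function(df, nm) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, basename(path))
  }
  stage <- function(nm, expr) {
    s0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    stages[[nm]] <<- round(proc.time()[["elapsed"]] - s0, 3)
    out
  }
  if (!is.null(proto) && length(proto)) {
    kind <- proto$kind
    if (kind == "steady") {
      md <- ead_mode(proto$mode %||% "stochastic", proto$Nb %||% 4000, seed)
      tr <- stage("pace", run_paced(params, proto$CL, proto$n_beats,
                                    mode = md, record_ca = TRUE))
      emit(tr$trace, "trace")
      ser <- measure_apd(tr)
      emit(as.data.frame(ser), "apd_series")
    } else if (kind == "dynamic_sweep") {
      md <- ead_mode(proto$mode %||% "deterministic", proto$Nb %||% 4000, seed)
      bif <- stage("sweep", dynamic_pacing_sweep(
        params, proto$CLs, proto$beats_per_CL %||% 200,
        proto$record_last %||% 50, proto$direction %||% "up", mode = md))
      emit(bif, "bifurcation")
      if (isTRUE(proto$compare_normal)) {
        pn <- modifyList(params, list(aca = 0.15))
        class(pn) <- class(params)
        bifn <- stage("sweep_normal", dynamic_pacing_sweep(
          pn, proto$CLs, proto$beats_per_CL %||% 200,
          proto$record_last %||% 50, proto$direction %||% "up", mode = md))
        emit(bifn, "bifurcation_normal")
      }
    } else if (kind == "s1s2") {
      pts <- stage("s1s2", s1s2_restitution(params, proto$S1, proto$s2_list,
                                            proto$beats_S1 %||% 50))
      emit(pts, "restitution_points")
    } else if (kind == "map_analysis") {
      pts <- stage("s1s2", s1s2_restitution(params, proto$S1, proto$s2_list,
                                            proto$beats_S1 %||% 50))
      emit(pts, "restitution_points")
      map <- fit_restitution_spline(pts, proto$dimin_block %||% 0)
      bif <- stage("map_bif", map_bifurcation_diagram(map, proto$T_range))
      emit(bif$data, "map_bifurcation")
      fps <- stage("fixed_points", do.call(rbind, lapply(proto$T_range,
        function(T) {
          fp <- second_iterate_fixed_points(map, T)
          if (!nrow(fp)) return(NULL)
          cbind(T = T, fp)
        })))
      if (is.null(fps)) fps <- data.frame(T = numeric(0), di = numeric(0))
      emit(fps, "fixed_points")
    } else if (kind == "phase_diagram") {
      pts <- stage("s1s2", s1s2_restitution(params, proto$S1, proto$s2_list,
                                            proto$beats_S1 %||% 20))
      emit(pts, "restitution_points")
      map <- fit_restitution_spline(pts, proto$dimin_block %||% 25)
      pd <- stage("phase_diagram",
                  phase_diagram(map, proto$T_grid, proto$DI0_grid))
      emit(as.data.frame(as.table(unclass(pd))), "phase_diagram")
    } else if (kind == "tissue") {
      md <- ead_mode(proto$mode %||% "stochastic", proto$Nb %||% 4000, seed)
      run <- stage("tissue", run_tissue(
        params, proto$nr, proto$nc, stim_times = proto$stim_times,
        stim_region = proto$stim_region, mode = md,
        snap_dt = proto$snap_dt %||% 0))
      emit(run$events, "events")
      emit(apd_map(run), "apd_map")
      if (length(run$snap_t)) {
        sn <- data.frame(time = rep(run$snap_t, each = run$nr * run$nc),
                         cell = rep(seq_len(run$nr * run$nc),
                                    length(run$snap_t)),
                         v = as.vector(t(run$snapshots)))
        emit(sn, "snapshots")
      }
    } else stop("unknown protocol kind: ", kind)
  }
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    name = config$name %||% "experiment",
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("eadsim")),
    seed = seed,
    stages_s = stages,
    wall_s = round(proc.time()[["elapsed"]] - t0, 3),
    files = files,
    complete = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
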