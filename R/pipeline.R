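#' Pipeline configuration
#'
#' Collects every analysis constant at its study default: 10 Hz
#' kinematic and 20 Hz EMG low-pass cutoffs (both order 4, zero-phase),
#' ten peaks per cycle, up to ten mixture modes, minimum 6 walk / 13
#' trot cycles per trial, significance level 0.05. Overrides are
#' validated here (an EMG cutoff at or above the 60 Hz Nyquist of the
#' 120 Hz envelope is rejected before any computation) and echoed into
#' the run log.
#'
#' @param data_dir directory holding the trial CSVs and `manifest.json`
#'   (written by [generate_study()] or following the same contract).
#' @param out_dir output directory for TSVs, the run manifest and log.
#' @param synthetic optional list with elements `session`
#'   ([session_spec()]), and optionally `gait_specs` and
#'   `burst_library`; when present the dataset is generated into
#'   `data_dir` first.
#' @param kin_cutoff_hz kinematic low-pass cutoff (default 10).
#' @param emg_cutoff_hz envelope low-pass cutoff (default 20).
#' @param filter_order Butterworth order for both filters (default 4).
#' @param n_peaks peaks kept per cycle (default 10).
#' @param K_max maximum mixture components (default 10).
#' @param merge_tol mode merge radius, % of cycle (default 2).
#' @param weight_floor minimum surviving mode weight (default
#'   `1/(4 x n_cycles)`, resolved per group).
#' @param normalization_scope `"dcd"` (pool gaits within a day, default)
#'   or `"dcd_gait"`.
#' @param min_cycles named vector, minimum cycles per trial per gait.
#' @param alpha_level significance level (default 0.05).
#' @param seed master seed.
#' @param overwrite allow regenerating an existing synthetic dataset.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            synthetic = NULL,
                            kin_cutoff_hz = 10, emg_cutoff_hz = 20,
                            filter_order = 4, n_peaks = 10L, K_max = 10L,
                            merge_tol = 2, weight_floor = NULL,
                            normalization_scope = c("dcd", "dcd_gait"),
                            min_cycles = c(walk = 6L, trot = 13L),
                            alpha_level = 0.05, seed = 1L,
                            overwrite = FALSE) {
  normalization_scope <- match.arg(normalization_scope)
  if (emg_cutoff_hz >= 60)
    stop("pipeline_config: EMG cutoff must be below the 60 Hz Nyquist of the 120 Hz envelope",
         call. = FALSE)
  if (kin_cutoff_hz >= 60)
    stop("pipeline_config: kinematic cutoff must be below 60 Hz", call. = FALSE)
  if (n_peaks < 1L || K_max < 1L)
    stop("pipeline_config: 'n_peaks' and 'K_max' must be >= 1", call. = FALSE)
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("pipeline_config: 'alpha_level' must be in (0, 1)", call. = FALSE)
  if (!all(c("walk", "trot") %in% names(min_cycles)))
    stop("pipeline_config: 'min_cycles' needs named walk and trot entries",
         call. = FALSE)
  structure(list(
    data_dir = data_dir, out_dir = out_dir, synthetic = synthetic,
    kin_cutoff_hz = kin_cutoff_hz, emg_cutoff_hz = emg_cutoff_hz,
    filter_order = filter_order, n_peaks = as.integer(n_peaks),
    K_max = as.integer(K_max), merge_tol = merge_tol,
    weight_floor = weight_floor, normalization_scope = normalization_scope,
    min_cycles = min_cycles, alpha_level = alpha_level,
    seed = as.integer(seed), overwrite = overwrite),
    class = "pipeline_config")
}

#' Validate a dataset against the CSV header contract
#'
#' Checks, for every trial in the manifest: file existence, the
#' `time_s` leading column, expected kinematic columns (`hoofL_z`,
#' `hoofR_z`), expected EMG channel columns (`side_position`), strictly
#' increasing time, and agreement between the declared sampling rate and
#' the median sample spacing.
#'
#' @param data_dir dataset directory containing `manifest.json`.
#' @param manifest optional pre-read manifest list.
#' @return data frame of violations (`file`, `check`, `detail`); zero
#'   rows when the dataset is well formed.
#' @export
validate_inputs <- function(data_dir, manifest = NULL) {
  if (is.null(manifest))
    manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                    simplifyVector = FALSE)
  bad <- list()
  flag <- function(file, check, detail)
    bad[[length(bad) + 1L]] <<- data.frame(file = file, check = check,
                                           detail = detail)
  sess <- manifest$session
  expected_chan <- as.vector(outer(unlist(sess$sides),
                                   unlist(sess$electrodes), paste, sep = "_"))
  check_rate <- function(tv, declared, file) {
    dt <- diff(tv)
    if (any(dt <= 0)) flag(file, "time_monotone", "time_s not strictly increasing")
    med <- stats::median(dt)
    if (abs(1 / med - declared) / declared > 1e-3)
      flag(file, "rate_mismatch",
           sprintf("declared %g Hz, observed %.3f Hz", declared, 1 / med))
  }
  for (tr in manifest$trials) {
    for (kind in c("kin_file", "emg_file")) {
      f <- tr[[kind]]
      p <- file.path(data_dir, f)
      if (!file.exists(p)) { flag(f, "missing_file", "file not found"); next }
      hdr <- utils::read.csv(p, nrows = 1, check.names = FALSE)
      if (names(hdr)[1] != "time_s") {
        flag(f, "header", "first column must be time_s"); next
      }
      d <- utils::read.csv(p, check.names = FALSE)
      if (kind == "kin_file") {
        miss <- setdiff(c("hoofL_z", "hoofR_z"), names(d))
        if (length(miss))
          flag(f, "missing_channel", paste(miss, collapse = ", "))
        check_rate(d$time_s, as.numeric(sess$kin_rate_hz), f)
      } else {
        miss <- setdiff(expected_chan, names(d))
        if (length(miss))
          flag(f, "missing_channel", paste(miss, collapse = ", "))
        check_rate(d$time_s, as.numeric(sess$emg_rate_hz), f)
      }
    }
  }
  if (!length(bad))
    data.frame(file = character(), check = character(), detail = character())
  else do.call(rbind, bad)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: optional synthetic-data generation, input
#' validation, kinematic filtering and cycle segmentation, the EMG
#' conditioning chain with per-electrode per-DCD normalization,
#' per-group peak pooling and mixture fitting, stance/swing phase
#' summaries, and (when the layout supports them) the comparison and
#' reliability statistics. All outputs are TSVs plus a JSON run
#' manifest and a plain-text log in `config$out_dir`.
#'
#' Trials failing the minimum-cycle rule for their gait are excluded and
#' listed in the run manifest; exclusion bookkeeping satisfies
#' detected = used + excluded.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a run summary list: per-group phase summaries
#'   (`$summaries` data frame), mixture fits (`$fits`), cycle table,
#'   exclusions, statistics tables, and output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("run_pipeline: 'config' must come from pipeline_config()",
         call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  logf("pipeline start, seed %d", config$seed)
  logf("cycle convention: hoof-on to next hoof-on; phases referenced to the left hind cycle")

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gait_specs <- syn$gait_specs
    if (is.null(gait_specs)) gait_specs <- default_gait_specs()
    burst_library <- syn$burst_library
    if (is.null(burst_library)) burst_library <- default_burst_library()
    generate_study(syn$session, gait_specs, burst_library,
                   out_dir = config$data_dir, overwrite = config$overwrite)
    logf("synthetic dataset generated in %s", config$data_dir)
  }
  manifest <- jsonlite::read_json(file.path(config$data_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  viol <- validate_inputs(config$data_dir, manifest)
  if (nrow(viol) > 0) {
    print(viol)
    stop("run_pipeline: input validation failed (stage: validate_inputs)",
         call. = FALSE)
  }
  logf("input validation passed (%d trials)", length(manifest$trials))

  sess <- manifest$session
  emg_rate <- as.numeric(sess$emg_rate_hz)

  # ---- segmentation + per-channel envelopes, per trial -------------------
  trials <- list()
  exclusions <- list()
  cycle_rows <- list()
  for (ti in seq_along(manifest$trials)) {
    tr <- manifest$trials[[ti]]
    gait <- tr$gait
    kin <- utils::read.csv(file.path(config$data_dir, tr$kin_file),
                           check.names = FALSE)
    hoofL <- time_series(kin$hoofL_z, as.numeric(sess$kin_rate_hz), "hoofL_z")
    hoofR <- time_series(kin$hoofR_z, as.numeric(sess$kin_rate_hz), "hoofR_z")
    fL <- lowpass_kinematics(hoofL, config$kin_cutoff_hz, config$filter_order)
    fR <- lowpass_kinematics(hoofR, config$kin_cutoff_hz, config$filter_order)
    min_c <- config$min_cycles[[gait]]
    cyc <- tryCatch(detect_cycles(fL, min_cycles = min_c, side = "L"),
                    insufficient_cycles_error = function(e) e)
    if (inherits(cyc, "error")) {
      exclusions[[length(exclusions) + 1L]] <- list(
        trial = ti, horse = tr$horse, dcd = tr$dcd, gait = gait,
        reason = sprintf("insufficient cycles: found %d, need %d",
                         e_count(cyc), min_c),
        n_cycles_detected = e_count(cyc))
      logf("trial %d (%s DCD%s %s T%s) excluded: %s cycles < %d",
           ti, tr$horse, tr$dcd, gait, tr$trial, e_count(cyc), min_c)
      next
    }
    rcyc <- tryCatch(contralateral_cycles(cyc, fR),
                     insufficient_cycles_error = function(e) NULL)
    emg <- utils::read.csv(file.path(config$data_dir, tr$emg_file),
                           check.names = FALSE)
    chans <- setdiff(names(emg), "time_s")
    envs <- lapply(chans, function(ch)
      preprocess_emg(time_series(emg[[ch]], emg_rate, ch),
                     cutoff_hz = config$emg_cutoff_hz))
    names(envs) <- chans
    trials[[length(trials) + 1L]] <- list(
      idx = ti, horse = tr$horse, dcd = as.integer(tr$dcd), gait = gait,
      trial = as.integer(tr$trial), cycles = cyc, right_cycles = rcyc,
      envelopes = envs)
    for (ci in seq_along(cyc)) {
      c1 <- cyc[[ci]]
      cycle_rows[[length(cycle_rows) + 1L]] <- data.frame(
        trial = ti, horse = tr$horse, dcd = as.integer(tr$dcd), gait = gait,
        side = "L", cycle_index = ci,
        start_s = (c1$start_idx - 1) / hoofL$rate_hz,
        hoof_off_s = (c1$hoof_off_idx - 1) / hoofL$rate_hz,
        end_s = (c1$end_idx - 1) / hoofL$rate_hz,
        duty_factor = cycle_duty_factor(c1))
    }
  }
  if (!length(trials))
    stop("run_pipeline: no trial passed the minimum-cycle rule (stage: segmentation)",
         call. = FALSE)
  cycles_df <- do.call(rbind, cycle_rows)
  write_tsv(cycles_df, file.path(config$out_dir, "cycles.tsv"))

  # ---- session-level normalization --------------------------------------
  norm_rows <- list()
  scope_key <- function(tr, ch) {
    base <- paste(tr$horse, tr$dcd, ch, sep = "|")
    if (config$normalization_scope == "dcd_gait")
      paste(base, tr$gait, sep = "|") else base
  }
  pools <- list()
  for (i in seq_along(trials)) {
    for (ch in names(trials[[i]]$envelopes)) {
      key <- scope_key(trials[[i]], ch)
      pools[[key]] <- c(pools[[key]], list(c(i, ch)))
    }
  }
  for (key in names(pools)) {
    members <- pools[[key]]
    envs <- lapply(members, function(m) trials[[as.integer(m[1])]]$envelopes[[m[2]]])
    normed <- normalize_session(envs)
    for (j in seq_along(members)) {
      m <- members[[j]]
      trials[[as.integer(m[1])]]$envelopes[[m[2]]] <- normed[[j]]
    }
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    norm_rows[[length(norm_rows) + 1L]] <- data.frame(
      horse = parts[1], dcd = parts[2], channel = parts[3],
      scope = config$normalization_scope,
      max_value = attr(normed, "norm_constant"),
      trial_of_max = attr(normed, "trial_of_max"))
  }
  write_tsv(do.call(rbind, norm_rows),
            file.path(config$out_dir, "norm_constants.tsv"))
  logf("normalization done: %d (horse, DCD, channel%s) pools",
       length(pools),
       if (config$normalization_scope == "dcd_gait") ", gait" else "")

  # ---- per-group mode analysis ------------------------------------------
  groups <- unique(do.call(rbind, lapply(trials, function(tr)
    expand.grid(horse = tr$horse, dcd = tr$dcd, gait = tr$gait,
                channel = names(tr$envelopes), stringsAsFactors = FALSE))))
  groups <- groups[order(groups$horse, groups$dcd, groups$gait,
                         groups$channel), ]
  mode_rows <- list(); summary_rows <- list(); fits <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    side <- sub("_.*", "", g$channel)
    electrode <- sub(".*_", "", g$channel)
    gtrials <- Filter(function(tr)
      tr$horse == g$horse && tr$dcd == g$dcd && tr$gait == g$gait &&
        g$channel %in% names(tr$envelopes), trials)
    peak_tables <- list()
    duties <- numeric(); r_on_phase <- numeric(); r_duty <- numeric()
    for (tr in gtrials) {
      env <- tr$envelopes[[g$channel]]
      nmax <- length(env$values)
      for (ci in seq_along(tr$cycles)) {
        cyc <- tr$cycles[[ci]]
        if (cyc$end_idx - 1L > nmax) next  # envelope a sample short at the edge
        duties <- c(duties, cycle_duty_factor(cyc))
        pk <- suppressWarnings(extract_cycle_peaks(
          env, cyc, n_peaks = config$n_peaks,
          cycle_id = tr$idx * 1000L + ci))
        pk$side <- side
        if (nrow(pk)) peak_tables[[length(peak_tables) + 1L]] <- pk
      }
      if (!is.null(tr$right_cycles)) {
        pr <- attr(tr$right_cycles, "pairing")
        if (!is.null(pr)) r_on_phase <- c(r_on_phase, pr$hoofon_phase_pct)
        r_duty <- c(r_duty, vapply(tr$right_cycles, cycle_duty_factor,
                                   numeric(1)))
      }
    }
    if (!length(peak_tables)) {
      logf("group %s DCD%s %s %s: no peaks; skipped",
           g$horse, g$dcd, g$gait, g$channel)
      next
    }
    pk_all <- pool_peaks(peak_tables,
                         group = list(horse = g$horse, dcd = g$dcd,
                                      gait = g$gait, side = side,
                                      electrode = electrode))
    gseed <- (config$seed + 7919L * gi) %% (.Machine$integer.max - 1L)
    fit <- fit_mixture(pk_all, K_max = config$K_max, seed = gseed,
                       merge_tol = config$merge_tol,
                       weight_floor = config$weight_floor)
    duty_hat <- mean(duties)
    if (side == "L") {
      stance_iv <- c(0, 100 * duty_hat)
    } else {
      p0 <- circular_mean_pct(r_on_phase)
      dR <- if (length(r_duty)) mean(r_duty) else duty_hat
      stance_iv <- c(p0, (p0 + 100 * dR) %% 100)
    }
    swing_iv <- c(stance_iv[2], stance_iv[1])
    ps <- suppressMessages(
      summarize_by_phase(fit, stance_iv, swing_iv,
                         group = attr(pk_all, "group")))
    key <- sprintf("%s|%s|%s|%s", g$horse, g$dcd, g$gait, g$channel)
    fits[[key]] <- fit
    mode_rows[[length(mode_rows) + 1L]] <- data.frame(
      horse = g$horse, dcd = g$dcd, gait = g$gait, side = side,
      electrode = electrode, mode_index = seq_len(fit$K),
      MML_pct = fit$means, MMV = fit$mode_values,
      weight = fit$weights, sd = fit$sds)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      horse = g$horse, dcd = as.integer(g$dcd), gait = g$gait, side = side,
      electrode = electrode,
      MML_St = ps$MML_St, MMV_St = ps$MMV_St,
      MML_Sw = ps$MML_Sw, MMV_Sw = ps$MMV_Sw,
      stance_start_pct = stance_iv[1], stance_end_pct = stance_iv[2],
      n_modes = fit$K)
  }
  modes_df <- do.call(rbind, mode_rows)
  summaries <- do.call(rbind, summary_rows)
  write_tsv(modes_df, file.path(config$out_dir, "modes.tsv"))
  write_tsv(summaries, file.path(config$out_dir, "phase_summary.tsv"))
  logf("mode analysis done: %d groups", length(fits))

  # ---- statistics --------------------------------------------------------
  stats_df <- pipeline_statistics(summaries, config$alpha_level)
  if (!is.null(stats_df$comparisons))
    write_tsv(stats_df$comparisons, file.path(config$out_dir, "stats.tsv"))
  if (!is.null(stats_df$reliability))
    write_tsv(stats_df$reliability, file.path(config$out_dir, "reliability.tsv"))

  # ---- run manifest ------------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tmp <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  n_detected <- nrow(cycles_df) +
    sum(vapply(exclusions, function(e) e$n_cycles_detected, numeric(1)))
  run_manifest <- list(
    package_version = as.character(utils::packageVersion("emgmodes")),
    seed = config$seed, config_hash = cfg_hash,
    hoofon_convention = "cycles run hoof-on to next hoof-on; phases referenced to the left hind cycle",
    n_trials_used = length(trials), n_trials_excluded = length(exclusions),
    n_cycles_used = nrow(cycles_df), n_cycles_detected_total = n_detected,
    exclusions = exclusions)
  jsonlite::write_json(run_manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done: %d groups, %d cycles used, %d trials excluded",
       length(fits), nrow(cycles_df), length(exclusions))
  writeLines(log_lines, log_path)

  invisible(list(summaries = summaries, modes = modes_df, fits = fits,
                 cycles = cycles_df, exclusions = exclusions,
                 stats = stats_df, config_hash = cfg_hash,
                 out_dir = config$out_dir))
}

e_count <- function(e) {
  cnt <- e$count
  if (is.null(cnt)) 0L else as.integer(cnt)
}

# Mean of phases on the circular [0, 100) axis.
circular_mean_pct <- function(p) {
  if (!length(p)) return(NA_real_)
  ang <- p / 100 * 2 * pi
  (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * 100) %% 100
}

# Comparison + reliability layer over the per-group phase summaries.
# Families: walk-vs-trot = electrodes x phases per quantity;
# left-vs-right likewise; DCD comparisons = one family per quantity.
pipeline_statistics <- function(summaries, alpha_level) {
  out <- list(comparisons = NULL, reliability = NULL)
  if (is.null(summaries) || !nrow(summaries)) return(out)
  quantities <- c("MML_St", "MMV_St", "MML_Sw", "MMV_Sw")
  rows <- list()
  electrodes <- unique(summaries$electrode)

  # walk vs trot, paired over (horse, side, dcd), per electrode x quantity
  if (all(c("walk", "trot") %in% summaries$gait)) {
    fam <- length(electrodes) * length(quantities)
    for (el in electrodes) for (q in quantities) {
      w <- summaries[summaries$gait == "walk" & summaries$electrode == el, ]
      t <- summaries[summaries$gait == "trot" & summaries$electrode == el, ]
      key <- function(d) paste(d$horse, d$side, d$dcd)
      common <- intersect(key(w), key(t))
      if (length(common) >= 3L) {
        a <- w[[q]][match(common, key(w))]
        b <- t[[q]][match(common, key(t))]
        res <- tryCatch(
          route_and_compare_paired(a, b, family_size = fam,
                                   alpha_level = alpha_level),
          error = function(e) NULL)
        if (!is.null(res))
          rows[[length(rows) + 1L]] <- data.frame(
            question = "walk_vs_trot", grouping = paste(el, q),
            test_name = res$test_name, statistic = res$statistic,
            p_raw = res$p_raw, p_adjusted = res$p_adjusted,
            family = fam, route = ifelse(res$normal_route, "normal",
                                         "non-normal"))
      }
    }
  }
  # left vs right, paired over (horse, gait, dcd, electrode)
  if (all(c("L", "R") %in% summaries$side)) {
    fam <- length(electrodes) * length(quantities)
    for (el in electrodes) for (q in quantities) {
      l <- summaries[summaries$side == "L" & summaries$electrode == el, ]
      r <- summaries[summaries$side == "R" & summaries$electrode == el, ]
      key <- function(d) paste(d$horse, d$gait, d$dcd)
      common <- intersect(key(l), key(r))
      if (length(common) >= 3L) {
        res <- tryCatch(
          route_and_compare_paired(l[[q]][match(common, key(l))],
                                   r[[q]][match(common, key(r))],
                                   family_size = fam,
                                   alpha_level = alpha_level),
          error = function(e) NULL)
        if (!is.null(res))
          rows[[length(rows) + 1L]] <- data.frame(
            question = "left_vs_right", grouping = paste(el, q),
            test_name = res$test_name, statistic = res$statistic,
            p_raw = res$p_raw, p_adjusted = res$p_adjusted,
            family = fam, route = ifelse(res$normal_route, "normal",
                                         "non-normal"))
      }
    }
  }
  # across DCDs, repeated measures over (horse, side, electrode, gait)
  dcds <- sort(unique(summaries$dcd))
  if (length(dcds) >= 2L) {
    for (q in quantities) {
      wide <- stats::reshape(
        summaries[, c("horse", "side", "electrode", "gait", "dcd", q)],
        idvar = c("horse", "side", "electrode", "gait"),
        timevar = "dcd", direction = "wide")
      m <- as.matrix(wide[, grepl(paste0("^", q, "\\."), names(wide)),
                          drop = FALSE])
      if (nrow(m) >= 3L && ncol(m) >= 2L &&
          sum(stats::complete.cases(m)) >= 3L) {
        res <- tryCatch(
          route_and_compare_repeated(m, family_size = length(quantities),
                                     alpha_level = alpha_level),
          error = function(e) NULL)
        if (!is.null(res))
          rows[[length(rows) + 1L]] <- data.frame(
            question = "between_dcds", grouping = q,
            test_name = res$test_name, statistic = res$statistic,
            p_raw = res$p_raw, p_adjusted = res$p_adjusted,
            family = length(quantities),
            route = ifelse(res$normal_route, "normal", "non-normal"))
      }
      # reliability across days
      if (ncol(m) >= 2L && sum(stats::complete.cases(m)) >= 2L) {
        alpha <- tryCatch(suppressMessages(cronbach_alpha(m)),
                          error = function(e) NA_real_)
        out$reliability <- rbind(out$reliability, data.frame(
          quantity = q, alpha = alpha,
          n_rows = sum(stats::complete.cases(m)), n_occasions = ncol(m)))
      }
    }
  }
  if (length(rows)) out$comparisons <- do.call(rbind, rows)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
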