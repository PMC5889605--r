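#' @title Gaussian-mixture mode analysis of envelope peaks
#' @description
#' The analysis core: collect the ten highest envelope peaks per motion
#' cycle, pool them per horse x gait x side x electrode, fit a
#' one-dimensional Gaussian mixture over the peak phases by EM, and
#' summarize the surviving modes as mean mode locations (MML, % of the
#' motion cycle) and mean mode values (MMV, normalized amplitude <= 1)
#' split by stance and swing phase.
#' @name mode-analysis
NULL

#' Extract the highest envelope peaks of one motion cycle
#'
#' Finds every interior local maximum of the envelope within the cycle
#' (plateaus contribute their first sample) and keeps the `n_peaks`
#' largest; equal amplitudes are broken in favour of the earlier phase.
#' Each kept peak carries its normalized phase through the supplied
#' phase map, which may belong to the ipsilateral or (for right-side
#' channels referenced to the left cycle) the paired contralateral cycle.
#'
#' @param envelope normalized envelope [time_series()] at 120 Hz.
#' @param cycle the [motion_cycle()] delimiting the search.
#' @param phase_map [cycle_phase_map()] used to convert sample indices to
#'   phase; defaults to the cycle's own map.
#' @param n_peaks maximum number of peaks kept per cycle (study value 10).
#' @param cycle_id identifier stored with each peak.
#' @return data frame with columns `phase_pct`, `amplitude`, `cycle_id`,
#'   `side`; zero rows (with a warning) if the envelope has no interior
#'   local maximum in the cycle.
#' @export
extract_cycle_peaks <- function(envelope, cycle, phase_map = NULL,
                                n_peaks = 10L, cycle_id = 1L) {
  assert_ts(envelope)
  if (!inherits(cycle, "motion_cycle"))
    stop("extract_cycle_peaks: 'cycle' must be a motion_cycle", call. = FALSE)
  if (cycle$end_idx - 1L > length(envelope$values) || cycle$start_idx < 1L)
    stop("extract_cycle_peaks: cycle exceeds envelope span", call. = FALSE)
  if (is.null(phase_map)) phase_map <- cycle_phase_map(cycle)
  seg <- envelope$values[cycle$start_idx:(cycle$end_idx - 1L)]
  loc <- local_maxima(seg)
  if (!length(loc)) {
    warning("extract_cycle_peaks: no interior local maximum in cycle")
    return(data.frame(phase_pct = numeric(), amplitude = numeric(),
                      cycle_id = integer(), side = character()))
  }
  amp <- seg[loc]
  ord <- order(-amp, loc)
  keep <- ord[seq_len(min(n_peaks, length(ord)))]
  idx <- cycle$start_idx + loc[keep] - 1L
  data.frame(phase_pct = phase_of_sample(phase_map, idx),
             amplitude = amp[keep],
             cycle_id = rep(as.integer(cycle_id), length(keep)),
             side = rep(cycle$side, length(keep)))
}

# Interior local maxima of a numeric vector; a plateau that is higher
# than both neighbours contributes its first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Pool per-cycle peaks into one peak set
#'
#' Concatenates the per-cycle peak tables of one
#' horse x gait x side x electrode (x DCD) group, preserving cycle
#' provenance.
#'
#' @param per_cycle_peaks list of data frames from
#'   [extract_cycle_peaks()]; `cycle_id`s must be distinct per cycle.
#' @param group named list or character giving the shared grouping key;
#'   stored as an attribute.
#' @return a `peak_set`: the concatenated data frame with attribute
#'   `"group"`.
#' @export
pool_peaks <- function(per_cycle_peaks, group = NULL) {
  if (!length(per_cycle_peaks)) {
    out <- data.frame(phase_pct = numeric(), amplitude = numeric(),
                      cycle_id = integer(), side = character())
  } else {
    sides <- unique(unlist(lapply(per_cycle_peaks, function(d) unique(d$side))))
    if (length(sides) > 1L)
      stop("pool_peaks: peaks from more than one side in one group",
           call. = FALSE)
    out <- do.call(rbind, per_cycle_peaks)
  }
  counts <- table(out$cycle_id)
  if (any(counts > 10L))
    stop("pool_peaks: a cycle contributed more than 10 peaks", call. = FALSE)
  attr(out, "group") <- group
  class(out) <- c("peak_set", class(out))
  out
}

#' Fit a Gaussian mixture to pooled peak phases
#'
#' Fits a one-dimensional `K_max`-component Gaussian mixture to the peak
#' phases by expectation-maximization with multiple restarts, then
#' post-processes the converged solution: components whose means lie
#' within `merge_tol` percent of the cycle are merged, and components
#' with weight below `weight_floor` are dropped. The surviving component
#' means are the mean mode locations (MML); each surviving mode's mean
#' mode value (MMV) is the responsibility-weighted mean amplitude of the
#' peaks assigned to it by maximum posterior responsibility.
#'
#' EM details: components are initialized at phase quantiles refined by
#' k-means; 10 restarts (the first deterministic, the rest with
#' resampled initial centers); convergence on relative log-likelihood
#' change below `tol`; component SDs floored at `sd_floor` percent of
#' the cycle to prevent singular components.
#'
#' @param peaks a [pool_peaks()] result (or data frame with `phase_pct`,
#'   `amplitude`, `cycle_id`).
#' @param K_max maximum number of components (study value 10); lowered
#'   to the number of peaks when fewer are available.
#' @param seed integer seed controlling initialization.
#' @param merge_tol merge radius in % of cycle (default 2).
#' @param weight_floor minimum surviving weight; default
#'   `1 / (4 x number of cycles)`.
#' @param n_restarts EM restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param sd_floor minimum component SD in % of cycle (default 0.25).
#' @param max_iter maximum EM iterations per restart.
#' @return a `mixture_fit` list: `K`, `weights`, `means`, `sds`,
#'   `mode_values`, `loglik`, `loglik_trace`, `n_restarts_used`, `seed`,
#'   and the per-peak `assignment`. Modes are sorted by mean phase.
#' @export
fit_mixture <- function(peaks, K_max = 10L, seed = 1L, merge_tol = 2,
                        weight_floor = NULL, n_restarts = 10L, tol = 1e-8,
                        sd_floor = 0.25, max_iter = 500L) {
  x <- peaks$phase_pct
  a <- peaks$amplitude
  n <- length(x)
  if (n == 0L) stop("fit_mixture: empty peak set", call. = FALSE)
  if (is.null(weight_floor)) {
    n_cycles <- max(1L, length(unique(peaks$cycle_id)))
    weight_floor <- 1 / (4 * n_cycles)
  }
  K <- min(K_max, n, length(unique(x)))

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init_mu <- if (r == 1L) {
        stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE,
                        type = 7)
      } else {
        sort(sample(x, K, replace = FALSE))
      }
      init_mu <- unique(init_mu)
      fit <- tryCatch(
        em_gmm_1d(x, init_mu, sd_floor = sd_floor, tol = tol,
                  max_iter = max_iter),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
        best <- fit
    }
  })
  if (is.null(best))
    stop(errorCondition("fit_mixture: EM failed in all restarts",
                        class = c("em_failure_error", "error")))

  post <- merge_and_drop(best, merge_tol, weight_floor)
  # responsibilities under the surviving components
  resp <- gmm_responsibilities(x, post$weights, post$means, post$sds)
  assign_k <- max.col(resp, ties.method = "first")
  present <- sort(unique(assign_k))
  # a surviving component with no assigned peak carries no mode value
  post$weights <- post$weights[present]
  post$means <- post$means[present]
  post$sds <- post$sds[present]
  resp <- resp[, present, drop = FALSE]
  assign_k <- match(assign_k, present)
  post$weights <- post$weights / sum(post$weights)

  mmv <- vapply(seq_along(post$means), function(k) {
    sel <- assign_k == k
    sum(resp[sel, k] * a[sel]) / sum(resp[sel, k])
  }, numeric(1))

  ord <- order(post$means)
  structure(list(
    K = length(ord),
    weights = post$weights[ord],
    means = post$means[ord],
    sds = post$sds[ord],
    mode_values = mmv[ord],
    loglik = best$loglik,
    loglik_trace = best$trace,
    n_restarts_used = n_restarts,
    seed = seed,
    assignment = match(assign_k, ord)),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: %d modes, loglik %.3f>\n", x$K, x$loglik))
  print(data.frame(mode = seq_len(x$K), MML_pct = round(x$means, 2),
                   MMV = round(x$mode_values, 3),
                   weight = round(x$weights, 3), sd = round(x$sds, 2)))
  invisible(x)
}

# Log-density matrix n x K of Normal(x | mu_k, sd_k)
gmm_logdens <- function(x, means, sds) {
  outer(x, seq_along(means), function(xi, k)
    stats::dnorm(xi, means[k], sds[k], log = TRUE))
}

gmm_responsibilities <- function(x, weights, means, sds) {
  lp <- sweep(gmm_logdens(x, means, sds), 2, log(weights), `+`)
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

# One EM run. Initial centers are refined by k-means when more than one
# component is requested. Log-likelihood is tracked per iteration; it is
# non-decreasing up to the SD floor's projection.
em_gmm_1d <- function(x, init_mu, sd_floor, tol, max_iter) {
  n <- length(x)
  K <- length(init_mu)
  if (K > 1L && length(unique(x)) > K) {
    km <- suppressWarnings(stats::kmeans(x, centers = matrix(init_mu, ncol = 1),
                                         iter.max = 50))
    mu <- as.numeric(km$centers)
    w <- as.numeric(km$size) / n
    sds <- vapply(seq_len(K), function(k) {
      s <- stats::sd(x[km$cluster == k])
      if (is.na(s)) 0 else s
    }, numeric(1))
  } else {
    mu <- init_mu
    w <- rep(1 / K, K)
    sds <- rep(stats::sd(x), K)
    if (is.na(sds[1])) sds <- rep(sd_floor, K)
  }
  sds <- pmax(sds, sd_floor)
  w <- pmax(w, 1e-6); w <- w / sum(w)

  ll_old <- -Inf
  trace <- numeric()
  for (it in seq_len(max_iter)) {
    lp <- sweep(gmm_logdens(x, mu, sds), 2, log(w), `+`)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        (ll - ll_old) < tol * max(1, abs(ll_old))) break
    ll_old <- ll
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-12)) nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sds <- vapply(seq_len(K), function(k)
      sqrt(sum(resp[, k] * (x - mu[k])^2) / nk[k]), numeric(1))
    sds <- pmax(sds, sd_floor)
  }
  list(weights = w, means = mu, sds = sds, loglik = ll, trace = trace)
}

# Merge components whose means differ by less than merge_tol — applied
# transitively (single linkage), so a chain of overlapping components
# collapses into one mode — then drop components lighter than
# weight_floor, renormalizing weights.
merge_and_drop <- function(fit, merge_tol, weight_floor) {
  ord <- order(fit$means)
  w <- fit$weights[ord]; mu <- fit$means[ord]; sds <- fit$sds[ord]
  grp <- cumsum(c(1, diff(mu) >= merge_tol))
  merged <- lapply(split(seq_along(mu), grp), function(idx) {
    wi <- w[idx]
    m <- sum(wi * mu[idx]) / sum(wi)
    s2 <- sum(wi * (sds[idx]^2 + (mu[idx] - m)^2)) / sum(wi)
    c(weight = sum(wi), mean = m, sd = sqrt(s2))
  })
  w <- unname(vapply(merged, `[[`, numeric(1), "weight"))
  mu <- unname(vapply(merged, `[[`, numeric(1), "mean"))
  sds <- unname(vapply(merged, `[[`, numeric(1), "sd"))
  keep <- w >= weight_floor
  if (!any(keep)) keep <- which.max(w)
  w <- w[keep]; mu <- mu[keep]; sds <- sds[keep]
  list(weights = w / sum(w), means = mu, sds = sds)
}

#' Split modes into stance- and swing-phase summaries
#'
#' Assigns each surviving mode to stance or swing by its mean mode
#' location. Within each phase the summary MMV is the mean of that
#' phase's mode MMVs and the summary MML is the location of the mode
#' with the largest MMV (the dominant mode). Intervals are given on the
#' cycle phase axis and may wrap (start > end), as the contralateral
#' limb's stance does when referenced to the ipsilateral cycle; together
#' they must partition \[0, 100).
#'
#' @param fit a [fit_mixture()] result.
#' @param stance_interval numeric `c(start, end)` in % of cycle.
#' @param swing_interval numeric `c(start, end)`; must be the circular
#'   complement of `stance_interval`.
#' @param group optional grouping key stored on the result.
#' @return a `phase_summary` list: `MML_St`, `MMV_St`, `MML_Sw`,
#'   `MMV_Sw` (NA when a phase holds no mode), plus the intervals and
#'   per-phase mode counts.
#' @export
summarize_by_phase <- function(fit, stance_interval, swing_interval,
                               group = NULL) {
  iv_len <- function(iv) (iv[2] - iv[1]) %% 100
  st_len <- iv_len(stance_interval); sw_len <- iv_len(swing_interval)
  if (abs(st_len + sw_len - 100) > 1e-6 ||
      abs((stance_interval[2] - swing_interval[1]) %% 100) > 1e-6 ||
      abs((swing_interval[2] - stance_interval[1]) %% 100) > 1e-6)
    stop("summarize_by_phase: intervals must partition [0, 100) without overlap",
         call. = FALSE)
  in_iv <- function(p, iv) {
    s <- iv[1] %% 100; e <- iv[2] %% 100
    if (s < e) p >= s & p < e else p >= s | p < e
  }
  st <- which(in_iv(fit$means, stance_interval))
  sw <- which(in_iv(fit$means, swing_interval))
  pick <- function(idx) {
    if (!length(idx)) return(list(MML = NA_real_, MMV = NA_real_))
    dom <- idx[which.max(fit$mode_values[idx])]
    list(MML = fit$means[dom], MMV = mean(fit$mode_values[idx]))
  }
  ps <- pick(st); pw <- pick(sw)
  if (!length(sw)) message("summarize_by_phase: no swing-phase mode; fields NA")
  if (!length(st)) message("summarize_by_phase: no stance-phase mode; fields NA")
  structure(list(MML_St = ps$MML, MMV_St = ps$MMV,
                 MML_Sw = pw$MML, MMV_Sw = pw$MMV,
                 stance_interval_pct = stance_interval,
                 swing_interval_pct = swing_interval,
                 n_modes_St = length(st), n_modes_Sw = length(sw),
                 group = group),
            class = "phase_summary")
}

#' Circular left-right shift of mean mode locations
#'
#' Circular distance `min(d, 100 - d)` between the left and right
#' summaries' MMLs, per phase. With hind limbs alternating at half a
#' cycle this is expected near 50% of the motion cycle.
#'
#' @param left,right [summarize_by_phase()] results for the two sides.
#' @return named numeric `c(St = , Sw = )` in \[0, 50\]; NA propagates
#'   from missing MMLs.
#' @export
left_right_shift <- function(left, right) {
  circ <- function(a, b) {
    d <- abs(a - b) %% 100
    pmin(d, 100 - d)
  }
  c(St = circ(left$MML_St, right$MML_St),
    Sw = circ(left$MML_Sw, right$MML_Sw))
}
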