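#' Homogeneous Poisson background spike trains
#'
#' Independent Poisson spike trains: each neuron's spike count over the
#' recording is Poisson with mean `rate_hz * duration_s` and spike times
#' are uniform on `[0, duration_s]`.
#'
#' @param n_neurons population size.
#' @param rate_hz per-neuron firing rate in Hz (>= 0).
#' @param duration_s recording length in seconds.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return A [spike_data] object.
#' @export
generate_background <- function(n_neurons, rate_hz, duration_s, seed = NULL) {
  stopifnot(n_neurons >= 1, rate_hz >= 0, duration_s > 0)
  with_seed(seed, {
    counts <- rpois(n_neurons, rate_hz * duration_s)
    events <- data.frame(
      neuron_id = rep(seq_len(n_neurons) - 1L, counts),
      time = runif(sum(counts), 0, duration_s))
    spike_data(events, n_neurons = n_neurons, duration = duration_s)
  })
}

#' Specification of one embedded cell assembly
#'
#' @param members 0-based neuron ids of the assembly members.
#' @param mode `"synchronous"` (all members fire together),
#'   `"sequential"` (members fire in order, evenly spaced over the span) or
#'   `"sequential-reverse"`.
#' @param span_s duration of one occurrence in seconds (0 for synchronous).
#' @param jitter_s uniform timing jitter half-width in seconds (each member
#'   spike is displaced by U(-jitter, jitter)).
#' @param occurrences number of embedded occurrences.
#' @param time_scale compression factor >= 1: the occurrence is emitted
#'   over `span_s / time_scale` seconds (temporally compressed replay).
#' @return An object of class `assembly_spec`.
#' @export
assembly_spec <- function(members, mode = c("synchronous", "sequential",
                                            "sequential-reverse"),
                          span_s = 0, jitter_s = 0, occurrences = 1,
                          time_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(length(members) >= 1, span_s >= 0, jitter_s >= 0,
            occurrences >= 1, time_scale >= 1)
  structure(list(members = as.integer(members), mode = mode, span_s = span_s,
                 jitter_s = jitter_s, occurrences = as.integer(occurrences),
                 time_scale = time_scale),
            class = "assembly_spec")
}

#' Embed assembly occurrences into background activity
#'
#' Places each occurrence at a random position; with the window-boundary
#' constraint (default), each occurrence is placed wholly inside one
#' window of length `window_s`, so no assembly spike crosses a window
#' boundary, and occurrences of all assemblies go to distinct windows.
#' Member neurons keep their background spikes in addition to the
#' assembly spikes.
#'
#' @param background a [spike_data] object.
#' @param specs list of [assembly_spec] objects.
#' @param window_s window length used for the boundary constraint.
#' @param seed integer seed.
#' @param distinct_windows place all occurrences in distinct windows
#'   (default TRUE, keeps the ground-truth labels unambiguous).
#' @return A list with `data` (spike_data including the embedded spikes)
#'   and `truth`, an object of class `synth_truth` holding the per-
#'   occurrence table (`assembly`, `start`, `end`, `window`).
#' @export
embed_assemblies <- function(background, specs, window_s, seed = NULL,
                             distinct_windows = TRUE) {
  stopifnot(inherits(background, "spike_data"))
  if (inherits(specs, "assembly_spec")) specs <- list(specs)
  lapply(specs, function(s) {
    if (any(s$members >= background$n_neurons)) {
      stop("assembly members outside the population")
    }
  })
  n_windows <- floor(background$duration / window_s + 1e-9)
  total_occ <- sum(vapply(specs, function(s) s$occurrences, integer(1)))
  if (distinct_windows && total_occ > n_windows) {
    stop(sprintf("cannot place %d occurrences in %d windows", total_occ,
                 n_windows))
  }
  with_seed(seed, {
    win_pool <- if (distinct_windows) {
      sample.int(n_windows, total_occ)
    } else {
      sample.int(n_windows, total_occ, replace = TRUE)
    }
    occ_rows <- list()
    new_events <- list()
    oc <- 0L
    for (a in seq_along(specs)) {
      s <- specs[[a]]
      A <- length(s$members)
      span_eff <- s$span_s / s$time_scale
      if (span_eff + 2 * s$jitter_s > window_s) {
        stop("occurrence (span / time_scale + jitter margins) does not fit in a window")
      }
      # sequential members are evenly spaced at intervals span/A (one
      # inter-spike interval of head room keeps the last spike strictly
      # inside the placement span)
      offsets <- if (s$mode == "synchronous") {
        rep(0, A)
      } else {
        o <- (seq_len(A) - 1) / A * span_eff
        if (s$mode == "sequential-reverse") rev(o) else o
      }
      for (k in seq_len(s$occurrences)) {
        oc <- oc + 1L
        w <- win_pool[oc]
        lo <- (w - 1) * window_s + s$jitter_s
        hi <- max(w * window_s - span_eff - s$jitter_s, lo)
        start <- runif(1, lo, hi)
        times <- start + offsets + runif(A, -s$jitter_s, s$jitter_s)
        new_events[[oc]] <- data.frame(neuron_id = s$members, time = times)
        occ_rows[[oc]] <- data.frame(assembly = a, start = min(times),
                                     end = max(times), window = w)
      }
    }
    events <- rbind(background$events, do.call(rbind, new_events))
    data <- spike_data(events, n_neurons = background$n_neurons,
                       duration = background$duration)
    occ <- do.call(rbind, occ_rows)
    truth <- structure(list(occurrences = occ, specs = specs,
                            window_s = window_s),
                       class = "synth_truth")
    list(data = data, truth = truth)
  })
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d occurrences of %d assemblies\n",
              nrow(x$occurrences), length(x$specs)))
  invisible(x)
}

#' Named synthetic benchmark regimes
#'
#' Generates datasets for the named benchmark regime, each with ground
#' truth and a recommended pipeline configuration. Regimes:
#' \describe{
#'   \item{`fig4`}{3 sequential assemblies of 20 neurons, 10 occurrences
#'     each, 60 neurons total, 1 Hz background, 60 s.}
#'   \item{`fig6a`}{5 synchronous assemblies of 20 neurons (+-10 ms
#'     jitter), 50 occurrences each, 100 neurons, 2 Hz, 300 s. `duration_s`
#'     may be reduced; occurrence counts scale proportionally.}
#'   \item{`fig6c`}{as `fig6a` with +-50 ms jitter.}
#'   \item{`fig6d`}{3 assemblies of 20 neurons, each embedded in forward,
#'     synchronous and reverse order (9 sequence types), 20 occurrences
#'     each, 60 neurons, 1 Hz, 60 s.}
#'   \item{`fig6f`}{one synchronous 100-neuron assembly without jitter,
#'     20 occurrences, 5 Hz background, 60 s; population size set by
#'     `population`.}
#'   \item{`fig6g`}{30-neuron sequences spanning 200 ms plus copies
#'     compressed 3x, 5x and 10x, 20 occurrences each, 100 neurons, 1 Hz,
#'     60 s.}
#'   \item{`sec3_5_100ms`}{one sequential 10-neuron assembly spanning
#'     100 ms, 60 occurrences, 100 neurons, 1 Hz, 60 s.}
#'   \item{`sec3_5_500ms`}{as above with a 500 ms span (and a 500 ms
#'     window).}
#' }
#'
#' @param name regime name.
#' @param n_datasets number of independently generated datasets.
#' @param seed master seed; per-dataset seeds are derived deterministically.
#' @param duration_s optional reduced duration for the `fig6a`/`fig6c`
#'   regimes.
#' @param population population size for `fig6f` (1000, 3000 or 5000 in
#'   the original design).
#' @return List of length `n_datasets`; each element has `data`, `truth`
#'   and `config` (a [pipeline_config]).
#' @export
benchmark_suite <- function(name, n_datasets = 1, seed = 1L,
                            duration_s = NULL, population = 1000) {
  regimes <- c("fig4", "fig6a", "fig6c", "fig6d", "fig6f", "fig6g",
               "sec3_5_100ms", "sec3_5_500ms")
  if (!name %in% regimes) {
    stop("unknown regime '", name, "'; available: ",
         paste(regimes, collapse = ", "))
  }
  lapply(seq_len(n_datasets), function(d) {
    s_bg <- derive_seed(seed, paste0(name, "-bg"), d)
    s_em <- derive_seed(seed, paste0(name, "-embed"), d)
    make_regime(name, s_bg, s_em, duration_s, population)
  })
}

make_regime <- function(name, s_bg, s_em, duration_s, population) {
  seq_members <- function(k, A) as.integer(((k - 1) * A):(k * A - 1))
  if (name %in% c("fig6a", "fig6c")) {
    dur <- duration_s %||% 300
    occ <- max(1L, as.integer(round(50 * dur / 300)))
    jit <- if (name == "fig6a") 0.010 else 0.050
    bg <- generate_background(100, 2, dur, seed = s_bg)
    specs <- lapply(1:5, function(k) {
      assembly_spec(seq_members(k, 20), "synchronous", span_s = 0,
                    jitter_s = jit, occurrences = occ)
    })
    emb <- embed_assemblies(bg, specs, window_s = 0.2, seed = s_em)
    cfg <- pipeline_config(window_s = 0.2, bin_s = 0.01, alpha = 1,
                           n3 = 10, min_pts = 5, v = 5)
  } else if (name == "fig4") {
    bg <- generate_background(60, 1, 60, seed = s_bg)
    specs <- lapply(1:3, function(k) {
      assembly_spec(seq_members(k, 20), "sequential", span_s = 0.1,
                    jitter_s = 0.010, occurrences = 10)
    })
    emb <- embed_assemblies(bg, specs, window_s = 0.2, seed = s_em)
    cfg <- pipeline_config(window_s = 0.2, bin_s = 0.01, alpha = 1,
                           n3 = 5, min_pts = 5, v = 5)
  } else if (name == "fig6d") {
    bg <- generate_background(60, 1, 60, seed = s_bg)
    modes <- c("sequential", "synchronous", "sequential-reverse")
    specs <- unlist(lapply(1:3, function(k) {
      lapply(modes, function(md) {
        assembly_spec(seq_members(k, 20), md,
                      span_s = if (md == "synchronous") 0 else 0.1,
                      jitter_s = 0.010, occurrences = 20)
      })
    }), recursive = FALSE)
    emb <- embed_assemblies(bg, specs, window_s = 0.2, seed = s_em)
    cfg <- pipeline_config(window_s = 0.2, bin_s = 0.01, alpha = 2,
                           n3 = "auto", min_pts = 20, v = 2)
  } else if (name == "fig6f") {
    bg <- generate_background(population, 5, 60, seed = s_bg)
    specs <- list(assembly_spec(0:99, "synchronous", span_s = 0,
                                jitter_s = 0, occurrences = 20))
    emb <- embed_assemblies(bg, specs, window_s = 0.2, seed = s_em)
    cfg <- pipeline_config(window_s = 0.2, bin_s = 0.01, alpha = 1,
                           n3 = "auto", min_pts = 5, v = 5)
  } else if (name == "fig6g") {
    bg <- generate_background(100, 1, 60, seed = s_bg)
    specs <- unlist(lapply(c(1, 3, 5, 10), function(ts) {
      list(assembly_spec(0:29, "sequential", span_s = 0.2, jitter_s = 0,
                         occurrences = 20, time_scale = ts))
    }), recursive = FALSE)
    emb <- embed_assemblies(bg, specs, window_s = 0.2, seed = s_em)
    cfg <- pipeline_config(window_s = 0.2, bin_s = 0.01, alpha = 0.1,
                           n3 = 8, min_pts = 5, v = 5)
  } else { # sec3_5_*
    span <- if (name == "sec3_5_100ms") 0.1 else 0.5
    win <- if (name == "sec3_5_100ms") 0.2 else 0.5
    bg <- generate_background(100, 1, 60, seed = s_bg)
    specs <- list(assembly_spec(0:9, "sequential", span_s = span,
                                jitter_s = 0, occurrences = 60))
    emb <- embed_assemblies(bg, specs, window_s = win, seed = s_em)
    cfg <- pipeline_config(window_s = win, bin_s = 0.01, alpha = 1,
                           n3 = "auto", min_pts = 5, v = 5)
  }
  list(data = emb$data, truth = emb$truth, config = cfg)
}
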