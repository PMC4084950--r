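#' Simulation parameters
#'
#' Assembles and validates the parameter set of the eco-evolutionary
#' simulator. Time is measured in hours, with one hour equal to the inverse
#' host growth rate (a typical host generation); the culture volume is
#' fixed at 1 mL so densities double as expected individual counts for the
#' stochastic event draws.
#'
#' @param S Maximum spacers per host CRISPR locus.
#' @param P Protospacers per viral genome.
#' @param q Spacer acquisition probability per adsorption.
#' @param mu Escape mutation probability per protospacer per new virion.
#' @param r Host growth rate, per hour.
#' @param K Host carrying capacity, cells/mL.
#' @param phi Adsorption rate constant, mL/hour.
#' @param beta Burst size, virions per lysis.
#' @param m_v Viral decay (deactivation) rate outside hosts, per hour.
#' @param f Immunity failure probability: chance a host with a matching
#'   spacer is nevertheless lysed.
#' @param dt Integration step, hours.
#' @param cutoff Extinction density cutoff, individuals/mL; strains below
#'   it are pruned and a side falling below it ends the run.
#' @param t_end Simulated horizon, hours.
#' @param record_every Snapshot interval, hours.
#' @param init_host,init_virus Founding densities of the single naive host
#'   strain (empty locus) and the single ancestral viral strain.
#' @return A list of class `sim_params`.
#' @examples
#' sim_params(P = 20, mu = 1e-7)
#' @export
sim_params <- function(S = 10, P = 10, q = 1e-5, mu = 5e-7,
                       r = 1, K = 3.158e5, phi = 1e-7, beta = 50,
                       m_v = 0.1, f = 1e-5, dt = 0.05, cutoff = 0.1,
                       t_end = 10000, record_every = 1,
                       init_host = 1e5, init_virus = 1e6) {
  p <- list(S = as.integer(S), P = as.integer(P), q = q, mu = mu, r = r,
            K = K, phi = phi, beta = beta, m_v = m_v, f = f, dt = dt,
            cutoff = cutoff, t_end = t_end, record_every = record_every,
            init_host = init_host, init_virus = init_virus)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  for (nm in c("q", "mu", "f")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      abort(paste0("'", nm, "' must lie in [0, 1]"))
    }
  }
  for (nm in c("r", "K", "phi", "beta", "m_v", "init_host", "init_virus")) {
    if (p[[nm]] < 0) abort(paste0("'", nm, "' must be >= 0"))
  }
  if (p$S < 1 || p$P < 1) abort("'S' and 'P' must be >= 1")
  if (p$dt <= 0 || p$dt >= 1) abort("'dt' must lie in (0, 1)")
  if (p$cutoff <= 0) abort("'cutoff' must be > 0")
  if (p$t_end <= 0) abort("'t_end' must be > 0")
  if (p$record_every < p$dt) abort("'record_every' must be >= 'dt'")
  invisible(p)
}

#' Simulate CRISPR host-phage coevolution
#'
#' Runs the hybrid deterministic/stochastic eco-evolutionary model: strain
#' densities follow Lotka-Volterra-like dynamics (logistic host growth,
#' adsorption-driven infection, burst-size viral production, free-virion
#' decay) integrated by fixed-step RK4, while new strains arise
#' stochastically through leader-end spacer acquisition by hosts and
#' protospacer escape mutation in viruses (infinite-alleles model). The run
#' starts from a single naive host strain and a single ancestral viral
#' strain and ends at `t_end` or when either side's total density falls
#' below the extinction cutoff.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the run is bit-reproducible given
#'   `params` and `seed`.
#' @return A `crispr_trajectory` object with elements
#'   \describe{
#'     \item{totals}{tibble: `time`, `host_total`, `viral_total`,
#'       `n_hosts`, `n_viruses`, `min_locus` (shortest host locus).}
#'     \item{raw}{per-snapshot strain ids and densities (lists parallel to
#'       `totals$time`); use [tidy()] for the long per-strain table.}
#'     \item{registry}{tibble mapping `side` + `strain_id` to the strain's
#'       allele content (list-column `alleles`; ordered spacers for hosts,
#'       positional protospacers for viruses).}
#'     \item{outcome}{`"completed"`, `"viral_extinction"` or
#'       `"host_extinction"`.}
#'     \item{locus_filled_in_window}{TRUE when every host strain carries
#'       `S` spacers at every recorded point of the final 500 h of a
#'       completed run.}
#'     \item{events}{named counts of acquisitions, escape mutations and
#'       negative-density clips.}
#'   }
#' @examples
#' traj <- simulate_coevolution(sim_params(t_end = 50), seed = 1)
#' glance(traj)
#' @seealso [trajectory_metrics()], [summarize_replicate()], [run_sweep()]
#' @export
simulate_coevolution <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  raw <- run_coevolution_cpp(unclass(params))
  if (raw$n_negative_clips > 0) {
    warn(paste0(raw$n_negative_clips, " negative densities clipped to 0; ",
                "the integration step may be too coarse"))
  }
  totals <- tibble(
    time = raw$times,
    host_total = raw$host_total,
    viral_total = raw$viral_total,
    n_hosts = vapply(raw$host_ids, length, 1L),
    n_viruses = vapply(raw$virus_ids, length, 1L),
    min_locus = raw$min_locus
  )
  registry <- tibble(
    side = rep(c("host", "virus"),
               c(length(raw$host_registry_id),
                 length(raw$virus_registry_id))),
    strain_id = c(raw$host_registry_id, raw$virus_registry_id),
    alleles = c(raw$host_registry_spacers, raw$virus_registry_protospacers)
  )
  new_trajectory(
    params = params, seed = seed, totals = totals,
    raw = list(host_ids = raw$host_ids,
               host_densities = raw$host_densities,
               virus_ids = raw$virus_ids,
               virus_densities = raw$virus_densities),
    registry = registry, outcome = raw$outcome,
    events = c(acquisitions = raw$n_acquisitions,
               acquisition_noops = raw$n_acquisition_noops,
               mutations = raw$n_mutations,
               negative_clips = raw$n_negative_clips)
  )
}

new_trajectory <- function(params, seed, totals, raw, registry, outcome,
                           events) {
  end_time <- tail(totals$time, 1)
  window <- totals$time > end_time - 500
  filled <- identical(outcome, "completed") &&
    all(totals$min_locus[window] == params$S)
  structure(list(
    params = params, seed = seed,
    totals = totals, raw = raw, registry = registry,
    outcome = outcome, end_time = end_time,
    locus_filled_in_window = filled,
    events = events
  ), class = "crispr_trajectory")
}

#' @export
print.crispr_trajectory <- function(x, ...) {
  cat("<crispr_trajectory> ", x$outcome, " at t = ", x$end_time, " h\n",
      sep = "")
  cat("  ", nrow(x$totals), " snapshots; final: ",
      tail(x$totals$n_hosts, 1), " host / ",
      tail(x$totals$n_viruses, 1), " viral strain(s)\n", sep = "")
  invisible(x)
}

#' Extract a community snapshot from a trajectory
#'
#' @param traj A `crispr_trajectory`.
#' @param time Requested time in hours; the nearest recorded snapshot is
#'   used.
#' @return A [community()] for that snapshot.
#' @examples
#' traj <- simulate_coevolution(sim_params(t_end = 50), seed = 1)
#' community_at(traj, 50)
#' @export
community_at <- function(traj, time) {
  stopifnot(inherits(traj, "crispr_trajectory"))
  m <- which.min(abs(traj$totals$time - time))
  t0 <- traj$totals$time[m]
  build_side <- function(ids, dens, side_name, allele_col) {
    reg <- traj$registry[traj$registry$side == side_name, , drop = FALSE]
    out <- tibble(strain_id = ids, density = dens)
    out[[allele_col]] <- reg$alleles[match(ids, reg$strain_id)]
    out
  }
  hosts <- build_side(traj$raw$host_ids[[m]], traj$raw$host_densities[[m]],
                      "host", "spacers")
  viruses <- build_side(traj$raw$virus_ids[[m]],
                        traj$raw$virus_densities[[m]], "virus",
                        "protospacers")
  as_community(hosts, viruses, time = t0, abundance_col = "density")
}

#' Distributed-immunity metrics along a trajectory
#'
#' Evaluates [di_metrics()] on the recorded snapshots of a simulation.
#'
#' @param traj A `crispr_trajectory`.
#' @param times Optional vector of times (hours) at which to evaluate; the
#'   default uses every recorded snapshot. Non-recorded times snap to the
#'   nearest snapshot.
#' @inheritParams di_metrics
#' @return A tibble with one row per evaluated snapshot: `time`, `pdi`,
#'   `idi`, `hvi`, `max_pdi`, `n_host_strains`, `n_viral_strains`,
#'   `host_total`, `viral_total`.
#' @examples
#' traj <- simulate_coevolution(sim_params(t_end = 50), seed = 1)
#' trajectory_metrics(traj, times = c(10, 50))
#' @export
trajectory_metrics <- function(traj, times = NULL,
                               sigma = c("pairwise", "population")) {
  stopifnot(inherits(traj, "crispr_trajectory"))
  sigma <- match.arg(sigma)
  rec <- traj$totals$time
  if (is.null(times)) {
    times <- rec
  } else {
    times <- rec[vapply(times, function(t) which.min(abs(rec - t)), 1L)]
    times <- unique(times)
  }
  reg_h <- traj$registry[traj$registry$side == "host", , drop = FALSE]
  reg_v <- traj$registry[traj$registry$side == "virus", , drop = FALSE]
  # position lookup by strain id (ids are small consecutive integers)
  pos_h <- integer(max(reg_h$strain_id))
  pos_h[reg_h$strain_id] <- seq_len(nrow(reg_h))
  pos_v <- integer(max(reg_v$strain_id))
  pos_v[reg_v$strain_id] <- seq_len(nrow(reg_v))
  idx <- match(times, rec)
  out <- matrix(NA_real_, length(idx), 4)
  extras <- matrix(0, length(idx), 4)
  for (j in seq_along(idx)) {
    m <- idx[j]
    hd <- traj$raw$host_densities[[m]]
    vd <- traj$raw$virus_densities[[m]]
    extras[j, ] <- c(length(hd), length(vd), sum(hd), sum(vd))
    if (length(hd) == 0 || length(vd) == 0 || sum(hd) <= 0 ||
        sum(vd) <= 0) {
      next
    }
    hs <- reg_h$alleles[pos_h[traj$raw$host_ids[[m]]]]
    vp <- reg_v$alleles[pos_v[traj$raw$virus_ids[[m]]]]
    out[j, ] <- di_metrics_cpp(hs, hd / sum(hd), vp, vd / sum(vd),
                               identical(sigma, "population"))
  }
  tibble(time = rec[idx], pdi = out[, 1], idi = out[, 2], hvi = out[, 3],
         max_pdi = out[, 4],
         n_host_strains = as.integer(extras[, 1]),
         n_viral_strains = as.integer(extras[, 2]),
         host_total = extras[, 3], viral_total = extras[, 4])
}

#' @method tidy crispr_trajectory
#' @export
tidy.crispr_trajectory <- function(x, ...) {
  nh <- x$totals$n_hosts
  nv <- x$totals$n_viruses
  out <- tibble(
    time = c(rep(x$totals$time, times = nh),
             rep(x$totals$time, times = nv)),
    side = rep(c("host", "virus"), c(sum(nh), sum(nv))),
    strain_id = c(unlist(x$raw$host_ids), unlist(x$raw$virus_ids)),
    density = c(unlist(x$raw$host_densities),
                unlist(x$raw$virus_densities))
  )
  dplyr::arrange(out, .data$time, .data$side, .data$strain_id)
}

#' @method glance crispr_trajectory
#' @export
glance.crispr_trajectory <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    end_time = x$end_time,
    locus_filled_in_window = x$locus_filled_in_window,
    final_host_total = tail(x$totals$host_total, 1),
    final_viral_total = tail(x$totals$viral_total, 1),
    final_n_hosts = tail(x$totals$n_hosts, 1),
    final_n_viruses = tail(x$totals$n_viruses, 1),
    acquisitions = unname(x$events["acquisitions"]),
    mutations = unname(x$events["mutations"])
  )
}

#' @method autoplot crispr_trajectory
#' @export
autoplot.crispr_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(object$totals,
                           c("host_total", "viral_total"),
                           names_to = "side", values_to = "density")
  d$side <- ifelse(d$side == "host_total", "host", "virus")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$density,
                                  colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "density (per mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot distributed-immunity metrics over time
#'
#' @param metrics A tibble from [trajectory_metrics()].
#' @return A ggplot object with PDI, IDI and HVI series.
#' @export
plot_di_series <- function(metrics) {
  d <- tidyr::pivot_longer(metrics, c("pdi", "idi", "hvi"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
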