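#' Locate host population peaks
#'
#' Finds local maxima of the total host density series: interior points
#' strictly greater than both neighbours, kept when their topographic
#' prominence reaches `min_prominence` and thinned so that no two retained
#' peaks lie within `min_separation` hours (the higher peak wins; ties go
#' to the earlier one).
#'
#' @param data A data frame with a time column and a value column, e.g.
#'   the `totals` table of a `crispr_trajectory`.
#' @param time_col,value_col Column names (default `"time"`,
#'   `"host_total"`).
#' @param min_prominence Minimum prominence; the default is 5% of the
#'   default carrying capacity.
#' @param min_separation Minimum spacing between retained peaks, hours.
#' @return A tibble with `time`, `value` and `prominence`, ordered by time.
#' @examples
#' d <- tibble::tibble(time = 0:4, host_total = c(1, 3, 2, 5, 4) * 1e5)
#' find_host_peaks(d, min_prominence = 0, min_separation = 0)
#' @export
find_host_peaks <- function(data, time_col = "time",
                            value_col = "host_total",
                            min_prominence = 0.05 * 3.158e5,
                            min_separation = 10) {
  tt <- data[[time_col]]
  v <- data[[value_col]]
  n <- length(v)
  if (n < 3) return(tibble(time = numeric(), value = numeric(),
                           prominence = numeric()))
  cand <- which(v[-c(1, n)] > v[-c(n - 1, n)] &
                  v[-c(1, n)] > v[-c(1, 2)]) + 1L
  if (length(cand) == 0) {
    return(tibble(time = numeric(), value = numeric(),
                  prominence = numeric()))
  }
  prom <- vapply(cand, function(i) {
    h <- v[i]
    left_higher <- which(v[seq_len(i - 1)] > h)
    key_l <- if (length(left_higher) == 0) min(v[seq_len(i)]) else
      min(v[(max(left_higher)):i])
    right_higher <- which(v[(i + 1):n] > h) + i
    key_r <- if (length(right_higher) == 0) min(v[i:n]) else
      min(v[i:(min(right_higher))])
    if (length(left_higher) == 0 && length(right_higher) == 0) {
      return(h - min(key_l, key_r)) # global maximum
    }
    h - max(key_l, key_r)
  }, 1.0)
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) > 1 && min_separation > 0) {
    ord <- order(-v[cand], tt[cand]) # highest first, earliest on ties
    chosen <- integer()
    for (j in ord) {
      if (all(abs(tt[cand[j]] - tt[cand[chosen]]) >= min_separation)) {
        chosen <- c(chosen, j)
      }
    }
    keep2 <- sort(chosen)
    cand <- cand[keep2]
    prom <- prom[keep2]
  }
  tibble(time = tt[cand], value = v[cand], prominence = prom)
}

#' Median over the final analysis window
#'
#' Summarizes a recorded series by its median over the final window of a
#' simulation (by default the last 500 hours), the replicate-level summary
#' used throughout the sweep analyses.
#'
#' @param time,value Recorded times (hours) and values.
#' @param t_end Nominal end of the run; defaults to the last recorded time.
#'   Points with `time > t_end - window` enter the median.
#' @param window Window length in hours.
#' @return The median, or `NA` (with a warning) when the series ended
#'   before `t_end` and the window is therefore undefined.
#' @examples
#' window_median(1:1000, rep(c(0, 1), 500), t_end = 1000)
#' @export
window_median <- function(time, value, t_end = max(time), window = 500) {
  if (max(time) < t_end) {
    warn("series ends before t_end; window median undefined")
    return(NA_real_)
  }
  sel <- time > t_end - window
  if (!any(sel)) return(NA_real_)
  median(value[sel])
}

#' Host population stability
#'
#' A run is stable when the host population remains strictly above the
#' threshold (close to carrying capacity) for a sufficiently long stretch:
#' some run of consecutive recorded points, all above `threshold`, spans at
#' least `span` hours.
#'
#' @param time,value Recorded times (hours) and total host densities.
#' @param threshold Density threshold, cells/mL (strict inequality).
#' @param span Required time span of the above-threshold stretch, hours.
#' @return Logical.
#' @examples
#' is_stable(0:200, rep(3.2e5, 201)) # TRUE
#' is_stable(0:50, rep(3.2e5, 51))   # FALSE: only 50 h
#' @export
is_stable <- function(time, value, threshold = 3e5, span = 100) {
  above <- value > threshold
  if (!any(above)) return(FALSE)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    if (time[ends[j]] - time[starts[j]] >= span) return(TRUE)
  }
  FALSE
}

#' Summarize one simulation replicate
#'
#' Condenses a trajectory into the replicate-level record used by the
#' sweep analyses: medians of the distributed-immunity metrics, densities
#' and strain counts over the final window, the outcome and locus-fill
#' state, the stability flag, and the host-peak table with PDI evaluated
#' at each peak.
#'
#' @param traj A `crispr_trajectory`.
#' @param window Final analysis window, hours.
#' @param stability_threshold,stability_span Passed to [is_stable()].
#' @param min_prominence,min_separation Passed to [find_host_peaks()];
#'   `min_prominence` defaults to 5% of the run's carrying capacity.
#' @inheritParams di_metrics
#' @return A one-row tibble; `peaks` is a list-column holding the peak
#'   table (`time`, `value`, `prominence`, `pdi`). Window medians are `NA`
#'   for runs that ended before `t_end`.
#' @examples
#' traj <- simulate_coevolution(sim_params(t_end = 60), seed = 1)
#' summarize_replicate(traj, window = 50)
#' @export
summarize_replicate <- function(traj, window = 500,
                                stability_threshold = 3e5,
                                stability_span = 100,
                                min_prominence = NULL,
                                min_separation = 10,
                                sigma = c("pairwise", "population")) {
  stopifnot(inherits(traj, "crispr_trajectory"))
  sigma <- match.arg(sigma)
  p <- traj$params
  tot <- traj$totals
  reached_end <- traj$outcome == "completed"
  min_prominence <- min_prominence %||% (0.05 * p$K)

  peaks <- find_host_peaks(tot, min_prominence = min_prominence,
                           min_separation = min_separation)
  if (nrow(peaks) > 0) {
    pk_m <- trajectory_metrics(traj, times = peaks$time, sigma = sigma)
    peaks$pdi <- pk_m$pdi[match(peaks$time, pk_m$time)]
  } else {
    peaks$pdi <- numeric()
  }

  wm <- function(value) {
    if (!reached_end) return(NA_real_)
    window_median(tot$time, value, t_end = p$t_end, window = window)
  }
  med <- tibble(median_pdi = NA_real_, median_idi = NA_real_,
                median_hvi = NA_real_, median_max_pdi = NA_real_)
  if (reached_end) {
    wsel <- tot$time > p$t_end - window
    m <- trajectory_metrics(traj, times = tot$time[wsel], sigma = sigma)
    med <- tibble(median_pdi = median(m$pdi),
                  median_idi = median(m$idi),
                  median_hvi = median(m$hvi),
                  median_max_pdi = median(m$max_pdi))
  }

  tibble(
    S = p$S, P = p$P, q = p$q, mu = p$mu,
    outcome = traj$outcome,
    end_time = traj$end_time,
    locus_filled = traj$locus_filled_in_window,
    filled_at_end = tail(tot$min_locus, 1) == p$S && tail(tot$n_hosts, 1) > 0,
    stable = is_stable(tot$time, tot$host_total,
                       threshold = stability_threshold,
                       span = stability_span),
    !!!med,
    median_host_density = wm(tot$host_total),
    median_viral_density = wm(tot$viral_total),
    median_n_hosts = wm(tot$n_hosts),
    median_n_viruses = wm(tot$n_viruses),
    peaks = list(peaks)
  )
}

#' Run a replicated parameter sweep
#'
#' Fans out [simulate_coevolution()] + [summarize_replicate()] over a
#' parameter grid.
#'
#' @param grid A data frame whose columns name [sim_params()] fields to
#'   override (e.g. `P`, `mu`), one row per condition.
#' @param replicates Replicates per condition.
#' @param base_params Baseline [sim_params()].
#' @param seed Integer seed; replicate seeds are derived deterministically
#'   from it.
#' @param ... Passed to [summarize_replicate()].
#' @return A tibble of replicate summaries with `condition`, `replicate`
#'   and `seed` columns.
#' @examples
#' \donttest{
#' grid <- tibble::tibble(P = c(5, 20))
#' sw <- run_sweep(grid, replicates = 2,
#'                 base_params = sim_params(t_end = 100), seed = 1)
#' }
#' @export
run_sweep <- function(grid, replicates, base_params = sim_params(),
                      seed = 1, ...) {
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("empty parameter grid")
  bad <- setdiff(names(grid), names(base_params))
  if (length(bad) > 0) {
    abort(paste0("unknown parameter(s) in grid: ",
                 paste(bad, collapse = ", ")))
  }
  counter <- 0L
  out <- vector("list", nrow(grid) * replicates)
  for (gi in seq_len(nrow(grid))) {
    pars <- unclass(base_params)
    for (nm in names(grid)) pars[[nm]] <- grid[[nm]][gi]
    pars <- do.call(sim_params, pars)
    for (rep_i in seq_len(replicates)) {
      counter <- counter + 1L
      rep_seed <- (seed * 10007L + counter * 7919L) %% 2147483647L
      traj <- simulate_coevolution(pars, seed = rep_seed)
      s <- summarize_replicate(traj, ...)
      s <- add_column(s, condition = gi, replicate = rep_i,
                      seed = rep_seed, .before = 1)
      out[[counter]] <- s
    }
  }
  dplyr::bind_rows(out)
}

#' Classify replicate outcomes
#'
#' Partitions replicate summaries into the bookkeeping classes used for
#' sweep statistics: `complete` (the run reached its horizon with every
#' host locus full throughout the final window), `viral_extinction` (the
#' viral population fell below the density cutoff before the horizon), and
#' `unfilled_locus` (the run reached its horizon but the locus was not
#' full throughout the final window). Host extinctions, if any, are
#' reported as their own class. The exclusion set for population averages
#' is the unfilled-locus runs together with viral extinctions that struck
#' before the locus had filled (`excluded` column).
#'
#' @param summaries A tibble from [summarize_replicate()]/[run_sweep()].
#' @return A tibble with `class`, `n`, `prop` and `excluded` (how many
#'   replicates of that class are excluded from population averages).
#' @export
classify_outcomes <- function(summaries) {
  cls <- replicate_class(summaries)
  excl <- cls == "unfilled_locus" |
    (cls == "viral_extinction" & !summaries$filled_at_end)
  out <- dplyr::count(tibble(class = cls), .data$class, name = "n")
  out$prop <- out$n / sum(out$n)
  out$excluded <- vapply(out$class, function(cl) {
    sum(excl[cls == cl])
  }, 1L, USE.NAMES = FALSE)
  out
}

replicate_class <- function(summaries) {
  dplyr::case_when(
    summaries$outcome == "host_extinction" ~ "host_extinction",
    summaries$outcome == "viral_extinction" ~ "viral_extinction",
    summaries$outcome == "completed" & summaries$locus_filled ~ "complete",
    TRUE ~ "unfilled_locus"
  )
}

#' Spearman rank correlations between sweep summary variables
#'
#' @param data A data frame of replicate summaries.
#' @param x_vars,y_vars Character vectors of column names to correlate.
#' @return A tibble with one row per (x, y) pair: `rho`, `p_value`, `n`.
#'   Pairs with a constant column yield `NA` (undefined rank correlation).
#' @examples
#' spearman_table(data.frame(a = 1:5, b = (1:5)^2), "a", "b")
#' @export
spearman_table <- function(data, x_vars, y_vars) {
  rows <- list()
  for (xv in x_vars) {
    for (yv in y_vars) {
      if (xv == yv) next
      x <- data[[xv]]
      y <- data[[yv]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]
      y <- y[ok]
      if (length(x) < 3 || length(unique(x)) < 2 ||
          length(unique(y)) < 2) {
        rows[[length(rows) + 1]] <- tibble(x = xv, y = yv, rho = NA_real_,
                                           p_value = NA_real_,
                                           n = length(x))
        next
      }
      ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1]] <- tibble(x = xv, y = yv,
                                         rho = unname(ct$estimate),
                                         p_value = ct$p.value,
                                         n = length(x))
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare linear and quadratic fits by AIC
#'
#' Fits `y ~ x` and `y ~ x + x^2` by least squares and compares them with
#' `AIC = n log(RSS/n) + 2k` (k = number of regression coefficients);
#' the lower AIC wins. Used to decide whether viral output variables
#' respond unimodally rather than linearly to distributed immunity.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names.
#' @return An object of class `lq_aic` with the two `lm` fits, both AIC
#'   values, `delta_aic` (quadratic minus linear) and `choice`.
#'   `tidy()` gives one row per model; `glance()` one row with the choice.
#' @examples
#' d <- data.frame(x = 1:10, y = (1:10 - 5)^2)
#' glance(linear_vs_quadratic_aic(d, x, y))$choice
#' @export
linear_vs_quadratic_aic <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 4) abort("need at least 4 points")
  if (length(unique(xv)) < 3) abort("degenerate x: too few distinct values")
  d <- data.frame(x = xv, y = yv)
  fit_lin <- lm(y ~ x, data = d)
  fit_quad <- lm(y ~ x + I(x^2), data = d)
  aic <- function(fit) {
    rss <- sum(resid(fit)^2)
    n * log(rss / n) + 2 * length(coef(fit))
  }
  a_lin <- aic(fit_lin)
  a_quad <- aic(fit_quad)
  structure(list(linear = fit_lin, quadratic = fit_quad,
                 aic_linear = a_lin, aic_quadratic = a_quad,
                 delta_aic = a_quad - a_lin,
                 choice = if (a_quad < a_lin) "quadratic" else "linear",
                 n = n),
            class = "lq_aic")
}

#' @export
print.lq_aic <- function(x, ...) {
  cat("linear vs quadratic fit (n = ", x$n, ")\n", sep = "")
  cat("  AIC linear:    ", format(x$aic_linear), "\n")
  cat("  AIC quadratic: ", format(x$aic_quadratic), "\n")
  cat("  choice:        ", x$choice, "\n")
  invisible(x)
}

#' @method tidy lq_aic
#' @export
tidy.lq_aic <- function(x, ...) {
  tibble(model = c("linear", "quadratic"),
         df = c(length(coef(x$linear)), length(coef(x$quadratic))),
         rss = c(sum(resid(x$linear)^2), sum(resid(x$quadratic)^2)),
         r_squared = c(summary(x$linear)$r.squared,
                       summary(x$quadratic)$r.squared),
         aic = c(x$aic_linear, x$aic_quadratic))
}

#' @method glance lq_aic
#' @export
glance.lq_aic <- function(x, ...) {
  tibble(choice = x$choice, delta_aic = x$delta_aic, n = x$n)
}

#' One-way ANOVA for unbalanced groups with pairwise comparisons
#'
#' Compares group means by a one-way analysis of variance fitted as a
#' linear model (valid for unequal group sizes), followed by pairwise
#' t-tests with Holm adjustment. Groups with fewer than 2 members are
#' excluded with a warning.
#'
#' @param data A data frame.
#' @param value,group Unquoted column names of the response and grouping
#'   variable.
#' @return An object of class `di_anova`; `glance()` gives the overall F
#'   test, `tidy()` the pairwise comparison table.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), c(4, 6)), v = c(1:4, 11:16))
#' glance(unbalanced_anova_pairwise(d, v, g))
#' @export
unbalanced_anova_pairwise <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.factor(rlang::eval_tidy(rlang::enquo(group), data))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]
  g <- droplevels(g[ok])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("excluding group(s) with < 2 members: ",
                paste(small, collapse = ", ")))
    keep <- !(g %in% small)
    v <- v[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) abort("need at least 2 groups with >= 2 members")
  fit <- lm(v ~ g)
  an <- anova(fit)
  overall <- tibble(f_statistic = an$`F value`[1],
                    p_value = an$`Pr(>F)`[1],
                    df_between = an$Df[1], df_within = an$Df[2],
                    n = length(v), n_groups = nlevels(g))
  pw <- suppressWarnings(pairwise.t.test(v, g, p.adjust.method = "holm"))
  pm <- pw$p.value
  pairs <- list()
  for (i in seq_len(nrow(pm))) {
    for (j in seq_len(ncol(pm))) {
      if (!is.na(pm[i, j])) {
        pairs[[length(pairs) + 1]] <- tibble(group1 = colnames(pm)[j],
                                             group2 = rownames(pm)[i],
                                             p_adj = pm[i, j])
      }
    }
  }
  structure(list(overall = overall, pairwise = dplyr::bind_rows(pairs),
                 fit = fit),
            class = "di_anova")
}

#' @export
print.di_anova <- function(x, ...) {
  cat("one-way ANOVA (unbalanced):  F = ",
      format(x$overall$f_statistic), ", p = ",
      format(x$overall$p_value), "\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' @method tidy di_anova
#' @export
tidy.di_anova <- function(x, ...) x$pairwise

#' @method glance di_anova
#' @export
glance.di_anova <- function(x, ...) x$overall

#' Subsampled stability/extinction proportions across DI bins
#'
#' Draws repeated random subsamples of replicate summaries, bins each by a
#' distributed-immunity metric (PDI in bins of width 0.1, IDI in bins of
#' width 0.6), computes the per-bin proportion of stable and of
#' viral-extinct replicates in every subsample, and compares bin means by
#' [unbalanced_anova_pairwise()].
#'
#' @param summaries Replicate summaries ([run_sweep()] output).
#' @param metric `"pdi"` or `"idi"`: which median metric defines the bins.
#' @param n_sub Subsample size (without replacement).
#' @param reps Number of subsamples.
#' @param bin_width Bin width; defaults to 0.1 for PDI, 0.6 for IDI.
#' @param seed Integer seed for the subsampling.
#' @return A list of class `di_subsample`: `bins` (per-bin means across
#'   subsamples), `anova_stable` and `anova_extinct` (bin-mean
#'   comparisons; `NULL` when fewer than two bins are occupied), and the
#'   long per-subsample table `draws`.
#' @export
subsample_compare <- function(summaries, metric = c("pdi", "idi"),
                              n_sub = 230, reps = 10000,
                              bin_width = NULL, seed = 1) {
  metric <- match.arg(metric)
  bin_width <- bin_width %||% if (metric == "pdi") 0.1 else 0.6
  col <- paste0("median_", metric)
  val <- summaries[[col]]
  ok <- !is.na(val)
  summaries <- summaries[ok, , drop = FALSE]
  val <- val[ok]
  n <- nrow(summaries)
  if (n_sub > n) abort("n_sub exceeds the number of usable summaries")
  bin <- floor(val / bin_width)
  bin_label <- sprintf("[%g,%g)", bin * bin_width, (bin + 1) * bin_width)
  stable <- summaries$stable
  extinct <- summaries$outcome == "viral_extinction"
  set.seed(seed)
  draws <- vector("list", reps)
  for (rix in seq_len(reps)) {
    idx <- sample.int(n, n_sub)
    d <- tibble(bin = bin_label[idx], stable = stable[idx],
                extinct = extinct[idx])
    agg <- dplyr::summarise(dplyr::group_by(d, .data$bin),
                            prop_stable = mean(.data$stable),
                            prop_extinct = mean(.data$extinct),
                            n_in_bin = dplyr::n(), .groups = "drop")
    agg$rep <- rix
    draws[[rix]] <- agg
  }
  draws <- dplyr::bind_rows(draws)
  bins <- dplyr::summarise(dplyr::group_by(draws, .data$bin),
                           mean_prop_stable = mean(.data$prop_stable),
                           mean_prop_extinct = mean(.data$prop_extinct),
                           mean_n = mean(.data$n_in_bin),
                           n_reps = dplyr::n(), .groups = "drop")
  run_anova <- function(col) {
    multi <- names(which(table(draws$bin) >= 2))
    dd <- draws[draws$bin %in% multi, , drop = FALSE]
    if (length(unique(dd$bin)) < 2) return(NULL)
    if (all(tapply(dd[[col]], dd$bin, function(z) {
      length(unique(z)) == 1
    }))) {
      return(NULL) # degenerate: no within-bin variation anywhere
    }
    unbalanced_anova_pairwise(dd, !!rlang::sym(col), bin)
  }
  structure(list(bins = bins,
                 anova_stable = run_anova("prop_stable"),
                 anova_extinct = run_anova("prop_extinct"),
                 draws = draws, metric = metric, bin_width = bin_width,
                 n_sub = n_sub, reps = reps),
            class = "di_subsample")
}

#' @export
print.di_subsample <- function(x, ...) {
  cat("<di_subsample> ", x$reps, " subsamples of ", x$n_sub,
      " replicates, ", x$metric, " bins of width ", x$bin_width, "\n",
      sep = "")
  print(x$bins)
  invisible(x)
}
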