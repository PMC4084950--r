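#' Read and write communities as JSON or TSV
#'
#' The JSON schema is
#' `{"hosts": [{"id", "spacers", "proportion"}], "viruses": [{"id",
#' "protospacers", "proportion"}], "time"}`. The TSV form uses one file
#' per side with one row per strain and the allele list comma-joined.
#' Round trips preserve numeric values at full precision.
#'
#' @param comm A [community()].
#' @param path Output path (for TSV: the hosts file; the viruses file
#'   derives from it, see `viruses_path`).
#' @return `read_community_json()` / `read_community_tsv()` return a
#'   [community()]; the writers return `path` invisibly.
#' @examples
#' comm <- make_community(n_hosts = 2, n_viruses = 1)
#' f <- tempfile(fileext = ".json")
#' write_community_json(comm, f)
#' identical(di_metrics(read_community_json(f)), di_metrics(comm))
#' @export
write_community_json <- function(comm, path) {
  stopifnot(inherits(comm, "crispr_community"))
  obj <- list(
    hosts = lapply(seq_len(nrow(comm$hosts)), function(i) {
      list(id = comm$hosts$strain_id[i],
           spacers = as.integer(comm$hosts$spacers[[i]]),
           proportion = comm$hosts$proportion[i])
    }),
    viruses = lapply(seq_len(nrow(comm$viruses)), function(k) {
      list(id = comm$viruses$strain_id[k],
           protospacers = as.integer(comm$viruses$protospacers[[k]]),
           proportion = comm$viruses$proportion[k])
    }),
    time = comm$time
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_community_json
#' @export
read_community_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$hosts) || is.null(obj$viruses)) {
    abort(paste0("not a community JSON file: ", path))
  }
  side <- function(entries, allele_key, allele_col) {
    out <- tibble(
      strain_id = vapply(entries, function(e) as.integer(e$id), 1L),
      proportion = vapply(entries, function(e) as.numeric(e$proportion),
                          1.0)
    )
    out[[allele_col]] <- lapply(entries, function(e) {
      as.integer(unlist(e[[allele_key]]))
    })
    out
  }
  community(side(obj$hosts, "spacers", "spacers"),
            side(obj$viruses, "protospacers", "protospacers"),
            time = if (is.null(obj$time)) NULL else as.numeric(obj$time))
}

#' @rdname write_community_json
#' @param viruses_path Path of the viruses TSV; defaults to `path` with a
#'   `_viruses` suffix (and the hosts file gets `_hosts`).
#' @export
write_community_tsv <- function(comm, path, viruses_path = NULL) {
  stopifnot(inherits(comm, "crispr_community"))
  paths <- tsv_pair(path, viruses_path)
  join <- function(lst) vapply(lst, paste, "", collapse = ",")
  hosts <- data.frame(strain_id = comm$hosts$strain_id,
                      spacers = join(comm$hosts$spacers),
                      proportion = format_full(comm$hosts$proportion))
  viruses <- data.frame(strain_id = comm$viruses$strain_id,
                        protospacers = join(comm$viruses$protospacers),
                        proportion = format_full(comm$viruses$proportion))
  utils::write.table(hosts, paths$hosts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(viruses, paths$viruses, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths$hosts)
}

#' @rdname write_community_json
#' @export
read_community_tsv <- function(path, viruses_path = NULL) {
  paths <- tsv_pair(path, viruses_path)
  rd <- function(p, allele_col) {
    x <- utils::read.table(p, sep = "\t", header = TRUE,
                           colClasses = c("integer", "character",
                                          "numeric"))
    out <- tibble(strain_id = x$strain_id, proportion = x$proportion)
    out[[allele_col]] <- lapply(strsplit(x[[2]], ","), function(v) {
      as.integer(v[nzchar(v)])
    })
    out
  }
  community(rd(paths$hosts, "spacers"), rd(paths$viruses, "protospacers"))
}

tsv_pair <- function(path, viruses_path) {
  if (!is.null(viruses_path)) {
    return(list(hosts = path, viruses = viruses_path))
  }
  stem <- sub("\\.tsv$", "", path)
  list(hosts = paste0(stem, "_hosts.tsv"),
       viruses = paste0(stem, "_viruses.tsv"))
}

format_full <- function(x) {
  vapply(x, function(v) format(v, digits = 17, scientific = TRUE), "")
}

#' Read and write trajectory tables
#'
#' `write_trajectory_tsv()` stores the per-strain density series of a
#' simulation as TSV (columns `time`, `side`, `strain_id`, `density`),
#' together with a strain-registry JSON mapping each strain to its allele
#' content, and a totals TSV. `read_trajectory_tsv()` restores a
#' `crispr_trajectory`-like object usable by the analysis functions
#' (metrics, peaks, window medians); the simulation parameters are stored
#' in the registry JSON.
#'
#' @param traj A `crispr_trajectory`.
#' @param stem Output path stem: files `<stem>_densities.tsv`,
#'   `<stem>_totals.tsv` and `<stem>_registry.json` are produced.
#' @return `read_trajectory_tsv()` returns a `crispr_trajectory`;
#'   the writer returns `stem` invisibly.
#' @export
write_trajectory_tsv <- function(traj, stem) {
  stopifnot(inherits(traj, "crispr_trajectory"))
  snap <- tidy(traj)
  snap$density <- format_full(snap$density)
  utils::write.table(snap, paste0(stem, "_densities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tot <- traj$totals
  tot$host_total <- format_full(tot$host_total)
  tot$viral_total <- format_full(tot$viral_total)
  utils::write.table(tot, paste0(stem, "_totals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reg <- list(
    params = unclass(traj$params),
    seed = traj$seed,
    outcome = traj$outcome,
    end_time = traj$end_time,
    locus_filled_in_window = traj$locus_filled_in_window,
    events = as.list(traj$events),
    registry = lapply(seq_len(nrow(traj$registry)), function(i) {
      list(side = traj$registry$side[i],
           strain_id = traj$registry$strain_id[i],
           alleles = as.integer(traj$registry$alleles[[i]]))
    })
  )
  jsonlite::write_json(reg, paste0(stem, "_registry.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(stem) {
  dens_path <- paste0(stem, "_densities.tsv")
  reg_path <- paste0(stem, "_registry.json")
  tot_path <- paste0(stem, "_totals.tsv")
  for (p in c(dens_path, reg_path, tot_path)) {
    if (!file.exists(p)) abort(paste0("missing trajectory file: ", p))
  }
  snap <- as_tibble(utils::read.table(
    dens_path, sep = "\t", header = TRUE,
    colClasses = c("numeric", "character", "integer", "numeric")))
  if (!identical(names(snap), c("time", "side", "strain_id", "density"))) {
    abort(paste0("unexpected columns in ", dens_path, " (line 1)"))
  }
  tot <- as_tibble(utils::read.table(tot_path, sep = "\t", header = TRUE))
  reg <- jsonlite::read_json(reg_path)
  registry <- tibble(
    side = vapply(reg$registry, `[[`, "", "side"),
    strain_id = vapply(reg$registry, function(e) as.integer(e$strain_id),
                       1L),
    alleles = lapply(reg$registry, function(e) {
      as.integer(unlist(e$alleles))
    })
  )
  params <- do.call(sim_params, reg$params)
  tf <- factor(snap$time, levels = tot$time)
  is_h <- snap$side == "host"
  # split() keeps every level, so absent sides give zero-length entries
  raw <- list(
    host_ids = unname(split(snap$strain_id[is_h], tf[is_h])),
    host_densities = unname(split(snap$density[is_h], tf[is_h])),
    virus_ids = unname(split(snap$strain_id[!is_h], tf[!is_h])),
    virus_densities = unname(split(snap$density[!is_h], tf[!is_h])))
  new_trajectory(params = params, seed = reg$seed, totals = tot,
                 raw = raw, registry = registry, outcome = reg$outcome,
                 events = unlist(reg$events))
}

#' Load and save run configuration
#'
#' A run configuration is a YAML file holding simulation parameters (any
#' [sim_params()] field) under `sim:` and analysis options under
#' `analysis:` (final `window` length in hours, the stability `threshold`
#' and `span`, peak `min_prominence` and `min_separation`, the `sigma`
#' evenness variant, the `pdi_bin_width` / `idi_bin_width` used for
#' subsampling, `n_sub` and `reps`), plus an optional top-level `seed`.
#' Missing keys take the package defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `sim`
#'   (a [sim_params()]), `analysis` and `seed`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("sim:\n  P: 20\nseed: 7", f)
#' load_config(f)$sim$P
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("sim", "analysis", "seed"))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(bad, collapse = ", ")))
  }
  sim_defaults <- unclass(sim_params())
  sim_over <- raw$sim %||% list()
  bad <- setdiff(names(sim_over), names(sim_defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown sim key(s): ", paste(bad, collapse = ", ")))
  }
  sim <- do.call(sim_params, modifyList(sim_defaults, sim_over))
  ana_defaults <- list(window = 500, threshold = 3e5, span = 100,
                       min_prominence = 0.05 * sim$K, min_separation = 10,
                       sigma = "pairwise", pdi_bin_width = 0.1,
                       idi_bin_width = 0.6, n_sub = 230, reps = 10000)
  ana_over <- raw$analysis %||% list()
  bad <- setdiff(names(ana_over), names(ana_defaults))
  if (length(bad) > 0) {
    abort(paste0("unknown analysis key(s): ",
                 paste(bad, collapse = ", ")))
  }
  analysis <- modifyList(ana_defaults, ana_over)
  if (!analysis$sigma %in% c("pairwise", "population")) {
    abort("'sigma' must be \"pairwise\" or \"population\"")
  }
  for (nm in c("window", "threshold", "span", "min_separation",
               "pdi_bin_width", "idi_bin_width", "n_sub", "reps")) {
    if (analysis[[nm]] <= 0) abort(paste0("'", nm, "' must be > 0"))
  }
  structure(list(sim = sim, analysis = analysis,
                 seed = if (is.null(raw$seed)) NULL else
                   as.integer(raw$seed)),
            class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(sim = unclass(config$sim),
                        analysis = config$analysis,
                        seed = config$seed), path)
  invisible(path)
}

#' Read and write empirical input tables
#'
#' TSV readers for the empirical pipeline: a spacer-per-read table
#' (`read_id`, comma-joined `spacers`, `has_leader`, `has_trailer`,
#' comma-joined 0/1 `novel` flags), a SNP table (`snp_id`, `frequency`,
#' `escaped_protospacer`, optional `fixed`), and a spacer-to-protospacer
#' map (`spacer`, `protospacer`).
#'
#' @param path TSV file path.
#' @return A tibble in the format expected by [filter_reads()],
#'   [viral_strains_from_snps()] or [empirical_community()].
#' @export
read_reads_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  needed <- c("read_id", "spacers", "has_leader", "has_trailer", "novel")
  if (!all(needed %in% names(x))) {
    abort(paste0("reads TSV lacks column(s): ",
                 paste(setdiff(needed, names(x)), collapse = ", ")))
  }
  tibble(
    read_id = x$read_id,
    spacers = lapply(strsplit(x$spacers, ","), as.integer),
    has_leader = as.logical(x$has_leader),
    has_trailer = as.logical(x$has_trailer),
    novel = lapply(strsplit(x$novel, ","), function(v) {
      as.logical(as.integer(v))
    })
  )
}

#' @rdname read_reads_tsv
#' @param reads A read table ([make_reads()] format).
#' @export
write_reads_tsv <- function(reads, path) {
  reads <- validate_reads(reads)
  out <- data.frame(
    read_id = reads$read_id,
    spacers = vapply(reads$spacers, paste, "", collapse = ","),
    has_leader = reads$has_leader,
    has_trailer = reads$has_trailer,
    novel = vapply(reads$novel, function(v) {
      paste(as.integer(v), collapse = ",")
    }, "")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_reads_tsv
#' @export
read_snps_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE)
  out <- tibble(snp_id = as.character(x$snp_id),
                frequency = as.numeric(x$frequency),
                escaped_protospacer = as.integer(x$escaped_protospacer))
  out$fixed <- if ("fixed" %in% names(x)) as.logical(x$fixed) else FALSE
  out
}

#' @rdname read_reads_tsv
#' @export
read_spacer_map_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE)
  tibble(spacer = as.integer(x$spacer),
         protospacer = as.integer(x$protospacer))
}
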