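# Config-driven orchestration: read a JSON analysis config, run both state
# criteria over every replica of every system, derive or apply cutoffs,
# aggregate per-replica statistics, run the replica-level tests, and write a
# deterministic TSV/JSON report bundle.

#' Default analysis configuration
#'
#' @param reference_pdb path to the active-state reference structure (PDB)
#' @param topology_pdb path to the trajectory topology (PDB); defaults to
#'   the reference
#' @param systems list of `list(label =, trajectories = character())`
#' @param frame_interval_ns frame interval metadata (ns)
#' @param output_dir report output directory
#' @param tests list of label pairs to compare; `NULL` means every ordered
#'   pair (a, b) of consecutive convention WT-vs-variant is left to the
#'   caller — by default all unordered pairs in listed order
#' @return An `h12_config` list. Criterion defaults carry the published
#'   constants: pair distance 296/466 C-beta with 4.6 A cutoff, helix RMSD
#'   466-473 C-alpha (fit on core 248-459) with 1.9 A cutoff, 0.1 A
#'   histogram bins, N = 15 replicas per system.
#' @export
default_config <- function(reference_pdb, topology_pdb = reference_pdb,
                           systems = list(), frame_interval_ns = 1,
                           output_dir = "h12_analysis", tests = NULL) {
  structure(list(
    reference_pdb = reference_pdb,
    topology_pdb = topology_pdb,
    systems = systems,
    frame_interval_ns = frame_interval_ns,
    criteria = list(
      distance = list(res_a = 296L, res_b = 466L, atom = "CB", cutoff_A = 4.6),
      rmsd = list(calc_residues = c(466L, 473L), fit_residues = c(248L, 459L),
                  atom = "CA", cutoff_A = 1.9, fit_from = NULL)),
    histogram_bin_width_A = 0.1,
    mann_whitney_continuity = TRUE,
    tests = tests,
    seed = 1L,
    output_dir = output_dir), class = "h12_config")
}

#' Read / write an analysis config (JSON)
#' @param path config file path
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- default_config(reference_pdb = cfg$reference_pdb)
  for (nm in names(cfg)) {
    if (nm == "criteria") {
      for (cn in names(cfg$criteria)) {
        for (fn in names(cfg$criteria[[cn]])) {
          base$criteria[[cn]][[fn]] <- cfg$criteria[[cn]][[fn]]
        }
      }
    } else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' @rdname read_config
#' @param config an `h12_config`
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

validate_config <- function(config) {
  err <- function(...) stop("config validation: ", sprintf(...), call. = FALSE)
  if (length(config$systems) == 0L) err("empty system list")
  labels <- vapply(config$systems, function(s) s$label, character(1))
  if (anyDuplicated(labels)) err("duplicate system labels")
  for (p in c(config$reference_pdb, config$topology_pdb)) {
    if (!file.exists(p)) err("referenced structure file does not exist: %s", p)
  }
  for (s in config$systems) {
    if (length(s$trajectories) == 0L) err("system '%s' has no trajectories", s$label)
    missing <- s$trajectories[!file.exists(unlist(s$trajectories))]
    if (length(missing)) err("missing trajectory file(s) for '%s': %s",
                             s$label, paste(missing, collapse = ", "))
  }
  if (config$criteria$distance$cutoff_A <= 0 || config$criteria$rmsd$cutoff_A <= 0) {
    err("criterion cutoffs must be positive")
  }
  ff <- config$criteria$rmsd$fit_from
  if (!is.null(ff) && !ff %in% labels) {
    err("rmsd fit_from label '%s' is not among systems", ff)
  }
  if (!is.null(config$tests)) {
    for (pair in config$tests) {
      if (length(pair) != 2L || !all(unlist(pair) %in% labels)) {
        err("test pair (%s) does not name two known systems",
            paste(unlist(pair), collapse = ", "))
      }
    }
  }
  if (config$frame_interval_ns <= 0) err("frame_interval_ns must be positive")
  invisible(labels)
}

fmt_pct <- function(x) sprintf("%.2f", x)
fmt_p <- function(x) sprintf("%.3f", x)

#' Run the full analysis pipeline
#'
#' For every system and both criteria: per-frame metrics, state
#' classification, per-replica occupancy/dwell summaries and pooled
#' histograms; optionally re-derives the RMSD cutoff from a designated
#' system's pooled values via the skew-normal fit (`criteria$rmsd$fit_from`);
#' then runs, per configured pair, the two-sided Mann-Whitney U on
#' per-replica frequencies and the one-sided indicator t test on reached
#' counts. All outputs are deterministic given the inputs (fixed ordering
#' and float formatting). Any per-replica failure aborts the run.
#'
#' @param config an `h12_config` (see [default_config()], [read_config()])
#' @return (invisibly) the report: summaries, comparisons, cutoffs,
#'   and output file paths. Side effect: TSV/JSON bundle in
#'   `config$output_dir`.
#' @export
run_analysis <- function(config) {
  labels <- validate_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  reference <- read_pdb(config$reference_pdb, multi = FALSE)
  topology <- if (identical(config$topology_pdb, config$reference_pdb)) {
    reference
  } else read_pdb(config$topology_pdb, multi = FALSE)

  cd <- config$criteria$distance
  cr <- config$criteria$rmsd
  crit_dist <- distance_criterion(cd$res_a, cd$res_b, cd$atom, cd$cutoff_A)
  crit_rmsd <- rmsd_criterion(unlist(cr$calc_residues), unlist(cr$fit_residues),
                              cr$atom, cr$cutoff_A)

  # metric series for every system x replica x criterion
  metrics <- list()
  for (s in config$systems) {
    trajs <- unlist(s$trajectories)
    reps <- if (!is.null(s$replica_indices)) as.integer(unlist(s$replica_indices)) else seq_along(trajs)
    metrics[[s$label]] <- lapply(seq_along(trajs), function(i) {
      tr <- read_traj(trajs[i], topology, config$frame_interval_ns,
                      system_label = s$label, replica_index = reps[i])
      list(distance = compute_metric_series(tr, crit_dist),
           rmsd = compute_metric_series(tr, crit_rmsd, reference))
    })
  }

  # cutoff derivation (skew-normal mean of a designated system's pooled RMSD)
  skewfit <- NULL
  if (!is.null(cr$fit_from)) {
    pooled <- unlist(lapply(metrics[[cr$fit_from]], function(m) m$rmsd$values))
    skewfit <- fit_skew_normal_cutoff(pooled, config$histogram_bin_width_A)
    crit_rmsd$cutoff_A <- skewfit$derived_mean
  }
  cutoffs <- c(distance = crit_dist$cutoff_A, rmsd = crit_rmsd$cutoff_A)

  # classification, summaries, histograms
  summaries <- list(distance = list(), rmsd = list())
  replica_rows <- list()
  for (label in labels) {
    for (criterion in c("distance", "rmsd")) {
      crit <- if (criterion == "distance") crit_dist else crit_rmsd
      states <- lapply(metrics[[label]], function(m) {
        classify_frames(m[[criterion]], crit)
      })
      summaries[[criterion]][[label]] <- summarize_system(states)
      pooled <- unlist(lapply(metrics[[label]], function(m) m[[criterion]]$values))
      bw <- config$histogram_bin_width_A
      breaks <- seq(floor(min(pooled) / bw) * bw,
                    ceiling(max(pooled) / bw) * bw + bw / 2, by = bw)
      h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
      utils::write.table(
        data.frame(bin_mid_A = sprintf("%.4f", h$mids), count = h$counts,
                   density = sprintf("%.6f", h$density)),
        file.path(out, sprintf("hist_%s_%s.tsv", label, criterion)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      ss <- summaries[[criterion]][[label]]
      for (i in seq_len(ss$n_replicas)) {
        dw <- ss$dwell_times_ns[[i]]
        replica_rows[[length(replica_rows) + 1L]] <- data.frame(
          system = label, criterion = criterion,
          replica = ss$replica_indices[i],
          frequency_pct = fmt_pct(ss$frequencies_pct[i]),
          reached_active = as.integer(ss$reached[i]),
          n_dwells = length(dw),
          max_dwell_ns = sprintf("%.3f", if (length(dw)) max(dw) else 0),
          total_active_ns = sprintf("%.3f", sum(dw)))
      }
    }
  }
  replica_table <- do.call(rbind, replica_rows)
  utils::write.table(replica_table, file.path(out, "replica_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # pairwise tests
  pairs <- config$tests
  if (is.null(pairs)) {
    pairs <- if (length(labels) >= 2) utils::combn(labels, 2, simplify = FALSE) else list()
  }
  comp_rows <- list(); comparisons <- list()
  for (pair in pairs) {
    pair <- unlist(pair)
    for (criterion in c("distance", "rmsd")) {
      cmp <- compare_systems(summaries[[criterion]][[pair[1]]],
                             summaries[[criterion]][[pair[2]]],
                             continuity = config$mann_whitney_continuity)
      comparisons[[sprintf("%s_vs_%s_%s", pair[1], pair[2], criterion)]] <- cmp
      for (tn in c("mann_whitney", "indicator_t")) {
        tr <- cmp[[tn]]
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          group_a = pair[1], group_b = pair[2], criterion = criterion,
          test = tr$test_name, sidedness = tr$sidedness,
          statistic = sprintf("%.4f", tr$statistic),
          p_value = fmt_p(tr$p_value), stars = tr$stars)
      }
    }
  }
  if (length(comp_rows)) {
    utils::write.table(do.call(rbind, comp_rows),
                       file.path(out, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # reached-state overview (one row per system x criterion + significance
  # rows per tested pair), mirroring the published summary-table layout
  t1 <- list()
  for (label in labels) {
    t1[[length(t1) + 1L]] <- data.frame(
      row_type = "reached",
      system = label, criterion_distance = sprintf(
        "%d out of %d runs", summaries$distance[[label]]$n_reached,
        summaries$distance[[label]]$n_replicas),
      criterion_rmsd = sprintf(
        "%d out of %d runs", summaries$rmsd[[label]]$n_reached,
        summaries$rmsd[[label]]$n_replicas))
  }
  for (pair in pairs) {
    pair <- unlist(pair)
    fmt_sig <- function(criterion) {
      tr <- comparisons[[sprintf("%s_vs_%s_%s", pair[1], pair[2], criterion)]]$indicator_t
      if (is.na(tr$p_value)) "n.s. (degenerate)" else
        sprintf("%s (p = %s)", tr$stars, fmt_p(tr$p_value))
    }
    t1[[length(t1) + 1L]] <- data.frame(
      row_type = "significance",
      system = sprintf("%s vs %s", pair[1], pair[2]),
      criterion_distance = fmt_sig("distance"),
      criterion_rmsd = fmt_sig("rmsd"))
  }
  utils::write.table(do.call(rbind, t1), file.path(out, "reached_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    cutoffs_A = as.list(cutoffs),
    skewfit = if (is.null(skewfit)) NULL else unclass(skewfit),
    systems = lapply(labels, function(label) list(
      label = label,
      distance = list(
        mean_frequency_pct = summaries$distance[[label]]$mean_frequency_pct,
        pooled_frame_pct = summaries$distance[[label]]$pooled_frame_pct,
        frequencies_pct = summaries$distance[[label]]$frequencies_pct,
        n_reached = summaries$distance[[label]]$n_reached),
      rmsd = list(
        mean_frequency_pct = summaries$rmsd[[label]]$mean_frequency_pct,
        pooled_frame_pct = summaries$rmsd[[label]]$pooled_frame_pct,
        frequencies_pct = summaries$rmsd[[label]]$frequencies_pct,
        n_reached = summaries$rmsd[[label]]$n_reached))),
    comparisons = lapply(comparisons, function(cmp) list(
      pair = cmp$pair,
      mann_whitney = list(U = cmp$mann_whitney$statistic,
                          p = cmp$mann_whitney$p_value,
                          stars = cmp$mann_whitney$stars,
                          method = cmp$mann_whitney$method),
      indicator_t = list(t = cmp$indicator_t$statistic,
                         p = cmp$indicator_t$p_value,
                         stars = cmp$indicator_t$stars))))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8,
                       null = "null")
  invisible(list(summaries = summaries, comparisons = comparisons,
                 cutoffs_A = cutoffs, skewfit = skewfit,
                 output_dir = out,
                 files = list.files(out, full.names = TRUE)))
}

# ---- Command-line interface ----------------------------------------------

cli_parse <- function(args) {
  opts <- list(); positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        opts[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        opts[[key]] <- args[[i + 1L]]; i <- i + 1L
      } else opts[[key]] <- TRUE
    } else positional <- c(positional, a)
    i <- i + 1L
  }
  list(opts = opts, positional = positional)
}

cli_usage <- function() {
  cat(
    "usage: h12switch <subcommand> [options]\n",
    "subcommands:\n",
    "  simulate   --preset paper-like --seed N --out DIR [--replicas N] [--frames N]\n",
    "  analyze    --config FILE\n",
    "  fit-cutoff --values TSV [--column value_A] [--bin-width 0.1]\n",
    "  compare    --report report.json --pair labelA,labelB\n",
    "  report     --dir ANALYSIS_DIR\n",
    file = stderr())
}

cli_log <- function(level, fmt, ..., verbose = TRUE) {
  if (verbose) cat(sprintf("[%s] %s\n", level, sprintf(fmt, ...)), file = stderr())
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (generate a synthetic cohort on disk), `analyze`
#' (run the full pipeline from a config), `fit-cutoff` (skew-normal fit on a
#' TSV column of pooled metric values), `compare` (replica-level tests on two
#' systems of an existing report), `report` (print the reached-state table
#' of a finished analysis). Logs go to stderr; data to files/stdout.
#'
#' @param argv character vector of arguments (default: the R session's
#'   command line)
#' @return integer exit code: 0 success, 1 runtime failure, 2 usage error.
#'   A wrapper script should pass it to `quit(status = )`.
#' @export
h12_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) { cli_usage(); return(2L) }
  sub <- argv[[1]]
  parsed <- cli_parse(argv[-1])
  o <- parsed$opts
  known <- list(
    simulate = c("preset", "seed", "out", "replicas", "frames", "quiet"),
    analyze = c("config", "quiet"),
    `fit-cutoff` = c("values", "column", "bin-width", "quiet"),
    compare = c("report", "pair", "quiet"),
    report = c("dir", "quiet"))
  if (!sub %in% names(known)) {
    cat("unknown subcommand: ", sub, "\n", file = stderr()); cli_usage()
    return(2L)
  }
  bad <- setdiff(names(o), known[[sub]])
  if (length(bad)) {
    cat("unknown option(s): ", paste0("--", bad, collapse = " "), "\n",
        file = stderr())
    return(2L)
  }
  verbose <- is.null(o$quiet)
  run <- function() {
    if (sub == "simulate") {
      seed <- as.integer(o$seed %||% 1)
      out_dir <- o$out %||% "h12_cohort"
      n_frames <- as.integer(o$frames %||% 1000)
      preset <- o$preset %||% "paper-like"
      if (preset != "paper-like") stop("unknown preset: ", preset, call. = FALSE)
      systems <- paper_like_systems(seed = seed, n_frames = n_frames)
      if (!is.null(o$replicas)) {
        for (nm in names(systems)) systems[[nm]]$n_replicas <- as.integer(o$replicas)
      }
      cli_log("INFO", "simulating %d systems into %s (seed %d)",
              length(systems), out_dir, seed, verbose = verbose)
      generate_cohort(systems, out_dir)
      cli_log("INFO", "wrote cohort and config stub: %s",
              file.path(out_dir, "config.json"), verbose = verbose)
    } else if (sub == "analyze") {
      if (is.null(o$config)) stop("analyze requires --config", call. = FALSE)
      cfg <- read_config(o$config)
      cli_log("INFO", "running analysis into %s", cfg$output_dir, verbose = verbose)
      rep <- run_analysis(cfg)
      cli_log("INFO", "report bundle: %s", paste(basename(rep$files), collapse = ", "),
              verbose = verbose)
    } else if (sub == "fit-cutoff") {
      if (is.null(o$values)) stop("fit-cutoff requires --values TSV", call. = FALSE)
      col <- o$column %||% "value_A"
      bw <- as.numeric(o[["bin-width"]] %||% 0.1)
      df <- utils::read.table(o$values, header = TRUE, sep = "\t")
      if (!col %in% names(df)) stop("column '", col, "' not in ", o$values, call. = FALSE)
      fit <- fit_skew_normal_cutoff(as.numeric(df[[col]]), bw)
      cat(jsonlite::toJSON(unclass(fit), auto_unbox = TRUE, digits = 8), "\n")
    } else if (sub == "compare") {
      if (is.null(o$report) || is.null(o$pair)) {
        stop("compare requires --report report.json and --pair labelA,labelB",
             call. = FALSE)
      }
      rep <- jsonlite::read_json(o$report, simplifyVector = FALSE)
      pair <- strsplit(o$pair, ",", fixed = TRUE)[[1]]
      if (length(pair) != 2) stop("--pair must be 'labelA,labelB'", call. = FALSE)
      get_sys <- function(lb) {
        for (s in rep$systems) if (identical(s$label, lb)) return(s)
        stop("system '", lb, "' not in report", call. = FALSE)
      }
      out <- list()
      for (criterion in c("distance", "rmsd")) {
        a <- get_sys(pair[1]); b <- get_sys(pair[2])
        mw <- mann_whitney_u(unlist(a[[criterion]]$frequencies_pct),
                             unlist(b[[criterion]]$frequencies_pct))
        na_ <- length(a[[criterion]]$frequencies_pct)
        nb_ <- length(b[[criterion]]$frequencies_pct)
        tt <- tryCatch(indicator_t_test(na_, a[[criterion]]$n_reached,
                                        nb_, b[[criterion]]$n_reached),
                       error = function(e) NULL)
        out[[criterion]] <- list(
          mann_whitney = list(U = mw$statistic, p = mw$p_value,
                              stars = significance_stars(mw$p_value)),
          indicator_t = if (is.null(tt)) "degenerate" else
            list(t = tt$statistic, p = tt$p_value,
                 stars = significance_stars(tt$p_value)))
      }
      cat(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 8), "\n")
    } else if (sub == "report") {
      dir <- o$dir %||% "."
      path <- file.path(dir, "reached_table.tsv")
      if (!file.exists(path)) stop("no reached_table.tsv under ", dir, call. = FALSE)
      writeLines(readLines(path))
    }
    0L
  }
  tryCatch(run(), error = function(e) {
    cat("error: ", conditionMessage(e), "\n", file = stderr())
    1L
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
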