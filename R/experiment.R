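#' Configure an end-to-end experiment
#'
#' Bundles the cohort specification, the epoching and band settings, the
#' classifier list and the validation schemes for [run_experiment()].
#' Defaults follow the package's reference pipeline: 250 Hz working rate,
#' 0.5--48 Hz conditioning band, 5 s epochs with 2.5 s stride, five rhythm
#' bands, ten folds.
#'
#' @param cohort A [cohort_spec()].
#' @param profiles Class spectral profiles (see [class_profiles_default()]).
#' @param duration_s,stride_s Epoching parameters (seconds).
#' @param bands Band definition table.
#' @param target_fs_hz Working sampling rate after decimation.
#' @param classifiers Character vector of classifier kinds, or a named list
#'   of [classifier_spec()] objects.
#' @param schemes Validation schemes to run (subset of `"kfold"`, `"lopo"`).
#' @param k Folds for the pooled k-fold scheme.
#' @param seed Experiment seed (fold shuffles and stochastic learners).
#' @param output_dir Optional directory for persisted reports.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              profiles = class_profiles_default(),
                              duration_s = 5, stride_s = 2.5,
                              bands = eeg_bands(), target_fs_hz = 250,
                              classifiers = names(all_classifiers()),
                              schemes = c("kfold", "lopo"),
                              k = 10L, seed = 1L, output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"), duration_s > 0, stride_s > 0)
  schemes <- match.arg(schemes, c("kfold", "lopo"), several.ok = TRUE)
  if (is.character(classifiers)) {
    classifiers <- stats::setNames(lapply(classifiers, classifier_spec),
                                   classifiers)
  }
  structure(
    list(cohort = cohort, profiles = profiles, duration_s = duration_s,
         stride_s = stride_s, bands = bands, target_fs_hz = target_fs_hz,
         classifiers = classifiers, schemes = schemes, k = as.integer(k),
         seed = as.integer(seed), output_dir = output_dir),
    class = "experiment_config")
}

# Small deterministic FNV-1a hash of the serialised config, for provenance.
# The output directory is not part of the scientific configuration.
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$output_dir <- NULL
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

pairwise_problems <- function(classes) {
  all_pairs <- list(c("AD", "CN"), c("FTD", "CN"), c("AD", "FTD"))
  keep <- vapply(all_pairs, function(p) all(p %in% classes), logical(1))
  all_pairs[keep]
}

#' Run the full comparison experiment
#'
#' Generates (or accepts) a cohort, preprocesses it, extracts epoch
#' features, and evaluates every configured classifier under every
#' configured scheme on every pairwise problem present (AD/CN, FTD/CN,
#' AD/FTD). The report places both schemes side by side with the
#' k-fold-minus-LOPO accuracy gap as an explicit column, since that
#' inflation gap is the methodological quantity of interest.
#'
#' @param cfg An [experiment_config()].
#' @param cohort Optional pre-generated list of recordings (bypasses
#'   generation; useful for EDF-loaded data).
#' @param verbose Log per-stage row/epoch counts.
#' @return A data frame of class `comparison_report`: one row per problem
#'   x classifier with per-scheme accuracy/SD/sensitivity/specificity
#'   columns and `gap_accuracy`. The underlying `cv_summary` objects are
#'   attached as the `"summaries"` attribute; provenance (config hash,
#'   seed) as attributes.
#' @export
run_experiment <- function(cfg, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    say("generating cohort: %d subject(s)", sum(cfg$cohort$n_per_class))
    cohort <- generate_cohort(cfg$cohort, cfg$profiles)
  }
  say("extracting features: %d recording(s)", length(cohort))
  table <- cohort_features(cohort, duration_s = cfg$duration_s,
                           stride_s = cfg$stride_s, bands = cfg$bands,
                           target_fs_hz = cfg$target_fs_hz)
  say("feature table: %d epoch row(s), %d column(s)", nrow(table),
      ncol(table))
  problems <- pairwise_problems(levels(table$class))
  if (length(problems) == 0L) {
    stop("need at least two classes for a pairwise problem", call. = FALSE)
  }
  summaries <- list()
  rows <- list()
  for (pb in problems) {
    pname <- paste(pb, collapse = "/")
    sub <- ft_rows(table, table$class %in% pb)
    sub$class <- droplevels(sub$class)
    positive <- default_positive(pb)
    for (cn in names(cfg$classifiers)) {
      clf <- cfg$classifiers[[cn]]
      row <- list(problem = pname, classifier = cn)
      for (sch in cfg$schemes) {
        s <- if (sch == "kfold") {
          pooled_kfold_cv(sub, clf, k = cfg$k, seed = cfg$seed,
                          positive = positive)
        } else {
          lopo_cv(sub, clf = clf, seed = cfg$seed, positive = positive)
        }
        summaries[[paste(pname, cn, sch, sep = "|")]] <- s
        row[[paste0(sch, "_accuracy")]] <- s$mean_accuracy
        row[[paste0(sch, "_sd")]] <- s$sd_accuracy
        row[[paste0(sch, "_sensitivity")]] <- s$mean_sensitivity
        row[[paste0(sch, "_specificity")]] <- s$mean_specificity
        say("%s %s %s: accuracy %.3f", pname, cn, sch, s$mean_accuracy)
      }
      if (all(c("kfold", "lopo") %in% cfg$schemes)) {
        row$gap_accuracy <- row$kfold_accuracy - row$lopo_accuracy
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "summaries") <- summaries
  attr(report, "config_hash") <- config_hash(cfg)
  attr(report, "seed") <- cfg$seed
  class(report) <- c("comparison_report", "data.frame")
  if (!is.null(cfg$output_dir)) {
    persist_report(report, cfg)
  }
  report
}

persist_report <- function(report, cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report),
                   file.path(cfg$output_dir, "report.csv"),
                   row.names = FALSE)
  for (key in names(attr(report, "summaries"))) {
    fname <- paste0(gsub("[^A-Za-z0-9]", "_", key), ".json")
    cv_summary_json(attr(report, "summaries")[[key]],
                    file.path(cfg$output_dir, fname))
  }
  jsonlite::write_json(
    list(config_hash = attr(report, "config_hash"), seed = cfg$seed,
         duration_s = cfg$duration_s, stride_s = cfg$stride_s,
         k = cfg$k, schemes = cfg$schemes,
         classifiers = names(cfg$classifiers)),
    file.path(cfg$output_dir, "provenance.json"),
    auto_unbox = TRUE)
  invisible(report)
}

#' Sweep epoch duration/stride settings
#'
#' Runs [run_experiment()] once per `(duration, stride)` pair (vectors are
#' zipped, not crossed), reusing one generated cohort across settings so
#' that only the epoching varies.
#'
#' @param cfg An [experiment_config()].
#' @param durations,strides Equal-length numeric vectors (seconds).
#' @param verbose Forwarded to [run_experiment()].
#' @return Named list of `comparison_report`s, names like `"d5_s2.5"`.
#' @export
epoch_sweep <- function(cfg, durations = c(2, 5, 10),
                        strides = c(1, 2.5, 5), verbose = FALSE) {
  stopifnot(length(durations) == length(strides), length(durations) >= 1)
  cohort <- generate_cohort(cfg$cohort, cfg$profiles)
  out <- list()
  for (i in seq_along(durations)) {
    cfg_i <- cfg
    cfg_i$duration_s <- durations[i]
    cfg_i$stride_s <- strides[i]
    if (!is.null(cfg$output_dir)) {
      cfg_i$output_dir <- file.path(cfg$output_dir,
                                    sprintf("d%g_s%g", durations[i],
                                            strides[i]))
    }
    out[[sprintf("d%g_s%g", durations[i], strides[i])]] <-
      run_experiment(cfg_i, cohort = cohort, verbose = verbose)
  }
  out
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file may contain a `cohort` block (fields of [cohort_spec()]), an
#' `epoch` block (`duration_s`, `stride_s`), and top-level `classifiers`,
#' `schemes`, `k`, `seed`, `target_fs_hz`, `output_dir`. Missing fields
#' fall back to package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$n_per_class)) {
    cohort_args$n_per_class <- unlist(cohort_args$n_per_class)
  }
  if (!is.null(cohort_args$duration_s) &&
      !is.null(names(cohort_args$duration_s))) {
    cohort_args$duration_s <- unlist(cohort_args$duration_s)
  }
  cohort <- do.call(cohort_spec, cohort_args)
  args <- list(cohort = cohort)
  ep <- raw$epoch %||% list()
  if (!is.null(ep$duration_s)) args$duration_s <- ep$duration_s
  if (!is.null(ep$stride_s)) args$stride_s <- ep$stride_s
  for (f in c("classifiers", "schemes", "k", "seed", "target_fs_hz",
              "output_dir")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(experiment_config, args)
}
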