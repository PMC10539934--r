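# End-to-end orchestration: cohort in (synthetic spec or EDF directory),
# preprocessing, the four analysis families, group statistics, TSV outputs
# and a reproducibility manifest.

#' Build a run configuration
#'
#' Defaults reproduce the study-scale analysis on the default synthetic
#' cohort. All randomised stages draw from child seeds derived from `seed`,
#' so partial re-runs are reproducible stage by stage.
#'
#' @param spec A [cohort_spec()] (synthetic input), or `NULL` when reading
#'   EDF files.
#' @param edf_dir,roster Directory of EDF files plus a TSV roster
#'   (columns `subject`, `group`, `file`); used when `spec` is `NULL`.
#' @param f_lo,f_hi Band-pass edges (Hz).
#' @param epoch_length Epoch length (s).
#' @param n_keep Artifact-free epochs per subject.
#' @param amp_limit,flat_limit Artifact screening thresholds (muV).
#' @param bands List of [band_spec()].
#' @param entropy_scales Scale factors for the multiscale curves.
#' @param entropy_test_scale Scale at which per-channel entropy group tests
#'   are run (default 4).
#' @param entropy_m,entropy_r Sample-entropy parameters (permutation entropy
#'   uses motif length 3).
#' @param efficiency_grid,sigma_grid Sparsity grids for the efficiency and
#'   small-world sweeps.
#' @param n_refs Random references per sigma evaluation.
#' @param n_boot Bootstrap resamples for group-mean CIs.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), edf_dir = NULL, roster = NULL,
                       f_lo = 0.1, f_hi = 50, epoch_length = 2,
                       n_keep = 50L, amp_limit = 150, flat_limit = 0.5,
                       bands = eeg_bands(), entropy_scales = 1:30,
                       entropy_test_scale = 4L, entropy_m = 1L,
                       entropy_r = 0.25,
                       efficiency_grid = seq(0.10, 0.70, by = 0.01),
                       sigma_grid = seq(0.70, 0.85, by = 0.01),
                       n_refs = 100L, n_boot = 1000L, seed = 42L) {
  if (is.null(spec) && (is.null(edf_dir) || is.null(roster))) {
    stop("either a cohort spec or an EDF directory with a roster is required")
  }
  structure(
    list(spec = spec, edf_dir = edf_dir, roster = roster, f_lo = f_lo,
         f_hi = f_hi, epoch_length = epoch_length, n_keep = n_keep,
         amp_limit = amp_limit, flat_limit = flat_limit, bands = bands,
         entropy_scales = entropy_scales,
         entropy_test_scale = as.integer(entropy_test_scale),
         entropy_m = entropy_m, entropy_r = entropy_r,
         efficiency_grid = efficiency_grid, sigma_grid = sigma_grid,
         n_refs = as.integer(n_refs), n_boot = as.integer(n_boot),
         seed = as.integer(seed)),
    class = "run_config")
}

.load_cohort <- function(cfg) {
  if (!is.null(cfg$spec)) {
    sp <- cfg$spec
    sp$seed <- cfg$seed
    return(generate_cohort(sp))
  }
  roster <- utils::read.delim(cfg$roster, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "group", "file") %in% names(roster)))
  recs <- list()
  for (i in seq_len(nrow(roster))) {
    recs[[roster$subject[i]]] <- read_edf(
      file.path(cfg$edf_dir, roster$file[i]),
      subject_id = roster$subject[i], group = roster$group[i])
  }
  list(recordings = recs,
       groups = stats::setNames(roster$group, roster$subject))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, spectral, complexity, connectivity, graph and stats
#' stages for every subject and writes all result tables plus a JSON run
#' manifest to `out_dir`. Identical `(config, seed)` reproduces identical
#' tables.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_pipeline <- function(cfg, out_dir, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  stage <- "load"
  tables <- list()
  t0 <- Sys.time()
  result <- tryCatch({
    say("stage: cohort")
    cohort <- .load_cohort(cfg)
    groups <- cohort$groups

    stage <- "preprocess"
    say("stage: preprocess")
    epoch_sets <- lapply(cohort$recordings, function(rec) {
      preprocess_subject(rec, cfg$f_lo, cfg$f_hi, cfg$epoch_length,
                         cfg$n_keep, cfg$amp_limit, cfg$flat_limit)
    })

    stage <- "spectral"
    say("stage: spectral")
    psds <- lapply(epoch_sets, multitaper_psd)
    bp <- band_power_table(psds, cfg$bands, groups)
    tables$band_power <- bp
    bp$value <- bp$power
    tables$band_power_stats <- group_contrast_table(
      bp, by = c("band", "channel"), groups = c("HC", "MCI"),
      scheme = "per_band_across_electrodes")
    topo <- do.call(rbind, lapply(cfg$bands, function(b) {
      tp <- band_topography(bp, b$name)
      tp$band <- b$name
      tp
    }))
    tables$band_topography <- merge(
      topo, tables$band_power_stats[, c("band", "channel", "p_raw", "p_fdr")],
      by = c("band", "channel"), sort = FALSE)

    stage <- "complexity"
    say("stage: complexity")
    ent <- do.call(rbind, c(
      lapply(epoch_sets, entropy_table, estimator = "sample",
             scales = cfg$entropy_scales, m = cfg$entropy_m,
             r = cfg$entropy_r),
      lapply(epoch_sets, entropy_table, estimator = "permutation",
             scales = cfg$entropy_scales)))
    rownames(ent) <- NULL
    tables$entropy <- ent
    et <- ent[ent$scale == cfg$entropy_test_scale, ]
    et$value <- et$value
    et$band <- et$estimator     # correction family: estimator map, 19 channels
    tables$entropy_stats <- group_contrast_table(
      et, by = c("estimator", "band", "channel"), groups = c("HC", "MCI"),
      scheme = "per_band_across_electrodes",
      n_boot = cfg$n_boot, seed = cfg$seed + 2000000L)

    stage <- "connectivity"
    say("stage: connectivity")
    # one connectivity matrix per subject x band, shared by the wPLI,
    # region and graph stages
    cms <- lapply(epoch_sets, function(es) {
      out <- lapply(cfg$bands, function(b) connectivity_matrix(es, b))
      names(out) <- vapply(cfg$bands, function(b) b$name, character(1))
      out
    })
    wp_rows <- list()
    for (sid in names(cms)) {
      for (bn in names(cms[[sid]])) {
        cm <- cms[[sid]][[bn]]
        ut <- which(upper.tri(cm$values), arr.ind = TRUE)
        ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
        wp_rows[[length(wp_rows) + 1L]] <- data.frame(
          subject = sid, group = groups[[sid]], band = bn,
          chan_i = cm$channels[ut[, 1]], chan_j = cm$channels[ut[, 2]],
          wpli = cm$values[ut], stringsAsFactors = FALSE)
      }
    }
    wp <- do.call(rbind, wp_rows)
    tables$wpli <- wp
    wp$value <- wp$wpli
    tables$wpli_stats <- group_contrast_table(
      wp, by = c("band", "chan_i", "chan_j"), groups = c("HC", "MCI"),
      scheme = "per_connection_across_bands")
    # region-level summaries
    region_rows <- list()
    rp <- region_partition()
    rnames <- names(rp)
    for (sid in names(epoch_sets)) {
      for (b in cfg$bands) {
        cm <- cms[[sid]][[b$name]]
        for (ra in seq_along(rnames)) {
          for (rb in ra:length(rnames)) {
            region_rows[[length(region_rows) + 1L]] <- data.frame(
              subject = sid, group = groups[[sid]], band = b$name,
              region_a = rnames[ra], region_b = rnames[rb],
              value = region_mean(cm, rnames[ra], rnames[rb]),
              stringsAsFactors = FALSE)
          }
        }
        region_rows[[length(region_rows) + 1L]] <- data.frame(
          subject = sid, group = groups[[sid]], band = b$name,
          region_a = "whole_brain", region_b = "whole_brain",
          value = whole_brain_mean(cm), stringsAsFactors = FALSE)
      }
    }
    regions <- do.call(rbind, region_rows)
    tables$wpli_regions <- regions
    tables$region_stats <- group_contrast_table(
      regions, by = c("band", "region_a", "region_b"),
      groups = c("HC", "MCI"), scheme = "none")

    stage <- "graph"
    say("stage: graph")
    sweep_rows <- list()
    nodal_rows <- list()
    sigma_rows <- list()
    for (sid in names(epoch_sets)) {
      for (b in cfg$bands) {
        cm <- cms[[sid]][[b$name]]
        sw <- sparsity_sweep(cm, cfg$efficiency_grid, n_refs = 0L)
        sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
          subject = sid, group = groups[[sid]], band = b$name,
          sw[, c("sparsity", "e_glob", "e_loc", "clustering",
                 "path_length")], stringsAsFactors = FALSE)
        nd <- attr(sw, "nodal")
        nodal_rows[[length(nodal_rows) + 1L]] <- data.frame(
          subject = sid, group = groups[[sid]], band = b$name, nd,
          stringsAsFactors = FALSE)
        if (length(cfg$sigma_grid) && cfg$n_refs > 0) {
          sig <- vapply(seq_along(cfg$sigma_grid), function(i) {
            g <- binarize_top_n(cm, cfg$sigma_grid[i])
            small_world_sigma(g, cfg$n_refs,
                              seed = cfg$seed + 1000000L + i)
          }, numeric(1))
          sigma_rows[[length(sigma_rows) + 1L]] <- data.frame(
            subject = sid, group = groups[[sid]], band = b$name,
            sparsity = cfg$sigma_grid, sigma = sig,
            stringsAsFactors = FALSE)
        }
      }
    }
    sweeps <- do.call(rbind, sweep_rows)
    tables$graph_sweep <- sweeps
    long_eff <- rbind(
      data.frame(sweeps[c("subject", "group", "band", "sparsity")],
                 metric = "e_glob", value = sweeps$e_glob),
      data.frame(sweeps[c("subject", "group", "band", "sparsity")],
                 metric = "e_loc", value = sweeps$e_loc))
    tables$graph_stats <- group_contrast_table(
      long_eff, by = c("band", "metric", "sparsity"),
      groups = c("HC", "MCI"), scheme = "none")
    nodal <- do.call(rbind, nodal_rows)
    tables$nodal <- nodal
    # nodal efficiency tests at the most diagnostic threshold (20%)
    nd_test <- nodal[abs(nodal$sparsity - 0.20) < 1e-9, ]
    if (!nrow(nd_test)) {
      nd_test <- nodal[nodal$sparsity == nodal$sparsity[1], ]
    }
    tables$nodal_stats <- group_contrast_table(
      nd_test, by = c("band", "sparsity", "channel"),
      groups = c("HC", "MCI"), scheme = "per_band_across_electrodes")
    if (length(sigma_rows)) {
      sigmas <- do.call(rbind, sigma_rows)
      tables$smallworld <- sigmas
      sigmas$value <- sigmas$sigma
      tables$smallworld_stats <- group_contrast_table(
        sigmas, by = c("band", "sparsity"), groups = c("HC", "MCI"),
        scheme = "none")
    }

    stage <- "write"
    say("stage: write")
    paths <- character(0)
    for (nm in names(tables)) {
      paths[nm] <- .write_tsv(tables[[nm]], file.path(out_dir,
                                                      paste0(nm, ".tsv")))
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("eegconn")),
      seed = cfg$seed,
      config = .config_echo(cfg),
      n_subjects = length(epoch_sets),
      groups = as.list(table(groups)),
      tables = lapply(paths, function(p) unname(tools::md5sum(p))),
      started = format(t0, "%Y-%m-%dT%H:%M:%S"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(tables = tables, manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

.config_echo <- function(cfg) {
  echo <- cfg
  class(echo) <- NULL
  echo$bands <- lapply(cfg$bands, function(b) list(name = b$name,
                                                   f_lo = b$f_lo,
                                                   f_hi = b$f_hi))
  if (!is.null(echo$spec)) {
    sp <- echo$spec
    class(sp) <- NULL
    sp$coupling_edges <- NULL   # summarised instead
    sp$n_coupling_edges <- nrow(cfg$spec$coupling_edges)
    echo$spec <- sp
  }
  echo
}

#' Summarise significant findings from a pipeline run
#'
#' Reads the stats tables of a finished run and lists, per analysis family,
#' the features significant at `alpha` (on `p_fdr` where the family has an
#' FDR scheme, else on `p_raw`) with the direction of the group difference.
#'
#' @param run A result of [run_pipeline()], or an output directory path.
#' @param alpha Significance level (default 0.05).
#' @return Character vector (one line per finding), invisibly; printed.
#' @export
report_summary <- function(run, alpha = 0.05) {
  tables <- if (is.character(run)) {
    files <- c("band_power_stats", "entropy_stats", "wpli_stats",
               "region_stats", "graph_stats", "nodal_stats",
               "smallworld_stats")
    out <- list()
    for (f in files) {
      p <- file.path(run, paste0(f, ".tsv"))
      if (file.exists(p)) out[[f]] <- utils::read.delim(p)
    }
    out
  } else {
    run$tables[c("band_power_stats", "entropy_stats", "wpli_stats",
                 "region_stats", "graph_stats", "nodal_stats",
                 "smallworld_stats")]
  }
  tables <- Filter(Negate(is.null), tables)
  if (!length(tables)) stop("no stats tables found")
  lines <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!all(c("p_raw", "median_a", "median_b") %in% names(tab))) {
      stop("table '", nm, "' is missing required columns")
    }
    use_fdr <- "p_fdr" %in% names(tab) && any(!is.na(tab$p_fdr))
    p <- if (use_fdr) tab$p_fdr else tab$p_raw
    hits <- which(!is.na(p) & p < alpha)
    for (h in hits) {
      keys <- setdiff(names(tab),
                      c("median_a", "median_b", "statistic", "p_raw",
                        "p_fdr", "ci_lo_a", "ci_hi_a", "ci_lo_b", "ci_hi_b"))
      desc <- paste(vapply(keys, function(k) paste0(k, "=", tab[[k]][h]),
                           character(1)), collapse = " ")
      dir <- if (tab$median_a[h] > tab$median_b[h]) "HC > MCI" else "HC < MCI"
      lines <- c(lines, sprintf(
        "[%s] %s: %s (%s=%.4f)", nm, desc, dir,
        if (use_fdr) "p_fdr" else "p", p[h]))
    }
  }
  if (!length(lines)) lines <- "no significant findings"
  cat(lines, sep = "\n")
  invisible(lines)
}
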