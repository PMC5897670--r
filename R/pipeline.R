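#' Pipeline configuration
#'
#' Collects paths and analysis options for [run_pipeline()]. Inputs are
#' assumed fully preprocessed ROI time series: the pipeline performs no
#' motion correction, filtering or smoothing, only (optional) per-epoch
#' column standardization.
#'
#' @param manifest,roiset,ratings Input CSV paths (see
#'   [read_timeseries_manifest()], [read_roi_set()], [read_ratings()]).
#' @param behavior Optional behavior CSV path; `NULL` skips the behavior
#'   stage.
#' @param out_dir Output directory for the result bundle.
#' @param tr_seconds Repetition time of the runs; default 3.
#' @param rate_hz,scale_levels Rating trace parameters; defaults 10 and 21.
#' @param epoch_alpha Wilcoxon threshold for the epoch search; default 0.01.
#' @param pairing Wilcoxon pairing unit, `"subjects"` or `"timepoints"`.
#' @param lag_seconds Hemodynamic lag applied when mapping epochs to TRs.
#' @param correlation_transform `"raw_r"` (default) or `"fisher_z"`.
#' @param intra_mode Passed to [intra_network_influence()].
#' @param normalization Pair normalization for inter-network schemes.
#' @param reactivity_net,regulation_net Names of the two sub-network tags in
#'   the ROI set; influence schemes are computed with the regulation network
#'   as source.
#' @param standardize_epochs Z-score columns within each epoch; default
#'   `TRUE`.
#' @param alpha_edges Edgewise contrast threshold; default 0.05.
#' @param fdr_q FDR threshold used to pick nodes for the behavior stage;
#'   default 0.05.
#' @param exclusion_sd Behavior-correlation outlier rule; default 3.
#' @param bootstrap_k Random networks for the specificity stage (0 = skip).
#' @param literal_eq5 Passed to [specificity_bootstrap()].
#' @param seed Integer seed for all pipeline randomness.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, roiset, ratings, behavior = NULL,
                            out_dir, tr_seconds = 3, rate_hz = 10,
                            scale_levels = 21, epoch_alpha = 0.01,
                            pairing = "subjects", lag_seconds = 0,
                            correlation_transform = "raw_r",
                            intra_mode = "subnetwork",
                            normalization = "mean",
                            reactivity_net = "reactivity",
                            regulation_net = "regulation",
                            standardize_epochs = TRUE,
                            alpha_edges = 0.05, fdr_q = 0.05,
                            exclusion_sd = 3, bootstrap_k = 0,
                            literal_eq5 = FALSE, seed = 1L) {
  cfg <- list(manifest = manifest, roiset = roiset, ratings = ratings,
              behavior = behavior, out_dir = out_dir,
              tr_seconds = tr_seconds, rate_hz = rate_hz,
              scale_levels = scale_levels, epoch_alpha = epoch_alpha,
              pairing = pairing, lag_seconds = lag_seconds,
              correlation_transform = correlation_transform,
              intra_mode = intra_mode, normalization = normalization,
              reactivity_net = reactivity_net,
              regulation_net = regulation_net,
              standardize_epochs = standardize_epochs,
              alpha_edges = alpha_edges, fdr_q = fdr_q,
              exclusion_sd = exclusion_sd, bootstrap_k = bootstrap_k,
              literal_eq5 = literal_eq5, seed = as.integer(seed))
  for (p in c("manifest", "roiset", "ratings"))
    if (!file.exists(cfg[[p]])) stop(p, " file not found: ", cfg[[p]])
  stopifnot(cfg$correlation_transform %in% c("raw_r", "fisher_z"),
            cfg$intra_mode %in% c("subnetwork", "masked_full"),
            cfg$normalization %in% c("mean", "sum"),
            cfg$epoch_alpha > 0, cfg$epoch_alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()]. Relative input paths
#' are resolved against the configuration file's directory.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(path)
  for (p in c("manifest", "roiset", "ratings", "behavior", "out_dir"))
    if (!is.null(raw[[p]]) && !grepl("^(/|[A-Za-z]:)", raw[[p]]))
      raw[[p]] <- file.path(base, raw[[p]])
  do.call(pipeline_config, raw)
}

.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full influence-hierarchy pipeline
#'
#' End-to-end composition: epoch selection from the rating traces; per
#' subject and condition, dependency matrices and the four influence
#' aggregates (global influencing degree; intra-regulation; regulation on
#' connections within the reactivity network; regulation on connections
#' between the two networks); paired condition contrasts with BH-FDR per
#' scheme, plus contrasts of the two total inter-network influences;
#' edgewise contrast graph with BrainNet and GraphML export; behavior
#' correlations (low minus high influence vs. each behavioral column) for
#' nodes surviving FDR; and an optional random-network specificity bootstrap
#' of the strongest global contrast, using i.i.d. Gaussian null networks as
#' the sampling pool. All tables, graph files and a provenance JSON are
#' written to `out_dir`.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the epoch pair, the per-scheme contrast
#'   tables, the edge graph, the behavior correlation table (or `NULL`) and
#'   the bootstrap result (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  roiset <- read_roi_set(config$roiset)
  ts <- read_timeseries_manifest(config$manifest, roiset, config$tr_seconds)
  ratings <- read_ratings(config$ratings, config$rate_hz,
                          config$scale_levels)

  # --- epochs ---------------------------------------------------------
  pair <- find_epoch_pair(ratings, alpha = config$epoch_alpha,
                          pairing = config$pairing)
  pair <- epochs_to_tr(pair, config$tr_seconds, config$lag_seconds)
  jsonlite::write_json(
    list(low_window_s = pair$low_window, high_window_s = pair$high_window,
         length_s = pair$length_s, wilcoxon_p = pair$wilcoxon_p,
         pairing = pair$pairing,
         tr_windows = pair$tr_windows),
    file.path(out, "epochs.json"), auto_unbox = TRUE, digits = NA)

  ts_low <- lapply(ts, slice_epoch, tr_window = pair$tr_windows$low,
                   standardize = config$standardize_epochs)
  ts_high <- lapply(ts, slice_epoch, tr_window = pair$tr_windows$high,
                    standardize = config$standardize_epochs)

  # --- influence schemes ---------------------------------------------
  reg <- config$regulation_net
  rea <- config$reactivity_net
  schemes <- list(
    global_degree = list(scheme = "global_degree"),
    intra_regulation = list(scheme = "intra", source_net = reg),
    inter_within_reactivity = list(scheme = "inter_within_other",
                                   source_net = reg, target_net = rea),
    inter_between = list(scheme = "inter_between",
                         source_net = reg, target_net = rea))
  tables <- list()
  totals <- list()
  for (nm in names(schemes)) {
    sc <- schemes[[nm]]
    lo <- cohort_influence(ts_low, roiset, scheme = sc$scheme,
                           source_net = sc$source_net,
                           target_net = sc$target_net,
                           normalization = config$normalization,
                           transform = config$correlation_transform,
                           intra_mode = config$intra_mode)
    hi <- cohort_influence(ts_high, roiset, scheme = sc$scheme,
                           source_net = sc$source_net,
                           target_net = sc$target_net,
                           normalization = config$normalization,
                           transform = config$correlation_transform,
                           intra_mode = config$intra_mode)
    tab <- paired_condition_ttest(lo, hi)
    tables[[nm]] <- tab
    .write_table(tab, file.path(out, paste0("influence_", nm, ".csv")))
    if (sc$scheme %in% c("inter_within_other", "inter_between")) {
      tot <- .paired_t(rowSums(hi), rowSums(lo))
      totals[[nm]] <- data.frame(scheme = nm, t = tot$t, df = tot$df,
                                 p = tot$p, mean_low = mean(rowSums(lo)),
                                 mean_high = mean(rowSums(hi)),
                                 stringsAsFactors = FALSE)
    }
    attr(tables[[nm]], "delta") <- lo - hi     # low minus high, per subject
  }
  .write_table(do.call(rbind, totals),
               file.path(out, "total_inter_network.csv"))

  # --- edgewise contrast graph ---------------------------------------
  dep_stack <- function(ts_list) {
    n <- length(roiset)
    arr <- array(0, dim = c(n, n, length(ts_list)),
                 dimnames = list(roiset$labels, roiset$labels,
                                 names(ts_list)))
    for (s in seq_along(ts_list)) {
      cm <- pearson_correlations(ts_list[[s]])
      if (config$correlation_transform == "fisher_z")
        cm <- suppressWarnings(fisher_z(cm))
      arr[, , s] <- suppressWarnings(dependency_matrix(cm))$values
    }
    arr
  }
  graph <- edge_contrast_graph(dep_stack(ts_low), dep_stack(ts_high),
                               alpha = config$alpha_edges)
  .write_table(graph$edges, file.path(out, "contrast_edges.csv"))
  write_brainnet(graph, roiset, file.path(out, "contrast"))
  write_contrast_graphml(graph, file.path(out, "contrast.graphml"))

  # --- behavior correlations -----------------------------------------
  behavior_tab <- NULL
  if (!is.null(config$behavior) && file.exists(config$behavior)) {
    beh <- read_behavior(config$behavior)
    rows <- list()
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      delta <- attr(tab, "delta")
      hits <- tab$node[tab$q < config$fdr_q & !tab$degenerate]
      for (node in hits) {
        dvec <- delta[, node]
        bsub <- beh[match(rownames(delta), beh$subject_id), , drop = FALSE]
        for (col in setdiff(names(bsub), "subject_id")) {
          if (!is.numeric(bsub[[col]])) next
          res <- tryCatch(
            behavior_correlation(dvec, bsub[[col]],
                                 exclusion_sd = config$exclusion_sd),
            error = function(e) NULL)
          if (is.null(res)) next
          rows[[length(rows) + 1L]] <- data.frame(
            scheme = nm, node = node, behavior = col, r = res$r, p = res$p,
            n_used = res$n_used, stringsAsFactors = FALSE)
        }
      }
    }
    behavior_tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(scheme = character(), node = character(),
                 behavior = character(), r = numeric(), p = numeric(),
                 n_used = integer(), stringsAsFactors = FALSE)
    .write_table(behavior_tab, file.path(out, "behavior_correlations.csv"))
  } else if (!is.null(config$behavior)) {
    warning("behavior file missing; behavior stage skipped")
  }

  # --- specificity bootstrap -----------------------------------------
  boot <- NULL
  if (config$bootstrap_k > 0) {
    glob <- tables$global_degree
    node_idx <- which.max(abs(glob$t))
    observed <- glob$t[node_idx]
    n_sub <- length(ts)
    n_nodes <- length(roiset)
    t_len <- pair$tr_windows$n_tr
    rand <- vapply(seq_len(config$bootstrap_k), function(b) {
      deg <- function() {
        vapply(seq_len(n_sub), function(s) {
          cm <- pearson_correlations(matrix(stats::rnorm(t_len * n_nodes),
                                            t_len))
          colSums(dependency_matrix(cm)$values)[node_idx]
        }, numeric(1))
      }
      .paired_t(deg(), deg())$t
    }, numeric(1))
    boot <- specificity_bootstrap(observed, rand, mode = "tstat",
                                  literal_eq5 = config$literal_eq5)
    jsonlite::write_json(
      c(boot, list(node = glob$node[node_idx])),
      file.path(out, "specificity.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- provenance -----------------------------------------------------
  prov <- unclass(config)
  prov$out_dir <- NULL                    # keep bundles byte-comparable
  jsonlite::write_json(
    list(software = "depna",
         version = as.character(utils::packageVersion("depna")),
         config = prov),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(epochs = pair, tables = tables, graph = graph,
                 behavior = behavior_tab, bootstrap = boot))
}
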