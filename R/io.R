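#' Write a simulated cohort as an on-disk input layout
#'
#' Produces the file layout the pipeline consumes: a subject manifest,
#' per-subject time-series CSVs (the two condition blocks concatenated into
#' one continuous run, low first), the ROI set, long-format ratings, the
#' behavior table and the generating spec as JSON.
#'
#' @param cohort A `depna_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "depna_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  paths <- character(length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    id <- cohort$subjects[s]
    run <- rbind(cohort$ts_low[[id]]$data, cohort$ts_high[[id]]$data)
    paths[s] <- file.path("timeseries", paste0(id, ".csv"))
    utils::write.csv(as.data.frame(run, check.names = FALSE),
                     file.path(dir, paths[s]), row.names = FALSE)
  }
  utils::write.csv(data.frame(subject_id = cohort$subjects, path = paths,
                              stringsAsFactors = FALSE),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  write_roi_set(cohort$roiset, file.path(dir, "roiset.csv"))
  ratings <- do.call(rbind, lapply(cohort$ratings, function(tr)
    data.frame(subject_id = tr$subject_id,
               t_seconds = (seq_along(tr$samples) - 1) / tr$rate_hz,
               value = tr$samples, stringsAsFactors = FALSE)))
  utils::write.csv(ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  spec_json <- spec[setdiff(names(spec), "roiset")]
  jsonlite::write_json(spec_json, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject manifest and its time-series files
#'
#' The manifest CSV has columns `subject_id` and `path` (relative to the
#' manifest's directory or absolute). Each time-series CSV has a header row
#' of ROI labels and one row per volume.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @param roiset An [roi_set]; files must contain exactly its labels, and
#'   columns are reordered to its order.
#' @param tr_seconds Repetition time attached to every subject.
#' @return Named list of [subject_timeseries].
#' @export
read_timeseries_manifest <- function(manifest_path, roiset, tr_seconds) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(man)))
    stop("manifest needs 'subject_id' and 'path' columns")
  base <- dirname(manifest_path)
  out <- lapply(seq_len(nrow(man)), function(s) {
    p <- man$path[s]
    if (!file.exists(p)) p <- file.path(base, man$path[s])
    df <- utils::read.csv(p, check.names = FALSE)
    if (!setequal(names(df), roiset$labels))
      stop("columns of ", p, " do not match the ROI set")
    subject_timeseries(man$subject_id[s],
                       as.matrix(df[, roiset$labels, drop = FALSE]),
                       tr_seconds)
  })
  names(out) <- man$subject_id
  out
}

#' Read long-format rating traces
#'
#' CSV columns: `subject_id`, `t_seconds`, `value`; one row per sample.
#'
#' @param path Ratings CSV path.
#' @param rate_hz,scale_levels Passed to [rating_trace()].
#' @return Named list of [rating_trace].
#' @export
read_ratings <- function(path, rate_hz = 10, scale_levels = 21) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "t_seconds", "value") %in% names(df)))
    stop("ratings file needs subject_id, t_seconds, value columns")
  split_df <- split(df, df$subject_id)
  out <- lapply(split_df, function(d)
    rating_trace(d$subject_id[1L], d$value[order(d$t_seconds)], rate_hz,
                 scale_levels))
  out[order(names(out))]
}

#' Read a behavior table
#'
#' @param path CSV with a `subject_id` column plus numeric behavioral
#'   columns (e.g. `anger_auc`, `trait_anger`, `reappraisal`,
#'   `suppression`); missing values allowed.
#' @return Data frame.
#' @export
read_behavior <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("behavior file needs a 'subject_id' column")
  df
}

#' Write a labelled matrix as CSV with a JSON sidecar
#'
#' The CSV carries row and column label headers; the sidecar (same path with
#' `.json` appended) records the package version plus any metadata supplied.
#'
#' @param m Matrix with dimnames.
#' @param path Output CSV path.
#' @param meta Named list of provenance fields (config, seed, ...).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, meta = list()) {
  df <- data.frame(label = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- c(list(software = "depna",
                    version = as.character(utils::packageVersion("depna"))),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Export a contrast graph for BrainNet Viewer
#'
#' Writes the plain-text `.node` file (columns: x y z color size label,
#' whitespace-separated, no header) and `.edge` file (N x N weighted
#' adjacency of edgewise t-values, zeros where not significant).
#'
#' @param graph An `edge_contrast_graph`.
#' @param roiset An [roi_set]; missing coordinates are written as 0.
#' @param prefix Output path prefix (writes `<prefix>.node`,
#'   `<prefix>.edge`).
#' @return The two paths, invisibly.
#' @export
write_brainnet <- function(graph, roiset, prefix) {
  stopifnot(inherits(graph, "edge_contrast_graph"),
            inherits(roiset, "roi_set"))
  coords <- roiset$coords
  if (is.null(coords))
    coords <- matrix(0, length(roiset), 3L,
                     dimnames = list(roiset$labels, c("x", "y", "z")))
  coords[!is.finite(coords)] <- 0
  labels <- graph$nodes$label
  color <- ifelse(graph$nodes$score >= 0, 1, 2)
  size <- abs(graph$nodes$score)
  node_path <- paste0(prefix, ".node")
  lines <- sprintf("%g\t%g\t%g\t%d\t%g\t%s",
                   coords[labels, "x"], coords[labels, "y"],
                   coords[labels, "z"], color, size,
                   gsub("\\s+", "_", labels))
  writeLines(lines, node_path)
  adj <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  if (nrow(graph$edges))
    for (e in seq_len(nrow(graph$edges)))
      adj[graph$edges$from[e], graph$edges$to[e]] <- graph$edges$t[e]
  edge_path <- paste0(prefix, ".edge")
  writeLines(apply(adj, 1L, function(rr) paste(sprintf("%g", rr),
                                               collapse = "\t")), edge_path)
  invisible(c(node_path, edge_path))
}

#' Export a contrast graph as GraphML
#'
#' Builds a directed [igraph][igraph::graph_from_data_frame] graph (edge
#' attributes `t`, `p`, `direction`; node attribute `score`) and writes it
#' with [igraph::write_graph()].
#'
#' @param graph An `edge_contrast_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_contrast_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "edge_contrast_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                     vertices = graph$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
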