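#' Define an ordered ROI set with sub-network membership
#'
#' An `roi_set` fixes the node order used by every matrix in the package:
#' correlation matrices, dependency matrices and influence profiles all index
#' nodes by position in `labels`. Each ROI carries a sub-network tag (for the
#' shipped default set: `"reactivity"` or `"regulation"`) and, optionally,
#' millimeter coordinates used only for graph export.
#'
#' @param labels Character vector of unique, non-empty ROI labels. Order is
#'   authoritative.
#' @param network Character vector (same length) of sub-network tags.
#' @param coords Optional numeric matrix or data frame with columns x, y, z
#'   (millimeters), one row per label. `NA` allowed.
#' @return An object of class `roi_set` with elements `labels`, `network`
#'   (named by label) and `coords` (named matrix or `NULL`).
#' @examples
#' rs <- roi_set(c("A", "B", "C"), c("reactivity", "reactivity", "regulation"))
#' network_members(rs, "reactivity")
#' @export
roi_set <- function(labels, network, coords = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L || anyNA(labels) || any(!nzchar(labels)))
    stop("ROI labels must be non-empty strings")
  if (anyDuplicated(labels))
    stop("ROI labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  network <- as.character(network)
  if (length(network) != length(labels) || anyNA(network) || any(!nzchar(network)))
    stop("every ROI needs a network tag")
  names(network) <- labels
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(labels) || ncol(coords) != 3L)
      stop("coords must have one (x, y, z) row per label")
    storage.mode(coords) <- "double"
    dimnames(coords) <- list(labels, c("x", "y", "z"))
  }
  structure(list(labels = labels, network = network, coords = coords),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", length(x$labels), "ROIs,",
      length(unique(x$network)), "sub-networks\n")
  for (net in unique(x$network))
    cat("  ", net, ": ",
        paste(x$labels[x$network == net], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$labels)

#' Labels belonging to one sub-network
#'
#' @param roiset An [roi_set].
#' @param net A network tag present in `roiset`.
#' @return Character vector of member labels, in `roiset` order.
#' @export
network_members <- function(roiset, net) {
  stopifnot(inherits(roiset, "roi_set"))
  if (!net %in% roiset$network)
    stop("unknown network tag: ", net)
  roiset$labels[roiset$network == net]
}

#' The default 14-ROI reactivity/regulation set
#'
#' Six limbic-salience "reactivity" regions (bilateral amygdala and mid-insula,
#' periaqueductal gray, dorsal anterior cingulate) and eight prefrontal-
#' parietal "regulation" regions (bilateral inferior and middle frontal gyri,
#' bilateral superior parietal lobule, pre-SMA and ventromedial prefrontal
#' cortex). Coordinates are left `NA`; supply your own for spatial export.
#'
#' @return An [roi_set] with 14 labels.
#' @export
default_roi_set <- function() {
  labels <- c("L Amy", "R Amy", "L midIns", "R midIns", "PAG", "dACC",
              "L IFG", "R IFG", "L MiFG", "R MiFG", "L SPL", "R SPL",
              "preSMA", "vmPFC")
  network <- c(rep("reactivity", 6L), rep("regulation", 8L))
  coords <- matrix(NA_real_, nrow = 14L, ncol = 3L)
  roi_set(labels, network, coords)
}

#' Read / write an ROI set as CSV
#'
#' The CSV has columns `label`, `network` and optionally `x`, `y`, `z`
#' (millimeters). Row order in the file defines node order.
#'
#' @param path File path.
#' @return `read_roi_set` returns an [roi_set]; `write_roi_set` returns
#'   `path` invisibly.
#' @export
read_roi_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("label", "network") %in% names(df)))
    stop("ROI set file needs 'label' and 'network' columns: ", path)
  coords <- NULL
  if (all(c("x", "y", "z") %in% names(df)))
    coords <- as.matrix(df[, c("x", "y", "z")])
  roi_set(df$label, df$network, coords)
}

#' @rdname read_roi_set
#' @param roiset An [roi_set] to write.
#' @export
write_roi_set <- function(roiset, path) {
  stopifnot(inherits(roiset, "roi_set"))
  df <- data.frame(label = roiset$labels,
                   network = unname(roiset$network),
                   stringsAsFactors = FALSE)
  if (!is.null(roiset$coords)) {
    df$x <- roiset$coords[, "x"]
    df$y <- roiset$coords[, "y"]
    df$z <- roiset$coords[, "z"]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
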