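#' Read a channel layout table
#'
#' A layout table is a whitespace/tab-delimited text file with columns
#' `name`, `role` (`scalp` or `eog`) and head-frame coordinates `x`, `y`, `z`
#' in meters. The package ships a 66-channel extended 10-20 layout
#' (64 scalp channels plus HEOG/VEOG) as its default.
#'
#' @param path Path to a layout file. Defaults to the layout shipped with the
#'   package.
#' @param adjacency_factor Electrodes closer than `adjacency_factor` times the
#'   median nearest-neighbour distance (scalp channels only) are considered
#'   neighbours for spatial-extent statistics.
#' @return An object of class `eeg_layout`: a data frame with one row per
#'   channel and an `adjacency` attribute holding a symmetric, irreflexive
#'   logical matrix over the scalp channels.
#' @examples
#' lay <- read_layout()
#' sum(lay$role == "scalp")
#' @export
read_layout <- function(path = system.file("extdata", "layout_1020_66.tsv",
                                           package = "icerp"),
                        adjacency_factor = 1.3) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "role", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("layout file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate channel name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  bad <- !tab$role %in% c("scalp", "eog")
  if (any(bad))
    stop("unknown role in layout row(s) ", paste(which(bad), collapse = ", "),
         " (expected 'scalp' or 'eog')")
  if (!all(vapply(tab[c("x", "y", "z")], is.numeric, logical(1))))
    stop("layout coordinates must be numeric")
  as_eeg_layout(tab, adjacency_factor = adjacency_factor)
}

#' Construct a layout object from a data frame
#'
#' @param tab Data frame with columns `name`, `role`, `x`, `y`, `z`.
#' @inheritParams read_layout
#' @return An `eeg_layout` object.
#' @export
as_eeg_layout <- function(tab, adjacency_factor = 1.3) {
  rownames(tab) <- NULL
  attr(tab, "adjacency") <- layout_adjacency(tab, adjacency_factor)
  attr(tab, "adjacency_factor") <- adjacency_factor
  class(tab) <- c("eeg_layout", "data.frame")
  tab
}

#' Scalp-electrode adjacency matrix
#'
#' Two scalp electrodes are adjacent when their Euclidean distance is at most
#' `factor` times the median nearest-neighbour distance of the montage. This
#' parameter-light rule reproduces the intuitive neighbourhoods of 10-20
#' montages and is configurable for sparser or denser caps.
#'
#' @param layout Data frame with `name`, `role`, `x`, `y`, `z`.
#' @param factor Multiplier on the median nearest-neighbour distance.
#' @return Symmetric irreflexive logical matrix (scalp channels only).
#' @export
layout_adjacency <- function(layout, factor = 1.3) {
  sc <- layout[layout$role == "scalp", , drop = FALSE]
  if (nrow(sc) < 2) {
    m <- matrix(FALSE, nrow(sc), nrow(sc),
                dimnames = list(sc$name, sc$name))
    return(m)
  }
  d <- as.matrix(stats::dist(sc[, c("x", "y", "z")]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- factor * stats::median(nn)
  adj <- d <= thr
  diag(adj) <- FALSE
  dimnames(adj) <- list(sc$name, sc$name)
  # enforce symmetry defensively (dist is symmetric, numeric ties aside)
  adj | t(adj)
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf("<eeg_layout> %d channels (%d scalp, %d eog)\n",
              nrow(x), sum(x$role == "scalp"), sum(x$role == "eog")))
  adj <- attr(x, "adjacency")
  if (!is.null(adj))
    cat(sprintf("  adjacency: %d edges, factor %.2f x median NN distance\n",
                sum(adj) / 2, attr(x, "adjacency_factor")))
  invisible(x)
}

#' Restrict a layout to a subset of channels
#'
#' Useful for reduced montages in simulation studies; the adjacency graph is
#' recomputed on the subset.
#'
#' @param layout An `eeg_layout`.
#' @param channels Character vector of channel names to keep.
#' @return An `eeg_layout` restricted to `channels` (in the given order).
#' @export
layout_subset <- function(layout, channels) {
  miss <- setdiff(channels, layout$name)
  if (length(miss))
    stop("channel(s) not in layout: ", paste(miss, collapse = ", "))
  tab <- as.data.frame(layout)[match(channels, layout$name), , drop = FALSE]
  as_eeg_layout(tab, adjacency_factor = attr(layout, "adjacency_factor") %||% 1.3)
}

#' Connected components of a significant-electrode set
#'
#' Breadth-first components of the induced subgraph of the adjacency matrix.
#' Isolated significant electrodes form singleton components.
#'
#' @param adjacency Logical adjacency matrix with dimnames.
#' @param members Character vector of electrode names (subset of rownames).
#' @return List of character vectors, one per connected component.
#' @keywords internal
adjacency_components <- function(adjacency, members) {
  members <- intersect(members, rownames(adjacency))
  comps <- list()
  seen <- character(0)
  for (m in members) {
    if (m %in% seen) next
    queue <- m
    comp <- character(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      nb <- rownames(adjacency)[adjacency[v, ]]
      queue <- c(queue, setdiff(intersect(nb, members), comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
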