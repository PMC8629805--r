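#' Observation matrix with an element map
#'
#' A `T x D` matrix of time samples of the system's microscopic variables,
#' together with a map describing which columns belong to which element
#' (individual). Element `i` owns `k_i` ordered columns (e.g. the two
#' velocity components of one fish); every column belongs to exactly one
#' element.
#'
#' @param values numeric matrix, `T` rows (samples) by `D` columns (variates).
#' @param element_map list mapping element index to an integer vector of
#'   column indices; defaults to one scalar element per column.
#' @param units optional character string recording the measurement units.
#' @return object of class `observation_matrix`.
#' @export
observation_matrix <- function(values, element_map = NULL, units = "arbitrary") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (nrow(values) < 2) stop("need at least T = 2 samples")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("observation matrix contains missing or non-finite values")
  }
  D <- ncol(values)
  if (is.null(element_map)) element_map <- as.list(seq_len(D))
  element_map <- lapply(element_map, as.integer)
  cols <- unlist(element_map)
  if (length(cols) != D || !setequal(cols, seq_len(D)) || anyDuplicated(cols)) {
    stop("element_map must assign every column to exactly one element")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("v", seq_len(D))
  }
  structure(
    list(values = values, element_map = element_map, units = units,
         n = length(element_map), D = D, T = nrow(values)),
    class = "observation_matrix"
  )
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat("Observation matrix:", x$T, "samples x", x$D, "variates,",
      x$n, "elements\n")
  invisible(x)
}

#' Build an element map with a fixed number of variates per element
#'
#' @param n number of elements.
#' @param k variates per element (e.g. 2 for planar velocities).
#' @return list of column-index vectors.
#' @export
element_map_blocks <- function(n, k = 1L) {
  lapply(seq_len(n), function(i) ((i - 1L) * k + 1L):(i * k))
}

#' Rank-Gaussianize the columns of an observation matrix
#'
#' Replaces each column by the standard-normal quantiles of its mid-ranks,
#' `qnorm((rank - 1/2) / T)` with average ranks for ties. The result is
#' invariant under any strictly increasing per-column transform of the input,
#' which makes the Gaussian mutual-information term computed from it a valid
#' lower bound on the total correlation of arbitrary continuous marginals.
#'
#' @param obs an [observation_matrix()] (a bare matrix is accepted).
#' @return an `observation_matrix` of the same shape with Gaussianized
#'   columns.
#' @export
rank_gaussianize <- function(obs) {
  if (!inherits(obs, "observation_matrix")) obs <- observation_matrix(obs)
  v <- obs$values
  Tn <- nrow(v)
  const <- which(apply(v, 2, function(x) max(x) - min(x) == 0))
  if (length(const) > 0) {
    stop("constant column(s): ", paste(colnames(v)[const], collapse = ", "),
         " (rank transform undefined)")
  }
  g <- apply(v, 2, function(x) {
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / Tn)
  })
  colnames(g) <- colnames(v)
  out <- observation_matrix(g, obs$element_map, units = "gaussianized")
  attr(out, "rank_gaussianized") <- TRUE
  out
}

#' Write / read an observation matrix as CSV plus a JSON sidecar
#'
#' The values go to `path` as a plain CSV; the element map and units go to
#' `paste0(path, ".json")`.
#'
#' @param obs an [observation_matrix()].
#' @param path CSV file path.
#' @return `write_observation` returns `path` invisibly; `read_observation`
#'   returns the reconstructed `observation_matrix`.
#' @export
write_observation <- function(obs, path) {
  stopifnot(inherits(obs, "observation_matrix"))
  utils::write.csv(as.data.frame(obs$values), path, row.names = FALSE)
  sidecar <- list(element_map = obs$element_map, units = obs$units,
                  columns = colnames(obs$values))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observation
#' @export
read_observation <- function(path) {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  em <- sidecar$element_map
  if (is.matrix(em)) em <- lapply(seq_len(nrow(em)), function(i) em[i, ])
  observation_matrix(values, lapply(em, as.integer), units = sidecar$units)
}
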