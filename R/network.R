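#' Construct a symptom network
#'
#' A symptom network is the static object the simulator and the estimator
#' share: a symmetric matrix of pairwise connection weights \code{w_ij}
#' (zero diagonal, no self-loops) and a per-symptom threshold \code{tau_i}
#' describing each symptom's disposition to be 'on' (positive) or 'off'
#' (negative).
#'
#' @param weights numeric J x J matrix; must be symmetric with an exactly
#'   zero diagonal. A nonzero diagonal is an error, never silently zeroed.
#' @param thresholds numeric vector of length J.
#' @param labels optional character vector of length J; defaults to the
#'   dimnames of \code{weights} or \code{S1..SJ}.
#' @return an object of class \code{symptom_network} with elements
#'   \code{weights}, \code{thresholds}, \code{labels}, \code{J}.
#' @examples
#' W <- matrix(c(0, 1.2, 1.2, 0), 2, 2)
#' net <- symptom_network(W, thresholds = c(-1, -2))
#' net$J
#' @export
symptom_network <- function(weights, thresholds, labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  J <- nrow(weights)
  if (ncol(weights) != J)
    stop(sprintf("`weights` must be square, got %d x %d", J, ncol(weights)),
         call. = FALSE)
  if (J < 2)
    stop("a symptom network needs at least 2 nodes", call. = FALSE)
  if (anyNA(weights) || anyNA(thresholds))
    stop("weights and thresholds must not contain NA", call. = FALSE)
  if (!isSymmetric(unname(weights), tol = 1e-10))
    stop("`weights` must be symmetric (w_ij = w_ji)", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("diagonal of `weights` must be exactly zero (no self-loops); ",
         "offending nodes: ",
         paste(which(diag(weights) != 0), collapse = ", "), call. = FALSE)
  if (length(thresholds) != J)
    stop(sprintf("`thresholds` has length %d, expected %d",
                 length(thresholds), J), call. = FALSE)
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("S", seq_len(J))
  if (length(labels) != J)
    stop(sprintf("`labels` has length %d, expected %d", length(labels), J),
         call. = FALSE)
  weights <- unname(weights)
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, thresholds = as.numeric(thresholds),
         labels = as.character(labels), J = J),
    class = "symptom_network"
  )
}

#' @export
print.symptom_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Symptom network: %d nodes, %d nonzero edges\n", x$J, nz))
  cat("  thresholds: ",
      paste(sprintf("%.2f", utils::head(x$thresholds, 8)), collapse = " "),
      if (x$J > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of free parameters of a fully parameterised network
#'
#' A network on J nodes has J thresholds and choose(J, 2) pairwise weights
#' (the symmetric zero-diagonal matrix has one free entry per unordered
#' pair). For the canonical 14-symptom system this is 14 + 91.
#'
#' @param net a \code{symptom_network}, or an integer node count.
#' @return named list with \code{n_thresholds}, \code{n_weights},
#'   \code{n_total}.
#' @export
network_parameter_count <- function(net) {
  J <- if (inherits(net, "symptom_network")) net$J else as.integer(net)
  if (is.na(J) || J < 2) stop("need a network or a node count >= 2",
                              call. = FALSE)
  list(n_thresholds = J, n_weights = (J * (J - 1L)) %/% 2L,
       n_total = J + (J * (J - 1L)) %/% 2L)
}

#' Write a symptom network to JSON
#'
#' The JSON layout has keys \code{labels}, \code{weights} (row-major list
#' of rows) and \code{thresholds}, and round-trips through
#' \code{\link{read_network_json}}.
#'
#' @param net a \code{symptom_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "symptom_network"))
  obj <- list(labels = net$labels,
              weights = unname(lapply(seq_len(net$J),
                                      function(i) net$weights[i, ])),
              thresholds = net$thresholds)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a symptom network from JSON
#'
#' @param path file written by \code{\link{write_network_json}} (keys
#'   \code{labels}, \code{weights}, \code{thresholds}).
#' @return a \code{symptom_network}.
#' @export
read_network_json <- function(path) {
  if (!file.exists(path))
    stop("network file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("labels", "weights", "thresholds"))
    if (is.null(obj[[k]]))
      stop("network JSON is missing key '", k, "': ", path, call. = FALSE)
  W <- obj$weights
  if (is.list(W)) W <- do.call(rbind, W)
  symptom_network(as.matrix(W), obj$thresholds, obj$labels)
}

#' Write a network as edge-list and threshold CSV files
#'
#' Interoperability format: an edge list (\code{source,target,weight}; one
#' row per unordered pair with nonzero weight) plus a threshold table
#' (\code{label,threshold}).
#'
#' @param net a \code{symptom_network}.
#' @param edges_path,thresholds_path output CSV paths.
#' @return invisibly, a list with both paths.
#' @export
write_network_csv <- function(net, edges_path, thresholds_path) {
  stopifnot(inherits(net, "symptom_network"))
  idx <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(source = net$labels[idx[, 1]],
                      target = net$labels[idx[, 2]],
                      weight = net$weights[idx])
  utils::write.csv(edges, edges_path, row.names = FALSE)
  utils::write.csv(data.frame(label = net$labels,
                              threshold = net$thresholds),
                   thresholds_path, row.names = FALSE)
  invisible(list(edges = edges_path, thresholds = thresholds_path))
}

#' Read a network from edge-list and threshold CSV files
#'
#' @param edges_path CSV with columns \code{source,target,weight}.
#' @param thresholds_path CSV with columns \code{label,threshold}; its
#'   label order defines the node order.
#' @return a \code{symptom_network}.
#' @export
read_network_csv <- function(edges_path, thresholds_path) {
  for (p in c(edges_path, thresholds_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  thr <- utils::read.csv(thresholds_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  labels <- as.character(thr$label)
  J <- length(labels)
  W <- matrix(0, J, J, dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    bad <- setdiff(c(edges$source, edges$target), labels)
    if (length(bad))
      stop("edge endpoints not in threshold table: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    for (r in seq_len(nrow(edges))) {
      i <- match(edges$source[r], labels)
      j <- match(edges$target[r], labels)
      if (i == j)
        stop("self-loop in edge list at row ", r, call. = FALSE)
      W[i, j] <- W[j, i] <- edges$weight[r]
    }
  }
  symptom_network(W, thr$threshold, labels)
}
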