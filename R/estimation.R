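#' Estimation configuration
#'
#' Settings for nodewise network estimation from binary data. Each
#' symptom is regressed on all others with an L1 penalty; the penalty
#' level is chosen per node by the extended Bayesian Information
#' Criterion \eqn{EBIC = -2\,\ell + k \log N + 2 \gamma k \log(J - 1)},
#' where k counts nonzero coefficients. Directed coefficient pairs are
#' then symmetrised into undirected edge weights.
#'
#' @param ebic_gamma non-negative EBIC hyperparameter (default 0.25, the
#'   conventional default for binary network estimation).
#' @param symmetrization \code{"AND"} (default: edge kept only when both
#'   directed coefficients are nonzero; weight is their mean) or
#'   \code{"OR"} (kept when either is nonzero; weight is the mean of the
#'   nonzero values).
#' @param lambda_grid optional descending vector of positive penalty
#'   values shared by all nodes; by default a per-node grid of
#'   \code{n_lambda} log-spaced values from the node's lambda_max down to
#'   \code{lambda_min_ratio * lambda_max} is generated from the data.
#' @param n_lambda,lambda_min_ratio grid-generation controls (defaults
#'   100 and 0.001).
#' @return an \code{estimation_config}.
#' @export
estimation_config <- function(ebic_gamma = 0.25,
                              symmetrization = c("AND", "OR"),
                              lambda_grid = NULL, n_lambda = 100,
                              lambda_min_ratio = 0.001) {
  if (!is.numeric(ebic_gamma) || ebic_gamma < 0)
    stop("`ebic_gamma` must be >= 0", call. = FALSE)
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid)))
      stop("`lambda_grid` must be positive and descending", call. = FALSE)
  }
  structure(list(ebic_gamma = ebic_gamma,
                 symmetrization = match.arg(symmetrization),
                 lambda_grid = lambda_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio),
            class = "estimation_config")
}

#' Validate a binary respondents-by-symptoms dataset
#'
#' @param data numeric matrix or data frame of 0/1 values, rows =
#'   respondents, columns = symptoms.
#' @param allow_constant keep constant columns instead of erroring
#'   (default FALSE).
#' @return a \code{binary_dataset}: the integer matrix with column
#'   labels, class-tagged.
#' @export
binary_dataset <- function(data, allow_constant = FALSE) {
  m <- as.matrix(data)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    rc <- arrayInd(bad, dim(m))
    stop(sprintf("non-binary value %s at row %d, column %d",
                 format(m[bad]), rc[1], rc[2]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  v <- apply(m, 2, function(col) length(unique(col)) > 1)
  if (!allow_constant && any(!v))
    stop("constant column(s): ", paste(colnames(m)[!v], collapse = ", "),
         "; pass allow_constant = TRUE to keep them", call. = FALSE)
  structure(m, class = c("binary_dataset", "matrix", "array"))
}

#' Read a binary dataset from delimited text
#'
#' @param path CSV or TSV file with a header row of symptom labels and
#'   0/1 cells; the delimiter is inferred from the extension (tsv/txt ->
#'   tab, otherwise comma).
#' @param ... passed to \code{\link{binary_dataset}}.
#' @return a \code{binary_dataset}.
#' @export
read_binary_dataset <- function(path, ...) {
  if (!file.exists(path)) stop("dataset not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  binary_dataset(df, ...)
}

#' Write a binary dataset to CSV
#' @param dataset a \code{binary_dataset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_binary_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(unclass(dataset)), path,
                   row.names = FALSE)
  invisible(path)
}

# Bernoulli log-likelihood of a fitted linear predictor, clamped away
# from 0/1 so separation yields a finite (if extreme) value.
logistic_loglik <- function(y, eta) {
  p <- stats::plogis(eta)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit one node's penalized logistic neighbourhood regression
#'
#' Regresses column \code{node} on all other columns with an L1 penalty
#' over a descending lambda grid (intercept never penalised) and returns
#' the fit minimising the EBIC, with ties broken toward the larger
#' lambda (the sparser model).
#'
#' @param dataset a \code{binary_dataset}.
#' @param node column index or label of the response symptom.
#' @param config an \code{\link{estimation_config}}.
#' @return list with \code{intercept}, \code{coefficients} (named,
#'   length J-1), \code{lambda}, \code{ebic}, \code{ebic_path},
#'   \code{lambda_grid}, \code{df_path}.
#' @export
fit_node <- function(dataset, node, config = estimation_config()) {
  stopifnot(inherits(dataset, "binary_dataset"))
  m <- unclass(dataset)
  J <- ncol(m)
  N <- nrow(m)
  if (N < 10 * J)
    stop(sprintf("N = %d is below the minimum 10 * J = %d", N, 10 * J),
         call. = FALSE)
  if (is.character(node)) node <- match(node, colnames(m))
  if (is.na(node) || node < 1 || node > J)
    stop("`node` does not identify a column", call. = FALSE)
  y <- m[, node]
  if (length(unique(y)) < 2)
    stop("response column '", colnames(m)[node], "' is constant",
         call. = FALSE)
  x <- m[, -node, drop = FALSE]
  # When no grid is supplied, let glmnet build its own log-spaced path
  # from the data's lambda_max (smallest penalty with an all-zero
  # solution) down to lambda_min_ratio * lambda_max: the solver
  # guarantees the null model heads that path, which a user-supplied
  # copy of the same grid does not.
  fit <- if (is.null(config$lambda_grid)) {
    glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                   nlambda = config$n_lambda,
                   lambda.min.ratio = config$lambda_min_ratio,
                   standardize = FALSE)
  } else {
    glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                   lambda = config$lambda_grid, standardize = FALSE)
  }
  lam <- fit$lambda
  beta <- as.matrix(fit$beta)
  a0 <- fit$a0
  k <- colSums(beta != 0)
  eta <- cbind(1, x) %*% rbind(a0, beta)
  ll <- vapply(seq_along(lam),
               function(i) logistic_loglik(y, eta[, i]), numeric(1))
  ebic <- -2 * ll + k * log(N) + 2 * config$ebic_gamma * k * log(J - 1)
  best <- which(ebic <= min(ebic) + 1e-9)[1]  # ties -> larger lambda
  coefs <- beta[, best]
  names(coefs) <- colnames(m)[-node]
  list(intercept = unname(a0[best]), coefficients = coefs,
       lambda = lam[best], ebic = unname(ebic[best]),
       ebic_path = unname(ebic), lambda_grid = lam,
       df_path = unname(as.integer(k)))
}

#' Estimate a symptom network from binary cross-sectional data
#'
#' Runs \code{\link{fit_node}} for every symptom, takes each node's
#' selected intercept as its threshold tau, and symmetrises the directed
#' coefficient pairs into an undirected weight matrix under the
#' configured AND/OR rule. The result always satisfies the
#' \code{symptom_network} invariants (symmetry, zero diagonal).
#'
#' @param dataset a \code{binary_dataset}.
#' @param config an \code{\link{estimation_config}}.
#' @return a \code{symptom_network} with attribute \code{fits} holding
#'   the per-node selection details.
#' @examples
#' net0 <- random_network(generator_spec(J = 5, N = 600, seed = 7))
#' dat <- sample_ising_exact(net0, N = 600, seed = 8)
#' est <- estimate_network(dat)
#' est$J
#' @export
estimate_network <- function(dataset, config = estimation_config()) {
  stopifnot(inherits(dataset, "binary_dataset"))
  m <- unclass(dataset)
  J <- ncol(m)
  labels <- colnames(m)
  fits <- vector("list", J)
  for (j in seq_len(J)) {
    fits[[j]] <- tryCatch(fit_node(dataset, j, config),
                          error = function(e)
                            stop("node '", labels[j], "': ",
                                 conditionMessage(e), call. = FALSE))
  }
  B <- matrix(0, J, J, dimnames = list(labels, labels))
  for (j in seq_len(J)) B[j, -j] <- fits[[j]]$coefficients
  W <- matrix(0, J, J, dimnames = list(labels, labels))
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    bij <- B[i, j]; bji <- B[j, i]
    w <- if (config$symmetrization == "AND") {
      if (bij != 0 && bji != 0) mean(c(bij, bji)) else 0
    } else {
      nz <- c(bij, bji)[c(bij, bji) != 0]
      if (length(nz)) mean(nz) else 0
    }
    W[i, j] <- W[j, i] <- w
  }
  tau <- vapply(fits, `[[`, numeric(1), "intercept")
  net <- symptom_network(W, tau, labels)
  attr(net, "fits") <- fits
  net
}
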