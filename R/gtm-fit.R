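# Generative Topographic Mapping: a constrained Gaussian mixture whose K
# component centres are the images y_l = W phi(u_l) of a regular latent
# lattice under an RBF-parameterised smooth map. Fitting is by (penalised)
# expectation-maximisation; beta is the shared PRECISION (inverse variance)
# of the spherical components.

new_gtm <- function(grid, basis, W, beta, lambda, seed, var_names = NULL,
                    scaler = NULL, trace = NULL, init = NA_character_) {
  structure(list(grid = grid, basis = basis, W = W, beta = beta,
                 lambda = lambda, seed = seed, var_names = var_names,
                 scaler = scaler, trace = trace, init = init),
            class = "gtm")
}

#' @export
print.gtm <- function(x, ...) {
  cat(sprintf("<gtm> %dx%d latent grid (K=%d), %d RBFs, D=%d, lambda=%g, beta=%.4g\n",
              x$grid$side, x$grid$side, x$grid$K, x$basis$M,
              nrow(x$W), x$lambda, x$beta))
  if (!is.null(x$trace)) {
    cat(sprintf("  EM: %d iterations, converged=%s, objective=%.6g\n",
                x$trace$iterations, x$trace$converged,
                utils::tail(x$trace$objective, 1)))
  }
  invisible(x)
}

as_data_matrix <- function(data) {
  if (inherits(data, "cohort_table")) {
    data <- modelling_matrix(data)
  }
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  data
}

#' Initialise a GTM model
#'
#' `method = "pca"` (the default) solves the least-squares problem mapping
#' the basis activations onto the plane of the first two principal
#' components, with latent coordinates scaled to the spread of the PC
#' scores; the initial noise variance is the larger of the third principal
#' eigenvalue and half the mean squared distance between lattice-adjacent
#' initial reference vectors. `method = "random"` draws the weights from a
#' seeded normal scaled by 0.1 and sets `beta = 1`.
#'
#' @param data complete numeric matrix (subjects x variables) or
#'   [cohort_table()].
#' @param grid a [build_latent_grid()] object.
#' @param basis a [build_rbf_basis()] object.
#' @param method `"pca"` or `"random"`.
#' @param seed integer seed (used by `"random"`; recorded either way).
#' @param lambda nonnegative weight-decay regularisation carried by the model.
#' @return A `gtm` model object (unfitted).
#' @export
gtm_init <- function(data, grid, basis, method = c("pca", "random"),
                     seed = 0L, lambda = 1.0) {
  method <- match.arg(method)
  x <- as_data_matrix(data)
  if (anyNA(x) || any(!is.finite(x))) stop("data must be complete and finite")
  n <- nrow(x)
  d <- ncol(x)
  phi <- basis$Phi
  if (method == "pca") {
    if (d < 2L) stop("pca initialisation needs D >= 2")
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    sv <- svd(xc, nu = 0L, nv = min(3L, d))
    eig <- sv$d^2 / (n - 1L)
    if (length(sv$d) < 2L || sv$d[2] <= sv$d[1] * 1e-10) {
      stop("data is effectively rank 1; use method = \"random\"")
    }
    scores_sd <- sv$d[1:2] / sqrt(n - 1L)
    # target reference vectors: lattice placed on the PC1/PC2 plane
    target <- outer(rep(1, grid$K), mu) +
      grid$nodes[, 1] %o% (sv$v[, 1] * scores_sd[1]) +
      grid$nodes[, 2] %o% (sv$v[, 2] * scores_sd[2])
    gram <- crossprod(phi) + 1e-8 * diag(ncol(phi))
    wt <- solve(gram, crossprod(phi, target))
    w <- t(wt)
    y <- phi %*% wt
    lambda3 <- if (length(eig) >= 3L) eig[3] else 0
    beta_inv <- max(lambda3, half_mean_neighbour_sq(grid, y), 1e-8)
    beta <- 1 / beta_inv
  } else {
    set.seed(seed)
    w <- matrix(stats::rnorm(d * ncol(phi)) * 0.1, nrow = d)
    beta <- 1
  }
  new_gtm(grid, basis, w, beta, lambda, as.integer(seed),
          var_names = colnames(x), init = method)
}

# Half the mean squared distance between lattice-adjacent reference vectors.
half_mean_neighbour_sq <- function(grid, y) {
  if (grid$K < 2L) return(0)
  side <- grid$side
  idx <- function(r, c) (r - 1L) * side + c
  tot <- 0
  cnt <- 0L
  for (r in seq_len(side)) {
    for (c in seq_len(side)) {
      if (c < side) {
        tot <- tot + sum((y[idx(r, c), ] - y[idx(r, c + 1L), ])^2)
        cnt <- cnt + 1L
      }
      if (r < side) {
        tot <- tot + sum((y[idx(r, c), ] - y[idx(r + 1L, c), ])^2)
        cnt <- cnt + 1L
      }
    }
  }
  tot / cnt / 2
}

#' E-step: responsibilities and log-likelihood
#'
#' Computes the posterior probability that each latent node generated each
#' subject, `R[n, l]` proportional to `exp(-beta/2 * ||x_n - y_l||^2)` with
#' rows normalised, and the mixture log-likelihood
#' `sum_n log[(1/K) sum_l (beta/2pi)^(D/2) exp(-beta/2 ||x_n - y_l||^2)]`,
#' evaluated with log-sum-exp stabilisation.
#'
#' @param model a `gtm` model.
#' @param data complete numeric matrix or [cohort_table()].
#' @return `list(R = N x K responsibility matrix, log_likelihood = scalar)`.
#' @export
gtm_e_step <- function(model, data) {
  x <- as_data_matrix(data)
  if (anyNA(x) || any(!is.finite(x))) stop("data must be complete and finite")
  y <- model$basis$Phi %*% t(model$W)
  d2 <- squared_distances(x, y)
  a <- -(model$beta / 2) * d2
  lse <- logsumexp_rows(a)
  r <- exp(a - lse)
  n <- nrow(x)
  d <- ncol(x)
  ll <- sum(lse) +
    n * ((d / 2) * log(model$beta / (2 * pi)) - log(model$grid$K))
  list(R = r, log_likelihood = ll)
}

#' M-step: update weights and noise precision
#'
#' Solves the regularised weighted least-squares normal equations
#' `(Phi' G Phi + (lambda/beta) I) W' = Phi' R' X` with `G` the diagonal of
#' responsibility column sums, then re-estimates the noise variance
#' `1/beta = (1/(N D)) sum_{n,l} R[n,l] ||x_n - W phi(u_l)||^2` (floored at
#' 1e-8 to keep degenerate fits finite).
#'
#' @param model a `gtm` model.
#' @param data complete numeric matrix or [cohort_table()].
#' @param resp responsibility matrix from [gtm_e_step()].
#' @return The updated `gtm` model.
#' @export
gtm_m_step <- function(model, data, resp) {
  x <- as_data_matrix(data)
  phi <- model$basis$Phi
  g <- colSums(resp)
  lhs <- crossprod(phi, phi * g)
  if (model$lambda > 0) {
    lhs <- lhs + (model$lambda / model$beta) * diag(ncol(phi))
  }
  rhs <- crossprod(phi, crossprod(resp, x))
  wt <- tryCatch(solve(lhs, rhs), error = function(e) {
    stop("singular M-step normal equations; use lambda > 0 for a ",
         "regularised solution (", conditionMessage(e), ")")
  })
  y <- phi %*% wt
  d2 <- squared_distances(x, y)
  beta_inv <- max(sum(resp * d2) / (nrow(x) * ncol(x)), 1e-8)
  model$W <- t(wt)
  model$beta <- 1 / beta_inv
  model
}

gtm_penalised_objective <- function(model, ll) {
  ll - (model$lambda / 2) * sum(model$W^2)
}

#' Fit a GTM by expectation-maximisation
#'
#' Alternates [gtm_e_step()] and [gtm_m_step()] until the relative change in
#' the penalised objective (log-likelihood minus `lambda/2 * ||W||^2`) drops
#' below `tol` or `max_iter` is reached. The default configuration - a
#' 15 x 15 latent grid, 196 RBFs on a 14 x 14 grid and `lambda = 1` - is the
#' reference setting used for cohort phenotyping.
#'
#' @param data complete, standardized numeric matrix or [cohort_table()].
#' @param side latent lattice side (default 15; `side = 1` fits the
#'   single-Gaussian limit).
#' @param rbf_side RBF lattice side (default 14; `rbf_side = 0` uses a
#'   bias-only constant map).
#' @param lambda nonnegative weight-decay regularisation (default 1).
#' @param width_factor RBF width as a multiple of centre spacing (default 1).
#' @param seed integer seed (drives random initialisation; recorded always).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param init `"pca"` (default) or `"random"`.
#' @param scaler optional standardisation parameters to carry with the model.
#' @return A fitted `gtm` model; `model$trace` holds the objective per
#'   iteration, `converged`, `iterations` and `seed`. Non-convergence is
#'   reported in the trace, not raised as an error.
#' @export
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' m <- gtm_fit(x, side = 4, rbf_side = 2, seed = 1)
#' all(diff(m$trace$objective) > -1e-8)
gtm_fit <- function(data, side = 15L, rbf_side = 14L, lambda = 1.0,
                    width_factor = 1.0, seed = 0L, max_iter = 200L,
                    tol = 1e-6, init = c("pca", "random"), scaler = NULL) {
  init <- match.arg(init)
  x <- as_data_matrix(data)
  if (anyNA(x) || any(!is.finite(x))) stop("data must be complete and finite")
  if (lambda < 0) stop("lambda must be nonnegative")
  grid <- if (side >= 2L) build_latent_grid(side) else single_node_grid()
  basis <- if (rbf_side >= 1L) {
    build_rbf_basis(grid, rbf_side, width_factor)
  } else {
    bias_basis(grid)
  }
  if (init == "pca" && ncol(x) < 2L) init <- "random"
  model <- gtm_init(x, grid, basis, init, seed, lambda)
  es <- gtm_e_step(model, x)
  obj <- gtm_penalised_objective(model, es$log_likelihood)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    model <- gtm_m_step(model, x, es$R)
    es <- gtm_e_step(model, x)
    new_obj <- gtm_penalised_objective(model, es$log_likelihood)
    trace <- c(trace, new_obj)
    if (abs(new_obj - obj) < tol * (abs(obj) + tol)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  model$var_names <- colnames(x)
  model$scaler <- scaler
  model$trace <- list(objective = trace, converged = converged,
                      iterations = iter, seed = as.integer(seed))
  model
}

#' Reference vectors of a fitted model
#'
#' Row `l` of the returned matrix is `y_l = W phi(u_l)`, the data-space image
#' of latent node `l`: the prototype ("reference vector") of micro-cluster
#' `l`, a composite representation of the subjects it attracts.
#'
#' @param model a `gtm` model.
#' @return K x D numeric matrix `Y = Phi W'` with variable names as columns.
#' @export
reference_vectors <- function(model) {
  y <- model$basis$Phi %*% t(model$W)
  colnames(y) <- model$var_names
  y
}

#' Hard micro-cluster assignment
#'
#' Assigns each subject to the latent node with the highest responsibility;
#' exact ties go to the lowest node index.
#'
#' @param model a fitted `gtm` model.
#' @param data complete numeric matrix or [cohort_table()].
#' @return Integer vector of node indices in `1..K`.
#' @export
assign_micro <- function(model, data) {
  r <- gtm_e_step(model, data)$R
  max.col(r, ties.method = "first")
}

#' Save / load a GTM model as JSON
#'
#' Serialises the model configuration (lattice and basis sides, width factor,
#' lambda, seed), the fitted `W` and `beta`, the variable names and any
#' standardisation parameters, at full double precision so a load round-trips
#' bit-exactly.
#'
#' @param model a `gtm` model.
#' @param path JSON file path.
#' @return `write_gtm()` returns `path` invisibly; `read_gtm()` the model.
#' @export
write_gtm <- function(model, path) {
  scaler <- model$scaler
  if (!is.null(scaler)) {
    scaler <- list(variable = scaler$variable,
                   center = num_format(scaler$center),
                   scale = num_format(scaler$scale))
  }
  obj <- list(
    package = "phenomap",
    type = "gtm",
    side = model$grid$side,
    rbf_side = model$basis$rbf_side,
    width_factor = model$basis$width_factor,
    lambda = model$lambda,
    seed = model$seed,
    # doubles are stored as 17-significant-digit strings so that reading
    # reproduces them bit-exactly
    beta = num_format(model$beta),
    var_names = model$var_names,
    W = lapply(seq_len(nrow(model$W)), function(i) num_format(model$W[i, ])),
    scaler = scaler,
    trace = model$trace,
    init = model$init
  )
  write_json_file(obj, path)
}

#' @rdname write_gtm
#' @export
read_gtm <- function(path) {
  obj <- read_json_file(path)
  grid <- if (obj$side >= 2L) build_latent_grid(obj$side) else single_node_grid()
  basis <- if (obj$rbf_side >= 1L) {
    build_rbf_basis(grid, obj$rbf_side, obj$width_factor)
  } else {
    bias_basis(grid)
  }
  w <- if (is.matrix(obj$W)) {
    matrix(as.numeric(obj$W), nrow = nrow(obj$W))
  } else {
    do.call(rbind, lapply(obj$W, as.numeric))
  }
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- data.frame(variable = obj$scaler$variable,
                         center = as.numeric(obj$scaler$center),
                         scale = as.numeric(obj$scaler$scale),
                         stringsAsFactors = FALSE)
  }
  trace <- obj$trace
  if (!is.null(trace)) trace$objective <- as.numeric(trace$objective)
  new_gtm(grid, basis, w, as.numeric(obj$beta), as.numeric(obj$lambda),
          as.integer(obj$seed),
          var_names = obj$var_names, scaler = scaler, trace = trace,
          init = obj$init %||% NA_character_)
}
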