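#' PCA statistical shape model over vertex-corresponded meshes
#'
#' Fits a point-distribution model to a population of meshes that share the
#' same vertex correspondence and face topology (as produced by deforming a
#' common template).  Each training shape is first centred on its own vertex
#' centroid, so the model captures shape only; placement is a separate
#' translation handled elsewhere in the pipeline.  The principal components
#' span the vertex-coordinate covariance of the population, and a compact
#' weight vector decodes back to a full 3-D mesh.
#'
#' @param training_meshes list of [triangle_mesh()] objects with identical
#'   vertex count and identical face matrices.
#' @param n_components number of components to keep; at most
#'   `length(training_meshes) - 1`.
#' @return An object of class `shape_model` with elements `mean_shape`
#'   (3V vector, mm), `components` (`n_components` x 3V orthonormal matrix),
#'   `explained_variance` (mm^2, non-increasing), `faces` (shared topology)
#'   and `n_vertices`.
#' @export
fit_shape_pca <- function(training_meshes, n_components) {
  if (!is.list(training_meshes) || length(training_meshes) < 2L) {
    stop("need at least 2 training meshes")
  }
  ref <- training_meshes[[1]]
  stopifnot(is_triangle_mesh(ref))
  nv <- nrow(ref$vertices)
  for (m in training_meshes[-1]) {
    if (!is_triangle_mesh(m) || nrow(m$vertices) != nv ||
        !identical(m$faces, ref$faces)) {
      stop("training meshes must share vertex count and face topology")
    }
  }
  n <- length(training_meshes)
  if (n_components < 1L || n_components > n - 1L) {
    stop("n_components must be in [1, n_training - 1]")
  }
  X <- t(vapply(training_meshes, function(m) {
    v <- m$vertices
    as.vector(t(sweep(v, 2, colMeans(v), "-")))  # row-major xyz per vertex
  }, numeric(3L * nv)))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- n_components
  structure(list(
    mean_shape = as.numeric(pc$center),
    components = unname(t(pc$rotation[, seq_len(k), drop = FALSE])),
    explained_variance = as.numeric(pc$sdev[seq_len(k)]^2),
    total_variance = sum(pc$sdev^2),
    faces = ref$faces,
    n_vertices = nv
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d components over %d vertices\n",
              nrow(x$components), x$n_vertices))
  pct <- 100 * sum(x$explained_variance) / max(x$total_variance, .Machine$double.eps)
  cat(sprintf("  retained variance: %.1f%%\n", min(pct, 100)))
  invisible(x)
}

#' Decode a weight vector to a mesh
#'
#' Pure linear map: vertices are `mean_shape + t(weights) %*% components`,
#' reshaped to n x 3 with the model's shared face topology.  Weights are in
#' mm along each (unit-norm) component; a zero vector returns the mean
#' shape exactly.
#'
#' @param model a [fit_shape_pca()] model.
#' @param weights numeric vector, one entry per model component.
#' @return A [triangle_mesh()].
#' @export
decode_shape <- function(model, weights) {
  stopifnot(inherits(model, "shape_model"))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(model$components)) {
    stop(sprintf("expected %d weights, got %d",
                 nrow(model$components), length(weights)))
  }
  flat <- model$mean_shape + as.numeric(crossprod(model$components, weights))
  v <- matrix(flat, ncol = 3, byrow = TRUE)
  triangle_mesh(v, model$faces)
}

#' Project a mesh onto the shape model
#'
#' Least-squares projection of the centred vertex configuration onto the
#' component basis (the inverse of [decode_shape()] on the model's span).
#' The mesh is centred on its vertex centroid first, matching the fitting
#' convention.  The returned vector carries the orthogonal residual norm in
#' attribute `"residual_norm"` (mm), non-zero when the mesh lies outside
#' the span.
#'
#' @param model a [fit_shape_pca()] model.
#' @param mesh a [triangle_mesh()] with the model's topology.
#' @return Numeric weight vector of length `n_components`.
#' @export
encode_shape <- function(model, mesh) {
  stopifnot(inherits(model, "shape_model"), is_triangle_mesh(mesh))
  if (nrow(mesh$vertices) != model$n_vertices ||
      !identical(mesh$faces, model$faces)) {
    stop("mesh topology does not match the shape model")
  }
  v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices), "-")
  d <- as.vector(t(v)) - model$mean_shape
  w <- as.numeric(model$components %*% d)
  resid <- d - as.numeric(crossprod(model$components, w))
  attr(w, "residual_norm") <- sqrt(sum(resid^2))
  w
}

#' Serialise / restore a shape model
#'
#' Writes the full model (mean, components, variances, topology) to a single
#' JSON file so a fitted model can be shipped or reloaded without the
#' training population.
#'
#' @param model a `shape_model`.
#' @param path output `.json` path.
#' @return `path` (write) or the restored `shape_model` (read).
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  obj <- list(mean_shape = model$mean_shape,
              components = model$components,
              explained_variance = model$explained_variance,
              total_variance = model$total_variance,
              faces = model$faces,
              n_vertices = model$n_vertices)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    mean_shape = as.numeric(obj$mean_shape),
    components = matrix(as.numeric(obj$components),
                        nrow = nrow(obj$components)),
    explained_variance = as.numeric(obj$explained_variance),
    total_variance = as.numeric(obj$total_variance),
    faces = {
      f <- matrix(as.integer(obj$faces), ncol = 3)
      f
    },
    n_vertices = as.integer(obj$n_vertices)
  ), class = "shape_model")
}
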