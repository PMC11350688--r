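# Habitat suitability: a minimal penalized maximum-entropy distribution
# model over a gridded landscape, threshold classification into suitability
# classes, habitat-area accounting and between-species range overlap.
#
# Model: cell-level Gibbs distribution p_i proportional to exp(lambda' f_i)
# over non-masked cells, with standardized linear (optionally quadratic)
# features, fitted by penalized maximum likelihood:
#   minimise  -(1/n) sum_presences lambda' f_i + log Z(lambda)
#             + (reg/2) ||lambda||^2
# The stationarity condition  E_p[f] - mean_presence[f] = -reg * lambda
# is the "feature expectations match presence means within regularization
# slack" contract.

#' Construct a suitability grid
#'
#' @param index numeric matrix of suitability values in `[0, 1]`; `NA` marks
#'   masked (nodata) cells.
#' @param cell_resolution cell area in km^2 (default 1).
#' @param xll,yll lower-left corner (for ASCII-grid round trips).
#' @return object of class `suitability_grid`.
#' @export
suitability_grid <- function(index, cell_resolution = 1, xll = 0, yll = 0) {
  index <- as.matrix(index)
  if (cell_resolution <= 0) stop("cell_resolution must be > 0")
  v <- index[!is.na(index)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("suitability indices must lie in [0, 1]")
  structure(list(index = index, cell_resolution = cell_resolution,
                 xll = xll, yll = yll),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("suitability grid: %d x %d cells at %g km^2 (%d masked)\n",
              nrow(x$index), ncol(x$index), x$cell_resolution,
              sum(is.na(x$index))))
  invisible(x)
}

# stack layers (list of matrices or 3-d array) into an n_cells x p feature
# matrix over non-masked cells; mask = union of layer NAs
layer_features <- function(layers) {
  if (is.array(layers) && length(dim(layers)) == 3L)
    layers <- lapply(seq_len(dim(layers)[3]), function(k) layers[, , k])
  if (is.matrix(layers)) layers <- list(layers)
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1L) stop("layers must share dimensions")
  mask <- Reduce(`|`, lapply(layers, is.na))
  feat <- vapply(layers, function(m) as.numeric(m), numeric(length(mask)))
  list(feat = feat, mask = as.logical(mask), dim = dims[[1]])
}

maxent_objective <- function(lambda, x_cells, x_pres_mean, reg) {
  eta <- drop(x_cells %*% lambda)
  m <- max(eta)
  logz <- m + log(sum(exp(eta - m)))
  -sum(lambda * x_pres_mean) + logz + reg / 2 * sum(lambda^2)
}

#' Fit a minimal maximum-entropy suitability model
#'
#' Penalized maximum-likelihood fit of a Gibbs distribution over grid cells
#' with linear (optionally quadratic) features of the environmental layers,
#' standardized to zero mean and unit variance over non-masked cells.
#' Solved by damped Newton iterations with backtracking line search, so the
#' recorded objective trace is non-increasing.
#'
#' @param presences occurrence cells: data.frame/matrix with `row`, `col`
#'   columns (1-based grid indices), at least 5 rows; presences on masked
#'   cells are an error.
#' @param layers environmental layers: list of equal-dimension matrices, a
#'   3-d array, or a single matrix; `NA` cells are masked.
#' @param regularization ridge penalty `reg` >= 0 (default 0.01).
#' @param features `"linear"` (default) or `"quadratic"` (adds squared
#'   standardized layers).
#' @param transform suitability output scale: `"cloglog"` (default;
#'   `1 - exp(-exp(H) * p)` with H the entropy of the fitted distribution)
#'   or `"raw"` (`p / max(p)`).
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return object of class `maxent_fit`: `lambda` (named feature weights),
#'   `regularization`, `converged`, `trace` (objective per accepted
#'   iterate, non-increasing), `p` (cell probabilities over non-masked
#'   cells), `suitability` (a [suitability_grid()]), `feature_gap`
#'   (E_p\[f\] - presence means, equal to `-reg * lambda` at the optimum).
#' @export
fit_maxent <- function(presences, layers, regularization = 0.01,
                       features = c("linear", "quadratic"),
                       transform = c("cloglog", "raw"),
                       max_iter = 200, tol = 1e-8) {
  features <- match.arg(features)
  transform <- match.arg(transform)
  if (regularization < 0) stop("regularization must be >= 0")
  lf <- layer_features(layers)
  presences <- as.data.frame(presences)
  if (nrow(presences) < 5L) stop("need at least 5 presences")
  if (any(presences$row < 1 | presences$row > lf$dim[1] |
          presences$col < 1 | presences$col > lf$dim[2]))
    stop("presences fall outside the layer extent")
  pres_idx <- presences$row + (presences$col - 1L) * lf$dim[1]
  if (any(lf$mask[pres_idx])) stop("presences fall on masked cells")
  keep <- !lf$mask
  x <- lf$feat[keep, , drop = FALSE]
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev < 1e-12] <- 1  # constant layer carries no information
  x <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  if (features == "quadratic") x <- cbind(x, x^2)
  colnames(x) <- c(paste0("layer", seq_along(sdev)),
                   if (features == "quadratic")
                     paste0("layer", seq_along(sdev), "_sq"))
  cell_of <- match(pres_idx, which(keep))
  x_pres_mean <- colMeans(x[cell_of, , drop = FALSE])

  p_dim <- ncol(x)
  lambda <- numeric(p_dim)
  reg <- regularization
  obj <- maxent_objective(lambda, x, x_pres_mean, reg)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% lambda)
    eta <- eta - max(eta)
    p <- exp(eta) / sum(exp(eta))
    ex <- drop(crossprod(x, p))
    grad <- ex - x_pres_mean + reg * lambda
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    xc <- sweep(x, 2, ex)
    hess <- crossprod(xc, xc * p) + diag(reg + 1e-10, p_dim)
    step <- tryCatch(solve(hess, grad), error = function(e) grad)
    t_ls <- 1
    repeat {
      cand <- lambda - t_ls * step
      obj_new <- maxent_objective(cand, x, x_pres_mean, reg)
      if (obj_new <= obj - 1e-4 * t_ls * sum(grad * step) || t_ls < 1e-10)
        break
      t_ls <- t_ls / 2
    }
    if (obj_new > obj) break  # no descent possible: stop, flag below
    lambda <- cand
    obj <- obj_new
    trace <- c(trace, obj)
  }
  if (!converged) {
    eta <- drop(x %*% lambda); eta <- eta - max(eta)
    p <- exp(eta) / sum(exp(eta))
    grad <- drop(crossprod(x, p)) - x_pres_mean + reg * lambda
    converged <- sqrt(sum(grad^2)) < tol
  }
  eta <- drop(x %*% lambda)
  eta <- eta - max(eta)
  p <- exp(eta) / sum(exp(eta))
  suit_vals <- switch(transform,
    raw = p / max(p),
    cloglog = {
      h <- -sum(p * log(p + 1e-300))
      1 - exp(-exp(h) * p)
    })
  grid <- matrix(NA_real_, lf$dim[1], lf$dim[2])
  grid[keep] <- pmin(1, pmax(0, suit_vals))
  fit <- structure(list(
    lambda = setNames(drop(lambda), colnames(x)),
    regularization = reg,
    converged = converged,
    trace = trace,
    p = p,
    feature_gap = drop(crossprod(x, p)) - x_pres_mean,
    transform = transform,
    n_presences = nrow(presences),
    suitability = suitability_grid(grid)),
    class = "maxent_fit")
  fit
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("maxent fit: %d presences, reg = %g, %s\n", x$n_presences,
              x$regularization,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$lambda, 4))
  invisible(x)
}

SUIT_CLASSES <- c("unsuitable", "potential", "high")

#' Classify suitability indices into habitat classes
#'
#' Threshold classification: unsuitable `[0, 0.5)`, potential habitat
#' `[0.5, 0.7)`, high-suitability habitat `[0.7, 1]` (lower-inclusive).
#' The "distribution range" of a species is potential plus high, i.e.
#' index >= 0.5.
#'
#' @param grid [suitability_grid()] or a numeric matrix/vector of indices.
#' @return factor (same shape as the input index) with levels unsuitable,
#'   potential, high; `NA` for masked cells.
#' @export
classify_suitability <- function(grid) {
  v <- if (inherits(grid, "suitability_grid")) grid$index else grid
  cls <- ifelse(is.na(v), NA_character_,
                ifelse(v < 0.5, "unsuitable",
                       ifelse(v < 0.7, "potential", "high")))
  out <- factor(cls, levels = SUIT_CLASSES)
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

#' Habitat area for a class or threshold
#'
#' Number of qualifying cells times the cell resolution. A numeric argument
#' counts cells with index >= that threshold (so 0.5 gives the distribution
#' range and 0.7 the high-suitability core); a class name counts that class.
#'
#' @param grid [suitability_grid()].
#' @param class_or_threshold numeric threshold in `[0, 1]`, or one of
#'   `"unsuitable"`, `"potential"`, `"high"`.
#' @return area in km^2.
#' @export
habitat_area <- function(grid, class_or_threshold = 0.5) {
  stopifnot(inherits(grid, "suitability_grid"))
  v <- grid$index
  if (is.numeric(class_or_threshold)) {
    n <- sum(v >= class_or_threshold, na.rm = TRUE)
  } else {
    cls <- match.arg(class_or_threshold, SUIT_CLASSES)
    n <- sum(classify_suitability(grid) == cls, na.rm = TRUE)
  }
  n * grid$cell_resolution
}

#' Range overlap between two species' suitability grids
#'
#' Cells where both grids reach `threshold` form the overlap region O. With
#' `base = "each"` the ratio pair is (O / area_A, O / area_B) — each
#' species' share of its own range that is shared; with `base = "union"`
#' both are divided by the union area. Both readings are exposed because
#' printed overlap ratios rarely state their base.
#'
#' @param grid_a,grid_b [suitability_grid()]s on a common extent and
#'   resolution.
#' @param threshold suitability threshold (default 0.5, the distribution
#'   range).
#' @param base `"each"` (default) or `"union"`.
#' @param report round the shares to 1 decimal place (report convention);
#'   default FALSE.
#' @return named numeric vector `c(share_a, share_b)`; attribute
#'   `overlap_km2` carries the overlap area.
#' @export
overlap_ratio <- function(grid_a, grid_b, threshold = 0.5,
                          base = c("each", "union"), report = FALSE) {
  base <- match.arg(base)
  stopifnot(inherits(grid_a, "suitability_grid"),
            inherits(grid_b, "suitability_grid"))
  if (!identical(dim(grid_a$index), dim(grid_b$index)) ||
      grid_a$cell_resolution != grid_b$cell_resolution)
    stop("grids must share extent and resolution")
  a <- !is.na(grid_a$index) & grid_a$index >= threshold
  b <- !is.na(grid_b$index) & grid_b$index >= threshold
  o <- sum(a & b)
  denom <- switch(base,
                  each = c(sum(a), sum(b)),
                  union = rep(sum(a | b), 2))
  shares <- ifelse(denom > 0, o / denom, 0)
  if (report) shares <- round(shares, 1)
  out <- setNames(shares, c("share_a", "share_b"))
  attr(out, "overlap_km2") <- o * grid_a$cell_resolution
  out
}
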