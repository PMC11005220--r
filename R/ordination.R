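# Unsupervised ordination of metabolic profiles: distance matrices,
# principal coordinates analysis (classical scaling) and non-metric
# multidimensional scaling with Kruskal stress-1.

#' Pairwise distance matrix of a feature table
#'
#' @param x numeric matrix or data.frame (rows = animals/samples); a
#'   feature table from [build_feature_table()] is reduced to its feature
#'   columns automatically.
#' @param metric currently only `"euclidean"`.
#' @param standardize z-score columns first (default `TRUE`; recommended
#'   because the features mix units). Zero-variance columns are dropped
#'   with a warning under standardization.
#' @return full symmetric matrix of class `ee_dist` with attributes
#'   `metric` and `standardized`.
#' @export
distance_matrix <- function(x, metric = c("euclidean"), standardize = TRUE) {
  metric <- match.arg(metric)
  fc <- attr(x, "feature_cols")
  if (!is.null(fc)) x <- x[, fc, drop = FALSE]
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("distance_matrix requires complete data")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    x <- scale(x)
  }
  d <- as.matrix(stats::dist(x, method = metric))
  structure(d, class = c("ee_dist", class(d)), metric = metric,
            standardized = standardize)
}

# Deterministic sign convention: flip each axis so its first coordinate
# of magnitude > tol is positive.
.fix_signs <- function(coords, tol = 1e-9) {
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > tol)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and scales eigenvectors by
#' the square roots of their (positive) eigenvalues. Negative eigenvalues
#' (possible for non-Euclidean input) are reported and never embedded.
#' For Euclidean distances computed from a coordinate matrix, the result
#' equals the PCA scores of that matrix up to axis sign.
#'
#' @param d an `ee_dist` (or any symmetric distance matrix / `dist`).
#' @param dims number of requested axes (default 2); truncated with a
#'   warning if fewer positive eigenvalues exist.
#' @return list of class `ee_pcoa`: `coordinates` (n x d, deterministic
#'   sign convention), `eigenvalues` (all n), `prop_variance`
#'   (per retained axis, relative to the positive spectrum).
#' @export
pcoa <- function(d, dims = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) stop("pcoa needs at least 3 points")
  # the full spectrum is requested and truncated explicitly below, so the
  # engine's own "only X eigenvalues > 0" notice is redundant
  cs <- withCallingHandlers(
    stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  eig <- cs$eig
  npos <- sum(eig > max(eig) * 1e-12)
  if (dims > npos) {
    if (npos > 0)
      warning(sprintf("only %d positive eigenvalue(s); returning %d axes",
                      npos, npos))
    dims <- npos
  }
  coords <- if (dims > 0) .fix_signs(cs$points[, seq_len(dims), drop = FALSE])
            else matrix(0, n, 0)
  rownames(coords) <- rownames(dm)
  structure(list(coordinates = coords, eigenvalues = eig,
                 prop_variance = if (dims > 0)
                   eig[seq_len(dims)] / sum(eig[eig > 0]) else numeric(0)),
            class = "ee_pcoa")
}

# Kruskal stress-1 and the isotonic (monotone) disparities for a
# configuration: disparities are the monotone-in-dissimilarity least
# squares fit to the configuration distances.
.stress1 <- function(dvec, dhat) sqrt(sum((dvec - dhat)^2) / sum(dvec^2))

.disparities <- function(dvec, ord) {
  dhat <- numeric(length(dvec))
  dhat[ord] <- stats::isoreg(dvec[ord])$yf
  dhat
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 with monotone (isotonic) regression of the
#' configuration distances on the rank order of the input dissimilarities,
#' alternating with a Guttman (SMACOF) configuration update. The update is
#' step-halved whenever it would increase stress, so the stress trace is
#' non-increasing by construction. The best of `restarts` initializations
#' (PCoA plus random starts) is returned.
#'
#' @param d an `ee_dist` or symmetric dissimilarity matrix.
#' @param dims embedding dimension (default 2).
#' @param restarts number of initializations (default 8: PCoA + 7 random).
#' @param seed seed for the random starts.
#' @param max_iter,tol iteration cap and relative stress-improvement
#'   tolerance per run.
#' @return list of class `ee_nmds`: `coordinates` (centered, deterministic
#'   sign convention), `stress` (final stress-1), `stress_trace` of the
#'   winning run, `converged` flag.
#' @export
nmds <- function(d, dims = 2, restarts = 8, seed = 1, max_iter = 200,
                 tol = 1e-7) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < dims + 1) stop("nmds needs at least dims + 1 points")
  dis <- dm[lower.tri(dm)]
  ord <- order(dis)
  pair <- which(lower.tri(dm), arr.ind = TRUE)

  run <- function(X0) {
    X <- scale(X0, scale = FALSE)
    dvec <- as.numeric(stats::dist(X))
    dhat <- .disparities(dvec, ord)
    s <- .stress1(dvec, dhat)
    trace <- s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # Guttman transform toward the current disparities
      ratio <- ifelse(dvec > 0, dhat / dvec, 0)
      B <- matrix(0, n, n)
      B[cbind(pair[, 1], pair[, 2])] <- -ratio
      B[cbind(pair[, 2], pair[, 1])] <- -ratio
      diag(B) <- -rowSums(B)
      XG <- B %*% X / n
      alpha <- 1
      repeat {
        Xn <- X + alpha * (XG - X)
        dvn <- as.numeric(stats::dist(Xn))
        dhn <- .disparities(dvn, ord)
        sn <- .stress1(dvn, dhn)
        if (sn <= s || alpha < 1e-4) break
        alpha <- alpha / 2
      }
      if (sn > s) { converged <- TRUE; break }  # no downhill step left
      improved <- s - sn
      X <- scale(Xn, scale = FALSE); dvec <- dvn; dhat <- dhn; s <- sn
      trace <- c(trace, s)
      if (improved < tol * max(s, 1e-12)) { converged <- TRUE; break }
    }
    list(X = X, stress = s, trace = trace, converged = converged)
  }

  inits <- vector("list", restarts)
  inits[[1]] <- tryCatch(
    pcoa(dm, dims = dims)$coordinates,
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(inits[[1]]) || ncol(inits[[1]]) < dims)
    inits[[1]] <- with_seed(mix_seed(seed, 0), matrix(stats::rnorm(n * dims), n))
  for (r in seq_len(restarts - 1) + 1)
    inits[[r]] <- with_seed(mix_seed(seed, r),
                            matrix(stats::rnorm(n * dims), n))
  runs <- lapply(inits, run)
  best <- runs[[which.min(vapply(runs, `[[`, 0, "stress"))]]
  coords <- .fix_signs(best$X)
  rownames(coords) <- rownames(dm)
  structure(list(coordinates = coords, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged),
            class = "ee_nmds")
}

#' @export
print.ee_pcoa <- function(x, ...) {
  cat(sprintf("<ee_pcoa> %d points, %d axes; variance explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$prop_variance), collapse = ", ")))
  invisible(x)
}

#' @export
print.ee_nmds <- function(x, ...) {
  cat(sprintf("<ee_nmds> %d points, %d axes; stress-1 = %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}
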