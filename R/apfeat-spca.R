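#' Sparse PCA with adjusted-explained-variance retention
#'
#' Runs sparse PCA separately within each feature category via
#' soft-thresholded power iteration with projection deflation. For each
#' category the adjusted explained variance of the (generally non-orthogonal)
#' sparse components is computed from the QR decomposition of the projected
#' data, the standard correction for correlated sparse components; components
#' with adjusted explained variance above \code{retention} (default 1%) are
#' kept, and the kept scores are z-scored and concatenated across categories.
#' At \code{penalty = 0} the procedure reduces to ordinary PCA.
#'
#' @param fm A [FeatureMatrix-class].
#' @param retention adjusted-EV fraction a component must exceed to be kept.
#' @param penalty soft-threshold level as a fraction of the largest absolute
#'   loading entry, in [0, 1).
#' @param seed integer (initialization is deterministic; the seed is kept in
#'   the signature for interface stability).
#' @param maxComp maximum components per category.
#' @return A [SparsePCResult-class].
#' @examples
#' x <- matrix(rnorm(60), 10, 6)
#' fm <- new("FeatureMatrix", values = x, category = rep("a", 6),
#'           dropped = character())
#' res <- sparsePCA(fm, penalty = 0)
#' @export
sparsePCA <- function(fm, retention = 0.01, penalty = 0, seed = 1L,
                      maxComp = 10L) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (nrow(fm@values) < 2L) stop("need at least 2 cells")
  if (any(!is.finite(fm@values))) stop("feature values must be finite")
  cats <- unique(fm@category)
  loadings <- list(); adjEV <- list(); kept <- list(); scoreCols <- list()
  for (cat in cats) {
    X <- fm@values[, fm@category == cat, drop = FALSE]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    k <- min(nrow(Xc) - 1L, ncol(Xc), maxComp)
    if (k < maxComp && maxComp <= ncol(Xc)) {
      warning("category ", cat, ": fewer cells than requested components; ",
              "truncated to ", k)
    }
    V <- spcaLoadings(Xc, k, penalty)
    ev <- adjustedEV(Xc, V)
    keep <- ev > retention
    loadings[[cat]] <- V[, keep, drop = FALSE]
    adjEV[[cat]] <- ev
    kept[[cat]] <- keep
    if (any(keep)) {
      sc <- Xc %*% V[, keep, drop = FALSE]
      sds <- apply(sc, 2, stats::sd)
      sds[sds == 0] <- 1
      sc <- scale(sc, center = TRUE, scale = sds)
      colnames(sc) <- sprintf("%s.%d", cat, which(keep))
      scoreCols[[cat]] <- sc
    }
  }
  scores <- if (length(scoreCols)) do.call(cbind, scoreCols) else
    matrix(0, nrow(fm@values), 0)
  rownames(scores) <- rownames(fm@values)
  new("SparsePCResult", loadings = loadings, scores = scores, adjEV = adjEV,
      kept = kept, retention = retention)
}

# Rank-one soft-thresholded power iterations with projection deflation.
spcaLoadings <- function(Xc, k, penalty, tol = 1e-10, maxIter = 1000L) {
  p <- ncol(Xc)
  V <- matrix(0, p, k)
  Xd <- Xc
  for (comp in seq_len(k)) {
    # deterministic init: column of X'X with the largest norm
    G <- crossprod(Xd)
    v <- G[, which.max(colSums(G^2))]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-300) break
    v <- v / nv
    for (it in seq_len(maxIter)) {
      u <- Xd %*% v
      nu <- sqrt(sum(u^2))
      if (nu < 1e-300) break
      u <- u / nu
      vRaw <- crossprod(Xd, u)
      if (penalty > 0) {
        lam <- penalty * max(abs(vRaw))
        vRaw <- sign(vRaw) * pmax(abs(vRaw) - lam, 0)
      }
      nv <- sqrt(sum(vRaw^2))
      if (nv < 1e-300) break
      vNew <- as.numeric(vRaw / nv)
      if (sum((vNew - v)^2) < tol && it > 1L) { v <- vNew; break }
      v <- vNew
    }
    # sign convention: largest-magnitude loading positive
    v <- v * sign(v[which.max(abs(v))])
    V[, comp] <- v
    Xd <- Xd - (Xd %*% v) %*% t(v)
  }
  V
}

# Adjusted explained variance (QR of the projected data) as EV fractions.
adjustedEV <- function(Xc, V) {
  tot <- sum(Xc^2)
  if (tot == 0) return(numeric(ncol(V)))
  Y <- Xc %*% V
  keepCols <- colSums(abs(V)) > 0
  r2 <- numeric(ncol(V))
  if (any(keepCols)) {
    R <- qr.R(qr(Y[, keepCols, drop = FALSE]))
    r2[keepCols] <- diag(as.matrix(R))^2
  }
  r2 / tot
}
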