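#' Construct a marker matrix
#'
#' Validates a numeric lines-by-markers genotype matrix. Missing genotypes
#' are either imputed by the column mean (\code{impute = TRUE}) or rejected.
#'
#' @param G numeric matrix with line identifiers as rownames; codes per
#'   marker in {0,1,2} or {-1,0,1}.
#' @param impute replace missing genotypes by their column mean?
#' @return a \linkS4class{MarkerMatrix}.
#' @export
markerMatrix <- function(G, impute = FALSE) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    if (!impute)
      stop("marker matrix contains missing genotypes (set impute = TRUE to column-mean impute)")
    nMiss <- sum(is.na(G))
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) {
        m <- mean(G[!nas, j])
        if (is.nan(m)) stop("marker column ", j, " is entirely missing")
        G[nas, j] <- m
      }
    }
    message(nMiss, " missing genotypes imputed by column means")
  }
  new("MarkerMatrix", genotypes = G)
}

#' Normalized squared Euclidean distances between lines
#'
#' Marker columns are mean-centered, pairwise squared Euclidean distances
#' between lines are computed, and the matrix is divided by its mean
#' off-diagonal entry. After normalization the exponent of the Gaussian
#' kernel is O(1) whatever the marker count, so a single bandwidth grid is
#' meaningful across datasets.
#'
#' @param markers a \linkS4class{MarkerMatrix} (or a plain matrix with line
#'   rownames).
#' @return a \linkS4class{DistanceMatrix}.
#' @export
squaredDistanceMatrix <- function(markers) {
  if (!is(markers, "MarkerMatrix")) markers <- markerMatrix(markers)
  G <- markers@genotypes
  J <- nrow(G)
  if (J < 2L) stop("need at least 2 lines to define pairwise distances")
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sq <- rowSums(Gc^2)
  D2raw <- outer(sq, sq, "+") - 2 * tcrossprod(Gc)
  D2raw[D2raw < 0] <- 0
  diag(D2raw) <- 0
  norm <- mean(D2raw[upper.tri(D2raw) | lower.tri(D2raw)])
  if (norm <= 0)
    stop("degenerate marker input: all lines are identical, ",
         "mean pairwise distance is zero")
  D2 <- D2raw / norm
  dimnames(D2) <- list(rownames(G), rownames(G))
  new("DistanceMatrix", D2 = D2, normalizer = norm)
}

#' Gaussian kernel at bandwidth rho
#'
#' K_ij = rho^(D2_ij) = exp(log(rho) * D2_ij), the bandwidth-rho
#' parameterization (rho = exp(-gamma)) of the Gaussian kernel over
#' normalized squared marker distances.
#'
#' @param dist a \linkS4class{DistanceMatrix}.
#' @param rho bandwidth in (0, 1).
#' @return a \linkS4class{KernelMatrix}.
#' @export
gaussianKernel <- function(dist, rho) {
  if (!is(dist, "DistanceMatrix")) stop("dist must be a DistanceMatrix")
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho <= 0 || rho >= 1)
    stop("rho must be a single value in the open interval (0, 1)")
  K <- exp(log(rho) * dist@D2)
  diag(K) <- 1
  new("KernelMatrix", K = K, rho = rho)
}

#' Linear genomic relationship matrix (VanRaden)
#'
#' Centered genotype cross-product scaled by 2 * sum p_k (1 - p_k), with
#' allele frequencies estimated from the observed genotypes. Included as the
#' linear comparison kernel; unlike the Gaussian kernel it has no unit
#' diagonal.
#'
#' @param markers a \linkS4class{MarkerMatrix}.
#' @return a \linkS4class{KernelMatrix} with \code{bandwidth} NA.
#' @export
linearGRM <- function(markers) {
  if (!is(markers, "MarkerMatrix")) markers <- markerMatrix(markers)
  G <- markers@genotypes
  if (min(G) < 0) G <- G + 1  # -1/0/1 coding -> 0/1/2
  p <- colMeans(G) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic: VanRaden scaling denominator is zero")
  W <- sweep(G, 2L, 2 * p)
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(G), rownames(G))
  new("KernelMatrix", K = K, rho = NA_real_)
}
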