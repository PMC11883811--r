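#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum |R p_i + t - q_i|^2` over paired coordinate sets, via SVD of the
#' cross-covariance matrix with the usual determinant sign correction.
#'
#' @param P n x 3 matrix of mobile coordinates.
#' @param Q n x 3 matrix of reference coordinates.
#' @return list with `R` (3 x 3), `t` (length 3), and `rmsd` of the fit.
#' @export
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), all(dim(P) == dim(Q)), ncol(P) == 3)
  if (nrow(P) < 3) stop("need at least 3 correspondence atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity guard: rank of the centred mobile set
  if (qr(Pc)$rank < 2)
    stop("correspondence atoms are collinear; superposition is degenerate")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  fitted <- tcrossprod(Pc, R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

apply_rigid <- function(X, R, t) sweep(tcrossprod(X, R), 2, t, `+`)

#' RMSD between two coordinate sets without refitting
#' @param A,B n x 3 matrices.
#' @export
coord_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))
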