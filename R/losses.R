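#' Reconstruction loss (vertex-wise MSE)
#'
#' Mean over corresponding vertices of the squared Euclidean distance
#' between two meshes sharing one topology, in mm^2.  Defined as a mean
#' (not a sum) so the value is comparable across template resolutions and
#' the regularization weight keeps its meaning.
#'
#' @param x,x_hat Two [face_mesh()] objects with identical topology.
#' @return Non-negative scalar; 0 iff the meshes are identical.
#' @export
recon_loss <- function(x, x_hat) {
  if (!same_topology(x, x_hat)) stopf("meshes do not share a topology")
  d <- x$vertices - x_hat$vertices
  mean(rowSums(d * d))
}

#' Spherical latent regularization
#'
#' `(||z|| - 1)^2`: pushes latent codes toward the unit hypersphere, which
#' keeps the latent region the decoder is trained on compact and makes the
#' downstream latent-space optimization better behaved.
#'
#' @param z Numeric latent vector.
#' @return Non-negative scalar; 0 iff `||z|| = 1`.
#' @export
reg_loss <- function(z) {
  (sqrt(sum(z^2)) - 1)^2
}

#' Total training loss
#'
#' `recon_loss(x, x_hat) + lambda_reg * reg_loss(z)`.
#'
#' @inheritParams recon_loss
#' @param z Latent vector that produced `x_hat`.
#' @param lambda_reg Non-negative regularization weight (default 0.01).
#' @return Scalar loss.
#' @export
total_loss <- function(x, x_hat, z, lambda_reg = 0.01) {
  if (lambda_reg < 0) stopf("lambda_reg must be >= 0")
  recon_loss(x, x_hat) + lambda_reg * reg_loss(z)
}
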