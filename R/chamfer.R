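#' Unidirectional chamfer distance
#'
#' `(1/|S1|) * sum_{x in S1} min_{y in S2} ||x - y||^2`, in mm^2.  Not
#' symmetric: every point of `s1` is matched to its nearest neighbor in
#' `s2`, so `s2` may contain extra structure (an intact face matched against
#' a defective one) without penalty.
#'
#' @param s1 N1 x 3 point matrix (or a [face_mesh()]); the side averaged
#'   over (the defective face during fitting).
#' @param s2 N2 x 3 point matrix (or a [face_mesh()]); the side searched
#'   for nearest neighbors (the generated face).
#' @return Non-negative scalar in mm^2.
#' @export
chamfer_unidirectional <- function(s1, s2) {
  if (inherits(s1, "face_mesh")) s1 <- s1$vertices
  if (inherits(s2, "face_mesh")) s2 <- s2$vertices
  if (is.null(dim(s1)) || nrow(s1) == 0L) stopf("s1 is empty")
  if (is.null(dim(s2)) || nrow(s2) == 0L) stopf("s2 is empty")
  nn <- nearest_neighbor(s1, s2)
  mean(nn$dist2)
}

# Nearest neighbor of each row of x in y: list(index, dist2).  Exhaustive
# scan in compiled code (exact; ties resolve to the lowest index).
nearest_neighbor <- function(x, y) {
  .nn_bruteforce(x, y)
}
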