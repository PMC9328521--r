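# Random pseudo star-M-orthogonal explicit rank-q tensor-to-vector maps, the
# competitor family for the variance-maximization / distortion-minimization
# properties: q hat-domain "read-out" columns are allocated at random across
# faces, each face contributing random orthonormal columns of R^p.
random_competitor_scores <- function(A_mdf, M, q) {
  A_hat <- mode3_product(A_mdf, M)
  d <- dim(A_mdf)
  alloc <- tabulate(sample.int(d[3], q, replace = TRUE), nbins = d[3])
  blocks <- lapply(seq_len(d[3]), function(i) {
    if (alloc[i] == 0) return(NULL)
    W <- qr.Q(qr(matrix(rnorm(d[2] * alloc[i]), d[2], alloc[i])))
    matrix(A_hat[, , i], d[1], d[2]) %*% W
  })
  do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
}

nuclear_norm <- function(X) sum(svd(X)$d)

# Distortion of a configuration: ||AA^T - ZZ^T||_* with A the mode-1
# unfolding of the (MDF) tensor.
configuration_distortion <- function(A_mdf, Z) {
  G <- tcrossprod(matrix(A_mdf, nrow = dim(A_mdf)[1]))
  nuclear_norm(G - tcrossprod(Z))
}
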