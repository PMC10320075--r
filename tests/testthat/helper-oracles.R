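# Independent oracles and in-code fixtures shared across the suite.

# Optimal superposition RMSD by Horn's closed-form quaternion method:
# the largest eigenvalue of the 4x4 key matrix gives the residual
# directly, with no SVD and no explicit rotation construction.
quaternionRmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lam) / n)
}

randomRotation <- function() {
  # QR of a random gaussian matrix, sign-fixed to a proper rotation
  qr0 <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr0) %*% diag(sign(diag(qr.R(qr0))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# A StructureModel holding one chain with backbone N/CA/C atoms and the
# given one-letter sequence, numbered from resnoStart.
makeChainModel <- function(seq, resnoStart = 1L, chain = "A",
    id = "fixture") {
  aa3 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN",
    E="GLU", G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET",
    F="PHE", P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL")
  letters1 <- strsplit(seq, "")[[1]]
  n <- length(letters1)
  resno <- seq.int(resnoStart, length.out = n)
  df <- data.frame(type = "ATOM", eleno = seq_len(3L * n),
    elety = rep(c("N", "CA", "C"), n), alt = "",
    resid = rep(unname(aa3[letters1]), each = 3L), chain = chain,
    resno = rep(resno, each = 3L), insert = "",
    x = rep(resno * 3.4, each = 3L) + c(-0.9, 0, 0.9),
    y = rep(sin(resno), each = 3L) + c(0.4, 0, -0.4),
    z = rep(cos(resno), each = 3L), o = 1, b = 0)
  new("StructureModel", atoms = df, metadata = list(id = id))
}

randomProteinSeq <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
    "F","P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}
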