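# Independent quadratic-space Smith-Waterman oracle (Gotoh affine gaps,
# BLAST convention: a gap of length g costs gapOpen + (g - 1) * gapExtend).
# Deliberately naive and separate from the package's alignment engine.
swOracle <- function(a, b, mat, gapOpen = 11, gapExtend = 1) {
    A <- strsplit(a, "", fixed = TRUE)[[1L]]
    B <- strsplit(b, "", fixed = TRUE)[[1L]]
    n <- length(A)
    m <- length(B)
    M <- matrix(0, n + 1L, m + 1L)
    Ix <- matrix(-Inf, n + 1L, m + 1L)
    Iy <- matrix(-Inf, n + 1L, m + 1L)
    best <- 0
    for (i in seq_len(n) + 1L) {
        for (j in seq_len(m) + 1L) {
            Ix[i, j] <- max(M[i - 1L, j] - gapOpen, Ix[i - 1L, j] - gapExtend)
            Iy[i, j] <- max(M[i, j - 1L] - gapOpen, Iy[i, j - 1L] - gapExtend)
            s <- mat[A[i - 1L], B[j - 1L]]
            M[i, j] <- max(0, s + max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                                      Iy[i - 1L, j - 1L]))
            if (M[i, j] > best)
                best <- M[i, j]
        }
    }
    best
}

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "", fixed = TRUE)[[1L]]

randomProtein <- function(len) {
    paste(sample(AA20, len, replace = TRUE), collapse = "")
}
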