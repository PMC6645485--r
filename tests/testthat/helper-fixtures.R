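# Shared fixtures for the test suite. Everything is generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny hand-checkable matrix: [[1,2],[3,4]]
# grand mean 2.5; SST = 5, SSBS = 4, SSBM = 1, SSE = 0
oracle_2x2 <- function() as_score_matrix(matrix(c(1, 3, 2, 4), nrow = 2))

# random complete matrices for property tests
random_matrix <- function(n = NULL, k = NULL) {
  n <- n %||% sample(2:30, 1)
  k <- k %||% sample(2:8, 1)
  matrix(rnorm(n * k, mean = 50, sd = 10), n, k)
}

# independent brute-force ANOVA oracle: definitional double loops, no
# shared code with ms_from_matrix()
anova_brute <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  S <- sapply(seq_len(n), function(i) sum(x[i, ]) / k)
  M <- sapply(seq_len(k), function(j) sum(x[, j]) / n)
  sst <- 0; ssbs <- 0; ssbm <- 0; ssws <- 0; sswm <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sst <- sst + (x[i, j] - gm)^2
    ssws <- ssws + (x[i, j] - S[i])^2
    sswm <- sswm + (x[i, j] - M[j])^2
  }
  for (i in seq_len(n)) ssbs <- ssbs + k * (S[i] - gm)^2
  for (j in seq_len(k)) ssbm <- ssbm + n * (M[j] - gm)^2
  list(sst = sst, ssbs = ssbs, ssbm = ssbm, ssws = ssws, sswm = sswm,
       sse = sst - ssbs - ssbm)
}

anova_lookup <- function(an, term, col = "meansq") {
  an[[col]][an$term == term]
}
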