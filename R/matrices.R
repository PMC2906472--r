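#' Load a bundled substitution or rate matrix
#'
#' The package ships two standard amino-acid tables as plain text under
#' `inst/extdata`: the Gonnet PAM-250 substitution matrix (Gonnet, Cohen &
#' Benner 1992), the default scoring matrix for all alignment steps, and the
#' JTT exchangeability matrix with its stationary frequencies (Jones, Taylor
#' & Thornton 1992), used for JTT-corrected distances.
#'
#' @param name `"gonnet250"` or `"jtt"`.
#' @return For `"gonnet250"`, a symmetric 20 x 20 numeric matrix with residue
#'   dimnames.  For `"jtt"`, a list with `Q` (the symmetric exchangeability
#'   matrix) and `freq` (stationary residue frequencies summing to 1).
#' @export
#' @examples
#' m <- load_matrix("gonnet250")
#' m["C", "C"]
load_matrix <- function(name = c("gonnet250", "jtt")) {
  name <- match.arg(name)
  if (name == "gonnet250") {
    path <- system.file("extdata", "gonnet250.tsv", package = "srcrtools")
    tab <- read.delim(path, comment.char = "#", row.names = 1,
                      check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    stopifnot(identical(rownames(m), colnames(m)), isTRUE(all.equal(m, t(m))))
    m
  } else {
    path <- system.file("extdata", "jtt_rates.tsv", package = "srcrtools")
    tab <- read.delim(path, comment.char = "#", row.names = 1,
                      check.names = FALSE)
    Q <- as.matrix(tab[, seq_len(20)])
    storage.mode(Q) <- "double"
    freq <- as.numeric(tab$freq)
    names(freq) <- rownames(tab)
    list(Q = Q, freq = freq / sum(freq))
  }
}

# Normalized JTT rate matrix (rows sum to 0, mean rate 1 substitution/site)
# with its eigendecomposition, cached per session.
jtt_generator <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    jtt <- load_matrix("jtt")
    pi <- jtt$freq
    R <- jtt$Q
    Q <- R * rep(pi, each = nrow(R))   # q_ij = r_ij * pi_j
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    mu <- -sum(pi * diag(Q))           # expected rate under stationarity
    Q <- Q / mu
    # symmetrize via pi^(1/2) similarity transform for a stable eigensystem
    s <- sqrt(pi)
    B <- diag(s) %*% Q %*% diag(1 / s)
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    cache <<- list(Q = Q, pi = pi, values = e$values,
                   U = diag(1 / s) %*% e$vectors,
                   Uinv = t(e$vectors) %*% diag(s))
    cache
  }
})

# Expected proportion of differing sites after evolving for time d under JTT:
# p(d) = 1 - sum_i pi_i * [exp(Qd)]_ii
jtt_expected_p <- function(d) {
  g <- jtt_generator()
  vapply(d, function(di) {
    P_diag <- rowSums(g$U * t(g$Uinv * exp(g$values * di)))
    1 - sum(g$pi * P_diag)
  }, numeric(1))
}
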