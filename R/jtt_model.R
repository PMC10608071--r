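# The Jones-Taylor-Thornton empirical amino-acid substitution model, packaged
# as a plain-text file of the published exchangeability counts and stationary
# frequencies. The rate matrix is built GTR-style, Q = S diag(pi) with the
# diagonal set so rows sum to zero, then scaled so the expected number of
# substitutions per site per unit time at stationarity is 1 -- distances are
# therefore in substitutions per site. Time-reversibility lets us
# eigendecompose the symmetrized matrix once and evaluate P(t) cheaply for
# any t.

#' Load the packaged JTT substitution model
#'
#' @param path TSV with the 20x20 symmetric exchangeability block and a final
#'   `pi` row of stationary frequencies; defaults to the packaged file
#' @return an `sts_model`: list with `name` (`"jtt-ml"`), `alphabet`, `pi`,
#'   `Q` (scaled rate matrix), and the eigendecomposition used by
#'   [transition_prob()]
#' @export
jtt_model <- function(path = sts_extdata("jtt_model.tsv")) {
  raw <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
  aa <- colnames(raw)
  stopifnot(length(aa) == 20L, identical(rownames(raw)[1:20], aa),
            rownames(raw)[21] == "pi")
  S <- as.matrix(raw[1:20, ])
  pi <- as.numeric(raw[21, ])
  names(pi) <- aa
  pi <- pi / sum(pi)
  if (max(abs(S - t(S))) > 0) stop("exchangeability matrix is not symmetric")

  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(aa, aa)

  # symmetrize: B = D^{1/2} Q D^{-1/2} has the same eigenvalues, real vectors
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = "jtt-ml", alphabet = aa, pi = pi, Q = Q,
                 eig_values = eig$values,
                 left = diag(1 / sp) %*% eig$vectors,
                 right = t(eig$vectors) %*% diag(sp)),
            class = "sts_model")
}

#' @export
print.sts_model <- function(x, ...) {
  cat("amino-acid substitution model", x$name,
      "(20 states, mean rate 1 at stationarity)\n")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model an `sts_model`
#' @param t branch length in expected substitutions per site
#' @return 20x20 stochastic matrix
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "sts_model"), t >= 0)
  P <- model$left %*% (exp(model$eig_values * t) * model$right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}
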