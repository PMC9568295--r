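#' Literal closed-form expressions for deep architectures
#'
#' A deliberately verbatim transcription of the published closed forms for
#' the Randic-type and Zagreb-type indices of DNN(M; N1..Nr; N) with
#' `r >= 3` hidden layers: two leading boundary terms, an interior sum over
#' `i = 2..r-2` (empty at `r = 3`), and two trailing boundary terms. It is
#' kept separate from, and structurally independent of, the generic
#' partition evaluator so the two can cross-check each other.
#'
#' Supported: `randic_half` (the \eqn{R_{1/2}} square-root form),
#' `general_randic`, `zagreb1`, `zagreb2`, `forgotten`, `hyper_zagreb`
#' (plain values) and `mult_zagreb1`, `mult_zagreb2` (returned on the
#' log10 scale, since the products are typically astronomical).
#'
#' @param spec A `dnn_spec` with at least three hidden layers.
#' @param name One of the index names above.
#' @param alpha Exponent for `general_randic`.
#' @return A double: the index value, or its log10 for the multiplicative
#'   Zagreb indices.
#' @export
theorem_literal_index <- function(spec, name, alpha = NULL) {
  stopifnot(inherits(spec, "dnn_spec"))
  if (spec$r < 3L) stop("the literal closed forms require r >= 3 hidden layers")
  name <- match.arg(name, c("randic_half", "general_randic", "zagreb1",
                            "zagreb2", "forgotten", "hyper_zagreb",
                            "mult_zagreb1", "mult_zagreb2"))
  if (name == "general_randic" && is.null(alpha))
    stop("general_randic requires an explicit alpha")
  M <- as.numeric(spec$M)
  N <- as.numeric(spec$N)
  h <- as.numeric(spec$hidden)
  r <- spec$r
  # interior sum over i = 2..r-2, empty when r == 3
  isum <- function(f) {
    s <- 0
    if (r >= 4L) for (i in 2:(r - 2L)) s <- s + f(i)
    s
  }
  switch(name,
    randic_half =
      (M * h[1]) * sqrt(h[1] * (M + h[2])) +
      (h[1] * h[2]) * sqrt((M + h[2]) * (h[1] + h[3])) +
      isum(function(i) h[i] * h[i + 1] *
             ((h[i - 1] + h[i + 1]) * (h[i] + h[i + 2]))^(1 / 2)) +
      (h[r - 1] * h[r]) * sqrt((h[r - 2] + h[r]) * (h[r - 1] + N)) +
      (h[r] * N) * sqrt((h[r - 1] + N) * h[r]),
    general_randic =
      (M * h[1]) * (h[1] * (M + h[2]))^alpha +
      (h[1] * h[2]) * ((M + h[2]) * (h[1] + h[3]))^alpha +
      isum(function(i) h[i] * h[i + 1] *
             ((h[i - 1] + h[i + 1]) * (h[i] + h[i + 2]))^alpha) +
      (h[r - 1] * h[r]) * ((h[r - 2] + h[r]) * (h[r - 1] + N))^alpha +
      (h[r] * N) * ((h[r - 1] + N) * h[r])^alpha,
    zagreb1 =
      (M * h[1]) * (h[1] + M + h[2]) +
      (h[1] * h[2]) * (M + h[2] + h[1] + h[3]) +
      isum(function(i) h[i] * h[i + 1] *
             (h[i - 1] + h[i + 1] + h[i] + h[i + 2])) +
      (h[r - 1] * h[r]) * (h[r - 2] + h[r] + h[r - 1] + N) +
      (h[r] * N) * (h[r - 1] + N + h[r]),
    zagreb2 =
      (M * h[1]) * (h[1] * (M + h[2])) +
      (h[1] * h[2]) * ((M + h[2]) * (h[1] + h[3])) +
      isum(function(i) h[i] * h[i + 1] *
             ((h[i - 1] + h[i + 1]) * (h[i] + h[i + 2]))) +
      (h[r - 1] * h[r]) * ((h[r - 2] + h[r]) * (h[r - 1] + N)) +
      (h[r] * N) * ((h[r - 1] + N) * h[r]),
    forgotten =
      (M * h[1]) * (h[1]^2 + (M + h[2])^2) +
      (h[1] * h[2]) * ((M + h[2])^2 + (h[1] + h[3])^2) +
      isum(function(i) h[i] * h[i + 1] *
             ((h[i - 1] + h[i + 1])^2 + (h[i] + h[i + 2])^2)) +
      (h[r - 1] * h[r]) * ((h[r - 2] + h[r])^2 + (h[r - 1] + N)^2) +
      (h[r] * N) * ((h[r - 1] + N)^2 + h[r]^2),
    hyper_zagreb =
      (M * h[1]) * (h[1] + M + h[2])^2 +
      (h[1] * h[2]) * (M + h[2] + h[1] + h[3])^2 +
      isum(function(i) h[i] * h[i + 1] *
             (h[i - 1] + h[i + 1] + h[i] + h[i + 2])^2) +
      (h[r - 1] * h[r]) * (h[r - 2] + h[r] + h[r - 1] + N)^2 +
      (h[r] * N) * (h[r - 1] + N + h[r])^2,
    mult_zagreb1 =  # log10 of (N1+M+N2)^(MN1) x ... x (N_{r-1}+N+N_r)^(N_r N)
      (M * h[1]) * log10(h[1] + M + h[2]) +
      (h[1] * h[2]) * log10(M + h[2] + h[1] + h[3]) +
      isum(function(i) h[i] * h[i + 1] *
             log10(h[i - 1] + h[i + 1] + h[i] + h[i + 2])) +
      (h[r - 1] * h[r]) * log10(h[r - 2] + h[r] + h[r - 1] + N) +
      (h[r] * N) * log10(h[r - 1] + N + h[r]),
    mult_zagreb2 =  # log10 of (N1(M+N2))^(MN1) x ... x ((N_{r-1}+N)N_r)^(N_r N)
      (M * h[1]) * log10(h[1] * (M + h[2])) +
      (h[1] * h[2]) * log10((M + h[2]) * (h[1] + h[3])) +
      isum(function(i) h[i] * h[i + 1] *
             log10((h[i - 1] + h[i + 1]) * (h[i] + h[i + 2]))) +
      (h[r - 1] * h[r]) * log10((h[r - 2] + h[r]) * (h[r - 1] + N)) +
      (h[r] * N) * log10((h[r - 1] + N) * h[r])
  )
}
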