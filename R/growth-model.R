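#' Unified-Richards growth curve
#'
#' Evaluates the four-parameter unified Richards sigmoid
#' \deqn{W(k) = A\,(1 + ((W_0/A)^{1-S} - 1)\,e^{-G k S^{S/(S-1)}})^{1/(1-S)},}
#' whose shape parameter `S` selects the classical growth laws as
#' submodels: Bertalanffy (`S = 2/3`), Gompertz (`S -> 1`) and logistic
#' (`S = 2`).  For `|S - 1| < 1e-6` the Gompertz limit
#' `W(k) = A (W_0/A)^{exp(-e G k)}` is used (the factor `S^{S/(S-1)}`
#' tends to `e`).  The curve satisfies `W(0) = W0` and `W(Inf) = A`.
#'
#' @param k time (vectorised); in fitting this is normalised to `[0, 1]`.
#' @param A upper asymptote (> 0).
#' @param W0 size at time zero (> 0).
#' @param G growth rate (per unit of `k`).
#' @param S shape parameter.
#' @return Numeric vector of sizes; clipped at 0 where the `S < 1` branch
#'   formally vanishes (far negative times).
#' @examples
#' urichards(0, A = 0.12, W0 = 0.005, G = 2.7, S = 1.4)   # = W0
#' @export
urichards <- function(k, A, W0, G, S) {
  if (A <= 0 || W0 <= 0) stop("A and W0 must be > 0")
  if (abs(S - 1) < 1e-6) {
    return(A * exp(log(W0 / A) * exp(-exp(1) * G * k)))
  }
  f <- S^(S / (S - 1))
  if (!is.finite(f)) stop("non-finite S^(S/(1-S)) for S = ", S)
  u <- expm1((1 - S) * log(W0 / A))        # (W0/A)^(1-S) - 1
  body <- u * exp(-G * k * f)
  w <- numeric(length(body))
  ok <- body > -1                          # S < 1 branch vanishes beyond this
  w[ok] <- A * exp(log1p(body[ok]) / (1 - S))
  if (any(!is.finite(w)))
    stop("non-finite intermediate in unified-Richards evaluation")
  w
}

# shape parameter of each classical submodel; NA = free
.model_shapes <- c(urichards = NA_real_, bertalanffy = 2 / 3,
                   gompertz = 1, logistic = 2)

#' @rdname urichards
#' @export
growth_model_tags <- function() names(.model_shapes)
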