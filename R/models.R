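#' Nucleotide substitution models
#'
#' Constructs a JC69 or K80 substitution model with stationary frequencies
#' pi = 1/4 and unit expected substitution rate, so branch lengths are in
#' expected substitutions per site.
#'
#' @param name "JC69" or "K80".
#' @param kappa Transition/transversion rate ratio (K80 only; `kappa = 1`
#'   recovers JC69).
#' @return An object of class `subst_model`.
#' @export
substitution_model <- function(name = c("JC69", "K80"), kappa = 2) {
  name <- match.arg(name)
  if (name == "K80" && (!is.numeric(kappa) || kappa <= 0)) {
    stop("kappa must be a positive number")
  }
  structure(list(name = name,
                 kappa = if (name == "K80") kappa else 1,
                 pi = stats::setNames(rep(0.25, 4), c("A", "C", "G", "T"))),
            class = "subst_model")
}

#' Transition probability matrix P(t)
#'
#' Rows and columns are ordered A, C, G, T. Rows sum to one for all t >= 0 and
#' P(0) is the identity. Transitions are A<->G and C<->T.
#'
#' @param model A `subst_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return A 4x4 matrix of transition probabilities.
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), is.numeric(t), t >= 0)
  k <- model$kappa
  beta <- 1 / (k + 2)
  e4 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (k + 1) * beta * t)
  p_tv <- 0.25 - 0.25 * e4            # each of the two transversion targets
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2 # the transition target
  p_same <- 1 - p_ts - 2 * p_tv
  b <- c("A", "C", "G", "T")
  P <- matrix(p_tv, 4, 4, dimnames = list(b, b))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- p_ts
  P["C", "T"] <- P["T", "C"] <- p_ts
  P
}
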