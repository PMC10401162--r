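#' Parameters of the equalized focal loss
#'
#' @param alpha_t Weighting factor balancing positive and negative samples;
#'   default 1.
#' @param gamma_b Basic focusing factor controlling behaviour in the
#'   balanced-data regime; must be > 0 (the per-category weighting factor
#'   divides by it). Default 2.
#' @param s Scale of the variable focusing factor; >= 0. Default 4.
#' @param g Named numeric vector of per-category imbalance values in
#'   `[0, 1]`; `g = 1` marks a perfectly balanced category, `g = 0` maximal
#'   imbalance, so the variable factor `s * (1 - g_j)` is nonnegative.
#' @return An object of class `efl_params`.
#' @examples
#' efl_params(gamma_b = 2, s = 4, g = c(common = 1, rare = 0.2))
#' @export
efl_params <- function(alpha_t = 1, gamma_b = 2, s = 4, g = numeric(0)) {
  stopifnot(is.numeric(alpha_t), length(alpha_t) == 1L,
            is.numeric(gamma_b), length(gamma_b) == 1L,
            is.numeric(s), length(s) == 1L, is.numeric(g))
  if (gamma_b <= 0) stop("gamma_b must be > 0", call. = FALSE)
  if (s < 0) stop("s must be >= 0", call. = FALSE)
  if (length(g) && (is.null(names(g)) || !all(nzchar(names(g)))))
    stop("g must be a named vector (category -> imbalance)", call. = FALSE)
  if (any(g < 0 | g > 1)) stop("all g values must lie in [0, 1]", call. = FALSE)
  structure(list(alpha_t = alpha_t, gamma_b = gamma_b, s = s, g = g),
            class = "efl_params")
}

#' @export
print.efl_params <- function(x, ...) {
  cat(sprintf("<efl_params> alpha_t = %g, gamma_b = %g, s = %g, %d categories\n",
              x$alpha_t, x$gamma_b, x$s, length(x$g)))
  invisible(x)
}

CONF_CLAMP <- 1e-12

#' Multiclass cross-entropy loss
#'
#' `-sum_i p_i * log(q_i)` for a true distribution `p` (one-hot or simplex)
#' and predicted distribution `q`; predictions are clamped at 1e-12 before
#' the log.
#'
#' @param p True distribution over C classes (nonnegative, sums to 1).
#' @param q Predicted distribution, same length.
#' @return A nonnegative scalar.
#' @examples
#' cross_entropy(c(1, 0, 0, 0), rep(0.25, 4))  # log(4)
#' @export
cross_entropy <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q))
  if (length(p) != length(q))
    stop("p and q must have equal length", call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a probability distribution", call. = FALSE)
  if (any(q < 0))
    stop("q must be nonnegative", call. = FALSE)
  -sum(p * log(pmax(q, CONF_CLAMP)))
}

#' Per-category focusing factor
#'
#' The focusing factor of category `j` decomposes into the basic part and a
#' variable part driven by the category's imbalance:
#' `gamma_j = gamma_b + s * (1 - g_j)`. Balanced categories (`g_j = 1`)
#' keep the basic factor; maximally imbalanced ones (`g_j = 0`) get
#' `gamma_b + s`.
#'
#' @param j Category name present in `params$g`.
#' @param params An [efl_params()].
#' @return A scalar >= `gamma_b`.
#' @export
focusing_factor <- function(j, params) {
  stopifnot(inherits(params, "efl_params"))
  if (!j %in% names(params$g))
    stop("unknown category: ", j, call. = FALSE)
  params$gamma_b + params$s * (1 - params$g[[j]])
}

#' Equalized focal loss
#'
#' Focal loss for long-tailed multiclass problems. Each category `j` with
#' confidence `p_t` contributes
#' `alpha_t * w_j * (1 - p_t)^gamma_j * (-log p_t)`, where
#' `gamma_j = gamma_b + s (1 - g_j)` is the category's focusing factor and
#' `w_j = gamma_j / gamma_b` the weighting factor that raises the loss
#' contribution of rare categories while leaving balanced ones near 1.
#' With every `g_j = 1` the loss reduces to the plain focal form with unit
#' weight.
#'
#' @param p_t Named numeric vector of confidence scores in `(0, 1]`, one per
#'   category; names must be present in `params$g`.
#' @param params An [efl_params()].
#' @return A nonnegative scalar.
#' @examples
#' pars <- efl_params(gamma_b = 2, s = 4, g = c(a = 1))
#' equalized_focal_loss(c(a = 0.5), pars)
#' @export
equalized_focal_loss <- function(p_t, params) {
  stopifnot(inherits(params, "efl_params"), is.numeric(p_t))
  if (is.null(names(p_t)) || !all(names(p_t) %in% names(params$g)))
    stop("p_t must be named with categories present in params$g",
         call. = FALSE)
  if (any(p_t <= 0 | p_t > 1))
    stop("all confidences must lie in (0, 1]", call. = FALSE)
  gam <- params$gamma_b + params$s * (1 - params$g[names(p_t)])
  w <- gam / params$gamma_b
  sum(params$alpha_t * w * (1 - p_t)^gam * (-log(pmax(p_t, CONF_CLAMP))))
}

#' Weighted multitask pretraining loss
#'
#' The pretraining objective combines a categorical cross-entropy term with
#' an equalized focal term; the combination weights are exposed (unit
#' defaults).
#'
#' @param ce Cross-entropy loss value.
#' @param efl Equalized focal loss value.
#' @param w_ce,w_efl Nonnegative combination weights, default 1.
#' @return `w_ce * ce + w_efl * efl`.
#' @export
multitask_loss <- function(ce, efl, w_ce = 1, w_efl = 1) {
  stopifnot(is.numeric(ce), is.numeric(efl), w_ce >= 0, w_efl >= 0)
  w_ce * ce + w_efl * efl
}
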