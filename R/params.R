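#' Error-model parameters for ancestry correction
#'
#' Bundles the three parameters of the ancestry error and transition model:
#' the allelic inference error rate `epsilon`, the admixed-population ancestry
#' proportion `lamb` (the genome-wide expected fraction of population-A
#' ancestry, e.g. the mean African proportion in African-Americans), and
#' `tau`, the number of generations since admixture, which scales the rate of
#' ancestry switches along the genetic map.
#'
#' @param epsilon Allelic error rate in `[0, 0.5)`. May be `NA` to request
#'   estimation from the data (see [correct_all()]).
#' @param lamb Ancestry proportion of population A, in `(0, 1)`. Default 0.8.
#' @param tau Generations since admixture, positive. Default 8, a standard
#'   value for African-American populations.
#' @return An object of class `error_model_params`.
#' @examples
#' error_model_params(0.01)
#' @export
error_model_params <- function(epsilon, lamb = 0.8, tau = 8) {
  stopifnot(length(epsilon) == 1, length(lamb) == 1, length(tau) == 1)
  if (!is.na(epsilon) && (epsilon < 0 || epsilon >= 0.5)) {
    stop("`epsilon` must lie in [0, 0.5)", call. = FALSE)
  }
  if (lamb <= 0 || lamb >= 1) stop("`lamb` must lie in (0, 1)", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  structure(
    list(epsilon = as.numeric(epsilon), lamb = as.numeric(lamb),
         tau = as.numeric(tau)),
    class = "error_model_params"
  )
}

#' @export
print.error_model_params <- function(x, ...) {
  cat("<error_model_params> epsilon =", x$epsilon,
      " lambda =", x$lamb, " tau =", x$tau, "\n")
  invisible(x)
}
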