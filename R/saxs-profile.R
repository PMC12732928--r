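#' Construct a 1-D scattering profile
#'
#' A `saxs_profile` is a tibble with columns `q` (momentum transfer,
#' 1/Angstrom, strictly increasing and positive), `I` (intensity, arbitrary
#' units) and `sigma` (per-point uncertainty, same units as `I`). When no
#' uncertainties are supplied, the conventional 2% of |I| is filled in;
#' negative intensities (possible after background subtraction) are accepted
#' only when explicit uncertainties are given.
#'
#' @param q strictly increasing positive numeric vector (1/Angstrom).
#' @param I intensities.
#' @param sigma optional per-point uncertainties (> 0).
#' @return a `saxs_profile` tibble.
#' @examples
#' p <- saxs_profile(seq(0.01, 0.3, 0.01), guinier_intensity(seq(0.01, 0.3, 0.01), 60))
#' @export
saxs_profile <- function(q, I, sigma = NULL) {
  if (length(q) != length(I)) abort("`q` and `I` must have equal length.")
  if (any(!is.finite(q)) || any(q <= 0)) abort("`q` must be finite and > 0.")
  if (any(diff(q) <= 0)) abort("`q` must be strictly increasing.")
  if (any(!is.finite(I))) abort("`I` must be finite.")
  if (is.null(sigma)) {
    if (any(I < 0)) {
      abort("negative intensities require explicit `sigma` (background-subtracted data).")
    }
    sigma <- 0.02 * abs(I)
  } else {
    if (length(sigma) != length(q)) abort("`sigma` must match `q` in length.")
    if (any(!is.finite(sigma)) || any(sigma < 0)) abort("`sigma` must be finite and >= 0.")
  }
  out <- tibble(q = as.numeric(q), I = as.numeric(I), sigma = as.numeric(sigma))
  class(out) <- c("saxs_profile", class(out))
  out
}

# fitting weights: 1/sigma^2 with an all-zero sigma column (noise-free
# simulation) falling back to the conventional 2% relative errors
profile_weights <- function(profile) {
  s <- profile$sigma
  if (all(s == 0)) s <- pmax(0.02 * abs(profile$I), 1e-12 * max(abs(profile$I)))
  s[s == 0] <- min(s[s > 0])
  1 / s^2
}

profile_sigma <- function(profile) {
  s <- profile$sigma
  if (all(s == 0)) s <- pmax(0.02 * abs(profile$I), 1e-12 * max(abs(profile$I)))
  s[s == 0] <- min(s[s > 0])
  s
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("<saxs_profile> %d points, q = [%g, %g] 1/Angstrom\n",
              nrow(x), min(x$q), max(x$q)))
  NextMethod()
}
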