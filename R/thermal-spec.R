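#' Thermal response function specifications
#'
#' A `thermal_spec` bundles a functional-form identifier with a named
#' parameter vector (and optional standard errors), and is the unit of
#' exchange between the fitting, simulation and mapping layers. The forms
#' are the temperature responses used in process-based phenology models of
#' tephritid fruit flies:
#'
#' * `briere1` -- development rate \eqn{r(T) = a T (T - T_{min}) \sqrt{T_{max} - T}};
#' * `linear_rate` -- linear development rate \eqn{r(T) = a + b T} (for the
#'   lower-threshold regression);
#' * `mortality_expquad` -- immature stage mortality
#'   \eqn{M(T) = \exp(b_1 + b_2 T + b_3 T^2)}, clipped to \[0, 1\];
#' * `senescence_exponential` -- adult senescence rate
#'   \eqn{s(T) = b_1 e^{b_2 T}} (expected longevity \eqn{1/s(T)});
#' * `senescence_stinner` -- double-logistic senescence
#'   \eqn{s(T) = C_1/(1+e^{k_1+k_2 T}) + C_2/(1+e^{k_1+k_2 (T_0-T)})};
#' * `fecundity_exppoly` -- lifetime eggs per female
#'   \eqn{f(T) = \exp(b_1 + b_2 T + b_3 T^2)};
#' * `fecundity_gaussian` -- lifetime eggs per female
#'   \eqn{f(T) = y_0 + a \exp(-\frac{1}{2}((T - x_0)/b)^2)}, floored at 0;
#' * `ovip_cubic_exponential`, `ovip_logistic`, `ovip_gamma` -- cumulative
#'   oviposition fraction against normalized female age;
#' * `devtime_logit` -- development-time distribution
#'   \eqn{F(x) = 1/(1 + e^{-(a_i + b \ln x)})} with per-temperature
#'   intercepts `a1..ak` and a common slope `b`;
#' * `lifetable_quadratic` -- quadratic trend \eqn{a + bT + cT^2} of a
#'   life-table parameter against temperature.
#'
#' @param form one of the form identifiers above.
#' @param params named numeric vector of parameters. Required names by form:
#'   `briere1`: a, Tmin, Tmax; `linear_rate`: a, b; `mortality_expquad` and
#'   `fecundity_exppoly`: b1, b2, b3; `senescence_exponential`: b1, b2;
#'   `senescence_stinner`: C1, C2, k1, k2, T0; `fecundity_gaussian`: y0, a,
#'   b, x0; `ovip_cubic_exponential`: a, b, c; `ovip_logistic` and
#'   `ovip_gamma`: a, b; `devtime_logit`: a1..ak plus b; quadratic: a, b, c.
#' @param param_se optional numeric vector of standard errors, same length
#'   and order as `params`.
#' @param scale for `mortality_expquad` only: `"proportion"` (default; the
#'   exponential is read directly as a mortality fraction) or `"percent"`
#'   (the exponential is read as a percentage and divided by 100).
#' @return an object of class `thermal_spec`.
#' @export
thermal_spec <- function(form, params, param_se = NULL, scale = NULL) {
  forms <- names(.spec_arity)
  form <- match.arg(form, forms)
  params <- unlist(params)
  if (!is.numeric(params) || anyNA(params) || any(!is.finite(params)))
    stop("`params` must be a finite numeric vector")
  required <- .spec_arity[[form]]
  if (form == "devtime_logit") {
    if (length(params) < 2L || !("b" %in% names(params)))
      stop("devtime_logit needs at least one intercept plus a slope named 'b'")
    if (params[["b"]] <= 0)
      stop("devtime_logit slope b must be positive")
  } else {
    if (is.null(names(params)) && length(params) == length(required))
      names(params) <- required
    if (!setequal(names(params), required))
      stop(sprintf("form '%s' needs parameters: %s", form,
                   paste(required, collapse = ", ")))
    params <- params[required]
  }
  if (!is.null(param_se)) {
    param_se <- unlist(param_se)
    if (length(param_se) != length(params))
      stop("`param_se` must match `params` in length")
    if (is.null(names(param_se))) names(param_se) <- names(params)
  }
  if (form == "briere1" && params[["Tmin"]] >= params[["Tmax"]])
    stop("briere1 requires Tmin < Tmax")
  if (form == "senescence_exponential" && params[["b1"]] <= 0)
    stop("senescence_exponential requires b1 > 0 (positive rate)")
  if (form == "ovip_gamma" && (params[["a"]] <= 0 || params[["b"]] <= 0))
    stop("ovip_gamma requires shape a > 0 and rate b > 0")
  if (!is.null(scale)) {
    if (form != "mortality_expquad")
      stop("`scale` applies only to mortality_expquad")
    scale <- match.arg(scale, c("proportion", "percent"))
  }
  structure(list(form = form, params = params, param_se = param_se,
                 scale = scale),
            class = "thermal_spec")
}

.spec_arity <- list(
  briere1               = c("a", "Tmin", "Tmax"),
  linear_rate           = c("a", "b"),
  mortality_expquad     = c("b1", "b2", "b3"),
  senescence_exponential = c("b1", "b2"),
  senescence_stinner    = c("C1", "C2", "k1", "k2", "T0"),
  fecundity_exppoly     = c("b1", "b2", "b3"),
  fecundity_gaussian    = c("y0", "a", "b", "x0"),
  ovip_cubic_exponential = c("a", "b", "c"),
  ovip_logistic         = c("a", "b"),
  ovip_gamma            = c("a", "b"),
  devtime_logit         = NULL,
  lifetable_quadratic   = c("a", "b", "c")
)

#' @export
print.thermal_spec <- function(x, ...) {
  cat("<thermal_spec>", x$form, "\n")
  print(x$params)
  if (!is.null(x$param_se)) {
    cat("SE:\n")
    print(x$param_se)
  }
  if (!is.null(x$scale)) cat("scale:", x$scale, "\n")
  invisible(x)
}

#' Serialize thermal specs and phenology models to and from lists
#'
#' Flat key-value representation suitable for JSON/YAML round-tripping:
#' the form identifier plus named parameters (and standard errors when
#' present).
#'
#' @param spec a `thermal_spec`.
#' @return `spec_to_list()`: a plain list; `spec_from_list()`: a
#'   `thermal_spec`.
#' @export
spec_to_list <- function(spec) {
  stopifnot(inherits(spec, "thermal_spec"))
  out <- list(form = spec$form, params = as.list(spec$params))
  if (!is.null(spec$param_se)) out$param_se <- as.list(spec$param_se)
  if (!is.null(spec$scale)) out$scale <- spec$scale
  out
}

#' @rdname spec_to_list
#' @param x a list as produced by `spec_to_list()`.
#' @export
spec_from_list <- function(x) {
  thermal_spec(x$form, unlist(x$params),
               param_se = if (!is.null(x$param_se)) unlist(x$param_se),
               scale = x$scale)
}

.check_temperature <- function(T) {
  if (!is.numeric(T) || anyNA(T) || any(!is.finite(T)))
    stop("temperature must be finite numeric")
  T
}

.expect_form <- function(spec, forms) {
  if (!inherits(spec, "thermal_spec"))
    stop("expected a thermal_spec object")
  if (!spec$form %in% forms)
    stop(sprintf("expected a spec of form %s, got '%s'",
                 paste(forms, collapse = "/"), spec$form))
  spec
}
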