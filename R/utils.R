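# Internal helpers.

#' @importFrom stats lm coef approx rnorm setNames var deviance
#' @importFrom utils head str capture.output packageVersion
#' @importFrom methods new is validObject setGeneric setMethod setClass
#'   setValidity show
#' @importFrom signal sgolayfilt
#' @importFrom minpack.lm nls.lm nls.lm.control
#' @importFrom jsonlite write_json fromJSON
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# R^2 of a fitted lm
.rsq <- function(fit) summary(fit)$r.squared

# Simple OLS on (x, y); returns intercept, slope, r.squared.
.ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::var(y) > 0) suppressWarnings(.rsq(fit)) else 1
  list(intercept = unname(co[1L]), slope = unname(co[2L]), r.squared = r2)
}

.PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn")
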